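#' Scenario matrix for the structure x photosynthesis decomposition
#'
#' The seven simulation scenarios combining the three-dimensional canopy
#' structure and the leaf photosynthetic capacity of the hybrid JNK728 and
#' its parents J2416 (male) and JMC01 (female): the three pure cultivars,
#' A1/A2 (parental structure with hybrid photosynthesis) and B1/B2 (hybrid
#' structure with parental photosynthesis).
#'
#' @return data.frame: `scenario`, `structure_source`,
#'   `photosynthesis_source`.
#' @export
scenario_table <- function() {
  data.frame(
    scenario = c("JNK728", "J2416", "JMC01", "A1", "A2", "B1", "B2"),
    structure_source = c("JNK728", "J2416", "JMC01", "J2416", "JMC01",
                         "JNK728", "JNK728"),
    photosynthesis_source = c("JNK728", "J2416", "JMC01", "JNK728",
                              "JNK728", "J2416", "JMC01"),
    stringsAsFactors = FALSE)
}

#' Run one structure x photosynthesis scenario
#'
#' Builds the canopy from the structure source's phytomer table, assigns
#' the photosynthesis source's layer parameter sets (the structure plant's
#' ear rank anchors the layer mapping, so mismatched phytomer counts are
#' joined layer-relative), runs the radiation and integration chain over
#' the weather window and returns yield and RUE.
#'
#' @param structure_source,photosynthesis_source cultivar names.
#' @param structures named list of `plant_spec` (canopy structure assets).
#' @param photo_params named list (by cultivar) of named lists (`upper`,
#'   `ear`, `lower`) of [light_response_params()].
#' @param weather hourly weather table covering the simulation window.
#' @param scenario label for the result row.
#' @param scene_args list of extra arguments to [assemble_canopy()]
#'   (grid size, tessellation, seed, ...).
#' @param window expected day count (default 60; pass `NA` to accept any).
#' @param latitude,sky,Cr,method forwarded to [simulate_season()].
#' @return one-row data.frame: scenario, structure_source,
#'   photosynthesis_source, yield_Mg_ha, RUE_g_MJ, ADM_g_m2, AIPAR_MJ_m2.
#' @export
run_scenario <- function(structure_source, photosynthesis_source,
                         structures, photo_params, weather,
                         scenario = NULL, scene_args = list(),
                         window = 60L, latitude = 39.93,
                         sky = sky_model(), Cr = 0.41, method = "grid") {
  if (is.null(structures[[structure_source]]))
    stop("missing structure asset for ", structure_source)
  if (is.null(photo_params[[photosynthesis_source]]))
    stop("missing photosynthesis asset for ", photosynthesis_source)
  scene <- do.call(assemble_canopy,
                   c(list(plants = structures[[structure_source]]),
                     scene_args))
  sim <- simulate_season(scene, photo_params[[photosynthesis_source]],
                         weather, latitude = latitude, sky = sky,
                         Cr = Cr, method = method)
  finish_scenario(sim, scenario %||% paste0(structure_source, "/",
                                            photosynthesis_source),
                  structure_source, photosynthesis_source, window)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

finish_scenario <- function(sim, scenario, structure_source,
                            photosynthesis_source, window) {
  acc <- accumulate_and_rue(sim$series,
                            window = if (is.na(window)) 0L else window,
                            allow_any_window = is.na(window))
  data.frame(scenario = scenario, structure_source = structure_source,
             photosynthesis_source = photosynthesis_source,
             yield_Mg_ha = acc$yield_Mg_ha, RUE_g_MJ = acc$RUE_g_MJ,
             ADM_g_m2 = acc$ADM_g_m2, AIPAR_MJ_m2 = acc$AIPAR_MJ_m2,
             stringsAsFactors = FALSE)
}

#' Run the full seven-scenario matrix
#'
#' Radiation interception depends only on canopy structure, so the
#' radiation chain is run once per distinct structure source and reused
#' across the scenarios that share it; only the (cheap) photosynthesis
#' integration differs between scenarios. This also guarantees the two
#' structural identities exactly: a pure-cultivar scenario and the
#' corresponding self-swap use identical interception records, and
#' swapping only photosynthesis leaves AIPAR unchanged.
#'
#' @inheritParams run_scenario
#' @param scenarios scenario table (default [scenario_table()]).
#' @return data.frame with one row per scenario.
#' @export
run_all_scenarios <- function(structures, photo_params, weather,
                              scenarios = scenario_table(),
                              scene_args = list(), window = 60L,
                              latitude = 39.93, sky = sky_model(),
                              Cr = 0.41, method = "grid") {
  recs_by_structure <- list()
  out <- vector("list", nrow(scenarios))
  for (k in seq_len(nrow(scenarios))) {
    st <- scenarios$structure_source[k]
    ph <- scenarios$photosynthesis_source[k]
    if (is.null(recs_by_structure[[st]])) {
      if (is.null(structures[[st]]))
        stop("missing structure asset for ", st)
      scene <- do.call(assemble_canopy,
                       c(list(plants = structures[[st]]), scene_args))
      fid <- focal_facets(scene)
      dfac <- diffuse_factor(scene, sky, fid, method = method)
      doys <- sort(unique(weather$doy))
      recs <- lapply(doys, function(d)
        interception_day(scene, d, weather, latitude = latitude,
                         sky = sky, dfac = dfac, method = method))
      recs_by_structure[[st]] <- list(scene = scene, recs = recs,
                                      doys = doys)
    }
    if (is.null(photo_params[[ph]]))
      stop("missing photosynthesis asset for ", ph)
    env <- recs_by_structure[[st]]
    days <- lapply(seq_along(env$doys), function(i) {
      ch <- daily_chain(env$recs[[i]], photo_params[[ph]],
                        env$scene$ear_rank, M = env$scene$M,
                        PD = env$scene$PD, Cr = Cr)
      data.frame(doy = env$doys[i], A_canDAY_mol_m2 = ch$A_canDAY_mol_m2,
                 DM_g_m2 = ch$DM_g_m2, IPAR_MJ_m2 = ch$IPAR_MJ_m2)
    })
    sim <- list(series = do.call(rbind, days))
    out[[k]] <- finish_scenario(sim, scenarios$scenario[k], st, ph, window)
  }
  do.call(rbind, out)
}

#' Structure and photosynthesis contributions to heterosis
#'
#' Given the seven scenario values of one metric (yield in Mg ha-1 or RUE
#' in g MJ-1), computes the relative contribution of canopy structure and
#' of leaf photosynthetic capacity to the hybrid-parent difference:
#' \deqn{C_{c,J2416} = (Y_{JNK728} - Y_{A1}) / (Y_{JNK728} - Y_{J2416}) \times 100}
#' \deqn{C_{p,J2416} = (Y_{JNK728} - Y_{B1}) / (Y_{JNK728} - Y_{J2416}) \times 100}
#' and the analogous pair against JMC01 using A2 and B2. The two
#' contributions are not forced to sum to 100; the residual
#' `100 - C_c - C_p` is reported as an interaction term (an extension
#' beyond the standard decomposition).
#'
#' @param values named numeric with elements JNK728, J2416, JMC01, A1, A2,
#'   B1, B2 (a scenario data.frame from [run_all_scenarios()] also works
#'   via `metric`).
#' @param metric when `values` is a scenario data.frame, the column to
#'   decompose (`"yield_Mg_ha"` or `"RUE_g_MJ"`).
#' @return data.frame: `parent`, `C_structure`, `C_photosynthesis`,
#'   `interaction` (percent; `NA` with a warning when the hybrid-parent
#'   gap is zero).
#' @examples
#' y <- c(JNK728 = 9.96, J2416 = 7.37, JMC01 = 7.83, A1 = 8.15,
#'        A2 = 9.07, B1 = 9.03, B2 = 8.38)
#' contributions(y)
#' @export
contributions <- function(values, metric = "yield_Mg_ha") {
  if (is.data.frame(values)) {
    v <- values[[metric]]
    names(v) <- values$scenario
    values <- v
  }
  need <- c("JNK728", "J2416", "JMC01", "A1", "A2", "B1", "B2")
  if (!all(need %in% names(values)))
    stop("values must name all 7 scenarios: ",
         paste(setdiff(need, names(values)), collapse = ", "))
  v <- values[need]
  one <- function(parent, a, b) {
    gap <- v[["JNK728"]] - v[[parent]]
    if (abs(gap) < 1e-12) {
      warning("zero hybrid-parent gap for ", parent,
              ": contributions undefined")
      return(data.frame(parent = parent, C_structure = NA_real_,
                        C_photosynthesis = NA_real_,
                        interaction = NA_real_))
    }
    cc <- (v[["JNK728"]] - v[[a]]) / gap * 100
    cp <- (v[["JNK728"]] - v[[b]]) / gap * 100
    data.frame(parent = parent, C_structure = cc, C_photosynthesis = cp,
               interaction = 100 - cc - cp)
  }
  rbind(one("J2416", "A1", "B1"), one("JMC01", "A2", "B2"))
}

#' Published 2021 scenario values for the worked-example decomposition
#'
#' The simulated post-silking yield (Mg ha-1) and RUE (g MJ-1) of the
#' seven scenarios as printed for the 2021 season of the field study the
#' package emulates. These serve as the worked-example inputs for
#' [contributions()] and [heterosis_ratios()]; they are study outputs
#' reproduced here as reference data, not values this package simulates.
#'
#' @return list with named numeric vectors `yield_Mg_ha` and `RUE_g_MJ`
#'   (elements JNK728, J2416, JMC01, A1, A2, B1, B2).
#' @export
published_scenario_values <- function() {
  list(
    yield_Mg_ha = c(JNK728 = 9.96, J2416 = 7.37, JMC01 = 7.83, A1 = 8.15,
                    A2 = 9.07, B1 = 9.03, B2 = 8.38),
    RUE_g_MJ = c(JNK728 = 4.07, J2416 = 3.60, JMC01 = 3.49, A1 = 3.97,
                 A2 = 4.04, B1 = 3.66, B2 = 3.40))
}

#' Relative hybrid advantage over each parent
#'
#' `100 * (hybrid / parent - 1)` for a metric's pure-cultivar values.
#'
#' @param values named numeric including JNK728, J2416, JMC01.
#' @return named numeric: percent increase vs J2416 and vs JMC01.
#' @export
heterosis_ratios <- function(values) {
  c(vs_J2416 = 100 * (values[["JNK728"]] / values[["J2416"]] - 1),
    vs_JMC01 = 100 * (values[["JNK728"]] / values[["JMC01"]] - 1))
}
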