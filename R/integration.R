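#' PPFD incident on a leaf from its hourly interception record
#'
#' `PPFD = IPP / 3600 / (LA * 1e-4)`: intercepted photons per hour spread
#' back over the leaf area and the hour.
#'
#' @param IPP intercepted photons, umol leaf-1 h-1 (vectorized).
#' @param LA_cm2 leaf area, cm^2.
#' @return PPFD, umol m-2 s-1.
#' @export
ppfd_per_leaf <- function(IPP, LA_cm2) {
  bad <- LA_cm2 <= 0 & IPP > 0
  if (any(bad)) stop("LA = 0 with IPP > 0 for ", sum(bad), " record(s)")
  out <- ifelse(LA_cm2 > 0, IPP / 3600 / (LA_cm2 * 1e-4), 0)
  out
}

#' Canopy layer of a phytomer rank relative to the ear
#'
#' The middle layer is the ear leaf plus the first leaf above and below;
#' upper and lower are the ranks above and below it. Layer labels join the
#' measured light-response sets (`upper`/`ear`/`lower`) to ranks.
#'
#' @param rank integer rank(s).
#' @param ear_rank ear-bearing rank.
#' @return character vector: `"upper"`, `"ear"` or `"lower"`.
#' @export
layer_of_rank <- function(rank, ear_rank) {
  ifelse(rank > ear_rank + 1, "upper",
         ifelse(rank < ear_rank - 1, "lower", "ear"))
}

get_layer_params <- function(params_by_layer, layer) {
  p <- params_by_layer[[layer]]
  if (is.null(p)) stop("layer parameters missing for layer '", layer, "'")
  p
}

#' Instantaneous canopy photosynthesis rate from one hour's records
#'
#' Evaluates the Ye model per leaf at its record PPFD using the parameters
#' of the leaf's canopy layer, and integrates over the focal plants:
#' `A_can = sum_j sum_i A_ji * LA_ji / (M / PD)` with leaf areas in m^2 and
#' the focal ground area `M / PD` in m^2.
#'
#' @param records_t one hour of records (one row per focal plant x rank).
#' @param params_by_layer named list of [light_response_params()] with
#'   elements `upper`, `ear`, `lower`.
#' @param ear_rank ear rank anchoring the layer mapping.
#' @param M,PD focal plant count and plant density (defaults 9 and 6).
#' @return `A_can_t`, umol m-2 ground s-1.
#' @export
canopy_assim_instant <- function(records_t, params_by_layer, ear_rank,
                                 M = 9, PD = 6) {
  stopifnot(M > 0, PD > 0)
  ppfd <- ppfd_per_leaf(records_t$IPP_umol_leaf_h, records_t$LA_cm2)
  layer <- layer_of_rank(records_t$rank, ear_rank)
  A <- numeric(nrow(records_t))
  for (ly in unique(layer)) {
    p <- get_layer_params(params_by_layer, ly)
    A[layer == ly] <- net_photosynthesis(p, ppfd[layer == ly])
  }
  sum(A * records_t$LA_cm2 * 1e-4) / (M / PD)
}

#' Daily chain: canopy assimilation, biomass and intercepted PAR
#'
#' From a full day of hourly records: integrates the instantaneous canopy
#' photosynthesis over daylight (`A_canDAY = sum_t 3600 * A_can_t`,
#' umol m-2 d-1), converts to dry mass
#' `DM = 44 * (A_canDAY * 1e-6) * Cr` (g m-2 d-1; 44 g mol-1 CO2, the
#' 1e-6 factor converting umol to mol, and `Cr` the CO2-to-dry-mass
#' conversion efficiency, 0.41 for maize), and converts intercepted
#' photons to energy (`IPAR_leaf = sum_t IPP / 4.55 * 1e-6` MJ leaf-1 d-1
#' with 4.55 umol J-1), aggregated to the canopy per unit ground area.
#'
#' @param records_day records for all daylight hours of one day.
#' @inheritParams canopy_assim_instant
#' @param Cr CO2-to-dry-mass conversion efficiency (default 0.41).
#' @return list: `A_canDAY_umol_m2` (and `A_canDAY_mol_m2`), `DM_g_m2`,
#'   `IPAR_MJ_m2`, `A_can_t` (per hour), `ipar_leaf` (per plant x rank,
#'   MJ leaf-1 d-1).
#' @export
daily_chain <- function(records_day, params_by_layer, ear_rank,
                        M = 9, PD = 6, Cr = 0.41) {
  if (any(!is.finite(records_day$IPP_umol_leaf_h)))
    stop("NaN/Inf in IPP records")
  hours <- sort(unique(records_day$hour))
  A_can_t <- vapply(hours, function(h) {
    canopy_assim_instant(records_day[records_day$hour == h, ],
                         params_by_layer, ear_rank, M = M, PD = PD)
  }, numeric(1))
  A_canDAY <- sum(3600 * A_can_t)
  DM <- 44 * (A_canDAY * 1e-6) * Cr
  ipar_leaf <- stats::aggregate(
    records_day$IPP_umol_leaf_h / 4.55 * 1e-6,
    list(plant = records_day$plant, rank = records_day$rank), sum)
  names(ipar_leaf)[3] <- "IPAR_MJ_leaf"
  IPAR_d <- sum(ipar_leaf$IPAR_MJ_leaf) / (M / PD)
  list(A_canDAY_umol_m2 = A_canDAY, A_canDAY_mol_m2 = A_canDAY * 1e-6,
       DM_g_m2 = DM, IPAR_MJ_m2 = IPAR_d,
       A_can_t = data.frame(hour = hours, A_can_t = A_can_t),
       ipar_leaf = ipar_leaf)
}

#' Accumulate a daily series and compute yield and RUE
#'
#' Over the fixed 60-day post-silking window: accumulated biomass `ADM`
#' and intercepted PAR `AIPAR` are running sums of the daily values; the
#' radiation use efficiency is their final quotient `RUE = ADM / AIPAR`
#' (g MJ-1) and the yield is the accumulated above-ground biomass
#' expressed as `ADM * 1e-2` Mg ha-1.
#'
#' @param series data.frame with columns `DM_g_m2` and `IPAR_MJ_m2`, one
#'   row per day.
#' @param window required number of days (default 60); set
#'   `allow_any_window = TRUE` to override.
#' @param allow_any_window bypass the fixed-window check.
#' @return list: `series` (with `ADM_g_m2`, `AIPAR_MJ_m2` columns added),
#'   `ADM_g_m2`, `AIPAR_MJ_m2`, `RUE_g_MJ`, `yield_Mg_ha`.
#' @export
accumulate_and_rue <- function(series, window = 60L,
                               allow_any_window = FALSE) {
  if (!allow_any_window && nrow(series) != window)
    stop("post-silking window must be ", window, " days (got ",
         nrow(series), "); set allow_any_window = TRUE to override")
  series$ADM_g_m2 <- cumsum(series$DM_g_m2)
  series$AIPAR_MJ_m2 <- cumsum(series$IPAR_MJ_m2)
  n <- nrow(series)
  AIPAR <- series$AIPAR_MJ_m2[n]
  if (AIPAR <= 0) stop("AIPAR = 0: RUE undefined for a zero-light season")
  ADM <- series$ADM_g_m2[n]
  list(series = series, ADM_g_m2 = ADM, AIPAR_MJ_m2 = AIPAR,
       RUE_g_MJ = ADM / AIPAR, yield_Mg_ha = ADM * 1e-2)
}

#' Seasonal intercepted PAR partitioned into canopy layers
#'
#' Sums each leaf's seasonal intercepted PAR and upscales to MJ m-2 of
#' ground by dividing by the focal ground area `M / PD`. The middle layer
#' is the ear leaf and the first leaf above and below; upper and lower are
#' the remaining ranks above and below.
#'
#' @param records season-worth of interception records.
#' @param ear_rank ear rank.
#' @param M,PD focal plant count and density.
#' @return list: `IPAR_upp`, `IPAR_mid`, `IPAR_low`, `IPAR_can` (MJ m-2)
#'   and `per_leaf` (seasonal MJ leaf-1 by plant x rank).
#' @export
layer_partition <- function(records, ear_rank, M = 9, PD = 6) {
  per_leaf <- stats::aggregate(
    records$IPP_umol_leaf_h / 4.55 * 1e-6,
    list(plant = records$plant, rank = records$rank), sum)
  names(per_leaf)[3] <- "IPAR_MJ_leaf"
  ground <- M / PD
  mid <- abs(per_leaf$rank - ear_rank) <= 1
  upp <- per_leaf$rank > ear_rank + 1
  low <- per_leaf$rank < ear_rank - 1
  out <- list(IPAR_upp = sum(per_leaf$IPAR_MJ_leaf[upp]) / ground,
              IPAR_mid = sum(per_leaf$IPAR_MJ_leaf[mid]) / ground,
              IPAR_low = sum(per_leaf$IPAR_MJ_leaf[low]) / ground,
              per_leaf = per_leaf)
  out$IPAR_can <- out$IPAR_upp + out$IPAR_mid + out$IPAR_low
  out
}

#' Simulate a multi-day season over a static canopy snapshot
#'
#' Holds the canopy static (the silking-stage snapshot) and chains
#' radiation interception and the daily photosynthesis/biomass chain over
#' the supplied weather series. The diffuse-sky visibility pass is
#' computed once and reused across all days and hours.
#'
#' @param scene a `canopy_scene`.
#' @param params_by_layer named list (`upper`, `ear`, `lower`) of
#'   [light_response_params()].
#' @param weather hourly weather data.frame (`doy`, `hour`, `I_dir`,
#'   `I_diff`).
#' @param latitude degrees north.
#' @param sky a [sky_model()].
#' @param ear_rank ear rank (default: the scene's).
#' @param Cr CO2-to-dry-mass conversion efficiency.
#' @param method occlusion method.
#' @return list: `series` (per-day data.frame: doy, A_canDAY_mol_m2,
#'   DM_g_m2, IPAR_MJ_m2), `records` (all hourly records).
#' @export
simulate_season <- function(scene, params_by_layer, weather,
                            latitude = 39.93, sky = sky_model(),
                            ear_rank = NULL, Cr = 0.41, method = "grid") {
  if (is.null(ear_rank)) ear_rank <- scene$ear_rank
  doys <- sort(unique(weather$doy))
  fid <- focal_facets(scene)
  dfac <- diffuse_factor(scene, sky, fid, method = method)
  days <- vector("list", length(doys))
  recs <- vector("list", length(doys))
  for (k in seq_along(doys)) {
    rec <- interception_day(scene, doys[k], weather, latitude = latitude,
                            sky = sky, dfac = dfac, method = method)
    ch <- daily_chain(rec, params_by_layer, ear_rank,
                      M = scene$M, PD = scene$PD, Cr = Cr)
    days[[k]] <- data.frame(doy = doys[k],
                            A_canDAY_mol_m2 = ch$A_canDAY_mol_m2,
                            DM_g_m2 = ch$DM_g_m2,
                            IPAR_MJ_m2 = ch$IPAR_MJ_m2)
    recs[[k]] <- rec
  }
  list(series = do.call(rbind, days), records = do.call(rbind, recs))
}
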