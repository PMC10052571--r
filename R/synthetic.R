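#' Built-in synthetic cultivar profiles
#'
#' Parameter sets that drive the synthetic phytomer-table generator for
#' the hybrid JNK728 and its parents J2416 and JMC01: plant height, ear
#' rank and height, target one-sided leaf area, leaf inclination, and the
#' peak value/rank pairs of the unimodal rank profiles of leaf length
#' (`LL`), rise to the highest midrib point (`HDBTop`), tip rise
#' (`HDBTip`), and the horizontal projections `Ltop` and `Ltip`. The
#' numbers encode the cultivar contrasts of the 2021 field study the
#' package emulates (heights/areas/ear ranks and the in-text profile
#' peaks); leaf-length peaks and tip rises, which are only reported
#' graphically, are set to values consistent with the stated peaks and
#' the feasibility constraints.
#'
#' @return named list of `cultivar_profile` lists.
#' @export
cultivar_profiles <- function() {
  prof <- list(
    JNK728 = list(
      cultivar = "JNK728", n_phytomers = 19L, ear_rank = 13L,
      plant_height = 266.37, ear_height = 106.85, leaf_area_m2 = 0.72,
      incl_mean = 66.7, incl_sd = 1.9,
      LL_peak = 92, LL_peak_rank = 12,
      HDBTop_peak = 67.68, HDBTop_peak_rank = 14,
      HDBTip_peak = 40.6, HDBTip_peak_rank = 14,
      Ltop_peak = 47.54, Ltop_peak_rank = 13,
      Ltip_peak = 73.74, Ltip_peak_rank = 11),
    J2416 = list(
      cultivar = "J2416", n_phytomers = 19L, ear_rank = 13L,
      plant_height = 187.50, ear_height = 74.29, leaf_area_m2 = 0.46,
      incl_mean = 66.3, incl_sd = 1.6,
      LL_peak = 75, LL_peak_rank = 12,
      HDBTop_peak = 60.43, HDBTop_peak_rank = 14,
      HDBTip_peak = 36.3, HDBTip_peak_rank = 14,
      Ltop_peak = 38.18, Ltop_peak_rank = 13,
      Ltip_peak = 54.25, Ltip_peak_rank = 11),
    JMC01 = list(
      cultivar = "JMC01", n_phytomers = 19L, ear_rank = 12L,
      plant_height = 251.68, ear_height = 67.42, leaf_area_m2 = 0.58,
      incl_mean = 65.3, incl_sd = 4.1,
      LL_peak = 88, LL_peak_rank = 11,
      HDBTop_peak = 74.96, HDBTop_peak_rank = 14,
      HDBTip_peak = 45.0, HDBTip_peak_rank = 14,
      Ltop_peak = 61.67, Ltop_peak_rank = 12,
      Ltip_peak = 74.04, Ltip_peak_rank = 11))
  lapply(prof, function(p) structure(p, class = "cultivar_profile"))
}

#' Measured light-response parameter triples per cultivar and layer
#'
#' The printed (alpha, Amax, Rd) triples of the 2021 A-Q campaign (upper
#' leaf = third leaf above the ear, ear leaf, lower leaf = third below),
#' completed to full Ye-model parameter sets by [solve_beta_gamma()] with
#' the documented fixed photoinhibition coefficient.
#'
#' @param beta fixed photoinhibition coefficient (default 5e-5).
#' @return named list (by cultivar) of named lists (`upper`, `ear`,
#'   `lower`) of [light_response_params()].
#' @export
light_response_library <- function(beta = 5e-5) {
  triples <- list(
    JNK728 = list(upper = c(0.057, 31.48, 2.88),
                  ear   = c(0.064, 30.54, 2.64),
                  lower = c(0.074, 29.48, 2.34)),
    J2416  = list(upper = c(0.049, 28.86, 2.45),
                  ear   = c(0.060, 29.43, 2.17),
                  lower = c(0.068, 26.06, 2.24)),
    JMC01  = list(upper = c(0.042, 28.54, 2.20),
                  ear   = c(0.057, 27.95, 2.24),
                  lower = c(0.063, 25.59, 1.98)))
  lapply(names(triples), function(cv) {
    out <- lapply(names(triples[[cv]]), function(ly) {
      tr <- triples[[cv]][[ly]]
      p <- solve_beta_gamma(tr[1], tr[2], tr[3], beta = beta)
      p$layer <- ly; p$cultivar <- cv
      p
    })
    names(out) <- names(triples[[cv]])
    out
  }) |> stats::setNames(names(triples))
}

# scaled-beta unimodal curve over ranks 1..n peaking at (peak_rank, peak)
unimodal_profile <- function(n, peak, peak_rank, shape = 3) {
  u <- seq_len(n) / (n + 1)
  um <- peak_rank / (n + 1)
  f <- (u / um)^(shape * um) * ((1 - u) / (1 - um))^(shape * (1 - um))
  peak * f
}

#' Generate a per-phytomer descriptor table for a synthetic cultivar
#'
#' Rank profiles of all descriptors follow scaled-beta unimodal curves
#' hitting the profile's stated peaks at the stated ranks; collar heights
#' follow a power curve calibrated so the ear-rank collar sits at the
#' cultivar's ear height; per-rank maximum blade widths are back-solved so
#' the 19-leaf one-sided area hits the cultivar target. A feasibility
#' repair pass enforces every chord-versus-arc constraint (scaling the
#' horizontal projections or capping rises where the raw curves would
#' violate them). Optional seed-controlled noise perturbs lengths and
#' inclination without breaking feasibility.
#'
#' @param profile a `cultivar_profile` from [cultivar_profiles()].
#' @param seed integer seed (controls the noise draws only).
#' @param noise_sd relative standard deviation of multiplicative noise on
#'   lengths (default 0, i.e. the deterministic profile).
#' @return a [plant_spec()].
#' @export
generate_phytomer_table <- function(profile, seed = 1L, noise_sd = 0) {
  stopifnot(inherits(profile, "cultivar_profile"))
  set.seed(seed)
  n <- profile$n_phytomers
  LL <- unimodal_profile(n, profile$LL_peak, profile$LL_peak_rank)
  HDBTop <- unimodal_profile(n, profile$HDBTop_peak,
                             profile$HDBTop_peak_rank)
  HDBTip <- unimodal_profile(n, profile$HDBTip_peak,
                             profile$HDBTip_peak_rank)
  Ltop <- unimodal_profile(n, profile$Ltop_peak, profile$Ltop_peak_rank)
  Ltip <- unimodal_profile(n, profile$Ltip_peak, profile$Ltip_peak_rank)
  if (noise_sd > 0) {
    LL <- LL * exp(stats::rnorm(n, 0, noise_sd))
    scale2 <- exp(stats::rnorm(n, 0, noise_sd))
    HDBTop <- HDBTop * scale2; HDBTip <- HDBTip * scale2
  }
  # collar heights: power curve anchored at the ear height
  top_collar <- 0.78 * profile$plant_height
  q <- log(profile$ear_height / top_collar) /
    log((profile$ear_rank - 1) / (n - 1))
  HLBase <- top_collar * (((seq_len(n) - 1) / (n - 1))^q)
  # feasibility repair: the highest point and tip must be reachable within
  # the midrib length, so raise LL to the collar->top->tip path length with
  # margin (the stated profile peaks stay untouched; widths absorb the area
  # calibration below)
  HDBTip <- pmin(HDBTip, HDBTop)
  Ltop <- pmin(Ltop, Ltip)
  path_len <- sqrt(Ltop^2 + HDBTop^2) +
    sqrt((Ltip - Ltop)^2 + (HDBTop - HDBTip)^2)
  LL <- pmax(LL, path_len / 0.92, 3)
  # widths: proportional to leaf length, scaled to the cultivar area target
  cw <- width_profile_integral()
  k_w <- profile$leaf_area_m2 * 1e4 / (cw * sum(LL^2))
  width <- k_w * LL
  incl <- pmin(85, pmax(20, stats::rnorm(n, profile$incl_mean,
                                         profile$incl_sd)))
  ph <- lapply(seq_len(n), function(i) {
    phytomer_spec(i, LL[i], HLBase[i], HLBase[i] + HDBTop[i],
                  HLBase[i] + HDBTip[i], Ltop[i], Ltip[i],
                  azimuth = if (i %% 2 == 1) 0 else 180,
                  max_width = width[i], inclination = incl[i],
                  has_ear = i == profile$ear_rank)
  })
  plant_spec(profile$cultivar, ph, profile$ear_rank,
             profile$plant_height)
}

#' Generate noisy A-Q observations from known parameters
#'
#' Evaluates the Ye model at the 12 standard chamber PPFD levels and adds
#' Gaussian measurement noise.
#'
#' @param params a [light_response_params()].
#' @param sigma noise standard deviation, umol m-2 s-1 (>= 0).
#' @param n_reps replicate curves.
#' @param seed integer seed.
#' @return data.frame: `ppfd`, `A`, `replicate`.
#' @export
generate_aq_data <- function(params, sigma = 0.5, n_reps = 1L, seed = 1L) {
  stopifnot(sigma >= 0, n_reps >= 1)
  set.seed(seed)
  lv <- aq_ppfd_levels()
  do.call(rbind, lapply(seq_len(n_reps), function(r) {
    data.frame(ppfd = lv,
               A = net_photosynthesis(params, lv) +
                 stats::rnorm(length(lv), 0, sigma),
               replicate = r)
  }))
}

#' Generate an hourly diurnal PAR weather series
#'
#' Sinusoidal diurnal course truncated at sunrise/sunset (from
#' [sun_position()]), with a configurable diffuse split and optional
#' day-to-day lognormal cloudiness. The diffuse split is either a constant
#' fraction or a Spitters-type clearness-index partition against
#' extraterrestrial PAR.
#'
#' @param latitude degrees north.
#' @param doys vector of days of year.
#' @param peak_par clear-day PAR at solar noon, umol m-2 s-1.
#' @param diffuse_fraction constant horizontal diffuse fraction in `[0,1]`,
#'   or `"spitters"` for the clearness-index partition.
#' @param cloud_sd lognormal sd of the day-to-day cloudiness multiplier
#'   (0 = clear every day).
#' @param seed integer seed.
#' @return data.frame: `doy`, `hour`, `PAR_total`, `I_dir`, `I_diff`
#'   (umol m-2 s-1 on the horizontal), for the integer daylight hours.
#' @export
generate_weather <- function(latitude = 39.93, doys = 228:287,
                             peak_par = 2000, diffuse_fraction = 0.2,
                             cloud_sd = 0, seed = 1L) {
  stopifnot(peak_par > 0)
  set.seed(seed)
  cloud <- if (cloud_sd > 0)
    exp(stats::rnorm(length(doys), -cloud_sd^2 / 2, cloud_sd)) else
      rep(1, length(doys))
  cloud <- pmin(cloud, 1)
  out <- vector("list", length(doys))
  for (k in seq_along(doys)) {
    d <- doys[k]
    s0 <- sun_position(latitude, d, 12)
    hours <- seq(ceiling(s0$sunrise), floor(s0$sunset))
    par_t <- peak_par * cloud[k] *
      pmax(0, sin(pi * (hours - s0$sunrise) / (s0$sunset - s0$sunrise)))
    fd <- if (identical(diffuse_fraction, "spitters")) {
      vapply(seq_along(hours), function(i) {
        sp <- sun_position(latitude, d, hours[i])
        spitters_diffuse_fraction(par_t[i], sp$elevation)
      }, numeric(1))
    } else rep(diffuse_fraction, length(hours))
    out[[k]] <- data.frame(doy = d, hour = hours, PAR_total = par_t,
                           I_dir = par_t * (1 - fd), I_diff = par_t * fd)
  }
  do.call(rbind, out)
}

# Spitters-type hourly diffuse fraction from the clearness index of PAR
# against extraterrestrial PAR (solar constant 1367 W m-2, ~50% PAR,
# 4.55 umol J-1).
spitters_diffuse_fraction <- function(par_total, elevation_deg) {
  if (elevation_deg <= 0 || par_total <= 0) return(1)
  sinb <- sin(elevation_deg * pi / 180)
  par_ext <- 1367 * 0.5 * 4.55 * sinb
  kt <- min(par_total / par_ext, 1)
  R <- 0.847 - 1.61 * sinb + 1.04 * sinb^2
  K <- (1.47 - R) / 1.66
  fd <- if (kt < 0.22) 1 else if (kt < 0.35) 1 - 6.4 * (kt - 0.22)^2
  else if (kt <= K) 1.47 - 1.66 * kt else R
  min(1, max(0, fd))
}

#' Expand a daily weather table to hourly PAR
#'
#' Distributes each day's total PAR over the daylight hours as a sinusoid
#' truncated at sunrise/sunset, scaled so the hourly integral reproduces
#' the daily total, then splits direct/diffuse.
#'
#' @param daily data.frame with columns `doy` and `PAR_MJ_m2` (daily total
#'   PAR in energy units).
#' @param latitude degrees north.
#' @param diffuse_fraction constant fraction or `"spitters"`.
#' @return hourly weather data.frame as in [generate_weather()].
#' @export
expand_daily_weather <- function(daily, latitude = 39.93,
                                 diffuse_fraction = 0.2) {
  out <- vector("list", nrow(daily))
  for (k in seq_len(nrow(daily))) {
    d <- daily$doy[k]
    s0 <- sun_position(latitude, d, 12)
    hours <- seq(ceiling(s0$sunrise), floor(s0$sunset))
    shape <- pmax(0, sin(pi * (hours - s0$sunrise) /
                           (s0$sunset - s0$sunrise)))
    tot_umol <- daily$PAR_MJ_m2[k] * 1e6 * 4.55      # MJ -> umol m-2 d-1
    par_t <- shape * tot_umol / (sum(shape) * 3600)
    fd <- if (identical(diffuse_fraction, "spitters")) {
      vapply(seq_along(hours), function(i) {
        sp <- sun_position(latitude, d, hours[i])
        spitters_diffuse_fraction(par_t[i], sp$elevation)
      }, numeric(1))
    } else rep(diffuse_fraction, length(hours))
    out[[k]] <- data.frame(doy = d, hour = hours, PAR_total = par_t,
                           I_dir = par_t * (1 - fd), I_diff = par_t * fd)
  }
  do.call(rbind, out)
}

#' Integrate an hourly weather series to daily PAR totals
#'
#' @param weather a [generate_weather()] table.
#' @return data.frame: `doy`, `PAR_MJ_m2` (daily total, energy units).
#' @export
daily_par_totals <- function(weather) {
  ag <- stats::aggregate(weather$PAR_total * 3600 / 4.55 * 1e-6,
                         list(doy = weather$doy), sum)
  names(ag)[2] <- "PAR_MJ_m2"
  ag
}

#' Generate every synthetic input family and write them as CSV
#'
#' Writes the three CSV families the pipeline consumes: the per-cultivar
#' phytomer tables, the fitted light-response parameter table (plus noisy
#' A-Q observations), and the hourly weather series.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param doys weather days of year (default the 60-day post-silking
#'   window starting at silking, DOY 228).
#' @return invisibly, the written paths.
#' @export
generate_all_inputs <- function(out_dir, seed = 1L, doys = 228:287) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profs <- cultivar_profiles()
  plants <- lapply(profs, generate_phytomer_table, seed = seed)
  p1 <- file.path(out_dir, "phytomer_tables.csv")
  write_phytomer_table(plants, p1)
  lib <- light_response_library()
  pr <- do.call(rbind, lapply(names(lib), function(cv)
    do.call(rbind, lapply(names(lib[[cv]]), function(ly) {
      p <- lib[[cv]][[ly]]
      data.frame(cultivar = cv, layer = ly, alpha = p$alpha,
                 beta = p$beta, gamma = p$gamma, Rd = p$Rd,
                 Amax = amax(p))
    }))))
  p2 <- file.path(out_dir, "light_response_params.csv")
  utils::write.csv(pr, p2, row.names = FALSE)
  aq <- do.call(rbind, lapply(names(lib), function(cv)
    do.call(rbind, lapply(names(lib[[cv]]), function(ly) {
      d <- generate_aq_data(lib[[cv]][[ly]], sigma = 0.3, n_reps = 3,
                            seed = seed + match(ly, names(lib[[cv]])))
      cbind(cultivar = cv, layer = ly, d)
    }))))
  p3 <- file.path(out_dir, "aq_observations.csv")
  utils::write.csv(aq, p3, row.names = FALSE)
  wx <- generate_weather(doys = doys, seed = seed)
  p4 <- file.path(out_dir, "weather_hourly.csv")
  utils::write.csv(wx, p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
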