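test_that("leaf PPFD back-calculation inverts the IPP aggregation", {
  expect_equal(ppfd_per_leaf(3.6e5, 1000), 1000)
  expect_equal(ppfd_per_leaf(0, 500), 0)
  expect_error(ppfd_per_leaf(10, 0), "LA = 0")

  # round trip: a uniformly lit isolated horizontal leaf gets back the
  # incident flux density it intercepted
  lf <- horizontal_leaf(1000, z = 50)
  sc <- scene_from_triangles(lf$v1, lf$v2, lf$v3)
  rec <- hourly_records(sc, 80, 12, 600, 400, latitude = 0)
  expect_equal(ppfd_per_leaf(rec$IPP_umol_leaf_h, rec$LA_cm2), 1000,
               tolerance = 0.02)
})

test_that("layer mapping keys ranks to the measured parameter sets", {
  expect_equal(layer_of_rank(c(10, 12, 13, 14, 15, 19), 13),
               c("lower", "ear", "ear", "ear", "upper", "upper"))
  rec <- data.frame(DOY = 1, plant = 1, rank = 5, hour = 12,
                    LA_cm2 = 100, IPP_umol_leaf_h = 100, LA_sun_cm2 = 0)
  expect_error(canopy_assim_instant(rec, list(upper = NULL), 13),
               "layer parameters missing")
})

test_that("instantaneous canopy assimilation integrates leaf rates", {
  p <- light_response_params(0.06, 5e-5, 2e-3, 2.5)
  # one 1 m^2 leaf, M = 1, PD = 1: A_can equals the leaf rate
  Q <- 800
  rec <- data.frame(plant = 1, rank = 13, LA_cm2 = 1e4,
                    IPP_umol_leaf_h = Q * 3600 * 1e4 * 1e-4)
  pb <- list(upper = p, ear = p, lower = p)
  expect_equal(canopy_assim_instant(rec, pb, 13, M = 1, PD = 1),
               net_photosynthesis(p, Q), tolerance = 1e-12)

  # darkness: respiration makes the canopy a net source
  dark <- data.frame(plant = 1, rank = c(12, 13, 14), LA_cm2 = 2000,
                     IPP_umol_leaf_h = 0)
  a_dark <- canopy_assim_instant(dark, pb, 13, M = 1, PD = 1)
  expect_equal(a_dark, -2.5 * 3 * 0.2, tolerance = 1e-12)
})

test_that("daily chain arithmetic and conversions are exact", {
  p <- light_response_params(0.06, 5e-5, 2e-3, 2.5)
  pb <- list(upper = p, ear = p, lower = p)
  # engineered records: one leaf whose PPFD makes A exactly 10, 10 hours
  Q <- uniroot(function(q) net_photosynthesis(p, q) - 10,
               c(100, 2000), tol = 1e-12)$root
  rec1 <- do.call(rbind, lapply(8:17, function(h)
    data.frame(DOY = 1, plant = 1, rank = 13, hour = h, LA_cm2 = 1e4,
               IPP_umol_leaf_h = Q * 3600, LA_sun_cm2 = 0)))
  ch <- daily_chain(rec1, pb, 13, M = 1, PD = 1)
  # A_canDAY = sum_t 3600 * 10 over 10 h = 3.6e5 umol m-2 d-1
  expect_equal(ch$A_canDAY_umol_m2, 3.6e5, tolerance = 1e-9)
  # DM = 44 g/mol * 0.36 mol * 0.41
  expect_equal(ch$DM_g_m2, 44 * 0.36 * 0.41, tolerance = 1e-9)

  # photons totalling 4.55e6 umol leaf-1 d-1 are exactly 1 MJ leaf-1 d-1
  rec2 <- data.frame(DOY = 1, plant = 1, rank = 13, hour = 12,
                     LA_cm2 = 1e4, IPP_umol_leaf_h = 4.55e6,
                     LA_sun_cm2 = 0)
  ch2 <- daily_chain(rec2, pb, 13, M = 1, PD = 1)
  expect_equal(ch2$ipar_leaf$IPAR_MJ_leaf, 1.0, tolerance = 1e-12)
  expect_equal(ch2$IPAR_MJ_m2, 1.0, tolerance = 1e-12)

  expect_error(daily_chain(transform(rec2, IPP_umol_leaf_h = NaN), pb, 13),
               "NaN")
})

test_that("accumulation window, RUE quotient and regression consistency", {
  series <- data.frame(DM_g_m2 = rep(10, 60), IPAR_MJ_m2 = rep(2.5, 60))
  acc <- accumulate_and_rue(series)
  expect_equal(acc$ADM_g_m2, 600)
  expect_equal(acc$AIPAR_MJ_m2, 150)
  expect_equal(acc$RUE_g_MJ, 4.0)
  expect_equal(acc$yield_Mg_ha, 6.0)
  expect_false(is.unsorted(acc$series$ADM_g_m2))

  expect_error(accumulate_and_rue(series[1:10, ]), "60 days")
  dark <- data.frame(DM_g_m2 = rep(0, 60), IPAR_MJ_m2 = rep(0, 60))
  expect_error(accumulate_and_rue(dark), "RUE undefined")

  # stationary DM/IPAR ratio: regression slope of ADM on AIPAR = quotient
  set.seed(3)
  f <- runif(60, 0.5, 1.5)
  st <- data.frame(DM_g_m2 = 12 * f, IPAR_MJ_m2 = 3 * f)
  acc2 <- accumulate_and_rue(st)
  slope <- coef(lm(ADM_g_m2 ~ AIPAR_MJ_m2, data = acc2$series))[2]
  expect_equal(unname(slope), acc2$RUE_g_MJ, tolerance = 1e-6)
})

test_that("layer partition is additive and respects the ear anchor", {
  rec <- expand.grid(plant = 1:2, rank = 1:19, hour = 10:14)
  rec$IPP_umol_leaf_h <- runif(nrow(rec), 0, 1e5)
  rec$DOY <- 1; rec$LA_cm2 <- 500; rec$LA_sun_cm2 <- 0
  lp <- layer_partition(rec, ear_rank = 13, M = 9, PD = 6)
  expect_equal(lp$IPAR_upp + lp$IPAR_mid + lp$IPAR_low, lp$IPAR_can,
               tolerance = 1e-12)
  # independent spreadsheet-style total from the raw records
  total <- sum(rec$IPP_umol_leaf_h) / 4.55 * 1e-6 / (9 / 6)
  expect_equal(lp$IPAR_can, total, tolerance = 1e-12)

  # degenerate three-leaf plant with the ear in the middle
  rec3 <- data.frame(DOY = 1, plant = 1, rank = 1:3, hour = 12,
                     LA_cm2 = 100, IPP_umol_leaf_h = 1e4, LA_sun_cm2 = 0)
  lp3 <- layer_partition(rec3, ear_rank = 2, M = 1, PD = 1)
  expect_equal(lp3$IPAR_upp, 0)
  expect_equal(lp3$IPAR_low, 0)
  expect_gt(lp3$IPAR_mid, 0)
})

test_that("doubling photon input doubles IPAR and sub-doubles assimilation", {
  p <- light_response_params(0.06, 5e-5, 2e-3, 0)
  pb <- list(upper = p, ear = p, lower = p)
  rec <- do.call(rbind, lapply(10:14, function(h)
    data.frame(DOY = 1, plant = 1, rank = 10:16, hour = h, LA_cm2 = 800,
               IPP_umol_leaf_h = seq(2e5, 8e5, length.out = 7),
               LA_sun_cm2 = 0)))
  rec2 <- transform(rec, IPP_umol_leaf_h = 2 * IPP_umol_leaf_h)
  ch1 <- daily_chain(rec, pb, 13, M = 1, PD = 6)
  ch2 <- daily_chain(rec2, pb, 13, M = 1, PD = 6)
  expect_equal(ch2$IPAR_MJ_m2, 2 * ch1$IPAR_MJ_m2, tolerance = 1e-12)
  expect_lt(ch2$A_canDAY_umol_m2, 2 * ch1$A_canDAY_umol_m2)
  expect_gt(ch2$A_canDAY_umol_m2, ch1$A_canDAY_umol_m2)
})
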