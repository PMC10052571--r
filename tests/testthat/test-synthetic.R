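test_that("generated rank profiles hit the stated peaks", {
  plants <- fix_plants()
  hdbtop <- vapply(plants$JNK728$phytomers, function(p) p$HDBTop,
                   numeric(1))
  expect_equal(which.max(hdbtop), 14)
  expect_equal(max(hdbtop), 67.68, tolerance = 1 / 67.68)

  ltip <- vapply(plants$JMC01$phytomers, function(p) p$Ltip, numeric(1))
  expect_equal(which.max(ltip), 11)
  expect_equal(max(ltip), 74.04, tolerance = 1 / 74.04)

  ltop <- vapply(plants$J2416$phytomers, function(p) p$Ltop, numeric(1))
  expect_equal(which.max(ltop), 13)
  expect_equal(max(ltop), 38.18, tolerance = 1 / 38.18)

  # every generated phytomer satisfies the spec invariants by construction
  for (cv in names(plants))
    for (p in plants[[cv]]$phytomers)
      expect_silent(maizecanopy:::validate_phytomer_spec(p))
})

test_that("generator is deterministic under a fixed seed", {
  pr <- cultivar_profiles()$JNK728
  a <- generate_phytomer_table(pr, seed = 42, noise_sd = 0.03)
  b <- generate_phytomer_table(pr, seed = 42, noise_sd = 0.03)
  expect_identical(a, b)
  c <- generate_phytomer_table(pr, seed = 43, noise_sd = 0.03)
  expect_false(identical(a, c))
})

test_that("cultivar orderings in height and leaf area persist over seeds", {
  profs <- cultivar_profiles()
  for (seed in 1:20) {
    pls <- lapply(profs, generate_phytomer_table, seed = seed,
                  noise_sd = 0.03)
    area <- vapply(pls, function(pl) sum(vapply(pl$phytomers, function(p)
      blade_area(p$LL, p$max_width), numeric(1))) * 1e-4, numeric(1))
    h <- vapply(pls, function(pl) pl$plant_height, numeric(1))
    expect_gt(area[["JNK728"]], area[["JMC01"]])
    expect_gt(area[["JMC01"]], area[["J2416"]])
    expect_gt(h[["JNK728"]], h[["JMC01"]])
    expect_gt(h[["JMC01"]], h[["J2416"]])
    # generated area stays within 10% of the cultivar target
    targets <- c(JNK728 = 0.72, J2416 = 0.46, JMC01 = 0.58)
    for (cv in names(targets))
      expect_lt(abs(area[[cv]] - targets[[cv]]) / targets[[cv]], 0.10)
  }
})

test_that("synthetic A-Q data round-trips through the fitter", {
  truth <- solve_beta_gamma(0.060, 29.43, 2.17)
  d <- generate_aq_data(truth, sigma = 0, seed = 1)
  expect_setequal(unique(d$ppfd), aq_ppfd_levels())
  f <- fit_light_response(d)
  expect_equal(f$params$alpha, truth$alpha, tolerance = 0.01)
  expect_equal(f$Amax, 29.43, tolerance = 0.01 * 29.43)
  # dark observation is -Rd plus noise
  expect_equal(d$A[d$ppfd == 0], -truth$Rd, tolerance = 1e-12)
  dn <- generate_aq_data(truth, sigma = 0.4, n_reps = 4, seed = 2)
  dark <- dn$A[dn$ppfd == 0]
  expect_lt(abs(mean(dark) + truth$Rd), 1)
})

test_that("weather generator: diurnal shape, quadrature, diffuse split", {
  wx <- generate_weather(doys = 233, peak_par = 2000,
                         diffuse_fraction = 0.2, seed = 1)
  s0 <- sun_position(39.93, 233, 12)
  # peak at solar noon
  expect_equal(max(wx$PAR_total), 2000, tolerance = 1e-3)
  expect_equal(wx$hour[which.max(wx$PAR_total)], 12)
  # hourly quadrature matches the analytic sine integral within 2%
  daylen <- (s0$sunset - s0$sunrise) * 3600
  analytic <- 2000 * 2 / pi * daylen          # umol m-2 d-1
  expect_equal(sum(wx$PAR_total) * 3600, analytic, tolerance = 0.02)
  expect_equal(daily_par_totals(wx)$PAR_MJ_m2,
               sum(wx$PAR_total) * 3600 / 4.55 * 1e-6, tolerance = 1e-12)

  # fully diffuse sky has no direct beam
  wd <- generate_weather(doys = 233, diffuse_fraction = 1, seed = 1)
  expect_true(all(wd$I_dir == 0))
  expect_equal(wd$I_diff, wd$PAR_total)

  # spitters partition stays in [0, 1] and is mostly direct on clear noon
  ws <- generate_weather(doys = 233, diffuse_fraction = "spitters",
                         seed = 1)
  expect_true(all(ws$I_dir >= 0 & ws$I_diff >= 0))
  fd_noon <- ws$I_diff[ws$hour == 12] / ws$PAR_total[ws$hour == 12]
  expect_lt(fd_noon, 0.5)

  # daily table expansion reproduces the stated totals
  daily <- data.frame(doy = c(240, 241), PAR_MJ_m2 = c(8, 5))
  hx <- expand_daily_weather(daily)
  expect_equal(daily_par_totals(hx)$PAR_MJ_m2, c(8, 5), tolerance = 1e-9)
})

test_that("generated input bundle is written and readable", {
  out <- tempfile("synth")
  paths <- generate_all_inputs(out, seed = 1, doys = 233:234)
  expect_true(all(file.exists(file.path(
    out, c("phytomer_tables.csv", "light_response_params.csv",
           "aq_observations.csv", "weather_hourly.csv")))))
  plants <- read_phytomer_table(file.path(out, "phytomer_tables.csv"))
  expect_setequal(names(plants), c("JNK728", "J2416", "JMC01"))
  pars <- read.csv(file.path(out, "light_response_params.csv"))
  expect_equal(nrow(pars), 9)
  expect_true(all(c("alpha", "beta", "gamma", "Rd", "Amax") %in%
                    names(pars)))
})
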