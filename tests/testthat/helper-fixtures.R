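# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# deterministic synthetic plants, one per cultivar
fix_plants <- function() fixture("plants", function() {
  lapply(cultivar_profiles(), generate_phytomer_table, seed = 1L)
})

fix_photo_library <- function() fixture("photo_lib", light_response_library)

# reduced study stand used across radiation/heterosis tests: 3 x 5 grid,
# single interior focal plant, coarse tessellation
reduced_scene_args <- function() {
  list(n_rows = 3L, n_cols = 5L, focal_block = 1L, n_segments = 6L,
       seed = 2L)
}

fix_scene_jnk <- function() fixture("scene_jnk", function() {
  do.call(assemble_canopy, c(list(plants = fix_plants()$JNK728),
                             reduced_scene_args()))
})

# reduced 10-day scenario matrix shared by heterosis and acceptance tests
fix_scenarios <- function() fixture("scenarios", function() {
  wx <- generate_weather(doys = 233:242, seed = 3L)
  run_all_scenarios(fix_plants(), fix_photo_library(), wx,
                    scene_args = reduced_scene_args(), window = NA)
})

# Random feasible phytomer spec: collar -> highest point -> tip path with
# length margin, so all five descriptors are simultaneously achievable.
random_feasible_spec <- function(seed) {
  set.seed(seed)
  LL <- runif(1, 20, 120)
  a <- runif(1, 0.30, 0.60) * LL                  # up-leg length
  b <- runif(1, 0.10, min(0.32, 0.88 - a / LL)) * LL
  th1 <- runif(1, 35, 85) * pi / 180              # up-leg elevation
  th2 <- runif(1, 5, 70) * pi / 180               # down-leg droop
  top <- a * c(cos(th1), sin(th1))
  tip <- top + b * c(cos(th2), -sin(th2))
  phytomer_spec(1L, LL = LL, HLBase = 0, HLTop = top[2], HLTip = tip[2],
                Ltop = top[1], Ltip = tip[1],
                inclination = runif(1, 45, 80))
}

# Random triangle-soup scene for occlusion oracle checks.
random_facet_scene <- function(n_facets, seed, box = 100) {
  set.seed(seed)
  ctr <- cbind(runif(n_facets, 0, box), runif(n_facets, 0, box),
               runif(n_facets, 10, box))
  mk <- function() {
    v <- matrix(rnorm(3 * n_facets), ncol = 3)
    v / sqrt(rowSums(v^2)) * runif(n_facets, 2, 8)
  }
  scene_from_triangles(ctr + mk(), ctr + mk(), ctr + mk())
}

# Independent solar declination (PSA algorithm, Blanco-Muriel 2001),
# assuming year 2021 for day-of-year dates and the study site longitude
# (116.27 E) to place local solar time on the UT scale; used as the second
# solar-position implementation in tests.
psa_declination <- function(doy, hour = 12, lon = 116.27) {
  # 2021-01-01 00:00 UT base; local solar hour -> UT instant
  jd <- 2459215.5 + (doy - 1) + (hour - lon / 15) / 24
  n <- jd - 2451545.0
  omega <- 2.1429 - 0.0010394594 * n
  L <- 4.8950630 + 0.017202791698 * n
  l <- 6.2400600 + 0.0172019699 * n
  lambda <- L + 0.03341607 * sin(l) + 0.00034894 * sin(2 * l) -
    0.0001134 - 0.0000203 * sin(omega)
  eps <- 0.4090928 - 6.2140e-9 * n + 0.0000396 * cos(omega)
  asin(sin(eps) * sin(lambda)) * 180 / pi
}

# zenith from an independently computed declination + shared hour angle
psa_zenith <- function(latitude, doy, hour) {
  decl <- psa_declination(doy, hour) * pi / 180
  phi <- latitude * pi / 180
  H <- (hour - 12) * 15 * pi / 180
  90 - asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)) * 180 / pi
}

# single horizontal square leaf of given area (cm^2) centred at (x, y, z)
horizontal_leaf <- function(area_cm2, x = 0, y = 0, z = 50) {
  s <- sqrt(area_cm2)
  h <- s / 2
  v <- rbind(c(x - h, y - h, z), c(x + h, y - h, z),
             c(x + h, y + h, z), c(x - h, y + h, z))
  list(v1 = rbind(v[1, ], v[1, ]), v2 = rbind(v[2, ], v[3, ]),
       v3 = rbind(v[3, ], v[4, ]))
}
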