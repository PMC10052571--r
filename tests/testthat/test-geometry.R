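test_that("descriptor invariants are enforced with named violations", {
  expect_error(
    phytomer_spec(1, LL = 10, HLBase = 0, HLTop = 5, HLTip = 2,
                  Ltop = 4, Ltip = 11),
    "chord <= arc")
  expect_error(
    phytomer_spec(1, LL = 50, HLBase = 10, HLTop = 40, HLTip = 20,
                  Ltop = 30, Ltip = 20),
    "Ltop <= Ltip")
  expect_error(
    phytomer_spec(1, LL = 50, HLBase = 30, HLTop = 20, HLTip = 10,
                  Ltop = 10, Ltip = 20),
    "HDBTop")
  expect_error(
    plant_spec("x", list(phytomer_spec(1, 50, 0, 30, 20, 20, 30),
                         phytomer_spec(3, 50, 10, 40, 30, 20, 30)),
               ear_rank = 1, plant_height = 100),
    "contiguous")
})

test_that("midrib construction meets the descriptor constraints", {
  # arc-length priority holds even for a mutually infeasible projection set
  ps <- phytomer_spec(1, LL = 60, HLBase = 0, HLTop = 30, HLTip = 0,
                      Ltop = 30, Ltip = 51.96)
  d <- midrib_descriptors(build_midrib(ps, 64))
  expect_equal(d$LL, 60, tolerance = 0.3 / 60)
  expect_equal(d$HDBTop, 30, tolerance = 0.3 / 30)

  # chord equal to arc forces a straight (here vertical) segment
  ps2 <- phytomer_spec(1, LL = 10, HLBase = 0, HLTop = 10, HLTip = 10,
                      Ltop = 0, Ltip = 0)
  m2 <- build_midrib(ps2, 16)
  expect_true(all(abs(m2[, 1]) < 1e-9) && all(abs(m2[, 2]) < 1e-9))
  expect_equal(m2[16, 3], 10)

  # infeasible descriptor rejection names the inequality
  expect_error(build_midrib(structure(list(rank = 1L, LL = 10, HLBase = 0,
                                           HLTop = 0, HLTip = 0, Ltop = 0,
                                           Ltip = 12, azimuth = 0,
                                           max_width = 5,
                                           inclination = NA_real_,
                                           has_ear = FALSE, HDBTop = 0,
                                           HDBTip = 0),
                                      class = "phytomer_spec")),
               "chord <= arc")

  # hybrid ear-leaf rank: highest-point projection reproduces the profile
  p13 <- fix_plants()$JNK728$phytomers[[13]]
  d13 <- midrib_descriptors(build_midrib(p13))
  expect_equal(d13$Ltop, 47.54, tolerance = 0.95 / 47.54)
})

test_that("midrib round-trips its descriptors on randomized feasible specs", {
  for (i in 1:200) {
    sp <- random_feasible_spec(1000 + i)
    d <- midrib_descriptors(build_midrib(sp))
    expect_lt(abs(d$LL - sp$LL), 0.005 * sp$LL)
    expect_lt(abs(d$HDBTop - sp$HDBTop), 0.005 * sp$LL)
    expect_lt(abs(d$HDBTip - sp$HDBTip), 0.005 * sp$LL)
    expect_lt(abs(d$Ltop - sp$Ltop), 0.02 * sp$LL)
    expect_lt(abs(d$Ltip - sp$Ltip), 0.02 * sp$LL)
  }
})

test_that("leaf meshes have exact rectangular area and convergent beta area", {
  straight <- cbind(seq(0, 100, length.out = 24), 0, 50)
  rect <- build_leaf_mesh(straight, 10, profile = "rectangular")
  expect_equal(sum(rect$area), 1000, tolerance = 1e-9)

  ps <- random_feasible_spec(42)
  mid <- build_midrib(ps)
  m1 <- build_leaf_mesh(mid, 8, n_segments = 12)
  m2 <- build_leaf_mesh(mid, 8, n_segments = 24)
  expect_lt(abs(sum(m2$area) - sum(m1$area)) / sum(m2$area), 0.01)
  # default tessellation is within 1% of the analytic blade area
  expect_lt(abs(sum(m1$area) - blade_area(midrib_descriptors(mid)$LL, 8)) /
              blade_area(midrib_descriptors(mid)$LL, 8), 0.01)

  # mesh validity: positive areas, unit normals
  expect_true(all(m1$area > 0))
  expect_lt(max(abs(sqrt(rowSums(m1$normal^2)) - 1)), 1e-9)

  expect_error(build_leaf_mesh(straight[1, , drop = FALSE], 5),
               "degenerate midrib")
})

test_that("generated plants hit the cultivar leaf-area totals", {
  pl <- fix_plants()$JNK728
  area <- sum(vapply(pl$phytomers, function(p)
    sum(build_leaf_mesh(build_midrib(p), p$max_width)$area), numeric(1)))
  expect_equal(area * 1e-4, 0.72, tolerance = 0.06 / 0.72)
})

test_that("canopy assembly: spacing, wall height, determinism, conservation", {
  sc <- fix_scene_jnk()
  # PD = 1 / (row spacing x within-row spacing)
  expect_equal(sc$within_spacing_cm, 100 / (6 * 0.6), tolerance = 1e-12)
  # wall at 60% of plant height (synthetic hybrid: 266.37 cm)
  expect_equal(sc$wall_height, 0.6 * 266.37, tolerance = 1e-12)
  # focal plants are interior
  expect_false(any(sc$plants$focal[c(1, sc$n_cols, nrow(sc$plants))]))

  sc2 <- do.call(assemble_canopy, c(list(plants = fix_plants()$JNK728),
                                    reduced_scene_args()))
  expect_identical(sc$v1, sc2$v1)   # same seed, same vertices

  # scene leaf area = n_plants x per-plant area for a single template
  per_plant <- sum(sc$area[sc$plant == 1])
  expect_equal(sum(sc$area), nrow(sc$plants) * per_plant,
               tolerance = 1e-9)
})

test_that("phytomer CSV and mesh export round-trip", {
  plants <- fix_plants()
  csv <- tempfile(fileext = ".csv")
  write_phytomer_table(plants, csv)
  back <- read_phytomer_table(csv)
  expect_setequal(names(back), names(plants))
  p0 <- plants$JNK728$phytomers[[10]]
  p1 <- back$JNK728$phytomers[[10]]
  expect_equal(p1$LL, p0$LL)
  expect_equal(p1$Ltip, p0$Ltip)
  expect_equal(back$JNK728$ear_rank, plants$JNK728$ear_rank)

  sc <- scene_from_triangles(rbind(c(0, 0, 0)), rbind(c(10, 0, 0)),
                             rbind(c(0, 10, 0)))
  obj <- tempfile(fileext = ".obj")
  write_scene_mesh(sc, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), 3)
  expect_equal(sum(startsWith(lines, "f ")), 1)
  ply <- tempfile(fileext = ".ply")
  write_scene_mesh(sc, ply)
  expect_true(any(grepl("element face 1", readLines(ply))))
})
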