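# Synthetic-data generators: density, determinism, carving, fixtures.

test_that("water bath hits the requested density and respects the hard core", {
  box <- 16
  bath <- generate_water_bath(box, 33.4, seed = 5, relax_sweeps = 0)
  n_mol <- length(unique(bath$solvent$mol))
  target <- round(33.4 * (box / 10)^3)
  expect_equal(n_mol, target)
  expect_true(all(bath$solvent$radius[bath$solvent$element == "O"] == 1.52))
  expect_true(all(bath$solvent$radius[bath$solvent$element == "H"] == 1.2))
  # raw insertion honors the O-O hard core under minimum image
  o <- as.matrix(bath$solvent[bath$solvent$element == "O", c("x", "y", "z")])
  dmin <- min(vapply(seq_len(nrow(o)), function(i)
    min(voidshape:::mi_dist(o[-i, , drop = FALSE], o[i, ], bath$box)),
    numeric(1)))
  expect_gte(dmin, 2.6)
  # all positions wrapped inside the box
  xyz <- as.matrix(bath$solvent[, c("x", "y", "z")])
  expect_true(all(xyz >= 0 & xyz < box))
})

test_that("water bath generation is reproducible and rejects bad input", {
  b1 <- small_bath(seed = 7)
  b2 <- generate_water_bath(16, 33.4, seed = 7, relax_sweeps = 60)
  expect_identical(b1$solvent, b2$solvent)
  b3 <- generate_water_bath(16, 33.4, seed = 8, relax_sweeps = 60)
  expect_false(identical(b1$solvent$x, b3$solvent$x))
  expect_error(generate_water_bath(16, 0, seed = 1), "density")
  expect_error(generate_water_bath(8, 33.4, seed = 1), "box_side")
  expect_error(generate_water_bath(16, 33.4, seed = 1, hardcore = 3.4),
               "infeasible")
})

test_that("O-H geometry is rigid 3-site with the gas-phase values", {
  bath <- small_bath(seed = 7)
  sv <- bath$solvent
  m1 <- sv[sv$mol == 1, ]
  o <- as.numeric(m1[m1$element == "O", c("x", "y", "z")])
  h <- as.matrix(m1[m1$element == "H", c("x", "y", "z")])
  d1 <- voidshape:::mi_dist(h, o, bath$box)
  expect_equal(unname(d1), c(0.9572, 0.9572), tolerance = 1e-6)
  v1 <- voidshape:::min_image(matrix(h[1, ] - o, 1, 3), bath$box)
  v2 <- voidshape:::min_image(matrix(h[2, ] - o, 1, 3), bath$box)
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, 104.52, tolerance = 1e-3)
})

test_that("sphere carve records the analytic volume and clears the region", {
  bath <- small_bath(seed = 3, box = 20)
  cv <- carve_phantom_cavity(bath, "sphere", core_radius = 6, seed = 2,
                             relax_sweeps = 40)
  expect_equal(cv$truth$analytic_volume, 4 / 3 * pi * 216, tolerance = 1e-12)
  expect_equal(cv$truth$analytic_area, 4 * pi * 36, tolerance = 1e-12)
  expect_identical(cv$truth$true_branch_count, 0L)
  # no kept atom sphere intersects the carved region
  sv <- cv$config$solvent
  d <- voidshape:::mi_dist(as.matrix(sv[, c("x", "y", "z")]),
                           bath$box / 2, bath$box)
  expect_true(all(d - 6 > sv$radius - 0.21))
  # determinism
  cv2 <- carve_phantom_cavity(bath, "sphere", core_radius = 6, seed = 2,
                              relax_sweeps = 40)
  expect_identical(cv$config$solvent, cv2$config$solvent)
})

test_that("zero-radius carve leaves the configuration untouched", {
  bath <- small_bath(seed = 3, box = 20)
  cv <- carve_phantom_cavity(bath, "sphere", core_radius = 0, seed = 1)
  expect_identical(cv$config$solvent, bath$solvent)
  expect_equal(cv$truth$analytic_volume, 0)
})

test_that("star carve has separated tendrils and a bracketed MC volume", {
  bath <- small_bath(seed = 3, box = 30, relax = 60)
  cv <- carve_phantom_cavity(bath, "star", core_radius = 3, n_tendrils = 4,
                             tendril_length = 8, tendril_radius = 1.8,
                             seed = 9, relax_sweeps = 20, mc_samples = 1e6)
  tr <- cv$truth
  expect_identical(tr$true_branch_count, 4L)
  expect_equal(tr$tendril_length, 8)
  # pairwise angular separation respects the floor
  dirs <- tr$directions
  cosmax <- cos(60 * pi / 180)
  gram <- dirs %*% t(dirs)
  expect_true(all(gram[upper.tri(gram)] < cosmax + 1e-9))
  # Monte-Carlo union volume sits between the core and core + k capsules
  v_core <- 4 / 3 * pi * 27
  v_capsule <- pi * 1.8^2 * (3 + 8 - 1.8) + 4 / 3 * pi * 1.8^3
  expect_gt(tr$analytic_volume, v_core)
  expect_lt(tr$analytic_volume, v_core + 4 * v_capsule)
  expect_lt(tr$volume_se, 5)
  expect_error(carve_phantom_cavity(bath, "sphere", core_radius = 20),
               "exceeds the box")
})

test_that("solute placement removes clashing waters and moves nothing", {
  bath <- small_bath(seed = 4, box = 20)
  spec <- data.frame(dx = c(0, 3), dy = 0, dz = 0, element = "C",
                     radius = 2, group = c("left", "right"))
  cfg <- place_model_solute(bath, spec)
  expect_equal(nrow(cfg$solute), 2L)
  # removal rule: every surviving atom clears every solute sphere
  sv <- cfg$solvent
  dmin <- voidshape:::min_dist_to_spheres(as.matrix(sv[, c("x", "y", "z")]),
                                          voidshape:::solute_xyz(cfg),
                                          cfg$solute$radius, cfg$box)
  expect_true(all(dmin >= sv$radius - 1e-9))
  # kept solvent atoms are exactly where they were
  keep_ids <- paste(sv$mol, sv$element, round(sv$x, 6))
  orig_ids <- paste(bath$solvent$mol, bath$solvent$element,
                    round(bath$solvent$x, 6))
  expect_true(all(keep_ids %in% orig_ids))
  expect_error(place_model_solute(bath, spec[0, ]), "at least one atom")
})

test_that("solute placement commutes with a rigid translation of the system", {
  bath <- small_bath(seed = 4, box = 20)
  spec <- data.frame(dx = 0, dy = 0, dz = 0, element = "C", radius = 3,
                     group = "core")
  a <- place_model_solute(bath, spec, center = bath$box / 2)
  shift <- c(9.7, -4.1, 15.3)
  b_shift <- bath
  b_shift$solvent[, c("x", "y", "z")] <- voidshape:::wrap_positions(
    sweep(as.matrix(bath$solvent[, c("x", "y", "z")]), 2, shift, "+"),
    bath$box)
  b <- place_model_solute(b_shift, spec, center = bath$box / 2 + shift)
  expect_equal(nrow(a$solvent), nrow(b$solvent))
})

test_that("regression fixtures are exact when noiseless and reproducible", {
  fx <- generate_regression_fixture(20, c(A = 1, B = 0, C = 0), 0, seed = 3)
  fit <- stats::lm(fx$y ~ 0 + ., data = fx$X)
  expect_equal(unname(stats::coef(fit)), c(1, 0, 0), tolerance = 1e-10)
  expect_lt(max(abs(stats::residuals(fit))), 1e-10)

  f1 <- generate_regression_fixture(20, rep(0.5, 8), 0.1, seed = 7)
  f2 <- generate_regression_fixture(20, rep(0.5, 8), 0.1, seed = 7)
  expect_identical(f1, f2)

  expect_error(generate_regression_fixture(3, c(1, 2), 0), "at least")
  expect_error(generate_regression_fixture(20, c(1, 2), -1), "noise_sd")
})

test_that("large-sample OLS recovers the generating weights", {
  fx <- generate_regression_fixture(2000, c(x1 = 0.7, x2 = -0.5), 0.2,
                                    seed = 11)
  fit <- stats::lm(fx$y ~ 0 + ., data = fx$X)
  se <- sqrt(diag(stats::vcov(fit)))
  expect_true(all(abs(stats::coef(fit) - fx$true_weights) < 3 * se))
})
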