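# Voronoi probe spheres, bottleneck merging, host selection, grid oracle.

test_that("regular tetrahedron yields the analytic interior probe", {
  a <- 6
  xyz <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
               c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  cfg <- solvated_configuration(
    box = 50,
    solvent = data.frame(element = "O", x = xyz[, 1] + 20, y = xyz[, 2] + 20,
                         z = xyz[, 3] + 20, radius = 1.52),
    wrap = FALSE)
  g <- compute_probe_spheres(cfg, periodic = FALSE)
  expect_equal(nrow(g$centers), 1L)
  expect_equal(g$empty_radius[1], a * sqrt(3 / 8) - 1.52, tolerance = 1e-3)
  expect_error(compute_probe_spheres(
    solvated_configuration(50, cfg$solvent[1:3, ]), periodic = FALSE),
    "at least 4")
})

test_that("a dense periodic packing has no probe sphere", {
  # periodic cubic crystal at 2.4 A spacing: the largest interstitial empty
  # radius is 2.4*sqrt(3)/2 - 1.52 = 0.56 < probe 1.2
  lat <- (as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) + 0.5) * 2.4
  cfg <- solvated_configuration(
    box = 9.6,
    solvent = data.frame(element = "O", x = lat[, 1], y = lat[, 2],
                         z = lat[, 3], radius = 1.52))
  g <- compute_probe_spheres(cfg)
  expect_equal(nrow(g$centers), 0L)
  expect_equal(length(merge_probes(g)), 0L)
})

test_that("extraction parameters default to the standard probe and bottleneck", {
  p <- extraction_params()
  expect_equal(p$probe_radius, 1.2)
  expect_equal(p$bottleneck_radius, 1.1)
  expect_error(extraction_params(1.0, 1.2), "exceed")
  expect_error(extraction_params(-1, 0.5), "positive")
})

test_that("bottleneck gating splits and keeps components as a flood fill would", {
  params <- extraction_params()
  # two probes with a narrow neck
  g2 <- toy_probe_graph(rbind(c(10, 10, 10), c(14, 10, 10)), c(1.5, 1.5),
                        data.frame(i = 1L, j = 2L, bottleneck = 1.0))
  expect_length(merge_probes(g2, params), 2L)
  # chain of 5 probes above the bottleneck
  centers <- cbind(10 + 3 * (0:4), 10, 10)
  edges <- data.frame(i = 1:4, j = 2:5, bottleneck = 1.15)
  g5 <- toy_probe_graph(centers, rep(1.5, 5), edges)
  voids <- merge_probes(g5, params)
  expect_length(voids, 1L)
  expect_setequal(voids[[1]]$probe_ids, 1:5)
  # singleton probe is its own void
  g1 <- toy_probe_graph(matrix(c(10, 10, 10), 1), 1.4,
                        data.frame(i = integer(), j = integer(),
                                   bottleneck = numeric()))
  expect_length(merge_probes(g1, params), 1L)
})

test_that("every probe sphere is empty of solvent", {
  for (s in 1:3) {
    bath <- small_bath(seed = s)
    g <- compute_probe_spheres(bath)
    if (nrow(g$centers) == 0) next
    d <- voidshape:::min_dist_to_spheres(
      g$centers, voidshape:::solvent_xyz(bath), bath$solvent$radius,
      bath$box)
    expect_true(all(d >= g$empty_radius - 1e-4))
    expect_true(all(g$empty_radius >= 1.2))
    # bottlenecks never exceed the endpoint radii
    if (nrow(g$edges) > 0)
      expect_true(all(g$edges$bottleneck <=
                      pmin(g$empty_radius[g$edges$i],
                           g$empty_radius[g$edges$j]) + 1e-9))
  }
})

test_that("probe count and void count respond monotonically to the radii", {
  sc <- sphere_scenario(4, bath_seed = 2, carve_seed = 61, box = 20,
                        bath_relax = 60, carve_relax = 40)
  cfg <- sc$config
  n_probe <- vapply(c(1.2, 1.5, 1.8), function(pr) {
    nrow(compute_probe_spheres(cfg, extraction_params(pr, min(pr, 1.1)))$centers)
  }, numeric(1))
  expect_true(all(diff(n_probe) <= 0))
  g <- compute_probe_spheres(cfg, extraction_params(1.2, 1.1))
  n_void <- vapply(c(0.9, 1.1, 1.2), function(br)
    length(merge_probes(g, extraction_params(1.2, br))), numeric(1))
  expect_true(all(diff(n_void) >= 0))
})

test_that("void extraction is invariant under periodic translation", {
  bath <- small_bath(seed = 1)
  g <- compute_probe_spheres(bath)
  v <- merge_probes(g)
  shift <- c(3.1, -5.2, 7.7)
  b2 <- bath
  b2$solvent[, c("x", "y", "z")] <- voidshape:::wrap_positions(
    sweep(as.matrix(bath$solvent[, c("x", "y", "z")]), 2, shift, "+"),
    bath$box)
  g2 <- compute_probe_spheres(b2)
  v2 <- merge_probes(g2)
  expect_lte(abs(nrow(g2$centers) - nrow(g$centers)),
             ceiling(0.01 * max(1, nrow(g$centers))))
  expect_lte(abs(length(v2) - length(v)), 1)
})

test_that("grid oracle reproduces an empty box and rejects bad cells", {
  cfg <- solvated_configuration(
    20, data.frame(element = character(), x = numeric(), y = numeric(),
                   z = numeric(), radius = numeric()))
  orc <- grid_cavity_oracle(cfg, cell = 0.5)
  expect_equal(orc$n_components, 1L)
  expect_equal(sum(orc$volume), 20^3, tolerance = 1e-9)
  expect_equal(sum(orc$eroded_volume), 20^3, tolerance = 1e-9)
  expect_error(grid_cavity_oracle(cfg, cell = 0), "positive")
})

test_that("oracle and probe merging agree on substantial components", {
  params <- extraction_params(1.2, 1.2)  # matched gating
  for (s in 1:5) {
    bath <- small_bath(seed = s, box = 20)
    cv <- carve_phantom_cavity(bath, "sphere", core_radius = 3.5,
                               seed = s + 50, relax_sweeps = 40)
    cfg <- cv$config
    g <- compute_probe_spheres(cfg, params)
    voids <- merge_probes(g, params)
    vol_of <- function(vd) {
      ctr <- g$centers[vd$probe_ids, , drop = FALSE]
      rad <- g$empty_radius[vd$probe_ids]
      smp <- voidshape:::with_seed(99, voidshape:::sample_sphere_union(ctr, rad, 4000))
      sum(smp$weight) / 4000 * smp$total
    }
    n_merge <- sum(vapply(voids, vol_of, numeric(1)) >= 25)
    orc <- grid_cavity_oracle(cfg, params, cell = 0.3)
    n_oracle <- sum(orc$volume >= 25)
    expect_equal(n_merge, n_oracle)
  }
})

test_that("host selection picks the void containing the solute", {
  params <- extraction_params()
  centers <- rbind(c(10, 10, 10), c(11, 10, 10), c(40, 40, 40))
  edges <- data.frame(i = 1L, j = 2L, bottleneck = 1.5)
  g <- toy_probe_graph(centers, c(3, 2.5, 3), edges)
  voids <- merge_probes(g, params)
  cfg <- solvated_configuration(
    50,
    data.frame(element = "O", x = 25, y = 25, z = 25, radius = 1.52),
    data.frame(element = "C", x = 10.5, y = 10, z = 10, radius = 1.7,
               group = "solute"),
    wrap = FALSE)
  host <- select_host_void(voids, cfg, g)
  expect_true(host$host)
  expect_true(all(host$probe_ids %in% 1:2))
  # no solute -> no host
  cfg0 <- cfg; cfg0$solute <- cfg0$solute[0, ]
  expect_null(select_host_void(voids, cfg0, g))
  expect_null(select_host_void(list(), cfg, g))
  # solute far away from every probe -> NULL
  cfg2 <- cfg; cfg2$solute$x <- 25; cfg2$solute$y <- 25; cfg2$solute$z <- 2
  expect_null(select_host_void(voids, cfg2, g))
})

test_that("the host void covers the carved sphere", {
  sc <- sphere_scenario(4, bath_seed = 2, carve_seed = 61, box = 20,
                        bath_relax = 60, carve_relax = 40)
  ext <- extract_host_void(sc$config)
  expect_false(is.null(ext$host))
  # MC coverage of the carved sphere by the host probe union
  ctr <- ext$graph$centers[ext$host$probe_ids, , drop = FALSE]
  rad <- ext$graph$empty_radius[ext$host$probe_ids]
  pts <- voidshape:::with_seed(5, {
    u <- matrix(stats::rnorm(3 * 5000), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- 4 * stats::runif(5000)^(1 / 3)
    sweep(u * r, 2, sc$config$box / 2, "+")
  })
  dmin <- voidshape:::min_dist_to_spheres(pts, ctr, rad, sc$config$box)
  expect_gte(mean(dmin < 0), 0.9)
})
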