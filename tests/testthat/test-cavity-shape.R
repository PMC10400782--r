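# Surface reconstruction, volume/area, geodesics, branches, facet counts.

test_that("volume and area of a hand-built unit cube are exact", {
  cube <- cube_mesh(1)
  vs <- compute_volume_area(cube)
  expect_equal(vs$V, 1, tolerance = 1e-12)
  expect_equal(vs$S, 6, tolerance = 1e-12)
  # a 2 A cube scales as expected
  vs2 <- compute_volume_area(cube_mesh(2))
  expect_equal(vs2$V, 8, tolerance = 1e-12)
  expect_equal(vs2$S, 24, tolerance = 1e-12)
})

test_that("an inward-oriented mesh is detected and corrected", {
  cube <- cube_mesh(1)
  flipped <- void_surface(cube$vertices, cube$faces[, c(1, 3, 2)])
  vs <- compute_volume_area(flipped)
  expect_equal(vs$V, 1, tolerance = 1e-12)
  # watertightness is enforced
  broken <- cube$faces[-1, ]
  expect_error(void_surface(cube$vertices, broken), "watertight")
})

test_that("icosphere volume, area and geodesic length match the analytics", {
  s <- icosphere(6, 3)
  vs <- compute_volume_area(s)
  expect_equal(vs$V, 4 / 3 * pi * 216, tolerance = 0.02)
  expect_equal(vs$S, 4 * pi * 36, tolerance = 0.02)
  L <- longest_geodesic(s)
  expect_equal(L, pi * 6, tolerance = 0.1)
})

test_that("surface graph diameter equals the brute-force all-pairs maximum", {
  voidshape:::with_seed(42, {
    for (rep in 1:20) {
      n <- sample(5:15, 1)
      w <- random_weighted_graph(n)
      g <- graph_from_weights(w)
      expect_equal(longest_geodesic(g), floyd_warshall_diameter(w),
                   tolerance = 1e-12)
    }
  })
  # trivial two-vertex case
  g2 <- graph_from_weights(matrix(c(Inf, 2.5, 2.5, Inf), 2))
  expect_equal(longest_geodesic(g2), 2.5)
})

test_that("a single ideal probe reconstructs its sphere", {
  g <- toy_probe_graph(matrix(c(15, 15, 15), 1), 6,
                       data.frame(i = integer(), j = integer(),
                                  bottleneck = numeric()))
  v <- structure(list(probe_ids = 1L, component_id = 1L, host = TRUE),
                 class = "void")
  s <- build_surface(v, g)
  vs <- compute_volume_area(s)
  expect_equal(vs$S, 4 * pi * 36, tolerance = 0.1)
  expect_equal(vs$V, 4 / 3 * pi * 216, tolerance = 0.1)
  expect_equal(longest_geodesic(s), pi * 6, tolerance = 0.1)
  # every edge bounds exactly two facets (watertight invariant)
  cnt <- table(voidshape:::face_edge_keys(s$faces))
  expect_true(all(cnt == 2))
  # isoperimetric inequality
  expect_gte(vs$S^3, 36 * pi * vs$V^2 * (1 - 1e-9))
})

test_that("an unresolvable alpha complex raises a degenerate-surface error", {
  g <- toy_probe_graph(rbind(c(10, 10, 10), c(14, 10, 10), c(18, 10, 10)),
                       rep(1.25, 3),
                       data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                  bottleneck = c(1.15, 1.15)))
  v <- structure(list(probe_ids = 1:3, component_id = 1L, host = TRUE),
                 class = "void")
  # alpha below the sampling resolution cannot span the probe spheres
  expect_error(build_surface(v, g, alpha = 0.45, interior_lattice = FALSE),
               "degenerate|alpha")
})

test_that("density-peak clustering separates well-spaced blobs", {
  voidshape:::with_seed(8, {
    blob <- function(center, n) sweep(matrix(stats::rnorm(3 * n, sd = 0.6),
                                             ncol = 3), 2, center, "+")
    pts <- rbind(blob(c(0, 0, 0), 40), blob(c(12, 0, 0), 40),
                 blob(c(0, 12, 0), 40))
    cl <- density_peak_cluster(pts, dc = 2.5)
    expect_length(cl$centers, 3L)
    expect_equal(sort(as.integer(table(cl$cluster))), c(40, 40, 40))
    # one blob -> one cluster
    cl1 <- density_peak_cluster(blob(c(0, 0, 0), 60), dc = 2.5)
    expect_length(cl1$centers, 1L)
  })
  expect_length(density_peak_cluster(matrix(0, 0, 3), 2.5)$centers, 0L)
  expect_length(density_peak_cluster(matrix(c(1, 2, 3), 1, 3), 2.5)$centers, 1L)
})

test_that("branch detection sees protrusions and respects the threshold", {
  # shell around an off-center solute: a single smooth height maximum
  s <- icosphere(8, 2, center = c(0, 0, 0))
  solute1 <- data.frame(element = "C", x = 2.5, y = 0, z = 0, radius = 1,
                        group = "core")
  br <- detect_branches(s, solute1, threshold = 5)
  expect_length(br, 1L)
  expect_equal(br[[1]]$length, 8 + 2.5 - 1, tolerance = 0.05)
  # large solute: nothing beyond the threshold
  solute2 <- data.frame(element = "C", x = 0, y = 0, z = 0, radius = 6.5,
                        group = "core")
  expect_length(detect_branches(s, solute2, threshold = 5), 0L)
  expect_error(detect_branches(s, solute1[0, ], threshold = 5), "solute")
  expect_error(detect_branches(s, solute1, threshold = -1), "positive")
})

test_that("descriptor assembly follows the definitions", {
  s <- icosphere(6, 2)
  fake_branch <- function(len) structure(
    list(members = 1L, peak = 1L, length = len), class = "branch")
  branches <- lapply(c(2, 4, 6), fake_branch)
  d <- summarize_descriptors(s, branches, n_heavy = 8)
  expect_equal(d$nbr, 3L)
  expect_equal(d$dmin, 2)
  expect_equal(d$dmax, 6)
  expect_equal(d$dave, 4)
  expect_equal(d$dtotal, 12)
  expect_equal(d$branch_density, 3 / 8^(2 / 3), tolerance = 1e-12)
  d5 <- summarize_descriptors(s, lapply(rep(1, 5), fake_branch), n_heavy = 8)
  expect_equal(d5$branch_density, 1.25, tolerance = 1e-12)
  d0 <- summarize_descriptors(s, list(), n_heavy = 8)
  expect_true(all(unlist(d0[c("dmin", "dmax", "dave", "dtotal")]) == 0))
  expect_equal(d0$nbr, 0L)
  expect_error(summarize_descriptors(s, list(), n_heavy = 0), "positive")
})

test_that("facet-group counts are exhaustive and symmetric", {
  s <- icosphere(6, 2)
  one_group <- data.frame(element = "C", x = 0, y = 0, z = 0, radius = 1.7,
                          group = "all")
  expect_equal(count_facets_near_group(s, one_group, "all"), nrow(s$faces))
  ax <- c(2, 1.3, 0.7)
  two_groups <- data.frame(element = c("N", "C"), x = c(ax[1], -ax[1]),
                           y = c(ax[2], -ax[2]), z = c(ax[3], -ax[3]),
                           radius = 1.6, group = c("N-term", "C-term"))
  n_up <- count_facets_near_group(s, two_groups, "N-term")
  n_dn <- count_facets_near_group(s, two_groups, "C-term")
  expect_equal(n_up + n_dn, nrow(s$faces))
  expect_lte(abs(n_up - n_dn), 2)
  expect_error(count_facets_near_group(s, two_groups, "side"), "unknown group")
})

test_that("frame aggregation returns means and standard errors", {
  r1 <- data.frame(V = 100, S = 50, nbr = 2L)
  r2 <- data.frame(V = 200, S = 70, nbr = 3L)
  agg <- aggregate_frames(list(r1, r2))
  expect_equal(agg$V, 150)
  expect_equal(agg$S, 60)
  expect_equal(agg$nbr, 2.5)  # non-integer mean is allowed
  se <- attr(agg, "se")
  expect_equal(unname(se["V"]), stats::sd(c(100, 200)) / sqrt(2))
  same <- aggregate_frames(list(r1, r1, r1))
  expect_equal(same$V, 100)
  expect_equal(unname(attr(same, "se")["V"]), 0)
  expect_error(aggregate_frames(list()), "no frames")
})
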