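# Shared fixtures: all built in code, cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_bath <- function(seed = 1, box = 16, relax = 60) {
  cached(sprintf("bath_%d_%g_%d", seed, box, relax),
         generate_water_bath(box, 33.4, seed = seed, relax_sweeps = relax))
}

# sphere phantom with sealed solute (clearance keeps the relaxed contact
# shell intact)
sphere_scenario <- function(r, bath_seed = 1, carve_seed = 100, box = 30,
                            bath_relax = 300, carve_relax = 200) {
  bath <- cached(sprintf("bigbath_%d_%g", bath_seed, box),
                 generate_water_bath(box, 33.4, seed = bath_seed,
                                     relax_sweeps = bath_relax))
  cv <- carve_phantom_cavity(bath, "sphere", core_radius = r,
                             seed = carve_seed, relax_sweeps = carve_relax)
  cfg <- place_model_solute(cv$config,
                            data.frame(dx = 0, dy = 0, dz = 0, element = "C",
                                       radius = r - 0.3, group = "core"))
  list(config = cfg, truth = cv$truth)
}

star_scenario <- function(k, bath_seed = 1, carve_seed = 20 + k, box = 30,
                          bath_relax = 300, carve_relax = 200) {
  bath <- cached(sprintf("bigbath_%d_%g", bath_seed, box),
                 generate_water_bath(box, 33.4, seed = bath_seed,
                                     relax_sweeps = bath_relax))
  cv <- carve_phantom_cavity(bath, "star", core_radius = 3, n_tendrils = k,
                             tendril_length = 8, tendril_radius = 1.8,
                             seed = carve_seed, relax_sweeps = carve_relax)
  cfg <- place_model_solute(cv$config,
                            data.frame(dx = 0, dy = 0, dz = 0, element = "C",
                                       radius = 3, group = "core"))
  list(config = cfg, truth = cv$truth)
}

# outward-oriented unit cube: 12 triangles
cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(x = c(0, edge), y = c(0, edge), z = c(0, edge)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0, normal -z
    c(5, 6, 7), c(6, 8, 7),   # z = 1, normal +z
    c(1, 2, 5), c(2, 6, 5),   # y = 0, normal -y
    c(3, 7, 4), c(4, 7, 8),   # y = 1, normal +y
    c(1, 5, 3), c(3, 5, 7),   # x = 0, normal -x
    c(2, 4, 6), c(4, 8, 6))   # x = 1, normal +x
  void_surface(v, f)
}

# independent all-pairs shortest path oracle (Floyd-Warshall on a weighted
# adjacency matrix; Inf where no edge)
floyd_warshall_diameter <- function(w) {
  n <- nrow(w)
  d <- w
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  max(d)
}

random_weighted_graph <- function(n, p_edge = 0.4) {
  repeat {
    w <- matrix(Inf, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        w[i, j] <- w[j, i] <- stats::runif(1, 0.5, 3)
      }
    }
    # spanning path guarantees connectivity
    for (i in seq_len(n - 1)) if (!is.finite(w[i, i + 1]))
      w[i, i + 1] <- w[i + 1, i] <- stats::runif(1, 0.5, 3)
    return(w)
  }
}

graph_from_weights <- function(w) {
  n <- nrow(w)
  el <- NULL; wt <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.finite(w[i, j])) { el <- rbind(el, c(i, j)); wt <- c(wt, w[i, j]) }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- wt
  g
}

# hand-built probe graph (for merge/host tests without a bath)
toy_probe_graph <- function(centers, radii, edges,
                            params = extraction_params(), box = c(50, 50, 50)) {
  structure(list(centers = as.matrix(centers), empty_radius = radii,
                 edges = edges, params = params, box = box,
                 periodic = FALSE, n_atoms = 0L),
            class = "probe_graph")
}

# independent best-subset oracle: enumerate subsets, standardized
# intercept-free lm() per LOO fold
oracle_best_subset <- function(tab, target, features) {
  y <- tab[[target]]
  n <- length(y)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  loo_mse <- function(feats) {
    X <- as.matrix(tab[, feats, drop = FALSE])
    pred <- numeric(n)
    for (kk in seq_len(n)) {
      tr <- setdiff(seq_len(n), kk)
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, psd)
      my <- mean(y[tr]); sy <- psd(y[tr])
      Z <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
      df <- as.data.frame(Z)
      df$..y <- (y[tr] - my) / sy
      fit <- stats::lm(..y ~ 0 + ., data = df)
      zt <- sweep(sweep(X[kk, , drop = FALSE], 2, mu), 2, sg, "/")
      pred[kk] <- sum(stats::coef(fit) * zt) * sy + my
    }
    mean((y - pred)^2)
  }
  subsets <- unlist(lapply(seq_along(features), function(k)
    utils::combn(sort(features), k, simplify = FALSE)), recursive = FALSE)
  subsets <- Filter(function(s) length(s) <= n - 3, subsets)
  scores <- vapply(subsets, loo_mse, numeric(1))
  sizes <- lengths(subsets)
  keys <- vapply(subsets, paste, "", collapse = ",")
  ord <- order(scores, sizes, keys)
  list(features = subsets[[ord[1]]], mse_loo = scores[ord[1]])
}
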