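# Internal helpers: seeding, periodic geometry, sphere sampling.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards (no global state leaks).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# wrap positions (n x 3) into [0, L) per dimension
wrap_positions <- function(x, box) {
  x <- as.matrix(x)
  for (k in 1:3) x[, k] <- x[, k] - box[k] * floor(x[, k] / box[k])
  x
}

# minimum-image displacement matrix a - b (both n x 3 or b 1 x 3)
min_image <- function(d, box) {
  d <- as.matrix(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# minimum-image distances from points (n x 3) to a single point
mi_dist <- function(pts, p, box = NULL) {
  d <- sweep(as.matrix(pts), 2, as.numeric(p))
  if (!is.null(box)) d <- min_image(d, box)
  sqrt(rowSums(d^2))
}

# signed distance to nearest sphere surface; box = NULL disables PBC
min_dist_to_spheres <- function(pts, centers, radii, box = NULL) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 3)
  centers <- matrix(as.numeric(as.matrix(centers)), ncol = 3)
  b <- if (is.null(box)) c(0, 0, 0) else as.numeric(box)
  .min_dist_to_spheres_cpp(pts, centers, as.numeric(radii), b)
}

# deterministic Fibonacci lattice on the unit sphere
fibonacci_sphere <- function(n) {
  n <- max(1L, as.integer(n))
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# deterministic sub-Angstrom jitter keyed to point index (degeneracy breaker
# for the Voronoi/Delaunay stage; amplitude 1e-6 Angstrom)
index_jitter <- function(n, amplitude = 1e-6) {
  i <- as.numeric(seq_len(n))
  frac <- function(x) x - floor(x)
  cbind(frac(i * 0.7548776662466927),
        frac(i * 0.5698402909980532),
        frac(i * 0.3279397621387067)) * 2 * amplitude - amplitude
}

# random unit vectors with pairwise angular separation >= floor_deg
separated_directions <- function(k, floor_deg = 60, max_tries = 5000) {
  cosmax <- cos(floor_deg * pi / 180)
  dirs <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(dirs) < k) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not sample ", k, " directions with pairwise separation >= ",
           floor_deg, " degrees")
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    if (nrow(dirs) == 0 || all(dirs %*% u < cosmax))
      dirs <- rbind(dirs, u)
  }
  dirs
}

# uniformly random 3D rotation matrix (Arvo's method via quaternion)
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# distance from points (n x 3) to a segment [a, b] (plain Euclidean)
dist_to_segment <- function(pts, a, b) {
  pts <- as.matrix(pts)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-20) return(mi_dist(pts, a))
  t <- pmin(1, pmax(0, (sweep(pts, 2, a) %*% ab) / len2))
  proj <- matrix(a, nrow(pts), 3, byrow = TRUE) + t %*% t(ab)
  sqrt(rowSums((pts - proj)^2))
}
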