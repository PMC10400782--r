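# Branch detection on the void surface (density-peak clustering of vertices
# far from the solute) and descriptor assembly.

#' Density-peak clustering (Rodriguez--Laio)
#'
#' Local density by a hard cutoff kernel at \code{dc} (self included);
#' \eqn{\delta_i} is the distance to the nearest point of strictly higher
#' density rank (ties broken by index, so the ordering is total and the
#' result deterministic); cluster centers are the candidates anomalously far
#' from any denser point (\eqn{\delta \ge} \code{delta_min}, default
#' \code{2 * dc}); every other point joins the cluster of its nearest
#' higher-ranked neighbor.
#'
#' @param pts n x 3 coordinate matrix.
#' @param dc Density cutoff distance.
#' @param delta_min Separation defining a cluster center (default
#'   \code{2 * dc}).
#' @param rho Optional externally supplied density (one value per point);
#'   the hard-cutoff kernel at \code{dc} is used when absent.
#' @return List with \code{cluster} (integer labels), \code{centers}
#'   (indices), \code{rho}, \code{delta}.
#' @export
density_peak_cluster <- function(pts, dc, delta_min = 2 * dc, rho = NULL) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n == 0) return(list(cluster = integer(0), centers = integer(0),
                          rho = numeric(0), delta = numeric(0)))
  if (n == 1) return(list(cluster = 1L, centers = 1L, rho = 1, delta = 0))
  d <- as.matrix(stats::dist(pts))
  if (is.null(rho)) rho <- rowSums(d <= dc)  # cutoff kernel, self included
  stopifnot(length(rho) == n)
  ord <- order(-rho, seq_len(n))  # total order: density desc, index asc
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  delta <- numeric(n)
  parent <- integer(n)
  for (k in 2:n) {
    i <- ord[k]
    higher <- ord[seq_len(k - 1)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]
    parent[i] <- j
  }
  top <- ord[1]
  delta[top] <- max(d[top, ])
  parent[top] <- 0L

  gamma <- rho * delta
  centers <- which(delta >= delta_min)
  if (length(centers) == 0) centers <- top  # one cluster at minimum
  centers <- centers[order(-gamma[centers], centers)]

  cluster <- integer(n)
  cluster[centers] <- seq_along(centers)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (cluster[i] == 0) cluster[i] <- cluster[parent[i]]
  }
  list(cluster = cluster, centers = centers, rho = rho, delta = delta)
}

#' Detect branches of a void surface
#'
#' For each surface vertex the height \eqn{h(v)} is its distance to the
#' nearest solute van der Waals sphere surface.  Vertices with
#' \eqn{h(v) >} \code{threshold} are branch candidates, partitioned into
#' branches by density-peak clustering; each branch's length is the maximum
#' height among its members.
#'
#' @param surface A \code{void_surface}.
#' @param solute Data frame of solute atoms (columns \code{x}, \code{y},
#'   \code{z}, \code{radius}) or a \code{solvated_configuration}.
#' @param threshold Candidate height cutoff in Angstrom (default 5).
#' @param dc Density-peak cutoff distance (default half the threshold).
#' @param delta_min Center-separation parameter passed to
#'   \code{\link{density_peak_cluster}}.
#'
#' The height field itself serves as the clustering density, so branch
#' centers are surface protrusion tips: candidates with no higher candidate
#' within \code{delta_min}.
#'
#' @return List of \code{branch} objects (fields \code{members} -- vertex
#'   ids, \code{peak} -- the highest-gamma member vertex, \code{length} in
#'   Angstrom), ordered by decreasing length; empty list when no vertex
#'   exceeds the threshold.
#' @export
detect_branches <- function(surface, solute, threshold = 5, dc = threshold / 2,
                            delta_min = 2 * dc) {
  stopifnot(inherits(surface, "void_surface"))
  if (inherits(solute, "solvated_configuration")) solute <- solute$solute
  if (is.null(solute) || nrow(solute) == 0)
    stop("solute atoms are required for branch detection")
  if (threshold <= 0) stop("threshold must be positive")
  h <- min_dist_to_spheres(surface$vertices,
                           as.matrix(solute[, c("x", "y", "z")]),
                           solute$radius, NULL)
  cand <- which(h > threshold)
  if (length(cand) == 0) return(list())
  pts <- surface$vertices[cand, , drop = FALSE]
  # the height field is the density: protrusion tips are density peaks, and
  # a center found at one threshold persists at every lower threshold, so
  # the branch count is non-increasing in the threshold
  cl <- density_peak_cluster(pts, dc, delta_min = delta_min, rho = h[cand])
  branches <- lapply(seq_along(cl$centers), function(k) {
    members <- cand[cl$cluster == k]
    structure(list(members = members,
                   peak = cand[cl$centers[k]],
                   length = max(h[members])),
              class = "branch")
  })
  branches[order(-vapply(branches, `[[`, 0, "length"))]
}

#' Assemble the void shape descriptors
#'
#' The eight shape variables: volume \code{V}, surface area \code{S},
#' longest surface geodesic \code{L}, branch count \code{nbr} and the
#' minimum/maximum/average/total branch lengths, plus the branch density
#' \code{nbr / n_heavy^(2/3)}.
#'
#' @param surface A \code{void_surface}.
#' @param branches List of branches from \code{\link{detect_branches}}.
#' @param n_heavy Number of solute heavy atoms (> 0).
#' @return A one-row data frame of class \code{void_descriptors}.
#' @export
summarize_descriptors <- function(surface, branches, n_heavy) {
  if (n_heavy <= 0) stop("n_heavy must be positive")
  vs <- compute_volume_area(surface)
  L <- longest_geodesic(surface)
  nbr <- length(branches)
  len <- vapply(branches, `[[`, 0, "length")
  d <- if (nbr >= 1) c(min(len), max(len), mean(len), sum(len))
       else c(0, 0, 0, 0)
  out <- data.frame(V = vs$V, S = vs$S, L = L, nbr = nbr,
                    dmin = d[1], dmax = d[2], dave = d[3], dtotal = d[4],
                    branch_density = nbr / n_heavy^(2 / 3),
                    n_heavy = as.integer(n_heavy))
  class(out) <- c("void_descriptors", class(out))
  out
}

#' Count surface facets nearest to a solute group
#'
#' Number of facets whose centroid has, as nearest solute atom, an atom of
#' the given group (ties break to the lowest atom index).
#'
#' @param surface A \code{void_surface}.
#' @param solute Solute atom table (or configuration) with a \code{group}
#'   column.
#' @param group Group label, e.g. \code{"N-term"}.
#' @return Integer facet count.
#' @export
count_facets_near_group <- function(surface, solute, group) {
  stopifnot(inherits(surface, "void_surface"))
  if (inherits(solute, "solvated_configuration")) solute <- solute$solute
  if (!group %in% solute$group)
    stop("unknown group: ", group)
  cent <- (surface$vertices[surface$faces[, 1], , drop = FALSE] +
           surface$vertices[surface$faces[, 2], , drop = FALSE] +
           surface$vertices[surface$faces[, 3], , drop = FALSE]) / 3
  near <- .nearest_center_cpp(cent, as.matrix(solute[, c("x", "y", "z")]))
  sum(solute$group[near] == group)
}

#' Average descriptors across frames
#'
#' Arithmetic mean and standard error of each descriptor over the frames of
#' one system.
#'
#' @param per_frame List of (or data frame stacking) per-frame
#'   \code{void_descriptors} rows.
#' @return One-row data frame of means with attached \code{"se"} attribute
#'   (named vector of standard errors).
#' @export
aggregate_frames <- function(per_frame) {
  if (is.data.frame(per_frame)) tab <- per_frame
  else {
    if (length(per_frame) == 0) stop("no frames to aggregate")
    tab <- do.call(rbind, per_frame)
  }
  if (nrow(tab) == 0) stop("no frames to aggregate")
  num <- vapply(tab, is.numeric, logical(1))
  mu <- as.data.frame(lapply(tab[num], mean))
  se <- vapply(tab[num], function(x)
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0, numeric(1))
  attr(mu, "se") <- se
  attr(mu, "n_frames") <- nrow(tab)
  mu
}
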