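# Void surface reconstruction: alpha complex of points sampled on (and
# inside) the probe-sphere union, outer boundary extraction, and the
# weighted surface graph.

# unwrap the probes of one void across periodic boundaries by BFS over the
# bottleneck-passing edges, so the surface is built in a contiguous frame
unwrap_void_probes <- function(graph, void) {
  ids <- void$probe_ids
  centers <- graph$centers[ids, , drop = FALSE]
  if (!graph$periodic || length(ids) == 1) return(centers)
  box <- graph$box
  pass <- graph$edges[graph$edges$bottleneck >= graph$params$bottleneck_radius, ,
                      drop = FALSE]
  sel <- pass$i %in% ids & pass$j %in% ids
  pass <- pass[sel, , drop = FALSE]
  local_id <- integer(nrow(graph$centers))
  local_id[ids] <- seq_along(ids)
  adj <- vector("list", length(ids))
  for (r in seq_len(nrow(pass))) {
    a <- local_id[pass$i[r]]; b <- local_id[pass$j[r]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- centers
  seen <- logical(length(ids))
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!seen[nb]) {
        d <- min_image(matrix(centers[nb, ] - out[cur, ], 1, 3), box)
        out[nb, ] <- out[cur, ] + d
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  out
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

signed_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

face_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Construct a void surface mesh from raw geometry
#'
#' Low-level constructor used by \code{\link{build_surface}} and by tests
#' that supply hand-built meshes.
#'
#' @param vertices n x 3 matrix of vertex positions (Angstrom).
#' @param faces m x 3 integer matrix of vertex indices, outward oriented.
#' @param check Verify the every-edge-has-two-facets (watertight) invariant.
#' @return A \code{void_surface} object.
#' @export
void_surface <- function(vertices, faces, check = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (check) {
    cnt <- table(face_edge_keys(faces))
    if (any(cnt != 2))
      stop("surface is not watertight: ", sum(cnt != 2),
           " edge(s) not shared by exactly two facets")
  }
  g <- surface_graph(vertices, faces)
  structure(list(vertices = vertices, faces = faces, graph = g),
            class = "void_surface")
}

# weighted graph over mesh vertices: edges of the triangulation with
# Euclidean lengths
surface_graph <- function(vertices, faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  w <- sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                     vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(nrow(vertices), directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  igraph::E(g)$weight <- w
  g
}

#' Build the alpha-shape surface of a void
#'
#' Samples points on each probe sphere's surface (deterministic Fibonacci
#' lattice, about one point per \code{sample_area} of sphere area, points
#' interior to other probes discarded), adds an interior support lattice so
#' the alpha complex is solid, tessellates, keeps tetrahedra with
#' circumradius at most \code{alpha}, selects the largest connected block,
#' and returns its outer boundary as a watertight outward-oriented mesh with
#' its weighted surface graph.
#'
#' @param void A \code{void} from \code{\link{merge_probes}}.
#' @param graph The \code{probe_graph} the void indexes into.
#' @param alpha Alpha-ball radius in Angstrom; default
#'   \code{alpha_factor * probe_radius}.
#' @param alpha_factor Multiplier applied to the probe radius when
#'   \code{alpha} is not given (default 2).
#' @param sample_area Sphere-surface area per sample point (A^2, default 0.8).
#' @param jitter Deterministic position jitter breaking cosphericality (A).
#' @param smooth_iter Taubin lambda/mu smoothing passes applied to the final
#'   mesh (volume-preserving removal of sampling-scale surface texture;
#'   0 disables).
#' @param interior_lattice Add the interior support lattice (default TRUE;
#'   disabling it leaves a hollow complex and is mainly useful for testing
#'   degenerate inputs).
#'
#' @return A \code{void_surface}: \code{vertices}, \code{faces} (outward),
#'   \code{graph}, plus \code{alpha} and shell diagnostics.
#' @export
build_surface <- function(void, graph, alpha = NULL, alpha_factor = 2,
                          sample_area = 0.8, jitter = 0.02,
                          smooth_iter = 10, interior_lattice = TRUE) {
  stopifnot(inherits(void, "void"), inherits(graph, "probe_graph"))
  alpha <- alpha %||% (alpha_factor * graph$params$probe_radius)
  centers <- unwrap_void_probes(graph, void)
  radii <- graph$empty_radius[void$probe_ids]
  if (nrow(centers) < 1) stop("empty void")

  # surface samples
  pts_list <- lapply(seq_len(nrow(centers)), function(i) {
    ni <- max(12L, as.integer(round(4 * pi * radii[i]^2 / sample_area)))
    sweep(fibonacci_sphere(ni) * radii[i], 2, centers[i, ], "+")
  })
  surf <- do.call(rbind, pts_list)
  # drop points strictly interior to any probe (own sphere contributes 0)
  dmin <- min_dist_to_spheres(surf, centers, radii, NULL)
  surf <- surf[dmin > -0.05, , drop = FALSE]

  # interior support lattice (keeps the alpha complex solid)
  h <- max(0.7 * alpha, 0.4)
  lat <- matrix(numeric(0), 0, 3)
  if (interior_lattice) {
    lo <- apply(centers - radii, 2, min)
    hi <- apply(centers + radii, 2, max)
    gx <- seq(lo[1], hi[1], by = h)
    gy <- seq(lo[2], hi[2], by = h)
    gz <- seq(lo[3], hi[3], by = h)
    lat <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    dl <- min_dist_to_spheres(lat, centers, radii, NULL)
    lat <- lat[dl < -0.3 * h, , drop = FALSE]
  }
  pts <- rbind(surf, lat, centers)
  # jitter large enough to break cosphericality decisively for the
  # tessellation's floating-point predicates, far below mesh resolution
  pts <- pts + index_jitter(nrow(pts), jitter)
  if (nrow(pts) < 4) stop("degenerate surface: fewer than 4 sample points")

  tess <- .delaunay3d_cpp(pts)
  kept <- which(tess$circumradius <= alpha)
  if (length(kept) == 0)
    stop("degenerate surface: alpha complex is empty (alpha = ", alpha, ")")
  in_kept <- logical(nrow(tess$tets))
  in_kept[kept] <- TRUE

  # largest face-connected block of kept tetrahedra
  nb <- tess$neighbors
  ei <- rep(kept, 4)
  ej <- as.vector(nb[kept, ])
  ok <- ej > 0 & in_kept[pmax(ej, 1)] & ei < ej
  map <- integer(nrow(tess$tets))
  map[kept] <- seq_along(kept)
  g <- igraph::make_empty_graph(length(kept), directed = FALSE)
  if (any(ok)) g <- igraph::add_edges(g, rbind(map[ei[ok]], map[ej[ok]]))
  comp <- igraph::components(g)
  tet_vol <- tet_volumes(pts, tess$tets[kept, , drop = FALSE])
  main <- which.max(vapply(seq_len(comp$no), function(k)
    sum(tet_vol[comp$membership == k]), numeric(1)))
  sel <- kept[comp$membership == main]

  res <- boundary_faces(tess, sel, pts)
  faces <- res$faces
  # repair: iteratively drop selected tets incident to non-manifold
  # boundary edges (sliver pinches)
  for (pass in 1:12) {
    bad <- nonmanifold_edges(faces)
    if (length(bad) == 0) break
    drop_tet <- tets_with_edges(tess$tets[sel, , drop = FALSE], bad)
    if (!any(drop_tet) || all(drop_tet)) break
    sel <- sel[!drop_tet]
    res <- boundary_faces(tess, sel, pts)
    faces <- res$faces
  }
  bad <- nonmanifold_edges(faces)
  if (length(bad) > 0)
    stop("surface-construction error: ", length(bad),
         " non-manifold edge(s) remain after repair")

  # split boundary into shells; keep the one of largest |signed volume|
  shells <- face_shells(faces)
  n_shells <- max(shells)
  if (n_shells > 1) {
    sv <- vapply(seq_len(n_shells), function(s)
      abs(signed_volume(pts, faces[shells == s, , drop = FALSE])), numeric(1))
    faces <- faces[shells == which.max(sv), , drop = FALSE]
  }

  # quality gate: the reconstruction must at least account for the largest
  # probe sphere, else the alpha complex failed to span the void
  v_mesh <- abs(signed_volume(pts, faces))
  if (v_mesh < 0.5 * 4 / 3 * pi * max(radii)^3)
    stop("degenerate surface: reconstructed volume ", round(v_mesh, 2),
         " A^3 cannot account for the largest probe (alpha too small?)")

  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(pts))
  remap[used] <- seq_along(used)
  vertices <- pts[used, , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3)

  if (smooth_iter > 0)
    vertices <- taubin_smooth(vertices, faces, smooth_iter)
  out <- void_surface(vertices, faces, check = TRUE)
  out$alpha <- alpha
  out$n_shells <- n_shells
  out
}

# Taubin lambda|mu mesh smoothing: alternating positive/negative Laplacian
# steps remove sampling-scale texture with negligible shrinkage
taubin_smooth <- function(vertices, faces, iterations = 10,
                          lambda = 0.5, mu = -0.53) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  n <- nrow(vertices)
  deg <- tabulate(c(e[, 1], e[, 2]), n)
  idx <- c(e[, 1], e[, 2])
  nbr <- c(e[, 2], e[, 1])
  step <- function(v, w) {
    # every mesh vertex occurs in idx, so rowsum rows align with 1..n
    nb_sum <- rowsum(v[nbr, , drop = FALSE], idx)
    lap <- nb_sum / pmax(deg, 1) - v
    v + w * lap
  }
  v <- vertices
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  v
}

tet_volumes <- function(pts, tets) {
  a <- pts[tets[, 1], , drop = FALSE]
  b <- pts[tets[, 2], , drop = FALSE] - a
  c_ <- pts[tets[, 3], , drop = FALSE] - a
  d <- pts[tets[, 4], , drop = FALSE] - a
  abs(b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
      b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
      b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# outward-oriented boundary faces of a set of tetrahedra
boundary_faces <- function(tess, sel, pts) {
  in_sel <- logical(nrow(tess$tets))
  in_sel[sel] <- TRUE
  faces <- NULL
  for (j in 1:4) {
    nb <- tess$neighbors[sel, j]
    is_b <- nb == 0 | !in_sel[pmax(nb, 1)]
    if (!any(is_b)) next
    t <- tess$tets[sel[is_b], , drop = FALSE]
    opp <- t[, j]
    f <- t[, -j, drop = FALSE]
    # orient: normal away from the opposite (interior-side) vertex
    a <- pts[f[, 1], , drop = FALSE]
    u <- pts[f[, 2], , drop = FALSE] - a
    v <- pts[f[, 3], , drop = FALSE] - a
    w <- pts[opp, , drop = FALSE] - a
    trip <- u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
            u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
            u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])
    flip <- trip > 0
    f[flip, ] <- f[flip, c(1, 3, 2), drop = FALSE]
    faces <- rbind(faces, f)
  }
  list(faces = faces)
}

nonmanifold_edges <- function(faces) {
  cnt <- table(face_edge_keys(faces))
  names(cnt)[cnt != 2]
}

tets_with_edges <- function(tets, edge_keys) {
  pairs <- utils::combn(4, 2)
  hit <- logical(nrow(tets))
  for (k in seq_len(ncol(pairs))) {
    a <- tets[, pairs[1, k]]; b <- tets[, pairs[2, k]]
    hit <- hit | paste(pmin(a, b), pmax(a, b)) %in% edge_keys
  }
  hit
}

# connected shells of boundary faces (faces sharing an edge)
face_shells <- function(faces) {
  keys <- face_edge_keys(faces)
  m <- nrow(faces)
  fid <- rep(seq_len(m), 3)
  by_edge <- split(fid, keys)
  el <- do.call(rbind, lapply(by_edge, function(v)
    if (length(v) == 2) v else NULL))
  g <- igraph::make_empty_graph(m, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  igraph::components(g)$membership
}

#' Volume and surface area of a watertight mesh
#'
#' Volume by the signed-tetrahedron (divergence) sum over facets, area by
#' the triangle-area sum.  A globally inward orientation is detected by the
#' sign of the volume and corrected.
#'
#' @param surface A \code{void_surface}.
#' @return List with \code{V} (A^3) and \code{S} (A^2).
#' @export
compute_volume_area <- function(surface) {
  stopifnot(inherits(surface, "void_surface"))
  cnt <- table(face_edge_keys(surface$faces))
  if (any(cnt != 2)) stop("mesh is not watertight")
  V <- signed_volume(surface$vertices, surface$faces)
  if (V < 0) V <- -V
  S <- sum(triangle_areas(surface$vertices, surface$faces))
  list(V = V, S = S)
}

#' Longest surface geodesic (weighted graph diameter)
#'
#' The maximum over vertex pairs of the shortest-path distance along the
#' edge-weighted surface graph.
#'
#' @param surface A \code{void_surface} (or an igraph with edge weights).
#' @return Length in Angstrom.
#' @export
longest_geodesic <- function(surface) {
  g <- if (inherits(surface, "void_surface")) surface$graph else surface
  if (!igraph::is_connected(g))
    stop("surface graph is disconnected")
  igraph::diameter(g, directed = FALSE, unconnected = FALSE,
                   weights = igraph::E(g)$weight)
}

#' Triangulated icosphere
#'
#' Subdivided icosahedron mesh of a sphere; handy as an analytic reference
#' surface (volume, area, great-circle geodesics).
#'
#' @param radius Sphere radius.
#' @param subdivisions Number of 4-to-1 triangle subdivisions (default 3).
#' @param center Sphere center (length 3).
#' @return A \code{void_surface}.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    nf <- matrix(0L, 0, 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- mget(key, envir = mid_cache, ifnotfound = NA)[[1]]
      if (!is.na(got)) return(got)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      id <- nrow(v)
      assign(key, id, envir = mid_cache)
      id
    }
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c_ <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  v <- sweep(v * radius, 2, center, "+")
  void_surface(v, f)
}
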