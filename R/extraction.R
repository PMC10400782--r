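# Void extraction: Voronoi probe spheres of the solvent sphere ensemble,
# bottleneck-gated merging into voids, host selection, and an independent
# grid flood-fill oracle.

#' Cavity-extraction parameters
#'
#' Defaults follow the established cavity-analysis convention: probe radius
#' 1.2 Angstrom, bottleneck radius 1.1 Angstrom.
#'
#' @param probe_radius Minimum empty radius for a retained probe sphere (A).
#' @param bottleneck_radius Minimum passage radius merging two probes (A).
#' @param pbc_shell Image-replication margin for the periodic tessellation (A).
#'
#' @return An \code{extraction_params} list.
#' @export
extraction_params <- function(probe_radius = 1.2, bottleneck_radius = 1.1,
                              pbc_shell = 6) {
  if (probe_radius <= 0 || bottleneck_radius <= 0)
    stop("radii must be positive")
  if (bottleneck_radius > probe_radius)
    stop("bottleneck_radius must not exceed probe_radius")
  structure(list(probe_radius = probe_radius,
                 bottleneck_radius = bottleneck_radius,
                 pbc_shell = pbc_shell),
            class = "extraction_params")
}

# replicate atoms within `shell` of each face by the 26 image translations
replicate_pbc <- function(xyz, box, shell) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  out_pos <- list(xyz)
  out_idx <- list(seq_len(n))
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    if (all(sh == 0)) next
    img <- sweep(xyz, 2, sh * box, "+")
    keep <- img[, 1] > -shell & img[, 1] < box[1] + shell &
            img[, 2] > -shell & img[, 2] < box[2] + shell &
            img[, 3] > -shell & img[, 3] < box[3] + shell
    if (any(keep)) {
      out_pos[[length(out_pos) + 1]] <- img[keep, , drop = FALSE]
      out_idx[[length(out_idx) + 1]] <- which(keep)
    }
  }
  list(pos = do.call(rbind, out_pos), idx = unlist(out_idx))
}

#' Compute Voronoi probe spheres of a solvent configuration
#'
#' Tessellates the solvent atom centers (replicated across periodic images
#' within \code{pbc_shell} of each face), takes the Voronoi vertices
#' (circumcenters of the Delaunay tetrahedra), assigns each vertex its empty
#' radius (distance to the nearest atom sphere surface, minimum image), and
#' keeps vertices with empty radius at least \code{probe_radius} lying in the
#' primary cell.  Edges join probes whose tetrahedra share a facet; each edge
#' carries a bottleneck, the minimum empty radius sampled at the two vertices
#' and the edge midpoint.
#'
#' The solute must already be absent: only \code{config$solvent} enters the
#' tessellation (the stored solute, if any, is ignored here and used later
#' for host selection).
#'
#' @param config A \code{\link{solvated_configuration}}.
#' @param params An \code{\link{extraction_params}} object.
#' @param periodic Use periodic boundaries (default TRUE).  With
#'   \code{FALSE} the tessellation is open-boundary and all finite Voronoi
#'   vertices are candidates.
#'
#' @return A \code{probe_graph}: list with \code{centers} (n x 3),
#'   \code{empty_radius}, \code{edges} (data frame \code{i}, \code{j},
#'   \code{bottleneck}), \code{params}, \code{box}, \code{periodic}.
#' @export
compute_probe_spheres <- function(config, params = extraction_params(),
                                  periodic = TRUE) {
  stopifnot(inherits(config, "solvated_configuration"))
  atoms <- config$solvent
  if (nrow(atoms) < 4) stop("need at least 4 solvent atoms")
  box <- config$box
  xyz <- solvent_xyz(config)
  radii <- atoms$radius
  # deterministic jitter keyed to atom index breaks cospherical degeneracies
  xyz_j <- xyz + index_jitter(nrow(xyz))

  if (periodic) {
    rep_ <- replicate_pbc(xyz_j, box, params$pbc_shell)
    pts <- rep_$pos
  } else {
    pts <- xyz_j
  }
  tess <- .delaunay3d_cpp(pts)
  cc <- tess$circumcenter
  if (nrow(cc) == 0) stop("degenerate tessellation: no finite tetrahedra")

  dist_box <- if (periodic) box else NULL
  empty_all <- min_dist_to_spheres(cc, xyz_j, radii, dist_box)

  in_cell <- if (periodic) {
    cc[, 1] >= 0 & cc[, 1] < box[1] & cc[, 2] >= 0 & cc[, 2] < box[2] &
      cc[, 3] >= 0 & cc[, 3] < box[3]
  } else rep(TRUE, nrow(cc))
  keep <- in_cell & empty_all >= params$probe_radius
  keep_id <- which(keep)
  new_id <- integer(nrow(cc))
  new_id[keep_id] <- seq_along(keep_id)

  centers <- cc[keep_id, , drop = FALSE]
  empty <- empty_all[keep_id]

  # candidate edges: facet-adjacent tetrahedra
  nb <- tess$neighbors
  m <- nrow(nb)
  ei <- rep(seq_len(m), 4)
  ej <- as.vector(nb)
  ok <- ej > 0 & ei < ej
  ei <- ei[ok]; ej <- ej[ok]
  # at least one endpoint retained in the primary cell
  ok2 <- keep[ei] | keep[ej]
  ei <- ei[ok2]; ej <- ej[ok2]

  edges <- data.frame(i = integer(), j = integer(), bottleneck = numeric())
  if (length(ei) > 0) {
    mid <- (cc[ei, , drop = FALSE] + cc[ej, , drop = FALSE]) / 2
    bmid <- min_dist_to_spheres(mid, xyz_j, radii, dist_box)
    bneck <- pmin(empty_all[ei], empty_all[ej], bmid)
    a <- new_id[ei]
    b <- new_id[ej]
    if (periodic) {
      # endpoints outside the primary cell are images of retained probes:
      # map them back by wrapped-position matching
      fix <- function(ids, raw) {
        missing <- ids == 0
        if (any(missing)) {
          w <- wrap_positions(cc[raw[missing], , drop = FALSE], box)
          near <- .nearest_center_cpp(w, centers)
          d <- sqrt(rowSums((w - centers[near, , drop = FALSE])^2))
          ids[missing] <- ifelse(d < 1e-4, near, 0L)
        }
        ids
      }
      a <- fix(a, ei)
      b <- fix(b, ej)
    }
    val <- a > 0 & b > 0 & a != b
    if (any(val)) {
      lo <- pmin(a[val], b[val]); hi <- pmax(a[val], b[val])
      bn <- bneck[val]
      key <- paste(lo, hi)
      first <- !duplicated(key)
      # duplicates across images: keep the larger bottleneck estimate
      bn_by <- tapply(bn, key, max)
      edges <- data.frame(i = lo[first], j = hi[first],
                          bottleneck = as.numeric(bn_by[key[first]]))
      edges <- edges[order(edges$i, edges$j), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }

  structure(list(centers = centers, empty_radius = empty, edges = edges,
                 params = params, box = box, periodic = periodic,
                 n_atoms = nrow(atoms)),
            class = "probe_graph")
}

#' @export
print.probe_graph <- function(x, ...) {
  cat(sprintf("Probe graph: %d probe spheres, %d edges (probe %.2f A, bottleneck %.2f A)\n",
              nrow(x$centers), nrow(x$edges),
              x$params$probe_radius, x$params$bottleneck_radius))
  invisible(x)
}

#' Merge probe spheres into voids
#'
#' Connected components of the probe graph restricted to edges whose
#' bottleneck is at least \code{bottleneck_radius}.
#'
#' @param graph A \code{probe_graph}.
#' @param params An \code{\link{extraction_params}} (defaults taken from the
#'   graph when omitted).
#'
#' @return List of \code{void} objects (fields \code{probe_ids},
#'   \code{component_id}, \code{host}), ordered by decreasing probe count.
#' @export
merge_probes <- function(graph, params = NULL) {
  stopifnot(inherits(graph, "probe_graph"))
  params <- params %||% graph$params
  n <- nrow(graph$centers)
  if (n == 0) return(list())
  pass <- graph$edges[graph$edges$bottleneck >= params$bottleneck_radius, ,
                      drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(pass) > 0)
    g <- igraph::add_edges(g, rbind(pass$i, pass$j))
  comp <- igraph::components(g)
  ord <- order(-comp$csize, seq_along(comp$csize))
  rank <- integer(comp$no)
  rank[ord] <- seq_len(comp$no)
  lapply(seq_len(comp$no), function(k) {
    cid <- ord[k]
    structure(list(probe_ids = which(comp$membership == cid),
                   component_id = k, host = FALSE),
              class = "void")
  })
}

# Monte-Carlo samples uniform on the union of spheres, each sample carrying
# weight 1/multiplicity; returns points and total reference volume
sample_sphere_union <- function(centers, radii, n_samples) {
  vols <- 4 / 3 * pi * radii^3
  pick <- sample.int(length(radii), n_samples, replace = TRUE,
                     prob = vols / sum(vols))
  u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rr <- radii[pick] * stats::runif(n_samples)^(1 / 3)
  pts <- centers[pick, , drop = FALSE] + u * rr
  # multiplicity = number of spheres containing each point
  mult <- rep(0L, n_samples)
  for (j in seq_along(radii)) {
    d <- mi_dist(pts, centers[j, ])
    mult <- mult + (d <= radii[j] + 1e-12)
  }
  list(pts = pts, weight = 1 / pmax(1L, mult), total = sum(vols))
}

#' Select the void hosting the solute
#'
#' Estimates, by fixed-seed Monte-Carlo sampling of the solute van der Waals
#' sphere union, the overlap volume between each void's probe-sphere union
#' and the solute, and returns the void with maximal overlap.  Ties within
#' Monte-Carlo error break to the smaller component id (logged).
#'
#' @param voids List of voids from \code{\link{merge_probes}}.
#' @param config The configuration holding the solute atoms.
#' @param graph The \code{probe_graph} the voids index into.
#' @param n_samples Monte-Carlo sample count (default 20000).
#'
#' @return The selected void with \code{host = TRUE}, or \code{NULL} when
#'   every overlap is zero (or there is no solute / no void).
#' @export
select_host_void <- function(voids, config, graph, n_samples = 20000) {
  if (length(voids) == 0) return(NULL)
  sol <- config$solute
  if (is.null(sol) || nrow(sol) == 0) return(NULL)
  with_seed(76543L, {
    smp <- sample_sphere_union(solute_xyz(config), sol$radius, n_samples)
    overlap <- vapply(voids, function(v) {
      ctr <- graph$centers[v$probe_ids, , drop = FALSE]
      rad <- graph$empty_radius[v$probe_ids]
      dmin <- min_dist_to_spheres(smp$pts, ctr, rad,
                                  if (graph$periodic) graph$box else NULL)
      sum(smp$weight[dmin < 0]) / n_samples * smp$total
    }, numeric(1))
    if (all(overlap <= 0)) return(NULL)
    se <- smp$total / sqrt(n_samples)
    best <- max(overlap)
    cand <- which(overlap > best - 2 * se)
    if (length(cand) > 1)
      message("host-void overlap tie within MC error; choosing smallest component id")
    sel <- cand[which.min(vapply(voids[cand], `[[`, 0, "component_id"))]
    host <- voids[[sel]]
    host$host <- TRUE
    host$overlap_volume <- overlap[sel]
    host
  })
}

#' Extract the host void in one call
#'
#' Convenience wrapper: probe spheres, bottleneck merging, host selection.
#'
#' @inheritParams compute_probe_spheres
#' @return List with \code{graph}, \code{voids}, \code{host} (may be NULL).
#' @export
extract_host_void <- function(config, params = extraction_params(),
                              periodic = TRUE) {
  graph <- compute_probe_spheres(config, params, periodic)
  voids <- merge_probes(graph, params)
  host <- select_host_void(voids, config, graph)
  list(graph = graph, voids = voids, host = host)
}

#' Brute-force grid cavity oracle
#'
#' Independent check of the Voronoi construction: marks grid cells whose
#' center keeps a distance of at least \code{probe_radius} from every solvent
#' atom sphere surface (the probe-center accessible region), labels
#' 26-connected components (periodic wrap), and dilates each component by the
#' probe radius, yielding the volume swept by admissible probe spheres --
#' the quantity comparable to the probe-union / alpha-shape volume.
#'
#' @param config A \code{\link{solvated_configuration}} (solvent only enters).
#' @param params An \code{\link{extraction_params}}; the oracle gates
#'   connectivity at \code{probe_radius}.
#' @param cell Grid spacing in Angstrom (<= 0.5 recommended).
#' @param periodic Periodic grid (default TRUE).
#'
#' @return A \code{grid_cavity} object: \code{n_components},
#'   \code{volume} (dilated, per component), \code{eroded_volume},
#'   label arrays and grid metadata.
#' @export
grid_cavity_oracle <- function(config, params = extraction_params(),
                               cell = 0.4, periodic = TRUE) {
  stopifnot(inherits(config, "solvated_configuration"))
  if (cell <= 0) stop("cell must be positive")
  atoms <- config$solvent
  res <- .grid_cavity_cpp(solvent_xyz(config), atoms$radius, config$box,
                          params$probe_radius, cell, periodic)
  structure(list(n_components = res$n_components,
                 volume = res$dilated_volume,
                 eroded_volume = res$eroded_volume,
                 dims = res$dims, cell_size = res$cell_size,
                 label = res$label, dilated_label = res$dilated_label,
                 box = config$box),
            class = "grid_cavity")
}

#' Component label of the oracle at a point
#'
#' @param oracle A \code{grid_cavity} from \code{\link{grid_cavity_oracle}}.
#' @param point Length-3 position (Angstrom).
#' @param dilated Query the dilated labels (default) or the eroded region.
#' @return Integer component label (0 = not in any cavity).
#' @export
oracle_component_at <- function(oracle, point, dilated = TRUE) {
  p <- wrap_positions(matrix(as.numeric(point), 1, 3), oracle$box)
  ix <- pmin(oracle$dims, pmax(1, ceiling(p / oracle$cell_size)))
  idx <- ((ix[1] - 1) * oracle$dims[2] + (ix[2] - 1)) * oracle$dims[3] +
    ix[3]
  if (dilated) oracle$dilated_label[idx] else oracle$label[idx]
}
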