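# Synthetic-data module: water-like baths, phantom cavities with analytic
# ground truth, and linear-model fixtures.  Every generator takes an explicit
# seed and leaves the caller's RNG state untouched.

# rigid 3-site water geometry (Angstrom / degrees)
WATER_OH <- 0.9572
WATER_HOH <- 104.52

#' Generate a water-like solvent bath
#'
#' Places rigid 3-site waters (one O, two H at the experimental gas-phase
#' geometry, random orientation) by random sequential insertion under a
#' minimum-image oxygen--oxygen hard-core constraint.  The result emulates
#' the sphere-packing statistics relevant for cavity geometry, not water
#' energetics.
#'
#' @param box_side Cubic box edge length in Angstrom (> 10).
#' @param number_density Target molecular density in molecules/nm^3
#'   (ambient water is about 33.4).
#' After insertion the oxygen packing is homogenized by a zero-temperature
#' quench of harmonic soft spheres (diameter \code{sigma}, the effective
#' Lennard-Jones size of water): without it a purely random packing keeps
#' large percolating interstitial voids that ambient water does not have.
#'
#' @param seed Integer seed; identical seeds give identical configurations.
#' @param hardcore Minimum O--O distance in Angstrom (default 2.6,
#'   an approximate first-peak exclusion distance).
#' @param sigma Soft-sphere diameter for the relaxation quench (A,
#'   default 3.1); \code{relax_sweeps = 0} disables relaxation.
#' @param relax_sweeps Quench sweeps over all molecules (default 60).
#' @param frame_id Frame identifier stored in the configuration.
#'
#' @return A \code{\link{solvated_configuration}} with no solute.
#' @export
generate_water_bath <- function(box_side, number_density = 33.4, seed = 1L,
                                hardcore = 2.6, sigma = 3.1,
                                relax_sweeps = 60, frame_id = 1L) {
  stopifnot(is.numeric(box_side), length(box_side) == 1)
  if (box_side <= 10) stop("box_side must exceed 10 Angstrom")
  if (number_density <= 10 || number_density >= 40)
    stop("number_density must lie in (10, 40) molecules/nm^3")
  box <- rep(box_side, 3)
  vol_nm3 <- prod(box / 10)
  n_target <- round(number_density * vol_nm3)
  with_seed(seed, {
    opos <- .rsa_insert_cpp(box, as.integer(n_target), hardcore,
                            as.integer(500 * n_target + 1000))
    if (nrow(opos) < 0.95 * n_target)
      stop(sprintf(
        "density infeasible: placed %d of %d waters at hard core %.2f A",
        nrow(opos), n_target, hardcore))
    if (relax_sweeps > 0)
      opos <- .relax_quench_cpp(opos, box, sigma, 0.35,
                                as.integer(relax_sweeps))
    n <- nrow(opos)
    # two hydrogens per oxygen: base geometry rotated by a random rotation
    half <- WATER_HOH / 2 * pi / 180
    base <- rbind(c(sin(half), 0, cos(half)) * WATER_OH,
                  c(-sin(half), 0, cos(half)) * WATER_OH)
    hx <- matrix(0, 2 * n, 3)
    for (i in seq_len(n)) {
      R <- random_rotation()
      hx[2 * i - 1, ] <- opos[i, ] + base[1, ] %*% t(R)
      hx[2 * i, ] <- opos[i, ] + base[2, ] %*% t(R)
    }
    solvent <- data.frame(
      element = c(rep("O", n), rep("H", 2 * n)),
      x = c(opos[, 1], hx[, 1]), y = c(opos[, 2], hx[, 2]),
      z = c(opos[, 3], hx[, 3]),
      radius = c(rep(VDW_RADII[["O"]], n), rep(VDW_RADII[["H"]], 2 * n)),
      mol = c(seq_len(n), rep(seq_len(n), each = 2)),
      stringsAsFactors = FALSE)
    # keep atoms of one molecule contiguous, O first
    solvent <- solvent[order(solvent$mol, solvent$element != "O"), ]
    rownames(solvent) <- NULL
    solvated_configuration(box, solvent, frame_id = frame_id)
  })
}

# membership test of the phantom region: distance of points to the region
# boundary <= 0 means inside.  Returns, for atom spheres, whether the sphere
# intersects the region.
phantom_region <- function(kind, center, core_radius, dirs = NULL,
                           tendril_length = 0, tendril_radius = 0) {
  force(kind); force(center); force(core_radius)
  # distance from points to the region (negative inside), plain Euclidean
  function(pts, box = NULL) {
    d <- mi_dist(pts, center, box) - core_radius
    if (!is.null(dirs) && nrow(dirs) > 0 && tendril_length > 0) {
      # capsule axes start at the center and end so that the spherical cap
      # surface reaches core_radius + tendril_length from the center
      reach <- core_radius + tendril_length - tendril_radius
      disp <- sweep(as.matrix(pts), 2, as.numeric(center))
      if (!is.null(box)) disp <- min_image(disp, box)
      for (j in seq_len(nrow(dirs))) {
        dj <- dist_to_segment(disp, c(0, 0, 0), reach * dirs[j, ]) -
          tendril_radius
        d <- pmin(d, dj)
      }
    }
    d
  }
}

#' Carve a phantom cavity of known geometry into a bath
#'
#' Removes every water molecule having at least one atom sphere intersecting
#' a spherical or star-shaped (core sphere plus capsule tendrils) region, and
#' records the analytic ground truth of the carved region.  Star tendril
#' directions are sampled with a pairwise angular separation floor so
#' tendrils do not merge; \code{tendril_length} is the reach of the tendril
#' cap surface beyond the core surface.
#'
#' @param config A \code{\link{solvated_configuration}}.
#' @param kind \code{"sphere"} or \code{"star"}.
#' @param center Cavity center (Angstrom, length 3); default box center.
#' @param core_radius Core sphere radius (Angstrom); 0 carves nothing.
#' @param n_tendrils,tendril_length,tendril_radius Star parameters (ignored
#'   for spheres).
#' After removal, the kept waters are packed to contact with the carved
#' boundary by a seeded zero-temperature rigid-molecule quench (harmonic
#' wall at the region boundary plus the O--O soft-sphere term), emulating an
#' equilibrated first solvation shell; without it the cavity is about one
#' molecular layer larger than the nominal region.  Set
#' \code{relax_sweeps = 0} to keep the raw carve.
#'
#' @param seed Integer seed (tendril directions, relaxation, Monte-Carlo
#'   volume).
#' @param min_separation_deg Pairwise angular floor between tendril
#'   directions (degrees).
#' @param relax_sweeps Boundary-relaxation sweeps (default 200).
#' @param mc_samples Monte-Carlo samples for the star union volume
#'   (at least 1e6 by default; the standard error is recorded).
#'
#' @return List with elements \code{config} (carved configuration) and
#'   \code{truth} (a \code{phantom_truth}: kind, analytic volume and area,
#'   true branch count, tendril length, tendril directions, MC error).
#' @export
carve_phantom_cavity <- function(config, kind = c("sphere", "star"),
                                 center = NULL, core_radius = 6,
                                 n_tendrils = 4, tendril_length = 8,
                                 tendril_radius = 1.8, seed = 1L,
                                 min_separation_deg = 60, relax_sweeps = 200,
                                 mc_samples = 1e6) {
  kind <- match.arg(kind)
  stopifnot(inherits(config, "solvated_configuration"))
  if (is.null(center)) center <- config$box / 2
  center <- as.numeric(center)
  if (core_radius < 0) stop("core_radius must be >= 0")
  reach <- if (kind == "star") core_radius + tendril_length else core_radius
  if (any(center - reach < 0) || any(center + reach > config$box))
    stop("carved region exceeds the box")
  if (kind == "star" && n_tendrils < 1) stop("star needs n_tendrils >= 1")

  with_seed(seed, {
    dirs <- NULL
    if (kind == "star" && core_radius > 0)
      dirs <- separated_directions(n_tendrils, min_separation_deg)
    if (core_radius == 0) {
      truth <- structure(list(
        cavity_kind = kind, analytic_volume = 0, analytic_area = 0,
        true_branch_count = 0L, tendril_length = 0, directions = NULL,
        center = center, core_radius = 0, tendril_radius = 0,
        volume_se = 0), class = "phantom_truth")
      return(list(config = config, truth = truth))
    }
    region <- phantom_region(kind, center, core_radius, dirs,
                             tendril_length, tendril_radius)

    if (kind == "sphere") {
      vol <- 4 / 3 * pi * core_radius^3
      area <- 4 * pi * core_radius^2
      vse <- 0
      nbr <- 0L
    } else {
      # Monte-Carlo union volume of core + capsules in a bounding cube
      bound <- core_radius + tendril_length  # cap surfaces reach this far
      side <- 2 * bound
      ns <- max(1e6, mc_samples)
      pts <- matrix(stats::runif(3 * ns, -bound, bound), ncol = 3)
      pts <- sweep(pts, 2, center, "+")
      inside <- region(pts) <= 0
      p <- mean(inside)
      vol <- p * side^3
      vse <- side^3 * sqrt(p * (1 - p) / ns)
      area <- NA_real_  # no closed form recorded for the union
      nbr <- as.integer(n_tendrils)
    }

    sv <- config$solvent
    d <- region(as.matrix(sv[, c("x", "y", "z")]), config$box)
    hit_atom <- d <= sv$radius          # atom sphere intersects the region
    mols <- if (!is.null(sv$mol)) sv$mol else seq_len(nrow(sv))
    bad_mol <- unique(mols[hit_atom])
    kept <- sv[!(mols %in% bad_mol), , drop = FALSE]
    rownames(kept) <- NULL
    if (relax_sweeps > 0 && nrow(kept) > 0) {
      # relax / refill cycles: pack the first shell to contact and restore
      # the bulk density lost to whole-molecule removal
      for (cycle in 1:3) {
        kept <- relax_against_region(kept, config$box, center, core_radius,
                                     dirs, tendril_length, tendril_radius,
                                     relax_sweeps, region)
        # saturating refill: water fills every molecule-sized pocket, as an
        # equilibrated liquid would
        kept <- refill_waters(kept, config$box, region, Inf)
      }
      kept <- relax_against_region(kept, config$box, center, core_radius,
                                   dirs, tendril_length, tendril_radius,
                                   relax_sweeps, region)
    }
    out <- config
    out$solvent <- kept
    truth <- structure(list(
      cavity_kind = kind, analytic_volume = vol, analytic_area = area,
      true_branch_count = nbr,
      tendril_length = if (kind == "star") tendril_length else 0,
      directions = dirs, center = center, core_radius = core_radius,
      tendril_radius = if (kind == "star") tendril_radius else 0,
      volume_se = vse), class = "phantom_truth")
    list(config = out, truth = truth)
  })
}

# insert waters (random position/orientation, O-O hard core 2.6, region
# clearance) until the molecule count reaches n_target (Inf = saturation);
# bounded attempts
refill_waters <- function(kept, box, region, n_target = Inf, hardcore = 2.6,
                          max_attempts = 20000) {
  if (is.na(n_target) || is.null(kept$mol)) return(kept)
  n_now <- length(unique(kept$mol))
  if (n_now >= n_target) return(kept)
  half <- WATER_HOH / 2 * pi / 180
  base <- rbind(c(sin(half), 0, cos(half)) * WATER_OH,
                c(-sin(half), 0, cos(half)) * WATER_OH)
  O <- as.matrix(kept[kept$element == "O", c("x", "y", "z")])
  new_rows <- list()
  added <- 0
  next_mol <- max(kept$mol) + 1
  tried <- 0
  dry <- 0
  while (tried < max_attempts && n_now + added < n_target && dry < 3) {
    batch <- min(2000L, max_attempts - tried)
    tried <- tried + batch
    cand <- matrix(stats::runif(3 * batch), ncol = 3) %*% diag(box)
    ok <- region(cand, box) >= VDW_RADII[["O"]]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) next
    # pre-filter against existing oxygens in one vectorized pass
    dmin <- min_dist_to_spheres(cand, O, rep(0, nrow(O)), box)
    cand <- cand[dmin >= hardcore, , drop = FALSE]
    hit <- FALSE
    for (ci in seq_len(nrow(cand))) {
      if (n_now + added >= n_target) break
      p <- cand[ci, ]
      # re-check against oxygens accepted within this batch
      if (added > 0 && min(mi_dist(O, p, box)) < hardcore) next
      R <- random_rotation()
      h <- sweep(base %*% t(R), 2, p, "+")
      if (any(region(h, box) < VDW_RADII[["H"]])) next
      new_rows[[length(new_rows) + 1]] <- data.frame(
        element = c("O", "H", "H"),
        x = c(p[1], h[, 1]), y = c(p[2], h[, 2]), z = c(p[3], h[, 3]),
        radius = c(VDW_RADII[["O"]], VDW_RADII[["H"]], VDW_RADII[["H"]]),
        mol = next_mol + added, stringsAsFactors = FALSE)
      O <- rbind(O, p)
      added <- added + 1
      hit <- TRUE
    }
    dry <- if (hit) 0 else dry + 1  # stop after consecutive dry batches
  }
  if (added == 0) return(kept)
  out <- rbind(kept, do.call(rbind, new_rows))
  rownames(out) <- NULL
  out
}

# pack kept 3-site waters to contact with the carved boundary (rigid
# translations, zero-temperature); falls back to the raw carve when the
# solvent is not in O+2H molecule form
relax_against_region <- function(kept, box, center, core_radius, dirs,
                                 tendril_length, tendril_radius, sweeps,
                                 region, att_w = 0.5) {
  if (is.null(kept$mol)) return(kept)
  ok_shape <- all(tapply(kept$element, kept$mol, function(e)
    sum(e == "O") == 1 && sum(e == "H") == 2 && length(e) == 3))
  if (!isTRUE(ok_shape)) return(kept)
  ids <- unique(kept$mol)
  orows <- kept[kept$element == "O", ]
  orows <- orows[match(ids, orows$mol), ]
  hrows <- kept[kept$element == "H", ]
  h1 <- hrows[!duplicated(hrows$mol), ]
  h1 <- h1[match(ids, h1$mol), ]
  h2 <- hrows[duplicated(hrows$mol), ]
  h2 <- h2[match(ids, h2$mol), ]
  opos <- as.matrix(orows[, c("x", "y", "z")])
  off1 <- min_image(as.matrix(h1[, c("x", "y", "z")]) - opos, box)
  off2 <- min_image(as.matrix(h2[, c("x", "y", "z")]) - opos, box)
  dmat <- if (is.null(dirs)) matrix(0, 0, 3) else dirs
  reach <- core_radius + tendril_length - tendril_radius
  onew <- .relax_wall_cpp(opos, off1, off2, box, 2.9, 0.35,
                          as.integer(sweeps), center, core_radius, dmat,
                          reach, tendril_radius, VDW_RADII[["O"]],
                          VDW_RADII[["H"]], 4, att_w, 0.8)
  # rebuild atom table; drop the (rare) molecules still penetrating the wall
  atom <- data.frame(
    element = rep(c("O", "H", "H"), times = length(ids)),
    x = as.vector(t(cbind(onew[, 1], onew[, 1] + off1[, 1], onew[, 1] + off2[, 1]))),
    y = as.vector(t(cbind(onew[, 2], onew[, 2] + off1[, 2], onew[, 2] + off2[, 2]))),
    z = as.vector(t(cbind(onew[, 3], onew[, 3] + off1[, 3], onew[, 3] + off2[, 3]))),
    radius = rep(c(VDW_RADII[["O"]], VDW_RADII[["H"]], VDW_RADII[["H"]]),
                 times = length(ids)),
    mol = rep(ids, each = 3),
    stringsAsFactors = FALSE)
  dreg <- region(as.matrix(atom[, c("x", "y", "z")]), box)
  bad <- unique(atom$mol[dreg <= atom$radius - 0.2])
  atom <- atom[!(atom$mol %in% bad), , drop = FALSE]
  atom[, c("x", "y", "z")] <- wrap_positions(atom[, c("x", "y", "z")], box)
  rownames(atom) <- NULL
  atom
}

#' Insert a model solute and clear overlapping waters
#'
#' Places solute atoms at \code{center + offset}, wraps them into the box,
#' and removes every water molecule having an atom sphere that overlaps any
#' solute van der Waals sphere (minimum image).  Kept solvent atoms are not
#' moved.
#'
#' @param config A \code{\link{solvated_configuration}}.
#' @param solute_spec Data frame with columns \code{dx}, \code{dy}, \code{dz}
#'   (offsets, Angstrom), \code{element}, \code{radius} (optional; element
#'   default used when absent), \code{group}.
#' @param center Placement origin (default box center).
#'
#' @return The configuration with solute added and clashing waters removed.
#' @export
place_model_solute <- function(config, solute_spec, center = NULL) {
  stopifnot(inherits(config, "solvated_configuration"))
  if (is.null(solute_spec) || nrow(solute_spec) == 0)
    stop("solute_spec must contain at least one atom")
  if (is.null(center)) center <- config$box / 2
  if (is.null(solute_spec$radius))
    solute_spec$radius <- vdw_radius(solute_spec$element)
  if (is.null(solute_spec$group)) solute_spec$group <- "solute"
  pos <- cbind(solute_spec$dx + center[1], solute_spec$dy + center[2],
               solute_spec$dz + center[3])
  pos <- wrap_positions(pos, config$box)
  solute <- data.frame(element = solute_spec$element,
                       x = pos[, 1], y = pos[, 2], z = pos[, 3],
                       radius = solute_spec$radius,
                       group = solute_spec$group, stringsAsFactors = FALSE)
  sv <- config$solvent
  if (nrow(sv) > 0) {
    dmin <- min_dist_to_spheres(as.matrix(sv[, c("x", "y", "z")]),
                                pos, solute$radius, config$box)
    hit <- dmin < sv$radius
    mols <- if (!is.null(sv$mol)) sv$mol else seq_len(nrow(sv))
    sv <- sv[!(mols %in% unique(mols[hit])), , drop = FALSE]
    rownames(sv) <- NULL
  }
  out <- config
  out$solvent <- sv
  out$solute <- solute
  out
}

#' Generate a linear-model fixture
#'
#' Draws independent standard-normal features and a response
#' \eqn{y = \sum_j w_j X_j + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)},
#' reproducible from the seed.
#'
#' @param n Number of rows (at least \code{length(true_weights) + 2}).
#' @param true_weights Numeric vector of weights (optionally named).
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#'
#' @return A \code{regression_fixture}: list with \code{X} (data frame),
#'   \code{y}, \code{true_weights}, \code{noise_sd}, \code{seed}.
#' @export
generate_regression_fixture <- function(n, true_weights, noise_sd = 0,
                                        seed = 1L) {
  p <- length(true_weights)
  if (n < p + 2) stop("n must be at least length(true_weights) + 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  nm <- names(true_weights) %||% paste0("X", seq_len(p))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(NULL, nm))
    y <- drop(X %*% true_weights) + stats::rnorm(n, 0, noise_sd)
    structure(list(X = as.data.frame(X), y = y,
                   true_weights = stats::setNames(as.numeric(true_weights), nm),
                   noise_sd = noise_sd, seed = seed),
              class = "regression_fixture")
  })
}
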