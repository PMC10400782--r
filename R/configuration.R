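#' Solvated configuration container
#'
#' A snapshot of a (possibly empty) solute in explicit solvent inside an
#' orthorhombic periodic box.  Positions are in Angstrom; solvent atoms carry
#' the water-sphere van der Waals radii (O 1.52, H 1.2 by default).
#'
#' @param box Numeric length-3 vector of box edge lengths (Angstrom).
#' @param solvent Data frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{radius}, and optionally \code{mol} (molecule index).
#' @param solute Data frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{radius}, \code{group} (e.g. \code{"N-term"},
#'   \code{"C-term"}, \code{"side"}); may have zero rows.
#' @param frame_id Integer frame identifier.
#' @param wrap Wrap all positions into the primary cell (default TRUE).
#'
#' @return An object of class \code{solvated_configuration}.
#' @export
solvated_configuration <- function(box, solvent, solute = NULL, frame_id = 1L,
                                   wrap = TRUE) {
  box <- as.numeric(box)
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(box > 0))
  if (is.null(solute))
    solute <- data.frame(element = character(), x = numeric(), y = numeric(),
                         z = numeric(), radius = numeric(),
                         group = character(), stringsAsFactors = FALSE)
  need <- c("element", "x", "y", "z", "radius")
  if (!all(need %in% names(solvent)))
    stop("solvent table must have columns ", paste(need, collapse = ", "))
  if (nrow(solute) > 0 && !all(need %in% names(solute)))
    stop("solute table must have columns ", paste(need, collapse = ", "))
  if (nrow(solute) > 0 && is.null(solute$group)) solute$group <- "solute"
  if (wrap) {
    if (nrow(solvent) > 0)
      solvent[, c("x", "y", "z")] <-
        wrap_positions(solvent[, c("x", "y", "z")], box)
    if (nrow(solute) > 0)
      solute[, c("x", "y", "z")] <-
        wrap_positions(solute[, c("x", "y", "z")], box)
  }
  structure(list(box = box, solvent = solvent, solute = solute,
                 frame_id = as.integer(frame_id)),
            class = "solvated_configuration")
}

#' @export
print.solvated_configuration <- function(x, ...) {
  cat(sprintf(
    "Solvated configuration (frame %d): box %.2f x %.2f x %.2f A\n",
    x$frame_id, x$box[1], x$box[2], x$box[3]))
  nw <- if (!is.null(x$solvent$mol)) length(unique(x$solvent$mol))
        else nrow(x$solvent)
  cat(sprintf("  solvent: %d atoms (%d molecules)\n", nrow(x$solvent), nw))
  cat(sprintf("  solute : %d atoms (%s)\n", nrow(x$solute),
              if (nrow(x$solute)) paste(unique(x$solute$group), collapse = ", ")
              else "none"))
  invisible(x)
}

solvent_xyz <- function(config) {
  as.matrix(config$solvent[, c("x", "y", "z")])
}

solute_xyz <- function(config) {
  as.matrix(config$solute[, c("x", "y", "z")])
}

#' Count solute heavy (non-hydrogen) atoms
#'
#' @param config A \code{solvated_configuration}.
#' @return Integer number of non-hydrogen solute atoms.
#' @export
n_heavy_atoms <- function(config) {
  sum(toupper(config$solute$element) != "H")
}
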