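# Snapshot I/O: GRO (nm, fixed columns), PDB (via bio3d), XYZ (Angstrom).
# Internally everything is Angstrom; nm appears only at the GRO boundary.

WATER_RESNAMES <- c("SOL", "HOH", "WAT", "TIP3", "TIP4", "SPC")

assign_radii <- function(element) vdw_radius(element)

element_from_name <- function(name) {
  e <- sub("^[0-9]*", "", trimws(name))
  e <- sub("[0-9'\"]*$", "", e)
  first <- toupper(substr(e, 1, 1))
  two <- toupper(substr(e, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA"), two, first)
}

#' Read a solvated snapshot
#'
#' Reads GRO, PDB or XYZ coordinates, converts units to Angstrom
#' (GRO nm are multiplied by 10), reads the box, and splits solute from
#' solvent: solvent = water residues (\code{SOL}, \code{HOH}, \code{WAT},
#' ...), solute = atoms matched by \code{solute_selector} (a residue name,
#' or an integer vector of atom indices); by default every non-water,
#' non-ion residue is solute.
#'
#' @param path File path.
#' @param format \code{"gro"}, \code{"pdb"} or \code{"xyz"}; guessed from
#'   the extension by default.
#' @param solute_selector Residue name (character) or atom indices
#'   (integer); \code{NULL} selects all non-water residues.
#' @param box Required for XYZ when the comment line carries no box.
#' @return A \code{\link{solvated_configuration}}.
#' @export
read_configuration <- function(path, format = NULL, solute_selector = NULL,
                               box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- tolower(format %||% tools::file_ext(path))
  raw <- switch(format,
                gro = read_gro_raw(path),
                pdb = read_pdb_raw(path),
                xyz = read_xyz_raw(path, box),
                stop("unsupported format: ", format))
  if (is.null(raw$box) || any(!is.finite(raw$box)) || any(raw$box <= 0))
    stop("missing or invalid box in ", path)
  at <- raw$atoms
  at$element <- element_from_name(at$name)
  is_water <- toupper(at$resname) %in% WATER_RESNAMES
  if (is.null(solute_selector)) {
    sol_idx <- which(!is_water)
  } else if (is.character(solute_selector)) {
    sol_idx <- which(toupper(at$resname) %in% toupper(solute_selector))
  } else {
    sol_idx <- as.integer(solute_selector)
  }
  if (length(sol_idx) == 0 && !is.null(solute_selector))
    stop("solute selector matched no atoms")
  solvent <- at[setdiff(seq_len(nrow(at)), sol_idx), , drop = FALSE]
  solvent <- solvent[toupper(solvent$resname) %in% WATER_RESNAMES |
                     solvent$element %in% c("O", "H"), , drop = FALSE]
  solute <- at[sol_idx, , drop = FALSE]
  mk <- function(d, grp = NULL) {
    if (nrow(d) == 0) return(NULL)
    out <- data.frame(element = d$element, x = d$x, y = d$y, z = d$z,
                      radius = assign_radii(d$element),
                      stringsAsFactors = FALSE)
    if (!is.null(d$resid)) out$mol <- d$resid
    if (!is.null(grp)) out$group <- grp
    out
  }
  svd <- mk(solvent)
  sod <- mk(solute, grp = if (nrow(solute)) solute$resname else NULL)
  if (is.null(svd))
    svd <- data.frame(element = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric())
  solvated_configuration(raw$box, svd, sod, frame_id = raw$frame_id %||% 1L)
}

read_gro_raw <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file")
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  atoms <- data.frame(
    resid = as.integer(substr(body, 1, 5)),
    resname = trimws(substr(body, 6, 10)),
    name = trimws(substr(body, 11, 15)),
    x = as.numeric(substr(body, 21, 28)) * 10,
    y = as.numeric(substr(body, 29, 36)) * 10,
    z = as.numeric(substr(body, 37, 44)) * 10,
    stringsAsFactors = FALSE)
  bx <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  list(atoms = atoms, box = bx[1:3] * 10)
}

read_pdb_raw <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  box <- NULL
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cr) >= 1)
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
  atoms <- data.frame(resid = a$resno, resname = a$resid,
                      name = a$elety, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, box = box)
}

read_xyz_raw <- function(path, box = NULL) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  comment <- lines[2]
  if (is.null(box)) {
    m <- regmatches(comment, regexpr("box\\s*=\\s*[0-9. ]+", comment))
    if (length(m) == 1)
      box <- as.numeric(strsplit(trimws(sub(".*=", "", m)), "\\s+")[[1]])
  }
  body <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  atoms <- data.frame(
    resid = seq_len(n),
    resname = "UNK",
    name = vapply(body, `[[`, "", 1),
    x = as.numeric(vapply(body, `[[`, "", 2)),
    y = as.numeric(vapply(body, `[[`, "", 3)),
    z = as.numeric(vapply(body, `[[`, "", 4)),
    stringsAsFactors = FALSE)
  # waters written by this package use resname-style names O/H; mark them
  atoms$resname <- ifelse(atoms$name %in% c("O", "H", "OW", "HW1", "HW2"),
                          "SOL", "UNK")
  list(atoms = atoms, box = box)
}

#' Write a configuration to GRO, PDB or XYZ
#'
#' GRO uses nm with the standard fixed columns; PDB and XYZ use Angstrom.
#' Solute atoms come first (residue \code{LIG}), then waters (\code{SOL}).
#'
#' @param config A \code{\link{solvated_configuration}}.
#' @param path Output path.
#' @param format Guessed from the extension by default.
#' @return \code{path}, invisibly.
#' @export
write_configuration <- function(config, path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  sol <- config$solute
  sv <- config$solvent
  n_sol <- nrow(sol)
  resname <- c(rep("LIG", n_sol),
               rep("SOL", nrow(sv)))
  resid <- c(rep(1L, n_sol),
             if (nrow(sv)) (sv$mol %||% seq_len(nrow(sv))) + 1L else integer())
  name <- c(if (n_sol) sol$element else character(), sv$element)
  xyz <- rbind(if (n_sol) as.matrix(sol[, c("x", "y", "z")]) else NULL,
               as.matrix(sv[, c("x", "y", "z")]))
  switch(format,
    gro = {
      hdr <- sprintf("voidshape frame %d", config$frame_id)
      body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                      resid %% 100000, resname, name,
                      seq_along(name) %% 100000,
                      xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10)
      writeLines(c(hdr, sprintf("%5d", length(name)), body,
                   sprintf("%10.5f%10.5f%10.5f", config$box[1] / 10,
                           config$box[2] / 10, config$box[3] / 10)), path)
    },
    pdb = {
      cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       config$box[1], config$box[2], config$box[3],
                       90, 90, 90)
      body <- sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_along(name) %% 100000, substr(name, 1, 4),
        substr(resname, 1, 3), resid %% 10000,
        xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, substr(name, 1, 2))
      writeLines(c(cryst, body, "END"), path)
    },
    xyz = {
      writeLines(c(sprintf("%d", length(name)),
                   sprintf("box = %.4f %.4f %.4f", config$box[1],
                           config$box[2], config$box[3]),
                   sprintf("%-3s %12.6f %12.6f %12.6f", name,
                           xyz[, 1], xyz[, 2], xyz[, 3])), path)
    },
    stop("unsupported format: ", format))
  invisible(path)
}

#' Export a surface mesh
#'
#' OFF (text) or PLY (binary little-endian).
#'
#' @param surface A \code{void_surface}.
#' @param path Output path.
#' @param format \code{"off"} or \code{"ply"}; guessed from the extension.
#' @return \code{path}, invisibly.
#' @export
write_mesh <- function(surface, path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  v <- surface$vertices
  f <- surface$faces
  if (format == "off") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else if (format == "ply") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("ply", "format binary_little_endian 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
    for (r in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[r, ] - 1L), con, size = 4, endian = "little")
    }
  } else stop("unsupported mesh format: ", format)
  invisible(path)
}
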