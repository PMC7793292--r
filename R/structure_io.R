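# Multi-model PDB reading/writing and atom selection.
#
# Structures are plain data.frames of atom records; an ensemble couples one
# topology (atom metadata) to an n_frames x n_atoms x 3 coordinate array.
# Author residue numbering from the source file is authoritative: records are
# never renumbered, and insertion codes are part of the residue key.

#' Read a (multi-model) PDB file
#'
#' Parses the fixed-column ATOM/HETATM/MODEL/ENDMDL subset of the PDB format.
#' Each MODEL block becomes one structure model; a file without MODEL records
#' yields a single implicit model. Alternate locations are reduced to a single
#' conformer per atom: the highest-occupancy altloc wins, ties broken by first
#' occurrence.
#'
#' @param path path to a PDB file.
#' @return a list of `structure_model` objects, each a list with elements
#'   `atoms` (data.frame: serial, name, altloc, resname, chain, resid, icode,
#'   x, y, z, occupancy, bfactor, element, hetatm) and `model_id`.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
#'   "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00 12.00           C",
#'   "END"), f)
#' models <- read_structure(f)
#' nrow(models[[1]]$atoms)
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- startsWith(rec, "ATOM") | startsWith(rec, "HETATM")
  if (!any(is_atom)) stop("empty structure: no ATOM/HETATM records in ", path)

  models <- list()
  cur <- integer(0)          # line indices of current model
  cur_id <- NA_integer_
  next_implicit <- 1L
  flush <- function() {
    if (length(cur) == 0) return()
    id <- if (is.na(cur_id)) next_implicit else cur_id
    models[[length(models) + 1L]] <<- parse_atom_lines(lines[cur], cur, id)
    next_implicit <<- next_implicit + 1L
    cur <<- integer(0); cur_id <<- NA_integer_
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      flush()
      cur_id <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
    } else if (startsWith(r, "ENDMDL")) {
      flush()
    } else if (is_atom[i]) {
      cur <- c(cur, i)
    }
  }
  flush()
  if (length(models) == 0) stop("empty structure: no ATOM/HETATM records in ", path)
  models
}

# Parse ATOM/HETATM lines (fixed PDB columns) into a structure_model.
parse_atom_lines <- function(lns, line_numbers, model_id) {
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad) || anyNA(v))
      stop("malformed ", what, " field at line ",
           ln[if (length(bad)) bad[1] else which(is.na(v))[1]])
    v
  }
  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(substr(lns, 7, 11))),
    name    = trimws(substr(lns, 13, 16)),
    altloc  = substr(lns, 17, 17),
    resname = trimws(substr(lns, 18, 20)),
    chain   = substr(lns, 22, 22),
    resid   = suppressWarnings(as.integer(substr(lns, 23, 26))),
    icode   = substr(lns, 27, 27),
    x = num(substr(lns, 31, 38), "x-coordinate", line_numbers),
    y = num(substr(lns, 39, 46), "y-coordinate", line_numbers),
    z = num(substr(lns, 47, 54), "z-coordinate", line_numbers),
    occupancy = suppressWarnings(as.numeric(substr(lns, 55, 60))),
    bfactor   = suppressWarnings(as.numeric(substr(lns, 61, 66))),
    element = trimws(substr(lns, 77, 78)),
    hetatm  = startsWith(substr(lns, 1, 6), "HETATM"),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms <- resolve_altlocs(atoms)
  structure(list(atoms = atoms, model_id = model_id),
            class = "structure_model")
}

# Keep one conformer per (chain, resid, icode, name): highest occupancy,
# first seen on ties. Blank-altloc atoms are unique already.
resolve_altlocs <- function(atoms) {
  alt <- atoms$altloc != " " & atoms$altloc != ""
  if (!any(alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resid, atoms$icode, atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[alt])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    best <- idx[which.max(atoms$occupancy[idx])]  # which.max: first on ties
    keep[setdiff(idx, best)] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with at least name, resname, chain, resid, x, y, z.
#' @param model_id integer model identifier.
#' @return a `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  defaults <- list(serial = seq_len(nrow(atoms)), altloc = " ", icode = " ",
                   occupancy = 1, bfactor = 0, element = "C", hetatm = FALSE,
                   resname = "GLY")
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  stopifnot(all(c("name", "chain", "resid", "x", "y", "z") %in% names(atoms)),
            all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "structure_model")
}

#' Atom coordinates as a matrix
#' @param model a `structure_model`.
#' @return n_atoms x 3 numeric matrix.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Write a structure model as PDB
#'
#' Fixed-column ATOM/HETATM records; coordinates at 3 decimals, so a
#' write/read round trip preserves (chain, resid, name, coords-to-3dp).
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  if (is.null(model$atoms) || nrow(model$atoms) == 0)
    stop("empty structure: refusing to write a model with no atoms")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format_atom_lines(model$atoms), con)
  writeLines("END", con)
  invisible(path)
}

format_atom_lines <- function(a) {
  # PDB atom-name justification: names shorter than 4 chars start in col 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(a$hetatm, "HETATM", "ATOM"),
          a$serial %% 100000L, nm, a$altloc, a$resname, a$chain,
          a$resid %% 10000L, a$icode, a$x, a$y, a$z,
          pmin(a$occupancy, 999.99), pmin(a$bfactor, 999.99), a$element)
}

#' Write an ensemble as a multi-model PDB
#'
#' @param traj an `ensemble_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ensemble_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$topology
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    a$x <- traj$frames[f, , 1]; a$y <- traj$frames[f, , 2]
    a$z <- traj$frames[f, , 3]
    writeLines(format_atom_lines(a), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Couple a list of structure models into a coordinate ensemble
#'
#' @param models list of `structure_model`s sharing one atom order, or a path
#'   to a multi-model PDB file.
#' @return an `ensemble_trajectory`: list(topology, frames) with `frames` an
#'   n_frames x n_atoms x 3 array in Angstrom.
#' @export
as_trajectory <- function(models) {
  if (is.character(models)) models <- read_structure(models)
  if (inherits(models, "structure_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  n_at <- nrow(models[[1]]$atoms)
  for (m in models)
    if (nrow(m$atoms) != n_at)
      stop("models have differing atom counts; cannot form an ensemble")
  frames <- array(NA_real_, c(length(models), n_at, 3))
  for (f in seq_along(models)) frames[f, , ] <- coords(models[[f]])
  structure(list(topology = models[[1]]$atoms, frames = frames),
            class = "ensemble_trajectory")
}

#' Number of frames in an ensemble
#' @param traj an `ensemble_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame of an ensemble as a structure model
#' @param traj an `ensemble_trajectory`.
#' @param frame frame index (1-based).
#' @export
frame_model <- function(traj, frame) {
  a <- traj$topology
  a$x <- traj$frames[frame, , 1]; a$y <- traj$frames[frame, , 2]
  a$z <- traj$frames[frame, , 3]
  structure_model(a, model_id = frame)
}

#' Atom selection criteria
#'
#' All supplied criteria are combined by conjunction; an empty selection
#' matches every atom. Selection by `resid` matches any insertion code.
#'
#' @param chain chain identifier, or NULL.
#' @param resid_range inclusive integer range c(lo, hi), or NULL.
#' @param resids explicit residue numbers, or NULL.
#' @param names atom-name set (e.g. "CA"), or NULL.
#' @return an `atom_selection`.
#' @export
atom_selection <- function(chain = NULL, resid_range = NULL, resids = NULL,
                           names = NULL) {
  if (!is.null(resid_range)) {
    stopifnot(length(resid_range) == 2)
    if (resid_range[1] > resid_range[2])
      stop("invalid resid_range: lo > hi")
  }
  structure(list(chain = chain, resid_range = resid_range,
                 resids = resids, names = names),
            class = "atom_selection")
}

#' Resolve an atom selection to topology indices
#'
#' @param x a `structure_model` or `ensemble_trajectory`.
#' @param sel an `atom_selection`.
#' @param require_one if TRUE, error unless exactly one atom matches.
#' @return integer indices into the topology atom order (ascending).
#' @export
select_atoms <- function(x, sel, require_one = FALSE) {
  a <- if (inherits(x, "ensemble_trajectory")) x$topology else x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resid_range))
    keep <- keep & a$resid >= sel$resid_range[1] & a$resid <= sel$resid_range[2]
  if (!is.null(sel$resids)) keep <- keep & a$resid %in% sel$resids
  if (!is.null(sel$names)) keep <- keep & a$name %in% sel$names
  idx <- which(keep)
  if (require_one && length(idx) != 1)
    stop("selection matched ", length(idx), " atoms (expected exactly 1): ",
         format_selection(sel))
  if (require_one == FALSE && length(idx) == 0 && !is_empty_selection(sel))
    idx
  idx
}

is_empty_selection <- function(sel)
  is.null(sel$chain) && is.null(sel$resid_range) &&
  is.null(sel$resids) && is.null(sel$names)

format_selection <- function(sel) {
  parts <- c(
    if (!is.null(sel$chain)) paste0("chain=", paste(sel$chain, collapse = ",")),
    if (!is.null(sel$resid_range)) paste0("resid ", sel$resid_range[1], "-",
                                          sel$resid_range[2]),
    if (!is.null(sel$resids)) paste0("resid in {",
                                     paste(sel$resids, collapse = ","), "}"),
    if (!is.null(sel$names)) paste0("name in {",
                                    paste(sel$names, collapse = ","), "}"))
  if (length(parts) == 0) "(all atoms)" else paste(parts, collapse = " & ")
}
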