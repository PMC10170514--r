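#' Trajectory container
#'
#' A minimal in-memory trajectory: an atom table plus a list of
#' per-frame coordinate matrices and an optional periodic cell. This is
#' the common currency of the CV, ion and synthetic-data machinery.
#'
#' @param atoms data.frame with at least columns `name`, `resid`,
#'   `resname`; optional `element` and arbitrary annotation columns
#'   (e.g. `group` for the stacking groups).
#' @param coords list of numeric matrices, one per frame, each
#'   `nrow(atoms)` x 3, in Angstrom.
#' @param box periodic cell: `NULL` (non-periodic), a length-3 vector of
#'   orthorhombic box lengths, or a 3x3 matrix whose rows are the cell
#'   vectors (general triclinic; truncated-octahedron cells enter
#'   through this representation).
#' @param time optional per-frame times in ps (default 0, 1, 2, ...).
#' @return an object of class `hj_trajectory`.
#' @export
hj_trajectory <- function(atoms, coords, box = NULL, time = NULL) {
  stopifnot(is.data.frame(atoms), is.list(coords), length(coords) >= 1)
  if (!all(c("name", "resid", "resname") %in% names(atoms)))
    stop("atoms needs columns name, resid, resname")
  n <- nrow(atoms)
  for (f in coords)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("each coords element must be an nrow(atoms) x 3 matrix")
  box <- validate_box(box)
  if (is.null(time)) time <- seq_along(coords) - 1
  structure(list(atoms = atoms, coords = coords, box = box,
                 time = as.numeric(time)),
            class = "hj_trajectory")
}

#' @export
print.hj_trajectory <- function(x, ...) {
  cat(sprintf("hj_trajectory: %d atoms, %d frames, %s\n",
              nrow(x$atoms), length(x$coords),
              if (is.null(x$box)) "non-periodic" else "periodic"))
  invisible(x)
}

#' @export
length.hj_trajectory <- function(x) length(x$coords)

validate_box <- function(box) {
  if (is.null(box)) return(NULL)
  if (is.matrix(box)) {
    stopifnot(nrow(box) == 3, ncol(box) == 3)
    if (abs(det(box)) < 1e-8) stop("degenerate periodic cell")
    return(box)
  }
  stopifnot(is.numeric(box), length(box) == 3, all(box > 0))
  diag(box)
}

#' Minimum-image displacement vectors
#'
#' Wraps a matrix of Cartesian displacement vectors into the primary
#' image of a periodic cell. General triclinic cells are handled by
#' rounding in fractional coordinates, which is exact for orthorhombic
#' cells and the standard convention for moderately skewed ones.
#'
#' @param d numeric matrix (n x 3) of displacements in Angstrom.
#' @param box periodic cell as in [hj_trajectory()]; `NULL` returns `d`
#'   unchanged.
#' @return matrix of the same shape.
#' @export
minimum_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  box <- validate_box(box)
  frac <- d %*% solve(box)
  (frac - round(frac)) %*% box
}

# all pairwise minimum-image distances between two coordinate blocks
cross_distances <- function(a, b, box = NULL) {
  na <- nrow(a); nb <- nrow(b)
  d <- cbind(rep(a[, 1], times = nb) - rep(b[, 1], each = na),
             rep(a[, 2], times = nb) - rep(b[, 2], each = na),
             rep(a[, 3], times = nb) - rep(b[, 3], each = na))
  d <- minimum_image(d, box)
  matrix(sqrt(rowSums(d^2)), nrow = na, ncol = nb)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-width PDB ATOM records. The
#' companion reader [read_trajectory_pdb()] round-trips coordinates to
#' the 0.001 Angstrom precision of the format.
#'
#' @param traj an [hj_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "hj_trajectory"))
  at <- traj$atoms
  elem <- if ("element" %in% names(at)) at$element else substr(at$name, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    b <- traj$box
    # CRYST1 carries only the orthorhombic lengths; angle bookkeeping is
    # not needed for these synthetic cells
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       b[1, 1], b[2, 2], b[3, 3]), con)
  }
  n <- nrow(at)
  serial <- ((seq_len(n) - 1) %% 99999) + 1
  for (k in seq_along(traj$coords)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- traj$coords[[k]]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, substr(at$name, 1, 4), substr(at$resname, 1, 3),
      at$resid %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], substr(elem, 1, 2)),
      con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a trajectory
#'
#' @param path PDB file written by [write_trajectory_pdb()] or any file
#'   restricted to CRYST1/ATOM/MODEL records.
#' @return an [hj_trajectory()].
#' @export
read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) >= 1) {
    b <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                      substr(cr[1], 25, 33)))
    box <- b
  }
  atom_lines <- grepl("^ATOM  |^HETATM", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (!any(model_id > 0)) model_id <- rep(1L, length(lines))
  al <- lines[atom_lines]
  mid <- model_id[atom_lines]
  if (length(al) == 0) stop("no ATOM records in ", path)
  first <- al[mid == mid[1]]
  atoms <- data.frame(
    name = trimws(substr(first, 13, 16)),
    resname = trimws(substr(first, 18, 20)),
    resid = as.integer(substr(first, 23, 26)),
    element = trimws(substr(first, 77, 78)),
    stringsAsFactors = FALSE)
  n <- nrow(atoms)
  xyz <- cbind(as.numeric(substr(al, 31, 38)),
               as.numeric(substr(al, 39, 46)),
               as.numeric(substr(al, 47, 54)))
  if (nrow(xyz) %% n != 0) stop("inconsistent atom counts across models")
  nf <- nrow(xyz) / n
  coords <- lapply(seq_len(nf), function(k)
    xyz[((k - 1) * n + 1):(k * n), , drop = FALSE])
  hj_trajectory(atoms, coords, box = box)
}
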