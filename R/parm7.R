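#' AMBER parm7 topology output with an expanded per-pair LJ matrix
#'
#' Pair-specific overrides cannot be represented in a parm7 file whose
#' atoms share LJ types, so the writer assigns every atom its own type
#' and expands the full `LENNARD_JONES_ACOEF`/`BCOEF` matrix. The
#' coefficient blocks use a wide exponent format so that a round trip
#' reproduces epsilon and rmin to better than 1e-10. Only the sections
#' needed for nonbonded work are written (pointers, names, charges,
#' residues, type indices, LJ coefficients).
#'
#' @param table an `hj_pair_table` derived from the topology being
#'   written.
#' @param path output file path.
#' @param title TITLE line content.
#' @param max_atoms refuse to expand per-pair matrices beyond this many
#'   atoms (the dense type matrix grows quadratically).
#' @return `path`, invisibly.
#' @export
write_parm7 <- function(table, path, title = "hjdyn modified topology",
                        max_atoms = 2000) {
  stopifnot(inherits(table, "hj_pair_table"))
  a <- table$atoms
  n <- nrow(a)
  if (n > max_atoms)
    stop("per-pair LJ expansion for ", n,
         " atoms exceeds the supported matrix size (max_atoms = ",
         max_atoms, ")")
  # dense pair parameters via the table's own lookup
  idx <- t(utils::combn(n, 2))
  # diagonal entries come straight from the per-atom parameters
  eps_mat <- matrix(0, n, n)
  rmin_mat <- matrix(0, n, n)
  diag(eps_mat) <- a$epsilon
  diag(rmin_mat) <- 2 * a$rmin_half
  if (n >= 2) {
    p <- lj_params(table, idx[, 1], idx[, 2])
    # excluded pairs still need a matrix entry; use combination rules
    miss <- p$excluded
    if (any(miss)) {
      p$epsilon[miss] <- sqrt(a$epsilon[p$i[miss]] * a$epsilon[p$j[miss]])
      p$rmin[miss] <- a$rmin_half[p$i[miss]] + a$rmin_half[p$j[miss]]
    }
    eps_mat[idx] <- p$epsilon; eps_mat[idx[, 2:1, drop = FALSE]] <- p$epsilon
    rmin_mat[idx] <- p$rmin;  rmin_mat[idx[, 2:1, drop = FALSE]] <- p$rmin
  }
  # lower-triangle (row-major over i >= j) packing used by parm7
  acoef <- numeric(n * (n + 1) / 2)
  bcoef <- numeric(n * (n + 1) / 2)
  parm_index <- matrix(0L, n, n)
  k <- 0L
  for (i in seq_len(n)) for (j in seq_len(i)) {
    k <- k + 1L
    acoef[k] <- eps_mat[i, j] * rmin_mat[i, j]^12
    bcoef[k] <- 2 * eps_mat[i, j] * rmin_mat[i, j]^6
    parm_index[i, j] <- k; parm_index[j, i] <- k
  }
  res_ids <- unique(a$resid)
  res_ptr <- match(res_ids, a$resid)
  res_lab <- a$resname[res_ptr]
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  fmt_block <- function(x, fmt, per_line) {
    if (length(x) == 0) return("")
    s <- sprintf(fmt, x)
    grp <- ceiling(seq_along(s) / per_line)
    vapply(split(s, grp), paste0, "", collapse = "")
  }
  w("%VERSION  VERSION_STAMP = V0001.000  DATE = 01/01/00  00:00:00")
  w("%FLAG TITLE", "%FORMAT(20a4)", substr(title, 1, 80))
  pointers <- integer(31)
  pointers[1] <- n        # NATOM
  pointers[2] <- n        # NTYPES: one LJ type per atom
  pointers[12] <- length(res_ids)  # NRES
  w("%FLAG POINTERS", "%FORMAT(10I8)", fmt_block(pointers, "%8d", 10))
  w("%FLAG ATOM_NAME", "%FORMAT(20a4)",
    fmt_block(sprintf("%-4s", substr(a$name, 1, 4)), "%s", 20))
  # parm7 stores charges scaled by 18.2223 (sqrt of Coulomb constant)
  w("%FLAG CHARGE", "%FORMAT(5E16.8)",
    fmt_block(a$charge * 18.2223, "%16.8E", 5))
  w("%FLAG ATOM_TYPE_INDEX", "%FORMAT(10I8)",
    fmt_block(seq_len(n), "%8d", 10))
  w("%FLAG AMBER_ATOM_TYPE", "%FORMAT(20a4)",
    fmt_block(sprintf("%-4s", substr(a$type, 1, 4)), "%s", 20))
  w("%FLAG RESIDUE_LABEL", "%FORMAT(20a4)",
    fmt_block(sprintf("%-4s", substr(res_lab, 1, 4)), "%s", 20))
  w("%FLAG RESIDUE_POINTER", "%FORMAT(10I8)", fmt_block(res_ptr, "%8d", 10))
  w("%FLAG NONBONDED_PARM_INDEX", "%FORMAT(10I8)",
    fmt_block(as.integer(t(parm_index)), "%8d", 10))
  w("%FLAG LENNARD_JONES_ACOEF", "%FORMAT(3E24.16)",
    fmt_block(acoef, "%24.16E", 3))
  w("%FLAG LENNARD_JONES_BCOEF", "%FORMAT(3E24.16)",
    fmt_block(bcoef, "%24.16E", 3))
  invisible(path)
}

parse_parm7_sections <- function(lines) {
  flags <- grep("^%FLAG", lines)
  out <- list()
  for (k in seq_along(flags)) {
    nm <- trimws(sub("^%FLAG", "", lines[flags[k]]))
    to <- if (k < length(flags)) flags[k + 1] - 1 else length(lines)
    body <- lines[(flags[k] + 1):to]
    body <- body[!grepl("^%", body)]
    out[[nm]] <- body
  }
  out
}

parm7_numeric <- function(body) {
  as.numeric(unlist(strsplit(trimws(paste(body, collapse = " ")), "\\s+")))
}

parm7_fixed_strings <- function(body, width = 4) {
  out <- character(0)
  for (ln in body) {
    starts <- seq(1, nchar(ln), by = width)
    out <- c(out, trimws(substring(ln, starts, starts + width - 1)))
  }
  out
}

#' Read the nonbonded sections of an AMBER parm7 file
#'
#' Parses pointers, atom names/types, charges, residues and the
#' Lennard-Jones coefficient matrix, and converts A/B coefficients back
#' to `eps_ij`/`rmin_ij`. Supports both shared-type files and the
#' expanded per-atom-type files written by [write_parm7()].
#'
#' @param path parm7 file.
#' @return list with `atoms` (an [hj_atoms()] table; per-atom epsilon
#'   and `rmin_half` taken from the diagonal), and `pairs`, a function
#'   `(i, j) -> data.frame(epsilon, rmin)` resolving any atom pair from
#'   the stored matrix.
#' @export
read_parm7 <- function(path) {
  sec <- parse_parm7_sections(readLines(path))
  need <- c("POINTERS", "ATOM_NAME", "ATOM_TYPE_INDEX",
            "NONBONDED_PARM_INDEX", "LENNARD_JONES_ACOEF",
            "LENNARD_JONES_BCOEF")
  miss <- setdiff(need, names(sec))
  if (length(miss)) stop("parm7 missing sections: ", paste(miss, collapse = ", "))
  ptr <- parm7_numeric(sec$POINTERS)
  natom <- as.integer(ptr[1]); ntypes <- as.integer(ptr[2])
  name <- parm7_fixed_strings(sec$ATOM_NAME)[seq_len(natom)]
  type_index <- as.integer(parm7_numeric(sec$ATOM_TYPE_INDEX))[seq_len(natom)]
  nb_index <- as.integer(parm7_numeric(sec$NONBONDED_PARM_INDEX))
  acoef <- parm7_numeric(sec$LENNARD_JONES_ACOEF)
  bcoef <- parm7_numeric(sec$LENNARD_JONES_BCOEF)
  charge <- if ("CHARGE" %in% names(sec))
    parm7_numeric(sec$CHARGE)[seq_len(natom)] / 18.2223 else rep(0, natom)
  atype <- if ("AMBER_ATOM_TYPE" %in% names(sec))
    parm7_fixed_strings(sec$AMBER_ATOM_TYPE)[seq_len(natom)] else name
  resid <- rep(1L, natom); resname <- rep("RES", natom)
  if (all(c("RESIDUE_POINTER", "RESIDUE_LABEL") %in% names(sec))) {
    rp <- as.integer(parm7_numeric(sec$RESIDUE_POINTER))
    rl <- parm7_fixed_strings(sec$RESIDUE_LABEL)[seq_along(rp)]
    ends <- c(rp[-1] - 1L, natom)
    for (r in seq_along(rp)) {
      resid[rp[r]:ends[r]] <- r
      resname[rp[r]:ends[r]] <- rl[r]
    }
  }
  type_pair <- function(ti, tj) {
    k <- nb_index[ntypes * (ti - 1) + tj]
    A <- acoef[k]; B <- bcoef[k]
    eps <- ifelse(B > 0, B^2 / (4 * A), 0)
    rmin <- ifelse(B > 0, (2 * A / B)^(1 / 6), 0)
    data.frame(epsilon = eps, rmin = rmin)
  }
  diag_p <- type_pair(type_index, type_index)
  atoms <- hj_atoms(name = name, resid = resid, resname = resname,
                    type = atype, epsilon = diag_p$epsilon,
                    rmin_half = ifelse(diag_p$rmin > 0, diag_p$rmin / 2, 1),
                    charge = charge)
  # zero-epsilon diagonal entries give rmin 0; keep a positive
  # placeholder half-radius but report the true pair values via pairs()
  pairs <- function(i, j) type_pair(type_index[i], type_index[j])
  list(atoms = atoms, pairs = pairs)
}

#' Write modified topology artefacts
#'
#' Convenience wrapper emitting both the expanded parm7 and the
#' GROMACS-style override block next to it.
#'
#' @param table an `hj_pair_table`.
#' @param path parm7 output path; the override block is written to
#'   `paste0(path, ".gmx_overrides")`.
#' @inheritParams write_parm7
#' @return named character vector of the two paths, invisibly.
#' @export
write_modified_topology <- function(table, path,
                                    title = "hjdyn modified topology") {
  write_parm7(table, path, title = title)
  gmx <- paste0(path, ".gmx_overrides")
  write_gromacs_overrides(table, gmx)
  invisible(c(parm7 = path, gromacs = gmx))
}
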