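#' Atom tables with Lennard-Jones parameters
#'
#' Builds the per-atom table that underlies all pair-parameter work.
#' Epsilon is the LJ well depth in kcal/mol and `rmin_half` the
#' per-atom half optimal distance in Angstrom, the AMBER convention in
#' which the combination rules are `eps_ij = sqrt(eps_i * eps_j)` and
#' `rmin_ij = rmin_half_i + rmin_half_j`.
#'
#' @param name,resid,resname atom name and residue bookkeeping.
#' @param type atom-type name (defaults to `name`).
#' @param epsilon LJ well depth, kcal/mol, `>= 0`.
#' @param rmin_half half of the LJ optimal distance, Angstrom, `> 0`.
#' @param charge partial charge in elementary charges.
#' @param element element symbol.
#' @return data.frame of class `hj_atoms`, one row per atom, with a
#'   contiguous `index` column.
#' @export
hj_atoms <- function(name, resid, resname, type = name,
                     epsilon, rmin_half, charge = 0, element = NA_character_) {
  n <- length(name)
  df <- data.frame(index = seq_len(n), name = as.character(name),
                   resid = as.integer(resid), resname = as.character(resname),
                   type = as.character(type),
                   epsilon = as.numeric(epsilon),
                   rmin_half = as.numeric(rmin_half),
                   charge = rep_len(as.numeric(charge), n),
                   element = rep_len(as.character(element), n),
                   stringsAsFactors = FALSE)
  bad <- which(!is.finite(df$epsilon) | df$epsilon < 0 |
                 !is.finite(df$rmin_half) | df$rmin_half <= 0)
  if (length(bad))
    stop("missing or invalid LJ parameters for atom(s): ",
         paste(df$name[bad], collapse = ", "))
  class(df) <- c("hj_atoms", "data.frame")
  df
}

canonical_pairs <- function(i, j) {
  cbind(pmin(i, j), pmax(i, j))
}

pair_key <- function(i, j) {
  p <- canonical_pairs(i, j)
  paste(p[, 1], p[, 2], sep = "-")
}

#' Pairwise Lennard-Jones table with NBfix-style overrides
#'
#' The table is lazy: default pairs are resolved through the
#' combination rules at lookup time, while overridden pairs (the NBfix
#' mechanism) are stored explicitly and flagged. Bonded/1-4 exclusions
#' are carried alongside and never receive numeric parameters.
#'
#' @param atoms an [hj_atoms()] table.
#' @param exclusions two-column matrix of excluded atom-index pairs
#'   (bonded and 1-4 neighbours), or `NULL`.
#' @return object of class `hj_pair_table`.
#' @export
build_pair_table <- function(atoms, exclusions = NULL) {
  stopifnot(inherits(atoms, "hj_atoms"))
  if (is.null(exclusions)) {
    exclusions <- matrix(integer(0), ncol = 2)
  } else {
    exclusions <- canonical_pairs(exclusions[, 1], exclusions[, 2])
    storage.mode(exclusions) <- "integer"
  }
  structure(list(
    atoms = atoms,
    overrides = data.frame(i = integer(0), j = integer(0),
                           epsilon = numeric(0), rmin = numeric(0),
                           scaled = logical(0)),
    exclusions = exclusions), class = "hj_pair_table")
}

#' @export
print.hj_pair_table <- function(x, ...) {
  cat(sprintf("hj_pair_table: %d atoms, %d overridden pairs (%d scaled), %d exclusions\n",
              nrow(x$atoms), nrow(x$overrides), sum(x$overrides$scaled),
              nrow(x$exclusions)))
  invisible(x)
}

#' Look up pair parameters
#'
#' Resolves `eps_ij`/`rmin_ij` for atom-index pairs, honouring
#' overrides and exclusions. Lookup is symmetric in (i, j).
#'
#' @param table an `hj_pair_table`.
#' @param i,j atom indices (vectors of equal length).
#' @return data.frame with columns `i`, `j`, `epsilon`, `rmin`,
#'   `scaled`, `excluded`; excluded pairs carry `NA` parameters.
#' @export
lj_params <- function(table, i, j) {
  stopifnot(inherits(table, "hj_pair_table"))
  a <- table$atoms
  p <- canonical_pairs(i, j)
  eps <- sqrt(a$epsilon[p[, 1]] * a$epsilon[p[, 2]])
  rmin <- a$rmin_half[p[, 1]] + a$rmin_half[p[, 2]]
  scaled <- rep(FALSE, nrow(p))
  if (nrow(table$overrides)) {
    key <- pair_key(p[, 1], p[, 2])
    okey <- pair_key(table$overrides$i, table$overrides$j)
    hit <- match(key, okey)
    has <- !is.na(hit)
    eps[has] <- table$overrides$epsilon[hit[has]]
    rmin[has] <- table$overrides$rmin[hit[has]]
    scaled[has] <- table$overrides$scaled[hit[has]]
  }
  excluded <- rep(FALSE, nrow(p))
  if (nrow(table$exclusions)) {
    excluded <- pair_key(p[, 1], p[, 2]) %in%
      pair_key(table$exclusions[, 1], table$exclusions[, 2])
  }
  eps[excluded] <- NA_real_
  rmin[excluded] <- NA_real_
  data.frame(i = p[, 1], j = p[, 2], epsilon = eps, rmin = rmin,
             scaled = scaled, excluded = excluded)
}

#' Default Watson-Crick hydrogen-bond atom templates
#'
#' Per-base atom names of the WC H-bond donors/acceptors and their
#' polar hydrogens, used to exempt base-pairing atoms from LJ scaling.
#' The exemption rule names a role, not an atom list, so the list is a
#' configurable template; these defaults cover the standard DNA bases
#' under both plain and DNA-prefixed residue names.
#'
#' @return named list: residue name -> character vector of atom names.
#' @export
wc_atom_templates <- function() {
  base <- list(
    A = c("N1", "N6", "H61", "H62"),
    T = c("O4", "N3", "H3", "O2"),
    G = c("O6", "N1", "H1", "N2", "H21", "H22"),
    C = c("N4", "H41", "H42", "N3", "O2"))
  out <- base
  for (nm in names(base)) {
    out[[paste0("D", nm)]] <- base[[nm]]
    for (suf in c("3", "5")) out[[paste0("D", nm, suf)]] <- base[[nm]]
  }
  out
}

#' Select branch-point atoms for LJ scaling
#'
#' All atoms of the named residues (nucleobases, sugars and phosphate
#' groups) form the selection; when `exclude_wc` is set, Watson-Crick
#' H-bond donors/acceptors and their polar hydrogens are listed as
#' exempt so base-pairing stability is untouched.
#'
#' @param atoms an [hj_atoms()] table.
#' @param branch_residues integer vector of residue ids at the branch
#'   point (must be non-empty and present in the topology).
#' @param lambda_factor LJ well-depth scaling factor, in (0, 1].
#' @param exclude_wc exempt WC atoms? (default TRUE)
#' @param wc_templates per-residue WC atom-name list, see
#'   [wc_atom_templates()].
#' @return object of class `hj_scaling_spec` with fields
#'   `lambda_factor`, `selection` (atom indices) and `wc_excluded`.
#' @export
select_branchpoint_atoms <- function(atoms, branch_residues,
                                     lambda_factor = 0.75,
                                     exclude_wc = TRUE,
                                     wc_templates = wc_atom_templates()) {
  stopifnot(inherits(atoms, "hj_atoms"))
  if (length(branch_residues) == 0)
    stop("branch_residues must name at least one residue")
  missing <- setdiff(branch_residues, atoms$resid)
  if (length(missing))
    stop("residues not in topology: ", paste(missing, collapse = ", "))
  in_res <- atoms$resid %in% branch_residues
  selection <- atoms$index[in_res]
  wc <- integer(0)
  if (exclude_wc) {
    tmpl <- wc_templates[match(atoms$resname, names(wc_templates))]
    is_wc <- mapply(function(nm, t) !is.null(t) && nm %in% t,
                    atoms$name, tmpl)
    wc <- atoms$index[in_res & is_wc]
  }
  hj_scaling_spec(lambda_factor, selection, wc)
}

#' @rdname select_branchpoint_atoms
#' @param selection,wc_excluded atom-index vectors.
#' @export
hj_scaling_spec <- function(lambda_factor, selection, wc_excluded = integer(0)) {
  if (!is.numeric(lambda_factor) || length(lambda_factor) != 1 ||
      lambda_factor <= 0 || lambda_factor > 1)
    stop("lambda_factor must be in (0, 1]")
  structure(list(lambda_factor = lambda_factor,
                 selection = sort(unique(as.integer(selection))),
                 wc_excluded = sort(unique(as.integer(wc_excluded)))),
            class = "hj_scaling_spec")
}

#' Scale branch-point LJ well depths (NBfix)
#'
#' Multiplies `eps_ij` by `lambda_factor` for every non-excluded pair
#' whose BOTH ends lie in the effective selection (selection minus WC
#' exemptions). `rmin` is untouched; pairs with at least one end
#' outside the region keep their original parameters bit-for-bit.
#' Applying the operation twice scales twice; it is not idempotent.
#'
#' @param table an `hj_pair_table`.
#' @param spec an `hj_scaling_spec`.
#' @return a new `hj_pair_table` with the scaled pairs stored as
#'   flagged overrides.
#' @export
apply_lambda_scaling <- function(table, spec) {
  stopifnot(inherits(table, "hj_pair_table"), inherits(spec, "hj_scaling_spec"))
  lam <- spec$lambda_factor
  eff <- setdiff(spec$selection, spec$wc_excluded)
  if (length(eff) < 2 || lam == 1) return(table)
  pr <- t(utils::combn(sort(eff), 2))
  cur <- lj_params(table, pr[, 1], pr[, 2])
  keep <- !cur$excluded
  cur <- cur[keep, , drop = FALSE]
  new_over <- data.frame(i = cur$i, j = cur$j,
                         epsilon = lam * cur$epsilon, rmin = cur$rmin,
                         scaled = TRUE)
  table$overrides <- merge_overrides(table$overrides, new_over)
  table
}

# later overrides replace earlier ones for the same pair
merge_overrides <- function(old, new) {
  if (nrow(old) == 0) return(new)
  okey <- pair_key(old$i, old$j)
  nkey <- pair_key(new$i, new$j)
  rbind(old[!(okey %in% nkey), , drop = FALSE], new)
}

#' Cation-phosphate vdW override (CUfix-style)
#'
#' @param cation_types atom-type names of the cations (default `"K+"`
#'   with common AMBER aliases).
#' @param oxygen_types phosphate-oxygen type names (default the
#'   non-bridging AMBER names `O1P`/`O2P`/`OP1`/`OP2`; the bridging
#'   ester oxygens are deliberately not included).
#' @param rmin_increase increase of the pair optimal distance, Angstrom.
#' @return object of class `hj_cufix_spec`.
#' @export
hj_cufix_spec <- function(cation_types = c("K+", "K", "k+"),
                          oxygen_types = c("O1P", "O2P", "OP1", "OP2"),
                          rmin_increase = 0.1) {
  stopifnot(is.numeric(rmin_increase), rmin_increase >= 0)
  structure(list(cation_types = cation_types, oxygen_types = oxygen_types,
                 rmin_increase = rmin_increase), class = "hj_cufix_spec")
}

#' Apply the cation-phosphate CUfix override
#'
#' Increases `rmin_ij` by `rmin_increase` for every cation x
#' phosphate-oxygen pair; epsilon is untouched. Type names absent from
#' the topology trigger a warning and are ignored.
#'
#' @param table an `hj_pair_table`.
#' @param spec an [hj_cufix_spec()].
#' @return a new `hj_pair_table`.
#' @export
apply_cufix <- function(table, spec) {
  stopifnot(inherits(table, "hj_pair_table"), inherits(spec, "hj_cufix_spec"))
  a <- table$atoms
  unknown <- setdiff(c(spec$cation_types, spec$oxygen_types), a$type)
  known_cat <- intersect(spec$cation_types, a$type)
  known_oxy <- intersect(spec$oxygen_types, a$type)
  if (length(unknown) && (length(known_cat) == 0 || length(known_oxy) == 0))
    warning("no atoms for type name(s): ", paste(unknown, collapse = ", "),
            "; CUfix is a no-op for those")
  if (spec$rmin_increase == 0) return(table)
  cat_idx <- a$index[a$type %in% known_cat]
  oxy_idx <- a$index[a$type %in% known_oxy]
  if (length(cat_idx) == 0 || length(oxy_idx) == 0) return(table)
  pr <- expand.grid(i = cat_idx, j = oxy_idx)
  pr <- pr[pr$i != pr$j, , drop = FALSE]
  cur <- lj_params(table, pr$i, pr$j)
  cur <- cur[!duplicated(pair_key(cur$i, cur$j)) & !cur$excluded, , drop = FALSE]
  if (nrow(cur) == 0) return(table)
  new_over <- data.frame(i = cur$i, j = cur$j, epsilon = cur$epsilon,
                         rmin = cur$rmin + spec$rmin_increase,
                         scaled = cur$scaled)
  table$overrides <- merge_overrides(table$overrides, new_over)
  table
}

#' Single-point van der Waals energy
#'
#' Plain pairwise 12-6 sum `E = sum eps_ij ((rmin_ij/r)^12 - 2
#' (rmin_ij/r)^6)` in kcal/mol over the non-excluded pairs (optionally
#' a subset), with minimum-image distances when a periodic cell is
#' given. Restricting to the scaled subset gives the quantity whose
#' lambda-dependence is exactly linear.
#'
#' @param coords n x 3 matrix of positions, Angstrom.
#' @param table an `hj_pair_table`.
#' @param pair_subset optional two-column matrix of atom-index pairs;
#'   default all non-excluded pairs.
#' @param box optional periodic cell.
#' @return energy in kcal/mol.
#' @export
single_point_vdw_energy <- function(coords, table, pair_subset = NULL,
                                    box = NULL) {
  stopifnot(inherits(table, "hj_pair_table"), is.matrix(coords))
  n <- nrow(table$atoms)
  if (nrow(coords) < n) stop("coordinates must cover all atoms")
  if (is.null(pair_subset)) {
    if (n < 2) return(0)
    pair_subset <- t(utils::combn(n, 2))
  }
  p <- lj_params(table, pair_subset[, 1], pair_subset[, 2])
  p <- p[!p$excluded, , drop = FALSE]
  if (nrow(p) == 0) return(0)
  d <- coords[p$i, , drop = FALSE] - coords[p$j, , drop = FALSE]
  d <- minimum_image(d, box)
  r <- sqrt(rowSums(d^2))
  if (any(r == 0)) stop("zero interatomic distance in vdW evaluation")
  x6 <- (p$rmin / r)^6
  sum(p$epsilon * (x6^2 - 2 * x6))
}

#' Write a GROMACS-style nonbonded pair-override block
#'
#' Emits the overridden pairs as a `[ nonbond_params ]`-dialect text
#' block keyed by atom type (one synthetic type per atom), converting
#' kcal/mol to kJ/mol with the exact factor 4.184 and Angstrom to nm;
#' sigma is `rmin / 2^(1/6)`.
#'
#' @param table an `hj_pair_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gromacs_overrides <- function(table, path) {
  stopifnot(inherits(table, "hj_pair_table"))
  ov <- table$overrides
  a <- table$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[ nonbond_params ]",
               "; ai aj func sigma(nm) epsilon(kJ/mol)"), con)
  if (nrow(ov)) {
    sigma_nm <- ov$rmin / 2^(1 / 6) / 10
    eps_kj <- kcal_to_kj(ov$epsilon)
    writeLines(sprintf("%-8s %-8s 1 %20.12e %20.12e",
                       sprintf("ty%d", ov$i), sprintf("ty%d", ov$j),
                       sigma_nm, eps_kj), con)
  }
  invisible(path)
}
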