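#' Radial distribution function around a selection
#'
#' Counts target atoms in spherical shells around the centre atoms,
#' averaged over frames and normalized by the ideal-gas expectation at
#' the target's mean density (targets per box volume), so a uniform
#' gas gives `g(r) = 1`. Minimum-image distances are used; a periodic
#' cell is required for the density normalization unless `density` is
#' supplied.
#'
#' @param traj an [hj_trajectory()].
#' @param center_idx,target_idx atom index vectors (non-empty).
#' @param breaks radial bin edges in Angstrom (e.g. `seq(0, 15, 0.2)`).
#' @param density target number density per cubic Angstrom (default:
#'   from the box volume).
#' @return data.frame `r` (bin centres), `g`, `count` (mean raw count
#'   per centre per frame).
#' @export
rdf <- function(traj, center_idx, target_idx, breaks = seq(0, 15, 0.25),
                density = NULL) {
  stopifnot(inherits(traj, "hj_trajectory"),
            length(center_idx) > 0, length(target_idx) > 0)
  if (any(diff(breaks) <= 0)) stop("bin widths must be positive")
  if (is.null(density)) {
    if (is.null(traj$box))
      stop("a periodic cell (or explicit density) is needed for RDF normalization")
    density <- length(target_idx) / abs(det(traj$box))
  }
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  nf <- length(traj$coords)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[[f]]
    r <- cross_distances(xyz[center_idx, , drop = FALSE],
                         xyz[target_idx, , drop = FALSE], traj$box)
    h <- graphics::hist(r[r >= breaks[1] & r <= breaks[nb + 1]],
                        breaks = breaks, plot = FALSE)
    counts <- counts + h$counts
  }
  shell_vol <- 4 / 3 * pi * diff(breaks^3)
  expected <- shell_vol * density * length(center_idx) * nf
  data.frame(r = (breaks[-1] + breaks[-(nb + 1)]) / 2,
             g = counts / expected,
             count = counts / (length(center_idx) * nf))
}

#' Ionic bridging incidence at the branch-point phosphates
#'
#' A frame counts as bridged when a potassium ion sits within `cutoff`
#' (default 6 Angstrom) of at least one of the three central phosphate
#' groups of each crossing strand. In the default `"single-ion"`
#' semantics one ion must satisfy both strands simultaneously (an ionic
#' bridge needs one bridging ion); `"any-ion"` lets different ions
#' serve the two strands.
#'
#' @param traj an [hj_trajectory()].
#' @param strand_a,strand_b atom indices of the three central
#'   phosphorus atoms of each crossing strand (distances are measured
#'   to the phosphorus atom).
#' @param ion_idx ion atom indices.
#' @param cutoff Angstrom, `> 0` (default 6).
#' @param mode `"single-ion"` (default) or `"any-ion"`.
#' @return list: `percentage` of bridged frames, logical `bridged`
#'   per frame.
#' @export
bridging_incidence <- function(traj, strand_a, strand_b, ion_idx,
                               cutoff = 6, mode = c("single-ion", "any-ion")) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj, "hj_trajectory"), cutoff > 0)
  if (length(strand_a) != 3 || length(strand_b) != 3)
    stop("each crossing strand needs exactly three central phosphate groups")
  if (length(ion_idx) == 0) {
    warning("no ions selected; bridging incidence is 0%")
    return(list(percentage = 0, bridged = rep(FALSE, length(traj$coords))))
  }
  nf <- length(traj$coords)
  bridged <- logical(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[[f]]
    da <- cross_distances(xyz[ion_idx, , drop = FALSE],
                          xyz[strand_a, , drop = FALSE], traj$box)
    db <- cross_distances(xyz[ion_idx, , drop = FALSE],
                          xyz[strand_b, , drop = FALSE], traj$box)
    near_a <- apply(da <= cutoff, 1, any)
    near_b <- apply(db <= cutoff, 1, any)
    bridged[f] <- if (mode == "single-ion") any(near_a & near_b)
    else any(near_a) && any(near_b)
  }
  list(percentage = 100 * mean(bridged), bridged = bridged)
}

#' Junction-centre position per frame
#'
#' The geometric centre of the two branch-point phosphates on the
#' crossing strands.
#'
#' @param traj an [hj_trajectory()].
#' @param phosphate_idx the two branch-point phosphorus atom indices.
#' @return matrix (frames x 3) of centre positions.
#' @export
junction_center <- function(traj, phosphate_idx) {
  stopifnot(length(phosphate_idx) == 2)
  t(vapply(traj$coords, function(xyz)
    colMeans(xyz[phosphate_idx, , drop = FALSE]), numeric(3)))
}

#' Ions around the junction centre
#'
#' @param traj an [hj_trajectory()].
#' @param center per-frame centre positions (frames x 3 matrix, e.g.
#'   from [junction_center()]) or a single length-3 point.
#' @param ion_idx ion atom indices.
#' @param cutoff counting radius, Angstrom (default 10).
#' @return list: `counts` per frame, `mean` time average.
#' @export
center_ion_count <- function(traj, center, ion_idx, cutoff = 10) {
  stopifnot(cutoff > 0)
  nf <- length(traj$coords)
  if (is.null(dim(center))) center <- matrix(center, nf, 3, byrow = TRUE)
  counts <- integer(nf)
  for (f in seq_len(nf)) {
    if (length(ion_idx) == 0) next
    d <- minimum_image(sweep(traj$coords[[f]][ion_idx, , drop = FALSE],
                             2, center[f, ]), traj$box)
    counts[f] <- sum(sqrt(rowSums(d^2)) <= cutoff)
  }
  list(counts = counts, mean = mean(counts))
}

#' Effective bulk cation concentration from radial profiles
#'
#' Radial concentration profile around the junction centre from the
#' ion-to-water-oxygen count ratio per shell,
#' `c(r) = n_ion(r)/n_water(r) * 55.34 mol/L`, with the bulk estimate
#' taken as the average of `c(r)` over the outermost `shell_fraction`
#' of sampled radii (near the box edge). Shells without water are
#' flagged undefined and excluded from the bulk average. Counterion
#' condensation near the solute makes this estimate fall below the
#' nominal box concentration.
#'
#' @param traj an [hj_trajectory()].
#' @param center per-frame centres (frames x 3) or one point.
#' @param ion_idx,water_idx ion and water-oxygen atom indices
#'   (water selection must be non-empty).
#' @param breaks radial bin edges, Angstrom.
#' @param shell_fraction outermost fraction of radii averaged for the
#'   bulk estimate (default 0.1).
#' @return list of class `hj_conc_profile`: `profile` (data.frame `r`,
#'   `n_ion`, `n_water`, `c_mol_l`) and `bulk_estimate` (mol/L) with
#'   attribute `shell` (the radii averaged).
#' @export
effective_bulk_concentration <- function(traj, center, ion_idx, water_idx,
                                         breaks = seq(0, 30, 1),
                                         shell_fraction = 0.1) {
  stopifnot(length(water_idx) > 0, shell_fraction > 0, shell_fraction <= 1)
  nf <- length(traj$coords)
  if (is.null(dim(center))) center <- matrix(center, nf, 3, byrow = TRUE)
  nb <- length(breaks) - 1
  n_ion <- numeric(nb); n_wat <- numeric(nb)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[[f]]
    radial_counts <- function(idx) {
      if (length(idx) == 0) return(numeric(nb))
      d <- minimum_image(sweep(xyz[idx, , drop = FALSE], 2, center[f, ]),
                         traj$box)
      r <- sqrt(rowSums(d^2))
      graphics::hist(r[r >= breaks[1] & r <= breaks[nb + 1]],
                     breaks = breaks, plot = FALSE)$counts
    }
    n_ion <- n_ion + radial_counts(ion_idx)
    n_wat <- n_wat + radial_counts(water_idx)
  }
  conc <- ifelse(n_wat > 0, n_ion / n_wat * .WATER_MOLARITY, NA_real_)
  r_mid <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  sampled <- which(n_wat > 0)
  if (length(sampled) == 0) stop("no water found in any radial shell")
  r_max <- max(r_mid[sampled])
  r_lo <- r_max * (1 - shell_fraction)
  outer_bins <- sampled[r_mid[sampled] >= r_lo]
  bulk <- stats::weighted.mean(conc[outer_bins], n_wat[outer_bins])
  structure(list(profile = data.frame(r = r_mid, n_ion = n_ion,
                                      n_water = n_wat, c_mol_l = conc),
                 bulk_estimate = bulk,
                 shell = range(r_mid[outer_bins])),
            class = "hj_conc_profile")
}

#' @export
print.hj_conc_profile <- function(x, ...) {
  cat(sprintf("radial concentration profile: bulk estimate %.4f mol/L (shell %.1f-%.1f A)\n",
              x$bulk_estimate, x$shell[1], x$shell[2]))
  invisible(x)
}
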