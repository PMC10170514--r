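# shared fixture builders and independent oracles

# random LJ atom table (no structure, for pair-table / energy property tests)
random_atoms <- function(n, seed = 1) {
  set.seed(seed)
  hj_atoms(name = sprintf("X%d", seq_len(n)),
           resid = rep(1:2, length.out = n),
           resname = "RES",
           epsilon = runif(n, 0.05, 0.5),
           rmin_half = runif(n, 1.2, 2.0))
}

random_coords <- function(n, seed = 1, spread = 12) {
  set.seed(seed)
  matrix(runif(3 * n, 0, spread), n, 3)
}

# independent brute-force vdW double loop (no table machinery)
brute_vdw <- function(coords, eps, rmin_half, pairs = NULL, scale = NULL,
                      scale_set = integer(0)) {
  n <- length(eps)
  if (is.null(pairs)) pairs <- t(combn(n, 2))
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    epsij <- sqrt(eps[i] * eps[j])
    if (!is.null(scale) && i %in% scale_set && j %in% scale_set)
      epsij <- epsij * scale
    rm <- rmin_half[i] + rmin_half[j]
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    x6 <- (rm / r)^6
    e <- e + epsij * (x6^2 - 2 * x6)
  }
  e
}

# independent rule evaluator for the seven state definitions
brute_classify <- function(s, lo = 5, hi = 50) {
  hits <- character(0)
  if (all(s < lo)) hits <- c(hits, "OPEN")
  if (s[1] > hi && s[2] > hi) hits <- c(hits, "CLOSED_I")
  if (s[3] > hi && s[4] > hi) hits <- c(hits, "CLOSED_II")
  if (s[1] > hi && all(s[2:4] < lo)) hits <- c(hits, "HC_IL")
  if (s[2] > hi && all(s[c(1, 3, 4)] < lo)) hits <- c(hits, "HC_IR")
  if (s[3] > hi && all(s[c(1, 2, 4)] < lo)) hits <- c(hits, "HC_IIL")
  if (s[4] > hi && all(s[1:3] < lo)) hits <- c(hits, "HC_IIR")
  if (length(hits) == 1) hits else "UNASSIGNED"
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# nucleotide-like residues with full atom lists, for WC-selection tests
dna_test_atoms <- function() {
  res <- list(
    list(resname = "DG", atoms = c("P", "O1P", "O2P", "O5'", "C5'", "C4'",
                                   "O4'", "C3'", "O3'", "C2'", "C1'", "N9",
                                   "C8", "H8", "N7", "C5", "C6", "O6", "N1",
                                   "H1", "C2", "N2", "H21", "H22", "N3", "C4")),
    list(resname = "DC", atoms = c("P", "O1P", "O2P", "O5'", "C5'", "C4'",
                                   "O4'", "C3'", "O3'", "C2'", "C1'", "N1",
                                   "C2", "O2", "N3", "C4", "N4", "H41", "H42",
                                   "C5", "H5", "C6", "H6")),
    list(resname = "DA", atoms = c("P", "O1P", "O2P", "O5'", "C5'", "C4'",
                                   "O4'", "C3'", "O3'", "C2'", "C1'", "N9",
                                   "C8", "H8", "N7", "C5", "C6", "N6", "H61",
                                   "H62", "N1", "C2", "H2", "N3", "C4")),
    list(resname = "DT", atoms = c("P", "O1P", "O2P", "O5'", "C5'", "C4'",
                                   "O4'", "C3'", "O3'", "C2'", "C1'", "N1",
                                   "C2", "O2", "N3", "H3", "C4", "O4", "C5",
                                   "C7", "C6", "H6")))
  name <- unlist(lapply(res, `[[`, "atoms"))
  resname <- rep(vapply(res, `[[`, "", "resname"),
                 vapply(res, function(r) length(r$atoms), 0L))
  resid <- rep(seq_along(res),
               vapply(res, function(r) length(r$atoms), 0L))
  hj_atoms(name = name, resid = resid, resname = resname,
           epsilon = 0.1, rmin_half = 1.7)
}

# the WC atom lists of the default template, spelled out independently
wc_oracle <- list(DA = c("N1", "N6", "H61", "H62"),
                  DT = c("O4", "N3", "H3", "O2"),
                  DG = c("O6", "N1", "H1", "N2", "H21", "H22"),
                  DC = c("N4", "H41", "H42", "N3", "O2"))

# 1D double-well study conditions shared by recovery tests: barrier
# 3.5 kT, wells at +-1, domain [-1.6, 1.6], tilt chosen by quadrature
# so the analytic closed-open difference is exactly 2 kT
dw_regions <- function() list(OPEN = state_region("OPEN", -1.6, 0),
                              CLOSED = state_region("CLOSED", 0, 1.6))
dw_tilt_for_2kt <- function() {
  f <- function(t) analytic_state_dg(double_well_1d(3.5, t), dw_regions(),
                                     -1.6, 1.6)$dg[2] - 2
  uniroot(f, c(1.5, 3), tol = 1e-10)$root
}
dw_params <- function(sigma = 0.15)
  wtmetad_params(w0 = 2.5, sigma = sigma, gamma = 15, deposit_stride = 500,
                 grid_min = -1.6, grid_max = 1.6, grid_n = 161)

# uniform-random "ideal gas" of ions around a single centre atom
make_gas_traj <- function(n_ions = 1500, n_frames = 20, L = 50, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(name = c("C", rep("K", n_ions)),
                      resid = seq_len(n_ions + 1),
                      resname = c("CTR", rep("K", n_ions)))
  coords <- lapply(seq_len(n_frames), function(f)
    rbind(c(0, 0, 0),
          matrix(runif(3 * n_ions, -L / 2, L / 2), n_ions, 3)))
  hj_trajectory(atoms, coords, box = c(L, L, L))
}

# closed-open free-energy difference (kT) recovered from a toy run
recover_dg <- function(run, regions = dw_regions()) {
  ens <- reweight(run$colvar, run$hills, estimator = "averaged_bias")
  state_free_energies(ens, regions, kT_energy = 1, cv_names = "cv1")$dg[2]
}
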