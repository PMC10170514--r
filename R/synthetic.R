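#' Markov model of the junction state kinetics
#'
#' Discrete-time Markov chain over the seven junction states restricted
#' to the opening-closing graph: each closed isomer exchanges with the
#' open state through its two half-closed intermediates, plus rare
#' direct closed-open edges. Forbidden moves (closed isomer to closed
#' isomer, half-closed to half-closed) have probability zero. Dwell
#' times are geometric. The default branching echoes the observed
#' pathway preferences (IL favoured over IR for isomer I, IIR for
#' isomer II, direct transitions rare).
#'
#' @param stay_end,stay_hc self-transition probability of end states
#'   and half-closed states.
#' @param branch named list overriding the per-state branching of the
#'   leave probability; see the function body for the defaults.
#' @return object of class `hj_state_model` with a row-stochastic
#'   transition matrix `P`.
#' @export
hj_state_model <- function(stay_end = 0.97, stay_hc = 0.6, branch = NULL) {
  states <- c("OPEN", "CLOSED_I", "CLOSED_II", "HC_IL", "HC_IR",
              "HC_IIL", "HC_IIR")
  br <- list(
    OPEN      = c(HC_IL = 0.33, HC_IR = 0.22, HC_IIL = 0.14, HC_IIR = 0.21,
                  CLOSED_I = 0.05, CLOSED_II = 0.05),
    CLOSED_I  = c(HC_IL = 0.65, HC_IR = 0.28, OPEN = 0.07),
    CLOSED_II = c(HC_IIR = 0.60, HC_IIL = 0.33, OPEN = 0.07),
    HC_IL     = c(OPEN = 0.5, CLOSED_I = 0.5),
    HC_IR     = c(OPEN = 0.5, CLOSED_I = 0.5),
    HC_IIL    = c(OPEN = 0.5, CLOSED_II = 0.5),
    HC_IIR    = c(OPEN = 0.5, CLOSED_II = 0.5))
  if (!is.null(branch)) br[names(branch)] <- branch
  P <- matrix(0, 7, 7, dimnames = list(states, states))
  for (s in states) {
    stay <- if (s %in% end_states()) stay_end else stay_hc
    P[s, s] <- stay
    b <- br[[s]] / sum(br[[s]])
    P[s, names(b)] <- (1 - stay) * b
  }
  if (any(abs(rowSums(P) - 1) > 1e-12)) stop("transition rows must sum to 1")
  structure(list(states = states, P = P), class = "hj_state_model")
}

#' Simulate a state-label sequence with ground-truth transitions
#'
#' Realizes the Markov chain and records, by construction, the
#' ground-truth reactive transitions (end state to different end
#' state, with the half-closed intermediates visited) and unsuccessful
#' attempts - the reference against which the transition-extraction
#' machinery is validated.
#'
#' @param model an [hj_state_model()].
#' @param n_frames sequence length.
#' @param seed integer seed.
#' @param init initial state (default `"OPEN"`).
#' @return list: `labels` (factor), `transitions`, `attempts`
#'   (data.frames in the [extract_transitions()] layout).
#' @export
generate_state_sequence <- function(model, n_frames, seed = 1,
                                    init = "OPEN") {
  stopifnot(inherits(model, "hj_state_model"))
  absorbing <- diag(model$P) >= 1
  if (all(absorbing))
    warning("all states are absorbing; the sequence will never move")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  states <- model$states
  lab <- character(n_frames)
  cur <- init
  for (f in seq_len(n_frames)) {
    lab[f] <- cur
    cur <- sample(states, 1, prob = model$P[cur, ])
  }
  gt <- extract_transitions(lab, max_unassigned_gap = 0)
  list(labels = factor(lab, levels = hj_state_levels()),
       transitions = gt$transitions, attempts = gt$attempts)
}

#' Scripted pathway sequence with exact transition counts
#'
#' Builds a deterministic label sequence shuttling between a closed
#' isomer and the open state with an exact, user-chosen number of
#' transitions through each half-closed intermediate and directly -
#' e.g. the 46-transition script (32 via IL, 11 via IR, 3 direct) used
#' to validate pathway counting.
#'
#' @param n_via named integer vector: transitions per half-closed
#'   intermediate (e.g. `c(HC_IL = 32, HC_IR = 11)`).
#' @param n_direct number of direct transitions.
#' @param closed which closed isomer (default `"CLOSED_I"`).
#' @param dwell_end,dwell_hc frames spent in end and half-closed
#'   states.
#' @param seed seed for shuffling the pathway order (deterministic
#'   given seed).
#' @return character label sequence.
#' @export
script_pathway_sequence <- function(n_via = c(HC_IL = 32, HC_IR = 11),
                                    n_direct = 3, closed = "CLOSED_I",
                                    dwell_end = 5, dwell_hc = 2,
                                    seed = 1) {
  pathway <- c(rep(names(n_via), times = n_via), rep("direct", n_direct))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pathway <- sample(pathway)
  ends <- c(closed, "OPEN")
  lab <- rep(ends[1], dwell_end)
  side <- 1L
  for (p in pathway) {
    if (p != "direct") lab <- c(lab, rep(p, dwell_hc))
    side <- 3L - side
    lab <- c(lab, rep(ends[side], dwell_end))
  }
  lab
}

#' Geometry template for synthetic junction trajectories
#'
#' Each of the four branch-point base-pair groups is rendered as a
#' rigid planar plate of pseudo-atoms (default 4 x 6 at 1.4 Angstrom
#' spacing, about the atom count of a two-base nucleobase pair);
#' stacked pairs sit `stack_sep` apart face-to-face, unstacked groups
#' at least 20 Angstrom from everything. Four 3-atom arm stubs and the
#' two crossing strands' three central phosphorus atoms are placed
#' around the junction centre. The distances guarantee that the state
#' classifier reproduces the generating state: a stacked pair scores a
#' raw CV near 100, an isolated one near 1.
#'
#' @param plate_nx,plate_ny plate dimensions (atoms).
#' @param spacing in-plane atom spacing, Angstrom.
#' @param stack_sep face-to-face separation of a stacked pair.
#' @param jitter Gaussian positional noise per coordinate, Angstrom.
#' @return object of class `hj_geometry_template`.
#' @export
hj_geometry_template <- function(plate_nx = 4, plate_ny = 6, spacing = 1.4,
                                 stack_sep = 3.2, jitter = 0.15) {
  stopifnot(plate_nx >= 2, plate_ny >= 2, spacing > 0, stack_sep > 0,
            jitter >= 0)
  structure(list(plate_nx = plate_nx, plate_ny = plate_ny,
                 spacing = spacing, stack_sep = stack_sep,
                 jitter = jitter), class = "hj_geometry_template")
}

plate_coords <- function(tmpl) {
  nx <- tmpl$plate_nx; ny <- tmpl$plate_ny; sp <- tmpl$spacing
  as.matrix(expand.grid(x = ((1:nx) - (nx + 1) / 2) * sp,
                        y = ((1:ny) - (ny + 1) / 2) * sp, z = 0))
}

# per-state group-centre layout; stacked pairs share a lateral site
state_layout <- function(state, stack_sep) {
  site_a <- c(-15, 0, 0); site_b <- c(15, 0, 0)
  iso <- list(c(15, 18, 0), c(15, -18, 0), c(-15, 18, 0), c(-15, -18, 0))
  up <- c(0, 0, stack_sep)
  open_pos <- list(I = c(-20, 0, 0), II = c(0, 20, 0),
                   III = c(20, 0, 0), IV = c(0, -20, 0))
  stacked <- switch(state,
    OPEN = list(),
    CLOSED_I = list(c("I", "II"), c("III", "IV")),
    CLOSED_II = list(c("I", "IV"), c("II", "III")),
    HC_IL = list(c("I", "II")),
    HC_IR = list(c("III", "IV")),
    HC_IIL = list(c("I", "IV")),
    HC_IIR = list(c("II", "III")),
    stop("unknown state: ", state))
  pos <- open_pos
  sites <- list(site_a, site_b)
  used <- character(0)
  for (k in seq_along(stacked)) {
    gg <- stacked[[k]]
    pos[[gg[1]]] <- sites[[k]]
    pos[[gg[2]]] <- sites[[k]] + up
    used <- c(used, gg)
  }
  if (length(stacked) == 1) {
    # isolated groups go to far corners away from the stacked site
    rest <- setdiff(c("I", "II", "III", "IV"), used)
    for (k in seq_along(rest)) pos[[rest[k]]] <- iso[[k]]
  }
  pos
}

synthetic_atom_table <- function(tmpl) {
  npp <- tmpl$plate_nx * tmpl$plate_ny
  groups <- c("I", "II", "III", "IV")
  at <- data.frame(
    name = c(rep(sprintf("B%02d", seq_len(npp)), 4),
             rep(c("A1", "A2", "A3"), 4), rep(c("P1", "P2", "P3"), 2)),
    resid = c(rep(1:4, each = npp), rep(5:8, each = 3), rep(9:10, each = 3)),
    # stem plates S1..S4 (PDB resname field is three characters wide)
    resname = c(rep(paste0("S", 1:4), each = npp),
                rep("ARM", 12), rep("PHO", 6)),
    element = c(rep("C", 4 * npp), rep("C", 12), rep("P", 6)),
    stringsAsFactors = FALSE)
  at$group <- c(rep(groups, each = npp), rep(NA, 18))
  at
}

static_scaffold <- function() {
  # arm stubs on the diagonals, three central phosphates per crossing
  # strand flanking the centre so one ion can bridge both strands
  arms <- do.call(rbind, lapply(list(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)),
                                function(d) cbind(28 * d[1] + c(0, 2, 4) * d[1],
                                                  28 * d[2], 0)))
  phos <- rbind(c(-3, 2.5, 0), c(0, 4, 0), c(3, 2.5, 0),
                c(-3, -2.5, 0), c(0, -4, 0), c(3, -2.5, 0))
  rbind(arms, phos)
}

#' Render a state sequence into a synthetic junction trajectory
#'
#' Generates coordinates for every frame: the four rigid nucleobase
#' plates arranged per the frame's state, the arm stubs and central
#' phosphates, plus optional ion and water-oxygen fields per
#' [hj_ion_field()]. Jitter is added to every junction atom. The
#' generator-classifier contract is checked when `verify` is on: the
#' stacking CVs of each rendered frame must classify back to the
#' generating label, otherwise rendering is refused.
#'
#' @param labels character/factor state sequence.
#' @param template an [hj_geometry_template()].
#' @param ion_field optional [hj_ion_field()].
#' @param seed integer seed.
#' @param verify check the generator-classifier round trip (default
#'   TRUE).
#' @return an [hj_trajectory()]; group atom indices are in
#'   `attr(, "groups")`, phosphate/ion/water selections in
#'   `attr(, "selections")`.
#' @export
render_trajectory <- function(labels, template = hj_geometry_template(),
                              ion_field = NULL, seed = 1, verify = TRUE) {
  labels <- as.character(labels)
  bad <- setdiff(labels, setdiff(hj_state_levels(), "UNASSIGNED"))
  if (length(bad)) stop("cannot render state(s): ", paste(unique(bad), collapse = ", "))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  plate <- plate_coords(template)
  npp <- nrow(plate)
  at <- synthetic_atom_table(template)
  scaff <- static_scaffold()
  n_junction <- 4 * npp + nrow(scaff)
  box <- NULL
  ion_idx <- integer(0); water_idx <- integer(0)
  n_ion <- 0L; n_wat <- 0L
  if (!is.null(ion_field)) {
    # the junction layout spans about +-32 A; smaller periodic cells
    # would fold distant groups onto each other under minimum image
    if (ion_field$box < 56)
      stop("periodic box edge must be at least 56 A to hold the ",
           "junction layout without image overlap")
    box <- rep(ion_field$box, 3)
    n_ion <- ion_field$n_ion; n_wat <- ion_field$n_water
    if (n_ion > 0) {
      ion_idx <- n_junction + seq_len(n_ion)
      at <- rbind(at, data.frame(name = "K", resid = 10L + seq_len(n_ion),
                                 resname = "K", element = "K", group = NA))
    }
    if (n_wat > 0) {
      water_idx <- n_junction + n_ion + seq_len(n_wat)
      at <- rbind(at, data.frame(name = "O",
                                 resid = 10L + n_ion + seq_len(n_wat),
                                 resname = "WAT", element = "O", group = NA))
    }
  }
  nf <- length(labels)
  coords <- vector("list", nf)
  for (f in seq_len(nf)) {
    pos <- state_layout(labels[f], template$stack_sep)
    xyz <- rbind(
      sweep(plate, 2, -pos$I), sweep(plate, 2, -pos$II),
      sweep(plate, 2, -pos$III), sweep(plate, 2, -pos$IV), scaff)
    if (template$jitter > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = template$jitter),
                          nrow(xyz), 3)
    if (!is.null(ion_field))
      xyz <- rbind(xyz, place_ion_field(ion_field))
    coords[[f]] <- xyz
  }
  traj <- hj_trajectory(at, coords, box = box)
  groups <- split(seq_len(4 * npp), rep(c("I", "II", "III", "IV"),
                                        each = npp))
  attr(traj, "groups") <- groups
  attr(traj, "selections") <- list(
    strand_a = 4 * npp + 12 + 1:3, strand_b = 4 * npp + 12 + 4:6,
    branch_phosphates = 4 * npp + 12 + c(2, 5),
    arms = 4 * npp + 1:12, ions = ion_idx, waters = water_idx)
  if (verify) {
    cv <- compute_cv_series(traj, groups)
    got <- as.character(classify_states(cv))
    if (!all(got == labels))
      stop("template violates the classifiability invariant: ",
           sum(got != labels), " frame(s) misclassified ",
           "(reduce jitter or widen the layout)")
  }
  traj
}

#' Ion and water-proxy field specification
#'
#' Monovalent cations and water-oxygen pseudo-atoms in a cubic periodic
#' box. Ion count comes from the nominal molar concentration and the
#' box volume; waters are placed at the density of liquid water
#' (55.34 mol/L) unless overridden. A `condensed_fraction` of the ions
#' is placed within `r_condensed` of the box centre (the junction),
#' emulating counterion condensation; the rest, and all waters, are
#' uniform.
#'
#' @param concentration nominal mol/L.
#' @param box cubic box edge, Angstrom.
#' @param condensed_fraction fraction of ions near the centre, in
#'   `[0, 1]`.
#' @param r_condensed condensation radius, Angstrom.
#' @param n_water override the water count (default from 55.34 mol/L).
#' @param n_ion override the ion count.
#' @return object of class `hj_ion_field`.
#' @export
hj_ion_field <- function(concentration = 0.15, box = 60,
                         condensed_fraction = 0, r_condensed = 8,
                         n_water = NULL, n_ion = NULL) {
  stopifnot(concentration >= 0, box > 0,
            condensed_fraction >= 0, condensed_fraction <= 1)
  vol_l <- (box * 1e-8)^3 * 1e-3         # A^3 -> cm^3 -> litres
  if (is.null(n_ion))
    n_ion <- round(concentration * .N_AVOGADRO * vol_l)
  if (is.null(n_water))
    n_water <- round(.WATER_MOLARITY * .N_AVOGADRO * vol_l)
  structure(list(concentration = concentration, box = box,
                 condensed_fraction = condensed_fraction,
                 r_condensed = r_condensed,
                 n_ion = as.integer(n_ion), n_water = as.integer(n_water)),
            class = "hj_ion_field")
}

# draw one frame of ion + water positions, centred on the origin
place_ion_field <- function(field) {
  L <- field$box
  unif <- function(n) matrix(stats::runif(3 * n, -L / 2, L / 2), n, 3)
  n_cond <- round(field$condensed_fraction * field$n_ion)
  ions <- unif(field$n_ion - n_cond)
  if (n_cond > 0) {
    # uniform within the condensation sphere
    u <- stats::runif(n_cond)^(1 / 3) * field$r_condensed
    dir <- matrix(stats::rnorm(3 * n_cond), n_cond, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    ions <- rbind(dir * u, ions)
  }
  rbind(ions, unif(field$n_water))
}

#' Analytic state free energies of a toy surface
#'
#' Quadrature oracle: integrates `exp(-F)` over rectangular regions of
#' a 1D or 2D surface on a fine grid and returns the exact
#' `-kT log(P/P_open)` values the sampling machinery should recover.
#'
#' @param surface function of a length-d point, kT units.
#' @param regions named list of [state_region()]s including `OPEN`.
#' @param lower,upper integration bounds per dimension.
#' @param n grid points per dimension.
#' @return data.frame `state`, `dg` (kT units).
#' @export
analytic_state_dg <- function(surface, regions, lower, upper, n = 801) {
  d <- length(lower)
  ax <- lapply(seq_len(d), function(k) seq(lower[k], upper[k],
                                           length.out = n))
  if (d == 1) {
    p_dens <- exp(-vapply(ax[[1]], function(x) surface(x), 0))
    pts <- matrix(ax[[1]], ncol = 1)
  } else {
    p_dens <- as.numeric(exp(-outer(ax[[1]], ax[[2]], function(x, y)
      mapply(function(a, b) surface(c(a, b)), x, y))))
    pts <- as.matrix(expand.grid(ax[[1]], ax[[2]]))
  }
  P <- vapply(regions, function(rg) {
    m <- rep(TRUE, nrow(pts))
    for (k in seq_len(d))
      m <- m & pts[, k] >= rg$lower[k] & pts[, k] <= rg$upper[k]
    sum(p_dens[m])
  }, 0)
  dg <- -log(P / P[["OPEN"]])
  dg[["OPEN"]] <- 0
  data.frame(state = names(regions), dg = unname(dg))
}

#' Tilted double-well surfaces and the lambda family
#'
#' `double_well_1d(barrier, tilt)` is the quartic
#' `barrier ((x/x0)^2 - 1)^2 + tilt x / (2 x0)` (kT units) with minima
#' near `x = -x0` ("open") and `x = +x0` ("closed");
#' `lambda_family_surfaces` interpolates the tilt linearly in lambda so
#' the two wells are exactly equally deep at `lambda_star` - the
#' analytic crossing the free-energy-versus-lambda fit must recover.
#'
#' @param barrier barrier height, kT.
#' @param tilt well asymmetry, kT (positive lowers the `x < 0` well).
#' @param x0 half-distance between the minima.
#' @return a surface function (for `double_well_1d`) or a list with
#'   `surfaces`, `lambdas` and `lambda_star` (for the family).
#' @export
double_well_1d <- function(barrier = 5, tilt = 0, x0 = 1) {
  force(barrier); force(tilt); force(x0)
  function(x) barrier * ((x[1] / x0)^2 - 1)^2 + tilt * x[1] / (2 * x0)
}

#' @rdname double_well_1d
#' @param lambdas ladder of scaling factors (replica 0 first,
#'   `lambda = 1`).
#' @param slope tilt change per unit lambda, kT.
#' @param lambda_star lambda at which the wells are equally deep.
#' @export
lambda_family_surfaces <- function(lambdas = c(1, 0.9, 0.8, 0.7, 0.6, 0.5),
                                   barrier = 5, slope = 8,
                                   lambda_star = 0.8, x0 = 1) {
  surfaces <- lapply(lambdas, function(l)
    double_well_1d(barrier = barrier, tilt = slope * (l - lambda_star),
                   x0 = x0))
  list(surfaces = surfaces, lambdas = lambdas, lambda_star = lambda_star)
}

#' Generate an annotated WT-MetaD bias fixture
#'
#' Runs the toy sampler on an analytic surface and writes the COLVAR
#' and HILLS tables plus a JSON sidecar holding the quadrature ground
#' truth (state free energies in kT) for recovery tests.
#'
#' @param surface analytic surface (kT).
#' @param params an [wtmetad_params()].
#' @param regions state regions for the ground-truth annotation.
#' @param dir output directory (created if needed).
#' @param steps,seed,... passed to [run_toy_wtmetad()].
#' @return list: `run` (the `hj_toy_run`), `paths` (colvar, hills,
#'   sidecar), `truth` (data.frame).
#' @export
generate_bias_fixture <- function(surface, params, regions, dir,
                                  steps = 2e5, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  run <- run_toy_wtmetad(surface, params = params, steps = steps,
                         seed = seed, ...)
  truth <- analytic_state_dg(surface, regions,
                             lower = params$grid_min,
                             upper = params$grid_max)
  paths <- c(colvar = file.path(dir, "COLVAR"),
             hills = file.path(dir, "HILLS"),
             sidecar = file.path(dir, "ground_truth.json"))
  write_plumed_table(run$colvar, paths["colvar"])
  write_hills(run$hills, paths["hills"])
  jsonlite::write_json(list(states = truth, seed = seed,
                            gamma = params$gamma, w0_kj = params$w0),
                       paths["sidecar"], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  list(run = run, paths = paths, truth = truth)
}
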