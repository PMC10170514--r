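#' Well-tempered metadynamics parameters
#'
#' Defaults follow the junction sampling setup: Gaussians deposited
#' every 500 steps with initial height 2.5 kJ/mol, per-CV widths sigma
#' (0.8/0.8 for the isomer-I CV pair, 0.2/0.2 for isomer II) and bias
#' factor gamma = 15; the bias is accumulated on a per-CV grid
#' (0..26 or 0..8 in the junction setups).
#'
#' @param w0 initial Gaussian height, kJ/mol.
#' @param sigma per-CV Gaussian widths (length = dimensionality, 1 or 2).
#' @param gamma bias factor, `> 1`.
#' @param deposit_stride steps between deposits.
#' @param grid_min,grid_max per-CV grid bounds.
#' @param grid_n grid points per CV.
#' @return object of class `hj_wtmetad_params`.
#' @export
wtmetad_params <- function(w0 = 2.5, sigma = c(0.8, 0.8), gamma = 15,
                           deposit_stride = 500,
                           grid_min = rep(0, length(sigma)),
                           grid_max = rep(26, length(sigma)),
                           grid_n = 301) {
  if (gamma <= 1) stop("bias factor gamma must be > 1")
  stopifnot(w0 > 0, all(sigma > 0), deposit_stride >= 1,
            length(sigma) %in% c(1L, 2L),
            length(grid_min) == length(sigma),
            length(grid_max) == length(sigma), all(grid_max > grid_min))
  structure(list(w0 = w0, sigma = sigma, gamma = gamma,
                 deposit_stride = as.integer(deposit_stride),
                 grid_min = grid_min, grid_max = grid_max,
                 grid_n = as.integer(grid_n)),
            class = "hj_wtmetad_params")
}

#' One-sided parabolic wall restraint
#'
#' `E(s) = k (s - onset)^2` for `s > onset`, zero below - the form of
#' the CV restraints that keep each sampling setup out of the other
#' isomer's region (onset 10, k = 0.02 kJ/mol in the junction setups).
#'
#' @param onset CV value where the wall starts.
#' @param k force constant, kJ/mol.
#' @param cv CV indices the wall acts on (default: all).
#' @export
wall_restraint <- function(onset = 10, k = 0.02, cv = NULL) {
  stopifnot(k >= 0)
  structure(list(onset = onset, k = k, cv = cv), class = "hj_wall")
}

#' Well-tempered deposit height
#'
#' `w = w0 exp(-V / (kT (gamma - 1)))`: the height of the next Gaussian
#' decays with the bias already accumulated at the walker's position,
#' so the bias converges to `-(1 - 1/gamma) F` instead of flattening
#' the surface completely.
#'
#' @param V_current bias at the walker position (same energy unit as
#'   `kT_energy`), `>= 0`.
#' @param params an [wtmetad_params()]; `w0` is taken in the same unit.
#' @param kT_energy thermal energy in that unit (default 2.479 kJ/mol).
#' @return deposit height in the same unit, vectorized over `V_current`.
#' @export
deposit_height <- function(V_current, params, kT_energy = kT(unit = "kJ")) {
  if (params$gamma <= 1) stop("bias factor gamma must be > 1")
  stopifnot(all(V_current >= 0))
  params$w0 * exp(-V_current / (kT_energy * (params$gamma - 1)))
}

#' Evaluate a deposited-Gaussian bias
#'
#' Sums the Gaussians of a HILLS-style history at CV points, matching
#' PLUMED HILLS semantics (diagonal sigmas, heights as stored - kJ/mol
#' in files written by this package).
#'
#' @param s numeric vector (one point per CV) or matrix (points x CVs).
#' @param hills HILLS data.frame from [run_toy_wtmetad()] or
#'   [read_hills()].
#' @param t_max only deposits with `time <= t_max` contribute.
#' @param average_from when given, return the time average of
#'   `V(s, t)` over `[average_from, t_max]` instead of the
#'   instantaneous bias at `t_max` (each deposit weighted by the
#'   fraction of the window it was present for); `t_max` must then be
#'   finite.
#' @return bias value(s), same unit as the stored heights.
#' @export
bias_value <- function(s, hills, t_max = Inf, average_from = NULL) {
  cvs <- hills_cv_names(hills)
  if (length(cvs) == 0) stop("hills table has no sigma_<cv> columns")
  if (is.null(dim(s))) s <- matrix(s, ncol = length(cvs))
  stopifnot(ncol(s) == length(cvs))
  hh <- hills[hills$time <= t_max, , drop = FALSE]
  n <- nrow(s)
  if (nrow(hh) == 0) return(numeric(n))
  height <- hh$height
  if (!is.null(average_from)) {
    if (!is.finite(t_max))
      stop("average_from needs a finite t_max")
    stopifnot(average_from < t_max)
    height <- height *
      pmin(1, pmax(0, (t_max - hh$time) / (t_max - average_from)))
  }
  out <- numeric(n)
  chunk <- max(1L, floor(2e6 / nrow(hh)))   # bound the work matrix
  for (from in seq(1, n, by = chunk)) {
    to <- min(n, from + chunk - 1L)
    expo <- 0
    for (k in seq_along(cvs)) {
      dev2 <- outer(s[from:to, k], hh[[cvs[k]]], "-")^2
      expo <- expo + sweep(dev2, 2, 2 * hh[[paste0("sigma_", cvs[k])]]^2, "/")
    }
    out[from:to] <- as.numeric(exp(-expo) %*% height)
  }
  out
}

#' Metropolis acceptance for a Hamiltonian replica exchange
#'
#' `p = min(1, exp(-beta [(U_ij + U_ji) - (U_ii + U_jj)]))`, where
#' `U_ab` is the energy of configuration b evaluated under replica a's
#' Hamiltonian.
#'
#' @param U_ii,U_ij,U_ji,U_jj energies (consistent units).
#' @param beta inverse thermal energy in the matching unit.
#' @return acceptance probability in `[0, 1]`, vectorized.
#' @export
hrex_accept <- function(U_ii, U_ij, U_ji, U_jj, beta = 1) {
  delta <- (U_ij + U_ji) - (U_ii + U_jj)
  pmin(1, exp(-beta * delta))
}

#' Replica ladder for Hamiltonian exchange
#'
#' @param lambdas strictly monotone scaling factors; replica 0 comes
#'   first and is unscaled (`lambda = 1`), the junction convention of
#'   ordering the ladder from the unmodified Hamiltonian down.
#' @param exchange_stride steps between swap attempts (default 2500).
#' @export
hrex_ladder <- function(lambdas = c(1, 0.9, 0.8, 0.7, 0.6, 0.5),
                        exchange_stride = 2500) {
  d <- diff(lambdas)
  if (length(lambdas) < 2 || !(all(d > 0) || all(d < 0)))
    stop("lambdas must be strictly monotone")
  if (lambdas[1] != 1)
    stop("replica 0 must be unscaled (lambda = 1)")
  structure(list(lambdas = lambdas,
                 exchange_stride = as.integer(exchange_stride)),
            class = "hj_hrex_ladder")
}

# ---- internal gridded Langevin engine -------------------------------

# evaluate surface energy and gradient on the bias grid (kT units)
grid_surface <- function(surface, params) {
  d <- length(params$sigma)
  ax <- lapply(seq_len(d), function(k)
    seq(params$grid_min[k], params$grid_max[k], length.out = params$grid_n))
  dx <- vapply(ax, function(a) a[2] - a[1], 0)
  n <- params$grid_n
  up <- c(2:n, n); dn <- c(1, 1:(n - 1)); den <- (up - dn)
  if (d == 1) {
    FF <- vapply(ax[[1]], function(x) surface(x), 0)
    G1 <- (FF[up] - FF[dn]) / (den * dx[1])
    list(d = 1, ax = ax, dx = dx, FF = FF, G = list(G1))
  } else {
    FF <- outer(ax[[1]], ax[[2]], function(x, y)
      mapply(function(a, b) surface(c(a, b)), x, y))
    G1 <- (FF[up, ] - FF[dn, ]) / (den * dx[1])
    G2 <- (FF[, up] - FF[, dn]) / rep(den * dx[2], each = n)
    list(d = 2, ax = ax, dx = dx, FF = FF, G = list(G1, G2))
  }
}

wall_energy_force <- function(x, walls, kT_kJ) {
  e <- 0; f <- numeric(length(x))
  for (w in walls) {
    dims <- if (is.null(w$cv)) seq_along(x) else w$cv
    k_kT <- w$k / kT_kJ
    for (kd in dims) {
      ex <- x[kd] - w$onset
      if (ex > 0) {
        e <- e + k_kT * ex^2
        f[kd] <- f[kd] - 2 * k_kT * ex
      }
    }
  }
  list(e = e, f = f)
}

# core overdamped-Langevin WT-MetaD stepper; carries walker and bias
# state so replica-exchange segments can resume. All energies in kT.
langevin_wtmetad <- function(gs, params, biased, walls, steps, dt,
                             diffusion, x, bias, t_off, colvar_stride,
                             kT_kJ) {
  d <- gs$d
  ng <- length(gs$ax[[1]])
  gmin <- vapply(gs$ax, min, 0); gmax <- vapply(gs$ax, max, 0)
  dx <- gs$dx
  if (is.null(bias)) bias <- if (d == 1) numeric(ng) else matrix(0, ng, ng)
  w0_kT <- params$w0 / kT_kJ
  gm1 <- params$gamma - 1
  stride <- params$deposit_stride
  sig <- params$sigma
  n_rec <- floor(steps / colvar_stride)
  cv_rec <- matrix(NA_real_, n_rec, d); t_rec <- numeric(n_rec); rec <- 0L
  hl_t <- numeric(0); hl_c <- matrix(numeric(0), ncol = d); hl_h <- numeric(0)
  span <- gmax - gmin
  centre <- (gmin + gmax) / 2
  noise_amp <- sqrt(2 * diffusion * dt)
  have_walls <- !is.null(walls) && length(walls) > 0
  for (s in seq_len(steps)) {
    i1 <- floor((x[1] - gmin[1]) / dx[1] + 0.5) + 1
    if (i1 < 2) i1 <- 2 else if (i1 > ng - 1) i1 <- ng - 1
    if (d == 1) {
      f <- -gs$G[[1]][i1] - (bias[i1 + 1] - bias[i1 - 1]) / (2 * dx[1])
    } else {
      i2 <- floor((x[2] - gmin[2]) / dx[2] + 0.5) + 1
      if (i2 < 2) i2 <- 2 else if (i2 > ng - 1) i2 <- ng - 1
      f <- c(-gs$G[[1]][i1, i2] -
               (bias[i1 + 1, i2] - bias[i1 - 1, i2]) / (2 * dx[1]),
             -gs$G[[2]][i1, i2] -
               (bias[i1, i2 + 1] - bias[i1, i2 - 1]) / (2 * dx[2]))
    }
    if (have_walls) f <- f + wall_energy_force(x, walls, kT_kJ)$f
    x <- x + diffusion * f * dt + noise_amp * stats::rnorm(d)
    if (any(!is.finite(x)) || any(abs(x - centre) > 10 * span))
      stop("toy trajectory diverged at step ", s + t_off / dt,
           "; reduce dt or enlarge the grid")
    for (k in seq_len(d)) {
      if (x[k] < gmin[k]) x[k] <- 2 * gmin[k] - x[k]
      if (x[k] > gmax[k]) x[k] <- 2 * gmax[k] - x[k]
      if (x[k] < gmin[k] || x[k] > gmax[k]) x[k] <- centre[k]
    }
    if (biased && s %% stride == 0L) {
      i1 <- floor((x[1] - gmin[1]) / dx[1] + 0.5) + 1
      Vhere <- if (d == 1) bias[i1] else {
        i2 <- floor((x[2] - gmin[2]) / dx[2] + 0.5) + 1
        bias[i1, i2]
      }
      h_kT <- w0_kT * exp(-Vhere / gm1)
      g1 <- exp(-(gs$ax[[1]] - x[1])^2 / (2 * sig[1]^2))
      if (d == 1) bias <- bias + h_kT * g1
      else bias <- bias + h_kT *
          outer(g1, exp(-(gs$ax[[2]] - x[2])^2 / (2 * sig[2]^2)))
      hl_t <- c(hl_t, t_off + s * dt); hl_c <- rbind(hl_c, x)
      hl_h <- c(hl_h, h_kT * kT_kJ)
    }
    if (s %% colvar_stride == 0L) {
      rec <- rec + 1L
      cv_rec[rec, ] <- x; t_rec[rec] <- t_off + s * dt
    }
  }
  cv_names <- paste0("cv", seq_len(d))
  colvar <- data.frame(time = t_rec[seq_len(rec)],
                       cv_rec[seq_len(rec), , drop = FALSE])
  names(colvar)[-1] <- cv_names
  hills <- NULL
  if (biased) {
    hills <- data.frame(time = hl_t)
    for (k in seq_len(d)) hills[[cv_names[k]]] <- hl_c[, k]
    for (k in seq_len(d)) hills[[paste0("sigma_", cv_names[k])]] <-
      rep(sig[k], nrow(hills))
    hills$height <- hl_h
    hills$biasf <- rep(params$gamma, nrow(hills))
  }
  list(colvar = colvar, hills = hills, bias = bias, x_final = x)
}

unbiased_params <- function(d, grid_min, grid_max, grid_n = 241) {
  # plain-Langevin runs still need a grid for the surface forces; the
  # (never-deposited) bias is kept at machine epsilon height
  p <- wtmetad_params(w0 = 1e-300, sigma = rep(0.1, d), gamma = 2,
                      deposit_stride = .Machine$integer.max,
                      grid_min = grid_min, grid_max = grid_max,
                      grid_n = grid_n)
  p
}

#' Toy well-tempered metadynamics run on an analytic surface
#'
#' Overdamped Langevin (Euler-Maruyama) dynamics on a 1D or 2D analytic
#' free-energy surface given in kT units, with a history-dependent
#' well-tempered bias accumulated on a grid. The desk-scale engine
#' reproduces the bias and exchange mathematics of the junction
#' sampling protocol (deposit rule, wall restraints, HILLS/COLVAR
#' output) without any molecular mechanics. Walkers reflect at the grid
#' boundaries, so the bias grid always covers the trajectory.
#'
#' @param surface function mapping a CV point (length-d vector) to a
#'   free energy in kT.
#' @param params an [wtmetad_params()]; dimensionality is taken from
#'   `length(params$sigma)`. `NULL` disables biasing (plain Langevin;
#'   then `grid_min`/`grid_max` must be given).
#' @param walls a [wall_restraint()] or list of them (kJ/mol).
#' @param steps number of integration steps.
#' @param dt time step (reduced units).
#' @param diffusion diffusion constant (reduced units).
#' @param x0 starting point (default: grid centre).
#' @param seed optional integer seed (applied locally).
#' @param colvar_stride record the CVs every this many steps.
#' @param temperature_K temperature used to convert kJ/mol at the file
#'   boundaries (default 298.15 K).
#' @param grid_min,grid_max grid bounds when `params` is `NULL`.
#' @return list of class `hj_toy_run`: `colvar` (time + CVs), `hills`
#'   (PLUMED-style columns, heights in kJ/mol), `bias_grid` (kT),
#'   `axes`, `surface_grid` (kT), `params`, `kT_kJ`.
#' @export
run_toy_wtmetad <- function(surface, params = wtmetad_params(),
                            walls = NULL, steps = 1e5, dt = 5e-4,
                            diffusion = 1, x0 = NULL, seed = NULL,
                            colvar_stride = 10L, temperature_K = 298.15,
                            grid_min = NULL, grid_max = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (inherits(walls, "hj_wall")) walls <- list(walls)
  biased <- !is.null(params)
  if (!biased) {
    if (is.null(grid_min) || is.null(grid_max))
      stop("grid_min/grid_max required for unbiased runs")
    params <- unbiased_params(length(grid_min), grid_min, grid_max)
  }
  kT_kJ <- kT(temperature_K, "kJ")
  gs <- grid_surface(surface, params)
  x <- if (is.null(x0)) (params$grid_min + params$grid_max) / 2
  else as.numeric(x0)
  run <- langevin_wtmetad(gs, params, biased, walls, steps, dt, diffusion,
                          x, NULL, 0, colvar_stride, kT_kJ)
  structure(list(colvar = run$colvar, hills = run$hills,
                 bias_grid = run$bias, axes = gs$ax,
                 surface_grid = gs$FF, params = params, kT_kJ = kT_kJ),
            class = "hj_toy_run")
}

#' @export
print.hj_toy_run <- function(x, ...) {
  cat(sprintf("hj_toy_run: %d CV records, %d deposited Gaussians\n",
              nrow(x$colvar), if (is.null(x$hills)) 0L else nrow(x$hills)))
  invisible(x)
}

# total replica energy (surface + own bias + walls) in kT at point x
replica_energy <- function(gs, bias, walls, x, kT_kJ) {
  d <- gs$d
  ng <- length(gs$ax[[1]])
  gmin <- vapply(gs$ax, min, 0)
  i1 <- min(max(floor((x[1] - gmin[1]) / gs$dx[1] + 0.5) + 1, 1), ng)
  e <- if (d == 1) gs$FF[i1] + bias[i1] else {
    i2 <- min(max(floor((x[2] - gmin[2]) / gs$dx[2] + 0.5) + 1, 1), ng)
    gs$FF[i1, i2] + bias[i1, i2]
  }
  if (!is.null(walls) && length(walls))
    e <- e + wall_energy_force(x, walls, kT_kJ)$e
  e
}

#' Toy Hamiltonian replica exchange (optionally with WT-MetaD)
#'
#' One Langevin walker per replica, each on its own analytic surface
#' (kT units), attempting neighbour swaps every
#' `ladder$exchange_stride` steps with the Metropolis rule of
#' [hrex_accept()]; even and odd neighbour pairs alternate between
#' attempts. When `params` is given each replica carries its own
#' well-tempered bias, which is included in the swap energies. Swaps
#' exchange walker configurations, and the `config` column of each
#' replica's CV record tracks walker identity so continuous (demuxed)
#' trajectories can be reassembled.
#'
#' @param surfaces list of surface functions, one per replica (kT).
#' @param ladder an [hrex_ladder()]; `length(lambdas)` must match.
#' @param params optional shared [wtmetad_params()].
#' @inheritParams run_toy_wtmetad
#' @return list of class `hj_hrex_run`: `replicas` (per replica:
#'   `lambda`, `colvar` with `config` column, `hills`, `bias_grid`),
#'   `exchange_log` (data.frame `time`, `i`, `j`, `delta_kT`, `prob`,
#'   `accepted`) and `ladder`.
#' @export
run_toy_hrex <- function(surfaces, ladder = hrex_ladder(), params = NULL,
                         walls = NULL, steps = 1e5, dt = 5e-4,
                         diffusion = 1, x0 = NULL, seed = NULL,
                         colvar_stride = 10L, temperature_K = 298.15,
                         grid_min = NULL, grid_max = NULL) {
  nrep <- length(ladder$lambdas)
  if (length(surfaces) != nrep)
    stop("need one surface per replica (", nrep, ")")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (inherits(walls, "hj_wall")) walls <- list(walls)
  biased <- !is.null(params)
  if (!biased) {
    if (is.null(grid_min) || is.null(grid_max))
      stop("grid_min/grid_max required for unbiased runs")
    params <- unbiased_params(length(grid_min), grid_min, grid_max)
  }
  kT_kJ <- kT(temperature_K, "kJ")
  gss <- lapply(surfaces, grid_surface, params = params)
  ex_stride <- ladder$exchange_stride
  n_seg <- max(1L, floor(steps / ex_stride))
  xs <- rep(list(if (is.null(x0)) (params$grid_min + params$grid_max) / 2
                 else as.numeric(x0)), nrep)
  biases <- rep(list(NULL), nrep)
  hills_acc <- rep(list(NULL), nrep)
  colvar_acc <- rep(list(NULL), nrep)
  config <- seq_len(nrep)
  logs <- vector("list", 0)
  t_off <- 0
  for (seg in seq_len(n_seg)) {
    for (r in seq_len(nrep)) {
      run <- langevin_wtmetad(gss[[r]], params, biased, walls, ex_stride,
                              dt, diffusion, xs[[r]], biases[[r]], t_off,
                              colvar_stride, kT_kJ)
      xs[[r]] <- run$x_final
      biases[[r]] <- run$bias
      if (nrow(run$colvar)) {
        run$colvar$config <- config[r]
        colvar_acc[[r]] <- rbind(colvar_acc[[r]], run$colvar)
      }
      if (!is.null(run$hills) && nrow(run$hills))
        hills_acc[[r]] <- rbind(hills_acc[[r]], run$hills)
    }
    t_off <- t_off + ex_stride * dt
    first <- if (seg %% 2 == 1) 1L else 2L
    if (first <= nrep - 1) for (i in seq(first, nrep - 1, by = 2)) {
      j <- i + 1L
      Uii <- replica_energy(gss[[i]], biases[[i]], walls, xs[[i]], kT_kJ)
      Ujj <- replica_energy(gss[[j]], biases[[j]], walls, xs[[j]], kT_kJ)
      Uij <- replica_energy(gss[[i]], biases[[i]], walls, xs[[j]], kT_kJ)
      Uji <- replica_energy(gss[[j]], biases[[j]], walls, xs[[i]], kT_kJ)
      p <- hrex_accept(Uii, Uij, Uji, Ujj, beta = 1)
      acc <- stats::runif(1) < p
      if (acc) {
        tmp <- xs[[i]]; xs[[i]] <- xs[[j]]; xs[[j]] <- tmp
        tmp <- config[i]; config[i] <- config[j]; config[j] <- tmp
      }
      logs[[length(logs) + 1]] <- data.frame(
        time = t_off, i = i - 1L, j = j - 1L,
        delta_kT = (Uij + Uji) - (Uii + Ujj), prob = p, accepted = acc)
    }
  }
  empty_log <- data.frame(time = numeric(0), i = integer(0),
                          j = integer(0), delta_kT = numeric(0),
                          prob = numeric(0), accepted = logical(0))
  replicas <- lapply(seq_len(nrep), function(r)
    list(lambda = ladder$lambdas[r], colvar = colvar_acc[[r]],
         hills = hills_acc[[r]], bias_grid = biases[[r]]))
  structure(list(replicas = replicas,
                 exchange_log = if (length(logs)) do.call(rbind, logs)
                 else empty_log,
                 ladder = ladder),
            class = "hj_hrex_run")
}
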