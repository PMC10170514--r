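#' Reweight a biased CV series
#'
#' Final-bias estimator (default): each frame receives weight
#' `w_t ~ exp(V_final(s_t) / kT)` where `V_final` is the fully
#' deposited bias evaluated at the frame's CVs - the simplest
#' estimator consistent with a converged well-tempered bias.
#' `estimator = "averaged_bias"` instead averages the bias over the
#' production window (after discarding a `burnin` fraction of the run)
#' and weights the production frames by the averaged bias; averaging
#' over deposits suppresses the hill-by-hill fluctuation of the
#' instantaneous bias and is the variant used for free-energy
#' recovery. `"time_dependent"` evaluates the bias at each frame's own
#' time.
#'
#' @param colvar data.frame with a `time` column and one column per CV
#'   (from [run_toy_wtmetad()] or [read_colvar()]).
#' @param hills bias history matching the COLVAR CVs.
#' @param kT_energy thermal energy in the unit of the stored heights
#'   (default 2.479 kJ/mol).
#' @param estimator `"final_bias"` (default), `"averaged_bias"` or
#'   `"time_dependent"`.
#' @param burnin initial fraction of the time span discarded by the
#'   averaged-bias estimator (default 0.25; ignored otherwise).
#' @param cv_names CV columns to keep; default: the hills CV names.
#' @return data.frame of class `hj_weighted_ensemble`: the CV columns
#'   plus a normalized `weight` column (sums to 1).
#' @export
reweight <- function(colvar, hills, kT_energy = kT(unit = "kJ"),
                     estimator = c("final_bias", "averaged_bias",
                                   "time_dependent"),
                     burnin = 0.25, cv_names = NULL) {
  estimator <- match.arg(estimator)
  if (is.null(cv_names)) cv_names <- hills_cv_names(hills)
  miss <- setdiff(cv_names, names(colvar))
  if (length(miss))
    stop("COLVAR is missing CV column(s): ", paste(miss, collapse = ", "))
  if (estimator == "averaged_bias") {
    t0 <- min(colvar$time); t1 <- max(colvar$time)
    t_start <- t0 + burnin * (t1 - t0)
    colvar <- colvar[colvar$time >= t_start, , drop = FALSE]
  }
  s <- as.matrix(colvar[, cv_names, drop = FALSE])
  V <- switch(estimator,
    final_bias = bias_value(s, hills),
    averaged_bias = bias_value(s, hills, t_max = t1,
                               average_from = t_start),
    time_dependent = vapply(seq_len(nrow(s)),
      function(i) bias_value(s[i, ], hills, t_max = colvar$time[i]), 0))
  # subtract the max before exponentiating for numerical stability
  w <- exp((V - max(V)) / kT_energy)
  w <- w / sum(w)
  out <- data.frame(colvar[, c("time", cv_names), drop = FALSE],
                    weight = w)
  class(out) <- c("hj_weighted_ensemble", "data.frame")
  out
}

#' Two-dimensional free-energy surface from a weighted ensemble
#'
#' Weighted histogram over a regular grid, converted to
#' `F = -kT log(p)` and shifted so the minimum is 0; empty bins carry
#' `Inf`.
#'
#' @param ensemble an `hj_weighted_ensemble` (or data.frame with CV
#'   columns and `weight`).
#' @param cv_names one or two CV column names.
#' @param breaks number of bins per CV, or a list of break vectors.
#' @param kT_energy output energy unit per kT (default 0.593 kcal/mol;
#'   use 1 for kT units).
#' @return list of class `hj_fes`: `F` (vector or matrix, min 0),
#'   `mids` (bin centres per CV), `kT_energy`.
#' @export
build_fes <- function(ensemble, cv_names = NULL, breaks = 60,
                      kT_energy = kT()) {
  if (is.null(cv_names))
    cv_names <- setdiff(names(ensemble), c("time", "weight", "config"))
  d <- length(cv_names)
  stopifnot(d %in% c(1L, 2L))
  if (!is.list(breaks))
    breaks <- lapply(cv_names, function(nm) {
      rng <- range(ensemble[[nm]])
      seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = breaks + 1)
    })
  bin <- lapply(seq_len(d), function(k)
    cut(ensemble[[cv_names[k]]], breaks[[k]], labels = FALSE,
        include.lowest = TRUE))
  keep <- Reduce(`&`, lapply(bin, function(b) !is.na(b)))
  if (!any(keep)) stop("no frames fall inside the FES grid")
  w <- ensemble$weight[keep]
  nb <- vapply(breaks, function(b) length(b) - 1L, 0L)
  if (d == 1) {
    p <- vapply(seq_len(nb[1]), function(i) sum(w[bin[[1]][keep] == i]), 0)
  } else {
    p <- matrix(0, nb[1], nb[2])
    idx <- cbind(bin[[1]][keep], bin[[2]][keep])
    for (r in seq_along(w)) p[idx[r, 1], idx[r, 2]] <-
        p[idx[r, 1], idx[r, 2]] + w[r]
  }
  FF <- -kT_energy * log(p / sum(p))
  FF <- FF - min(FF[is.finite(FF)])
  mids <- lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
  structure(list(F = FF, mids = mids, cv_names = cv_names,
                 kT_energy = kT_energy), class = "hj_fes")
}

#' Rectangular state regions in CV space
#'
#' @param name state name.
#' @param lower,upper per-CV bounds (same length as the CV columns the
#'   region will be applied to).
#' @export
state_region <- function(name, lower, upper) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  structure(list(name = name, lower = lower, upper = upper),
            class = "hj_state_region")
}

#' Default state rectangles for a junction sampling setup
#'
#' Maps the raw-CV classification thresholds (5/50) through the
#' normalization exponent alpha of the setup, giving the approximate
#' rectangles used to integrate state probabilities: open below
#' `5^alpha` in both CVs, closed above `50^alpha` in both, each
#' half-closed state high in one CV and low in the other.
#'
#' @param setup `"isomerI"` (CVs s_I-II/s_III-IV, alpha 0.65) or
#'   `"isomerII"` (s_I-IV/s_II-III, alpha 0.4).
#' @param alpha override the setup's exponent.
#' @param thresholds raw-CV thresholds, see [state_thresholds()].
#' @param cv_max upper edge of the closed rectangles (default: the
#'   grid upper bound of the setup, 26 or 8).
#' @return named list of [state_region()]s (`OPEN`, `CLOSED`, `HC_L`,
#'   `HC_R`), rectangles pairwise disjoint.
#' @export
default_state_regions <- function(setup = c("isomerI", "isomerII"),
                                  alpha = NULL,
                                  thresholds = state_thresholds(),
                                  cv_max = NULL) {
  setup <- match.arg(setup)
  if (is.null(alpha)) alpha <- if (setup == "isomerI") 0.65 else 0.4
  if (is.null(cv_max)) cv_max <- if (setup == "isomerI") 26 else 8
  lo <- thresholds$open_below^alpha
  hi <- thresholds$closed_above^alpha
  list(
    OPEN = state_region("OPEN", c(0, 0), c(lo, lo)),
    CLOSED = state_region("CLOSED", c(hi, hi), c(cv_max, cv_max)),
    HC_L = state_region("HC_L", c(hi, 0), c(cv_max, lo)),
    HC_R = state_region("HC_R", c(0, hi), c(lo, cv_max)))
}

region_mask <- function(ensemble, cv_names, region) {
  m <- rep(TRUE, nrow(ensemble))
  for (k in seq_along(cv_names)) {
    v <- ensemble[[cv_names[k]]]
    m <- m & v >= region$lower[k] & v <= region$upper[k]
  }
  m
}

#' State free energies relative to the open state
#'
#' Integrates the ensemble probability over each state rectangle and
#' reports `dG_state = -kT log(P_state / P_open)`; the open state is
#' the reference with `dG = 0` by construction. Frames outside all
#' regions do not affect the ratios.
#'
#' @param ensemble an `hj_weighted_ensemble`.
#' @param regions named list of [state_region()]s; must contain
#'   `"OPEN"`.
#' @param kT_energy output energy unit per kT (default 0.593 kcal/mol).
#' @param cv_names CV columns; default: all but `time`/`weight`.
#' @return data.frame of class `hj_state_dg`: `state`, `probability`,
#'   `dg` (kT_energy units; OPEN exactly 0).
#' @export
state_free_energies <- function(ensemble, regions, kT_energy = kT(),
                                cv_names = NULL) {
  if (is.null(cv_names))
    cv_names <- setdiff(names(ensemble), c("time", "weight", "config"))
  if (!"OPEN" %in% names(regions))
    stop("regions must include the OPEN reference state")
  P <- vapply(regions, function(rg)
    sum(ensemble$weight[region_mask(ensemble, cv_names, rg)]), 0)
  if (P[["OPEN"]] <= 0)
    stop("no probability mass in the OPEN reference region")
  dg <- -kT_energy * log(P / P[["OPEN"]])
  dg[["OPEN"]] <- 0
  out <- data.frame(state = names(regions), probability = unname(P),
                    dg = unname(dg), row.names = NULL)
  class(out) <- c("hj_state_dg", "data.frame")
  out
}

# crude integrated autocorrelation time of a numeric series (frames)
autocorr_time <- function(x, max_lag = min(1000L, length(x) %/% 2)) {
  x <- x - mean(x)
  v <- mean(x^2)
  if (v == 0) return(1)
  tau <- 1
  for (lag in seq_len(max_lag)) {
    rho <- mean(x[seq_len(length(x) - lag)] * x[-seq_len(lag)]) / v
    if (rho < 0.05) break
    tau <- tau + 2 * rho
  }
  max(1, tau)
}

#' Block-bootstrap errors of the state free energies
#'
#' Circular block bootstrap over frames: resampled ensembles are built
#' from wrapped contiguous blocks, the state free energies recomputed,
#' and their standard deviation reported per state. The open reference
#' has no error by construction. The default block length is an
#' autocorrelation-time estimate of the occupancy series, capped at
#' N/20.
#'
#' @inheritParams state_free_energies
#' @param n_boot bootstrap replicates (`>= 2`, default 200).
#' @param block_len block length in frames (default: automatic).
#' @param seed integer seed for reproducible resampling.
#' @return data.frame `state`, `dg`, `dg_se` (`NA` for OPEN).
#' @export
bootstrap_errors <- function(ensemble, regions, kT_energy = kT(),
                             n_boot = 200, block_len = NULL, seed = 1,
                             cv_names = NULL) {
  stopifnot(n_boot >= 2)
  if (is.null(cv_names))
    cv_names <- setdiff(names(ensemble), c("time", "weight", "config"))
  n <- nrow(ensemble)
  if (is.null(block_len)) {
    occ <- as.numeric(region_mask(ensemble, cv_names, regions[["OPEN"]]))
    block_len <- min(max(1L, round(autocorr_time(occ))), max(1L, n %/% 20))
  }
  if (block_len > n) stop("block_len exceeds the series length")
  base <- state_free_energies(ensemble, regions, kT_energy, cv_names)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nblocks <- ceiling(n / block_len)
  dgs <- matrix(NA_real_, n_boot, length(regions))
  for (b in seq_len(n_boot)) {
    starts <- sample.int(n, nblocks, replace = TRUE)
    idx <- as.integer(outer(0:(block_len - 1), starts, "+") - 1L) %% n + 1L
    idx <- idx[seq_len(n)]
    res <- ensemble[idx, , drop = FALSE]
    res$weight <- res$weight / sum(res$weight)
    dgb <- try(state_free_energies(res, regions, kT_energy, cv_names),
               silent = TRUE)
    if (!inherits(dgb, "try-error")) dgs[b, ] <- dgb$dg
  }
  se <- apply(dgs, 2, stats::sd, na.rm = TRUE)
  se[base$state == "OPEN"] <- NA_real_
  data.frame(state = base$state, dg = base$dg, dg_se = se)
}

#' Linear fit of the closed-open free energy versus lambda
#'
#' Least-squares line `dG(lambda) = a lambda + c`; the ideal lambda is
#' the root `-c/a` where the closed and open states are equally stable,
#' and the expected open-state population follows the sigmoid
#' `1 / (1 + exp(-(a lambda + c)/kT))`, whose midpoint sits at the
#' ideal lambda.
#'
#' @param lambda scaling factors (>= 2 distinct values).
#' @param dg free-energy differences closed minus open (energy units
#'   consistent with `kT_energy`).
#' @param kT_energy thermal energy in the same unit (default 0.593
#'   kcal/mol).
#' @param weights optional inverse-variance weights for the fit
#'   (default unweighted).
#' @return object of class `hj_lambda_fit` with `slope`, `intercept`,
#'   `ideal_lambda`, the underlying `lm` fit and `kT_energy`.
#' @export
fit_ideal_lambda <- function(lambda, dg, kT_energy = kT(), weights = NULL) {
  if (length(unique(lambda)) < 2)
    stop("need at least two distinct lambda values")
  fit <- if (is.null(weights)) stats::lm(dg ~ lambda)
  else stats::lm(dg ~ lambda, weights = weights)
  a <- unname(stats::coef(fit)[2]); cc <- unname(stats::coef(fit)[1])
  if (!is.finite(a) || abs(a) < 1e-10)
    stop("zero slope: dG does not depend on lambda, no root")
  structure(list(slope = a, intercept = cc, ideal_lambda = -cc / a,
                 fit = fit, kT_energy = kT_energy,
                 data = data.frame(lambda = lambda, dg = dg)),
            class = "hj_lambda_fit")
}

#' @export
print.hj_lambda_fit <- function(x, ...) {
  cat("Linear free-energy dependence on the LJ scaling factor\n")
  cat(sprintf("  dG(lambda) = %.4g * lambda + %.4g\n", x$slope, x$intercept))
  cat(sprintf("  ideal lambda (dG = 0): %.4f\n", x$ideal_lambda))
  invisible(x)
}

#' @export
coef.hj_lambda_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope,
    ideal_lambda = object$ideal_lambda)
}

#' @export
predict.hj_lambda_fit <- function(object, lambda = NULL, ...) {
  if (is.null(lambda)) lambda <- object$data$lambda
  object$slope * lambda + object$intercept
}

#' Expected open-state population fraction at a given lambda
#'
#' @param fit an `hj_lambda_fit`.
#' @param lambda scaling factor(s).
#' @return sigmoid open fraction(s) in (0, 1); 0.5 exactly at the
#'   ideal lambda.
#' @export
open_fraction <- function(fit, lambda) {
  stopifnot(inherits(fit, "hj_lambda_fit"))
  1 / (1 + exp(-(fit$slope * lambda + fit$intercept) / fit$kT_energy))
}
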