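test_that("reweighting reproduces its closed forms", {
  kT_kJ <- kT(unit = "kJ")
  hills <- data.frame(time = 1, cv1 = 0, sigma_cv1 = 1e-6,
                      height = 1, biasf = 15)
  # zero bias everywhere (hills far away): uniform weights
  colvar <- data.frame(time = 1:4, cv1 = c(5, 6, 7, 8))
  ens <- reweight(colvar, hills)
  expect_equal(ens$weight, rep(0.25, 4))
  # two frames with V = 0 and kT log 2: weights 1/3, 2/3
  h2 <- data.frame(time = 1, cv1 = 1, sigma_cv1 = 1e-4,
                   height = kT_kJ * log(2), biasf = 15)
  ens2 <- reweight(data.frame(time = 1:2, cv1 = c(50, 1)), h2)
  expect_equal(ens2$weight, c(1 / 3, 2 / 3))
  expect_error(reweight(data.frame(time = 1, bad = 1), h2), "cv1")
})

test_that("weighted FES has zero minimum and correct cluster gap", {
  set.seed(3)
  # two tight clusters with 9:1 total weight
  n <- 4000
  cv1 <- c(rnorm(n * 0.9, 0, 0.05), rnorm(n * 0.1, 1, 0.05))
  ens <- data.frame(time = seq_along(cv1), cv1 = cv1,
                    weight = rep(1 / length(cv1), length(cv1)))
  fes <- build_fes(ens, "cv1", breaks = list(seq(-0.5, 1.5, 0.05)),
                   kT_energy = 1)
  expect_equal(min(fes$F[is.finite(fes$F)]), 0)
  f_at <- function(x) fes$F[which.min(abs(fes$mids[[1]] - x))]
  expect_equal(f_at(1) - f_at(0), log(9), tolerance = 0.15)
  # uniform weights over uniform samples: flat within binning noise
  u <- data.frame(time = 1:20000, cv1 = runif(20000),
                  weight = rep(1 / 20000, 20000))
  fu <- build_fes(u, "cv1", breaks = list(seq(0, 1, 0.1)), kT_energy = 1)
  expect_lt(max(abs(fu$F[is.finite(fu$F)] - mean(fu$F))), 0.15)
  expect_error(build_fes(u, "cv1", breaks = list(c(5, 6))), "grid")
})

test_that("state free energies integrate region probabilities", {
  regions <- list(OPEN = state_region("OPEN", 0, 1),
                  CLOSED = state_region("CLOSED", 2, 3))
  # equal probability: dG = 0
  ens <- data.frame(time = 1:4, cv1 = c(0.5, 0.5, 2.5, 2.5),
                    weight = rep(0.25, 4))
  dg <- state_free_energies(ens, regions, kT_energy = 0.593)
  expect_equal(dg$dg[dg$state == "CLOSED"], 0)
  expect_equal(dg$dg[dg$state == "OPEN"], 0)
  # P_closed / P_open = 10 at kT = 0.593: -1.365 kcal/mol
  ens2 <- data.frame(time = 1:11, cv1 = c(0.5, rep(2.5, 10)),
                     weight = rep(1 / 11, 11))
  dg2 <- state_free_energies(ens2, regions, kT_energy = 0.593)
  expect_equal(dg2$dg[dg2$state == "CLOSED"], -0.593 * log(10),
               tolerance = 1e-10)
  expect_equal(round(dg2$dg[dg2$state == "CLOSED"], 3), -1.365)
  # spectator frames outside all regions leave the ratios alone
  ens3 <- rbind(ens2, data.frame(time = 12:16, cv1 = 9,
                                 weight = 1 / 11))
  ens3$weight <- ens3$weight / sum(ens3$weight)
  dg3 <- state_free_energies(ens3, regions, kT_energy = 0.593)
  expect_equal(dg3$dg, dg2$dg, tolerance = 1e-12)
  # uniform weight rescaling changes nothing (weights renormalized)
  ens4 <- ens2; ens4$weight <- ens4$weight * 7
  expect_equal(state_free_energies(ens4, regions, kT_energy = 0.593)$dg,
               dg2$dg)
  # missing reference
  expect_error(state_free_energies(ens2, regions["CLOSED"]), "OPEN")
  ens5 <- ens2; ens5$weight[1] <- 0
  expect_error(state_free_energies(ens5, regions), "OPEN")
})

test_that("block bootstrap errors behave and reproduce", {
  regions <- list(OPEN = state_region("OPEN", 0, 1),
                  CLOSED = state_region("CLOSED", 2, 3))
  # constant-composition series: with blocks spanning one full period
  # of the alternation every resample reproduces the same ratio exactly
  const <- data.frame(time = 1:400,
                      cv1 = rep(c(0.5, 2.5), 200),
                      weight = rep(1 / 400, 400))
  be <- bootstrap_errors(const, regions, n_boot = 50, block_len = 2,
                         seed = 1)
  expect_lt(be$dg_se[be$state == "CLOSED"], 1e-10)
  expect_true(is.na(be$dg_se[be$state == "OPEN"]))
  # determinism
  be2 <- bootstrap_errors(const, regions, n_boot = 50, block_len = 2,
                          seed = 1)
  expect_identical(be$dg_se, be2$dg_se)
  expect_error(bootstrap_errors(const, regions, block_len = 1000),
               "block_len")
  expect_error(bootstrap_errors(const, regions, n_boot = 1), "n_boot")
})

test_that("bootstrap error shrinks like 1/sqrt(N) on i.i.d. series", {
  regions <- list(OPEN = state_region("OPEN", 0, 1),
                  CLOSED = state_region("CLOSED", 2, 3))
  ses <- vapply(c(1e3, 4e3, 1.6e4), function(n) {
    set.seed(42)
    cv <- ifelse(runif(n) < 0.3, 0.5, 2.5)
    ens <- data.frame(time = seq_len(n), cv1 = cv, weight = rep(1 / n, n))
    bootstrap_errors(ens, regions, n_boot = 120, block_len = 1,
                     seed = 7)$dg_se[2]
  }, 0)
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.25)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.25)
})

test_that("lambda fit recovers the analytic line and sigmoid midpoint", {
  # two points: (0.7, +1), (1.0, -2) -> slope -10, intercept 8, root 0.8
  fit <- fit_ideal_lambda(c(0.7, 1.0), c(1, -2))
  expect_equal(fit$slope, -10)
  expect_equal(fit$intercept, 8)
  expect_equal(fit$ideal_lambda, 0.8)
  expect_equal(unname(coef(fit)["ideal_lambda"]), 0.8)
  # sigmoid midpoint at the ideal lambda
  expect_equal(open_fraction(fit, 0.8), 0.5)
  expect_gt(open_fraction(fit, 0.7), 0.5)   # less stable closed state
  # exact line through 6 points: zero residuals
  lam <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5)
  fit6 <- fit_ideal_lambda(lam, -10 * lam + 8)
  expect_equal(unname(residuals(fit6$fit)), rep(0, 6), tolerance = 1e-10)
  expect_equal(predict(fit6, 0.75), 0.5)
  expect_error(fit_ideal_lambda(c(0.8, 0.8), c(1, 1)), "distinct")
  expect_error(fit_ideal_lambda(c(0.7, 1), c(1, 1)), "slope")
})

test_that("FES region integrals agree with the state free energies", {
  set.seed(8)
  n <- 20000
  cv1 <- c(rnorm(n * 0.8, 0.5, 0.1), rnorm(n * 0.2, 2.5, 0.1))
  ens <- data.frame(time = seq_along(cv1), cv1 = cv1,
                    weight = rep(1 / length(cv1), length(cv1)))
  regions <- list(OPEN = state_region("OPEN", 0, 1),
                  CLOSED = state_region("CLOSED", 2, 3))
  dg <- state_free_energies(ens, regions, kT_energy = 1)
  fes <- build_fes(ens, "cv1", breaks = list(seq(0, 3, 0.05)),
                   kT_energy = 1)
  in_region <- function(rg) fes$mids[[1]] >= rg$lower &
    fes$mids[[1]] <= rg$upper
  lse <- function(f) -log(sum(exp(-f[is.finite(f)])))
  dg_fes <- lse(fes$F[in_region(regions$CLOSED)]) -
    lse(fes$F[in_region(regions$OPEN)])
  expect_equal(dg_fes, dg$dg[dg$state == "CLOSED"], tolerance = 0.05)
})

test_that("default state rectangles map thresholds through alpha", {
  rg <- default_state_regions("isomerI")
  expect_equal(rg$OPEN$upper, rep(5^0.65, 2))
  expect_equal(rg$CLOSED$lower, rep(50^0.65, 2))
  expect_equal(rg$CLOSED$upper, rep(26, 2))
  rg2 <- default_state_regions("isomerII")
  expect_equal(rg2$OPEN$upper, rep(5^0.4, 2))
  expect_equal(rg2$CLOSED$upper, rep(8, 2))
  # rectangles pairwise disjoint
  corners <- function(r) expand.grid(x = c(r$lower[1], r$upper[1]),
                                     y = c(r$lower[2], r$upper[2]))
  inside <- function(p, r) all(p >= r$lower) && all(p <= r$upper)
  for (a in seq_along(rg)) for (b in seq_along(rg)) if (a != b) {
    mid <- (rg[[a]]$lower + rg[[a]]$upper) / 2
    expect_false(inside(mid, rg[[b]]))
  }
})
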