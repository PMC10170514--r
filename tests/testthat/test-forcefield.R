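test_that("pair table resolves combination rules, symmetry and exclusions", {
  at <- hj_atoms(name = c("A", "B", "C"), resid = c(1, 1, 2),
                 resname = "RES", epsilon = c(0.1, 0.4, 0.2),
                 rmin_half = c(1.5, 1.5, 1.6))
  tb <- build_pair_table(at, exclusions = cbind(1, 2))
  p <- lj_params(tb, 1, 2)   # excluded bonded pair
  expect_true(p$excluded)
  expect_true(is.na(p$epsilon))
  p <- lj_params(tb, 1, 3)
  expect_equal(p$epsilon, sqrt(0.1 * 0.2))
  expect_equal(p$rmin, 3.1)
  # sqrt-rule identity for identical atoms
  at2 <- hj_atoms(c("A", "A2"), c(1, 1), "RES", epsilon = 0.2,
                  rmin_half = 1.5)
  expect_equal(lj_params(build_pair_table(at2), 1, 2)$epsilon, 0.2)
  # symmetry under order swap
  tb2 <- apply_lambda_scaling(tb, hj_scaling_spec(0.5, c(1, 3)))
  expect_identical(lj_params(tb2, 1, 3), lj_params(tb2, 3, 1))
  # missing parameters are a named error
  expect_error(hj_atoms("BAD", 1, "RES", epsilon = -1, rmin_half = 1),
               "BAD")
})

test_that("branch-point selection subtracts the WC template atoms", {
  at <- dna_test_atoms()
  # no WC flags: all atoms of the residue selected
  spec <- select_branchpoint_atoms(at, 1, exclude_wc = FALSE)
  expect_length(spec$selection, sum(at$resid == 1))
  expect_length(spec$wc_excluded, 0)
  # full G-C and A-T pairs against the hand-enumerated oracle
  spec <- select_branchpoint_atoms(at, 1:4, exclude_wc = TRUE)
  expect_setequal(spec$selection, at$index[at$resid %in% 1:4])
  expected_wc <- unlist(lapply(1:4, function(r) {
    rn <- at$resname[at$resid == r][1]
    at$index[at$resid == r & at$name %in% wc_oracle[[rn]]]
  }))
  expect_setequal(spec$wc_excluded, expected_wc)
  # every templated WC atom name must actually occur in its residue
  expect_length(spec$wc_excluded,
                sum(lengths(wc_oracle)))
  expect_error(select_branchpoint_atoms(at, integer(0)), "at least one")
  expect_error(select_branchpoint_atoms(at, 99), "not in topology")
})

test_that("lambda scaling multiplies eps of intra-selection pairs only", {
  at <- random_atoms(6)
  tb <- build_pair_table(at)
  spec <- hj_scaling_spec(0.75, selection = 1:4, wc_excluded = 4)
  tb2 <- apply_lambda_scaling(tb, spec)
  # both ends inside the effective selection (1:3): scaled
  p <- lj_params(tb2, 1, 2)
  expect_equal(p$epsilon, 0.75 * sqrt(at$epsilon[1] * at$epsilon[2]))
  expect_true(p$scaled)
  # rmin untouched by scaling
  expect_equal(p$rmin, at$rmin_half[1] + at$rmin_half[2])
  # one end outside the selection: bit-identical
  for (pr in list(c(1, 5), c(4, 2), c(5, 6))) {
    b <- lj_params(tb, pr[1], pr[2]); a <- lj_params(tb2, pr[1], pr[2])
    expect_identical(a$epsilon, b$epsilon)
    expect_false(a$scaled)
  }
  # lambda = 1 is the identity
  expect_equal(lj_params(apply_lambda_scaling(tb, hj_scaling_spec(1, 1:4)),
                         1, 2)$epsilon,
               lj_params(tb, 1, 2)$epsilon)
  # applying twice scales twice (documented non-idempotence)
  tb3 <- apply_lambda_scaling(tb2, spec)
  expect_equal(lj_params(tb3, 1, 2)$epsilon,
               0.75^2 * sqrt(at$epsilon[1] * at$epsilon[2]))
  # invalid lambda
  expect_error(hj_scaling_spec(0, 1:2), "lambda")
  expect_error(hj_scaling_spec(1.2, 1:2), "lambda")
})

test_that("CUfix shifts rmin of cation-phosphate-oxygen pairs only", {
  at <- hj_atoms(name = c("K", "O1P", "N3", "K2"), resid = 1:4,
                 resname = c("K", "DT", "DT", "K"),
                 type = c("K+", "O1P", "N", "K+"),
                 epsilon = c(0.3, 0.2, 0.17, 0.3),
                 rmin_half = c(1.7, 1.6, 1.8, 1.7))
  tb <- build_pair_table(at)
  tb2 <- apply_cufix(tb, hj_cufix_spec(rmin_increase = 0.1))
  p <- lj_params(tb2, 1, 2)
  expect_equal(p$rmin, 3.3 + 0.1)
  expect_equal(p$epsilon, sqrt(0.3 * 0.2))  # epsilon untouched
  expect_equal(lj_params(tb2, 4, 2)$rmin, 3.3 + 0.1)
  # K-N pair untouched
  expect_identical(lj_params(tb2, 1, 3), lj_params(tb, 1, 3))
  # zero increase is the identity
  expect_identical(apply_cufix(tb, hj_cufix_spec(rmin_increase = 0))$overrides,
                   tb$overrides)
  # unknown type names warn and no-op
  expect_warning(tb3 <- apply_cufix(tb, hj_cufix_spec(
    cation_types = "NA+", oxygen_types = "OX", rmin_increase = 0.1)),
    "NA\\+|OX")
  expect_identical(tb3$overrides, tb$overrides)
})

test_that("scaling perturbs only eps and CUfix only rmin", {
  at <- hj_atoms(name = c("K", "O1P", "C1", "C2"), resid = c(1, 2, 2, 2),
                 resname = c("K", "DT", "DT", "DT"),
                 type = c("K+", "O1P", "CT", "CT"),
                 epsilon = c(0.3, 0.2, 0.1, 0.1), rmin_half = 1.6)
  tb <- build_pair_table(at)
  tb2 <- apply_cufix(apply_lambda_scaling(tb, hj_scaling_spec(0.5, 2:4)),
                     hj_cufix_spec())
  base <- lj_params(tb, 1, 2)
  mod <- lj_params(tb2, 1, 2)
  expect_equal(mod$rmin, base$rmin + 0.1)
  expect_equal(mod$epsilon, base$epsilon)       # cufix left eps alone
  mod34 <- lj_params(tb2, 3, 4)
  expect_equal(mod34$epsilon, 0.5 * lj_params(tb, 3, 4)$epsilon)
  expect_equal(mod34$rmin, lj_params(tb, 3, 4)$rmin)  # scaling left rmin
})

test_that("single-point vdW energy matches closed forms and the LJ zero", {
  at <- hj_atoms(c("A", "B"), 1:2, "RES", epsilon = c(0.1, 0.1),
                 rmin_half = c(1.5, 1.5))
  tb <- build_pair_table(at)
  at_rmin <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(single_point_vdw_energy(at_rmin, tb), -0.1)
  sigma <- 3 / 2^(1 / 6)
  at_sigma <- matrix(c(0, 0, 0, sigma, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(single_point_vdw_energy(at_sigma, tb), 0, tolerance = 1e-12)
  expect_error(single_point_vdw_energy(matrix(0, 2, 3), tb), "zero")
})

test_that("scaled-subset energy is exactly linear in lambda", {
  n <- 20
  at <- random_atoms(n, seed = 7)
  coords <- random_coords(n, seed = 8, spread = 15)
  sel <- 3:12
  pairs_sel <- t(combn(sel, 2))
  tb <- build_pair_table(at)
  e1_pkg <- single_point_vdw_energy(coords, tb, pair_subset = pairs_sel)
  e1_brute <- brute_vdw(coords, at$epsilon, at$rmin_half, pairs_sel)
  expect_equal(e1_pkg, e1_brute, tolerance = 1e-12)
  for (lam in c(0.5, 0.625, 0.75, 1.0)) {
    tbl <- apply_lambda_scaling(tb, hj_scaling_spec(lam, sel))
    e_pkg <- single_point_vdw_energy(coords, tbl, pair_subset = pairs_sel)
    e_brute <- brute_vdw(coords, at$epsilon, at$rmin_half, pairs_sel,
                         scale = lam, scale_set = sel)
    expect_equal(e_pkg, e_brute, tolerance = 1e-12)
    expect_equal(e_pkg, lam * e1_pkg, tolerance = 1e-10)
    # pairs straddling the selection boundary are untouched
    out_pair <- rbind(c(1, 5), c(13, 14))
    expect_identical(single_point_vdw_energy(coords, tbl, out_pair),
                     single_point_vdw_energy(coords, tb, out_pair))
  }
})

test_that("minimum image is honoured when a periodic cell is given", {
  at <- hj_atoms(c("A", "B"), 1:2, "RES", epsilon = 0.1, rmin_half = 1.5)
  tb <- build_pair_table(at)
  # images at 3 A through the boundary of a 10 A box
  coords <- matrix(c(0.5, 0, 0, 7.5, 0, 0), 2, 3, byrow = TRUE)
  e_pbc <- single_point_vdw_energy(coords, tb, box = c(10, 10, 10))
  expect_equal(e_pbc, -0.1)
})

test_that("parm7 round trip reproduces modified pair parameters", {
  at <- random_atoms(8, seed = 3)
  tb <- build_pair_table(at)
  tb <- apply_lambda_scaling(tb, hj_scaling_spec(0.75, 2:5))
  path <- withr::local_tempfile(fileext = ".parm7")
  paths <- write_modified_topology(tb, path)
  back <- read_parm7(paths["parm7"])
  expect_equal(nrow(back$atoms), 8)
  idx <- t(combn(8, 2))
  orig <- lj_params(tb, idx[, 1], idx[, 2])
  rt <- back$pairs(idx[, 1], idx[, 2])
  expect_equal(rt$epsilon, orig$epsilon, tolerance = 1e-10)
  expect_equal(rt$rmin, orig$rmin, tolerance = 1e-10)
  # scaled pair epsilon is 0.75x the combination value after reread
  p23 <- back$pairs(2, 3)
  expect_equal(p23$epsilon,
               0.75 * sqrt(at$epsilon[2] * at$epsilon[3]),
               tolerance = 1e-10)
  # GROMACS boundary uses exactly 4.184 and rmin -> sigma conversion
  gmx <- readLines(paths["gromacs"])
  row <- strsplit(trimws(gmx[grepl("^ty2\\s+ty3", gmx)]), "\\s+")[[1]]
  expect_equal(as.numeric(row[5]),
               4.184 * 0.75 * sqrt(at$epsilon[2] * at$epsilon[3]),
               tolerance = 1e-10)
  expect_equal(as.numeric(row[4]),
               (at$rmin_half[2] + at$rmin_half[3]) / 2^(1 / 6) / 10,
               tolerance = 1e-10)
  # oversized expansion refused explicitly
  expect_error(write_parm7(tb, path, max_atoms = 4), "max_atoms")
})

test_that("unmodified tables round-trip their LJ parameters losslessly", {
  at <- random_atoms(5, seed = 11)
  tb <- build_pair_table(at)
  p1 <- withr::local_tempfile()
  write_parm7(tb, p1)
  back <- read_parm7(p1)
  # per-atom parameters recovered exactly at the printed precision
  expect_equal(back$atoms$epsilon, at$epsilon, tolerance = 1e-12)
  expect_equal(back$atoms$rmin_half, at$rmin_half, tolerance = 1e-12)
  # parsing is deterministic: two reads give identical numbers
  back2 <- read_parm7(p1)
  idx <- t(combn(5, 2))
  expect_identical(back$pairs(idx[, 1], idx[, 2]),
                   back2$pairs(idx[, 1], idx[, 2]))
})
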