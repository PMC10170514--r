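test_that("rational switching function matches its closed forms", {
  expect_equal(switch_rational(0), 1.0)
  # removable singularity at r0: limit n/m
  expect_equal(switch_rational(3.0), 0.5)
  expect_equal(switch_rational(3 + 1e-13), 0.5)
  # direct arithmetic at 2 r0
  expect_equal(switch_rational(6.0), 15 / 255)
  # custom exponents keep the limit rule
  expect_equal(switch_rational(2, switching_params(n = 3, m = 6, r0 = 2)),
               0.5)
  expect_error(switching_params(n = 4, m = 4), "m > n")
})

test_that("switching function decreases strictly and stays in (0, 1]", {
  r <- seq(0, 30, by = 1e-3)
  s <- switch_rational(r)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(diff(s) < 0))
})

test_that("coordination numbers count smooth contacts", {
  p <- switching_params()
  # 1x1 atoms at r0
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(coordination_number(xyz, 1, 2, params = p), 0.5)
  # far groups are practically zero
  far <- rbind(matrix(rnorm(9), 3, 3), matrix(rnorm(9) + 40, 3, 3))
  expect_lt(coordination_number(far, 1:3, 4:6, params = p), 1e-4)
  # 2x2 atoms all at ~0.1 A: four nearly saturated pairs
  near <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0, 0.1, 0), c(0.1, 0.1, 0))
  expect_equal(coordination_number(near, 1:2, 3:4, params = p), 4,
               tolerance = 1e-3)
  expect_warning(z <- coordination_number(near, integer(0), 3:4),
                 "empty")
  expect_equal(z, 0)
  expect_error(coordination_number(near, 1:2, 2:3), "disjoint")
})

test_that("coordination is invariant under rigid motion and reordering", {
  set.seed(5)
  xyz <- matrix(rnorm(60, sd = 3), 20, 3)
  gA <- 1:8; gB <- 9:20
  ref <- coordination_number(xyz, gA, gB)
  for (k in 1:5) {
    R <- random_rotation(seed = k)
    moved <- xyz %*% R + matrix(runif(3, -20, 20), 20, 3, byrow = TRUE)
    expect_equal(coordination_number(moved, gA, gB), ref,
                 tolerance = 1e-10)
    expect_equal(coordination_number(xyz, sample(gA), sample(gB)), ref)
  }
})

test_that("CV series separates stacked from unstacked stems", {
  lab <- c("CLOSED_I", "CLOSED_I", "OPEN")
  traj <- render_trajectory(lab, hj_geometry_template(jitter = 0.05),
                            seed = 2)
  cv <- compute_cv_series(traj, attr(traj, "groups"))
  expect_equal(nrow(cv), 3)
  # constructed closed-I geometry: intra-stack CVs dominate
  expect_gt(cv$s_I_II[1], 50)
  expect_gt(cv$s_III_IV[1], 50)
  expect_lt(cv$s_I_IV[1], 5)
  expect_lt(cv$s_II_III[1], 5)
  expect_true(all(cv[3, c("s_I_II", "s_III_IV", "s_I_IV", "s_II_III")] < 5))
  # alpha = 1: normalized equals raw
  expect_equal(cv$s_I_II_n, cv$s_I_II)
  # alpha = 0.65 normalization
  cv2 <- compute_cv_series(traj, attr(traj, "groups"), alpha = 0.65)
  expect_equal(cv2$s_I_II_n, cv2$s_I_II^0.65)
})

test_that("COLVAR round trip reproduces the CV table", {
  traj <- render_trajectory(c("OPEN", "HC_IL"), seed = 3)
  cv <- compute_cv_series(traj, attr(traj, "groups"), alpha = 0.65)
  path <- withr::local_tempfile()
  write_colvar(cv, path)
  back <- read_colvar(path)
  expect_equal(back$s_I_II, cv$s_I_II, tolerance = 1e-6)
  expect_equal(back$s_II_III_n, cv$s_II_III_n, tolerance = 1e-6)
  expect_error(read_colvar(withr::local_tempfile(lines = "no header")),
               "FIELDS")
})

test_that("classification reproduces the worked seven-state examples", {
  mk <- function(a, b, c, d) data.frame(s_I_II = a, s_III_IV = b,
                                        s_I_IV = c, s_II_III = d)
  expect_equal(as.character(classify_states(mk(2, 2, 2, 2))), "OPEN")
  expect_equal(as.character(classify_states(mk(60, 60, 1, 1))), "CLOSED_I")
  expect_equal(as.character(classify_states(mk(1, 1, 60, 60))), "CLOSED_II")
  expect_equal(as.character(classify_states(mk(60, 1, 1, 1))), "HC_IL")
  expect_equal(as.character(classify_states(mk(1, 60, 1, 1))), "HC_IR")
  expect_equal(as.character(classify_states(mk(1, 1, 60, 1))), "HC_IIL")
  expect_equal(as.character(classify_states(mk(1, 1, 1, 60))), "HC_IIR")
  expect_equal(as.character(classify_states(mk(60, 1, 60, 1))), "UNASSIGNED")
  expect_equal(as.character(classify_states(mk(20, 20, 20, 20))), "UNASSIGNED")
})

test_that("classifier agrees with the brute-force rules on a 4D grid", {
  vals <- c(0, 1, 4.9, 5, 20, 50, 51, 100)
  grid <- expand.grid(s_I_II = vals, s_III_IV = vals,
                      s_I_IV = vals, s_II_III = vals)
  got <- as.character(classify_states(grid))
  want <- apply(as.matrix(grid), 1, brute_classify)
  expect_identical(got, want)
  # total function: every frame gets exactly one label
  expect_false(anyNA(got))
})

test_that("transition extraction handles the canonical micro-cases", {
  r <- extract_transitions(c("CLOSED_I", "HC_IL", "OPEN"))
  expect_equal(nrow(r$transitions), 1)
  expect_equal(r$transitions$start, "CLOSED_I")
  expect_equal(r$transitions$end, "OPEN")
  expect_equal(r$transitions$intermediates, "HC_IL")
  expect_false(r$transitions$direct)
  r <- extract_transitions(c("CLOSED_I", "OPEN"))
  expect_equal(nrow(r$transitions), 1)
  expect_true(r$transitions$direct)
  # reverted excursion: zero transitions, one attempt
  r <- extract_transitions(c("CLOSED_I", "HC_IL", "CLOSED_I"))
  expect_equal(nrow(r$transitions), 0)
  expect_equal(nrow(r$attempts), 1)
  expect_equal(r$attempts$intermediates, "HC_IL")
})

test_that("unassigned gaps are tolerated up to the limit, then split", {
  lab <- c("CLOSED_I", rep("UNASSIGNED", 3), "OPEN")
  r <- extract_transitions(lab, max_unassigned_gap = 5)
  expect_equal(nrow(r$transitions), 1)
  r <- extract_transitions(lab, max_unassigned_gap = 2)
  expect_equal(nrow(r$transitions), 0)
})

test_that("event conservation: labels changes all land somewhere", {
  set.seed(9)
  model <- hj_state_model()
  sim <- generate_state_sequence(model, 4000, seed = 17)
  r <- extract_transitions(sim$labels)
  # every half-closed visit bounded by end states is in exactly one
  # transition or attempt
  n_recorded <- nrow(r$transitions) + nrow(r$attempts)
  lab <- as.character(sim$labels)
  runs <- rle(lab)$values
  ends <- runs[runs %in% c("OPEN", "CLOSED_I", "CLOSED_II")]
  expect_equal(nrow(r$transitions), sum(ends[-1] != ends[-length(ends)]))
  expect_gt(n_recorded, 0)
})

test_that("pathway summary returns scripted counts and direct fraction", {
  lab <- script_pathway_sequence(n_via = c(HC_IL = 32, HC_IR = 11),
                                 n_direct = 3, seed = 4)
  ps <- pathway_summary(extract_transitions(lab))
  expect_equal(ps$n_total, 46)
  counts <- setNames(ps$counts$n, ps$counts$pathway)
  expect_equal(counts[["HC_IL"]], 32)
  expect_equal(counts[["HC_IR"]], 11)
  expect_equal(counts[["direct"]], 3)
  expect_equal(ps$direct_fraction, 3 / 46)
  # empty input
  ps0 <- pathway_summary(extract_transitions(character(0)))
  expect_equal(ps0$n_total, 0)
  expect_equal(nrow(ps0$counts), 0)
})

test_that("pathway counts are invariant under segment concatenation order", {
  # both segments carry an even transition count, so they start and
  # end in the same end state and concatenation adds no boundary event
  seg1 <- script_pathway_sequence(c(HC_IL = 4, HC_IR = 2), 0, seed = 1)
  seg2 <- script_pathway_sequence(c(HC_IL = 3, HC_IR = 5), 0, seed = 2)
  tally <- function(lab) {
    ps <- pathway_summary(extract_transitions(lab))
    out <- setNames(ps$counts$n, ps$counts$pathway)
    out[order(names(out))]
  }
  expect_equal(tally(c(seg1, seg2)), tally(c(seg2, seg1)))
  expect_equal(sum(tally(c(seg1, seg2))), 14)
})
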