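#' Rational switching function for coordination numbers
#'
#' `s(r) = (1 - x^n) / (1 - x^m)` with `x = (r - d0)/r0`, the standard
#' smooth contact-counting function; at `x = 1` the removable
#' singularity takes its limit `n/m`. The junction CVs use `n = 4`,
#' `m = 2n = 8`, `r0 = 3` Angstrom, `d0 = 0`, giving `s(0) = 1`,
#' `s(r0) = 0.5` and a fast decay beyond the stacking contact range.
#'
#' @param r distance(s), Angstrom, `>= 0`.
#' @param params switching parameters, see [switching_params()].
#' @return values in (0, 1], vectorized over `r`.
#' @export
switch_rational <- function(r, params = switching_params()) {
  stopifnot(all(r >= 0))
  x <- (r - params$d0) / params$r0
  x[x < 0] <- 0
  xn <- x^params$n
  xm <- x^params$m
  s <- (1 - xn) / (1 - xm)
  # removable singularity at x = 1 and its numerical neighbourhood
  near <- !is.finite(s) | abs(1 - xm) < 1e-12
  s[near] <- params$n / params$m
  s
}

#' @rdname switch_rational
#' @param n,m rational exponents, `m > n > 0` (default `n = 4`,
#'   `m = 2n`).
#' @param r0 switching radius, Angstrom (default 3).
#' @param d0 offset, Angstrom (default 0).
#' @export
switching_params <- function(n = 4L, m = 2L * n, r0 = 3.0, d0 = 0.0) {
  stopifnot(n > 0, m > n, r0 > 0, d0 >= 0)
  list(n = n, m = m, r0 = r0, d0 = d0)
}

#' Coordination number between two atom groups
#'
#' Sum of the switching function over all cross-group distances; the
#' stacking CV when the groups are the nucleobase atoms of two
#' branch-point base pairs. Invariant under rigid motions of the whole
#' system and under atom reordering within groups.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param groupA,groupB disjoint atom index vectors.
#' @param box optional periodic cell (minimum image applied).
#' @param params switching parameters.
#' @return non-negative coordination number.
#' @export
coordination_number <- function(coords, groupA, groupB, box = NULL,
                                params = switching_params()) {
  if (length(groupA) == 0 || length(groupB) == 0) {
    warning("empty atom group; coordination number is 0")
    return(0)
  }
  if (length(intersect(groupA, groupB)))
    stop("coordination groups must be disjoint")
  r <- cross_distances(coords[groupA, , drop = FALSE],
                       coords[groupB, , drop = FALSE], box)
  sum(switch_rational(as.numeric(r), params))
}

#' Stacking CV series over a trajectory
#'
#' Computes the four stacking coordination numbers s_I-II, s_III-IV,
#' s_I-IV and s_II-III for every frame, raw and normalized
#' (`raw^alpha`). The exponent alpha (0.65 for the isomer-I setup, 0.4
#' for isomer II) equalizes the CV standard deviations of open and
#' closed states; `alpha = 1` leaves the raw values.
#'
#' @param traj an [hj_trajectory()].
#' @param groups named list `I`, `II`, `III`, `IV` of atom index
#'   vectors (the four branch-point base-pair nucleobase groups).
#' @param params switching parameters.
#' @param alpha normalization exponent.
#' @return data.frame of class `hj_cv_series`: `frame`, `time`, raw
#'   columns `s_I_II`, `s_III_IV`, `s_I_IV`, `s_II_III` and normalized
#'   counterparts with suffix `_n`.
#' @export
compute_cv_series <- function(traj, groups, params = switching_params(),
                              alpha = 1) {
  stopifnot(inherits(traj, "hj_trajectory"))
  if (!all(c("I", "II", "III", "IV") %in% names(groups)))
    stop("groups must be named I, II, III, IV")
  nat <- nrow(traj$atoms)
  if (max(unlist(groups)) > nat)
    stop("group atom indices exceed trajectory atom count")
  combos <- list(s_I_II = c("I", "II"), s_III_IV = c("III", "IV"),
                 s_I_IV = c("I", "IV"), s_II_III = c("II", "III"))
  nf <- length(traj$coords)
  out <- matrix(0, nf, 4, dimnames = list(NULL, names(combos)))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[[f]]
    for (k in seq_along(combos)) {
      gg <- combos[[k]]
      out[f, k] <- coordination_number(xyz, groups[[gg[1]]], groups[[gg[2]]],
                                       box = traj$box, params = params)
    }
  }
  df <- data.frame(frame = seq_len(nf), time = traj$time, out)
  for (nm in names(combos)) df[[paste0(nm, "_n")]] <- df[[nm]]^alpha
  attr(df, "alpha") <- alpha
  class(df) <- c("hj_cv_series", "data.frame")
  df
}

#' State thresholds for the seven-state classification
#'
#' A CV below `open_below` counts as unstacked, above `closed_above`
#' as fully stacked; the thresholds apply to the RAW coordination
#' numbers.
#'
#' @param open_below default 5.
#' @param closed_above default 50.
#' @export
state_thresholds <- function(open_below = 5, closed_above = 50) {
  stopifnot(open_below < closed_above)
  list(open_below = open_below, closed_above = closed_above)
}

#' @rdname classify_states
#' @export
hj_state_levels <- function() {
  c("OPEN", "CLOSED_I", "CLOSED_II", "HC_IL", "HC_IR", "HC_IIL", "HC_IIR",
    "UNASSIGNED")
}

#' Seven-state conformational classification
#'
#' Classifies frames by the four raw stacking CVs:
#' * `OPEN` - all four below `open_below`;
#' * `CLOSED_I` - s_I-II and s_III-IV above `closed_above` (isomer I,
#'   stems I+II and III+IV stacked);
#' * `CLOSED_II` - s_I-IV and s_II-III above `closed_above`;
#' * half-closed `HC_IL`/`HC_IR`/`HC_IIL`/`HC_IIR` - exactly one CV
#'   (s_I-II / s_III-IV / s_I-IV / s_II-III respectively) above
#'   `closed_above` with the remaining three below `open_below`. The
#'   "L" states have stem I stacked, the "R" states have it unstacked.
#'
#' A frame matching no definition, or more than one, is `UNASSIGNED`,
#' which makes the seven assigned labels mutually exclusive by
#' construction.
#'
#' @param cv an `hj_cv_series` data.frame, or any data.frame with raw
#'   columns `s_I_II`, `s_III_IV`, `s_I_IV`, `s_II_III`.
#' @param thresholds see [state_thresholds()].
#' @return factor of state labels, levels [hj_state_levels()].
#' @export
classify_states <- function(cv, thresholds = state_thresholds()) {
  need <- c("s_I_II", "s_III_IV", "s_I_IV", "s_II_III")
  if (!all(need %in% names(cv)))
    stop("cv must contain raw columns ", paste(need, collapse = ", "))
  lo <- thresholds$open_below
  hi <- thresholds$closed_above
  s12 <- cv$s_I_II; s34 <- cv$s_III_IV; s14 <- cv$s_I_IV; s23 <- cv$s_II_III
  below <- cbind(s12 < lo, s34 < lo, s14 < lo, s23 < lo)
  above <- cbind(s12 > hi, s34 > hi, s14 > hi, s23 > hi)
  defs <- cbind(
    OPEN      = below[, 1] & below[, 2] & below[, 3] & below[, 4],
    CLOSED_I  = above[, 1] & above[, 2],
    CLOSED_II = above[, 3] & above[, 4],
    HC_IL     = above[, 1] & below[, 2] & below[, 3] & below[, 4],
    HC_IR     = above[, 2] & below[, 1] & below[, 3] & below[, 4],
    HC_IIL    = above[, 3] & below[, 1] & below[, 2] & below[, 4],
    HC_IIR    = above[, 4] & below[, 1] & below[, 2] & below[, 3])
  nhit <- rowSums(defs)
  lab <- rep("UNASSIGNED", nrow(defs))
  one <- which(nhit == 1)
  lab[one] <- colnames(defs)[max.col(defs[one, , drop = FALSE])]
  factor(lab, levels = hj_state_levels())
}

end_states <- function() c("OPEN", "CLOSED_I", "CLOSED_II")
half_closed_states <- function() c("HC_IL", "HC_IR", "HC_IIL", "HC_IIR")

#' Reactive transitions and unsuccessful attempts
#'
#' Walks a state-label sequence and records every complete transition
#' between two distinct end states (open and the two closed isomers) -
#' the "reactive trajectory" portions - along with the ordered list of
#' half-closed intermediates visited in between. Excursions that reach
#' a half-closed state but revert to the same end state are counted as
#' unsuccessful attempts. UNASSIGNED frames are tolerated inside a
#' transition up to `max_unassigned_gap` consecutive frames; a longer
#' gap splits the record.
#'
#' @param labels factor/character sequence of state labels.
#' @param max_unassigned_gap maximum tolerated run of UNASSIGNED frames
#'   (default 50).
#' @return list with `transitions` (data.frame: `start`, `end`,
#'   `intermediates` comma-joined, `direct`, `frame_start`,
#'   `frame_end`) and `attempts` (data.frame: `end_state`,
#'   `intermediates`, `frame_start`, `frame_end`).
#' @export
extract_transitions <- function(labels, max_unassigned_gap = 50) {
  labels <- as.character(labels)
  ends <- end_states(); half <- half_closed_states()
  trans <- list(); att <- list()
  last_end <- NA_character_
  last_end_frame <- NA_integer_
  inter <- character(0)
  gap <- 0L
  for (f in seq_along(labels)) {
    lb <- labels[f]
    if (lb == "UNASSIGNED") {
      gap <- gap + 1L
      if (gap > max_unassigned_gap) {
        last_end <- NA_character_; inter <- character(0)
      }
      next
    }
    gap <- 0L
    if (lb %in% half) {
      if (!is.na(last_end) &&
          (length(inter) == 0 || inter[length(inter)] != lb))
        inter <- c(inter, lb)
      next
    }
    # end state
    if (is.na(last_end)) {
      last_end <- lb; last_end_frame <- f; inter <- character(0)
    } else if (lb == last_end) {
      if (length(inter))
        att[[length(att) + 1]] <- data.frame(
          end_state = lb, intermediates = paste(inter, collapse = ","),
          frame_start = last_end_frame, frame_end = f)
      last_end_frame <- f; inter <- character(0)
    } else {
      trans[[length(trans) + 1]] <- data.frame(
        start = last_end, end = lb,
        intermediates = paste(inter, collapse = ","),
        direct = length(inter) == 0,
        frame_start = last_end_frame, frame_end = f)
      last_end <- lb; last_end_frame <- f; inter <- character(0)
    }
  }
  empty_tr <- data.frame(start = character(0), end = character(0),
                         intermediates = character(0), direct = logical(0),
                         frame_start = integer(0), frame_end = integer(0))
  empty_at <- data.frame(end_state = character(0),
                         intermediates = character(0),
                         frame_start = integer(0), frame_end = integer(0))
  list(transitions = if (length(trans)) do.call(rbind, trans) else empty_tr,
       attempts = if (length(att)) do.call(rbind, att) else empty_at)
}

#' Pathway summary of reactive transitions
#'
#' Counts transitions per (end-state pair, pathway) edge, where the
#' pathway is "direct", a single half-closed intermediate, or "multi"
#' when several distinct intermediates were visited, plus the overall
#' fraction of direct transitions.
#'
#' @param transitions the `transitions` data.frame from
#'   [extract_transitions()] (or the whole result list).
#' @return list with `counts` (data.frame `pair`, `pathway`, `n`),
#'   `n_total` and `direct_fraction`.
#' @export
pathway_summary <- function(transitions) {
  if (is.list(transitions) && !is.data.frame(transitions))
    transitions <- transitions$transitions
  if (nrow(transitions) == 0)
    return(list(counts = data.frame(pair = character(0),
                                    pathway = character(0), n = integer(0)),
                n_total = 0L, direct_fraction = NaN))
  pair <- apply(cbind(transitions$start, transitions$end), 1,
                function(x) paste(sort(x), collapse = "<->"))
  pathway <- vapply(transitions$intermediates, function(s) {
    if (s == "") return("direct")
    u <- unique(strsplit(s, ",")[[1]])
    if (length(u) == 1) u else "multi"
  }, "", USE.NAMES = FALSE)
  tab <- as.data.frame(table(pair = pair, pathway = pathway),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  rownames(tab) <- NULL
  list(counts = tab, n_total = nrow(transitions),
       direct_fraction = mean(transitions$direct))
}
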