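# Automatic transition labeling from the Euler-angle signals. A trial has
# two transitions (relax -> motion, motion -> relax); the three Euler axes
# are direction-aligned and summed into one regulated signal whose slope
# peaks at each transition. The two dominant slope extrema locate the
# transitions, and threshold crossings of the slope magnitude around them
# give the four boundaries L1-L4.

#' Parameters of the automatic labeler
#'
#' @param duration_ms Minimum temporal separation (ms) for two slope extrema
#'   to count as distinct transitions rather than noise; default 2000 ms
#'   (well below the ~10 s hold, well above a single transition).
#' @param middle_ms Length (ms) of the static mid-trial segment used both
#'   for the flip decision and the crossing threshold (fixed 2000 ms).
#' @param lead_ms Length (ms) of the initial relaxed segment whose mean
#'   anchors the flip-direction decision (default 1000 ms).
#' @return An object of class `autolabel_params`.
#' @export
autolabel_params <- function(duration_ms = 2000, middle_ms = 2000,
                             lead_ms = 1000) {
  if (duration_ms <= 0) stop("duration_ms must be > 0", call. = FALSE)
  structure(list(duration_ms = duration_ms, middle_ms = middle_ms,
                 lead_ms = lead_ms), class = "autolabel_params")
}

middle_indices <- function(n, middle_ms, sample_rate = 100) {
  half <- round(middle_ms / 1000 * sample_rate / 2)
  centre <- floor(n / 2)
  seq.int(max(1L, centre - half + 1L), min(n, centre + half))
}

#' Regulate the Euler-angle signals
#'
#' Direction-aligns the three Euler axes so all change the same way from
#' relax toward the motion plateau: an axis whose mid-trial mean is below
#' its lead-window mean (it decreased going into the motion) is flipped
#' about its trial mean (`x' = 2 mean(x) - x`). The aligned axes are summed
#' into the regulated signal, whose first-difference slope `S` peaks at the
#' two transitions.
#'
#' @param imu Numeric matrix, samples x 3 (pitch, roll, yaw in degrees).
#' @param params An [autolabel_params()].
#' @return Object of class `regulated_signal` with elements `regulated`
#'   (length n), `slope` (length n - 1) and `flipped` (logical length 3).
#' @export
regulate_imu <- function(imu, params = autolabel_params()) {
  imu <- as.matrix(imu)
  n <- nrow(imu)
  n_lead <- round(params$lead_ms / 10)
  if (n < 2 * round(params$middle_ms / 10)) {
    stop("trial too short to regulate", call. = FALSE)
  }
  mid <- middle_indices(n, params$middle_ms)
  flipped <- logical(3)
  out <- imu
  for (a in 1:3) {
    if (mean(imu[mid, a]) < mean(imu[seq_len(n_lead), a])) {
      out[, a] <- 2 * mean(imu[, a]) - imu[, a]
      flipped[a] <- TRUE
    }
  }
  regulated <- rowSums(out)
  structure(list(regulated = regulated, slope = diff(regulated),
                 flipped = flipped), class = "regulated_signal")
}

# local maxima of a sequence via the sign-change rule on its first
# differences: d(i) > 0 and d(i+1) < 0 marks position i+1 as a maximum.
# Zero differences (flat-topped extrema, possible in noise-free signals)
# carry the preceding slope sign so a plateau peak is reported once.
local_maxima <- function(v) {
  s <- sign(diff(v))
  last <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) s[i] <- last else last <- s[i]
  }
  which(s[-length(s)] > 0 & s[-1] < 0) + 1L
}

#' Locate the two transition slope extrema
#'
#' Candidate extrema of the slope magnitude `|S|` are found by the
#' sign-change rule on the differences of `|S|` and sorted by magnitude in
#' descending order (ties broken by earlier position). The largest is the
#' first transition peak; the second is the first candidate farther than the
#' duration threshold from it, which rejects secondary ripples of the same
#' transition. The pair is returned in temporal order.
#'
#' @param S Numeric slope sequence (first differences of the regulated
#'   signal).
#' @param params An [autolabel_params()].
#' @param sample_rate Sampling rate in Hz.
#' @return Named integer vector `c(P1, P2)` with `P1 < P2` (positions in S).
#' @export
find_transition_peaks <- function(S, params = autolabel_params(),
                                  sample_rate = 100) {
  a <- abs(S)
  cand <- local_maxima(a)
  if (length(cand) < 1L) {
    stop("no interior slope extremum found", call. = FALSE)
  }
  ord <- cand[order(-a[cand], cand)]
  p1 <- ord[1L]
  min_sep <- params$duration_ms / 1000 * sample_rate
  p2 <- NA_integer_
  for (m in ord[-1L]) {
    if (abs(m - p1) > min_sep) { p2 <- m; break }
  }
  if (is.na(p2)) {
    stop("only one transition found: no second slope extremum beyond the duration threshold; trial flagged for manual review",
         call. = FALSE)
  }
  c(P1 = min(p1, p2), P2 = max(p1, p2))
}

#' Detect the boundary set around the transition peaks
#'
#' The crossing threshold is the standard deviation of the slope over the
#' static middle 2 s of the trial (pure noise there). Candidate boundaries
#' are the points where `|S|` crosses the threshold; the crossings nearest
#' each peak on either side become the boundaries: L1/L2 bracket the first
#' peak, L3/L4 the second.
#'
#' @param S Slope sequence.
#' @param P1,P2 Transition peak positions from [find_transition_peaks()].
#' @param params An [autolabel_params()].
#' @return A [boundary_set()] with the threshold in attribute `"theta"`.
#' @export
detect_boundaries <- function(S, P1, P2, params = autolabel_params()) {
  if (!(P1 < P2)) stop("P1 must precede P2", call. = FALSE)
  mid <- middle_indices(length(S), params$middle_ms)
  theta <- stats::sd(S[mid])
  a <- abs(S)
  below <- a <= theta
  # crossing = change of side between consecutive samples; record the sample
  # on the below-threshold side as the boundary candidate
  ch <- which(below[-length(below)] != below[-1L])
  if (length(ch) == 0L) stop("no threshold crossings found", call. = FALSE)
  cand_before <- ifelse(below[ch], ch, ch + 1L)   # below-side sample of each crossing
  nearest <- function(peak, side) {
    if (side == "before") {
      ok <- cand_before[cand_before <= peak]
      if (!length(ok)) stop("no crossing before a transition peak", call. = FALSE)
      max(ok)
    } else {
      ok <- cand_before[cand_before >= peak]
      if (!length(ok)) stop("no crossing after a transition peak", call. = FALSE)
      min(ok)
    }
  }
  b <- boundary_set(L1 = nearest(P1, "before"), L2 = nearest(P1, "after"),
                    L3 = nearest(P2, "before"), L4 = nearest(P2, "after"))
  attr(b, "theta") <- theta
  b
}

#' Automatically label a trial's transition boundaries
#'
#' Runs the full labeling chain (regulate, locate slope extrema, threshold
#' detection) on the trial's Euler-angle signals and returns the trial with
#' its `boundaries` field set. Existing boundaries are overwritten; the old
#' and new values are reported via `message()` when they differ.
#'
#' @param trial A [trial_record()].
#' @param params An [autolabel_params()].
#' @return The trial with `boundaries` replaced by the detected set.
#' @export
autolabel_trial <- function(trial, params = autolabel_params()) {
  reg <- regulate_imu(trial$imu, params)
  pk <- find_transition_peaks(reg$slope, params, trial$sample_rate)
  b <- detect_boundaries(reg$slope, pk["P1"], pk["P2"], params)
  if (!is.null(trial$boundaries)) {
    old <- trial$boundaries
    delta <- c(b$L1 - old$L1, b$L2 - old$L2, b$L3 - old$L3, b$L4 - old$L4)
    if (any(delta != 0)) {
      message(sprintf("relabeled %s/%s trial %d: boundary shift (%s) samples",
                      trial$subject_id, trial$motion, trial$trial_index,
                      paste(delta, collapse = ", ")))
    }
  }
  trial$boundaries <- b
  trial
}
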