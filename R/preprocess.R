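#' Low-pass filter specification
#'
#' The capacitance channels carry high-frequency noise well above the
#' muscle-deformation band; a 4th-order Butterworth low-pass filter with a
#' 5 Hz cutoff removes it at the 100 Hz sampling rate.
#'
#' @param order Filter order (default 4).
#' @param cutoff Cutoff frequency in Hz (default 5); must be below Nyquist.
#' @param sample_rate Sampling rate in Hz (default 100).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff = 5, sample_rate = 100) {
  if (order < 1) stop("filter order must be >= 1", call. = FALSE)
  if (!(cutoff > 0 && cutoff < sample_rate / 2)) {
    stop("cutoff must lie in (0, sample_rate/2)", call. = FALSE)
  }
  structure(list(order = order, cutoff = cutoff, sample_rate = sample_rate),
            class = "filter_spec")
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Applies the Butterworth design forward and backward (zero-phase), so the
#' filtered signal has no group delay and boundary labels derived from the
#' IMU stay aligned with the capacitance features. The effective magnitude
#' response is the square of the single-pass response.
#'
#' @param x Numeric signal.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
lowpass_filter <- function(x, spec = filter_spec()) {
  if (length(x) < 3 * spec$order) {
    stop(sprintf("signal too short to filter: %d < %d samples",
                 length(x), 3 * spec$order), call. = FALSE)
  }
  bf <- signal::butter(spec$order, spec$cutoff / (spec$sample_rate / 2),
                       type = "low")
  zero_phase(bf$b, bf$a, x)
}

# forward-backward filtering with odd (point-reflected) end padding and
# DC-steady-state initial conditions, so constants pass through exactly and
# edge transients stay out of the signal
zero_phase <- function(b, a, x) {
  n <- length(x)
  p <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  dc <- sum(b) / sum(a)
  one_pass <- function(v) {
    head_pad <- 2 * v[1] - v[(p + 1):2]
    tail_pad <- 2 * v[length(v)] - v[(length(v) - 1):(length(v) - p)]
    vp <- c(head_pad, v, tail_pad)
    y <- signal::filter(b, a, vp,
                        init.x = rep(vp[1], length(b) - 1L),
                        init.y = rep(vp[1] * dc, length(a) - 1L))
    as.numeric(y)[(p + 1):(p + length(v))]
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Sliding-window specification
#'
#' @param win_len_ms Window length in ms; must be a multiple of the 10 ms
#'   sample interval (default 100, i.e. 10 samples).
#' @param stride Window step in samples (default 1, so a recognition
#'   decision can be updated every 10 ms).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(win_len_ms = 100, stride = 1) {
  if (win_len_ms %% 10 != 0 || win_len_ms < 20) {
    stop("win_len_ms must be a multiple of 10 ms and at least 20 ms", call. = FALSE)
  }
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  structure(list(win_len_ms = win_len_ms, win_len = as.integer(win_len_ms / 10),
                 stride = as.integer(stride)), class = "window_spec")
}

#' Time-domain features of one window
#'
#' The four features of one channel's window: the mean (AVE), the population
#' standard deviation (STD, divide-by-n), the maximum (MAX), and the
#' normalized slope TAN = (last - first) / window length, with the window
#' length in samples.
#'
#' @param window Numeric vector of at least 2 samples.
#' @return Named numeric vector `c(ave, std, max, tan)`.
#' @export
window_features <- function(window) {
  n <- length(window)
  if (n < 2) stop("window must contain at least 2 samples", call. = FALSE)
  m <- mean(window)
  c(ave = m,
    std = sqrt(mean((window - m)^2)),
    max = max(window),
    tan = (window[n] - window[1]) / n)
}

feature_names <- function() {
  as.vector(t(outer(paste0("cap", 1:6), c("ave", "std", "max", "tan"),
                    paste, sep = "_")))
}

#' Extract the 24-column feature matrix from a feature table
#' @param ft A `feature_table` from [featurize_trial()].
#' @return Numeric matrix, windows x 24.
#' @export
feature_matrix <- function(ft) {
  as.matrix(ft[, feature_names()])
}

#' Featurize a trial with sliding windows
#'
#' Low-pass filters each capacitance channel, slides a fixed-length window
#' from the beginning to the end of the trial, and computes the four
#' time-domain features per channel. The six channels' features are
#' serially concatenated, giving a 24-element feature vector per window
#' (channel-major order: cap1 ave/std/max/tan, cap2 ave/std/max/tan, ...).
#'
#' Each window is labeled by the segment containing its full extent: `R`
#' before L1 and after L4, the trial motion between L2 and L3. Windows that
#' overlap a transition interval (\[L1,L2\] or \[L3,L4\]) get
#' `transition = TRUE` and an `NA` label; they are excluded from accuracy
#' metrics but kept in the decision stream for prediction-time metrics.
#'
#' @param trial A [trial_record()].
#' @param wspec A [window_spec()].
#' @param boundaries A [boundary_set()], or `NULL` to use the trial's own
#'   (possibly absent) boundaries. With no boundaries every window is
#'   labeled with the trial motion and no window is flagged.
#' @param fspec A [filter_spec()], or `NULL` to skip filtering.
#' @return A `feature_table`: data frame with `end_index` (window end
#'   sample), `label`, `transition`, and the 24 feature columns.
#' @export
featurize_trial <- function(trial, wspec = window_spec(), boundaries = NULL,
                            fspec = filter_spec()) {
  n <- n_samples(trial)
  w <- wspec$win_len
  if (n < w) stop("trial shorter than the window length", call. = FALSE)
  if (is.null(boundaries)) boundaries <- trial$boundaries

  cap <- trial$cap
  if (!is.null(fspec)) cap <- apply(cap, 2L, lowpass_filter, spec = fspec)

  starts <- seq.int(1L, n - w + 1L, by = wspec$stride)
  ends <- starts + w - 1L
  idx <- outer(starts, 0:(w - 1L), `+`)

  feats <- matrix(0, nrow = length(starts), ncol = 24L,
                  dimnames = list(NULL, feature_names()))
  for (j in 1:6) {
    X <- matrix(cap[, j][idx], nrow = length(starts))
    mu <- rowMeans(X)
    feats[, (j - 1L) * 4L + 1L] <- mu
    feats[, (j - 1L) * 4L + 2L] <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
    feats[, (j - 1L) * 4L + 3L] <- do.call(pmax, as.data.frame(X))
    feats[, (j - 1L) * 4L + 4L] <- (X[, w] - X[, 1L]) / w
  }

  if (is.null(boundaries)) {
    label <- rep(trial$motion, length(starts))
    transition <- rep(FALSE, length(starts))
  } else {
    b <- boundaries
    transition <- (starts <= b$L2 & ends >= b$L1) | (starts <= b$L4 & ends >= b$L3)
    label <- rep(NA_character_, length(starts))
    label[ends < b$L1 | starts > b$L4] <- "R"
    label[starts > b$L2 & ends < b$L3] <- trial$motion
    label[transition] <- NA_character_
  }

  ft <- data.frame(end_index = ends, label = label, transition = transition,
                   stringsAsFactors = FALSE)
  ft <- cbind(ft, as.data.frame(feats))
  class(ft) <- c("feature_table", "data.frame")
  attr(ft, "motion") <- trial$motion
  attr(ft, "subject_id") <- trial$subject_id
  attr(ft, "trial_index") <- trial$trial_index
  ft
}
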