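# Synthetic trials emulate the measurement protocol: a relaxed lead-in, a
# smooth (half-cosine) transition to a motion-specific quasi-static plateau,
# a hold of several seconds, a transition back, and a relaxed tail. The
# capacitance channels carry motion-specific pF-scale offsets plus Gaussian
# noise and a high-frequency sinusoid (so the 5 Hz low-pass filter has work
# to do); the Euler angles carry motion-specific excursions whose slope
# peaks at the two transitions.

#' Motion profile for the synthetic generator
#'
#' Describes how one motion pattern manifests in the signals: per-channel
#' capacitance offsets from the relaxed baseline, per-axis Euler-angle
#' excursions, segment durations, and noise levels.
#'
#' @param cap_offset Numeric length-6, capacitance plateau offset per
#'   channel (pF, deviation from the relaxed baseline).
#' @param euler_delta Numeric length-3, Euler-angle excursion per axis
#'   (degrees; large for wrist motions, small for palm/fist).
#' @param transition_ms Transition (ramp) duration in ms.
#' @param hold_ms Plateau hold duration in ms.
#' @param lead_ms,tail_ms Relaxed lead-in/out durations in ms.
#' @param cap_noise_sd Gaussian noise sd on capacitance (pF).
#' @param imu_noise_sd Gaussian noise sd on Euler angles (degrees).
#' @param hf_amp,hf_freq Amplitude (pF) and frequency (Hz) of the additive
#'   high-frequency sinusoid on capacitance; frequency must lie above the
#'   5 Hz filter cutoff and below the 50 Hz Nyquist limit.
#' @param cap_baseline Relaxed capacitance baseline (pF) common to channels.
#' @param euler_base Numeric length-3 relaxed Euler angles (degrees).
#' @return An object of class `motion_profile`.
#' @export
motion_profile <- function(cap_offset, euler_delta,
                           transition_ms = 600, hold_ms = 10000,
                           lead_ms = 3000, tail_ms = 3000,
                           cap_noise_sd = 0.05, imu_noise_sd = 0.05,
                           hf_amp = 0.2, hf_freq = 20,
                           cap_baseline = 30,
                           euler_base = c(5, -10, 20)) {
  stopifnot(length(cap_offset) == 6L, length(euler_delta) == 3L,
            length(euler_base) == 3L)
  if (transition_ms <= 0) stop("transition duration must be > 0", call. = FALSE)
  if (cap_noise_sd < 0 || imu_noise_sd < 0) stop("noise sds must be >= 0", call. = FALSE)
  if (hf_amp > 0 && !(hf_freq > 5 && hf_freq < 50)) {
    stop("high-frequency noise must lie in (5, 50) Hz", call. = FALSE)
  }
  structure(list(
    cap_offset = as.numeric(cap_offset), euler_delta = as.numeric(euler_delta),
    transition_ms = transition_ms, hold_ms = hold_ms,
    lead_ms = lead_ms, tail_ms = tail_ms,
    cap_noise_sd = cap_noise_sd, imu_noise_sd = imu_noise_sd,
    hf_amp = hf_amp, hf_freq = hf_freq,
    cap_baseline = cap_baseline, euler_base = as.numeric(euler_base)
  ), class = "motion_profile")
}

#' Default motion profiles
#'
#' One profile per motion pattern. Capacitance offsets are on the pF scale
#' observed for muscle-deformation sensing (magnitudes roughly 1-5 pF), with
#' a distinct offset pattern per motion. Wrist motions produce 30-60 degree
#' Euler excursions on their dominant axis; palm and fist are "gesture"
#' profiles with small (3-8 degree) excursions and slightly noisier Euler
#' output, which makes their transition slopes much less prominent.
#'
#' @return Named list of [motion_profile()] objects, one per motion label.
#' @export
default_profiles <- function() {
  wrist <- function(off, d) motion_profile(off, d)
  gesture <- function(off, d) motion_profile(off, d, imu_noise_sd = 0.08)
  list(
    R  = motion_profile(rep(0, 6), rep(0, 3)),
    WF = wrist(c( 3.5,  1.0, -2.0,  4.0,  0.5,  1.5), c(-45,   5,   3)),
    WE = wrist(c(-2.5,  4.0,  1.5, -1.0,  3.0, -2.0), c( 45,  -5,   3)),
    WP = wrist(c( 1.5, -3.0,  4.5,  2.0, -1.5,  3.5), c(  5,  55,  -5)),
    WS = wrist(c(-4.0,  2.5, -1.0,  3.0,  2.0, -3.0), c( -5, -50,   5)),
    RD = wrist(c( 2.0,  1.5,  3.0, -4.5,  1.0,  2.5), c(  5,   8,  35)),
    UD = wrist(c(-1.5, -2.0,  2.5,  1.0, -4.0,  3.0), c( -3,  -5, -40)),
    P  = gesture(c( 1.0,  3.0, -1.5, -2.5,  4.5,  1.0), c(  4,   6,   3)),
    F  = gesture(c( 4.5, -1.0,  2.0,  1.5, -3.0, -1.0), c( -4,   6,  -3))
  )
}

#' Session specification for the synthetic generator
#'
#' @param subject_id Subject identifier for the generated trials.
#' @param motions Motion patterns to measure (default: the eight non-relax
#'   patterns; relax data comes from each trial's lead-in and tail).
#' @param trials_per_motion Number of trials per motion (default 5).
#' @param seed Session seed; all per-trial randomness derives from it.
#' @param jitter Fractional trial-to-trial jitter applied to capacitance
#'   offsets, Euler excursions and segment durations (default 0.05).
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(subject_id = "SYN1",
                         motions = setdiff(motion_labels(), "R"),
                         trials_per_motion = 5, seed = 1, jitter = 0.05) {
  stopifnot(all(motions %in% motion_labels()), trials_per_motion >= 1,
            jitter >= 0)
  structure(list(subject_id = subject_id, motions = motions,
                 trials_per_motion = as.integer(trials_per_motion),
                 seed = as.integer(seed), jitter = jitter),
            class = "session_spec")
}

# run code under a temporary RNG state so generation never disturbs the
# caller's random stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic per-trial seed derived from a session seed and trial counter
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + counter * 16807) %% (2^31 - 1))
}

half_cosine_envelope <- function(n_lead, n_trans, n_hold, n_tail) {
  up <- (1 - cos(pi * seq_len(n_trans) / n_trans)) / 2
  c(rep(0, n_lead), up, rep(1, n_hold), rev(up), rep(0, n_tail))
}

#' Generate one synthetic trial
#'
#' Builds a trial with the canonical structure (relax, transition, hold,
#' transition, relax) and records the ground-truth boundary set: L1/L3 are
#' the last samples before each ramp starts, L2/L4 the samples where the
#' ramp completes, so `L2 - L1` equals the transition duration in samples.
#' Identical `(motion, profile, seed)` give bitwise-identical trials.
#'
#' @param motion Motion label; `"R"` yields a boundary-free relax trial.
#' @param profile A [motion_profile()].
#' @param seed Nonnegative integer seed.
#' @param subject_id,trial_index Metadata for the resulting record.
#' @return A [trial_record()] with ground-truth boundaries (non-R motions).
#' @export
generate_trial <- function(motion, profile, seed, subject_id = "SYN1",
                           trial_index = 1L) {
  stopifnot(motion %in% motion_labels(), seed >= 0)
  p <- profile
  if (motion != "R" && all(p$cap_offset == 0) && all(p$euler_delta == 0)) {
    stop(sprintf("degenerate profile for motion %s: no capacitance offset or Euler excursion",
                 motion), call. = FALSE)
  }
  n_lead <- round(p$lead_ms / 10)
  n_trans <- round(p$transition_ms / 10)
  n_hold <- round(p$hold_ms / 10)
  n_tail <- round(p$tail_ms / 10)
  if (motion == "R") {
    env <- rep(0, n_lead + n_trans + n_hold + n_trans + n_tail)
  } else {
    env <- half_cosine_envelope(n_lead, n_trans, n_hold, n_tail)
  }
  n <- length(env)
  tt <- (seq_len(n) - 1) / 100
  with_local_seed(seed, {
    cap <- sapply(1:6, function(j) {
      p$cap_baseline + p$cap_offset[j] * env +
        stats::rnorm(n, 0, p$cap_noise_sd) +
        p$hf_amp * sin(2 * pi * p$hf_freq * tt)
    })
    imu <- sapply(1:3, function(a) {
      # fused Euler-angle output is band-limited, not white: draw white noise
      # and low-pass it to the signal band, rescaled to the requested sd
      noise <- if (p$imu_noise_sd > 0) {
        raw <- lowpass_filter(stats::rnorm(n), filter_spec())
        raw * (p$imu_noise_sd / stats::sd(raw))
      } else rep(0, n)
      p$euler_base[a] + p$euler_delta[a] * env + noise
    })
    imu <- pmin(pmax(imu, -180), 180)
    boundaries <- if (motion == "R") NULL else {
      boundary_set(L1 = n_lead, L2 = n_lead + n_trans,
                   L3 = n_lead + n_trans + n_hold,
                   L4 = n_lead + 2 * n_trans + n_hold, n_samples = n)
    }
    trial_record(subject_id, motion, trial_index, cap, imu,
                 boundaries = boundaries)
  })
}

jitter_profile <- function(p, jitter, u) {
  # u: 8 uniform(-1,1) draws; per-channel offset jitter, one scalar for the
  # Euler excursions and one per duration
  p$cap_offset <- p$cap_offset * (1 + jitter * u[1:6])
  p$euler_delta <- p$euler_delta * (1 + jitter * u[7])
  p$transition_ms <- p$transition_ms * (1 + jitter * u[8])
  p
}

#' Generate a full synthetic session
#'
#' Produces `trials_per_motion` trials per motion, each with its own
#' deterministic seed derived from the session seed, and trial-to-trial
#' jitter on capacitance offsets, Euler excursions and transition duration.
#'
#' @param spec A [session_spec()].
#' @param profiles Named list of [motion_profile()] objects covering
#'   `spec$motions` (default [default_profiles()]).
#' @return List of [trial_record()] objects with ground-truth boundaries.
#' @export
generate_session <- function(spec, profiles = default_profiles()) {
  missing <- setdiff(spec$motions, names(profiles))
  if (length(missing)) {
    stop(sprintf("no profile for motion(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  counter <- 0L
  trials <- list()
  for (m in spec$motions) {
    for (k in seq_len(spec$trials_per_motion)) {
      counter <- counter + 1L
      tseed <- derive_seed(spec$seed, counter)
      p <- with_local_seed(derive_seed(spec$seed, 100000L + counter), {
        jitter_profile(profiles[[m]], spec$jitter, stats::runif(8, -1, 1))
      })
      trials[[counter]] <- generate_trial(m, p, tseed,
                                          subject_id = spec$subject_id,
                                          trial_index = k)
    }
  }
  trials
}
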