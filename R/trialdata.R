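#' Motion pattern labels
#'
#' The nine forearm motion patterns, in the fixed label ordering used
#' throughout the package (also the classifier tie-break order): relax (R),
#' wrist flexion/extension (WF/WE), wrist pronation/supination (WP/WS),
#' radial/ulnar deviation (RD/UD), palm (P), and fist (F).
#'
#' @return Character vector of the nine motion labels.
#' @export
motion_labels <- function() {
  c("R", "WF", "WE", "WP", "WS", "RD", "UD", "P", "F")
}

#' Transition boundary set
#'
#' The four sample indices delimiting the two motion transitions of a trial:
#' L1/L2 are the initiation and termination of the relax-to-motion
#' transition, L3/L4 those of the motion-to-relax transition. Indices are
#' 1-based sample positions; the corresponding time in ms is
#' `(index - 1) * 10` at the 100 Hz sampling rate.
#'
#' @param L1,L2,L3,L4 Sample indices with `1 < L1 < L2 < L3 < L4`.
#' @param n_samples Optional trial length used to check `L4 < n_samples`.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(L1, L2, L3, L4, n_samples = NULL) {
  b <- c(L1 = as.numeric(L1), L2 = as.numeric(L2),
         L3 = as.numeric(L3), L4 = as.numeric(L4))
  if (anyNA(b) || any(b != round(b))) {
    stop("boundaries must be integer sample indices", call. = FALSE)
  }
  if (!(b[1] > 1 && all(diff(b) > 0))) {
    stop("boundaries must satisfy 1 < L1 < L2 < L3 < L4", call. = FALSE)
  }
  if (!is.null(n_samples) && b[4] >= n_samples) {
    stop("L4 must be smaller than the trial length", call. = FALSE)
  }
  structure(as.list(b), class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("boundary_set: L1=%d L2=%d L3=%d L4=%d (samples; %g-%g ms)\n",
              x$L1, x$L2, x$L3, x$L4, (x$L1 - 1) * 10, (x$L4 - 1) * 10))
  invisible(x)
}

#' Single experimental trial
#'
#' One trial of the measurement protocol: six capacitance channels (pF) and
#' three Euler angles (pitch, roll, yaw; degrees) sampled synchronously at
#' 100 Hz, plus subject/motion metadata and, once labeled, the four
#' transition boundaries. A trial starts and ends in the relaxed state with
#' the target motion held for several seconds in between, so valid trials
#' are at least 15 s (1500 samples) long.
#'
#' @param subject_id Subject identifier string.
#' @param motion One of [motion_labels()].
#' @param trial_index Positive integer trial number.
#' @param cap Numeric matrix, samples x 6, capacitance in pF.
#' @param imu Numeric matrix, samples x 3, Euler angles in degrees
#'   (each within \[-180, 180\]).
#' @param boundaries Optional [boundary_set()].
#' @param sample_rate Sampling rate in Hz (fixed at 100 by the protocol).
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(subject_id, motion, trial_index, cap, imu,
                         boundaries = NULL, sample_rate = 100) {
  cap <- as.matrix(cap)
  imu <- as.matrix(imu)
  x <- structure(list(
    subject_id = as.character(subject_id),
    motion = as.character(motion),
    trial_index = as.integer(trial_index),
    sample_rate = sample_rate,
    cap = cap,
    imu = imu,
    boundaries = boundaries
  ), class = "trial_record")
  validate_trial(x)
  x
}

#' Validate a trial record
#'
#' Checks all trial invariants: matching capacitance/IMU sample counts,
#' channel counts (6 capacitance, 3 Euler), minimum length of 1500 samples,
#' Euler angles within \[-180, 180\], a known motion label, and boundary
#' ordering when boundaries are present.
#'
#' @param trial A [trial_record()].
#' @return The trial, invisibly; stops with a validation error otherwise.
#' @export
validate_trial <- function(trial) {
  if (!inherits(trial, "trial_record")) stop("not a trial_record", call. = FALSE)
  if (!trial$motion %in% motion_labels()) {
    stop(sprintf("unknown motion label '%s'", trial$motion), call. = FALSE)
  }
  if (is.na(trial$trial_index) || trial$trial_index < 1L) {
    stop("trial_index must be a positive integer", call. = FALSE)
  }
  if (nrow(trial$cap) != nrow(trial$imu)) {
    stop("cap and imu must have identical sample counts", call. = FALSE)
  }
  if (ncol(trial$cap) != 6L) stop("cap must have 6 channels", call. = FALSE)
  if (ncol(trial$imu) != 3L) stop("imu must have 3 axes", call. = FALSE)
  if (nrow(trial$cap) < 1500L) {
    stop("trial must have at least 1500 samples (15 s at 100 Hz)", call. = FALSE)
  }
  if (anyNA(trial$cap) || anyNA(trial$imu)) {
    stop("trial signals must not contain NA", call. = FALSE)
  }
  if (any(abs(trial$imu) > 180)) {
    stop("Euler angles must lie within [-180, 180] degrees", call. = FALSE)
  }
  if (!is.null(trial$boundaries)) {
    b <- trial$boundaries
    if (!inherits(b, "boundary_set")) stop("boundaries must be a boundary_set", call. = FALSE)
    if (b$L4 >= nrow(trial$cap)) stop("L4 must be smaller than the trial length", call. = FALSE)
  }
  invisible(trial)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("trial_record: subject %s, motion %s, trial %d, %d samples (%.1f s)\n",
              x$subject_id, x$motion, x$trial_index, nrow(x$cap),
              nrow(x$cap) / x$sample_rate))
  if (!is.null(x$boundaries)) print(x$boundaries) else cat("  boundaries: none\n")
  invisible(x)
}

#' Number of samples in a trial
#' @param trial A [trial_record()].
#' @return Integer sample count.
#' @export
n_samples <- function(trial) nrow(trial$cap)

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta")

#' Write a trial to disk
#'
#' Writes the signals as a comma-separated text file with the header
#' `t_ms,cap1..cap6,pitch,roll,yaw` (one row per sample, `t_ms = (i-1)*10`)
#' and a plain key-value metadata sidecar (`<path stem>.meta`) holding the
#' subject, motion, trial index, sample rate and, when known, the boundary
#' indices. Values round-trip through [read_trial()] to 1e-6.
#'
#' @param trial A valid [trial_record()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  n <- n_samples(trial)
  dat <- cbind((seq_len(n) - 1) * 10, trial$cap, trial$imu)
  colnames(dat) <- c("t_ms", paste0("cap", 1:6), "pitch", "roll", "yaw")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory '%s' does not exist", dir), call. = FALSE)
  # fixed 6-decimal formatting so round-trips are exact to stated precision
  lines <- c(paste(colnames(dat), collapse = ","),
             apply(dat, 1L, function(r) paste(sprintf("%.6f", r), collapse = ",")))
  writeLines(lines, path)
  meta <- c(
    paste0("subject_id: ", trial$subject_id),
    paste0("motion: ", trial$motion),
    paste0("trial_index: ", trial$trial_index),
    paste0("sample_rate: ", trial$sample_rate)
  )
  if (!is.null(trial$boundaries)) {
    b <- trial$boundaries
    meta <- c(meta, sprintf("boundaries: %d %d %d %d", b$L1, b$L2, b$L3, b$L4))
  }
  writeLines(meta, sidecar_path(path))
  invisible(path)
}

parse_sidecar <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  stats::setNames(as.list(vals), keys)
}

#' Read a trial from disk
#'
#' Reads a trial written by [write_trial()] and validates all invariants.
#'
#' @param path Path to the per-trial CSV; its `.meta` sidecar must exist.
#' @return A [trial_record()].
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  mp <- sidecar_path(path)
  if (!file.exists(mp)) stop(sprintf("missing metadata sidecar: %s", mp), call. = FALSE)
  dat <- utils::read.csv(path, check.names = FALSE)
  expected <- c("t_ms", paste0("cap", 1:6), "pitch", "roll", "yaw")
  if (!identical(colnames(dat), expected)) {
    stop(sprintf("malformed header in %s: expected %s", path,
                 paste(expected, collapse = ",")), call. = FALSE)
  }
  for (j in seq_along(dat)) {
    if (!is.numeric(dat[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dat[[j]]))))[1]
      stop(sprintf("non-numeric cell at row %d, column '%s' of %s",
                   bad, colnames(dat)[j], path), call. = FALSE)
    }
  }
  meta <- parse_sidecar(mp)
  boundaries <- NULL
  if (!is.null(meta$boundaries)) {
    b <- as.numeric(strsplit(meta$boundaries, " ")[[1]])
    boundaries <- boundary_set(b[1], b[2], b[3], b[4], n_samples = nrow(dat))
  }
  trial_record(
    subject_id = meta$subject_id,
    motion = meta$motion,
    trial_index = as.integer(meta$trial_index),
    cap = as.matrix(dat[, paste0("cap", 1:6)]),
    imu = as.matrix(dat[, c("pitch", "roll", "yaw")]),
    boundaries = boundaries,
    sample_rate = as.numeric(meta$sample_rate)
  )
}

#' Write a session manifest
#'
#' A manifest lists the per-trial files of a session together with subject,
#' motion and trial metadata, so downstream stages can load a session
#' without scanning directories.
#'
#' @param trials List of [trial_record()] objects.
#' @param dir Directory receiving the trial files and `manifest.csv`.
#' @return Path to the manifest, invisibly.
#' @export
write_session <- function(trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(trials, function(tr) {
    fn <- sprintf("%s_%s_%02d.csv", tr$subject_id, tr$motion, tr$trial_index)
    write_trial(tr, file.path(dir, fn))
    data.frame(file = fn, subject_id = tr$subject_id, motion = tr$motion,
               trial_index = tr$trial_index, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Read a session manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_session()].
#' @return List of [trial_record()] objects in manifest order.
#' @export
read_session <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  lapply(manifest$file, function(f) read_trial(file.path(dir, f)))
}
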