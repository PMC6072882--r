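# Evaluation metrics: recognition accuracy over non-transition decisions,
# per-class confusion matrices, the mean-diagonal accuracy, transition
# prediction times, and the trial-wise cross-validation schemes.

#' Recognition accuracy
#'
#' Percentage of correct recognition decisions, `RA = Ncorrect/Ntotal x 100`.
#' Decisions within the transition periods are excluded from both counts.
#'
#' @param predicted,actual Label vectors of equal length.
#' @param excluded Logical mask of decisions to leave out (transition
#'   windows); `NULL` for none. Decisions with `NA` actual labels are always
#'   excluded.
#' @return Accuracy in percent.
#' @export
recognition_accuracy <- function(predicted, actual, excluded = NULL) {
  stopifnot(length(predicted) == length(actual))
  keep <- !is.na(actual)
  if (!is.null(excluded)) keep <- keep & !excluded
  if (!any(keep)) stop("no decisions left after exclusion; RA undefined", call. = FALSE)
  100 * sum(predicted[keep] == actual[keep]) / sum(keep)
}

#' Confusion matrix
#'
#' Counts `n_ij` of class-i test decisions recognized as class j, and the
#' row-normalized percentages `c_ij = 100 n_ij / n_i.`; each defined row
#' sums to 100. A class with no test decisions yields an undefined
#' (all-`NA`) percentage row, flagged in `undefined`.
#'
#' @param predicted,actual Label vectors (transition decisions already
#'   excluded by the caller).
#' @param labels Class labels ordering the matrix; must cover all values
#'   present.
#' @return Object of class `confusion_matrix` with `counts`, `percent`,
#'   `labels`, `undefined`.
#' @export
confusion <- function(predicted, actual, labels) {
  seen <- unique(c(predicted, actual))
  seen <- seen[!is.na(seen)]
  if (!all(seen %in% labels)) {
    stop(sprintf("labels not covered by the class set: %s",
                 paste(setdiff(seen, labels), collapse = ", ")), call. = FALSE)
  }
  keep <- !is.na(actual)
  counts <- table(factor(actual[keep], levels = labels),
                  factor(predicted[keep], levels = labels))
  counts <- unclass(as.matrix(counts))
  row_tot <- rowSums(counts)
  percent <- 100 * counts / ifelse(row_tot > 0, row_tot, NA)
  structure(list(counts = counts, percent = percent, labels = labels,
                 undefined = row_tot == 0), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (% of row class):\n")
  print(round(x$percent, 2))
  if (any(x$undefined)) {
    cat("undefined rows (no test data):",
        paste(x$labels[x$undefined], collapse = " "), "\n")
  }
  invisible(x)
}

#' Mean of the confusion-matrix diagonal
#'
#' The per-class-balanced accuracy `RA_c = (1/M) sum_i c_ii`, which weights
#' every motion pattern equally regardless of its test data size.
#'
#' @param C A [confusion()] matrix.
#' @return RA_c in percent.
#' @export
average_diagonal <- function(C) {
  if (any(C$undefined)) {
    stop("confusion matrix has undefined rows; RA_c undefined", call. = FALSE)
  }
  mean(diag(C$percent))
}

#' Transition prediction times
#'
#' For each of a trial's two transitions, the recognized transition time
#' `T_r` is the time of the first decision that begins a run of at least
#' `min_run` consecutive decisions for the upcoming class (the trial motion
#' for the relax-to-motion transition, relax for the return). The prediction
#' times are `PT1 = T_r - T_i` (initiation, L1/L3) and `PT2 = T_r - T_t`
#' (termination, L2/L4); negative values are advanced decisions. The search
#' for the second transition starts after the first transition's
#' termination, so the lead-in relax run is never mistaken for the return
#' recognition; runs beginning before a transition's initiation do count.
#'
#' @param times_ms Decision times in ms (window end times), increasing.
#' @param decisions Predicted label per decision.
#' @param boundaries The trial's [boundary_set()].
#' @param motion The trial's motion label.
#' @param min_run Minimum run length (default 10 decisions, i.e. 100 ms).
#' @return Data frame with one row per transition: `type` (1 = relax to
#'   motion, 2 = motion to relax), `T_i`, `T_t`, `T_r`, `PT1`, `PT2` in ms.
#' @export
prediction_times <- function(times_ms, decisions, boundaries, motion,
                             min_run = 10) {
  stopifnot(length(times_ms) == length(decisions))
  b <- boundaries
  to_ms <- function(idx) (idx - 1) * 10
  find_tr <- function(upcoming, from_ms) {
    i0 <- which(times_ms >= from_ms)[1]
    if (is.na(i0)) stop("decision stream ends before the transition", call. = FALSE)
    r <- rle(decisions[i0:length(decisions)])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values == upcoming & r$lengths >= min_run)[1]
    if (is.na(hit)) {
      stop(sprintf("transition to %s never recognized (%d consecutive decisions required)",
                   upcoming, min_run), call. = FALSE)
    }
    times_ms[i0 - 1L + starts[hit]]
  }
  t1 <- list(T_i = to_ms(b$L1), T_t = to_ms(b$L2))
  t2 <- list(T_i = to_ms(b$L3), T_t = to_ms(b$L4))
  tr1 <- find_tr(motion, from_ms = times_ms[1])
  tr2 <- find_tr("R", from_ms = t1$T_t)
  data.frame(
    type = c(1L, 2L),
    T_i = c(t1$T_i, t2$T_i), T_t = c(t1$T_t, t2$T_t), T_r = c(tr1, tr2),
    PT1 = c(tr1 - t1$T_i, tr2 - t2$T_i),
    PT2 = c(tr1 - t1$T_t, tr2 - t2$T_t)
  )
}

#' Cross-validation fold assignments over trial indices
#'
#' Folds are whole trials. `loocv5` leaves one trial index out per fold;
#' `cv32` trains on every 3-subset of the five trials (10 combinations),
#' `cv23` on every 2-subset; `accumulated` trains on trials 1..k and tests
#' trial k+1 for k from `first_train` upward.
#'
#' @param scheme One of `"loocv5"`, `"cv32"`, `"cv23"`, `"accumulated"`.
#' @param trial_indices Sorted unique trial indices available.
#' @param first_train For `accumulated`: size of the initial training block
#'   (default 5).
#' @return List of folds, each `list(train = ..., test = ...)` of trial
#'   indices.
#' @export
cv_folds <- function(scheme, trial_indices, first_train = 5) {
  ti <- sort(unique(trial_indices))
  switch(scheme,
    loocv5 = lapply(ti, function(t) list(train = setdiff(ti, t), test = t)),
    cv32 = apply(utils::combn(ti, 3L), 2L, function(tr)
      list(train = tr, test = setdiff(ti, tr)), simplify = FALSE),
    cv23 = apply(utils::combn(ti, 2L), 2L, function(tr)
      list(train = tr, test = setdiff(ti, tr)), simplify = FALSE),
    accumulated = {
      ks <- seq.int(first_train, max(ti) - 1L)
      lapply(ks, function(k) list(train = ti[ti <= k], test = k + 1L))
    },
    stop(sprintf("unknown CV scheme '%s'", scheme), call. = FALSE)
  )
}

#' Session-wise fold assignments for re-wear evaluation
#'
#' For two recording sessions: `cv11` trains on one whole session and tests
#' on the other (two folds, averaged); `cv64` trains on one session plus one
#' trial of the other and tests on that session's remaining trials (ten
#' combinations).
#'
#' @param scheme `"cv11"` or `"cv64"`.
#' @param sessions Integer session id (1 or 2) per trial position.
#' @param trial_indices Trial index per trial position.
#' @return List of folds of *positions* into the trial list.
#' @export
session_folds <- function(scheme, sessions, trial_indices) {
  stopifnot(length(sessions) == length(trial_indices))
  pos <- seq_along(sessions)
  s1 <- pos[sessions == 1]; s2 <- pos[sessions == 2]
  if (scheme == "cv11") {
    list(list(train = s1, test = s2), list(train = s2, test = s1))
  } else if (scheme == "cv64") {
    folds <- list()
    for (tr_sess in list(list(train = s1, other = s2),
                         list(train = s2, other = s1))) {
      for (k in sort(unique(trial_indices[tr_sess$other]))) {
        extra <- tr_sess$other[trial_indices[tr_sess$other] == k]
        folds[[length(folds) + 1L]] <- list(
          train = c(tr_sess$train, extra),
          test = setdiff(tr_sess$other, extra))
      }
    }
    folds
  } else stop(sprintf("unknown session scheme '%s'", scheme), call. = FALSE)
}

# fit on the pooled non-transition windows of the training trials
fit_fold <- function(tables, train_pos, classes, ridge) {
  rows <- lapply(tables[train_pos], function(ft) {
    keep <- !ft$transition & !is.na(ft$label) & ft$label %in% classes
    list(x = feature_matrix(ft)[keep, , drop = FALSE], y = ft$label[keep])
  })
  x <- do.call(rbind, lapply(rows, `[[`, "x"))
  y <- unlist(lapply(rows, `[[`, "y"))
  missing <- setdiff(classes, unique(y))
  if (length(missing)) {
    stop(sprintf("degenerate fold: class(es) %s absent from training data",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  fit_qda(x, y, ridge = ridge)
}

#' Run a cross-validated evaluation
#'
#' Featurizes every trial, then for each fold fits the quadratic
#' discriminant model on the pooled non-transition windows of the training
#' trials and predicts every window of the test trials. Reports pooled
#' recognition accuracy (transition windows excluded), the confusion matrix
#' with its mean diagonal, per-combination accuracies, and the prediction
#' times of every test-trial transition. For multi-combination schemes
#' (`cv32`, `cv23`, `cv64`) the reported RA is the mean over combinations;
#' for `accumulated` the per-step accuracies are the result of interest.
#'
#' @param trials List of labeled [trial_record()] objects (boundaries set,
#'   e.g. by [autolabel_trial()] or the synthetic generator).
#' @param scheme CV scheme name (see [cv_folds()] and [session_folds()]).
#' @param wspec A [window_spec()].
#' @param motions Motion subset to evaluate (default: relax plus every
#'   motion present). Removing `"R"` also removes relax windows from
#'   training and testing and disables prediction-time metrics.
#' @param sessions Session id per trial, required for `cv11`/`cv64`.
#' @param fspec A [filter_spec()] applied during featurization.
#' @param ridge Ridge passed to [fit_qda()].
#' @param min_run Run length for [prediction_times()].
#' @return An object of class `eval_report`.
#' @export
run_cv <- function(trials, scheme = "loocv5", wspec = window_spec(),
                   motions = NULL, sessions = NULL, fspec = filter_spec(),
                   ridge = 1e-8, min_run = 10) {
  trial_motions <- vapply(trials, `[[`, "", "motion")
  if (is.null(motions)) {
    motions <- intersect(motion_labels(), c("R", unique(trial_motions)))
  }
  use <- trial_motions %in% setdiff(motions, "R")
  trials <- trials[use]
  trial_motions <- trial_motions[use]
  if (!is.null(sessions)) sessions <- sessions[use]
  if (!length(trials)) stop("no trials left for the motion subset", call. = FALSE)
  classes <- intersect(motion_labels(), motions)
  with_R <- "R" %in% classes

  tables <- lapply(trials, featurize_trial, wspec = wspec, fspec = fspec)
  tindex <- vapply(trials, `[[`, 1L, "trial_index")

  if (scheme %in% c("cv11", "cv64")) {
    if (is.null(sessions)) stop("scheme requires per-trial session ids", call. = FALSE)
    folds <- session_folds(scheme, sessions, tindex)
    fold_pos <- folds
  } else {
    folds <- cv_folds(scheme, tindex)
    fold_pos <- lapply(folds, function(f) {
      list(train = which(tindex %in% f$train), test = which(tindex %in% f$test))
    })
  }

  all_pred <- character(0); all_act <- character(0)
  fold_ra <- numeric(0)
  pt_rows <- list()
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(classes, classes))
  for (f in fold_pos) {
    model <- fit_fold(tables, f$train, classes, ridge)
    pred_f <- character(0); act_f <- character(0)
    for (pos in f$test) {
      ft <- tables[[pos]]
      pred <- predict(model, feature_matrix(ft))
      keep <- !ft$transition & !is.na(ft$label) & ft$label %in% classes
      pred_f <- c(pred_f, pred[keep]); act_f <- c(act_f, ft$label[keep])
      if (with_R && !is.null(trials[[pos]]$boundaries)) {
        pt <- tryCatch(
          prediction_times((ft$end_index - 1) * 10, pred,
                           trials[[pos]]$boundaries, trials[[pos]]$motion,
                           min_run = min_run),
          error = function(e) NULL)
        if (!is.null(pt)) {
          pt$subject <- trials[[pos]]$subject_id
          pt$motion <- trials[[pos]]$motion
          pt$trial_index <- trials[[pos]]$trial_index
          pt_rows[[length(pt_rows) + 1L]] <- pt
        }
      }
    }
    fold_ra <- c(fold_ra, recognition_accuracy(pred_f, act_f))
    cm <- confusion(pred_f, act_f, classes)
    counts <- counts + cm$counts
    all_pred <- c(all_pred, pred_f); all_act <- c(all_act, act_f)
  }

  pooled_cm <- confusion(all_pred, all_act, classes)
  averaged <- scheme %in% c("cv32", "cv23", "cv64")
  ra <- if (averaged) mean(fold_ra) else recognition_accuracy(all_pred, all_act)
  ra_c <- if (any(pooled_cm$undefined)) NA_real_ else average_diagonal(pooled_cm)
  pt <- if (length(pt_rows)) do.call(rbind, pt_rows) else NULL
  structure(list(scheme = scheme, motions = classes,
                 win_len_ms = wspec$win_len_ms,
                 ra = ra, ra_c = ra_c, confusion = pooled_cm,
                 fold_ra = fold_ra, n_folds = length(fold_pos),
                 prediction_times = pt),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: scheme %s, window %d ms, %d folds\n",
              x$scheme, x$win_len_ms, x$n_folds))
  cat(sprintf("  RA  = %.2f%%   RA_c = %.2f%%\n", x$ra, x$ra_c))
  print(x$confusion)
  if (!is.null(x$prediction_times)) {
    pt <- x$prediction_times
    cat(sprintf("  prediction times over %d transitions: mean PT1 = %.1f ms, mean PT2 = %.1f ms\n",
                nrow(pt), mean(pt$PT1), mean(pt$PT2)))
  }
  invisible(x)
}
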