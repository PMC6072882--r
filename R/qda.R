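# Quadratic discriminant analysis from its generative definition: each
# motion class is modeled as a multivariate Gaussian with its own mean
# vector and covariance matrix; a window is assigned to the class with the
# largest Gaussian log-density plus log-prior. Implemented directly (not via
# an external classifier) because the per-class second-order statistics are
# the model.

#' Fit a quadratic discriminant model
#'
#' Estimates, for every class, the sample mean vector and the sample
#' covariance matrix (divide-by-n form), plus a prior equal to the class's
#' training proportion. A small ridge proportional to each class's average
#' variance is added to the covariance diagonal to guard against
#' near-singular classes (plateau windows can make some features nearly
#' constant).
#'
#' @param x Numeric feature matrix (rows = training windows). Transition-
#'   flagged rows must be excluded by the caller before fitting.
#' @param labels Class label per row.
#' @param ridge Ridge coefficient: each class covariance receives
#'   `ridge * tr(Sigma_k)/d` on its diagonal. Default `1e-8`; set to 0 for
#'   exact covariances (requires all classes non-singular).
#' @return An object of class `qda_model` with `classes`, `means` (d x M),
#'   `covs` (list of d x d matrices), `priors`, `ridge`.
#' @export
fit_qda <- function(x, labels, ridge = 1e-8) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), ridge >= 0)
  # fixed label ordering where applicable, otherwise first appearance
  known <- motion_labels()
  present <- unique(labels)
  classes <- c(intersect(known, present), setdiff(present, known))
  d <- ncol(x)
  means <- matrix(0, d, length(classes), dimnames = list(colnames(x), classes))
  covs <- vector("list", length(classes))
  names(covs) <- classes
  chols <- vector("list", length(classes))
  for (k in seq_along(classes)) {
    rows <- x[labels == classes[k], , drop = FALSE]
    if (nrow(rows) < 2L) {
      stop(sprintf("class %s has fewer than 2 training rows", classes[k]),
           call. = FALSE)
    }
    mu <- colMeans(rows)
    xc <- sweep(rows, 2L, mu)
    sigma <- crossprod(xc) / nrow(rows)      # divide-by-n covariance
    if (ridge > 0) {
      scale <- sum(diag(sigma)) / d
      if (scale <= 0) scale <- 1   # zero-variance class: absolute ridge
      sigma <- sigma + diag(ridge * scale, d)
    }
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      stop(sprintf("covariance of class %s is singular; increase ridge",
                   classes[k]), call. = FALSE)
    }
    means[, k] <- mu
    covs[[k]] <- sigma
    chols[[k]] <- ch
  }
  priors <- as.numeric(table(factor(labels, levels = classes)) / length(labels))
  structure(list(classes = classes, means = means, covs = covs,
                 chols = chols, priors = priors, ridge = ridge, d = d),
            class = "qda_model")
}

#' @export
print.qda_model <- function(x, ...) {
  cat(sprintf("qda_model: %d classes, %d features, ridge %g\n",
              length(x$classes), x$d, x$ridge))
  cat("  classes:", paste(x$classes, collapse = " "), "\n")
  cat("  priors: ", paste(sprintf("%.3f", x$priors), collapse = " "), "\n")
  invisible(x)
}

#' Per-class discriminant scores
#'
#' The quadratic discriminant score of class k for feature vector x is
#' `-1/2 log det Sigma_k - 1/2 (x - mu_k)' Sigma_k^{-1} (x - mu_k) +
#' log prior_k` (the Gaussian log-density up to a shared constant).
#'
#' @param model A [fit_qda()] model.
#' @param x A feature vector of length `model$d`, or a matrix with that many
#'   columns.
#' @return Matrix of scores, rows = inputs, columns = classes.
#' @export
qda_scores <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != model$d) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(x), model$d), call. = FALSE)
  }
  scores <- matrix(0, nrow(x), length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (k in seq_along(model$classes)) {
    ch <- model$chols[[k]]
    logdet <- 2 * sum(log(diag(ch)))
    xc <- sweep(x, 2L, model$means[, k])
    # Mahalanobis via Cholesky: solve t(ch) y = xc' per row, maha = |y|^2
    y <- forwardsolve(t(ch), t(xc))
    maha <- colSums(y^2)
    scores[, k] <- -0.5 * logdet - 0.5 * maha + log(model$priors[k])
  }
  scores
}

#' Predict class labels
#'
#' Row-wise argmax of the discriminant scores. Exact ties are broken toward
#' the lowest class index in the model's fixed ordering.
#'
#' @param object A [fit_qda()] model.
#' @param newdata Feature matrix (or a `feature_table`).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.qda_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- feature_matrix(newdata)
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (nrow(newdata) == 0L) return(character(0))
  s <- qda_scores(object, newdata)
  object$classes[apply(s, 1L, which.max)]
}
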