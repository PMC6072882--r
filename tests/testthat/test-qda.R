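test_that("per-class moments match hand computation", {
  # two 2-D classes with hand-set data
  xa <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  xb <- rbind(c(10, 5), c(12, 7), c(11, 3))
  m <- fit_qda(rbind(xa, xb), c("A", "A", "A", "A", "B", "B", "B"), ridge = 0)
  expect_equal(unname(m$means[, "A"]), c(1, 1))
  expect_equal(unname(m$means[, "B"]), c(11, 5))
  # divide-by-n covariance of class A: var of {0,2} about mean 1 is 1
  expect_equal(unname(m$covs[["A"]]), matrix(c(1, 0, 0, 1), 2))
  # class B deviations (-1,0),(1,2),(0,-2): S = [[2/3,2/3],[2/3,8/3]]
  expect_equal(unname(m$covs[["B"]]), matrix(c(2, 2, 2, 8) / 3, 2))
  expect_equal(m$priors, c(4, 3) / 7)

  # one class of identical rows with a ridge
  xc <- rbind(c(3, 4, 5), c(3, 4, 5), c(3, 4, 5))
  m1 <- fit_qda(xc, rep("Z", 3), ridge = 1e-6)
  expect_equal(unname(m1$means[, 1]), c(3, 4, 5))
  expect_equal(unname(m1$covs[[1]]), diag(1e-6, 3))

  expect_error(fit_qda(xc[1, , drop = FALSE], "Z"), "fewer than 2")
  expect_error(fit_qda(rbind(c(1, 1), c(2, 2), c(5, 4), c(6, 5)),
                       c("A", "A", "B", "B"), ridge = 0), "singular")
})

test_that("discriminant scores implement the Gaussian rule", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 5), ncol = 2))
  y <- rep(c("A", "B"), each = 20)
  m <- fit_qda(x, y, ridge = 0)
  # direct evaluation of -1/2 log det - 1/2 maha + log prior
  pt <- c(1.3, -0.2)
  s <- qda_scores(m, pt)
  for (k in 1:2) {
    sigma <- m$covs[[k]]
    expected <- -0.5 * determinant(sigma)$modulus[1] -
      0.5 * mahalanobis(pt, m$means[, k], sigma) + log(m$priors[k])
    expect_equal(s[1, k], expected, ignore_attr = TRUE)
  }
  # x at a class mean with shared spherical covariances: that class wins
  expect_equal(predict(m, m$means[, "B"]), "B")
  expect_error(qda_scores(m, c(1, 2, 3)), "dimension")
})

test_that("prediction is deterministic, permutation-equivariant, tie-broken low", {
  set.seed(2)
  x <- rbind(matrix(rnorm(60, 0, 1), ncol = 3), matrix(rnorm(60, 8, 1), ncol = 3))
  y <- rep(c("WF", "R"), each = 20)
  m <- fit_qda(x, y)
  set.seed(3)
  xt <- matrix(rnorm(30, 4), ncol = 3)
  p1 <- predict(m, xt)
  perm <- sample(nrow(xt))
  expect_identical(predict(m, xt[perm, ]), p1[perm])
  expect_identical(predict(m, xt[0, , drop = FALSE]), character(0))

  # exact ties: two classes with identical moments and priors; the lower
  # index in the fixed label ordering (R before WF) wins
  x2 <- rbind(x[1:20, ], x[1:20, ])
  m2 <- fit_qda(x2, rep(c("WF", "R"), each = 20))
  expect_true(all(predict(m2, xt) == "R"))

  # well-separated classes: 100% training accuracy
  expect_identical(predict(m, x), y)
})

test_that("predictions agree with an independent reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(7)
  d <- 4; n_per <- 200
  mus <- list(c(0, 0, 0, 0), c(2.5, 0, 1, -1), c(-1, 2, -2, 0.5))
  make_cov <- function(seed) {
    set.seed(seed); a <- matrix(rnorm(d * d), d); crossprod(a) / d + diag(d) * 0.5
  }
  covs <- lapply(1:3, make_cov)
  set.seed(8)
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per * d), ncol = d) %*% chol(covs[[k]]) +
      matrix(mus[[k]], n_per, d, byrow = TRUE)
  }))
  y <- rep(c("a", "b", "c"), each = n_per)
  xt <- do.call(rbind, lapply(1:3, function(k) {
    m <- matrix(rnorm(334 * d), ncol = d) %*% chol(covs[[k]]) +
      matrix(mus[[k]], 334, d, byrow = TRUE)
  }))[1:1000, ]

  ours <- predict(fit_qda(x, y, ridge = 0), xt)
  ref <- as.character(predict(MASS::qda(x, grouping = factor(y)), xt)$class)
  expect_gte(mean(ours == ref), 0.99)
})

test_that("a common affine map leaves predictions unchanged", {
  set.seed(11)
  d <- 5
  x <- rbind(matrix(rnorm(150, 0), ncol = d),
             matrix(rnorm(150, 3), ncol = d),
             matrix(rnorm(150, -3), ncol = d))
  y <- rep(c("a", "b", "c"), each = 30)
  xt <- matrix(rnorm(100 * d, 1), ncol = d)
  A <- matrix(rnorm(d * d), d); while (abs(det(A)) < 0.1) A <- matrix(rnorm(d * d), d)
  b <- rnorm(d)
  f <- function(z) sweep(z %*% t(A), 2, b, `+`)
  p0 <- predict(fit_qda(x, y, ridge = 0), xt)
  p1 <- predict(fit_qda(f(x), y, ridge = 0), f(xt))
  expect_identical(p1, p0)
})

test_that("error rate approaches the Bayes rate on model-true data", {
  mu1 <- c(0, 0); mu2 <- c(2, 1)
  s1 <- diag(2); s2 <- diag(c(2, 0.5))
  gen <- function(n, mu, s) sweep(matrix(rnorm(2 * n), ncol = 2) %*% chol(s), 2, mu, `+`)
  set.seed(21)
  xtr <- rbind(gen(3000, mu1, s1), gen(3000, mu2, s2))
  ytr <- rep(c("a", "b"), each = 3000)
  xte <- rbind(gen(4000, mu1, s1), gen(4000, mu2, s2))
  yte <- rep(c("a", "b"), each = 4000)
  # Monte-Carlo Bayes oracle from the true densities
  dens <- function(x, mu, s) exp(-0.5 * mahalanobis(x, mu, s)) / sqrt(det(s))
  bayes <- ifelse(dens(xte, mu1, s1) >= dens(xte, mu2, s2), "a", "b")
  bayes_err <- mean(bayes != yte)
  qda_err <- mean(predict(fit_qda(xtr, ytr, ridge = 0), xte) != yte)
  expect_lt(qda_err, bayes_err + 0.02)
  expect_gt(qda_err, bayes_err - 0.02)
})
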