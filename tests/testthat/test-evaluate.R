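test_that("recognition accuracy follows the correct/total definition", {
  pred <- c(rep("A", 90), rep("B", 10))
  act <- rep("A", 100)
  expect_equal(recognition_accuracy(pred, act), 90)
  expect_equal(recognition_accuracy(act, act), 100)
  # transition decisions drop out of numerator and denominator
  excl <- c(rep(FALSE, 50), rep(TRUE, 50))
  expect_equal(recognition_accuracy(pred, act, excl), 100)
  expect_error(recognition_accuracy(pred, act, rep(TRUE, 100)), "undefined")
})

test_that("confusion percentages are row-normalized counts", {
  act <- c(rep("A", 10), rep("B", 5), rep("C", 4))
  pred <- c(rep("A", 8), "B", "B", rep("B", 5), rep("C", 4))
  cm <- confusion(pred, act, c("A", "B", "C"))
  expect_equal(cm$counts["A", "B"], 2)
  expect_equal(cm$percent["A", "B"], 20)
  expect_equal(unname(rowSums(cm$percent)), rep(100, 3))
  expect_equal(average_diagonal(cm), mean(c(80, 100, 100)))

  perfect <- confusion(act, act, c("A", "B", "C"))
  expect_equal(unname(diag(perfect$percent)), rep(100, 3))
  expect_equal(average_diagonal(perfect), 100)

  # single class
  one <- confusion(rep("A", 4), rep("A", 4), "A")
  expect_equal(average_diagonal(one), 100)

  # absent class rows are undefined and block RA_c
  cm2 <- confusion(pred, act, c("A", "B", "C", "D"))
  expect_true(cm2$undefined["D"])
  expect_error(average_diagonal(cm2), "undefined")
  expect_error(confusion(c("A", "Q"), c("A", "A"), c("A", "B")), "not covered")
})

test_that("RA equals the count-weighted confusion diagonal", {
  set.seed(5)
  labs <- c("R", "WF", "WE")
  act <- sample(labs, 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.8, act, sample(labs, 500, replace = TRUE))
  cm <- confusion(pred, act, labs)
  expect_equal(recognition_accuracy(pred, act),
               100 * sum(diag(cm$counts)) / sum(cm$counts))
})

test_that("prediction times locate the first qualifying decision run", {
  n <- 2001  # decisions at 0..20000 ms
  times <- (0:(n - 1)) * 10
  b <- boundary_set(L1 = 501, L2 = 561, L3 = 1501, L4 = 1561)  # 5000/5600/15000/15600 ms
  dec <- rep("R", n)
  dec[times >= 5340 & times < 15200] <- "WF"
  pt <- prediction_times(times, dec, b, "WF")
  expect_equal(pt$PT1[1], 340)          # run starts 340 ms after L1
  expect_equal(pt$PT2[1], 5340 - 5600)  # before L2: negative by convention
  expect_equal(pt$T_r[2], 15200)
  expect_equal(pt$PT1[2], 200)
  expect_equal(pt$PT2[2], -400)

  # 9 correct, one wrong, then 10 correct: T_r comes from the later run
  dec2 <- rep("R", n)
  dec2[535:543] <- "WF"       # 9 decisions
  dec2[544] <- "WE"
  dec2[545:1520] <- "WF"
  pt2 <- prediction_times(times, dec2, b, "WF")
  expect_equal(pt2$T_r[1], times[545])

  # never a long-enough run
  dec3 <- rep("R", n)
  dec3[600:605] <- "WF"
  expect_error(prediction_times(times, dec3, b, "WF"), "never recognized")
})

test_that("fold construction matches the schemes", {
  f5 <- cv_folds("loocv5", 1:5)
  expect_length(f5, 5L)
  tested <- sort(unlist(lapply(f5, `[[`, "test")))
  expect_equal(tested, 1:5)  # each trial tested exactly once
  expect_true(all(vapply(f5, function(f) length(f$train) == 4L, TRUE)))

  expect_length(cv_folds("cv32", 1:5), choose(5, 3))
  expect_length(cv_folds("cv23", 1:5), choose(5, 2))

  fa <- cv_folds("accumulated", 1:15, first_train = 5)
  expect_length(fa, 10L)
  expect_equal(fa[[1]]$train, 1:5)
  expect_equal(fa[[1]]$test, 6)
  expect_equal(fa[[10]]$test, 15)

  s <- rep(1:2, each = 5)
  ti <- rep(1:5, 2)
  expect_length(session_folds("cv11", s, ti), 2L)
  f64 <- session_folds("cv64", s, ti)
  expect_length(f64, 10L)
  expect_true(all(vapply(f64, function(f) length(f$train) == 6L, TRUE)))
  expect_true(all(vapply(f64, function(f) length(f$test) == 4L, TRUE)))
})

test_that("trial-wise CV reports accuracy, confusion and prediction times", {
  spec <- session_spec(motions = c("WF", "WP", "F"), trials_per_motion = 3,
                       seed = 7)
  trials <- generate_session(spec)
  rep <- run_cv(trials, scheme = "loocv5", wspec = window_spec(100))
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$n_folds, 3L)
  expect_equal(rep$motions, c("R", "WF", "WP", "F"))
  expect_equal(dim(rep$confusion$percent), c(4L, 4L))
  expect_equal(unname(rowSums(rep$confusion$percent)), rep(100, 4))
  expect_gte(rep$ra, 0); expect_lte(rep$ra, 100)
  expect_equal(nrow(rep$prediction_times), 2 * length(trials))

  # motion subset restricts classes and confusion dimensions
  rep2 <- run_cv(trials, scheme = "loocv5", motions = c("R", "WF", "WP"))
  expect_equal(rep2$motions, c("R", "WF", "WP"))
  expect_equal(dim(rep2$confusion$percent), c(3L, 3L))

  # multi-combination scheme averages over all train subsets
  rep3 <- run_cv(trials, scheme = "cv23", motions = c("R", "WF"))
  expect_equal(rep3$n_folds, choose(3, 2))
  expect_equal(rep3$ra, mean(rep3$fold_ra))
})

test_that("accumulated training refits on all earlier trials", {
  spec <- session_spec(motions = "WE", trials_per_motion = 7, seed = 12)
  trials <- generate_session(spec)
  rep <- run_cv(trials, scheme = "accumulated")
  expect_equal(rep$n_folds, 2L)   # k = 5 and 6 with 7 trials
  expect_length(rep$fold_ra, 2L)
  expect_true(all(rep$fold_ra >= 0 & rep$fold_ra <= 100))
})
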