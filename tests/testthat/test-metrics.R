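test_that("binary cross-entropy matches direct evaluation and stays non-negative", {
  y <- c(1, 0, 0, 0, 0, 0)
  expect_equal(bce_multilabel_loss(y, rep(0.5, 6)), 6 * log(2), tolerance = 1e-12)
  # perfect-prediction limit (clamped at 1e-7)
  expect_lt(bce_multilabel_loss(y, c(1, 0, 0, 0, 0, 0)), 1e-5)
  set.seed(51)
  for (i in 1:50) {
    Y <- matrix(rbinom(18, 1, 0.5), 3, 6)
    P <- matrix(runif(18, 0.01, 0.99), 3, 6)
    naive <- 0
    for (r in 1:3) for (j in 1:6) {
      naive <- naive - (Y[r, j] * log(P[r, j]) + (1 - Y[r, j]) * log(1 - P[r, j]))
    }
    expect_equal(bce_multilabel_loss(Y, P), naive / 3, tolerance = 1e-9)
    expect_gte(bce_multilabel_loss(Y, P), 0)
  }
})

test_that("binarize applies the >= convention and per-label thresholds", {
  expect_equal(binarize(c(0.9, 0.4, 0.5, 0.1, 0.6, 0.2)), c(1L, 0L, 1L, 0L, 1L, 0L))
  thr <- c(0.8, 0.3, 0.5, 0.5, 0.5, 0.5)
  P <- matrix(c(0.7, 0.4, 0.5, 0.5, 0.4, 0.6), 1)
  expect_equal(as.integer(binarize(P, thr)), c(0L, 1L, 1L, 1L, 0L, 1L))
  expect_error(binarize(0.5, threshold = 1), "configuration error")
})

test_that("the worked single-sample example reproduces all six metrics", {
  Y <- matrix(c(1, 1, 0, 0, 0, 0), 1)
  P <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.3, 0.05), 1)
  m <- multilabel_metrics(Y, P, threshold = 0.5)
  expect_equal(m$one_error, 0)
  expect_equal(m$coverage, 1)
  expect_equal(m$ranking_loss, 0)
  expect_equal(m$average_precision, 1)
  expect_equal(m$hamming_loss, 0)
  expect_equal(m$acc_exam, 1)
  # top-ranked label false -> one-error 1
  m2 <- multilabel_metrics(matrix(c(0, 1, 0, 0, 0, 0), 1),
                           matrix(c(0.9, 0.8, 0.1, 0.2, 0.3, 0.05), 1))
  expect_equal(m2$one_error, 1)
})

test_that("perfect rankings yield the ideal metric values", {
  set.seed(52)
  n <- 20L
  Y <- matrix(rbinom(n * 6, 1, 0.4), n, 6)
  Y[rowSums(Y) == 0, 1] <- 1L
  # separate true from false labels cleanly
  P <- Y * matrix(runif(n * 6, 0.7, 0.99), n, 6) +
    (1 - Y) * matrix(runif(n * 6, 0.01, 0.3), n, 6)
  m <- multilabel_metrics(Y, P)
  expect_equal(m$one_error, 0)
  expect_equal(m$ranking_loss, 0)
  expect_equal(m$hamming_loss, 0)
  expect_equal(m$acc_exam, 1)
  expect_equal(m$average_precision, 1)
  expect_equal(m$coverage, mean(rowSums(Y)) - 1)
})

test_that("metrics agree with the naive double-loop oracle on random instances", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    Y <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
    Y[rowSums(Y) == 0, sample(6, 1)] <- 1L
    P <- matrix(runif(n * 6), n, 6)
    m <- multilabel_metrics(Y, P)
    o <- oracle_metrics(Y, P)
    for (f in names(o)) expect_equal(m[[f]], o[[f]], tolerance = 1e-9)
  }
})

test_that("all bounded metrics stay in bounds on random draws", {
  set.seed(54)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    Y <- matrix(rbinom(n * 6, 1, 0.3), n, 6)
    P <- matrix(runif(n * 6), n, 6)
    m <- suppressWarnings(multilabel_metrics(Y, P))
    for (f in c("acc_exam", "hamming_loss")) {
      expect_gte(m[[f]], 0); expect_lte(m[[f]], 1)
    }
    if (m$n_ranked > 0) {
      for (f in c("average_precision", "one_error", "ranking_loss")) {
        expect_gte(m[[f]], 0); expect_lte(m[[f]], 1)
      }
      expect_gte(m$coverage, 0); expect_lte(m$coverage, 5)
    }
  }
})

test_that("rank-based metrics are invariant to monotone transforms of the scores", {
  set.seed(55)
  Y <- matrix(rbinom(60, 1, 0.4), 10, 6)
  Y[rowSums(Y) == 0, 2] <- 1L
  P <- matrix(runif(60, 0.05, 0.95), 10, 6)
  m1 <- multilabel_metrics(Y, P)
  m2 <- multilabel_metrics(Y, P^3)            # strictly monotone on (0, 1)
  m3 <- multilabel_metrics(Y, 1 / (1 + exp(-5 * P)))
  for (f in c("one_error", "coverage", "ranking_loss", "average_precision")) {
    expect_equal(m1[[f]], m2[[f]], tolerance = 1e-12)
    expect_equal(m1[[f]], m3[[f]], tolerance = 1e-12)
  }
})

test_that("samples without true labels are excluded from ranking but scored on calls", {
  Y <- rbind(c(1, 0, 0, 0, 0, 0), rep(0, 6))
  P <- rbind(c(0.9, rep(0.1, 5)), rep(0.1, 6))
  expect_warning(m <- multilabel_metrics(Y, P), "excluded")
  expect_equal(m$n_ranked, 1L)
  expect_equal(m$acc_exam, 1)   # empty prediction for empty truth scores 1
  expect_equal(m$hamming_loss, 0)
})

test_that("per-label accuracy and MCC follow the confusion-matrix definitions", {
  Y <- matrix(rbinom(120, 1, 0.5), 20, 6)
  pl <- per_label_metrics(Y, Y)
  expect_equal(pl$accuracy, rep(1, 6))
  expect_equal(pl$mcc, rep(1, 6))
  pl2 <- per_label_metrics(Y, 1L - Y)
  expect_true(all(pl2$mcc <= 0))
  # TP=4 TN=3 FP=1 FN=2 -> MCC = (4*3 - 1*2) / sqrt(5 * 6 * 4 * 5)
  y <- c(rep(1, 4), rep(0, 3), 0, 1, 1)
  z <- c(rep(1, 4), rep(0, 3), 1, 0, 0)
  pl3 <- per_label_metrics(matrix(y, ncol = 1), matrix(z, ncol = 1))
  expect_equal(pl3$mcc, 10 / sqrt(600), tolerance = 1e-9)
  expect_equal(pl3$accuracy, 7 / 10)
  # zero marginal -> MCC defined as 0
  pl4 <- per_label_metrics(matrix(c(1, 1), ncol = 1), matrix(c(1, 1), ncol = 1))
  expect_equal(pl4$mcc, 0)
})

test_that("tidy() flattens a metrics report into one row", {
  Y <- matrix(c(1, 1, 0, 0, 0, 0), 1)
  P <- matrix(c(0.9, 0.8, 0.1, 0.2, 0.3, 0.05), 1)
  tt <- tidy(multilabel_metrics(Y, P))
  expect_s3_class(tt, "tbl_df")
  expect_equal(nrow(tt), 1L)
  expect_named(tt, c("acc_exam", "average_precision", "coverage", "one_error",
                     "ranking_loss", "hamming_loss"))
})
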