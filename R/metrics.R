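#' Binarize probability vectors into label calls
#'
#' Label j is called present when `p_j >= threshold_j` (ties at the cutoff
#' count as positive; documented convention).
#'
#' @param p Numeric vector of 6 probabilities, or an n x 6 matrix.
#' @param threshold Scalar cutoff in (0, 1), or one cutoff per label.
#' @return Integer vector or matrix of 0/1 calls, same shape as `p`.
#' @export
binarize <- function(p, threshold = 0.5) {
  if (any(threshold <= 0 | threshold >= 1)) {
    stop("configuration error: threshold must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (is.matrix(p)) {
    thr <- if (length(threshold) == 1L) {
      matrix(threshold, nrow(p), ncol(p))
    } else {
      matrix(threshold, nrow(p), ncol(p), byrow = TRUE)
    }
    z <- (p >= thr) * 1L
    storage.mode(z) <- "integer"
    z
  } else {
    as.integer(p >= threshold)
  }
}

#' Binary cross-entropy loss for multi-label targets
#'
#' `loss_i = -sum_j [ y_ij log p_ij + (1 - y_ij) log(1 - p_ij) ]`, summed
#' over the six compartments; for a matrix input the batch loss is the mean
#' of the per-sample sums. Probabilities at exactly 0 or 1 are clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param y 0/1 vector or n x 6 matrix of true labels.
#' @param p Probability vector or matrix of matching shape.
#' @return Non-negative scalar.
#' @export
bce_multilabel_loss <- function(y, p) {
  if (length(y) != length(p)) {
    stop("data error: label/probability shape mismatch", call. = FALSE)
  }
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  per_entry <- -(y * log(pc) + (1 - y) * log(1 - pc))
  if (is.matrix(y)) mean(rowSums(per_entry)) else sum(per_entry)
}

# Ranks of each row of P by descending probability, ties broken by ascending
# label index (deterministic).
rank_desc <- function(p) {
  ord <- order(-p, seq_along(p))
  r <- integer(length(p))
  r[ord] <- seq_along(p)
  r
}

#' The six multi-label evaluation metrics
#'
#' Computes example-based accuracy (mean Jaccard index between true and
#' binarized predicted label sets), average precision, coverage, one-error,
#' ranking loss and hamming loss. Rank-based metrics (average precision,
#' coverage, one-error, ranking loss) use ranks by descending probability
#' with ties broken by ascending label index; ranking-loss ties between a
#' true and a false label's probabilities count one half. Samples without
#' any true label are excluded from the rank-based metrics (with a warning)
#' but kept in hamming loss and example-based accuracy, where an empty
#' prediction for an empty truth scores 1.
#'
#' @param Y n x 6 binary matrix of true labels.
#' @param P n x 6 matrix of predicted probabilities.
#' @param threshold Binarization cutoff (scalar or per label).
#' @return A list of class `metrics_report` with fields `acc_exam`,
#'   `average_precision`, `coverage`, `one_error`, `ranking_loss`,
#'   `hamming_loss`, `n`, `n_ranked` and `per_label` (tibble with per-label
#'   accuracy and MCC).
#' @export
multilabel_metrics <- function(Y, P, threshold = 0.5) {
  Y <- as.matrix(Y); P <- as.matrix(P)
  if (!all(dim(Y) == dim(P))) {
    stop("data error: label/probability shape mismatch", call. = FALSE)
  }
  n <- nrow(Y); q <- ncol(Y)
  if (n < 1L) stop("data error: no samples", call. = FALSE)
  Z <- binarize(P, threshold)

  jacc <- vapply(seq_len(n), function(i) {
    inter <- sum(Y[i, ] & Z[i, ]); uni <- sum(Y[i, ] | Z[i, ])
    if (uni == 0L) 1 else inter / uni
  }, numeric(1))
  hamming <- mean(Y != Z)

  has_pos <- rowSums(Y) > 0L
  if (!all(has_pos)) {
    warning(sprintf("%d sample(s) without true labels excluded from rank-based metrics",
                    sum(!has_pos)))
  }
  idx <- which(has_pos)
  if (length(idx) > 0L) {
    one_err <- vapply(idx, function(i) {
      top <- which(rank_desc(P[i, ]) == 1L)
      as.numeric(Y[i, top] == 0L)
    }, numeric(1))
    cover <- vapply(idx, function(i) {
      max(rank_desc(P[i, ])[Y[i, ] == 1L]) - 1
    }, numeric(1))
    rloss <- vapply(idx, function(i) {
      pos <- which(Y[i, ] == 1L); neg <- which(Y[i, ] == 0L)
      if (length(neg) == 0L) return(0)
      pairs <- expand.grid(t = pos, f = neg)
      wrong <- (P[i, pairs$t] < P[i, pairs$f]) + 0.5 * (P[i, pairs$t] == P[i, pairs$f])
      mean(wrong)
    }, numeric(1))
    avg_prec <- vapply(idx, function(i) {
      r <- rank_desc(P[i, ])
      pos <- which(Y[i, ] == 1L)
      mean(vapply(pos, function(j) sum(r[pos] <= r[j]) / r[j], numeric(1)))
    }, numeric(1))
    one_error <- mean(one_err); coverage <- mean(cover)
    ranking_loss <- mean(rloss); average_precision <- mean(avg_prec)
  } else {
    one_error <- NA_real_; coverage <- NA_real_
    ranking_loss <- NA_real_; average_precision <- NA_real_
  }

  structure(list(
    acc_exam = mean(jacc), average_precision = average_precision,
    coverage = coverage, one_error = one_error, ranking_loss = ranking_loss,
    hamming_loss = hamming, n = n, n_ranked = length(idx),
    per_label = per_label_metrics(Y, Z)
  ), class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metrics_report> n = %d (ranked %d)\n",
    "  Acc_exam %.4f | AvgPrec %.4f | Coverage %.4f\n",
    "  OneError %.4f | RankLoss %.4f | Hamming %.4f\n"),
    x$n, x$n_ranked, x$acc_exam, x$average_precision, x$coverage,
    x$one_error, x$ranking_loss, x$hamming_loss))
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble with the six metric columns.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    acc_exam = x$acc_exam, average_precision = x$average_precision,
    coverage = x$coverage, one_error = x$one_error,
    ranking_loss = x$ranking_loss, hamming_loss = x$hamming_loss
  )
}

#' Per-label accuracy and Matthews correlation coefficient
#'
#' MCC is computed from the 2 x 2 confusion counts of each label and defined
#' as 0 whenever any marginal is zero (documented convention).
#'
#' @param Y n x 6 binary truth matrix.
#' @param Z n x 6 binarized prediction matrix.
#' @return Tibble with columns `label`, `accuracy`, `mcc`.
#' @export
per_label_metrics <- function(Y, Z) {
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  if (!all(dim(Y) == dim(Z))) {
    stop("data error: shape mismatch", call. = FALSE)
  }
  labs <- if (ncol(Y) == 6L) localization_labels() else paste0("label", seq_len(ncol(Y)))
  rows <- lapply(seq_len(ncol(Y)), function(j) {
    tp <- sum(Y[, j] == 1 & Z[, j] == 1); tn <- sum(Y[, j] == 0 & Z[, j] == 0)
    fp <- sum(Y[, j] == 0 & Z[, j] == 1); fn <- sum(Y[, j] == 1 & Z[, j] == 0)
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
    tibble::tibble(label = labs[j], accuracy = mean(Y[, j] == Z[, j]), mcc = mcc)
  })
  dplyr::bind_rows(rows)
}

#' Evaluate predictions against a truth table
#'
#' Joins a prediction table (as written by [write_predictions()]) with a
#' label table by `id` and computes the full metrics report.
#'
#' @param truth Tibble with `id` and the six 0/1 label columns.
#' @param predictions Tibble with `id` and the six `*_prob` columns.
#' @param threshold Binarization cutoff.
#' @return A `metrics_report`.
#' @export
evaluate_predictions <- function(truth, predictions, threshold = 0.5) {
  labs <- localization_labels()
  joined <- dplyr::inner_join(truth[, c("id", labs)],
                              predictions[, c("id", paste0(labs, "_prob"))],
                              by = "id")
  if (nrow(joined) == 0L) {
    stop("data error: no shared ids between truth and predictions", call. = FALSE)
  }
  multilabel_metrics(as.matrix(joined[, labs]),
                     as.matrix(joined[, paste0(labs, "_prob")]),
                     threshold = threshold)
}
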