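#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Split records into train / validation / test sets
#'
#' Seeded random shuffle followed by an exact partition: the validation and
#' test sets take `floor(n * ratio)` records each and the remainder goes to
#' training.
#'
#' @param records Records tibble (>= 10 rows).
#' @param ratios Train/validation/test ratios summing to 1 (default 8:1:1).
#' @param seed Integer seed.
#' @return Named list of three disjoint tibbles: `train`, `validation`,
#'   `test`.
#' @export
split_dataset <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8) {
    stop("configuration error: split ratios must sum to 1", call. = FALSE)
  }
  n <- nrow(records)
  if (n < 10L) stop("data error: need at least 10 records to split", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ord <- sample.int(n)
  n_val <- floor(n * ratios[2L])
  n_test <- floor(n * ratios[3L])
  n_train <- n - n_val - n_test
  list(
    train = records[ord[seq_len(n_train)], ],
    validation = records[ord[n_train + seq_len(n_val)], ],
    test = records[ord[n_train + n_val + seq_len(n_test)], ]
  )
}

# One Adam update; state carries first/second moments and the step counter.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p))),
       v = lapply(params, function(p) array(0, dim = dim(p))))
}

# Loss (and optionally gradients) of the current parameters over samples.
batch_pass <- function(params, samples, config, training, with_grad = TRUE) {
  tape <- ad_tape()
  pn <- if (with_grad) lapply(params, function(p) ad_var(tape, p)) else params
  Y <- do.call(rbind, lapply(samples, function(s) matrix(s$y, 1L)))
  w <- if (is.null(config$pos_weight)) NULL else {
    matrix(config$pos_weight, nrow(Y), 6L, byrow = TRUE)
  }
  logits <- fw_allocator_batch(tape, pn, samples, config, training)
  loss <- ad_scale(tape, ad_bce_logits(tape, logits, Y, w), 1 / length(samples))
  if (!with_grad) return(list(loss = ad_val(loss)[1L, 1L]))
  ad_backward(tape, loss)
  grads <- lapply(pn, function(node) node$grad)
  list(loss = ad_val(loss)[1L, 1L], grads = grads)
}

# Eval-mode probabilities for prepared samples (n x 6 matrix), computed in
# chunks to bound tape size.
predict_samples <- function(params, samples, config, chunk = 32L) {
  idx <- split(seq_along(samples), ceiling(seq_along(samples) / chunk))
  out <- do.call(rbind, lapply(idx, function(ii) {
    tape <- ad_tape()
    z <- ad_val(fw_allocator_batch(tape, params, samples[ii], config,
                                   training = FALSE))
    1 / (1 + exp(-z))
  }))
  colnames(out) <- localization_labels()
  rownames(out) <- vapply(samples, `[[`, character(1), "id")
  out
}

#' Train a multi-view localization model
#'
#' Full-batch-shuffled mini-batch training with Adam on the summed
#' multi-label binary cross-entropy. With a fixed seed the whole run
#' (initialization, shuffling, dropout) is reproducible. When a validation
#' set is supplied, per-epoch validation loss and all six multi-label
#' metrics are recorded and the parameters with the lowest validation loss
#' are kept alongside the final ones.
#'
#' @param records Labelled records tibble (sequence, structure columns as
#'   required by the enabled branches, and the six label columns).
#' @param config An [allocator_config()].
#' @param validation Optional labelled records tibble for per-epoch
#'   monitoring.
#' @param quiet Suppress per-epoch progress messages (default TRUE).
#' @return An object of class `allocator_fit`: final `params`, `config`,
#'   `history` tibble, `best` (parameters and epoch of lowest validation
#'   loss, when validation was given).
#' @export
train_allocator <- function(records, config = allocator_config(),
                            validation = NULL, quiet = TRUE) {
  missing_lab <- setdiff(localization_labels(), names(records))
  if (length(missing_lab) > 0L) {
    stop("data error: training records lack label columns", call. = FALSE)
  }
  if (sum(rowSums(records[, localization_labels()])) == 0L) {
    message("note: training set contains no positive labels")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  params <- init_params(config)
  samples <- prepare_samples(records, config, require_labels = TRUE)
  val_samples <- if (!is.null(validation)) {
    prepare_samples(validation, config, require_labels = TRUE)
  }
  state <- adam_init(params)
  n <- length(samples)
  history <- vector("list", config$epochs)
  best <- list(val_loss = Inf, params = NULL, epoch = NA_integer_)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    epoch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      pass <- batch_pass(params, samples[idx], config, training = TRUE)
      upd <- adam_step(params, pass$grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      epoch_losses[bi] <- pass$loss
    }
    row <- tibble::tibble(epoch = epoch, train_loss = mean(epoch_losses))
    if (!is.null(val_samples)) {
      vp <- predict_samples(params, val_samples, config)
      vy <- label_matrix(validation)
      row$val_loss <- bce_multilabel_loss(vy, vp)
      m <- suppressWarnings(multilabel_metrics(vy, vp, config$threshold))
      row <- dplyr::bind_cols(row, tidy(m))
      if (row$val_loss < best$val_loss) {
        best <- list(val_loss = row$val_loss, params = params, epoch = epoch)
      }
    }
    history[[epoch]] <- row
    if (!quiet) {
      message(sprintf("epoch %3d | train loss %.4f%s", epoch, row$train_loss,
                      if (!is.null(val_samples)) sprintf(" | val loss %.4f", row$val_loss) else ""))
    }
  }

  structure(list(
    params = params, config = config,
    history = dplyr::bind_rows(history),
    best = if (is.null(val_samples)) NULL else best
  ), class = "allocator_fit")
}

#' @exportS3Method base::print
print.allocator_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<allocator_fit> %d epochs | branches %s | final train loss %.4f\n",
              nrow(x$history), paste(x$config$branches, collapse = "+"),
              last$train_loss))
  if (!is.null(x$best)) {
    cat(sprintf("  best validation loss %.4f at epoch %d\n",
                x$best$val_loss, x$best$epoch))
  }
  invisible(x)
}

#' Predict localization probabilities for new records
#'
#' @param object An `allocator_fit`.
#' @param newdata Records tibble (structure columns required when graph
#'   branches are enabled).
#' @param threshold Binarization cutoff (defaults to the training
#'   configuration's).
#' @param use_best Use the best-on-validation checkpoint instead of the
#'   final parameters, when available (default FALSE).
#' @param ... Unused.
#' @return Tibble with `id`, six `*_prob` columns and six 0/1 call columns.
#' @export
predict.allocator_fit <- function(object, newdata, threshold = NULL,
                                  use_best = FALSE, ...) {
  params <- if (use_best && !is.null(object$best)) object$best$params else object$params
  threshold <- if (is.null(threshold)) object$config$threshold else threshold
  samples <- prepare_samples(newdata, object$config)
  P <- predict_samples(params, samples, object$config)
  Z <- binarize(P, threshold)
  probs <- tibble::as_tibble(P)
  names(probs) <- paste0(localization_labels(), "_prob")
  calls <- tibble::as_tibble(Z)
  dplyr::bind_cols(tibble::tibble(id = newdata$id), probs, calls)
}

#' Tidy a fitted model's training history
#'
#' @param x An `allocator_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (train loss, and validation loss
#'   plus metrics when a validation set was used).
#' @export
tidy.allocator_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x An `allocator_fit`.
#' @param ... Unused.
#' @return Tibble with epochs trained, final training loss, and (when
#'   available) best validation loss and epoch.
#' @export
glance.allocator_fit <- function(x, ...) {
  out <- tibble::tibble(
    epochs = nrow(x$history),
    train_loss = x$history$train_loss[nrow(x$history)],
    branches = paste(x$config$branches, collapse = "+"),
    gnn_variant = x$config$gnn_variant
  )
  if (!is.null(x$best)) {
    out$best_val_loss <- x$best$val_loss
    out$best_epoch <- x$best$epoch
  }
  out
}

#' Plot training curves
#'
#' @param object An `allocator_fit`.
#' @param ... Unused.
#' @return A ggplot of training (and validation) loss against epoch.
#' @export
autoplot.allocator_fit <- function(object, ...) {
  h <- object$history
  df <- tidyr::pivot_longer(
    h[, c("epoch", intersect(c("train_loss", "val_loss"), names(h)))],
    -"epoch", names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
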