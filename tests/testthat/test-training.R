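test_that("split_dataset produces an exact, seeded partition", {
  rec <- rna_records(sprintf("r%04d", 1:1000),
                     rep("ACGUACGUACGU", 1000))
  sp <- split_dataset(rec, seed = 3)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 800L, validation = 100L, test = 100L))
  rec17 <- rec[1:17, ]
  sp17 <- split_dataset(rec17, seed = 3)
  expect_equal(vapply(sp17, nrow, integer(1)),
               c(train = 15L, validation = 1L, test = 1L))
  expect_identical(split_dataset(rec, seed = 3), sp)
  expect_error(split_dataset(rec, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_dataset(rec[1:5, ]), "at least 10")
})

test_that("splits partition the input for many seeds", {
  rec <- rna_records(sprintf("r%03d", 1:53), rep("ACGU", 53))
  for (seed in 1:100) {
    sp <- split_dataset(rec, seed = seed)
    ids <- c(sp$train$id, sp$validation$id, sp$test$id)
    expect_setequal(ids, rec$id)
    expect_equal(anyDuplicated(ids), 0L)
  }
})

test_that("training demands labels and is reproducible under a fixed seed", {
  rec <- labelled_records(6, L = 40, seed = 61)
  expect_error(train_allocator(dplyr::select(rec, id, sequence, structure)),
               "data error")
  cfg <- tiny_config(epochs = 3L, seed = 11, batch_size = 3L)
  f1 <- train_allocator(rec, cfg)
  f2 <- train_allocator(rec, cfg)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-12)
  expect_equal(f1$params, f2$params, tolerance = 1e-12)
  expect_equal(nrow(f1$history), 3L)
})

test_that("one Adam step on one sample decreases that sample's loss", {
  rec <- labelled_records(1, L = 40, seed = 62)
  cfg <- tiny_config(seed = 7, dropout = 0, learning_rate = 1e-3)
  m <- allocator_model(cfg)
  s <- rnaloc:::prepare_samples(rec, cfg, require_labels = TRUE)
  pass <- rnaloc:::batch_pass(m$params, s, cfg, training = FALSE)
  st <- rnaloc:::adam_init(m$params)
  upd <- rnaloc:::adam_step(m$params, pass$grads, st, lr = 1e-3)
  after <- rnaloc:::batch_pass(upd$params, s, cfg, FALSE, with_grad = FALSE)
  expect_lt(after$loss, pass$loss)
})

test_that("validation history carries loss, metrics and the best checkpoint", {
  rec <- labelled_records(10, L = 40, seed = 63)
  cfg <- tiny_config(epochs = 4L, seed = 2, batch_size = 4L)
  fit <- train_allocator(rec[1:8, ], cfg, validation = rec[9:10, ])
  h <- fit$history
  expect_true(all(c("val_loss", "acc_exam", "coverage", "hamming_loss") %in% names(h)))
  expect_equal(fit$best$val_loss, min(h$val_loss))
  expect_false(is.null(fit$best$params))
  g <- glance(fit)
  expect_equal(g$epochs, 4L)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("predictions are tidy, thresholded and usable for evaluation", {
  rec <- labelled_records(8, L = 40, seed = 64)
  cfg <- tiny_config(epochs = 2L, seed = 3, batch_size = 4L)
  fit <- train_allocator(rec, cfg)
  preds <- predict(fit, rec)
  expect_s3_class(preds, "tbl_df")
  expect_named(preds, c("id", paste0(localization_labels(), "_prob"),
                        localization_labels()))
  probs <- as.matrix(preds[, paste0(localization_labels(), "_prob")])
  expect_true(all(probs > 0 & probs < 1))
  expect_equal(as.matrix(preds[, localization_labels()]),
               unname(binarize(probs, 0.5)), ignore_attr = TRUE)
  rep <- suppressWarnings(
    evaluate_predictions(rec[, c("id", localization_labels())], preds))
  expect_s3_class(rep, "metrics_report")
})

test_that("per-label positive weights scale the loss gradient sensibly", {
  rec <- labelled_records(2, L = 30, seed = 65)
  cfg_w <- tiny_config(seed = 4, dropout = 0, pos_weight = rep(2, 6))
  cfg_u <- tiny_config(seed = 4, dropout = 0)
  m <- allocator_model(cfg_u)
  s <- rnaloc:::prepare_samples(rec, cfg_u, require_labels = TRUE)
  lw <- rnaloc:::batch_pass(m$params, s, cfg_w, training = FALSE,
                            with_grad = FALSE)$loss
  lu <- rnaloc:::batch_pass(m$params, s, cfg_u, training = FALSE,
                            with_grad = FALSE)$loss
  expect_gt(lw, lu)  # positives up-weighted
})
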