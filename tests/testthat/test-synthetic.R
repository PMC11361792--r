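test_that("generate_records is seeded and honours the length range", {
  r1 <- generate_records(30, seed = 5)
  r2 <- generate_records(30, seed = 5)
  expect_identical(r1, r2)
  lens <- nchar(r1$sequence)
  expect_true(all(lens >= 100 & lens <= 400))
  expect_false(identical(r1, generate_records(30, seed = 6)))
})

test_that("base frequencies match the generator probabilities within 3 sigma", {
  rec <- generate_records(60, length_range = c(200L, 300L), seed = 8)
  chars <- strsplit(paste(rec$sequence, collapse = ""), "")[[1L]]
  n <- length(chars)
  expect_gte(n, 1e4)
  for (b in BASES) {
    phat <- mean(chars == b)
    se <- sqrt(0.25 * 0.75 / n)
    expect_lt(abs(phat - 0.25), 3 * se)
  }
})

test_that("motif rules plant the motif exactly in positive records", {
  rec <- generate_records(40, seed = 9)
  rules <- default_rules()
  planted <- plant_signals(rec, rules, seed = 10)
  motif <- rules$nucleus$motif
  has_motif <- grepl(motif, planted$sequence, fixed = TRUE)
  expect_equal(has_motif, planted$nucleus == 1L)
})

test_that("hairpin-positive records fold into a stem inside the planted window", {
  rec <- generate_records(30, seed = 11)
  rules <- default_rules()
  planted <- plant_signals(rec, rules, seed = 12)
  pos <- which(planted$cytosol == 1L)
  expect_gt(length(pos), 3L)
  stem <- rules$cytosol$stem
  hits <- 0L
  for (i in pos) {
    iv <- Filter(function(e) e$label == "cytosol", planted$elements[[i]])[[1L]]
    db <- nussinov_fold(planted$sequence[i])
    pairs <- parse_dotbracket(db) + 1L
    inside <- pairs[, 1] >= iv$start & pairs[, 2] <= iv$end
    if (sum(inside) >= stem) hits <- hits + 1L
  }
  # the planted perfect stem is recovered by the folder in most records
  expect_gte(hits, ceiling(0.7 * length(pos)))
})

test_that("hairpin rules keep base composition balanced between classes", {
  rec <- generate_records(60, seed = 13)
  rules <- list(
    nucleus  = list(type = "motif", motif = "ACGAGGUCCAAG", prob = 0, copies = 2L),
    exosome  = list(type = "motif", motif = "UUCGACGGAUCC", prob = 0, copies = 2L),
    cytosol  = list(type = "hairpin", stem = 20L, loop = "GAAA", prob = 0.5),
    ribosome = list(type = "hairpin", stem = 20L, loop = "GAAA", prob = 0),
    membrane = list(type = "motif", motif = "GGAUCCUAGCAU", prob = 0, copies = 2L),
    er       = list(type = "motif", motif = "CUUAGGCAUCGU", prob = 0, copies = 2L)
  )
  planted <- plant_signals(rec, rules, seed = 14)
  gc_frac <- vapply(planted$sequence, function(s) {
    ch <- strsplit(s, "")[[1L]]; mean(ch %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  pos <- planted$cytosol == 1L
  # positives and negatives both receive the element bases (decoy shuffled),
  # so mean GC content cannot separate the classes
  expect_lt(abs(mean(gc_frac[pos]) - mean(gc_frac[!pos])), 0.02)
})

test_that("label marginals match the configured probabilities within 3 sigma", {
  rec <- generate_records(300, seed = 15)
  planted <- plant_signals(rec, default_rules(), seed = 16)
  probs <- c(nucleus = 0.65, exosome = 0.85, membrane = 0.25, er = 0.15)
  for (lab in names(probs)) {
    p <- probs[[lab]]
    se <- sqrt(p * (1 - p) / 300)
    expect_lt(abs(mean(planted[[lab]]) - p), 3 * se + 0.02)
  }
})

test_that("motifs longer than the shortest sequence are rejected", {
  rec <- generate_records(5, length_range = c(20L, 25L), seed = 17)
  rules <- default_rules()
  rules$nucleus$motif <- paste(rep("ACGU", 10), collapse = "")
  expect_error(plant_signals(rec, rules, seed = 1), "configuration error")
})

test_that("make_benchmark writes byte-identical files across runs", {
  cfg <- benchmark_config(n = 12, seed = 7, split = c(0.8, 0.1, 0.1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(b1 <- make_benchmark(cfg, outdir = d1))
  suppressMessages(b2 <- make_benchmark(cfg, outdir = d2))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_false(is.na(b1$records$structure[1]))
  expect_identical(b1$records$structure, b1$records$structure2)
  expect_equal(nrow(b1$train) + nrow(b1$validation) + nrow(b1$test), 12L)
})
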