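# Shared fixtures and independent oracles used across the test files.

BASES <- c("A", "C", "G", "U")

random_rna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, L, replace = TRUE), collapse = "")
}

# Naive nested-loop k-mer counting oracle (windows with N skipped).
oracle_kmer <- function(seq, k_values = 1:5) {
  ch <- strsplit(seq, "")[[1L]]
  out <- numeric(0)
  for (k in sort(k_values)) {
    lv <- character(0)
    # enumerate all k-mers lexicographically by counting in base 4
    for (idx in 0:(4^k - 1)) {
      digits <- integer(k)
      x <- idx
      for (pos in k:1) { digits[pos] <- x %% 4; x <- x %/% 4 }
      lv <- c(lv, paste(BASES[digits + 1L], collapse = ""))
    }
    counts <- setNames(numeric(length(lv)), lv)
    n_windows <- 0
    if (length(ch) >= k) {
      for (i in 1:(length(ch) - k + 1L)) {
        w <- paste(ch[i:(i + k - 1L)], collapse = "")
        if (grepl("N", w, fixed = TRUE)) next
        counts[w] <- counts[w] + 1
        n_windows <- n_windows + 1
      }
    }
    out <- c(out, if (n_windows > 0) counts / n_windows else counts)
  }
  unname(out)
}

# Naive CKSNAP oracle.
oracle_cksnap <- function(seq, gap_values = 0:5) {
  ch <- strsplit(seq, "")[[1L]]
  pairs <- as.vector(t(outer(BASES, BASES, paste0)))
  out <- numeric(0)
  for (g in sort(gap_values)) {
    counts <- setNames(numeric(16L), pairs)
    n <- 0
    if (length(ch) >= g + 2L) {
      for (i in 1:(length(ch) - g - 1L)) {
        a <- ch[i]; b <- ch[i + g + 1L]
        if (a == "N" || b == "N") next
        counts[paste0(a, b)] <- counts[paste0(a, b)] + 1
        n <- n + 1
      }
    }
    out <- c(out, if (n > 0) counts / n else counts)
  }
  unname(out)
}

# Independent stack parser for dot-bracket strings (0-based pairs).
oracle_pairs <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  stack <- integer(0)
  res <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      res <- rbind(res, c(stack[length(stack)] - 1L, i - 1L))
      stack <- stack[-length(stack)]
    }
  }
  if (is.null(res)) matrix(integer(0), ncol = 2L) else res[order(res[, 1L]), , drop = FALSE]
}

# Random valid dot-bracket string of length L (grammar-based generation).
random_dotbracket <- function(L) {
  ch <- rep(".", L)
  open <- integer(0)
  i <- 1L
  while (i <= L) {
    r <- runif(1)
    if (r < 0.3 && L - i >= 4L) {
      ch[i] <- "("; open <- c(open, i)
    } else if (r < 0.55 && length(open) > 0L && i - open[length(open)] >= 4L) {
      ch[i] <- ")"; open <- open[-length(open)]
    }
    i <- i + 1L
  }
  # close anything still open as dots
  ch[open] <- "."
  paste(ch, collapse = "")
}

# Exhaustive enumeration of the maximum nested pairing for tiny sequences.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "")[[1L]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (ok(ch[i], ch[k])) {
        inner <- if (k > i + 1L) rec(i + 1L, k - 1L) else 0L
        right <- if (k < j) rec(k + 1L, j) else 0L
        best <- max(best, inner + right + 1L)
      }
    }
    best
  }
  if (length(ch) < min_loop + 2L) return(0L)
  rec(1L, length(ch))
}

# Naive per-definition multi-label metrics oracle (explicit loops; rows
# without positives are dropped from every rank-based metric).
oracle_metrics <- function(Y, P, threshold = 0.5) {
  n <- nrow(Y); q <- ncol(Y)
  Z <- matrix(as.integer(P >= threshold), n, q)
  jacc <- ham <- numeric(n)
  for (i in 1:n) {
    inter <- 0; uni <- 0; mism <- 0
    for (j in 1:q) {
      if (Y[i, j] == 1 && Z[i, j] == 1) inter <- inter + 1
      if (Y[i, j] == 1 || Z[i, j] == 1) uni <- uni + 1
      if (Y[i, j] != Z[i, j]) mism <- mism + 1
    }
    jacc[i] <- if (uni == 0) 1 else inter / uni
    ham[i] <- mism / q
  }
  keep <- which(rowSums(Y) > 0)
  oe <- cov <- rl <- ap <- numeric(0)
  for (i in keep) {
    r <- integer(q)
    ord <- order(-P[i, ], seq_len(q))
    r[ord] <- seq_len(q)
    top <- ord[1]
    oe <- c(oe, as.numeric(Y[i, top] == 0))
    cov <- c(cov, max(r[Y[i, ] == 1]) - 1)
    pos <- which(Y[i, ] == 1); neg <- which(Y[i, ] == 0)
    if (length(neg) > 0) {
      wrong <- 0
      for (a in pos) for (b in neg) {
        if (P[i, a] < P[i, b]) wrong <- wrong + 1
        if (P[i, a] == P[i, b]) wrong <- wrong + 0.5
      }
      rl <- c(rl, wrong / (length(pos) * length(neg)))
    } else rl <- c(rl, 0)
    prec <- numeric(0)
    for (a in pos) prec <- c(prec, sum(r[pos] <= r[a]) / r[a])
    ap <- c(ap, mean(prec))
  }
  list(acc_exam = mean(jacc), hamming_loss = mean(ham),
       one_error = mean(oe), coverage = mean(cov), ranking_loss = mean(rl),
       average_precision = mean(ap))
}

# Records tibble with fallback-folded structures and random labels.
labelled_records <- function(n, L = 60L, seed = 1L) {
  set.seed(seed)
  rec <- rna_records(
    id = sprintf("t%03d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) random_rna(L), character(1))
  )
  rec$structure <- vapply(rec$sequence, nussinov_fold, character(1),
                          USE.NAMES = FALSE)
  rec$structure2 <- rec$structure
  for (lab in localization_labels()) {
    rec[[lab]] <- as.integer(runif(n) < 0.5)
  }
  # guarantee at least one positive per row for rank-based metrics
  zero <- rowSums(rec[, localization_labels()]) == 0
  rec$nucleus[zero] <- 1L
  rec
}

# A small full model shared by forward-pass tests.
tiny_config <- function(...) {
  allocator_config(tokens = 4L, token_dim = 8L, n_heads = 2L,
                   seq_hidden = 32L, gin_hidden = 16L, head_hidden = 16L,
                   set2set_steps = 2L, ...)
}
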