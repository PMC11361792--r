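test_that("scaled dot-product attention matches the hand-computed oracle", {
  # one head, all projections identity, X a 2x1 column (1, 0):
  # row 1 attention = softmax((1, 0)) = (e, 1) / (e + 1)
  I <- matrix(1, 1, 1)
  params <- list(heads = list(list(Wq = I, Wk = I, Wv = I)), W0 = I)
  X <- matrix(c(1, 0), 2, 1)
  out <- multi_head_self_attention(X, params)
  e <- exp(1)
  expect_equal(out[1, 1], e / (e + 1), tolerance = 1e-12)
  expect_equal(out[2, 1], 0.5, tolerance = 1e-12)
  # zero input stays zero (V = 0)
  expect_equal(multi_head_self_attention(matrix(0, 3, 1), params),
               matrix(0, 3, 1))
  expect_error(multi_head_self_attention(matrix(0, 3, 2), params),
               "configuration error")
})

test_that("attention rows are probability distributions", {
  set.seed(4)
  X <- matrix(rnorm(32), 8, 4)
  Wq <- matrix(rnorm(8), 4, 2); Wk <- matrix(rnorm(8), 4, 2)
  S <- X %*% Wq %*% t(X %*% Wk) / sqrt(2)
  A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
  expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-6)
  expect_true(all(A >= 0))
})

test_that("sequence extractors emit 128-dim embeddings, deterministically in eval mode", {
  m <- allocator_model(allocator_config(seed = 21))
  kv <- kmer_frequencies(random_rna(70, seed = 1))
  cv <- cksnap_frequencies(random_rna(70, seed = 2))
  ek <- sequence_extractor_forward(kv, m, "kmer")
  ec <- sequence_extractor_forward(cv, m, "cksnap")
  expect_length(ek, 128L)
  expect_length(ec, 128L)
  expect_identical(ek, sequence_extractor_forward(kv, m, "kmer"))
  # zero input stays finite
  expect_true(all(is.finite(sequence_extractor_forward(numeric(1364), m, "kmer"))))
  expect_error(sequence_extractor_forward(numeric(10), m, "kmer"),
               "configuration error")
})

test_that("the GIN layer equals the explicit neighbor-sum formula", {
  # path graph 1-2-3, scalar features (1, 2, 3), eps = 0, identity update
  g <- dotbracket_to_graph("AAA", "...")
  h <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(gin_layer_forward(g, h), matrix(c(3, 6, 5), 3, 1))
  # isolated node: L = 1 graph has no neighbors
  g1 <- dotbracket_to_graph("A", ".")
  expect_equal(gin_layer_forward(g1, matrix(2), eps = 0.5), matrix(3))
})

test_that("the GIN layer matches a brute-force oracle on random graphs", {
  set.seed(13)
  for (rep in 1:20) {
    L <- sample(4:10, 1)
    db <- random_dotbracket(L)
    g <- dotbracket_to_graph(random_rna(L), db)
    h <- matrix(rnorm(L * 3), L, 3)
    eps <- runif(1, -0.5, 0.5)
    # brute force: for every node, sum neighbor rows from the edge list
    expected <- matrix(0, L, 3)
    for (v in seq_len(L)) {
      nb <- c(g$edges$to[g$edges$from == v], g$edges$from[g$edges$to == v])
      acc <- (1 + eps) * h[v, ]
      for (u in nb) acc <- acc + h[u, ]
      expected[v, ] <- acc
    }
    expect_equal(gin_layer_forward(g, h, eps = eps), expected, tolerance = 1e-9)
  }
})

test_that("GIN aggregation is permutation equivariant", {
  set.seed(14)
  L <- 8L
  db <- "((.))..."
  g <- dotbracket_to_graph(random_rna(L), "((..))..")
  h <- matrix(rnorm(L * 2), L, 2)
  out <- gin_layer_forward(g, h)
  perm <- sample(L)
  # relabel nodes by perm: edge {u, v} -> {perm[u], perm[v]}
  g2 <- g
  g2$edges$from <- perm[g$edges$from]
  g2$edges$to <- perm[g$edges$to]
  h2 <- h; h2[perm, ] <- h
  out2 <- gin_layer_forward(g2, h2)
  expect_equal(out2[perm, ], out, tolerance = 1e-12)
})

test_that("set2set pools to twice the width, invariant to node order", {
  set.seed(15)
  H <- matrix(rnorm(7 * 5), 7, 5)
  v <- set2set_pool(H, processing_steps = 3, seed = 2)
  expect_length(v, 10L)
  expect_equal(set2set_pool(H[sample(7), ], processing_steps = 3, seed = 2), v,
               tolerance = 1e-6)
  expect_error(set2set_pool(matrix(numeric(0), 0, 3)), "at least one node")
})

test_that("single-node set2set reduces to the direct recurrence", {
  set.seed(16)
  d <- 3L
  H <- matrix(rnorm(d), 1, d)
  Wx <- matrix(rnorm(2 * d * 4 * d), 2 * d, 4 * d)
  Wh <- matrix(rnorm(d * 4 * d), d, 4 * d)
  b <- matrix(0, 1, 4 * d)
  v <- set2set_pool(H, processing_steps = 2,
                    params = list(Wx = Wx, Wh = Wh, b = b))
  # direct computation: with one node the attention weight is exactly 1
  sig <- function(x) 1 / (1 + exp(-x))
  q_star <- matrix(0, 1, 2 * d); hh <- matrix(0, 1, d); cc <- matrix(0, 1, d)
  for (s in 1:2) {
    gates <- q_star %*% Wx + hh %*% Wh + b
    i <- sig(gates[, 1:d]); f <- sig(gates[, (d + 1):(2 * d)])
    o <- sig(gates[, (2 * d + 1):(3 * d)]); gg <- tanh(gates[, (3 * d + 1):(4 * d)])
    cc <- f * cc + i * gg
    hh <- matrix(o * tanh(cc), 1, d)
    q_star <- cbind(hh, H)  # point-mass attention on the single node
  }
  expect_equal(v, as.numeric(q_star), tolerance = 1e-9)
})

test_that("graph extractor gives identical embeddings for isomorphic inputs", {
  m <- allocator_model(allocator_config(seed = 22))
  g1 <- dotbracket_to_graph("GGAAACCAA", "((...))..")
  e1 <- graph_extractor_forward(g1, m, "graph1")
  expect_length(e1, 128L)
  expect_identical(e1, graph_extractor_forward(g1, m, "graph1"))
  # same features and structure -> same embedding
  g2 <- dotbracket_to_graph("GGAAACCAA", "((...))..")
  expect_equal(graph_extractor_forward(g2, m, "graph1"), e1, tolerance = 1e-9)
})

test_that("the prediction head is a two-layer sigmoid map", {
  p0 <- list(W1 = matrix(0, 4, 3), b1 = matrix(0, 1, 3),
             W2 = matrix(0, 3, 6), b2 = matrix(0, 1, 6))
  expect_equal(prediction_head(rep(1, 4), p0), rep(0.5, 6))
  p1 <- list(W1 = matrix(1), b1 = matrix(0), W2 = matrix(1), b2 = matrix(0))
  expect_equal(prediction_head(0.8473, p1), 1 / (1 + exp(-0.8473)),
               tolerance = 1e-9)
  set.seed(17)
  pr <- list(W1 = matrix(rnorm(8), 4, 2), b1 = matrix(rnorm(2), 1),
             W2 = matrix(rnorm(12), 2, 6), b2 = matrix(rnorm(6), 1))
  out <- prediction_head(rnorm(4), pr)
  expect_true(all(out > 0 & out < 1))
  expect_error(prediction_head(rnorm(3), pr), "configuration error")
})

test_that("the full forward pass composes the enabled branches", {
  rec <- labelled_records(1, L = 50, seed = 31)
  m <- allocator_model(tiny_config(seed = 1))
  p <- allocator_forward(m, rec)
  expect_length(p, 6L)
  expect_named(p, localization_labels())
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, allocator_forward(m, rec))  # eval-mode determinism
  # concat width: 4 branches x embed_dim feed the head
  expect_equal(nrow(m$params[["head.W1"]]), 4L * m$config$embed_dim)
  m2 <- allocator_model(tiny_config(branches = c("kmer", "cksnap"), seed = 1))
  expect_equal(nrow(m2$params[["head.W1"]]), 2L * m2$config$embed_dim)
  expect_error(allocator_config(branches = character(0)), "at least one branch")
})

test_that("gcn and gat variants run forward and are deterministic", {
  rec <- labelled_records(1, L = 40, seed = 32)
  for (variant in c("gcn", "gat")) {
    m <- allocator_model(tiny_config(gnn_variant = variant, seed = 5))
    p <- allocator_forward(m, rec)
    expect_true(all(is.finite(p)))
    expect_identical(p, allocator_forward(m, rec))
  }
})

test_that("analytic gradients match numerical differentiation", {
  rec <- labelled_records(2, L = 30, seed = 33)
  cfg <- tiny_config(seed = 2, dropout = 0)
  m <- allocator_model(cfg)
  samples <- rnaloc:::prepare_samples(rec, cfg, require_labels = TRUE)
  pass <- rnaloc:::batch_pass(m$params, samples, cfg, training = FALSE)
  eps <- 1e-5
  for (nm in c("kmer.W1", "cksnap.head1.Wq", "graph1.l1.eps", "graph1.l2.W2",
               "graph2.lstm.Wx", "head.W2")) {
    g <- pass$grads[[nm]]
    idx <- which(abs(g) == max(abs(g)), arr.ind = TRUE)[1, ]
    p2 <- m$params
    p2[[nm]][idx[1], idx[2]] <- p2[[nm]][idx[1], idx[2]] + eps
    up <- rnaloc:::batch_pass(p2, samples, cfg, FALSE, with_grad = FALSE)$loss
    p2[[nm]][idx[1], idx[2]] <- p2[[nm]][idx[1], idx[2]] - 2 * eps
    dn <- rnaloc:::batch_pass(p2, samples, cfg, FALSE, with_grad = FALSE)$loss
    expect_equal(g[idx[1], idx[2]], (up - dn) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("model checkpoints round-trip and refuse foreign files", {
  m <- allocator_model(tiny_config(seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$params, m$params, tolerance = 1e-12)
  expect_equal(back$config$branches, m$config$branches)
  rec <- labelled_records(1, L = 35, seed = 34)
  expect_equal(allocator_forward(back, rec), allocator_forward(m, rec),
               tolerance = 1e-9)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(read_model(bad), "configuration error")
})
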