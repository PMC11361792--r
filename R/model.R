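#' Model and training configuration
#'
#' One configuration object drives model construction and training. The
#' canonical defaults are learning rate 3e-4, dropout 0.1, 200 epochs, an
#' 8:1:1 split and 128-dimensional branch outputs; architecture internals
#' (token shape, head count, GIN depth and width, set2set steps) are
#' exposed with declared defaults.
#'
#' @param learning_rate Adam learning rate.
#' @param dropout Dropout rate applied after MLP hidden layers and on the
#'   prediction head's first layer.
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param split Train/validation/test ratios (must sum to 1).
#' @param branches Character subset of
#'   `c("kmer", "cksnap", "graph1", "graph2")`; the seq-only ablation is
#'   `c("kmer", "cksnap")`.
#' @param gnn_variant `"gin"` (default), `"gcn"` or `"gat"`.
#' @param threshold Probability cutoff for binarization (scalar or one per
#'   label).
#' @param tokens,token_dim Attention tokenization: the sequence MLP maps a
#'   composition vector to `tokens` tokens of `token_dim` dimensions.
#' @param n_heads Number of attention heads (`token_dim` must be divisible).
#' @param seq_hidden Hidden width of the sequence-branch MLP.
#' @param gin_layers,gin_hidden GNN depth and width.
#' @param set2set_steps Processing steps of the set2set readout.
#' @param embed_dim Output dimensionality of every branch (128).
#' @param head_hidden Hidden width of the two-layer prediction head.
#' @param min_loop Minimum hairpin-loop size for the fallback folder.
#' @param pos_weight Optional per-label positive-class weights (length 6);
#'   off (`NULL`) by default.
#' @return A list of class `allocator_config`.
#' @export
allocator_config <- function(learning_rate = 3e-4, dropout = 0.1,
                             epochs = 200L, batch_size = 16L, seed = 1L,
                             split = c(0.8, 0.1, 0.1),
                             branches = c("kmer", "cksnap", "graph1", "graph2"),
                             gnn_variant = c("gin", "gcn", "gat"),
                             threshold = 0.5,
                             tokens = 16L, token_dim = 32L, n_heads = 4L,
                             seq_hidden = 256L,
                             gin_layers = 2L, gin_hidden = 64L,
                             set2set_steps = 3L, embed_dim = 128L,
                             head_hidden = 64L, min_loop = 3L,
                             pos_weight = NULL) {
  gnn_variant <- match.arg(gnn_variant)
  if (abs(sum(split) - 1) > 1e-8) {
    stop("configuration error: split ratios must sum to 1", call. = FALSE)
  }
  if (epochs < 1L) stop("configuration error: epochs must be >= 1", call. = FALSE)
  if (length(branches) == 0L) {
    stop("configuration error: at least one branch must be enabled", call. = FALSE)
  }
  branches <- match.arg(branches, several.ok = TRUE)
  if (token_dim %% n_heads != 0L) {
    stop("configuration error: token_dim must be divisible by n_heads", call. = FALSE)
  }
  structure(list(
    learning_rate = learning_rate, dropout = dropout, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), seed = as.integer(seed), split = split,
    branches = branches, gnn_variant = gnn_variant, threshold = threshold,
    tokens = as.integer(tokens), token_dim = as.integer(token_dim),
    n_heads = as.integer(n_heads), seq_hidden = as.integer(seq_hidden),
    gin_layers = as.integer(gin_layers), gin_hidden = as.integer(gin_hidden),
    set2set_steps = as.integer(set2set_steps), embed_dim = as.integer(embed_dim),
    head_hidden = as.integer(head_hidden), min_loop = as.integer(min_loop),
    pos_weight = pos_weight,
    kmer_dim = 1364L, cksnap_dim = 96L, node_dim = 10L,
    label_order = localization_labels(), version = 1L
  ), class = "allocator_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros <- function(nin, nout) matrix(0, nin, nout)

# Flat named list of parameter matrices for the configured architecture.
init_params <- function(config) {
  P <- list()
  dk <- config$token_dim %/% config$n_heads
  for (b in intersect(config$branches, c("kmer", "cksnap"))) {
    p_in <- if (b == "kmer") config$kmer_dim else config$cksnap_dim
    td <- config$tokens * config$token_dim
    P[[paste0(b, ".W1")]] <- glorot(p_in, config$seq_hidden)
    P[[paste0(b, ".b1")]] <- zeros(1L, config$seq_hidden)
    P[[paste0(b, ".W2")]] <- glorot(config$seq_hidden, td)
    P[[paste0(b, ".b2")]] <- zeros(1L, td)
    for (h in seq_len(config$n_heads)) {
      for (w in c("Wq", "Wk", "Wv")) {
        P[[paste0(b, ".head", h, ".", w)]] <- glorot(config$token_dim, dk)
      }
    }
    P[[paste0(b, ".W0")]] <- glorot(config$n_heads * dk, config$token_dim)
    P[[paste0(b, ".Wp")]] <- glorot(config$token_dim, config$embed_dim)
    P[[paste0(b, ".bp")]] <- zeros(1L, config$embed_dim)
  }
  for (g in intersect(config$branches, c("graph1", "graph2"))) {
    hid <- config$gin_hidden
    for (l in seq_len(config$gin_layers)) {
      nin <- if (l == 1L) config$node_dim else hid
      pre <- paste0(g, ".l", l, ".")
      if (config$gnn_variant == "gin") {
        P[[paste0(pre, "eps")]] <- zeros(1L, 1L)
        P[[paste0(pre, "W1")]] <- glorot(nin, hid)
        P[[paste0(pre, "b1")]] <- zeros(1L, hid)
        P[[paste0(pre, "W2")]] <- glorot(hid, hid)
        P[[paste0(pre, "b2")]] <- zeros(1L, hid)
      } else if (config$gnn_variant == "gcn") {
        P[[paste0(pre, "W")]] <- glorot(nin, hid)
        P[[paste0(pre, "b")]] <- zeros(1L, hid)
      } else { # gat
        P[[paste0(pre, "W")]] <- glorot(nin, hid)
        P[[paste0(pre, "a1")]] <- glorot(hid, 1L)
        P[[paste0(pre, "a2")]] <- glorot(hid, 1L)
      }
    }
    P[[paste0(g, ".lstm.Wx")]] <- glorot(2L * hid, 4L * hid)
    P[[paste0(g, ".lstm.Wh")]] <- glorot(hid, 4L * hid)
    P[[paste0(g, ".lstm.b")]] <- zeros(1L, 4L * hid)
    P[[paste0(g, ".Wout")]] <- glorot(2L * hid, config$embed_dim)
    P[[paste0(g, ".bout")]] <- zeros(1L, config$embed_dim)
  }
  concat_dim <- length(config$branches) * config$embed_dim
  P[["head.W1"]] <- glorot(concat_dim, config$head_hidden)
  P[["head.b1"]] <- zeros(1L, config$head_hidden)
  P[["head.W2"]] <- glorot(config$head_hidden, 6L)
  P[["head.b2"]] <- zeros(1L, 6L)
  P
}

#' Construct an untrained model
#'
#' Initializes all learnable parameters (Glorot-uniform weights, zero biases,
#' zero GIN epsilons) for the configured architecture.
#'
#' @param config An [allocator_config()].
#' @param seed Integer seed for the initialization (defaults to
#'   `config$seed`).
#' @return An object of class `allocator_model` holding `params` and
#'   `config`.
#' @export
allocator_model <- function(config = allocator_config(), seed = config$seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  structure(list(params = init_params(config), config = config),
            class = "allocator_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @exportS3Method base::print
print.allocator_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<allocator_model> branches: %s | gnn: %s | %s parameters\n",
              paste(x$config$branches, collapse = "+"), x$config$gnn_variant,
              format(n_par, big.mark = ",")))
  invisible(x)
}

# ---- tape-level forward passes --------------------------------------------

# Multi-head scaled dot-product self-attention over token matrix X (T x d).
fw_attention <- function(tape, X, heads, W0) {
  outs <- lapply(heads, function(hp) {
    Q <- ad_mm(tape, X, hp$Wq)
    K <- ad_mm(tape, X, hp$Wk)
    V <- ad_mm(tape, X, hp$Wv)
    dk <- ncol(ad_val(hp$Wk))
    S <- ad_softmax_rows(tape, ad_scale(tape, ad_mm(tape, Q, ad_t(tape, K)), 1 / sqrt(dk)))
    ad_mm(tape, S, V)
  })
  ad_mm(tape, ad_concat_cols(tape, outs), W0)
}

# Sequence branch over a whole mini-batch: the MLP layers and the final
# projection run on the stacked B x p matrix (one weight-gradient
# accumulation per batch rather than per sample); the token-level attention
# is inherently per-sample.
fw_seq_branch_batch <- function(tape, P, b, X, config, training) {
  pre <- function(n) P[[paste0(b, ".", n)]]
  B <- nrow(ad_val(X))
  h1 <- ad_linear(tape, X, pre("W1"), pre("b1"), relu = TRUE)
  h1 <- ad_dropout(tape, h1, config$dropout, training)
  h2 <- ad_linear(tape, h1, pre("W2"), pre("b2"))
  heads <- lapply(seq_len(config$n_heads), function(h) {
    list(Wq = P[[paste0(b, ".head", h, ".Wq")]],
         Wk = P[[paste0(b, ".head", h, ".Wk")]],
         Wv = P[[paste0(b, ".head", h, ".Wv")]])
  })
  pooled <- lapply(seq_len(B), function(i) {
    tok <- ad_reshape(tape, ad_row(tape, h2, i), config$tokens, config$token_dim)
    ad_mean_rows(tape, fw_attention(tape, tok, heads, pre("W0")))
  })
  stacked <- if (B == 1L) pooled[[1L]] else ad_concat_rows(tape, pooled)
  ad_linear(tape, stacked, pre("Wp"), pre("bp"))
}

fw_seq_branch <- function(tape, P, b, x, config, training) {
  fw_seq_branch_batch(tape, P, b, x, config, training)
}

# One GNN layer; `aggregate` maps a node-feature node H to the neighbor sum
# (default: sparse adjacency product; the interpretation module swaps in a
# masked aggregator).
fw_gnn_layer <- function(tape, P, prefix, H, gdata, config, training, aggregate) {
  if (config$gnn_variant == "gin") {
    agg <- if (is.null(aggregate)) {
      ad_gin_agg(tape, P[[paste0(prefix, "eps")]], H, gdata$A)
    } else {
      ad_add(tape,
             ad_scalar_shift_mul(tape, P[[paste0(prefix, "eps")]], H, shift = 1),
             aggregate(tape, H))
    }
    h1 <- ad_linear(tape, agg, P[[paste0(prefix, "W1")]],
                    P[[paste0(prefix, "b1")]], relu = TRUE)
    h1 <- ad_dropout(tape, h1, config$dropout, training)
    ad_linear(tape, h1, P[[paste0(prefix, "W2")]], P[[paste0(prefix, "b2")]],
              relu = TRUE)
  } else if (config$gnn_variant == "gcn") {
    ad_linear(tape, ad_mm(tape, gdata$A_norm, H), P[[paste0(prefix, "W")]],
              P[[paste0(prefix, "b")]], relu = TRUE)
  } else { # gat (single attention head per layer)
    HW <- ad_mm(tape, H, P[[paste0(prefix, "W")]])
    f1 <- ad_mm(tape, HW, P[[paste0(prefix, "a1")]])
    f2 <- ad_mm(tape, HW, P[[paste0(prefix, "a2")]])
    n <- gdata$n
    ones_row <- matrix(1, 1L, n)
    E <- ad_add(tape, ad_mm(tape, f1, ones_row),
                ad_t(tape, ad_mm(tape, f2, ones_row)))
    E <- ad_leakyrelu(tape, E, 0.2)
    alpha <- ad_softmax_rows(tape, ad_add(tape, E, gdata$att_mask))
    ad_relu(tape, ad_mm(tape, alpha, HW))
  }
}

# set2set readout: recurrent LSTM query over attention-weighted node sums.
fw_set2set <- function(tape, P, g, H, config) {
  hid <- ncol(ad_val(H))
  n <- nrow(ad_val(H))
  Wx <- P[[paste0(g, ".lstm.Wx")]]
  Wh <- P[[paste0(g, ".lstm.Wh")]]
  bb <- P[[paste0(g, ".lstm.b")]]
  q_star <- matrix(0, 1L, 2L * hid)
  h_prev <- matrix(0, 1L, hid)
  c_prev <- matrix(0, 1L, hid)
  for (step in seq_len(config$set2set_steps)) {
    gates <- ad_add(tape, ad_mm(tape, q_star, Wx),
                    ad_linear(tape, h_prev, Wh, bb))
    i_g <- ad_sigmoid(tape, ad_cols(tape, gates, 1:hid))
    f_g <- ad_sigmoid(tape, ad_cols(tape, gates, (hid + 1L):(2L * hid)))
    o_g <- ad_sigmoid(tape, ad_cols(tape, gates, (2L * hid + 1L):(3L * hid)))
    g_g <- ad_tanh(tape, ad_cols(tape, gates, (3L * hid + 1L):(4L * hid)))
    c_prev <- ad_add(tape, ad_mul(tape, f_g, c_prev), ad_mul(tape, i_g, g_g))
    h_prev <- ad_mul(tape, o_g, ad_tanh(tape, c_prev))
    # attention of the query over the node set
    e <- ad_mm(tape, H, ad_t(tape, h_prev))            # n x 1
    a <- ad_softmax_rows(tape, ad_t(tape, e))          # 1 x n
    r <- ad_mm(tape, a, H)                             # 1 x hid
    q_star <- ad_concat_cols(tape, list(h_prev, r))    # 1 x 2 hid
  }
  q_star
}

fw_graph_branch <- function(tape, P, g, gdata, config, training,
                            aggregate = NULL) {
  if (is.null(aggregate)) {
    aggregate <- function(tape, H) ad_mm(tape, gdata$A, H)
  }
  H <- gdata$X
  for (l in seq_len(config$gin_layers)) {
    H <- fw_gnn_layer(tape, P, paste0(g, ".l", l, "."), H, gdata, config,
                      training, aggregate)
  }
  pooled <- fw_set2set(tape, P, g, H, config)
  ad_linear(tape, pooled, P[[paste0(g, ".Wout")]], P[[paste0(g, ".bout")]])
}

# Graph branch over a whole mini-batch via disjoint-union batching: the GNN
# layers run once on the block-diagonal adjacency and stacked node features;
# the set2set readout then pools each graph's rows separately.
fw_graph_branch_batch <- function(tape, P, g, samples, config, training) {
  gl <- lapply(samples, `[[`, g)
  ns <- vapply(gl, `[[`, integer(1), "n")
  ends <- cumsum(ns)
  starts <- ends - ns + 1L
  A_big <- Matrix::bdiag(lapply(gl, `[[`,
                                if (config$gnn_variant == "gcn") "A_norm" else "A"))
  big <- list(A = A_big, A_norm = A_big,
              X = do.call(rbind, lapply(gl, `[[`, "X")))
  H <- big$X
  for (l in seq_len(config$gin_layers)) {
    H <- fw_gnn_layer(tape, P, paste0(g, ".l", l, "."), H, big, config,
                      training, aggregate = NULL)
  }
  parts <- ad_split_rows(tape, H, starts, ends)
  pooled <- lapply(parts, function(Hi) fw_set2set(tape, P, g, Hi, config))
  stacked <- if (length(pooled) == 1L) pooled[[1L]] else ad_concat_rows(tape, pooled)
  ad_linear(tape, stacked, P[[paste0(g, ".Wout")]], P[[paste0(g, ".bout")]])
}

fw_head <- function(tape, P, xcat, config, training) {
  h1 <- ad_linear(tape, xcat, P[["head.W1"]], P[["head.b1"]])
  h1 <- ad_dropout(tape, h1, config$dropout, training)
  ad_linear(tape, h1, P[["head.W2"]], P[["head.b2"]])
}

# Full forward to logits (B x 6) for a list of prepared samples. Sequence
# branches and the head run batched; graph branches run per sample and are
# stacked. `graph_aggregates` (used by the interpretation module, batch of
# one) swaps in a masked neighbor aggregation per branch.
fw_allocator_batch <- function(tape, P, samples, config, training,
                               graph_aggregates = NULL) {
  B <- length(samples)
  outs <- list()
  for (b in config$branches) {
    outs[[b]] <- if (b %in% c("kmer", "cksnap")) {
      X <- do.call(rbind, lapply(samples, `[[`, b))
      fw_seq_branch_batch(tape, P, b, X, config, training)
    } else if (is.null(graph_aggregates[[b]]) &&
               config$gnn_variant %in% c("gin", "gcn")) {
      fw_graph_branch_batch(tape, P, b, samples, config, training)
    } else {
      rows <- lapply(samples, function(s) {
        fw_graph_branch(tape, P, b, s[[b]], config, training,
                        aggregate = graph_aggregates[[b]])
      })
      if (B == 1L) rows[[1L]] else ad_concat_rows(tape, rows)
    }
  }
  fw_head(tape, P, ad_concat_cols(tape, outs), config, training)
}

# Single-sample forward to logits (1 x 6).
fw_allocator <- function(tape, P, sample, config, training,
                         graph_aggregates = NULL) {
  fw_allocator_batch(tape, P, list(sample), config, training,
                     graph_aggregates = graph_aggregates)
}

# ---- sample preparation ----------------------------------------------------

graph_data <- function(sequence, structure, config) {
  g <- dotbracket_to_graph(sequence, structure)
  A <- graph_adjacency(g)
  out <- list(graph = g, A = A, X = g$node_features, n = g$n_nodes)
  if (config$gnn_variant == "gcn") {
    deg <- Matrix::rowSums(A) + 1
    Dm <- Matrix::Diagonal(x = 1 / sqrt(deg))
    out$A_norm <- Dm %*% (A + Matrix::Diagonal(g$n_nodes)) %*% Dm
  } else if (config$gnn_variant == "gat") {
    mask <- matrix(-1e9, g$n_nodes, g$n_nodes)
    Ad <- as.matrix(A)
    mask[Ad > 0] <- 0
    diag(mask) <- 0
    out$att_mask <- mask
  }
  out
}

# Precompute per-record model inputs. When only one structure source is
# available it feeds both graph branches (logged once).
prepare_samples <- function(records, config, require_labels = FALSE) {
  needs_graph <- any(c("graph1", "graph2") %in% config$branches)
  has_s2 <- "structure2" %in% names(records) && !all(is.na(records$structure2))
  if (needs_graph && !"structure" %in% names(records)) {
    stop("data error: records lack a 'structure' column; run a folder first",
         call. = FALSE)
  }
  if (needs_graph && !has_s2 && "graph2" %in% config$branches) {
    message("single structure source: using 'structure' for both graph branches")
  }
  Y <- if (require_labels) label_matrix(records) else NULL
  lapply(seq_len(nrow(records)), function(i) {
    s <- list(id = records$id[i])
    if ("kmer" %in% config$branches) {
      s$kmer <- matrix(kmer_frequencies(records$sequence[i]), 1L)
    }
    if ("cksnap" %in% config$branches) {
      s$cksnap <- matrix(cksnap_frequencies(records$sequence[i]), 1L)
    }
    if ("graph1" %in% config$branches) {
      s$graph1 <- graph_data(records$sequence[i], records$structure[i], config)
    }
    if ("graph2" %in% config$branches) {
      db2 <- if (has_s2) records$structure2[i] else records$structure[i]
      s$graph2 <- graph_data(records$sequence[i], db2, config)
    }
    if (!is.null(Y)) s$y <- Y[i, ]
    s
  })
}

# ---- user-facing single operations ----------------------------------------

#' Multi-head scaled dot-product self-attention
#'
#' Computes `head_i = softmax(Q_i K_i^T / sqrt(d_k)) V_i` with
#' `Q_i = X W_i^Q`, `K_i = X W_i^K`, `V_i = X W_i^V`, concatenates the heads
#' and applies the output projection `W_0`.
#'
#' @param X Token-feature matrix (T x d).
#' @param params List with `heads` (a list of lists carrying `Wq`, `Wk`,
#'   `Wv`) and `W0`.
#' @return Matrix of the same number of rows as `X`.
#' @export
multi_head_self_attention <- function(X, params) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  dk <- ncol(params$heads[[1L]]$Wk)
  if (ncol(X) != nrow(params$heads[[1L]]$Wq)) {
    stop("configuration error: attention input width does not match projections",
         call. = FALSE)
  }
  tape <- ad_tape()
  ad_val(fw_attention(tape, X, params$heads, params$W0))
}

#' Sequence-branch forward pass
#'
#' Runs one composition vector through a sequence-context extractor of a
#' model (MLP projection, tokenized multi-head self-attention, mean pooling,
#' linear projection) in evaluation mode.
#'
#' @param features Numeric vector: length 1364 for the `"kmer"` branch, 96
#'   for `"cksnap"`.
#' @param model An [allocator_model()] or fitted model.
#' @param branch `"kmer"` or `"cksnap"`.
#' @return Numeric vector of length `embed_dim` (128 by default).
#' @export
sequence_extractor_forward <- function(features, model, branch = c("kmer", "cksnap")) {
  branch <- match.arg(branch)
  config <- model$config
  want <- if (branch == "kmer") config$kmer_dim else config$cksnap_dim
  if (length(features) != want) {
    stop(sprintf("configuration error: branch '%s' expects %d features, got %d",
                 branch, want, length(features)), call. = FALSE)
  }
  tape <- ad_tape()
  out <- fw_seq_branch(tape, model$params, branch, matrix(features, 1L),
                       config, training = FALSE)
  as.numeric(ad_val(out))
}

#' One GIN layer (explicit form)
#'
#' `h_v' = MLP((1 + eps) * h_v + sum over neighbors u of h_u)`, with the
#' neighborhood taken over the union of adjacent and base-pair edges.
#'
#' @param graph An `rna_graph`.
#' @param h Node-representation matrix (one row per node).
#' @param eps Scalar epsilon.
#' @param mlp Update function applied to the aggregated matrix (default
#'   identity).
#' @return Updated node matrix.
#' @export
gin_layer_forward <- function(graph, h, eps = 0, mlp = identity) {
  stopifnot(nrow(h) == graph$n_nodes)
  A <- graph_adjacency(graph)
  mlp(as.matrix((1 + eps) * h + A %*% h))
}

#' set2set graph readout
#'
#' Permutation-invariant pooling: for a fixed number of processing steps an
#' LSTM emits a query, attention of the query over the node embeddings forms
#' a weighted sum, and query and sum are concatenated into the next LSTM
#' input. Output dimensionality is twice the node-embedding width.
#'
#' @param node_embeddings Matrix (n nodes x d).
#' @param processing_steps Number of recurrent steps (default 3).
#' @param params Optional LSTM weights (`Wx`, `Wh`, `b`); drawn from `seed`
#'   when omitted.
#' @param seed Seed used when `params` is `NULL`.
#' @return Numeric vector of length `2 * d`.
#' @export
set2set_pool <- function(node_embeddings, processing_steps = 3L, params = NULL,
                         seed = 1L) {
  if (!is.matrix(node_embeddings) || nrow(node_embeddings) < 1L) {
    stop("contract violation: set2set needs at least one node", call. = FALSE)
  }
  d <- ncol(node_embeddings)
  if (is.null(params)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    params <- list(Wx = glorot(2L * d, 4L * d), Wh = glorot(d, 4L * d),
                   b = zeros(1L, 4L * d))
  }
  P <- list("s.lstm.Wx" = params$Wx, "s.lstm.Wh" = params$Wh,
            "s.lstm.b" = params$b)
  tape <- ad_tape()
  cfg <- list(set2set_steps = as.integer(processing_steps))
  as.numeric(ad_val(fw_set2set(tape, P, "s", node_embeddings, cfg)))
}

#' Graph-branch forward pass
#'
#' Stacked GNN layers followed by set2set readout and a linear projection to
#' the branch embedding, in evaluation mode.
#'
#' @param graph An `rna_graph`.
#' @param model An [allocator_model()].
#' @param branch `"graph1"` or `"graph2"`.
#' @return Numeric vector of length `embed_dim`.
#' @export
graph_extractor_forward <- function(graph, model, branch = c("graph1", "graph2")) {
  branch <- match.arg(branch)
  config <- model$config
  A <- graph_adjacency(graph)
  gdata <- list(graph = graph, A = A, X = graph$node_features, n = graph$n_nodes)
  if (config$gnn_variant == "gcn") {
    deg <- Matrix::rowSums(A) + 1
    Dm <- Matrix::Diagonal(x = 1 / sqrt(deg))
    gdata$A_norm <- Dm %*% (A + Matrix::Diagonal(graph$n_nodes)) %*% Dm
  } else if (config$gnn_variant == "gat") {
    mask <- matrix(-1e9, graph$n_nodes, graph$n_nodes)
    mask[as.matrix(A) > 0] <- 0
    diag(mask) <- 0
    gdata$att_mask <- mask
  }
  tape <- ad_tape()
  out <- fw_graph_branch(tape, model$params, branch, gdata, config,
                         training = FALSE)
  as.numeric(ad_val(out))
}

#' Two-layer sigmoid prediction head
#'
#' `sigmoid(W2 (W1 x + b1) + b2)`.
#'
#' @param x_concat Numeric vector (concatenated branch embeddings).
#' @param params List with `W1`, `b1`, `W2`, `b2`.
#' @return Numeric probability vector strictly inside (0, 1).
#' @export
prediction_head <- function(x_concat, params) {
  if (length(x_concat) != nrow(params$W1)) {
    stop("configuration error: head input width mismatch", call. = FALSE)
  }
  z <- matrix(x_concat, 1L) %*% params$W1
  z <- sweep(z, 2L, as.numeric(params$b1), "+")
  z <- z %*% params$W2
  z <- sweep(z, 2L, as.numeric(params$b2), "+")
  as.numeric(1 / (1 + exp(-z)))
}

#' Full multi-view forward pass for one record
#'
#' Runs the enabled branches on a prepared record and returns the six
#' localization probabilities in [localization_labels()] order.
#'
#' @param model An `allocator_model` or `allocator_fit`.
#' @param record One-row records tibble with sequence and (for graph
#'   branches) structure columns.
#' @return Named numeric vector of six probabilities.
#' @export
allocator_forward <- function(model, record) {
  model <- as_allocator_model(model)
  sample <- prepare_samples(record, model$config)[[1L]]
  tape <- ad_tape()
  z <- ad_val(fw_allocator(tape, model$params, sample, model$config,
                           training = FALSE))
  stats::setNames(as.numeric(1 / (1 + exp(-z))), model$config$label_order)
}

as_allocator_model <- function(x) {
  if (inherits(x, "allocator_fit")) {
    structure(list(params = x$params, config = x$config),
              class = "allocator_model")
  } else if (inherits(x, "allocator_model")) {
    x
  } else {
    stop("configuration error: not an allocator model", call. = FALSE)
  }
}

# ---- checkpointing ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes weights, full configuration and label order to a versioned JSON
#' file.
#'
#' @param model An `allocator_model` or `allocator_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  model <- as_allocator_model(model)
  payload <- list(
    format = "rnaloc-checkpoint", version = model$config$version,
    config = unclass(model$config),
    params = lapply(model$params, function(m) list(dim = dim(m), data = as.numeric(m)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' Refuses checkpoints whose declared format or label order does not match
#' this package.
#'
#' @param path Checkpoint path written by [write_model()].
#' @return An `allocator_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "rnaloc-checkpoint")) {
    stop("configuration error: not an rnaloc checkpoint", call. = FALSE)
  }
  cfg <- payload$config
  if (!identical(as.character(cfg$label_order), localization_labels())) {
    stop("configuration error: checkpoint label order mismatch", call. = FALSE)
  }
  args <- cfg[intersect(names(formals(allocator_config)), names(cfg))]
  config <- do.call(allocator_config, args)
  params <- lapply(payload$params, function(p) matrix(p$data, p$dim[1L], p$dim[2L]))
  structure(list(params = params, config = config), class = "allocator_model")
}
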