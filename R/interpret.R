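# Edge-importance interpretation: a sigmoid-squashed mask over the edges of
# one record's structure graph is optimized to keep the model's probability
# for the record's positive labels high while penalizing mask size (L1) and
# mask entropy. This is the classic edge-mask explanation objective for
# graph neural networks, implemented natively; it supports the default GIN
# aggregation.

# Directed-edge bookkeeping for masked aggregation. One mask value per
# undirected edge, shared by both directions (so the two directional values
# are identical and their max is the shared value).
masked_edge_data <- function(gdata) {
  e <- gdata$graph$edges
  m <- nrow(e)
  src <- c(e$from, e$to)
  dst <- c(e$to, e$from)
  n_dir <- 2L * m
  list(
    n_und = m,
    expand = Matrix::sparseMatrix(i = seq_len(n_dir), j = rep(seq_len(m), 2L),
                                  x = 1, dims = c(n_dir, m)),
    S_src = Matrix::sparseMatrix(i = seq_len(n_dir), j = src, x = 1,
                                 dims = c(n_dir, gdata$n)),
    T_dst = Matrix::sparseMatrix(i = dst, j = seq_len(n_dir), x = 1,
                                 dims = c(gdata$n, n_dir))
  )
}

# Forward pass with a fixed or learnable edge mask on the chosen graph
# branch; returns the logits node.
masked_forward <- function(tape, params, sample, config, branch, med, mask_node) {
  aggregate <- function(tape, H) {
    msg <- ad_rowscale(tape, ad_mm(tape, med$expand, mask_node),
                       ad_mm(tape, med$S_src, H))
    ad_mm(tape, med$T_dst, msg)
  }
  aggs <- stats::setNames(list(aggregate), branch)
  fw_allocator(tape, params, sample, config, training = FALSE,
               graph_aggregates = aggs)
}

#' Localization probabilities under an edge mask
#'
#' Runs the model with the given per-edge mask applied to the neighbor
#' aggregation of one graph branch. With an all-ones mask this equals the
#' unmasked forward pass.
#'
#' @param model An `allocator_model` or `allocator_fit` (GIN variant).
#' @param record One-row records tibble.
#' @param mask Numeric vector in `[0, 1]`, one value per (undirected) edge
#'   of the record's graph, in the edge order of `dotbracket_to_graph()`.
#' @param branch Graph branch to mask (default `"graph1"`).
#' @return Named numeric vector of six probabilities.
#' @export
masked_record_probs <- function(model, record, mask, branch = "graph1") {
  model <- as_allocator_model(model)
  if (model$config$gnn_variant != "gin") {
    stop("configuration error: edge masking supports the GIN variant", call. = FALSE)
  }
  sample <- prepare_samples(record, model$config)[[1L]]
  med <- masked_edge_data(sample[[branch]])
  if (length(mask) != med$n_und) {
    stop("configuration error: mask length does not match edge count", call. = FALSE)
  }
  tape <- ad_tape()
  z <- ad_val(masked_forward(tape, model$params, sample, model$config, branch,
                             med, matrix(mask, ncol = 1L)))
  stats::setNames(as.numeric(1 / (1 + exp(-z))), model$config$label_order)
}

#' Learn per-edge importance scores for one record
#'
#' Optimizes mask logits with Adam so that the masked model keeps predicting
#' the record's positive labels (its labelled compartments, or its thresholded
#' predictions when unlabelled) while the mask stays small and crisp:
#' `loss = -sum_j log p_j  +  size_weight * mean(mask)  +
#' entropy_weight * mean(binary entropy of mask)`.
#'
#' @param model A trained `allocator_fit` or `allocator_model` (GIN
#'   variant).
#' @param record One-row records tibble with a structure column.
#' @param steps Optimization steps (default 100).
#' @param seed Seed for the mask initialization.
#' @param branch Graph branch to explain (default `"graph1"`).
#' @param size_weight L1 penalty weight on the mask (default 0.005).
#' @param entropy_weight Entropy penalty weight (default 0.1).
#' @param learning_rate Adam learning rate for the mask (default 0.05).
#' @return Tibble with one row per undirected edge: `from`, `to` (1-based
#'   positions), `type` (`adjacent`/`base_pair`) and `score` in `[0, 1]`.
#' @export
learn_edge_mask <- function(model, record, steps = 100L, seed = 1L,
                            branch = "graph1", size_weight = 0.005,
                            entropy_weight = 0.1, learning_rate = 0.05) {
  model <- as_allocator_model(model)
  config <- model$config
  if (config$gnn_variant != "gin") {
    stop("configuration error: edge masking supports the GIN variant", call. = FALSE)
  }
  if (!branch %in% config$branches) {
    stop("configuration error: branch not enabled in this model", call. = FALSE)
  }
  sample <- prepare_samples(record, config)[[1L]]
  med <- masked_edge_data(sample[[branch]])

  pos <- which(as.numeric(record[1L, intersect(localization_labels(),
                                               names(record))] |> unlist()) == 1L)
  if (length(pos) == 0L) {
    probs <- allocator_forward(model, record)
    pos <- which(binarize(probs, config$threshold) == 1L)
    if (length(pos) == 0L) pos <- which.max(probs)
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  theta <- list(theta = matrix(stats::rnorm(med$n_und, 1, 0.5), ncol = 1L))
  state <- adam_init(theta)
  for (step in seq_len(steps)) {
    tape <- ad_tape()
    tnode <- ad_var(tape, theta$theta)
    mask <- ad_sigmoid(tape, tnode)
    z <- masked_forward(tape, model$params, sample, config, branch, med, mask)
    zpos <- ad_cols(tape, z, pos)
    fit <- ad_bce_logits(tape, zpos, matrix(1, 1L, length(pos)))
    size_pen <- ad_scale(tape, ad_sum(tape, mask), size_weight / med$n_und)
    one_minus <- ad_add(tape, ad_scale(tape, mask, -1), matrix(1, med$n_und, 1L))
    ent <- ad_scale(tape,
                    ad_sum(tape, ad_add(tape,
                                        ad_mul(tape, mask, ad_log(tape, mask)),
                                        ad_mul(tape, one_minus, ad_log(tape, one_minus)))),
                    -entropy_weight / med$n_und)
    loss <- ad_add(tape, ad_add(tape, fit, size_pen), ent)
    ad_backward(tape, loss)
    upd <- adam_step(theta, list(theta = tnode$grad), state, learning_rate)
    theta <- upd$params; state <- upd$state
  }
  scores <- as.numeric(1 / (1 + exp(-theta$theta)))
  e <- sample[[branch]]$graph$edges
  tibble::tibble(from = e$from, to = e$to, type = e$type, score = scores)
}

#' Select the top-k most important edges
#'
#' Descending by score; ties broken by the smaller `from`, then smaller
#' `to`, for determinism.
#'
#' @param scores Tibble from [learn_edge_mask()].
#' @param k Number of edges to keep (default 300).
#' @return The k highest-scoring rows, in rank order.
#' @export
top_edges <- function(scores, k = 300L) {
  stopifnot(k >= 1L)
  ord <- order(-scores$score, scores$from, scores$to)
  scores[utils::head(ord, k), ]
}

#' Extract substructures from important edges
#'
#' Builds the subgraph induced by the selected edges and reports its
#' connected components with at least `min_bases` bases. Edges are rendered
#' in the field's notation: `==` for base pairing, \eqn{\leftrightarrow}
#' for backbone neighbors; positions are 1-based.
#'
#' @param graph An `rna_graph`.
#' @param edges Tibble with `from`, `to`, `type` rows belonging to the
#'   graph (e.g. from [top_edges()]).
#' @param min_bases Minimum component size to keep (default 3).
#' @return Tibble with one row per substructure: `substructure` (index),
#'   `n_bases`, `positions` (list of 1-based positions), `bases` (their
#'   base string), `notation` (edge rendering).
#' @export
extract_substructures <- function(graph, edges, min_bases = 3L) {
  chars <- seq_chars(graph$sequence)
  if (nrow(edges) == 0L) {
    return(tibble::tibble(substructure = integer(0), n_bases = integer(0),
                          positions = list(), bases = character(0),
                          notation = character(0)))
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes))
  )
  comp <- igraph::components(ig)
  membership <- stats::setNames(comp$membership, igraph::V(ig)$name)
  keep <- which(comp$csize >= min_bases)
  rows <- lapply(seq_along(keep), function(kk) {
    cid <- keep[kk]
    pos <- sort(as.integer(names(membership)[membership == cid]))
    in_comp <- edges$from %in% pos & edges$to %in% pos
    note <- vapply(which(in_comp), function(r) {
      sym <- if (edges$type[r] == "base_pair") "==" else "\u2194"
      sprintf("%s(%d)%s%s(%d)", chars[edges$from[r]], edges$from[r], sym,
              chars[edges$to[r]], edges$to[r])
    }, character(1))
    tibble::tibble(substructure = kk, n_bases = length(pos),
                   positions = list(pos),
                   bases = paste(chars[pos], collapse = ""),
                   notation = paste(note, collapse = ", "))
  })
  dplyr::bind_rows(rows)
}

#' Importance of the four node-feature groups
#'
#' Occlusion analysis: each encoding group (one-hot, NCP, EIIP, ANF) is
#' zeroed in turn in the node-feature matrices and the resulting drop in
#' predicted probability, averaged over records, is reported per
#' localization label. Deterministic.
#'
#' @param model An `allocator_model` or `allocator_fit` with at least one
#'   graph branch.
#' @param records Records tibble with structure column(s).
#' @return Tibble with columns `group`, `label`, `importance` (mean
#'   probability drop when the group is occluded).
#' @export
node_feature_importance <- function(model, records) {
  model <- as_allocator_model(model)
  config <- model$config
  groups <- list(onehot = 1:5, ncp = 6:8, eiip = 9L, anf = 10L)
  samples <- prepare_samples(records, config)
  gbranches <- intersect(c("graph1", "graph2"), config$branches)
  if (length(gbranches) == 0L) {
    stop("configuration error: no graph branch enabled", call. = FALSE)
  }
  run <- function(s) {
    tape <- ad_tape()
    z <- ad_val(fw_allocator(tape, model$params, s, config, training = FALSE))
    as.numeric(1 / (1 + exp(-z)))
  }
  base <- t(vapply(samples, run, numeric(6L)))
  rows <- lapply(names(groups), function(gname) {
    occluded <- t(vapply(samples, function(s) {
      s2 <- s
      for (gb in gbranches) {
        s2[[gb]]$X[, groups[[gname]]] <- 0
      }
      run(s2)
    }, numeric(6L)))
    tibble::tibble(group = gname, label = localization_labels(),
                   importance = colMeans(base - occluded))
  })
  dplyr::bind_rows(rows)
}
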