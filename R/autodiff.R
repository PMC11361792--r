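# Minimal reverse-mode automatic differentiation over base-R matrices.
#
# A tape records nodes in creation order; backward() replays it in reverse.
# Nodes are environments holding $val (a base matrix), $grad (accumulated,
# same shape) and $backward (closure distributing the node's gradient to its
# parents). Plain matrices (including Matrix sparse matrices) passed to ops
# are treated as constants and receive no gradient. All values are 2-D;
# scalars are 1x1 matrices.

# The tape is a reverse-linked chain of nodes: O(1) push, and backward
# walks the chain from the most recent node, which is reverse topological
# order by construction.
ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$last <- NULL
  tape
}

ad_is_node <- function(x) is.environment(x)

ad_val <- function(x) if (is.environment(x)) x$val else x

ad_push <- function(tape, val, backward = NULL) {
  # force val before linking: a lazily evaluated val expression may itself
  # push nodes onto the tape
  force(val)
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$backward <- backward
  node$prev <- tape$last
  tape$last <- node
  node
}

# A leaf with respect to which gradients are wanted (parameter).
ad_var <- function(tape, val) ad_push(tape, val)

ad_accum <- function(x, g) {
  if (ad_is_node(x)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

# Run backprop from a (scalar) root node.
ad_backward <- function(tape, root) {
  root$grad <- array(1, dim = dim(root$val))
  node <- tape$last
  while (!is.null(node)) {
    if (!is.null(node$grad) && !is.null(node$backward)) {
      node$backward(node$grad)
    }
    node <- node$prev
  }
  invisible(NULL)
}

# ---- ops -------------------------------------------------------------------

ad_mm <- function(tape, a, b) {
  A <- ad_val(a); B <- ad_val(b)
  out <- ad_push(tape, as.matrix(A %*% B))
  out$backward <- function(g) {
    if (ad_is_node(a)) {
      ga <- if (inherits(B, "Matrix")) Matrix::tcrossprod(g, B) else tcrossprod(g, B)
      ad_accum(a, as.matrix(ga))
    }
    if (ad_is_node(b)) {
      gb <- if (inherits(A, "Matrix")) Matrix::crossprod(A, g) else crossprod(A, g)
      ad_accum(b, as.matrix(gb))
    }
  }
  out
}

# Fused affine layer x %*% W + b (bias broadcast over rows) with optional
# ReLU, as a single tape node: the hot path of every MLP in the model.
ad_linear <- function(tape, x, W, b, relu = FALSE) {
  X <- ad_val(x); Wv <- ad_val(W); bv <- ad_val(b)
  Z <- X %*% Wv
  Z <- sweep(Z, 2L, bv[1L, ], "+")
  val <- if (relu) pmax(Z, 0) else Z
  out <- ad_push(tape, val)
  out$backward <- function(g) {
    if (relu) g <- g * (Z > 0)
    if (ad_is_node(x)) ad_accum(x, tcrossprod(g, Wv))
    if (ad_is_node(W)) ad_accum(W, crossprod(X, g))
    if (ad_is_node(b)) ad_accum(b, matrix(colSums(g), 1L))
  }
  out
}

# a + b; b may be a 1 x ncol(a) row vector (bias broadcast over rows).
ad_add <- function(tape, a, b) {
  A <- ad_val(a); B <- ad_val(b)
  broadcast <- nrow(B) == 1L && nrow(A) > 1L
  val <- if (broadcast) sweep(A, 2L, B[1L, ], "+") else A + B
  out <- ad_push(tape, val)
  out$backward <- function(g) {
    if (ad_is_node(a)) ad_accum(a, g)
    if (ad_is_node(b)) {
      ad_accum(b, if (broadcast) matrix(colSums(g), 1L) else g)
    }
  }
  out
}

# Elementwise product, equal shapes.
ad_mul <- function(tape, a, b) {
  A <- ad_val(a); B <- ad_val(b)
  out <- ad_push(tape, A * B)
  out$backward <- function(g) {
    if (ad_is_node(a)) ad_accum(a, g * B)
    if (ad_is_node(b)) ad_accum(b, g * A)
  }
  out
}

# Scale each row i of an m x d matrix by scale[i, 1].
ad_rowscale <- function(tape, scale, mat) {
  S <- ad_val(scale); M <- ad_val(mat)
  s <- S[, 1L]
  out <- ad_push(tape, M * s)
  out$backward <- function(g) {
    if (ad_is_node(scale)) ad_accum(scale, matrix(rowSums(g * M), ncol = 1L))
    if (ad_is_node(mat)) ad_accum(mat, g * s)
  }
  out
}

# Fused GIN aggregation (1 + eps) * H + A %*% H with learnable 1x1 eps and
# constant (sparse) symmetric adjacency A.
ad_gin_agg <- function(tape, eps, H, A) {
  E <- ad_val(eps); Hv <- ad_val(H)
  k <- 1 + E[1L, 1L]
  AH <- as.matrix(A %*% Hv)
  out <- ad_push(tape, k * Hv + AH)
  out$backward <- function(g) {
    if (ad_is_node(eps)) ad_accum(eps, matrix(sum(g * Hv), 1L, 1L))
    if (ad_is_node(H)) {
      ad_accum(H, k * g + as.matrix(Matrix::crossprod(A, g)))
    }
  }
  out
}

# (shift + s) * M with s a 1x1 node (learnable scalar, e.g. GIN epsilon).
ad_scalar_shift_mul <- function(tape, s, mat, shift = 1) {
  S <- ad_val(s); M <- ad_val(mat)
  k <- shift + S[1L, 1L]
  out <- ad_push(tape, k * M)
  out$backward <- function(g) {
    if (ad_is_node(s)) ad_accum(s, matrix(sum(g * M), 1L, 1L))
    if (ad_is_node(mat)) ad_accum(mat, k * g)
  }
  out
}

ad_scale <- function(tape, a, k) {
  out <- ad_push(tape, ad_val(a) * k)
  out$backward <- function(g) if (ad_is_node(a)) ad_accum(a, g * k)
  out
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-ad_val(a)))
  out <- ad_push(tape, s)
  out$backward <- function(g) if (ad_is_node(a)) ad_accum(a, g * s * (1 - s))
  out
}

# Elementwise log with clamping away from zero.
ad_log <- function(tape, a, floor = 1e-12) {
  A <- pmax(ad_val(a), floor)
  out <- ad_push(tape, log(A))
  out$backward <- function(g) if (ad_is_node(a)) ad_accum(a, g / A)
  out
}

ad_tanh <- function(tape, a) {
  v <- tanh(ad_val(a))
  out <- ad_push(tape, v)
  out$backward <- function(g) if (ad_is_node(a)) ad_accum(a, g * (1 - v^2))
  out
}

ad_relu <- function(tape, a) {
  A <- ad_val(a)
  out <- ad_push(tape, pmax(A, 0))
  out$backward <- function(g) if (ad_is_node(a)) ad_accum(a, g * (A > 0))
  out
}

ad_leakyrelu <- function(tape, a, alpha = 0.2) {
  A <- ad_val(a)
  out <- ad_push(tape, ifelse(A > 0, A, alpha * A))
  out$backward <- function(g) {
    if (ad_is_node(a)) ad_accum(a, g * ifelse(A > 0, 1, alpha))
  }
  out
}

# Row-wise softmax; each row becomes a probability distribution.
ad_softmax_rows <- function(tape, a) {
  A <- ad_val(a)
  m <- A - apply(A, 1L, max)
  e <- exp(m)
  s <- e / rowSums(e)
  out <- ad_push(tape, s)
  out$backward <- function(g) {
    if (ad_is_node(a)) ad_accum(a, (g - rowSums(g * s)) * s)
  }
  out
}

ad_mean_rows <- function(tape, a) {
  A <- ad_val(a)
  m <- nrow(A)
  out <- ad_push(tape, matrix(colMeans(A), 1L))
  out$backward <- function(g) {
    if (ad_is_node(a)) {
      ad_accum(a, matrix(g[1L, ], m, ncol(A), byrow = TRUE) / m)
    }
  }
  out
}

ad_sum <- function(tape, a) {
  A <- ad_val(a)
  out <- ad_push(tape, matrix(sum(A), 1L, 1L))
  out$backward <- function(g) {
    if (ad_is_node(a)) ad_accum(a, array(g[1L, 1L], dim = dim(A)))
  }
  out
}

ad_t <- function(tape, a) {
  out <- ad_push(tape, t(ad_val(a)))
  out$backward <- function(g) if (ad_is_node(a)) ad_accum(a, t(g))
  out
}

ad_reshape <- function(tape, a, nrow, ncol) {
  A <- ad_val(a)
  # R fills column-major; reshape row-major so token t = row t of the output
  # is the t-th contiguous chunk of the flattened input row.
  out <- ad_push(tape, matrix(as.vector(t(A)), nrow, ncol, byrow = TRUE))
  out$backward <- function(g) {
    if (ad_is_node(a)) {
      ad_accum(a, matrix(as.vector(t(g)), nrow(A), ncol(A), byrow = TRUE))
    }
  }
  out
}

ad_cols <- function(tape, a, idx) {
  A <- ad_val(a)
  out <- ad_push(tape, A[, idx, drop = FALSE])
  out$backward <- function(g) {
    if (ad_is_node(a)) {
      G <- array(0, dim = dim(A))
      G[, idx] <- g
      ad_accum(a, G)
    }
  }
  out
}

ad_row <- function(tape, a, i) {
  A <- ad_val(a)
  out <- ad_push(tape, A[i, , drop = FALSE])
  out$backward <- function(g) {
    if (ad_is_node(a)) {
      G <- array(0, dim = dim(A))
      G[i, ] <- g
      ad_accum(a, G)
    }
  }
  out
}

# Split a matrix node into per-block row slices (disjoint-union graph
# batching). The children stash their incoming gradients; the first child,
# which backward() reaches last, assembles them into a single full-size
# gradient for the parent. Every child must be consumed downstream.
ad_split_rows <- function(tape, a, starts, ends) {
  A <- ad_val(a)
  shared <- new.env(parent = emptyenv())
  shared$pieces <- vector("list", length(starts))
  lapply(seq_along(starts), function(j) {
    out <- ad_push(tape, A[starts[j]:ends[j], , drop = FALSE])
    out$backward <- function(g) {
      shared$pieces[[j]] <- g
      if (j == 1L && ad_is_node(a)) {
        G <- array(0, dim = dim(A))
        for (k in seq_along(starts)) {
          if (!is.null(shared$pieces[[k]])) {
            G[starts[k]:ends[k], ] <- shared$pieces[[k]]
          }
        }
        ad_accum(a, G)
      }
    }
    out
  })
}

ad_concat_rows <- function(tape, parts) {
  vals <- lapply(parts, ad_val)
  heights <- vapply(vals, nrow, integer(1))
  out <- ad_push(tape, do.call(rbind, vals))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  out$backward <- function(g) {
    for (j in seq_along(parts)) {
      if (ad_is_node(parts[[j]])) {
        ad_accum(parts[[j]], g[starts[j]:ends[j], , drop = FALSE])
      }
    }
  }
  out
}

ad_concat_cols <- function(tape, parts) {
  vals <- lapply(parts, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  out <- ad_push(tape, do.call(cbind, vals))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  out$backward <- function(g) {
    for (j in seq_along(parts)) {
      if (ad_is_node(parts[[j]])) {
        ad_accum(parts[[j]], g[, starts[j]:ends[j], drop = FALSE])
      }
    }
  }
  out
}

# Numerically stable binary cross-entropy on logits, summed over entries:
#   sum_j (1-y_j) softplus(z_j) + y_j w_j softplus(-z_j)
# which for w = 1 equals -sum_j [y log p + (1-y) log(1-p)]. `w` optionally
# reweights the positive term per entry.
ad_bce_logits <- function(tape, z, y, w = NULL) {
  Z <- ad_val(z)
  if (is.null(w)) w <- 1
  sp_pos <- pmax(Z, 0) + log1p(exp(-abs(Z)))   # softplus(z)  = -log(1-p)
  sp_neg <- pmax(-Z, 0) + log1p(exp(-abs(Z)))  # softplus(-z) = -log(p)
  out <- ad_push(tape, matrix(sum((1 - y) * sp_pos + y * w * sp_neg), 1L, 1L))
  out$backward <- function(g) {
    if (ad_is_node(z)) {
      s <- 1 / (1 + exp(-Z))
      ad_accum(z, g[1L, 1L] * ((1 - y) * s - y * w * (1 - s)))
    }
  }
  out
}

# Inverted dropout; identity when not training. Uses the session RNG so a
# seeded training run is reproducible.
ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  A <- ad_val(a)
  mask <- (matrix(stats::runif(length(A)), nrow(A)) >= rate) / (1 - rate)
  ad_mul(tape, a, mask)
}
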