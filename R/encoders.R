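#' @importFrom rlang .data
#' @importFrom stats runif setNames
#' @importFrom utils head
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Canonical localization label order
#'
#' All label vectors, probability vectors and metric tables in rnaloc use this
#' fixed compartment order.
#'
#' @return Character vector of the six compartment names.
#' @export
localization_labels <- function() {
  c("nucleus", "exosome", "cytosol", "ribosome", "membrane", "er")
}

#' Sanitize a raw RNA/DNA sequence
#'
#' Uppercases, maps T to U (DNA input), and replaces any character outside
#' A/C/G/U with N. The returned string always has the same length as the
#' input.
#'
#' @param raw Non-empty character scalar.
#' @return Sanitized sequence over the alphabet A, C, G, U, N.
#' @examples
#' sanitize_sequence("acgt") # "ACGU"
#' @export
sanitize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L) {
    stop("malformed record: sequence must be a non-empty string", call. = FALSE)
  }
  s <- chartr("t", "u", raw)
  s <- toupper(s)
  s <- chartr("T", "U", s)
  gsub("[^ACGU]", "N", s)
}

# All k-mers over A<C<G<U in lexicographic order, first position most
# significant (AA..A, AA..C, ...).
kmer_levels <- function(k) {
  grid <- expand.grid(rep(list(RNA_BASES), k), stringsAsFactors = FALSE)
  # expand.grid varies the first column fastest; reverse so the last sequence
  # position varies fastest, giving lexicographic order on the string.
  apply(as.matrix(grid[, rev(seq_len(k)), drop = FALSE]), 1L, paste0, collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' k-mer composition vector
#'
#' Relative frequencies of all k-mers for each k, concatenated. Within each
#' k-block the count of every k-mer is divided by the number of counted
#' windows of size k; windows containing N are excluded from numerator and
#' denominator. Blocks are ordered by increasing k, entries lexicographically
#' (A < C < G < U). For k = 1..5 the vector has length 4 + 16 + ... + 1024 =
#' 1364.
#'
#' @param seq Sanitized sequence string.
#' @param k_values Integer vector of k values (default 1:5).
#' @return Named numeric vector of relative frequencies.
#' @export
kmer_frequencies <- function(seq, k_values = 1:5) {
  seq <- sanitize_sequence(seq)
  L <- nchar(seq)
  out <- lapply(sort(k_values), function(k) {
    lv <- kmer_levels(k)
    block <- setNames(numeric(length(lv)), paste0("k", k, "_", lv))
    if (L < k) {
      warning(sprintf("sequence shorter than k = %d; block left at zero", k))
      return(block)
    }
    windows <- substring(seq, 1:(L - k + 1L), k:L)
    windows <- windows[!grepl("N", windows, fixed = TRUE)]
    if (length(windows) == 0L) {
      warning(sprintf("no N-free windows for k = %d; block left at zero", k))
      return(block)
    }
    counts <- table(factor(windows, levels = lv))
    block[] <- as.numeric(counts) / length(windows)
    block
  })
  unlist(out)
}

#' Composition of k-spaced nucleic acid pairs (CKSNAP)
#'
#' For each gap g, the relative frequency of each ordered base pair
#' (s_i, s_{i+g+1}); each 16-entry gap block is normalized by the number of
#' counted pairs (pairs touching N are excluded). For gaps 0..5 the vector
#' has length 96.
#'
#' @param seq Sanitized sequence string.
#' @param gap_values Integer vector of gap sizes (default 0:5).
#' @return Named numeric vector of relative frequencies.
#' @export
cksnap_frequencies <- function(seq, gap_values = 0:5) {
  seq <- sanitize_sequence(seq)
  ch <- seq_chars(seq)
  L <- length(ch)
  pair_levels <- kmer_levels(2L)
  out <- lapply(sort(gap_values), function(g) {
    block <- setNames(numeric(16L), paste0("g", g, "_", pair_levels))
    n_pos <- L - g - 1L
    if (n_pos < 1L) {
      warning(sprintf("no countable pair for gap = %d; block left at zero", g))
      return(block)
    }
    first <- ch[1:n_pos]
    second <- ch[(g + 2L):L]
    keep <- first != "N" & second != "N"
    if (!any(keep)) {
      warning(sprintf("no N-free pair for gap = %d; block left at zero", g))
      return(block)
    }
    pairs <- paste0(first[keep], second[keep])
    counts <- table(factor(pairs, levels = pair_levels))
    block[] <- as.numeric(counts) / sum(keep)
    block
  })
  unlist(out)
}

NCP_TABLE <- rbind(
  A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0), U = c(0, 0, 1), N = c(0, 0, 0)
)

EIIP_TABLE <- c(A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335, N = 0)

#' Per-base node feature matrix
#'
#' Builds the L x 10 node-feature matrix consumed by the graph branches:
#' one-hot over (A, C, G, U, N), nucleotide chemical properties (ring
#' structure, hydrogen bonding, functional group), the electron-ion
#' interaction pseudopotential, and the accumulated nucleotide frequency
#' ANF(i) = count of base s_i within s[1..i] divided by i.
#'
#' @param seq Sequence string (sanitized internally).
#' @return Numeric matrix with L rows and 10 named columns.
#' @export
node_feature_matrix <- function(seq) {
  seq <- sanitize_sequence(seq)
  ch <- seq_chars(seq)
  L <- length(ch)
  alphabet <- c(RNA_BASES, "N")
  onehot <- matrix(0, L, 5L, dimnames = list(NULL, paste0("onehot_", alphabet)))
  onehot[cbind(seq_len(L), match(ch, alphabet))] <- 1
  ncp <- NCP_TABLE[ch, , drop = FALSE]
  dimnames(ncp) <- list(NULL, c("ncp_ring", "ncp_hbond", "ncp_group"))
  eiip <- matrix(EIIP_TABLE[ch], ncol = 1L, dimnames = list(NULL, "eiip"))
  # running count of the base at each position within its prefix
  anf <- numeric(L)
  for (b in alphabet) {
    is_b <- ch == b
    anf[is_b] <- cumsum(is_b)[is_b]
  }
  anf <- matrix(anf / seq_len(L), ncol = 1L, dimnames = list(NULL, "anf"))
  cbind(onehot, ncp, eiip, anf)
}

#' Encode sequences into composition feature tables
#'
#' Data-frame-in, tibble-out wrapper around [kmer_frequencies()] and
#' [cksnap_frequencies()]: one row per record, an `id` column followed by the
#' 1364 k-mer and 96 CKSNAP feature columns.
#'
#' @param records Data frame with `id` and `sequence` columns (see
#'   [rna_records()]).
#' @return Tibble with 1 + 1364 + 96 columns.
#' @export
encode_sequences <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  feats <- purrr::map(records$sequence, function(s) {
    c(kmer_frequencies(s), cksnap_frequencies(s))
  })
  dplyr::bind_cols(
    tibble::tibble(id = records$id),
    tibble::as_tibble(do.call(rbind, feats))
  )
}
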