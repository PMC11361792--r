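#' Parse dot-bracket notation into base pairs
#'
#' Stack-matches '(' and ')' characters. Pseudoknot-style brackets
#' (\code{[ ] \{ \}}) are treated as unpaired with a warning, since nested
#' dot-bracket output from standard folding tools never contains them.
#'
#' @param db Dot-bracket string over `(`, `)`, `.`.
#' @return Integer matrix with columns `i`, `j` (0-based, i < j), one row per
#'   base pair.
#' @examples
#' parse_dotbracket("(.)") # pair (0, 2)
#' @export
parse_dotbracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L, !is.na(db))
  ch <- seq_chars(db)
  knots <- ch %in% c("[", "]", "{", "}")
  if (any(knots)) {
    warning("pseudoknot bracket characters treated as unpaired")
    ch[knots] <- "."
  }
  bad <- which(!ch %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    stop(sprintf("structure parse error: invalid character '%s' at position %d",
                 ch[bad[1L]], bad[1L]), call. = FALSE)
  }
  open <- integer(0)
  from <- integer(0)
  to <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      open <- c(open, i)
    } else if (ch[i] == ")") {
      if (length(open) == 0L) {
        stop(sprintf("structure parse error: unmatched ')' at position %d", i),
             call. = FALSE)
      }
      from <- c(from, open[length(open)])
      to <- c(to, i)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) {
    stop(sprintf(
      "structure parse error: %d unmatched '(' at end of string (first at position %d)",
      length(open), open[1L]), call. = FALSE)
  }
  m <- cbind(i = from - 1L, j = to - 1L)
  m[order(m[, 1L]), , drop = FALSE]
}

#' Build the secondary-structure graph of a record
#'
#' Converts a sequence plus dot-bracket structure into the two-edge-type
#' graph consumed by the graph branches: every base is a node carrying its
#' 10-dimensional feature vector; `adjacent` edges join consecutive bases
#' (the phosphodiester backbone) and `base_pair` edges join stack-matched
#' bracket pairs (hydrogen bonds). The graph is undirected; edges are stored
#' once with 1-based endpoints `from < to`.
#'
#' @param sequence RNA sequence (sanitized internally).
#' @param structure Dot-bracket string of the same length.
#' @return An object of class `rna_graph`: list with `n_nodes`,
#'   `node_features` (L x 10 matrix) and `edges` (tibble `from`, `to`,
#'   `type`).
#' @examples
#' g <- dotbracket_to_graph("GGAACC", "((..))")
#' g$edges
#' @export
dotbracket_to_graph <- function(sequence, structure) {
  sequence <- sanitize_sequence(sequence)
  if (!is.character(structure) || length(structure) != 1L || is.na(structure)) {
    stop("structure/sequence mismatch: structure missing", call. = FALSE)
  }
  L <- nchar(sequence)
  if (nchar(structure) != L) {
    stop(sprintf("structure/sequence mismatch: sequence length %d, structure length %d",
                 L, nchar(structure)), call. = FALSE)
  }
  pairs <- parse_dotbracket(structure)
  adj <- if (L > 1L) cbind(from = 1:(L - 1L), to = 2:L) else cbind(from = integer(0), to = integer(0))
  edges <- tibble::tibble(
    from = c(adj[, "from"], pairs[, "i"] + 1L),
    to   = c(adj[, "to"],   pairs[, "j"] + 1L),
    type = c(rep("adjacent", nrow(adj)), rep("base_pair", nrow(pairs)))
  )
  structure(
    list(n_nodes = L, node_features = node_feature_matrix(sequence),
         sequence = sequence, edges = edges),
    class = "rna_graph"
  )
}

#' @exportS3Method base::print
print.rna_graph <- function(x, ...) {
  cat(sprintf("<rna_graph> %d nodes, %d adjacent edges, %d base-pair edges\n",
              x$n_nodes, sum(x$edges$type == "adjacent"),
              sum(x$edges$type == "base_pair")))
  invisible(x)
}

# Sparse symmetric adjacency matrix (both edge types pooled); neighbor
# aggregation in the GNN layers multiplies by this.
graph_adjacency <- function(graph) {
  e <- graph$edges
  Matrix::sparseMatrix(
    i = c(e$from, e$to), j = c(e$to, e$from), x = 1,
    dims = c(graph$n_nodes, graph$n_nodes)
  )
}

#' Fallback secondary-structure folder (maximum base pairing)
#'
#' A Nussinov-style dynamic program maximizing the number of nested base
#' pairs (AU, GC, GU wobble) with a minimum hairpin-loop size, recovered by a
#' deterministic traceback (prefer leaving the left base unpaired, then the
#' smallest admissible partner). It is a dependency-free stand-in for a
#' thermodynamic folding tool so that the full pipeline runs without
#' external executables; see [run_external_folder()] for RNAfold/LinearFold.
#'
#' @param seq RNA sequence (sanitized internally).
#' @param min_loop Minimum number of unpaired bases inside a hairpin loop
#'   (default 3).
#' @return Dot-bracket string of the same length.
#' @examples
#' nussinov_fold("GGGAAAACCC")
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  seq <- sanitize_sequence(seq)
  nussinov_db_cpp(seq, as.integer(min_loop))
}

#' Attach structures predicted by an external folding tool
#'
#' Runs RNAfold or LinearFold on each record's sequence and stores the first
#' dot-bracket line of the tool's plain-text output (any trailing free-energy
#' annotation is stripped) in the chosen structure column. Never required by
#' the package itself: [nussinov_fold()] is the built-in fallback.
#'
#' @param records Records tibble (see [rna_records()]).
#' @param tool `"rnafold"` or `"linearfold"`.
#' @param executable Path to the executable; defaults to the conventional
#'   binary name looked up on `PATH`.
#' @param column Name of the structure column to fill (default
#'   `"structure"`).
#' @return The records tibble with the structure column filled, order
#'   preserved.
#' @export
run_external_folder <- function(records, tool = c("rnafold", "linearfold"),
                                executable = NULL, column = "structure") {
  tool <- match.arg(tool)
  if (is.null(executable)) {
    executable <- c(rnafold = "RNAfold", linearfold = "linearfold")[[tool]]
  }
  if (Sys.which(executable) == "" && !file.exists(executable)) {
    stop(sprintf(paste0(
      "environment error: executable '%s' not found; install the tool or use ",
      "nussinov_fold() as the built-in fallback folder"), executable),
      call. = FALSE)
  }
  args <- if (tool == "rnafold") c("--noPS") else character(0)
  structures <- vapply(records$sequence, function(s) {
    out <- tryCatch(
      suppressWarnings(system2(executable, args, stdout = TRUE, input = s)),
      error = function(e) character(0)
    )
    line <- grep("^[.()]+( +\\(.*\\))?$", out, value = TRUE)
    if (length(line) == 0L) {
      warning("unparseable folder output; structure left empty")
      return(NA_character_)
    }
    sub(" +\\(.*\\)$", "", line[[1L]])
  }, character(1), USE.NAMES = FALSE)
  records[[column]] <- structures
  records
}

#' Write records to a Vienna-style structure file
#'
#' Per record: a `>id` header line, the sequence line, and the dot-bracket
#' line.
#'
#' @param records Records tibble with `id`, `sequence` and a structure
#'   column.
#' @param path Output file path.
#' @param column Structure column to write (default `"structure"`).
#' @return `path`, invisibly.
#' @export
write_structures <- function(records, path, column = "structure") {
  stopifnot(all(c("id", "sequence", column) %in% names(records)))
  lines <- unlist(Map(function(id, s, db) c(paste0(">", id), s, db),
                      records$id, records$sequence, records[[column]]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Vienna-style structure file
#'
#' Expects per-record triplets: `>id`, sequence, dot-bracket (an optional
#' trailing free-energy annotation in parentheses is ignored).
#'
#' @param path File path.
#' @return Tibble with `id`, `sequence`, `structure`.
#' @export
read_structures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(lines) %% 3L != 0L || !identical(heads, seq(1L, length(lines), by = 3L))) {
    stop("data error: malformed structure file (expected >id / sequence / dot-bracket triplets)",
         call. = FALSE)
  }
  tibble::tibble(
    id = sub("^>\\s*", "", sub("\\s.*$", "", lines[heads])),
    sequence = trimws(lines[heads + 1L]),
    structure = sub(" +\\(.*\\)$", "", trimws(lines[heads + 2L]))
  )
}
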