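#' Assemble an RNA record table
#'
#' The package's central data structure is an ordinary tibble with one row
#' per transcript: `id`, sanitized `sequence`, optional dot-bracket columns
#' `structure` and `structure2` (the two structure sources feeding the two
#' graph branches), and optional 0/1 label columns named after
#' [localization_labels()].
#'
#' @param id Character vector of unique sequence identifiers.
#' @param sequence Character vector of RNA/DNA sequences (sanitized on
#'   ingest: uppercase, T to U, unknown characters to N).
#' @param structure,structure2 Optional dot-bracket strings, same lengths as
#'   the sequences.
#' @param labels Optional data frame or matrix with the six 0/1 label
#'   columns.
#' @return Records tibble.
#' @export
rna_records <- function(id, sequence, structure = NULL, structure2 = NULL,
                        labels = NULL) {
  if (anyDuplicated(id)) {
    stop(sprintf("data error: duplicate sequence id '%s'",
                 id[duplicated(id)][1L]), call. = FALSE)
  }
  sequence <- vapply(sequence, sanitize_sequence, character(1), USE.NAMES = FALSE)
  rec <- tibble::tibble(id = as.character(id), sequence = sequence)
  for (col in c("structure", "structure2")) {
    val <- if (col == "structure") structure else structure2
    if (!is.null(val)) {
      ok <- is.na(val) | nchar(val) == nchar(sequence)
      if (!all(ok)) {
        stop(sprintf("structure/sequence mismatch for id '%s'",
                     rec$id[which(!ok)[1L]]), call. = FALSE)
      }
      rec[[col]] <- val
    }
  }
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    missing <- setdiff(localization_labels(), names(labels))
    if (length(missing) > 0L) {
      stop(sprintf("data error: label columns missing: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    for (lab in localization_labels()) {
      v <- labels[[lab]]
      if (!all(v %in% c(0, 1))) {
        stop(sprintf("data error: non-binary value in label column '%s'", lab),
             call. = FALSE)
      }
      rec[[lab]] <- as.integer(v)
    }
  }
  rec
}

# n x 6 integer label matrix from a records tibble (errors if absent).
label_matrix <- function(records) {
  missing <- setdiff(localization_labels(), names(records))
  if (length(missing) > 0L) {
    stop(sprintf("data error: records lack label columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m <- as.matrix(records[, localization_labels()])
  storage.mode(m) <- "integer"
  rownames(m) <- records$id
  m
}

#' Read RNA sequences from a FASTA file
#'
#' Multi-line records with `>` headers; the record id is the first
#' whitespace-delimited token of the header. Sequences are sanitized on
#' ingest. Parsing is delegated to Biostrings when available.
#'
#' @param path FASTA file path.
#' @return Records tibble with `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("data error: file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file")
    return(tibble::tibble(id = character(0), sequence = character(0)))
  }
  if (!startsWith(trimws(lines[nonempty[1L]]), ">")) {
    stop(sprintf("data error: malformed FASTA record at line %d (expected '>')",
                 nonempty[1L]), call. = FALSE)
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    headers <- grep("^>", trimws(lines))
    ids <- sub("\\s.*$", "", sub("^>", "", trimws(lines[headers])))
    bounds <- c(headers, length(lines) + 1L)
    seqs <- vapply(seq_along(headers), function(k) {
      body <- lines[setdiff(seq(bounds[k] + 1L, bounds[k + 1L] - 1L), headers)]
      paste0(trimws(body), collapse = "")
    }, character(1))
  }
  rna_records(id = ids, sequence = seqs)
}

#' Write records to a FASTA file
#'
#' @param records Records tibble.
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  lines <- unlist(Map(function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }, records$id, records$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a localization label table
#'
#' Tab-separated file with header `id` plus the six label columns in
#' [localization_labels()] order; values must be 0 or 1. Extra columns are
#' ignored with a warning.
#'
#' @param path TSV file path.
#' @return Tibble with `id` and the six integer label columns.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  needed <- c("id", localization_labels())
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("data error: label table lacks columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), needed)
  if (length(extra) > 0L) {
    warning(sprintf("ignoring extra label-table columns: %s",
                    paste(extra, collapse = ", ")))
  }
  for (lab in localization_labels()) {
    bad <- which(!df[[lab]] %in% c(0, 1))
    if (length(bad) > 0L) {
      stop(sprintf("data error: non-binary value '%s' in column '%s', row %d",
                   df[[lab]][bad[1L]], lab, bad[1L]), call. = FALSE)
    }
  }
  tibble::as_tibble(df[, needed]) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(localization_labels()), as.integer))
}

#' Write a label table
#'
#' @param records Records tibble carrying the six label columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(records, path) {
  df <- as.data.frame(records[, c("id", localization_labels())])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach labels from a label table to records
#'
#' @param records Records tibble.
#' @param labels Tibble as returned by [read_labels()].
#' @return Records tibble with the six label columns joined by `id`.
#' @export
attach_labels <- function(records, labels) {
  unknown <- setdiff(records$id, labels$id)
  if (length(unknown) > 0L) {
    stop(sprintf("data error: no labels for id '%s'", unknown[1L]), call. = FALSE)
  }
  dplyr::left_join(
    dplyr::select(records, -dplyr::any_of(localization_labels())),
    labels, by = "id"
  )
}

#' Write a prediction table
#'
#' CSV with header `id`, the six probability columns (`nucleus_prob`, ...,
#' `er_prob`, 6 decimal places) and the six binarized label columns.
#'
#' @param predictions Tibble as returned by [predict.allocator_fit()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  labs <- localization_labels()
  prob_cols <- paste0(labs, "_prob")
  stopifnot(all(c("id", prob_cols, labs) %in% names(predictions)))
  out <- as.data.frame(predictions[, c("id", prob_cols, labs)])
  out[prob_cols] <- lapply(out[prob_cols], function(x) sprintf("%.6f", x))
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path CSV path.
#' @return Tibble with id, probability and binarized label columns.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
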