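#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated AIRR rearrangement file into a repertoire tibble.
#' Rows missing a V call, J call or CDR3/junction amino-acid sequence are
#' dropped (they cannot be clustered) and the kept/dropped counts are
#' reported.  Multi-allele calls such as `"IGHV1-69*01,IGHV1-69*02"` keep the
#' first listed call.  Convenience columns `v_gene` / `j_gene` (allele
#' suffix stripped) and `cdr3_aa` (the selected CDR3 column, upper-cased) are
#' added.
#'
#' @param path path to a tab-separated file with a header row containing at
#'   least `sequence_id`, `v_call`, `j_call` and `junction_aa` (or `cdr3_aa`).
#' @param cdr3_column which column to use as the CDR3 amino-acid sequence:
#'   `"auto"` (default: `cdr3_aa` when present, otherwise `junction_aa`),
#'   `"junction_aa"` or `"cdr3_aa"`.
#' @param column_map optional named character vector mapping AIRR names to
#'   the file's column names, e.g. `c(v_call = "V.GENE")`.
#' @param quiet suppress the kept/dropped message.
#' @return a tibble with one row per retained sequence; the number of dropped
#'   rows is attached as attribute `"dropped"`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("sequence_id\tv_call\tj_call\tjunction_aa",
#'              "s1\tIGHV1-69*01\tIGHJ4*02\tCARDYW"), f)
#' read_airr(f, quiet = TRUE)
#' @export
read_airr <- function(path, cdr3_column = c("auto", "junction_aa", "cdr3_aa"),
                      column_map = NULL, quiet = FALSE) {
  cdr3_column <- match.arg(cdr3_column)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  if (nrow(tbl) == 0 && ncol(tbl) == 0) abort(sprintf("empty input file: %s", path))
  if (!is.null(column_map)) {
    for (airr_name in names(column_map)) {
      if (column_map[[airr_name]] %in% names(tbl)) {
        names(tbl)[names(tbl) == column_map[[airr_name]]] <- airr_name
      }
    }
  }
  for (col in c("sequence_id", "v_call", "j_call")) {
    if (!col %in% names(tbl)) {
      abort(sprintf("AIRR format error: required column '%s' is missing", col))
    }
  }
  cdr3_col <- switch(cdr3_column,
    auto = if ("cdr3_aa" %in% names(tbl)) "cdr3_aa" else "junction_aa",
    cdr3_column)
  if (!cdr3_col %in% names(tbl)) {
    abort(sprintf("AIRR format error: required column '%s' is missing", cdr3_col))
  }
  if (nrow(tbl) == 0) abort(sprintf("empty input file: %s", path))

  dup <- tbl$sequence_id[duplicated(tbl$sequence_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated sequence_id: %s",
                  paste(unique(dup), collapse = ", ")))
  }

  blankish <- function(x) is.na(x) | !nzchar(x) | x %in% c("NA", ".")
  keep <- !(blankish(tbl$v_call) | blankish(tbl$j_call) | blankish(tbl[[cdr3_col]]))
  dropped <- sum(!keep)
  tbl <- tbl[keep, , drop = FALSE]

  out <- tbl |>
    mutate(
      v_call = sub(",.*$", "", .data$v_call),
      j_call = sub(",.*$", "", .data$j_call),
      v_gene = strip_allele(.data$v_call),
      j_gene = strip_allele(.data$j_call),
      cdr3_aa = toupper(.data[[cdr3_col]]),
      duplicate_count = if ("duplicate_count" %in% names(tbl)) {
        dc <- suppressWarnings(as.integer(.data$duplicate_count))
        ifelse(is.na(dc) | dc < 1L, 1L, dc)
      } else 1L,
      productive = if ("productive" %in% names(tbl)) {
        toupper(substr(.data$productive, 1, 1)) %in% c("T", "Y", "1")
      } else TRUE
    )
  if (!quiet) {
    inform(sprintf("read_airr: kept %d sequences, dropped %d without full V/J/CDR3 annotation",
                   nrow(out), dropped))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Write a clustering next to its repertoire
#'
#' Writes the repertoire table augmented with a `clone_id` column and,
#' optionally, a per-cluster summary (size in unique sequences, size in
#' reads, abundance fraction, representative V/J genes, uniformity).
#'
#' @param rep repertoire tibble (as from [read_airr()]).
#' @param clustering tibble with columns `sequence_id`, `clone_id`, or a
#'   `clonal_clustering` object.
#' @param path output TSV path for the augmented table.
#' @param summary_path optional output TSV path for the per-cluster summary.
#' @param dist_config [distance_config()] used for the uniformity column of
#'   the summary.
#' @return invisibly, the augmented tibble.
#' @export
write_clustering <- function(rep, clustering, path, summary_path = NULL,
                             dist_config = distance_config()) {
  if (inherits(clustering, "clonal_clustering")) clustering <- clustering$clustering
  stopifnot(all(c("sequence_id", "clone_id") %in% names(clustering)))
  extra <- setdiff(clustering$sequence_id, rep$sequence_id)
  if (length(extra) > 0) {
    abort(sprintf("clustering refers to ids absent from the repertoire: %s",
                  paste(utils::head(extra, 5), collapse = ", ")))
  }
  aug <- dplyr::left_join(rep, clustering, by = "sequence_id")
  readr::write_tsv(aug, path, progress = FALSE)
  if (!is.null(summary_path)) {
    readr::write_tsv(cluster_summary(rep, clustering, dist_config), summary_path,
                     progress = FALSE)
  }
  invisible(aug)
}

#' Per-cluster summary table
#'
#' @inheritParams write_clustering
#' @return a tibble with one row per cluster: `clone_id`, `n_sequences`,
#'   `n_reads`, `abundance` (read fraction), modal `v_gene` / `j_gene`, and
#'   `uniformity`.
#' @export
cluster_summary <- function(rep, clustering, dist_config = distance_config()) {
  if (inherits(clustering, "clonal_clustering")) clustering <- clustering$clustering
  if (nrow(clustering) == 0) {
    return(tibble(clone_id = character(), n_sequences = integer(),
                  n_reads = integer(), abundance = numeric(),
                  v_gene = character(), j_gene = character(),
                  uniformity = numeric()))
  }
  aug <- dplyr::inner_join(rep, clustering, by = "sequence_id")
  if ("duplicate_count" %in% names(aug)) {
    aug$duplicate_count <- as.integer(aug$duplicate_count)
  } else {
    aug$duplicate_count <- 1L
  }
  total_reads <- sum(aug$duplicate_count)
  d <- distance_matrix(aug, dist_config)
  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  aug |>
    mutate(.row = row_number()) |>
    group_by(.data$clone_id) |>
    summarise(
      n_sequences = n(),
      n_reads = sum(.data$duplicate_count),
      abundance = sum(.data$duplicate_count) / total_reads,
      v_gene = modal(.data$v_gene),
      j_gene = modal(.data$j_gene),
      uniformity = uniformity_from_dist(d[.data$.row, .data$.row, drop = FALSE]),
      .groups = "drop"
    ) |>
    arrange(desc(.data$n_sequences), .data$clone_id)
}

#' Read a FASTA file of nucleotide sequences
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `sequence_id` and `sequence` (upper-cased).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(ss))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(sprintf("empty sequence for FASTA record(s): %s",
                  paste(ids[empty], collapse = ", ")))
  }
  tibble(sequence_id = ids, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param df tibble with `sequence_id` and `sequence` columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(df, path) {
  writeLines(paste0(">", df$sequence_id, "\n", df$sequence), path)
  invisible(path)
}
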