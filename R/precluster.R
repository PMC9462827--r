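#' CDR3 amino-acid identity
#'
#' Fraction of positions with equal residues (Hamming identity) for strings
#' of equal length.  When `allow_levenshtein = TRUE` and the lengths differ,
#' identity is `1 - normalized_levenshtein(a, b)` instead (used when a CDR3
#' length tolerance is active).
#'
#' @param a,b amino-acid strings.
#' @param allow_levenshtein fall back to Levenshtein-based identity for
#'   unequal lengths instead of erroring.
#' @return a number in \[0, 1\].
#' @examples
#' cdr3_identity("CARDYW", "CARDFW")  # 5/6
#' @export
cdr3_identity <- function(a, b, allow_levenshtein = FALSE) {
  assert_scalar_string(a, "a"); assert_scalar_string(b, "b")
  if (nchar(a) != nchar(b)) {
    if (!allow_levenshtein) {
      abort("cdr3_identity: length mismatch within a fixed-length group")
    }
    return(1 - normalized_levenshtein(a, b))
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

# Pairwise Hamming identity matrix for equal-length strings (position loop,
# vectorized over the n^2 pair grid).
hamming_identity_matrix <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(1, 1, 1))
  l <- nchar(x[1])
  chars <- matrix(unlist(strsplit(x, "")), nrow = n, byrow = TRUE)
  acc <- matrix(0, n, n)
  for (p in seq_len(l)) {
    acc <- acc + outer(chars[, p], chars[, p], "==")
  }
  acc / l
}

# Pairwise identity for possibly unequal lengths (Levenshtein-based).
levenshtein_identity_matrix <- function(x) {
  ed <- utils::adist(x, x)
  len <- nchar(x)
  1 - ed / outer(len, len, pmax)
}

#' Group sequences by V gene, J gene and CDR3 length
#'
#' The first pre-clustering stage: a partition keyed by
#' `(v_gene, j_gene, nchar(cdr3_aa))`.  With a positive
#' `cdr3_length_tolerance`, length bins within the tolerance are pooled
#' (connected runs of lengths differing by at most the tolerance).
#'
#' @param rep repertoire tibble.
#' @param allele_level group at allele level (`v_call`/`j_call`) instead of
#'   gene level.
#' @param cdr3_length_tolerance non-negative integer; lengths within this many
#'   residues fall in the same group.
#' @return an integer vector of group indices aligned with `rep` rows.
#' @export
group_by_vj_len <- function(rep, allele_level = FALSE, cdr3_length_tolerance = 0L) {
  v <- if (allele_level) rep$v_call else (rep$v_gene %||% strip_allele(rep$v_call))
  j <- if (allele_level) rep$j_call else (rep$j_gene %||% strip_allele(rep$j_call))
  len <- nchar(rep$cdr3_aa)
  if (cdr3_length_tolerance > 0L) {
    # pool lengths whose gaps are within the tolerance (per V/J pair)
    key_vj <- paste(v, j, sep = "\r")
    len_bin <- integer(length(len))
    for (kv in unique(key_vj)) {
      idx <- which(key_vj == kv)
      ls <- sort(unique(len[idx]))
      bin <- cumsum(c(1L, diff(ls) > cdr3_length_tolerance))
      len_bin[idx] <- bin[match(len[idx], ls)]
    }
    key <- paste(key_vj, len_bin, sep = "\r")
  } else {
    key <- paste(v, j, len, sep = "\r")
  }
  match(key, unique(key))
}

#' Split a V/J/length group at the CDR3 identity threshold
#'
#' Single-linkage connected components of the graph whose edges join pairs
#' with CDR3 identity at least `s`; pairs with identity strictly below `s`
#' can only stay together through a chain of linked intermediates.
#'
#' @param cdr3 character vector of CDR3 amino-acid sequences (one group).
#' @param s identity threshold (fraction or percent).
#' @param equal_lengths if `TRUE` (tolerance 0) identity is positional
#'   (Hamming); otherwise Levenshtein-based.
#' @return integer vector of component indices, numbered by first appearance
#'   in input order.
#' @export
split_group <- function(cdr3, s = 0.70, equal_lengths = TRUE) {
  s <- normalize_threshold(s)
  n <- length(cdr3)
  if (n == 1L) return(1L)
  idm <- if (equal_lengths) hamming_identity_matrix(cdr3)
         else levenshtein_identity_matrix(cdr3)
  adj <- idm >= s
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by first member in input order (deterministic labels)
  match(comp, unique(comp))
}

#' Pre-cluster a repertoire
#'
#' Initial clonal groups: sequences with the same IGHV gene, IGHJ gene and
#' CDR3 length are grouped, then each group is separated at the CDR3
#' amino-acid identity threshold `s` (default 70%): sequences with identity
#' below `s` to every member of a component end up in different initial
#' clusters.
#'
#' @param rep repertoire tibble with `v_gene`/`j_gene` (or `v_call`/`j_call`)
#'   and `cdr3_aa` columns.
#' @param s CDR3 identity threshold, fraction or percent (default 0.70).
#' @param allele_level group by full allele calls instead of gene names.
#' @param cdr3_length_tolerance pool CDR3-length bins within this many
#'   residues (identity then uses normalized Levenshtein); default 0.
#' @param quiet suppress the cluster-count message.
#' @return tibble with columns `sequence_id`, `clone_id` (character labels,
#'   deterministic in input order).
#' @examples
#' rep <- tibble::tibble(
#'   sequence_id = c("s1", "s2", "s3"),
#'   v_call = c("IGHV1-69", "IGHV1-69", "IGHV3-23"),
#'   j_call = "IGHJ4", cdr3_aa = c("CARDYW", "CARDFW", "CTTTTW"))
#' precluster(rep, quiet = TRUE)
#' @export
precluster <- function(rep, s = 0.70, allele_level = FALSE,
                       cdr3_length_tolerance = 0L, quiet = FALSE) {
  if (nrow(rep) == 0) {
    warn("precluster: empty repertoire")
    return(tibble(sequence_id = character(), clone_id = character()))
  }
  if (is.null(rep$cdr3_aa)) rep$cdr3_aa <- rep$junction_aa
  assign <- precluster_assign(rep, s, allele_level, cdr3_length_tolerance)
  if (!quiet) inform(sprintf("precluster: %d initial clusters", max(assign)))
  tibble(sequence_id = rep$sequence_id, clone_id = as.character(assign))
}

# Internal: integer assignment vector aligned with rep rows; cluster indices
# are numbered by first appearance in input order.
precluster_assign <- function(rep, s = 0.70, allele_level = FALSE,
                              cdr3_length_tolerance = 0L) {
  grp <- group_by_vj_len(rep, allele_level, cdr3_length_tolerance)
  assign <- integer(nrow(rep))
  nxt <- 0L
  for (g in seq_len(max(grp))) {
    idx <- which(grp == g)
    comp <- split_group(rep$cdr3_aa[idx], s,
                        equal_lengths = cdr3_length_tolerance == 0L)
    assign[idx] <- comp + nxt
    nxt <- nxt + max(comp)
  }
  # renumber by first appearance in input order
  match(assign, unique(assign[order(seq_along(assign))]))
}
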