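#' Distance configuration for the composed sequence distance
#'
#' The composed distance between two annotated IGH sequences is a weighted
#' (''ponderate'') mean of three per-segment distances,
#' \deqn{d(i,j) = \frac{\alpha d_V + \beta d_{CDR3} + \lambda d_J}{\alpha+\beta+\lambda},}
#' where each segment distance is one of four types: `"binary"` (0 iff the
#' annotations are equal), `"levenshtein"` (edit distance normalized by the
#' longer string), `"kmer"` (one minus the shared fraction of distinct k-mers)
#' or `"giana"` (normalized Euclidean distance between substitution-matrix
#' embeddings).  With equal coefficients the arithmetic mean is computed.
#'
#' The published default is a binary IGHV distance, Levenshtein IGHJ and CDR3
#' distances, and equal coefficients.
#'
#' @param v_metric,cdr3_metric,j_metric one of `"binary"`, `"levenshtein"`,
#'   `"kmer"`, `"giana"`.
#' @param alpha,beta,lambda non-negative coefficients for the V, CDR3 and J
#'   segment distances; at least one must be positive.  Only their ratios
#'   matter.
#' @param kmer_k k-mer size for the `"kmer"` metric (amino acids, default 3).
#' @param kmer_denominator `"max"` (containment in the larger k-mer set, the
#'   default: identity gives 0 and k-mer disjointness gives 1 exactly) or
#'   `"jaccard"`.
#' @param allele_level if `FALSE` (default), gene labels are compared after
#'   stripping the allele suffix (`"IGHV1-69*01"` matches `"IGHV1-69*02"`).
#' @return an object of class `distance_config`.
#' @examples
#' cfg <- distance_config()
#' cfg$v_metric
#' @export
distance_config <- function(v_metric = "binary",
                            cdr3_metric = "levenshtein",
                            j_metric = "levenshtein",
                            alpha = 1, beta = 1, lambda = 1,
                            kmer_k = 3L,
                            kmer_denominator = c("max", "jaccard"),
                            allele_level = FALSE) {
  metrics <- c("binary", "levenshtein", "kmer", "giana")
  v_metric <- match.arg(v_metric, metrics)
  cdr3_metric <- match.arg(cdr3_metric, metrics)
  j_metric <- match.arg(j_metric, metrics)
  kmer_denominator <- match.arg(kmer_denominator)
  coefs <- c(alpha = alpha, beta = beta, lambda = lambda)
  if (any(!is.finite(coefs)) || any(coefs < 0)) {
    abort("alpha, beta and lambda must be non-negative finite numbers")
  }
  if (sum(coefs) <= 0) abort("at least one of alpha, beta, lambda must be positive")
  if (kmer_k < 1) abort("kmer_k must be >= 1")
  structure(
    list(v_metric = v_metric, cdr3_metric = cdr3_metric, j_metric = j_metric,
         alpha = alpha, beta = beta, lambda = lambda,
         kmer_k = as.integer(kmer_k), kmer_denominator = kmer_denominator,
         allele_level = isTRUE(allele_level)),
    class = "distance_config"
  )
}

#' @export
print.distance_config <- function(x, ...) {
  cat(sprintf(
    "<distance_config> V:%s CDR3:%s J:%s  (alpha=%g, beta=%g, lambda=%g)\n",
    x$v_metric, x$cdr3_metric, x$j_metric, x$alpha, x$beta, x$lambda))
  invisible(x)
}

#' Serialize / restore a distance configuration
#'
#' Round-trips a [distance_config()] through a plain named list suitable for
#' YAML/JSON config files (keys `v_metric`, `cdr3_metric`, `j_metric`,
#' `alpha`, `beta`, `lambda`, `kmer_k`, ...).
#'
#' @param cfg a `distance_config`.
#' @param x a named list as produced by `distance_config_to_list()`.
#' @return a list, or a `distance_config`.
#' @export
distance_config_to_list <- function(cfg) {
  stopifnot(inherits(cfg, "distance_config"))
  unclass(cfg)
}

#' @rdname distance_config_to_list
#' @export
distance_config_from_list <- function(x) {
  do.call(distance_config, x[names(x) %in% names(formals(distance_config))])
}

#' Binary (identity) distance between annotations
#'
#' 0 if the two labels are equal, 1 otherwise.  Gene labels are compared after
#' allele-stripping unless `allele_level = TRUE`.  Vectorized over pairs.
#'
#' @param a,b character vectors of equal length (gene labels or sequences).
#' @param allele_level compare full allele calls instead of gene names.
#' @return numeric vector in \{0, 1\}.
#' @examples
#' binary_distance("IGHV1-69*01", "IGHV1-69*02")  # 0: same gene
#' @export
binary_distance <- function(a, b, allele_level = FALSE) {
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    abort("binary_distance: empty input")
  }
  if (!allele_level) {
    a <- strip_allele(a)
    b <- strip_allele(b)
  }
  as.numeric(a != b)
}

#' Normalized Levenshtein distance
#'
#' Minimum number of single-character edits (insertions, deletions,
#' substitutions) divided by the length of the longer string.  Symmetric, 0
#' iff the strings are equal, at most 1.  Vectorized over pairs.
#'
#' @param a,b character vectors of equal length (recycled if scalar).
#' @return numeric vector in \[0, 1\].
#' @examples
#' normalized_levenshtein("KITTEN", "SITTING")  # 3/7
#' @export
normalized_levenshtein <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    abort("normalized_levenshtein: empty string")
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  ed <- mapply(function(x, y) utils::adist(x, y)[1, 1], a, b, USE.NAMES = FALSE)
  ed / pmax(nchar(a), nchar(b))
}

kmer_set <- function(s, k) {
  l <- nchar(s)
  if (l < k) abort(sprintf("kmer_distance: string shorter than k = %d", k))
  unique(substring(s, 1:(l - k + 1L), k:l))
}

#' k-mer distance
#'
#' One minus the fraction of distinct k-mers shared by both strings, with the
#' larger k-mer set as denominator (so identical strings give 0 and strings
#' sharing no k-mer give 1).  `denominator = "jaccard"` uses the union instead.
#'
#' @param a,b non-empty strings of length at least `k`.
#' @param k k-mer size.
#' @param denominator `"max"` (default) or `"jaccard"`.
#' @return a number in \[0, 1\].
#' @examples
#' kmer_distance("ABCD", "ABCE", 3)  # 0.5
#' @export
kmer_distance <- function(a, b, k = 3L, denominator = c("max", "jaccard")) {
  assert_scalar_string(a, "a"); assert_scalar_string(b, "b")
  denominator <- match.arg(denominator)
  if (a == b) return(0)
  ka <- kmer_set(a, k)
  kb <- kmer_set(b, k)
  shared <- length(intersect(ka, kb))
  den <- switch(denominator,
                max = max(length(ka), length(kb)),
                jaccard = length(union(ka, kb)))
  1 - shared / den
}

# --- GIANA-style embedding ---------------------------------------------------
# Each residue maps to the leading components of an SVD factorization of
# BLOSUM62 (rows over the 20 standard amino acids); a sequence becomes the
# concatenation of its residue vectors, center-padded with zeros to a common
# length.  Distances are Euclidean, rescaled to [0, 1] by sqrt(L) times the
# largest single-residue embedding distance.
giana_env <- new.env(parent = emptyenv())

giana_embedding_matrix <- function(rank = 5L) {
  key <- paste0("emb", rank)
  if (!is.null(giana_env[[key]])) return(giana_env[[key]])
  bl <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = bl)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  m <- bl$BLOSUM62[aa, aa]
  sv <- svd(m)
  emb <- sv$u[, seq_len(rank), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(rank)]))
  rownames(emb) <- aa
  dmax <- max(stats::dist(emb))
  res <- list(emb = emb, dmax = dmax, rank = rank)
  giana_env[[key]] <- res
  res
}

embed_sequence <- function(s, len, emb) {
  chars <- strsplit(s, "")[[1]]
  v <- matrix(0, nrow = len, ncol = ncol(emb$emb))
  known <- chars %in% rownames(emb$emb)
  # center-pad: place the sequence in the middle of the fixed-length frame
  offset <- (len - length(chars)) %/% 2L
  idx <- offset + seq_along(chars)
  v[idx[known], ] <- emb$emb[chars[known], , drop = FALSE]
  as.vector(v)
}

#' GIANA-style embedding distance
#'
#' Encodes each amino-acid sequence as a numeric vector (per-residue rows of a
#' low-rank SVD factorization of BLOSUM62, center-padded to a common length)
#' and returns the Euclidean distance between the two embeddings, rescaled to
#' \[0, 1\].  `d(a, a) = 0`; symmetric.  This is a documented simplification of
#' the original isometric encoding and is not part of the default
#' configuration.
#'
#' @param a,b non-empty amino-acid strings.
#' @param rank number of SVD components per residue (default 5).
#' @return a number in \[0, 1\].
#' @export
giana_distance <- function(a, b, rank = 5L) {
  assert_scalar_string(a, "a"); assert_scalar_string(b, "b")
  if (a == b) return(0)
  emb <- giana_embedding_matrix(rank)
  len <- max(nchar(a), nchar(b))
  va <- embed_sequence(a, len, emb)
  vb <- embed_sequence(b, len, emb)
  sqrt(sum((va - vb)^2)) / (sqrt(len) * emb$dmax)
}

segment_distance <- function(metric, a, b, cfg) {
  switch(metric,
    binary = binary_distance(a, b, allele_level = cfg$allele_level),
    levenshtein = normalized_levenshtein(a, b),
    kmer = kmer_distance(a, b, k = cfg$kmer_k, denominator = cfg$kmer_denominator),
    giana = giana_distance(a, b))
}

#' Composed distance between two annotated sequences
#'
#' Weighted mean of the per-segment V, CDR3 and J distances (see
#' [distance_config()]).  For the V and J segments the configured metric is
#' applied to the annotation strings (gene labels); for CDR3 it is applied to
#' the amino-acid sequence.
#'
#' @param i,j lists or one-row data frames with fields `v_gene` (or `v_call`),
#'   `j_gene` (or `j_call`) and `cdr3_aa`.
#' @param cfg a [distance_config()].
#' @return a number in \[0, 1\] when all component metrics are in \[0, 1\].
#' @examples
#' a <- list(v_gene = "IGHV1-69", j_gene = "IGHJ4", cdr3_aa = "CARDYW")
#' b <- list(v_gene = "IGHV3-23", j_gene = "IGHJ4", cdr3_aa = "CARDYW")
#' composed_distance(a, b, distance_config())  # 1/3: only the V segment differs
#' @export
composed_distance <- function(i, j, cfg = distance_config()) {
  vi <- i$v_gene %||% i$v_call
  vj <- j$v_gene %||% j$v_call
  ji <- i$j_gene %||% i$j_call
  jj <- j$j_gene %||% j$j_call
  dv <- segment_distance(cfg$v_metric, vi, vj, cfg)
  dc <- segment_distance(cfg$cdr3_metric, i$cdr3_aa, j$cdr3_aa, cfg)
  dj <- segment_distance(cfg$j_metric, ji, jj, cfg)
  (cfg$alpha * dv + cfg$beta * dc + cfg$lambda * dj) /
    (cfg$alpha + cfg$beta + cfg$lambda)
}

# Pairwise matrix of a segment metric over a character vector, computed on the
# unique values and expanded; this is the memoization layer that guarantees
# bit-identical repeated queries within a run.
segment_distance_matrix <- function(x, metric, cfg) {
  ux <- unique(x)
  m <- length(ux)
  d <- switch(metric,
    binary = {
      lab <- if (cfg$allele_level) ux else strip_allele(ux)
      1 - outer(lab, lab, "==")
    },
    levenshtein = {
      ed <- utils::adist(ux, ux)
      len <- nchar(ux)
      ed / outer(len, len, pmax)
    },
    kmer = {
      sets <- lapply(ux, kmer_set, k = cfg$kmer_k)
      sizes <- lengths(sets)
      out <- matrix(0, m, m)
      if (m > 1) {
        for (i in 1:(m - 1)) {
          for (j in (i + 1):m) {
            shared <- length(intersect(sets[[i]], sets[[j]]))
            den <- if (cfg$kmer_denominator == "max") max(sizes[i], sizes[j])
                   else length(union(sets[[i]], sets[[j]]))
            out[i, j] <- out[j, i] <- 1 - shared / den
          }
        }
      }
      out
    },
    giana = {
      emb <- giana_embedding_matrix(5L)
      len <- max(nchar(ux))
      vecs <- t(vapply(ux, embed_sequence, numeric(len * ncol(emb$emb)),
                       len = len, emb = emb))
      as.matrix(stats::dist(vecs)) / (sqrt(len) * emb$dmax)
    })
  storage.mode(d) <- "double"
  idx <- match(x, ux)
  d[idx, idx, drop = FALSE]
}

#' Composed distance matrix over a repertoire
#'
#' Computes the full symmetric matrix of composed distances between all rows
#' of a repertoire tibble.  Per-segment distances are evaluated once per
#' unique annotation value and reused, so repeated pairs are bit-identical.
#'
#' @param rep a repertoire tibble with columns `v_gene` (or `v_call`),
#'   `j_gene` (or `j_call`) and `cdr3_aa` (or `junction_aa`).
#' @param cfg a [distance_config()].
#' @return an n-by-n numeric matrix.
#' @export
distance_matrix <- function(rep, cfg = distance_config()) {
  v <- rep$v_gene %||% rep$v_call
  j <- rep$j_gene %||% rep$j_call
  c3 <- rep$cdr3_aa %||% rep$junction_aa
  if (is.null(v) || is.null(j) || is.null(c3)) {
    abort("distance_matrix: repertoire must carry V, J and CDR3 columns")
  }
  dv <- segment_distance_matrix(v, cfg$v_metric, cfg)
  dc <- segment_distance_matrix(c3, cfg$cdr3_metric, cfg)
  dj <- segment_distance_matrix(j, cfg$j_metric, cfg)
  out <- (cfg$alpha * dv + cfg$beta * dc + cfg$lambda * dj) /
    (cfg$alpha + cfg$beta + cfg$lambda)
  dimnames(out) <- NULL
  out
}
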