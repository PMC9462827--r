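# Clustering evaluation: pairwise and closeness precision/recall/F-score,
# five-event comparison of two clonal distributions, Gini/Lorenz clonality.

as_clustering_tbl <- function(x, what = "clustering") {
  if (inherits(x, "clonal_clustering")) x <- x$clustering
  if (!is.data.frame(x) || !all(c("sequence_id", "clone_id") %in% names(x))) {
    abort(sprintf("%s must be a tibble with columns sequence_id, clone_id", what))
  }
  if (anyDuplicated(x$sequence_id)) {
    abort(sprintf("%s assigns some sequence_id more than once", what))
  }
  x
}

check_same_ids <- function(truth, inferred) {
  only_t <- setdiff(truth$sequence_id, inferred$sequence_id)
  only_i <- setdiff(inferred$sequence_id, truth$sequence_id)
  if (length(only_t) || length(only_i)) {
    abort(sprintf(
      "truth and inferred clusterings cover different sequences (only in truth: %s%s; only in inferred: %s%s)",
      paste(utils::head(only_t, 5), collapse = ","),
      if (length(only_t) > 5) ",..." else "",
      paste(utils::head(only_i, 5), collapse = ","),
      if (length(only_i) > 5) ",..." else ""))
  }
}

prf <- function(tp, fp, fn, mode) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  fs <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble(mode = mode, precision = p, recall = r, fscore = fs,
         tp = tp, fp = fp, fn = fn)
}

#' Pairwise clustering metrics
#'
#' Over all unordered pairs of sequences: a pair is a true positive when
#' co-clustered in both truth and inference, a false positive when
#' co-clustered only in the inference, a false negative when co-clustered
#' only in the truth.  Precision, recall and F-score follow.
#'
#' @param truth,inferred clustering tibbles (`sequence_id`, `clone_id`) or
#'   `clonal_clustering` objects, over the same set of sequences.
#' @return one-row tibble: `mode`, `precision`, `recall`, `fscore`, `tp`,
#'   `fp`, `fn`.
#' @examples
#' truth <- tibble::tibble(sequence_id = c("a", "b", "c", "d"),
#'                         clone_id = c("1", "1", "1", "2"))
#' inf <- tibble::tibble(sequence_id = c("a", "b", "c", "d"),
#'                       clone_id = c("1", "1", "2", "2"))
#' pairwise_metrics(truth, inf)  # precision 0.5, recall 1/3, F 0.4
#' @export
pairwise_metrics <- function(truth, inferred) {
  truth <- as_clustering_tbl(truth, "truth")
  inferred <- as_clustering_tbl(inferred, "inferred")
  check_same_ids(truth, inferred)
  it <- truth$clone_id[match(inferred$sequence_id, truth$sequence_id)]
  tab <- table(it, inferred$clone_id)
  ch2 <- function(x) sum(choose(x, 2))
  tp <- ch2(tab)
  fp <- ch2(colSums(tab)) - tp
  fn <- ch2(rowSums(tab)) - tp
  prf(tp, fp, fn, "pairwise")
}

#' Match inferred clusters to truth clusters
#'
#' Greedy one-to-one association of inferred and truth clusters by
#' decreasing shared-sequence count (ties: larger truth cluster first, then
#' lexicographic truth label, then inferred label); each cluster is used at
#' most once and zero-overlap pairs are never matched.
#'
#' With `method = "optimal"` the greedy pass is replaced by an exact
#' assignment maximizing the total overlap (bitmask dynamic programming over
#' the smaller side; intended for small instances, at most 20 clusters on
#' the smaller side).
#'
#' @inheritParams pairwise_metrics
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return tibble with `inferred_id`, `truth_id`, `overlap`.
#' @export
match_clusters <- function(truth, inferred, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  truth <- as_clustering_tbl(truth, "truth")
  inferred <- as_clustering_tbl(inferred, "inferred")
  if (method == "optimal") return(match_clusters_optimal(truth, inferred))
  joined <- dplyr::inner_join(
    rename(truth, truth_id = "clone_id"),
    rename(inferred, inferred_id = "clone_id"),
    by = "sequence_id")
  cand <- joined |>
    count(.data$truth_id, .data$inferred_id, name = "overlap")
  tsize <- count(truth, .data$clone_id, name = "truth_size")
  cand <- cand |>
    left_join(tsize, by = c(truth_id = "clone_id")) |>
    arrange(desc(.data$overlap), desc(.data$truth_size),
            .data$truth_id, .data$inferred_id)
  used_t <- character(0); used_i <- character(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ti <- cand$truth_id[r]; ii <- cand$inferred_id[r]
    if (ti %in% used_t || ii %in% used_i) next
    keep[r] <- TRUE
    used_t <- c(used_t, ti); used_i <- c(used_i, ii)
  }
  cand[keep, c("inferred_id", "truth_id", "overlap")]
}

# Exact maximum-overlap one-to-one assignment via bitmask DP over the smaller
# cluster set; the larger side is scanned in sorted-label order.
match_clusters_optimal <- function(truth, inferred) {
  t_labels <- sort(unique(truth$clone_id))
  i_labels <- sort(unique(inferred$clone_id))
  swap <- length(t_labels) > length(i_labels)
  small <- if (swap) i_labels else t_labels
  big <- if (swap) t_labels else i_labels
  if (length(small) > 20L) {
    abort("match_clusters(method = \"optimal\"): more than 20 clusters on the smaller side")
  }
  joined <- dplyr::inner_join(
    rename(truth, truth_id = "clone_id"),
    rename(inferred, inferred_id = "clone_id"),
    by = "sequence_id")
  ov <- matrix(0L, length(big), length(small))
  cnt <- count(joined, .data$truth_id, .data$inferred_id, name = "overlap")
  bi <- if (swap) cnt$truth_id else cnt$inferred_id
  si <- if (swap) cnt$inferred_id else cnt$truth_id
  ov[cbind(match(bi, big), match(si, small))] <- cnt$overlap

  nb <- length(big)
  full_mask <- bitwShiftL(1L, length(small)) - 1L
  # best[r, mask]: max overlap using big clusters r..nb with 'mask' of small
  # clusters still available
  best <- matrix(NA_real_, nb + 1L, full_mask + 1L)
  best[nb + 1L, ] <- 0
  for (r in nb:1) {
    for (mask in 0:full_mask) {
      v <- best[r + 1L, mask + 1L]   # leave big cluster r unmatched
      for (s in seq_along(small)) {
        bit <- bitwShiftL(1L, s - 1L)
        if (bitwAnd(mask, bit) > 0L && ov[r, s] > 0L) {
          v <- max(v, ov[r, s] + best[r + 1L, bitwAnd(mask, bitwNot(bit)) + 1L])
        }
      }
      best[r, mask + 1L] <- v
    }
  }
  # trace back (prefer leaving unmatched, then lowest small label, on ties)
  pairs <- list()
  mask <- full_mask
  for (r in seq_len(nb)) {
    if (best[r, mask + 1L] == best[r + 1L, mask + 1L]) next
    for (s in seq_along(small)) {
      bit <- bitwShiftL(1L, s - 1L)
      if (bitwAnd(mask, bit) > 0L && ov[r, s] > 0L &&
          best[r, mask + 1L] == ov[r, s] + best[r + 1L, bitwAnd(mask, bitwNot(bit)) + 1L]) {
        pairs[[length(pairs) + 1L]] <-
          if (swap) c(inferred = small[s], truth = big[r])
          else c(inferred = big[r], truth = small[s])
        mask <- bitwAnd(mask, bitwNot(bit))
        break
      }
    }
  }
  if (length(pairs) == 0L) {
    return(tibble(inferred_id = character(), truth_id = character(),
                  overlap = integer()))
  }
  res <- tibble(inferred_id = vapply(pairs, `[[`, "", "inferred"),
                truth_id = vapply(pairs, `[[`, "", "truth"))
  cnt2 <- count(joined, .data$truth_id, .data$inferred_id, name = "overlap")
  left_join(res, cnt2, by = c("truth_id", "inferred_id")) |>
    arrange(desc(.data$overlap), .data$truth_id)
}

#' Closeness clustering metrics
#'
#' After matching inferred to truth clusters ([match_clusters()]), each
#' matched pair contributes its intersection to TP, the inferred-only
#' sequences to FP and the truth-only sequences to FN; the three sets are
#' unioned over matched pairs and precision/recall/F-score computed from
#' their cardinalities.  Sequences of unmatched clusters contribute nothing.
#' This mode is sensitive to the repertoire structure rather than to raw
#' pair counts.
#'
#' @inheritParams match_clusters
#' @return one-row tibble as in [pairwise_metrics()], `mode = "closeness"`.
#' @export
closeness_metrics <- function(truth, inferred, method = c("greedy", "optimal")) {
  truth <- as_clustering_tbl(truth, "truth")
  inferred <- as_clustering_tbl(inferred, "inferred")
  check_same_ids(truth, inferred)
  m <- match_clusters(truth, inferred, method = method)
  tp <- 0L; fp <- 0L; fn <- 0L
  t_sets <- split(truth$sequence_id, truth$clone_id)
  i_sets <- split(inferred$sequence_id, inferred$clone_id)
  for (r in seq_len(nrow(m))) {
    Ti <- t_sets[[m$truth_id[r]]]
    Ii <- i_sets[[m$inferred_id[r]]]
    tp <- tp + length(intersect(Ii, Ti))
    fp <- fp + length(setdiff(Ii, Ti))
    fn <- fn + length(setdiff(Ti, Ii))
  }
  prf(tp, fp, fn, "closeness")
}

#' Five-event comparison of two clonal distributions
#'
#' Labels every cluster of distribution `d2` by comparing it with the
#' clusters of distribution `d1`: `not_found` when it contains sequences
#' absent from `d1`; `identical` when it equals a `d1` cluster; `join` when
#' it is exactly the union of two or more whole `d1` clusters; `split` when
#' it is a proper subset of one `d1` cluster; `mix` otherwise.  The
#' precedence makes the five labels a total, mutually exclusive
#' classification.
#'
#' @param d1,d2 clustering tibbles (`sequence_id`, `clone_id`) or
#'   `clonal_clustering` objects; `d2` may contain sequences absent from
#'   `d1` (they feed `not_found`).
#' @return a list with `counts` (one-row tibble: `identical`, `join`,
#'   `split`, `mix`, `not_found`) and `events` (tibble `clone_id`, `event`
#'   for every `d2` cluster).
#' @export
compare_distributions <- function(d1, d2) {
  d1 <- as_clustering_tbl(d1, "d1")
  d2 <- as_clustering_tbl(d2, "d2")
  d1_of <- setNames(d1$clone_id, d1$sequence_id)
  d1_sizes <- table(d1$clone_id)
  classify <- function(ids) {
    src <- d1_of[ids]
    if (anyNA(src)) return("not_found")
    src_tab <- table(src)
    whole <- all(src_tab == d1_sizes[names(src_tab)])
    if (length(src_tab) == 1L) {
      if (whole) "identical" else "split"
    } else {
      if (whole) "join" else "mix"
    }
  }
  events <- d2 |>
    group_by(.data$clone_id) |>
    summarise(event = classify(.data$sequence_id), .groups = "drop")
  lv <- c("identical", "join", "split", "mix", "not_found")
  cnt <- table(factor(events$event, levels = lv))
  counts <- as_tibble(as.list(as.integer(cnt)), .name_repair = "minimal")
  names(counts) <- lv
  list(counts = counts, events = events)
}

#' Gini coefficient of cluster sizes
#'
#' Mean-absolute-difference Gini of a size distribution:
#' \eqn{\sum_{ij} |x_i - x_j| / (2 n^2 \bar x)}.  0 means a perfectly even
#' repertoire; values near 1 indicate one dominant clone (the maximum for n
#' values is 1 - 1/n).
#'
#' @param sizes positive numeric vector (cluster sizes).
#' @return a number in \[0, 1\].
#' @examples
#' gini_coefficient(c(5, 5, 5, 5))  # 0
#' gini_coefficient(c(1, 1, 8))     # 28/60
#' @export
gini_coefficient <- function(sizes) {
  if (length(sizes) == 0) abort("gini_coefficient: empty size vector")
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    abort("gini_coefficient: sizes must be positive")
  }
  n <- length(sizes)
  xs <- sort(sizes)
  # sorted closed form of the pairwise mean-difference formula
  (2 * sum(seq_len(n) * xs) / (n * sum(xs))) - (n + 1) / n
}

#' Lorenz curve of cluster sizes
#'
#' Cumulative-fraction curve of a size distribution: clusters ordered from
#' least to most abundant on the x axis, cumulative sequence fraction on the
#' y axis.  Starts at (0, 0), ends at (1, 1), convex;
#' `1 - 2 * AUC` equals the Gini coefficient.
#'
#' @param sizes positive numeric vector.
#' @return tibble with columns `p` (cumulative cluster fraction) and `L`
#'   (cumulative sequence fraction), including the (0, 0) point.
#' @export
lorenz_curve <- function(sizes) {
  if (length(sizes) == 0) abort("lorenz_curve: empty size vector")
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    abort("lorenz_curve: sizes must be positive")
  }
  xs <- sort(sizes)
  n <- length(xs)
  tibble(p = c(0, seq_len(n) / n), L = c(0, cumsum(xs) / sum(xs)))
}

#' Plot a Lorenz curve
#'
#' @param object output of [lorenz_curve()], or a positive size vector.
#' @param ... unused.
#' @return a ggplot with the curve, the equality diagonal and the Gini
#'   coefficient in the subtitle.
#' @export
plot_lorenz <- function(object, ...) {
  if (is.numeric(object)) {
    g <- gini_coefficient(object)
    object <- lorenz_curve(object)
  } else {
    g <- NA_real_
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p, y = .data$L)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "cumulative fraction of clonal lineages",
                  y = "cumulative fraction of sequences",
                  title = "Lorenz curve of clonal lineage sizes",
                  subtitle = if (is.na(g)) NULL else sprintf("Gini = %.3f", g)) +
    ggplot2::theme_minimal()
}

#' Evaluate an inferred clustering against truth
#'
#' Convenience wrapper: both metric modes, the five-event comparison (truth
#' as `d1`, inference as `d2`) and the Gini coefficient of the inferred
#' cluster sizes.
#'
#' @inheritParams pairwise_metrics
#' @return a list with `metrics` (two-row tibble), `events` (one-row count
#'   tibble), `gini`.
#' @export
evaluate_clustering <- function(truth, inferred) {
  truth <- as_clustering_tbl(truth, "truth")
  inferred <- as_clustering_tbl(inferred, "inferred")
  metrics <- bind_rows(pairwise_metrics(truth, inferred),
                       closeness_metrics(truth, inferred))
  ev <- compare_distributions(truth, inferred)
  sizes <- as.integer(table(inferred$clone_id))
  list(metrics = metrics, events = ev$counts, gini = gini_coefficient(sizes))
}
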