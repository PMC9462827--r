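# Independent oracles and small fixture builders used across the suite.

# Quadratic dynamic-programming Levenshtein, written independently of the
# package implementation (which delegates to utils::adist).
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- as.integer(ca[i] != cb[j])
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# Explicit O(n^2) enumeration of co-clustered pairs.
pair_metrics_oracle <- function(truth, inferred) {
  ids <- truth$sequence_id
  t_of <- setNames(truth$clone_id, truth$sequence_id)
  i_of <- setNames(inferred$clone_id, inferred$sequence_id)
  tp <- fp <- fn <- 0L
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_t <- t_of[ids[i]] == t_of[ids[j]]
      same_i <- i_of[ids[i]] == i_of[ids[j]]
      if (same_t && same_i) tp <- tp + 1L
      else if (!same_t && same_i) fp <- fp + 1L
      else if (same_t && !same_i) fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Exhaustive one-to-one assignment maximizing total overlap (for small
# cluster counts): the optimal-matching oracle for closeness metrics.
# Enumerates every matching (each truth cluster pairs with an unused inferred
# cluster of positive overlap, or stays unmatched) and returns all
# (tp, fp, fn) triples achieved by maximum-total-overlap matchings: ties in
# the optimum can differ in fp/fn while sharing tp.
closeness_oracle <- function(truth, inferred) {
  t_sets <- split(truth$sequence_id, truth$clone_id)
  i_sets <- split(inferred$sequence_id, inferred$clone_id)
  nt <- length(t_sets); ni <- length(i_sets)
  results <- list()
  recurse <- function(t_idx, used_i, pairs) {
    if (t_idx > nt) {
      tp <- fp <- fn <- 0L
      for (p in pairs) {
        Ti <- t_sets[[p[1]]]; Ii <- i_sets[[p[2]]]
        tp <- tp + length(intersect(Ii, Ti))
        fp <- fp + length(setdiff(Ii, Ti))
        fn <- fn + length(setdiff(Ti, Ii))
      }
      results[[length(results) + 1L]] <<- c(tp = tp, fp = fp, fn = fn)
      return(invisible())
    }
    recurse(t_idx + 1L, used_i, pairs)          # leave this truth cluster out
    for (ii in setdiff(seq_len(ni), used_i)) {
      if (length(intersect(t_sets[[t_idx]], i_sets[[ii]])) > 0) {
        recurse(t_idx + 1L, c(used_i, ii), c(pairs, list(c(t_idx, ii))))
      }
    }
  }
  recurse(1L, integer(0), list())
  m <- do.call(rbind, results)
  max_tp <- max(m[, "tp"])
  unique(as.data.frame(m[m[, "tp"] == max_tp, , drop = FALSE]))
}

# Union-find single-linkage components over an identity matrix.
components_oracle <- function(idm, s) {
  n <- nrow(idm)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (idm[i, j] >= s) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) {
          parent[rj] <- min(ri, rj)
          parent[ri] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Tiny repertoire builder.
make_rep <- function(v, j, cdr3, ids = NULL) {
  n <- max(length(v), length(j), length(cdr3))
  tibble::tibble(
    sequence_id = ids %||% sprintf("s%02d", seq_len(n)),
    v_call = rep_len(v, n), j_call = rep_len(j, n),
    v_gene = sub("\\*.*$", "", rep_len(v, n)),
    j_gene = sub("\\*.*$", "", rep_len(j, n)),
    cdr3_aa = rep_len(cdr3, n))
}

clustering_tbl <- function(ids, labels) {
  tibble::tibble(sequence_id = ids, clone_id = as.character(labels))
}

random_aa <- function(n, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(aa, len[i], replace = TRUE), collapse = ""), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical form of a partition: sorted member sets, ordered by first member.
canonical_partition <- function(cl) {
  if (inherits(cl, "clonal_clustering")) cl <- cl$clustering
  sets <- lapply(split(cl$sequence_id, cl$clone_id), sort)
  unname(sets[order(vapply(sets, `[`, "", 1))])
}

expect_same_partition <- function(a, b) {
  expect_equal(canonical_partition(a), canonical_partition(b))
}
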