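# Internal helpers -----------------------------------------------------------

# Convert a clustering tibble (sequence_id, clone_id) into an integer
# assignment vector aligned with the repertoire rows; checks the partition
# property.
assignment_from_tibble <- function(clustering, rep) {
  if (inherits(clustering, "clonal_clustering")) clustering <- clustering$clustering
  miss <- setdiff(rep$sequence_id, clustering$sequence_id)
  extra <- setdiff(clustering$sequence_id, rep$sequence_id)
  if (length(miss) || length(extra)) {
    abort(sprintf(
      "clustering is not a partition of the repertoire (missing: %d, foreign: %d)",
      length(miss), length(extra)))
  }
  lab <- clustering$clone_id[match(rep$sequence_id, clustering$sequence_id)]
  num <- suppressWarnings(as.numeric(lab))
  ord_labels <- if (!anyNA(num)) unique(lab)[order(unique(num))] else sort(unique(lab))
  match(lab, ord_labels)
}

# Per-sequence mean distance to every cluster.  Returns list(S = n x K sum
# matrix, sizes, labels) with columns in ascending label order.
cluster_sums <- function(D, a) {
  labels <- sort(unique(a))
  Z <- outer(a, labels, "==") * 1
  list(S = D %*% Z, sizes = colSums(Z), labels = labels)
}

# Silhouette-style terms for all sequences at once.  b_i is the smallest
# *average* distance of i to the members of any other cluster (the textual,
# Silhouette-consistent definition); nearest is its argmin, ties broken by
# the smallest cluster label.
silhouette_terms <- function(D, a) {
  cs <- cluster_sums(D, a)
  K <- length(cs$labels)
  n <- length(a)
  own_col <- match(a, cs$labels)
  own_size <- cs$sizes[own_col]
  a_i <- ifelse(own_size > 1, cs$S[cbind(seq_len(n), own_col)] / (own_size - 1), NA_real_)
  M <- sweep(cs$S, 2, cs$sizes, "/")
  M[cbind(seq_len(n), own_col)] <- Inf
  if (K > 1) {
    nearest_col <- apply(M, 1, which.min)
    b_i <- M[cbind(seq_len(n), nearest_col)]
    nearest <- cs$labels[nearest_col]
  } else {
    b_i <- rep(NA_real_, n)
    nearest <- rep(NA_integer_, n)
  }
  list(a_i = a_i, b_i = b_i, nearest = nearest, sizes = cs$sizes, labels = cs$labels)
}

# Algorithm-1 refinement on an assignment vector.  Clusters are visited in
# ascending label order and sequences in input order; the first sequence with
# a_i > b_i triggers an immediate merge of its cluster with the nearest
# cluster, and a new pass begins.
refine_assign <- function(D, a, max_iter = 1000L) {
  merges <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (length(unique(a)) < 2L) break
    st <- silhouette_terms(D, a)
    eligible <- which(!is.na(st$a_i) & st$a_i > st$b_i)
    if (length(eligible) == 0L) break
    first <- eligible[order(a[eligible], eligible)][1]
    k <- a[first]
    l <- st$nearest[first]
    new_label <- min(k, l)
    a[a == k | a == l] <- new_label
    merges <- merges + 1L
    if (iter >= max_iter) {
      warn(sprintf("refinement stopped after max_iter = %d passes", max_iter))
      break
    }
  }
  list(assignment = a, iterations = iter, merges = merges)
}

# Uniformity (absolute-deviation form by default) from a cluster's distance
# submatrix.
uniformity_from_dist <- function(subD, literal = FALSE) {
  n <- nrow(subD)
  if (is.null(n) || n <= 1L) return(0)
  diag(subD) <- Inf
  local <- apply(subD, 1, min)
  avg <- mean(local)
  if (avg == 0) return(0)
  if (literal) sum(local - avg) / avg else sum(abs(local - avg)) / avg
}

# Algorithm-2 singleton absorption on an assignment vector.  Singletons are
# processed in ascending label order; merges are applied immediately so later
# singletons see enlarged clusters.
merge_singletons_assign <- function(D, a, delta = 0.05, literal = FALSE) {
  merged <- 0L
  sizes0 <- table(a)
  singleton_labels <- sort(as.integer(names(sizes0)[sizes0 == 1L]))
  for (k in singleton_labels) {
    members_k <- which(a == k)
    if (length(members_k) != 1L) next   # absorbed meanwhile
    if (length(unique(a)) < 2L) break
    i <- members_k
    labels <- sort(setdiff(unique(a), k))
    means <- vapply(labels, function(l) mean(D[i, a == l]), numeric(1))
    l <- labels[which.min(means)]
    idx_l <- which(a == l)
    u_l <- uniformity_from_dist(D[idx_l, idx_l, drop = FALSE], literal)
    idx_lk <- c(idx_l, i)
    u_lk <- uniformity_from_dist(D[idx_lk, idx_lk, drop = FALSE], literal)
    if (abs(u_lk - u_l) < delta) {
      a[i] <- l
      merged <- merged + 1L
    }
  }
  list(assignment = a, merged = merged)
}

# Exported, tibble-facing surfaces -------------------------------------------

#' Intra-clonal mean distances (silhouette a-terms)
#'
#' For every sequence in a cluster with at least two members, the mean
#' composed distance to the other members of its cluster; `NA` for
#' singletons (the term is undefined there and the refinement never uses it).
#'
#' @param rep repertoire tibble.
#' @param clustering tibble with `sequence_id`, `clone_id`.
#' @param dist_config a [distance_config()].
#' @return tibble with `sequence_id`, `clone_id`, `a_i`.
#' @export
intra_distances <- function(rep, clustering, dist_config = distance_config()) {
  a <- assignment_from_tibble(clustering, rep)
  D <- distance_matrix(rep, dist_config)
  st <- silhouette_terms(D, a)
  if (inherits(clustering, "clonal_clustering")) clustering <- clustering$clustering
  lab <- clustering$clone_id[match(rep$sequence_id, clustering$sequence_id)]
  tibble(sequence_id = rep$sequence_id, clone_id = lab, a_i = st$a_i)
}

#' Inter-clonal distances (silhouette b-terms)
#'
#' For every sequence, the smallest mean composed distance to the members of
#' any other cluster, and the cluster attaining it (ties broken by the
#' smallest cluster label).
#'
#' @inheritParams intra_distances
#' @return tibble with `sequence_id`, `clone_id`, `b_i`, `nearest_clone_id`.
#' @export
inter_distances <- function(rep, clustering, dist_config = distance_config()) {
  a <- assignment_from_tibble(clustering, rep)
  if (length(unique(a)) < 2L) {
    abort("inter_distances: clustering must have at least two clusters")
  }
  D <- distance_matrix(rep, dist_config)
  st <- silhouette_terms(D, a)
  if (inherits(clustering, "clonal_clustering")) clustering <- clustering$clustering
  labs <- clustering$clone_id[match(rep$sequence_id, clustering$sequence_id)]
  nearest_lab <- vapply(st$nearest, function(l) {
    labs[which(a == l)[1]]
  }, character(1))
  tibble(sequence_id = rep$sequence_id, clone_id = labs,
         b_i = st$b_i, nearest_clone_id = nearest_lab)
}

#' Local densities within clusters
#'
#' The minimum composed distance from each sequence to another member of its
#' cluster (`NA` for singletons).
#'
#' @inheritParams intra_distances
#' @return tibble with `sequence_id`, `clone_id`, `local_density`.
#' @export
local_densities <- function(rep, clustering, dist_config = distance_config()) {
  a <- assignment_from_tibble(clustering, rep)
  D <- distance_matrix(rep, dist_config)
  diag(D) <- Inf
  local <- vapply(seq_along(a), function(i) {
    others <- which(a == a[i])
    if (length(others) < 2L) return(NA_real_)
    min(D[i, setdiff(others, i)])
  }, numeric(1))
  if (inherits(clustering, "clonal_clustering")) clustering <- clustering$clustering
  lab <- clustering$clone_id[match(rep$sequence_id, clustering$sequence_id)]
  tibble(sequence_id = rep$sequence_id, clone_id = lab, local_density = local)
}

#' Cluster uniformity and average density
#'
#' For each cluster: `avg_density`, the mean of the members' local densities
#' (minimum distance to another member), and `uniformity`, the sum of
#' deviations of local densities from their mean, divided by the mean.
#' Smaller values indicate a more uniform cluster.  Singletons and clusters
#' whose average density is zero (e.g. duplicated clonotypes) have
#' uniformity 0 by definition.
#'
#' As printed, the uniformity sum uses signed deviations, which is
#' identically zero; the default here uses absolute deviations
#' (`literal = FALSE`), the variability measure the statistic is meant to be.
#' Set `literal = TRUE` to audit the printed form.
#'
#' @inheritParams intra_distances
#' @param literal use the literal signed-deviation form (identically 0).
#' @return tibble with `clone_id`, `n`, `avg_density`, `uniformity`.
#' @export
cluster_uniformity <- function(rep, clustering, dist_config = distance_config(),
                               literal = FALSE) {
  a <- assignment_from_tibble(clustering, rep)
  D <- distance_matrix(rep, dist_config)
  if (inherits(clustering, "clonal_clustering")) clustering <- clustering$clustering
  lab <- clustering$clone_id[match(rep$sequence_id, clustering$sequence_id)]
  labels <- unique(lab)
  purrr::map_dfr(labels, function(cl) {
    idx <- which(lab == cl)
    sub <- D[idx, idx, drop = FALSE]
    n <- length(idx)
    avg <- if (n > 1) { d2 <- sub; diag(d2) <- Inf; mean(apply(d2, 1, min)) } else NA_real_
    tibble(clone_id = cl, n = n, avg_density = avg,
           uniformity = uniformity_from_dist(sub, literal))
  })
}

#' Refine a clustering by merging inconsistent clusters
#'
#' Iterated cohesion/separation refinement: clusters are visited in ascending
#' label order and their members in input order; the first sequence whose
#' intra-clonal mean distance exceeds its smallest inter-clonal mean distance
#' (`a_i > b_i`) causes its cluster to be merged with the nearest cluster,
#' and a new pass begins.  Stops when a full pass performs no merge, or after
#' `max_iter` passes.
#'
#' @inheritParams intra_distances
#' @param max_iter pass cap (default 1000).
#' @return tibble with `sequence_id`, `clone_id`; attributes `iterations` and
#'   `merges`.
#' @export
refine_clusters <- function(rep, clustering, dist_config = distance_config(),
                            max_iter = 1000L) {
  a <- assignment_from_tibble(clustering, rep)
  D <- distance_matrix(rep, dist_config)
  res <- refine_assign(D, a, max_iter)
  out <- tibble(sequence_id = rep$sequence_id,
                clone_id = as.character(res$assignment))
  attr(out, "iterations") <- res$iterations
  attr(out, "merges") <- res$merges
  out
}

#' Absorb singletons into uniform clusters
#'
#' Every singleton cluster (in ascending label order) is tentatively merged
#' with its closest cluster — the one minimizing the mean composed distance
#' from the singleton's sequence — and the merge is kept iff the cluster's
#' uniformity changes by less than `delta`:
#' `|unif(l + k) - unif(l)| < delta`.  Enlarged clusters are visible to the
#' singletons processed after them.
#'
#' @inheritParams cluster_uniformity
#' @param delta uniformity-change tolerance (default 0.05).
#' @return tibble with `sequence_id`, `clone_id`; attribute `merged` counts
#'   absorbed singletons.
#' @export
merge_singletons <- function(rep, clustering, dist_config = distance_config(),
                             delta = 0.05, literal = FALSE) {
  a <- assignment_from_tibble(clustering, rep)
  D <- distance_matrix(rep, dist_config)
  res <- merge_singletons_assign(D, a, delta, literal)
  out <- tibble(sequence_id = rep$sequence_id,
                clone_id = as.character(res$assignment))
  attr(out, "merged") <- res$merged
  out
}
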