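#' Infer clonal lineages from an annotated IGH repertoire
#'
#' The full pipeline: pre-clustering (same V gene, same J gene, same CDR3
#' length, split at the CDR3 identity threshold `s`), cohesion/separation
#' refinement, and singleton absorption.  Both refinement stages only ever
#' merge clusters, so the pre-clustering fixes the finest partition the
#' method can output.
#'
#' @param rep repertoire tibble (as from [read_airr()] or
#'   [simulate_repertoire()]`$repertoire`): columns `sequence_id`,
#'   `v_gene`/`v_call`, `j_gene`/`j_call`, `cdr3_aa` (or `junction_aa`).
#' @param s CDR3 amino-acid identity threshold, fraction or percent
#'   (default 0.70).
#' @param dist_config a [distance_config()]; the default is the published
#'   default (binary V, Levenshtein CDR3 and J, equal coefficients).
#' @param delta singleton-absorption uniformity tolerance (default 0.05).
#' @param refine run the cohesion/separation refinement (default `TRUE`).
#' @param merge_singletons run the singleton-absorption step (default `TRUE`).
#' @param max_iter refinement pass cap (default 1000).
#' @param allele_level pre-cluster by full allele calls.
#' @param cdr3_length_tolerance pool CDR3-length bins within this many
#'   residues during pre-clustering (default 0).
#' @param quiet suppress progress messages.
#' @return an object of class `clonal_clustering`: a list with
#'   \describe{
#'     \item{clustering}{tibble `sequence_id`, `clone_id` (labels `"1"`,
#'       `"2"`, ... in decreasing cluster size)}
#'     \item{report}{list of per-stage cluster counts, merge counts,
#'       iterations and wall time}
#'     \item{config}{the parameters used}
#'   }
#'   Use [generics::tidy()] for the per-sequence assignment,
#'   [generics::glance()] for a one-row summary, and `autoplot()` for a
#'   rank-abundance view.
#' @examples
#' rep <- tibble::tibble(
#'   sequence_id = paste0("s", 1:4),
#'   v_call = c("IGHV1-69", "IGHV1-69", "IGHV1-69", "IGHV3-23"),
#'   j_call = "IGHJ4",
#'   cdr3_aa = c("CARDYW", "CARDFW", "CARDYW", "CTTTTW"))
#' fit <- cluster_lineages(rep, quiet = TRUE)
#' generics::glance(fit)
#' @export
cluster_lineages <- function(rep,
                             s = 0.70,
                             dist_config = distance_config(),
                             delta = 0.05,
                             refine = TRUE,
                             merge_singletons = TRUE,
                             max_iter = 1000L,
                             allele_level = FALSE,
                             cdr3_length_tolerance = 0L,
                             quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (nrow(rep) == 0) abort("cluster_lineages: empty repertoire")
  if (is.null(rep$cdr3_aa)) rep$cdr3_aa <- rep$junction_aa
  if (anyDuplicated(rep$sequence_id)) abort("cluster_lineages: duplicated sequence_id")

  a <- precluster_assign(rep, s, allele_level, cdr3_length_tolerance)
  n_pre <- length(unique(a))
  if (!quiet) inform(sprintf("pre-clustering: %d initial clusters", n_pre))

  iterations <- 0L; refine_merges <- 0L; singleton_merges <- 0L
  n_refined <- n_pre
  if (refine || merge_singletons) {
    D <- distance_matrix(rep, dist_config)
    if (refine) {
      res <- refine_assign(D, a, max_iter)
      a <- res$assignment
      iterations <- res$iterations
      refine_merges <- res$merges
      n_refined <- length(unique(a))
      if (!quiet) inform(sprintf("refinement: %d merges in %d passes -> %d clusters",
                                 refine_merges, iterations, n_refined))
    }
    if (merge_singletons) {
      res <- merge_singletons_assign(D, a, delta)
      a <- res$assignment
      singleton_merges <- res$merged
      if (!quiet) inform(sprintf("singleton absorption: %d singletons merged -> %d clusters",
                                 singleton_merges, length(unique(a))))
    }
  }

  # final labels: "1", "2", ... by decreasing size, ties by first appearance
  sizes <- table(a)
  first_seen <- match(names(sizes), as.character(a))
  ord <- order(-as.integer(sizes), first_seen)
  relabel <- setNames(as.character(seq_along(ord)), names(sizes)[ord])
  clustering <- tibble(sequence_id = rep$sequence_id,
                       clone_id = unname(relabel[as.character(a)]))

  structure(list(
    clustering = clustering,
    repertoire = rep,
    report = list(
      n_sequences = nrow(rep),
      n_preclusters = n_pre,
      n_after_refine = n_refined,
      n_clusters = length(unique(a)),
      refine_iterations = iterations,
      refine_merges = refine_merges,
      singleton_merges = singleton_merges,
      elapsed_sec = unname(proc.time()[["elapsed"]] - t0)
    ),
    config = list(s = normalize_threshold(s), dist_config = dist_config,
                  delta = delta, refine = refine,
                  merge_singletons = merge_singletons, max_iter = max_iter,
                  allele_level = allele_level,
                  cdr3_length_tolerance = cdr3_length_tolerance)
  ), class = "clonal_clustering")
}

#' @export
print.clonal_clustering <- function(x, ...) {
  r <- x$report
  cat(sprintf("<clonal_clustering> %d sequences in %d clonal lineages\n",
              r$n_sequences, r$n_clusters))
  cat(sprintf("  pre-clusters: %d; after refinement: %d (%d merges, %d passes); singletons absorbed: %d\n",
              r$n_preclusters, r$n_after_refine, r$refine_merges,
              r$refine_iterations, r$singleton_merges))
  sizes <- sort(table(x$clustering$clone_id), decreasing = TRUE)
  cat(sprintf("  largest lineage: %d sequences (%.1f%%); singletons: %d\n",
              sizes[1], 100 * sizes[1] / r$n_sequences, sum(sizes == 1)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a clonal clustering
#'
#' @param x a `clonal_clustering`.
#' @param ... unused.
#' @return per-sequence tibble: `sequence_id`, `clone_id`, `clone_size`,
#'   `clone_abundance`.
#' @method tidy clonal_clustering
#' @export
tidy.clonal_clustering <- function(x, ...) {
  x$clustering |>
    group_by(.data$clone_id) |>
    mutate(clone_size = n()) |>
    ungroup() |>
    mutate(clone_abundance = .data$clone_size / n())
}

#' Glance at a clonal clustering
#'
#' @param x a `clonal_clustering`.
#' @param ... unused.
#' @return one-row tibble: sequence and cluster counts, singleton count,
#'   largest-lineage fraction, and the Gini coefficient of cluster sizes.
#' @method glance clonal_clustering
#' @export
glance.clonal_clustering <- function(x, ...) {
  sizes <- as.integer(table(x$clustering$clone_id))
  tibble(
    n_sequences = x$report$n_sequences,
    n_clusters = length(sizes),
    n_singletons = sum(sizes == 1L),
    largest_fraction = max(sizes) / sum(sizes),
    gini = gini_coefficient(sizes),
    refine_iterations = x$report$refine_iterations,
    elapsed_sec = x$report$elapsed_sec
  )
}

#' Rank-abundance plot of a clonal clustering
#'
#' @param object a `clonal_clustering`.
#' @param top number of top-ranked lineages to display (default 100).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot clonal_clustering
#' @export
autoplot.clonal_clustering <- function(object, top = 100, ...) {
  sizes <- object$clustering |>
    count(.data$clone_id, name = "size") |>
    arrange(desc(.data$size)) |>
    mutate(rank = row_number(),
           abundance = .data$size / sum(.data$size)) |>
    filter(.data$rank <= top)
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$rank, y = .data$abundance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%g%%", 100 * v)) +
    ggplot2::labs(x = "clonal lineage rank", y = "abundance",
                  title = "Clonal lineage rank-abundance") +
    ggplot2::theme_minimal()
}
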