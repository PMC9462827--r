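# Parameter-grid runner: enumerate threshold x per-segment metric x
# coefficient-scheme x singleton-merge configurations and score each on
# truth-labelled benchmarks.

#' Default coefficient schemes for the composed distance
#'
#' Seven (alpha, beta, lambda) weightings: the arithmetic mean plus the six
#' distinct 2/1 emphases of one or two segments.  Scheme labels follow the
#' `d<alpha><beta><lambda>` convention (`"mean"` for equal weights).
#'
#' @return tibble with `scheme`, `alpha`, `beta`, `lambda` (7 rows).
#' @export
coefficient_schemes <- function() {
  tibble(
    scheme = c("mean", "d211", "d121", "d112", "d221", "d212", "d122"),
    alpha  = c(1, 2, 1, 1, 2, 2, 1),
    beta   = c(1, 1, 2, 1, 2, 1, 2),
    lambda = c(1, 1, 1, 2, 1, 2, 2))
}

#' Enumerate a parameter grid
#'
#' Cartesian product of pre-clustering thresholds, per-segment distance
#' metrics, coefficient schemes and the singleton-merge switch.  The default
#' axes (5 thresholds x 4 metrics per each of 3 segments x 7 schemes x 2)
#' enumerate 4480 configurations.
#'
#' @param s thresholds, percent or fraction (default 50..90 by 10).
#' @param metrics metric choices applied independently to each of the V,
#'   CDR3 and J segments.
#' @param schemes coefficient schemes tibble (`scheme`, `alpha`, `beta`,
#'   `lambda`); default [coefficient_schemes()].
#' @param merge_singletons logical axis (default both on and off).
#' @return tibble with one row per configuration: `config_id`, `s`,
#'   `v_metric`, `cdr3_metric`, `j_metric`, `scheme`, `alpha`, `beta`,
#'   `lambda`, `merge_singletons`.
#' @examples
#' nrow(grid_configs())  # 4480
#' @export
grid_configs <- function(s = c(50, 60, 70, 80, 90),
                         metrics = c("binary", "levenshtein", "kmer", "giana"),
                         schemes = coefficient_schemes(),
                         merge_singletons = c(TRUE, FALSE)) {
  if (length(s) == 0 || length(metrics) == 0 || nrow(schemes) == 0 ||
      length(merge_singletons) == 0) {
    abort("grid_configs: every grid axis must be non-empty")
  }
  g <- tidyr::expand_grid(
    s = vapply(s, normalize_threshold, numeric(1)),
    v_metric = metrics, cdr3_metric = metrics, j_metric = metrics,
    scheme = schemes$scheme,
    merge_singletons = merge_singletons) |>
    left_join(schemes, by = "scheme") |>
    mutate(config_id = row_number()) |>
    select("config_id", dplyr::everything())
  g
}

#' Run a parameter grid on truth-labelled benchmarks
#'
#' Runs [cluster_lineages()] for every configuration on every benchmark and
#' scores each run in both metric modes.  The full default grid on the full
#' benchmark set is a large computation; use the `configs` argument to run a
#' subset at desk scale.
#'
#' @param benchmarks a named list of benchmarks, each a list with elements
#'   `repertoire` and `truth` (e.g. [simulate_repertoire()] outputs).
#' @param configs a grid tibble from [grid_configs()] (possibly subset).
#' @param delta singleton-absorption tolerance (default 0.05).
#' @param quiet suppress the planned-run announcement and progress.
#' @return tidy results tibble: one row per configuration x benchmark with
#'   the config fields, `benchmark`, and `pairwise_*` / `closeness_*`
#'   precision, recall, F-score columns.
#' @export
grid_run <- function(benchmarks, configs = grid_configs(), delta = 0.05,
                     quiet = FALSE) {
  if (is.null(names(benchmarks))) {
    names(benchmarks) <- sprintf("benchmark%02d", seq_along(benchmarks))
  }
  planned <- nrow(configs) * length(benchmarks)
  if (!quiet) {
    inform(sprintf("grid_run: %d configurations x %d benchmarks = %d planned runs",
                   nrow(configs), length(benchmarks), planned))
  }
  purrr::map_dfr(names(benchmarks), function(bn) {
    bench <- benchmarks[[bn]]
    purrr::pmap_dfr(configs, function(config_id, s, v_metric, cdr3_metric,
                                      j_metric, scheme, merge_singletons,
                                      alpha, beta, lambda, ...) {
      dcfg <- distance_config(v_metric = v_metric, cdr3_metric = cdr3_metric,
                              j_metric = j_metric, alpha = alpha, beta = beta,
                              lambda = lambda)
      fit <- cluster_lineages(bench$repertoire, s = s, dist_config = dcfg,
                              delta = delta,
                              merge_singletons = merge_singletons,
                              quiet = TRUE)
      pw <- pairwise_metrics(bench$truth, fit$clustering)
      cl <- closeness_metrics(bench$truth, fit$clustering)
      tibble(config_id = config_id, benchmark = bn, s = s,
             v_metric = v_metric, cdr3_metric = cdr3_metric,
             j_metric = j_metric, scheme = scheme,
             merge_singletons = merge_singletons,
             n_clusters = length(unique(fit$clustering$clone_id)),
             pairwise_precision = pw$precision, pairwise_recall = pw$recall,
             pairwise_fscore = pw$fscore,
             closeness_precision = cl$precision, closeness_recall = cl$recall,
             closeness_fscore = cl$fscore)
    })
  })
}

#' Number of planned grid runs
#'
#' @param configs grid tibble from [grid_configs()].
#' @param n_benchmarks number of benchmarks the grid would run on.
#' @return integer: configurations times benchmarks.
#' @export
grid_plan <- function(configs = grid_configs(), n_benchmarks = 12L) {
  nrow(configs) * as.integer(n_benchmarks)
}
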