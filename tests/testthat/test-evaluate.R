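test_that("pairwise metrics match exhaustive pair enumeration on fixed examples", {
  truth <- clustering_tbl(c("a", "b", "c", "d"), c(1, 1, 1, 2))
  inf <- clustering_tbl(c("a", "b", "c", "d"), c(1, 1, 2, 2))
  got <- pairwise_metrics(truth, inf)
  # pairs: TP = (a,b); FP = (c,d); FN = (a,c), (b,c)
  expect_equal(got$tp, 1)
  expect_equal(got$fp, 1)
  expect_equal(got$fn, 2)
  expect_equal(got$precision, 0.5)
  expect_equal(got$recall, 1 / 3)
  expect_equal(got$fscore, 0.4)

  expect_equal(pairwise_metrics(truth, truth)$fscore, 1)

  # all-singletons inference: no co-clustered pair at all -> 0 by convention
  singl <- clustering_tbl(c("a", "b", "c", "d"), 1:4)
  one <- clustering_tbl(c("a", "b", "c", "d"), c(1, 1, 1, 1))
  z <- pairwise_metrics(one, singl)
  expect_equal(c(z$precision, z$recall, z$fscore), c(0, 0, 0))

  expect_error(pairwise_metrics(truth, clustering_tbl(c("a", "b", "c", "x"), 1:4)),
               "different sequences")
})

test_that("pairwise metrics equal the O(n^2) enumeration oracle", {
  set.seed(55)
  for (n in c(25, 80, 200)) {
    ids <- sprintf("r%03d", seq_len(n))
    truth <- clustering_tbl(ids, sample(seq_len(max(2, n %/% 8)), n, TRUE))
    inf <- clustering_tbl(ids, sample(seq_len(max(2, n %/% 6)), n, TRUE))
    got <- pairwise_metrics(truth, inf)
    want <- pair_metrics_oracle(truth, inf)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
  }
})

test_that("pairwise metrics are invariant to cluster relabelling", {
  set.seed(56)
  ids <- sprintf("r%02d", 1:40)
  truth <- clustering_tbl(ids, sample(1:5, 40, TRUE))
  inf <- clustering_tbl(ids, sample(1:6, 40, TRUE))
  relab <- clustering_tbl(ids, paste0("zz", inf$clone_id))
  expect_equal(pairwise_metrics(truth, inf)[, -1],
               pairwise_metrics(truth, relab)[, -1])
})

test_that("cluster matching is greedy on overlap with deterministic ties", {
  truth <- clustering_tbl(sprintf("s%d", 1:6), c(1, 1, 1, 1, 2, 2))
  # inferred splits truth cluster 1 into {s1,s2,s3} and {s4}
  inf <- clustering_tbl(sprintf("s%d", 1:6), c("a", "a", "a", "b", "c", "c"))
  m <- match_clusters(truth, inf)
  expect_equal(m$inferred_id[m$truth_id == "1"], "a")   # larger fragment wins
  expect_false("b" %in% m$inferred_id)                  # smaller fragment unmatched
  expect_equal(m$inferred_id[m$truth_id == "2"], "c")

  perfect <- match_clusters(truth, truth)
  expect_equal(nrow(perfect), 2)
  expect_equal(perfect$overlap, c(4, 2))
})

test_that("closeness metrics follow the matched set algebra", {
  truth <- clustering_tbl(c("a", "b", "c", "d"), c(1, 1, 1, 1))
  inf <- clustering_tbl(c("a", "b", "c", "d"), c(1, 1, 2, 2))
  got <- closeness_metrics(truth, inf)
  # one matched pair: TP = {a,b}, FP = {}, FN = {c,d}
  expect_equal(got$tp, 2)
  expect_equal(got$fp, 0)
  expect_equal(got$fn, 2)
  expect_equal(got$precision, 1)
  expect_equal(got$recall, 0.5)
  expect_equal(got$fscore, 2 / 3)

  expect_equal(closeness_metrics(truth, truth)$fscore, 1)
})

test_that("exact-assignment closeness equals the exhaustive enumeration oracle", {
  set.seed(66)
  for (trial in 1:40) {
    n <- sample(8:18, 1)
    ids <- sprintf("q%02d", seq_len(n))
    truth <- clustering_tbl(ids, sample(seq_len(sample(2:5, 1)), n, TRUE))
    inf <- clustering_tbl(ids, sample(seq_len(sample(2:6, 1)), n, TRUE))
    got <- closeness_metrics(truth, inf, method = "optimal")
    opts <- closeness_oracle(truth, inf)
    expect_equal(got$tp, opts$tp[1])   # maximum overlap is unique
    hit <- any(opts$tp == got$tp & opts$fp == got$fp & opts$fn == got$fn)
    expect_true(hit)                   # fp/fn from one of the optimal matchings
  }
})

test_that("greedy matching attains the optimum on truth-like inferences", {
  # perturb a truth clustering mildly (split one cluster, merge two):
  # the regime where clonal grouping tools actually land
  set.seed(77)
  for (trial in 1:10) {
    n <- 60
    ids <- sprintf("p%02d", seq_len(n))
    truth <- clustering_tbl(ids, sort(sample(1:6, n, TRUE)))
    lab <- truth$clone_id
    lab[lab == "1"][seq_len(min(3, sum(lab == "1")))] <- "1b"   # split
    lab[lab == "5"] <- "6"                                      # join
    inf <- clustering_tbl(ids, lab)
    g <- closeness_metrics(truth, inf)
    o <- closeness_metrics(truth, inf, method = "optimal")
    expect_equal(g$tp, o$tp)
    expect_equal(g$fscore, o$fscore)
  }
})

test_that("over-splitting depresses pairwise recall at least as much as closeness", {
  # For a pure over-split, the matched (largest) fragment covers at least as
  # large a fraction of each truth cluster as the fraction of its preserved
  # pairs, so pairwise recall <= closeness recall; both drop below 1.
  set.seed(88)
  for (trial in 1:10) {
    n <- 40
    ids <- sprintf("w%02d", seq_len(n))
    truth <- clustering_tbl(ids, sort(sample(1:4, n, TRUE)))
    # split every truth cluster into two halves
    lab <- paste0(truth$clone_id, rep_len(c("x", "y"), n))
    inf <- clustering_tbl(ids, lab)
    pw <- pairwise_metrics(truth, inf)
    cl <- closeness_metrics(truth, inf)
    expect_lte(pw$recall, cl$recall + 1e-12)
    expect_lt(cl$recall, 1)
    expect_equal(pw$precision, 1)  # splits create no false-positive pairs
  }
})

test_that("the five comparison events classify clusters exclusively", {
  d1 <- clustering_tbl(c("a", "b", "c"), c(1, 1, 2))
  same <- compare_distributions(d1, d1)
  expect_equal(same$counts$identical, 2)
  expect_equal(sum(same$counts), 2)

  joined <- clustering_tbl(c("a", "b", "c"), c(9, 9, 9))
  ev <- compare_distributions(d1, joined)
  expect_equal(ev$counts$join, 1)

  d1b <- clustering_tbl(c("a", "b", "c"), c(1, 1, 1))
  d2 <- clustering_tbl(c("a", "b", "c", "x"), c("u", "u", "v", "v"))
  ev2 <- compare_distributions(d1b, d2)
  expect_equal(ev2$counts$split, 1)       # {a,b} proper subset of {a,b,c}
  expect_equal(ev2$counts$not_found, 1)   # {c,x} contains a foreign id

  # mix: members span two d1 clusters without being a whole union
  d2m <- clustering_tbl(c("a", "b", "c"), c("m", "m", "m"))
  d1m <- clustering_tbl(c("a", "b", "c", "d"), c(1, 1, 2, 2))
  evm <- compare_distributions(d1m, d2m)
  expect_equal(evm$counts$mix, 1)

  # every d2 cluster gets exactly one label
  expect_equal(nrow(ev2$events), 2)
})

test_that("gini coefficient matches closed forms", {
  expect_equal(gini_coefficient(c(5, 5, 5, 5)), 0)
  expect_equal(gini_coefficient(c(1, 1, 8)), 28 / 60)
  expect_equal(gini_coefficient(10), 0)
  # two-point closed form |x - y| / (2 (x + y))
  set.seed(91)
  for (i in 1:20) {
    x <- sample(1:50, 1); y <- sample(1:50, 1)
    expect_equal(gini_coefficient(c(x, y)), abs(x - y) / (2 * (x + y)))
  }
  # pairwise mean-difference definition on random vectors
  for (i in 1:10) {
    v <- sample(1:30, sample(2:12, 1), replace = TRUE)
    direct <- sum(outer(v, v, function(a, b) abs(a - b))) /
      (2 * length(v)^2 * mean(v))
    expect_equal(gini_coefficient(v), direct)
  }
  expect_error(gini_coefficient(numeric(0)), "empty")
  expect_error(gini_coefficient(c(1, 0)), "positive")
})

test_that("lorenz curve accumulates least-to-most and ties to Gini via its AUC", {
  lc <- lorenz_curve(c(1, 9))
  expect_equal(lc$p, c(0, 0.5, 1))
  expect_equal(lc$L, c(0, 0.1, 1))

  eq <- lorenz_curve(rep(4, 5))
  expect_equal(eq$L, eq$p)

  set.seed(92)
  for (i in 1:10) {
    v <- sample(1:100, sample(2:20, 1), replace = TRUE)
    lc <- lorenz_curve(v)
    expect_equal(lc$p[1], 0); expect_equal(lc$L[1], 0)
    expect_equal(utils::tail(lc$p, 1), 1); expect_equal(utils::tail(lc$L, 1), 1)
    expect_true(all(diff(lc$L, differences = 2) >= -1e-12))  # convex
    auc <- sum(diff(lc$p) * (utils::head(lc$L, -1) + utils::tail(lc$L, -1)) / 2)
    expect_equal(gini_coefficient(v), 1 - 2 * auc, tolerance = 1e-9)
  }
})

test_that("evaluate_clustering bundles both modes, events and Gini", {
  truth <- clustering_tbl(c("a", "b", "c", "d"), c(1, 1, 1, 2))
  res <- evaluate_clustering(truth, truth)
  expect_equal(res$metrics$fscore, c(1, 1))
  expect_equal(res$events$identical, 2)
  expect_equal(res$gini, gini_coefficient(c(3, 1)))
})
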