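# Benchmark simulator: germline V(D)J recombination, Galton-Watson lineage
# growth with hotspot-biased somatic hypermutation, productive-only filtering,
# and assembly into clonality-profiled repertoires with ground-truth labels.

#' Load a germline gene pool
#'
#' Reads V/D/J germline FASTA files into the pool structure used by
#' [recombine_ancestor()].  Defaults to the bundled synthetic pool (20 V,
#' 12 D, 8 J genes; filenames carry `synthetic`).  V genes must be in frame
#' and end with a cysteine codon (the CDR3 5' anchor); J headers carry
#' `anchor=<pos>`, the 1-based position of the conserved tryptophan codon
#' (the CDR3 3' anchor).
#'
#' @param v_path,d_path,j_path FASTA paths; `NULL` uses the bundled set.
#' @return a list with tibbles `v`, `d`, `j` (columns `name`, `seq`, and for
#'   J `anchor`).
#' @export
load_germlines <- function(v_path = NULL, d_path = NULL, j_path = NULL) {
  pick <- function(p, default) {
    p %||% system.file("extdata", default, package = "bcrclone", mustWork = TRUE)
  }
  read_pool <- function(path) {
    ss <- Biostrings::readBStringSet(path)
    tibble(header = names(ss),
           name = sub("\\s.*$", "", names(ss)),
           seq = toupper(unname(as.character(ss))))
  }
  v <- read_pool(pick(v_path, "synthetic_germlines_v.fasta"))
  d <- read_pool(pick(d_path, "synthetic_germlines_d.fasta"))
  j <- read_pool(pick(j_path, "synthetic_germlines_j.fasta"))
  anchor <- suppressWarnings(as.integer(sub(".*anchor=(\\d+).*", "\\1", j$header)))
  if (anyNA(anchor)) {
    # fall back to the first TGG triplet
    anchor <- vapply(j$seq, function(s) as.integer(regexpr("TGG", s, fixed = TRUE)),
                     integer(1))
  }
  if (any(anchor < 1)) abort("J germlines must contain a TGG anchor codon")
  j$anchor <- anchor
  bad_v <- nchar(v$seq) %% 3L != 0 | substr(v$seq, nchar(v$seq) - 2L, nchar(v$seq)) != "TGT"
  if (any(bad_v)) abort("V germlines must be in frame and end with a TGT (Cys) codon")
  list(v = v[, c("name", "seq")], d = d[, c("name", "seq")],
       j = j[, c("name", "seq", "anchor")])
}

sample1 <- function(n) sample.int(n, 1L)
random_nt <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Recombine a naive (unmutated) ancestor sequence
#'
#' Draws one V, D and J germline gene uniformly, trims 0-5 nt from each side
#' of D and from the 5' end of J, and inserts uniform-random N1/N2 regions of
#' 0-10 nt.  The N2 length is padded (mod 3) so the J anchor tryptophan stays
#' in the V reading frame: junctions are in frame and the CDR3 (junction)
#' spans the V-terminal cysteine codon through the J anchor tryptophan codon.
#' Ancestors whose translation contains a stop codon are redrawn (up to
#' `max_tries`).
#'
#' @param germlines a pool from [load_germlines()].
#' @param max_tries retry budget for a productive ancestor.
#' @return a list: `sequence`, `v_call`, `d_call`, `j_call`, `cdr3_start`,
#'   `cdr3_end` (1-based nucleotide coordinates of the junction),
#'   `junction_aa`.
#' @export
recombine_ancestor <- function(germlines = load_germlines(), max_tries = 100L) {
  for (try in seq_len(max_tries)) {
    v <- germlines$v[sample1(nrow(germlines$v)), ]
    d <- germlines$d[sample1(nrow(germlines$d)), ]
    j <- germlines$j[sample1(nrow(germlines$j)), ]
    v_len <- nchar(v$seq)
    d_len <- nchar(d$seq)
    d_trim5 <- sample.int(min(5L, d_len - 3L) + 1L, 1L) - 1L
    d_trim3 <- sample.int(min(5L, d_len - 3L - d_trim5) + 1L, 1L) - 1L
    d_seq <- substr(d$seq, 1L + d_trim5, d_len - d_trim3)
    j_trim <- sample.int(min(5L, j$anchor - 1L) + 1L, 1L) - 1L
    j_seq <- substr(j$seq, 1L + j_trim, nchar(j$seq))
    n1 <- sample.int(11L, 1L) - 1L
    n2 <- sample.int(11L, 1L) - 1L
    pad <- (-(n1 + nchar(d_seq) + n2 + j$anchor - 1L - j_trim)) %% 3L
    n2 <- n2 + pad
    seq <- paste0(v$seq, random_nt(n1), d_seq, random_nt(n2), j_seq)
    cdr3_start <- v_len - 2L
    tgg_start <- v_len + n1 + nchar(d_seq) + n2 + (j$anchor - j_trim)
    cdr3_end <- tgg_start + 2L
    if (has_stop(seq)) next
    junction_aa <- translate_nt(substr(seq, cdr3_start, cdr3_end))
    return(list(sequence = seq, v_call = v$name, d_call = d$name,
                j_call = j$name, cdr3_start = cdr3_start, cdr3_end = cdr3_end,
                junction_aa = junction_aa))
  }
  abort(sprintf("recombine_ancestor: no productive ancestor after %d tries", max_tries))
}

#' Hotspot mutability model
#'
#' The default somatic-hypermutation targeting model: every position has
#' baseline mutability 1, and the mutable base of each classic hotspot motif
#' (the C of WRC and the G of GYW, W = A/T, R = A/G, Y = C/T) is elevated to
#' `weight`.  Positions too close to the sequence edge for a full motif
#' context keep the baseline.  An S5F-style 5-mer table can replace this
#' model via [read_s5f()].
#'
#' @param weight hotspot mutability multiplier (default 5).
#' @return a mutability model (a function mapping a nucleotide string to a
#'   per-site positive rate vector).
#' @export
hotspot_model <- function(weight = 5) {
  if (weight <= 0) abort("hotspot weight must be positive")
  f <- function(seq) {
    l <- nchar(seq)
    mu <- rep(1, l)
    wrc <- gregexpr("(?=[AT][AG]C)", seq, perl = TRUE)[[1]]
    if (wrc[1] != -1L) mu[wrc + 2L] <- weight
    gyw <- gregexpr("(?=G[CT][AT])", seq, perl = TRUE)[[1]]
    if (gyw[1] != -1L) mu[gyw] <- weight
    mu
  }
  structure(f, class = c("mutability_model", "function"))
}

#' Load an S5F-style 5-mer mutability table
#'
#' Reads a CSV/TSV with columns `fivemer` and `mutability` and returns a
#' mutability model: each position's rate is the table entry for its 5-mer
#' context; edge positions (truncated context) and unknown 5-mers receive
#' the table mean.
#'
#' @param path path to the table.
#' @return a mutability model usable in [site_mutabilities()] and
#'   [simulate_repertoire()].
#' @export
read_s5f <- function(path) {
  tbl <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("fivemer", "mutability") %in% names(tbl))) {
    abort("S5F table needs columns 'fivemer' and 'mutability'")
  }
  rates <- setNames(tbl$mutability, toupper(tbl$fivemer))
  fallback <- mean(rates)
  f <- function(seq) {
    l <- nchar(seq)
    mu <- rep(fallback, l)
    if (l >= 5L) {
      pos <- 3L:(l - 2L)
      ctx <- substring(seq, pos - 2L, pos + 2L)
      hit <- rates[ctx]
      mu[pos] <- ifelse(is.na(hit), fallback, hit)
    }
    mu
  }
  structure(f, class = c("mutability_model", "function"))
}

#' Per-site mutabilities and whole-sequence mutability
#'
#' Applies a mutability model to a nucleotide sequence, returning the
#' per-site rates and their arithmetic mean (the whole-sequence mutability
#' that scales the mutation load of offspring).
#'
#' @param seq nucleotide string (A/C/G/T), length at least 5.
#' @param model a mutability model (default [hotspot_model()]).
#' @return a list with `mu` (positive per-site rates) and `mu0` (their mean).
#' @export
site_mutabilities <- function(seq, model = hotspot_model()) {
  assert_scalar_string(seq, "seq")
  if (grepl("[^ACGT]", seq)) abort("site_mutabilities: sequence must be A/C/G/T only")
  if (nchar(seq) < 5L) abort("site_mutabilities: sequence shorter than the 5-mer context")
  mu <- model(seq)
  list(mu = mu, mu0 = mean(mu))
}

mutate_sequence <- function(seq, m, mu) {
  if (m == 0L) return(seq)
  l <- nchar(seq)
  m <- min(m, l)
  pos <- sample.int(l, m, prob = mu)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Grow one B-cell lineage by a Galton-Watson branching process
#'
#' Starting from a productive ancestor, every node draws a
#' Poisson(`lambda`) number of offspring; each offspring receives
#' `m ~ Poisson(mu0 * lambda0)` point substitutions, where `mu0` is the
#' parent's whole-sequence mutability, at positions drawn proportionally to
#' the parent's per-site mutabilities (the substituted base is uniform over
#' the three alternatives).  Growth stops when the tree reaches `max_nodes`
#' or goes extinct.  Sequences whose translation contains a stop codon are
#' flagged non-productive (the tree topology is kept).
#'
#' @param ancestor a list from [recombine_ancestor()].
#' @param lambda offspring Poisson rate (default 2).
#' @param lambda0 baseline mutation rate (default 0.26).
#' @param model mutability model (default [hotspot_model()]).
#' @param max_nodes tree size cap (default 500).
#' @return a tibble with one row per node: `node`, `parent` (0 for the
#'   ancestor), `sequence`, `junction_aa`, `productive`.
#' @export
simulate_lineage <- function(ancestor, lambda = 2, lambda0 = 0.26,
                             model = hotspot_model(), max_nodes = 500L) {
  seqs <- character(max_nodes)
  parents <- integer(max_nodes)
  seqs[1] <- ancestor$sequence
  parents[1] <- 0L
  n <- 1L
  queue <- 1L
  while (length(queue) > 0L && n < max_nodes) {
    node <- queue[1]
    queue <- queue[-1]
    n_off <- rpois(1L, lambda)
    if (n_off == 0L) next
    mut <- site_mutabilities(seqs[node], model)
    for (k in seq_len(n_off)) {
      if (n >= max_nodes) break
      m <- rpois(1L, mut$mu0 * lambda0)
      child_seq <- mutate_sequence(seqs[node], m, mut$mu)
      n <- n + 1L
      seqs[n] <- child_seq
      parents[n] <- node
      queue <- c(queue, n)
    }
  }
  seqs <- seqs[seq_len(n)]
  parents <- parents[seq_len(n)]
  junction <- vapply(seqs, function(s)
    translate_nt(substr(s, ancestor$cdr3_start, ancestor$cdr3_end)), character(1),
    USE.NAMES = FALSE)
  productive <- !vapply(seqs, has_stop, logical(1), USE.NAMES = FALSE)
  tibble(node = seq_len(n), parent = parents, sequence = seqs,
         junction_aa = junction, productive = productive)
}

clonality_quotas <- function(type, n_lineages, target_size) {
  if (n_lineages < 1L || target_size < n_lineages) {
    abort("need n_lineages >= 1 and target_size >= n_lineages")
  }
  spread <- function(total, k) {
    if (k == 0L) return(integer(0))
    base <- rep(total %/% k, k)
    extra <- total %% k
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  q <- switch(type,
    monoclonal = {
      major <- as.integer(ceiling(0.70 * target_size))
      c(major, spread(target_size - major, n_lineages - 1L))
    },
    oligoclonal = {
      if (n_lineages < 3L) abort("oligoclonal profile needs at least 3 lineages")
      q1 <- as.integer(round(0.14 * target_size))
      q2 <- as.integer(round(0.09 * target_size))
      c(q1, q2, spread(target_size - q1 - q2, n_lineages - 2L))
    },
    polyclonal = {
      q <- spread(target_size, n_lineages)
      if (max(q) / target_size > 0.05) {
        abort("polyclonal profile infeasible: even split exceeds the 5% cap; increase n_lineages")
      }
      q
    })
  if (any(q < 1L)) abort("clonality profile infeasible: some lineage quota is below 1")
  q
}

#' Simulate a truth-labelled IGH repertoire
#'
#' Simulates `n_lineages` independent B-cell lineages ([recombine_ancestor()]
#' then [simulate_lineage()]), keeps productive sequences only, and
#' subsamples each lineage to the clonality profile of the repertoire type:
#' monoclonal — the major lineage holds at least 70% of sequences;
#' oligoclonal — two dominant lineages at 14% and 9%; polyclonal — no lineage
#' above 5%.  Each lineage's true V/D/J picks annotate all its members, so
#' the output is directly clusterable by [cluster_lineages()] and scorable
#' against the attached truth labels.
#'
#' @param type `"monoclonal"`, `"oligoclonal"` or `"polyclonal"`.
#' @param n_lineages number of lineages; defaults to 34 / 43 / 44 for the
#'   three types.
#' @param target_size total sequence target (default 1000); realized sizes
#'   can undershoot when lineages run out of productive sequences.
#' @param lambda offspring Poisson rate (default 2).
#' @param lambda0 baseline mutation rate (default 0.26; benchmark grid
#'   \{0.16, 0.26, 0.36, 0.46\}).
#' @param model mutability model (default [hotspot_model()]).
#' @param seed optional RNG seed for a reproducible benchmark.
#' @param germlines germline pool (default: bundled synthetic set).
#' @return an object of class `sim_repertoire`: list with `repertoire`
#'   (AIRR-style tibble: `sequence_id`, `v_call`, `d_call`, `j_call`,
#'   `junction_aa`, `cdr3_aa`, `sequence`, `duplicate_count`, `productive`),
#'   `truth` (tibble `sequence_id`, `clone_id`), `trees` (per-lineage
#'   parent→child edge tibbles), `params`.
#' @examples
#' \donttest{
#' sim <- simulate_repertoire("polyclonal", target_size = 200, n_lineages = 25,
#'                            seed = 1)
#' nrow(sim$repertoire)
#' }
#' @export
simulate_repertoire <- function(type = c("polyclonal", "monoclonal", "oligoclonal"),
                                n_lineages = NULL, target_size = 1000L,
                                lambda = 2, lambda0 = 0.26,
                                model = hotspot_model(), seed = NULL,
                                germlines = load_germlines()) {
  type <- match.arg(type)
  n_lineages <- n_lineages %||%
    switch(type, monoclonal = 34L, oligoclonal = 43L, polyclonal = 44L)
  if (lambda <= 0 || lambda0 <= 0) abort("lambda and lambda0 must be positive")
  quotas <- clonality_quotas(type, n_lineages, target_size)

  body <- function() {
    rows <- vector("list", n_lineages)
    truth <- vector("list", n_lineages)
    trees <- vector("list", n_lineages)
    for (li in seq_len(n_lineages)) {
      q <- quotas[li]
      pool <- NULL
      anc <- recombine_ancestor(germlines)
      cap <- max(2L * q + 20L, 60L)
      for (attempt in 1:6) {
        tree <- simulate_lineage(anc, lambda, lambda0, model, max_nodes = cap)
        pool <- tree[tree$productive, , drop = FALSE]
        if (nrow(pool) >= q) break
        if (nrow(tree) < cap / 2) anc <- recombine_ancestor(germlines)  # likely extinct
        cap <- cap * 2L
      }
      if (nrow(pool) < q) {
        warn(sprintf("lineage %d undershoots its quota (%d < %d productive sequences)",
                     li, nrow(pool), q))
      }
      take <- pool[sample.int(nrow(pool), min(q, nrow(pool))), , drop = FALSE]
      lineage_id <- sprintf("L%02d", li)
      ids <- sprintf("%s_%04d", lineage_id, take$node)
      rows[[li]] <- tibble(
        sequence_id = ids,
        v_call = anc$v_call, d_call = anc$d_call, j_call = anc$j_call,
        junction_aa = take$junction_aa,
        cdr3_aa = take$junction_aa,
        sequence = take$sequence,
        duplicate_count = 1L,
        productive = TRUE)
      truth[[li]] <- tibble(sequence_id = ids, clone_id = lineage_id)
      trees[[li]] <- tree[, c("node", "parent")]
    }
    repertoire <- bind_rows(rows)
    truth <- bind_rows(truth)
    shuffle <- sample.int(nrow(repertoire))
    repertoire <- repertoire[shuffle, , drop = FALSE]
    truth <- truth[shuffle, , drop = FALSE]
    repertoire$v_gene <- strip_allele(repertoire$v_call)
    repertoire$j_gene <- strip_allele(repertoire$j_call)
    names(trees) <- sprintf("L%02d", seq_len(n_lineages))
    list(repertoire = repertoire, truth = truth, trees = trees)
  }

  res <- if (is.null(seed)) body() else withr::with_seed(seed, body())
  structure(c(res, list(params = list(
    type = type, n_lineages = n_lineages, target_size = target_size,
    lambda = lambda, lambda0 = lambda0, seed = seed))),
    class = "sim_repertoire")
}

#' @export
print.sim_repertoire <- function(x, ...) {
  p <- x$params
  sizes <- sort(table(x$truth$clone_id), decreasing = TRUE)
  cat(sprintf("<sim_repertoire> %s: %d sequences, %d lineages (lambda=%g, lambda0=%g)\n",
              p$type, nrow(x$repertoire), length(sizes), p$lambda, p$lambda0))
  cat(sprintf("  top lineage fraction: %.3f\n", sizes[1] / nrow(x$repertoire)))
  invisible(x)
}

#' Write a simulated benchmark to disk
#'
#' Writes the AIRR table, the ground-truth clone assignments, a FASTA of the
#' nucleotide sequences, per-lineage parent→child edge lists and a JSON
#' manifest of the simulation parameters.
#'
#' @param sim a `sim_repertoire`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_benchmark <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_repertoire"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  airr <- file.path(dir, "repertoire.tsv")
  readr::write_tsv(sim$repertoire, airr, progress = FALSE)
  truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, truth, progress = FALSE)
  fasta <- file.path(dir, "sequences.fasta")
  write_fasta(sim$repertoire, fasta)
  edges <- file.path(dir, "lineage_edges.tsv")
  edge_tbl <- purrr::imap_dfr(sim$trees, function(tr, nm) {
    mutate(tr, lineage = nm)
  })
  readr::write_tsv(edge_tbl, edges, progress = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(sim$params, manifest, auto_unbox = TRUE, null = "null")
  invisible(c(airr, truth, fasta, edges, manifest))
}
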