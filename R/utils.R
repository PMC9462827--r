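#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n row_number desc distinct rename count pull
#' @importFrom stats rpois setNames
NULL

# Strip the IMGT allele suffix ("IGHV1-69*01" -> "IGHV1-69").
strip_allele <- function(x) sub("\\*.*$", "", x)

# Accept thresholds written either as percentages (70) or fractions (0.70).
normalize_threshold <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0) {
    abort("threshold must be a single positive number (fraction or percent)")
  }
  if (s > 1) s <- s / 100
  if (s > 1) abort("threshold above 100%")
  s
}

# Translate a nucleotide string in frame 1; incomplete trailing codon dropped.
translate_nt <- function(nt) {
  l <- nchar(nt)
  n_codon <- l %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(nt, seq(1L, by = 3L, length.out = n_codon),
                      seq(3L, by = 3L, length.out = n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

has_stop <- function(nt) grepl("\\*", translate_nt(nt))

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("%s must be a non-empty string", what))
  }
  invisible(x)
}
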