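# Generates the bundled synthetic germline V/D/J pool shipped under
# inst/extdata/.  Run once; the output is committed as plain-text FASTA.
#
# Design:
#  * V genes: in-frame, stop-free random codon bodies ending with the
#    conserved TGT (Cys) codon that anchors the 5' end of the CDR3/junction.
#  * D genes: short random nucleotide cores.
#  * J genes: a short random head, the conserved TGG (Trp) anchor codon, and
#    a stop-free codon tail; headers carry anchor=<pos> (1-based position of
#    the TGG).
set.seed(20260915)

codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
nonstop <- setdiff(codons, c("TAA", "TAG", "TGA"))

rand_codons <- function(n) paste(sample(nonstop, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

n_v <- 20L; n_d <- 12L; n_j <- 8L

v_names <- sprintf("SYNV%d-%d*01", rep(1:5, each = 4), rep(1:4, times = 5))
v_seqs <- vapply(seq_len(n_v), function(i) {
  body_codons <- sample(84:96, 1)
  paste0(rand_codons(body_codons), "TGT")
}, character(1))

d_names <- sprintf("SYND%d*01", 1:n_d)
d_seqs <- vapply(seq_len(n_d), function(i) rand_nt(sample(12:24, 1)), character(1))

j_names <- sprintf("SYNJ%d*01", 1:n_j)
j <- lapply(seq_len(n_j), function(i) {
  head_len <- sample(6:12, 1)
  head <- rand_nt(head_len)
  # no premature TGG in the head (keeps the anchor unambiguous)
  while (grepl("TGG", paste0(head, "TGG"), fixed = TRUE) &&
         regexpr("TGG", paste0(head, "TGG"), fixed = TRUE) <= head_len) {
    head <- rand_nt(head_len)
  }
  tail <- rand_codons(10)
  list(seq = paste0(head, "TGG", tail), anchor = head_len + 1L)
})

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeLines(paste0(">", v_names, "\n", v_seqs), "inst/extdata/synthetic_germlines_v.fasta")
writeLines(paste0(">", d_names, "\n", d_seqs), "inst/extdata/synthetic_germlines_d.fasta")
writeLines(paste0(">", j_names, " anchor=", vapply(j, `[[`, 1L, "anchor"), "\n",
                  vapply(j, `[[`, "", "seq")), "inst/extdata/synthetic_germlines_j.fasta")
cat("wrote", n_v, "V,", n_d, "D,", n_j, "J synthetic germlines\n")
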