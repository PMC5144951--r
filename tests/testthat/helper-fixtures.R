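# Shared fixtures: PAF line builder, exon-chain shorthand, tiny known-mature
# table for the miRNA tests.

paf_line <- function(qid, qlen, qs, qe, strand, tid, tlen, ts, te, nm, bl,
                     cg = NULL) {
  line <- paste(qid, qlen, qs, qe, strand, tid, tlen, ts, te, nm, bl, 60,
                sep = "\t")
  if (!is.null(cg)) line <- paste0(line, "\tcg:Z:", cg)
  line
}

# chain(0,100, 200,300) -> exons [(0,100),(200,300)]
chain <- function(..., scaffold = "s1", strand = "+") {
  v <- c(...)
  new_exon_chain(matrix(v, ncol = 2, byrow = TRUE), scaffold, strand)
}

# A single-exon PAF record whose exonic length is `len`, placed at `ts`.
simple_paf_record <- function(qid, len, tid = "s1", ts = 0, strand = "+",
                              id_frac = 1.0, cov = 1.0) {
  qlen <- len
  qe <- round(qlen * cov)
  nm <- round(qe * id_frac)
  paf_line(qid, qlen, 0, qe, strand, tid, 1e6, ts, ts + qe, nm, qe,
           cg = paste0(qe, "M"))
}

known_matures <- data.frame(
  family = c("miR156", "miR172", "miR950"),
  sequence = c("TGACAGAAGAGAGTGAGCACA",   # 21 nt
               "AGAATCTTGATGATGCTGCAT",   # 21 nt
               "TGGACGGAGGGAGTATCGTAC"),  # 21 nt
  stringsAsFactors = FALSE)

mutate_seq <- function(seq, positions, to = NULL) {
  b <- strsplit(seq, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), b[p])
    b[p] <- if (is.null(to)) alt[1] else to
  }
  paste(b, collapse = "")
}
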