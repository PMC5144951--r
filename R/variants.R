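# Splice-variant classification of a candidate exon chain against a
# reference chain. The taxonomy follows the usual event classes reported for
# spliced-alignment comparisons:
#   identical        same intron set and same terminal coordinates
#   intron_retention a reference intron lies fully inside a candidate exon
#   exon_skipping    a candidate intron fully contains a reference exon
#   alt_start        5' terminus differs (strand-resolved)
#   premature_stop   3' terminus differs (strand-resolved)
#   complex          any intron boundary difference not covered above
# Event labels (retention/skipping/terminus) may co-occur; `identical` is
# exclusive.

VARIANT_LABELS <- c("identical", "alt_start", "premature_stop",
                    "intron_retention", "exon_skipping", "complex")

#' Classify a candidate exon chain against a reference chain
#'
#' @param candidate,reference `exon_chain` objects on the same scaffold and
#'   strand, with at least 1 bp of exonic overlap.
#' @param candidate_id,reference_id Optional identifiers carried through to
#'   the returned call.
#' @return A list of class `variant_call`: `candidate_id`, `reference_id`,
#'   `labels` (character subset of the taxonomy), `n_retained_introns`,
#'   `n_skipped_exons`.
#' @export
classify_variant <- function(candidate, reference,
                             candidate_id = NA_character_,
                             reference_id = NA_character_) {
  if (!identical(candidate$scaffold, reference$scaffold) ||
      !identical(candidate$strand, reference$strand))
    stop("candidate and reference must share scaffold and strand")
  if (!chains_overlap(candidate$exons, reference$exons))
    stop("candidate and reference exon chains do not overlap")
  res <- classify_chain_pair(candidate$exons, reference$exons, candidate$strand)
  structure(list(candidate_id = candidate_id, reference_id = reference_id,
                 labels = res$labels,
                 n_retained_introns = res$n_ret,
                 n_skipped_exons = res$n_skip),
            class = "variant_call")
}

#' @export
print.variant_call <- function(x, ...) {
  cat("variant call: ", paste(x$labels, collapse = "+"),
      if (x$n_retained_introns) paste0(" (", x$n_retained_introns, " retained intron(s))"),
      if (x$n_skipped_exons) paste0(" (", x$n_skipped_exons, " skipped exon(s))"),
      "\n", sep = "")
  invisible(x)
}

chains_overlap <- function(ce, re) {
  for (i in seq_len(nrow(ce)))
    if (any(pmin(ce[i, 2L], re[, 2L]) > pmax(ce[i, 1L], re[, 1L])))
      return(TRUE)
  FALSE
}

# Core rule engine on bare exon matrices; kept lean because the exhaustive
# grid comparison calls it hundreds of thousands of times.
classify_chain_pair <- function(ce, re, strand = "+") {
  nc <- nrow(ce); nr <- nrow(re)
  cs <- ce[, 1L]; cee <- ce[, 2L]
  rs <- re[, 1L]; ree <- re[, 2L]
  ci_s <- cee[-nc]; ci_e <- cs[-1L]       # candidate introns
  ri_s <- ree[-nr]; ri_e <- rs[-1L]       # reference introns
  c_lo <- cs[1L]; c_hi <- cee[nc]
  r_lo <- rs[1L]; r_hi <- ree[nr]

  if (c_lo == r_lo && c_hi == r_hi && length(ci_s) == length(ri_s) &&
      all(ci_s == ri_s) && all(ci_e == ri_e))
    return(list(labels = "identical", n_ret = 0L, n_skip = 0L))

  shared_lo <- max(c_lo, r_lo)
  shared_hi <- min(c_hi, r_hi)
  complex <- FALSE

  # candidate introns: matched / skipping / outside shared span / complex
  n_skip <- 0L
  skip_s <- integer(0); skip_e <- integer(0)
  for (j in seq_along(ci_s)) {
    if (any(ri_s == ci_s[j] & ri_e == ci_e[j])) next
    inside <- sum(ci_s[j] <= rs & ree <= ci_e[j])
    if (inside > 0L) {
      n_skip <- n_skip + inside
      skip_s <- c(skip_s, ci_s[j]); skip_e <- c(skip_e, ci_e[j])
      next
    }
    if (ci_e[j] <= shared_lo || ci_s[j] >= shared_hi) next
    complex <- TRUE
  }

  # reference introns: matched / retained / outside shared span /
  # subsumed by a skipping candidate intron / complex
  n_ret <- 0L
  for (j in seq_along(ri_s)) {
    if (any(ci_s == ri_s[j] & ci_e == ri_e[j])) next
    if (any(cs <= ri_s[j] & ri_e[j] <= cee)) { n_ret <- n_ret + 1L; next }
    if (ri_e[j] <= shared_lo || ri_s[j] >= shared_hi) next
    if (length(skip_s) && any(skip_s <= ri_s[j] & ri_e[j] <= skip_e)) next
    complex <- TRUE
  }

  labels <- character(0)
  if (n_ret > 0L) labels <- c(labels, "intron_retention")
  if (n_skip > 0L) labels <- c(labels, "exon_skipping")
  if (strand == "+") {
    if (c_lo != r_lo) labels <- c(labels, "alt_start")
    if (c_hi != r_hi) labels <- c(labels, "premature_stop")
  } else {
    if (c_hi != r_hi) labels <- c(labels, "alt_start")
    if (c_lo != r_lo) labels <- c(labels, "premature_stop")
  }
  if (complex) labels <- c(labels, "complex")
  if (!length(labels)) labels <- "complex"
  list(labels = labels, n_ret = n_ret, n_skip = n_skip)
}

#' Summarize splice-variant calls by type
#'
#' Counts calls carrying each label. Labels co-occur, so per-label counts may
#' sum to more than the total; `identical` calls are excluded from the
#' variant total. A pooled `length_variant` count (calls labelled alt_start
#' or premature_stop or both) is reported alongside the split labels.
#'
#' @param calls A list of `variant_call` objects.
#' @return A list with `counts` (named integer per label), `length_variant`
#'   (pooled count) and `total` (number of non-identical calls).
#' @export
summarize_variant_types <- function(calls) {
  counts <- stats::setNames(integer(length(VARIANT_LABELS)), VARIANT_LABELS)
  pooled <- 0L; total <- 0L
  for (cl in calls) {
    for (lb in cl$labels) counts[lb] <- counts[lb] + 1L
    if (!"identical" %in% cl$labels) total <- total + 1L
    if (any(c("alt_start", "premature_stop") %in% cl$labels)) pooled <- pooled + 1L
  }
  list(counts = counts, length_variant = pooled, total = total)
}
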