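# miRNA precursor triage: mature-sequence matching against known families
# (Hamming distance, no indels), MFEI computation and cutoff filtering, the
# long-precursor/low-MFEI fold-back heuristic, and duplex-strand collapsing.
# Minimum free energy (MFE) values are consumed from upstream folding output,
# not computed here.

norm_rna <- function(x) chartr("Uu", "Tt", toupper(x))

hamming <- function(a, b) {
  # equal-length strings only
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Match a mature miRNA sequence against known families
#'
#' Best family by minimum Hamming distance among known matures of equal
#' length (U/T equivalent; no gapped alignment, so length-mismatched matures
#' are skipped). A match is returned only when the distance does not exceed
#' `max_mismatch`; distance ties go to the lexicographically smallest family.
#'
#' @param mature Mature sequence (19-25 nt).
#' @param known_matures Data frame with columns `family` and `sequence`.
#' @param max_mismatch Maximum allowed mismatches, default 2.
#' @return List with `family` and `mismatches`, or `NULL` when no family is
#'   within the allowance.
#' @export
match_mature <- function(mature, known_matures, max_mismatch = 2L) {
  n <- nchar(mature)
  if (n < 19L || n > 25L)
    stop("mature sequence length ", n, " outside the 19-25 nt range")
  mat <- norm_rna(mature)
  ref <- norm_rna(known_matures$sequence)
  same_len <- nchar(ref) == n
  if (!any(same_len)) return(NULL)
  d <- vapply(ref[same_len], hamming, integer(1), a = mat, USE.NAMES = FALSE)
  fams <- known_matures$family[same_len]
  if (min(d) > max_mismatch) return(NULL)
  hitf <- sort(fams[d == min(d)])[1L]
  list(family = hitf, mismatches = as.integer(min(d)))
}

#' Minimal folding free energy index (MFEI)
#'
#' AMFE = (MFE / length) x 100; MFEI = AMFE / (GC x 100). MFE in kcal/mol,
#' length in nt, GC as a fraction.
#'
#' @param mfe Minimum free energy (kcal/mol, non-positive).
#' @param length Precursor length (nt).
#' @param gc GC fraction in (0, 1\].
#' @return MFEI (dimensionless, non-positive).
#' @export
compute_mfei <- function(mfe, length, gc) {
  stopifnot(length > 0)
  if (any(gc <= 0)) stop("MFEI undefined for GC content 0")
  ((mfe / length) * 100) / (gc * 100)
}

#' Filter miRNA precursor candidates
#'
#' A candidate is rejected when its mature sequence matches no known family
#' within the mismatch allowance or its MFEI exceeds the cutoff (i.e. is not
#' at least as negative as `mfei_cutoff`). Accepted candidates are high
#' quality unless they trip the fold-back-repeat heuristic: longer than
#' `long_precursor_nt` with MFEI below `mfei_floor` (strongly negative), in
#' which case they are flagged low quality.
#'
#' @param candidates Data frame with columns `precursor_id`,
#'   `source_transcript_id`, `sequence`, `mature_start`, `mature_end`
#'   (0-based half-open within the precursor) and `mfe` (kcal/mol).
#' @param known_matures Data frame with columns `family` and `sequence`.
#' @param mfei_cutoff MFEI acceptance cutoff, default -0.85.
#' @param max_mismatch Mature-match allowance, default 2.
#' @param long_precursor_nt,mfei_floor Fold-back heuristic thresholds,
#'   defaults 250 nt and -2.0.
#' @return Data frame of verdicts: `precursor_id`, `family` (NA when
#'   unmatched), `mismatches`, `mfei`, `quality` (high/low/rejected).
#' @export
filter_precursors <- function(candidates, known_matures,
                              mfei_cutoff = -0.85, max_mismatch = 2L,
                              long_precursor_nt = 250L, mfei_floor = -2.0) {
  stopifnot(all(candidates$mfe <= 0),
            all(candidates$mature_start >= 0),
            all(candidates$mature_start < candidates$mature_end),
            all(candidates$mature_end <= nchar(candidates$sequence)))
  n <- nrow(candidates)
  len <- nchar(candidates$sequence)
  gc <- gc_content(candidates$sequence)
  mfei <- compute_mfei(candidates$mfe, len, gc)
  family <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  quality <- character(n)
  for (i in seq_len(n)) {
    mature <- substr(candidates$sequence[i],
                     candidates$mature_start[i] + 1L, candidates$mature_end[i])
    hit <- match_mature(mature, known_matures, max_mismatch)
    if (!is.null(hit)) {
      family[i] <- hit$family
      mismatches[i] <- hit$mismatches
    }
    quality[i] <- if (is.null(hit) || mfei[i] > mfei_cutoff) "rejected"
      else if (len[i] > long_precursor_nt && mfei[i] < mfei_floor) "low"
      else "high"
  }
  data.frame(precursor_id = candidates$precursor_id,
             source_transcript_id = candidates$source_transcript_id,
             family = family, mismatches = mismatches,
             mfei = mfei, quality = quality, stringsAsFactors = FALSE)
}

# Connected components of duplex relations among candidates: two predictions
# on the same source transcript whose mature sequences reverse-complement
# match within the allowance (arms of one hairpin). When mature coordinates
# are comparable, the interval offset must not exceed the loop allowance.
duplex_components <- function(candidates, max_mismatch = 2L,
                              loop_allowance = Inf) {
  n <- nrow(candidates)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  mats <- toupper(vapply(seq_len(n), function(i)
    substr(candidates$sequence[i], candidates$mature_start[i] + 1L,
           candidates$mature_end[i]), character(1)))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(norm_rna(mats))))
  by_src <- split(seq_len(n), candidates$source_transcript_id)
  for (idx in by_src) {
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-1L]) for (b in seq_len(a - 1L)) {
      i <- idx[a]; j <- idx[b]
      if (nchar(mats[i]) != nchar(mats[j])) next
      if (hamming(norm_rna(mats[i]), rc[j]) > max_mismatch) next
      if (is.finite(loop_allowance) &&
          abs(candidates$mature_start[i] - candidates$mature_start[j]) >
            loop_allowance + nchar(mats[i])) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse duplex-strand miRNA predictions
#'
#' Multiple predictions on the same source transcript whose mature sequences
#' correspond to the two strands of one miRNA duplex (reverse-complement
#' match within `max_mismatch`) are merged into a single record, keeping the
#' representative with the lowest (most negative) MFEI.
#'
#' @param verdicts Verdict table from [filter_precursors()] (or any table
#'   with `precursor_id` and `mfei`).
#' @param candidates The candidate table the verdicts were computed from
#'   (supplies sequences and mature coordinates).
#' @param max_mismatch Reverse-complement match allowance, default 2.
#' @param loop_allowance Maximum offset (nt) between the two mature intervals
#'   within the precursor; `Inf` (default) disables the positional check.
#' @return The collapsed verdict table.
#' @export
collapse_duplex <- function(verdicts, candidates, max_mismatch = 2L,
                            loop_allowance = Inf) {
  if (!nrow(verdicts)) return(verdicts)
  cand <- candidates[match(verdicts$precursor_id, candidates$precursor_id), ,
                     drop = FALSE]
  comp <- duplex_components(cand, max_mismatch, loop_allowance)
  keep <- vapply(split(seq_len(nrow(verdicts)), comp), function(idx)
    idx[order(verdicts$mfei[idx], verdicts$precursor_id[idx])][1L],
    integer(1))
  verdicts[sort(unname(keep)), , drop = FALSE]
}
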