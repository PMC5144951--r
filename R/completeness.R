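# Full-length completeness scoring (H1/H2/H3) from protein hit tables,
# genome mapping rates, assembly length and GC statistics, and rarefaction
# curves (analytic hypergeometric and Monte Carlo).

#' Read a 12- or 14-column tabular protein hit table
#'
#' Accepts the classic 12-column local-alignment format
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), in which case a sequence-length sidecar must supply
#' `query_len`/`target_len`, or a 14-column dialect with qlen and slen
#' appended (auto-detected). One-based inclusive alignment coordinates are
#' converted to 0-based half-open; reversed target intervals are normalized.
#'
#' @param path Path to the tabular hit file.
#' @param lengths Optional data frame with columns `id` and `length`
#'   (required for the 12-column format).
#' @return Hit table with columns `query_id`, `query_len`, `target_id`,
#'   `target_len`, `q_start`, `q_end`, `t_start`, `t_end`, `e_value`.
#' @export
read_hit_table <- function(path, lengths = NULL) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (!ncol(raw) %in% c(12L, 14L))
    stop("hit table must have 12 or 14 columns, found ", ncol(raw))
  hits <- data.frame(query_id = as.character(raw[[1]]),
                     target_id = as.character(raw[[2]]),
                     q_start = as.integer(raw[[7]]) - 1L,
                     q_end = as.integer(raw[[8]]),
                     t_start = pmin(as.integer(raw[[9]]), as.integer(raw[[10]])) - 1L,
                     t_end = pmax(as.integer(raw[[9]]), as.integer(raw[[10]])),
                     e_value = as.numeric(raw[[11]]),
                     stringsAsFactors = FALSE)
  if (ncol(raw) == 14L) {
    hits$query_len <- as.integer(raw[[13]])
    hits$target_len <- as.integer(raw[[14]])
  } else {
    if (is.null(lengths))
      stop("12-column hit tables need a `lengths` sidecar (columns id, length)")
    len <- stats::setNames(as.integer(lengths$length), lengths$id)
    hits$query_len <- unname(len[hits$query_id])
    hits$target_len <- unname(len[hits$target_id])
    if (anyNA(hits$query_len) || anyNA(hits$target_len))
      stop("sequence length missing for some hit table ids")
  }
  hits[, c("query_id", "query_len", "target_id", "target_len",
           "q_start", "q_end", "t_start", "t_end", "e_value")]
}

#' Score H1/H2/H3 completeness categories
#'
#' Per query, the best hit is the one with the lowest e-value (ties broken by
#' the highest product of query and target coverage). H1 counts queries with
#' any hit; H2 those whose best hit covers at least `cov_threshold` of the
#' query; H3 additionally requires the same coverage of the target (aligned
#' protein). Coverages are aligned span over sequence length, each in the
#' sequence's own units.
#'
#' @param hits Hit table (see [read_hit_table()]).
#' @param cov_threshold Coverage threshold, default 0.70.
#' @param queries Full query universe (ids); queries without hits count only
#'   toward the total `T`. Defaults to the ids present in `hits`.
#' @return List of class `completeness_summary`: `T`, `H1`, `H2`, `H3`,
#'   `fractions`, and `per_query` (data frame with the best category per
#'   query: `none`, `H1`, `H2` or `H3`).
#' @export
score_hits <- function(hits, cov_threshold = 0.70,
                       queries = unique(hits$query_id)) {
  if (any(hits$query_len == 0L)) {
    warning(sum(hits$query_len == 0L), " hit record(s) with query_len 0 rejected")
    hits <- hits[hits$query_len > 0L, , drop = FALSE]
  }
  category <- stats::setNames(rep("none", length(queries)), queries)
  if (nrow(hits)) {
    qcov <- (hits$q_end - hits$q_start) / hits$query_len
    tcov <- (hits$t_end - hits$t_start) / hits$target_len
    for (grp in split(seq_len(nrow(hits)), hits$query_id)) {
      i <- grp[order(hits$e_value[grp], -(qcov[grp] * tcov[grp]))][1L]
      q <- hits$query_id[i]
      if (!q %in% queries) next
      category[q] <- if (qcov[i] >= cov_threshold && tcov[i] >= cov_threshold)
        "H3" else if (qcov[i] >= cov_threshold) "H2" else "H1"
    }
  }
  h1 <- sum(category != "none")
  h2 <- sum(category %in% c("H2", "H3"))
  h3 <- sum(category == "H3")
  total <- length(queries)
  stopifnot(h3 <= h2, h2 <= h1, h1 <= total)
  structure(list(T = total, H1 = h1, H2 = h2, H3 = h3,
                 fractions = c(H1 = h1, H2 = h2, H3 = h3) / total,
                 per_query = data.frame(query_id = queries,
                                        category = unname(category),
                                        stringsAsFactors = FALSE)),
            class = "completeness_summary")
}

#' @export
print.completeness_summary <- function(x, ...) {
  cat(sprintf("completeness: T=%d  H1=%d (%.1f%%)  H2=%d (%.1f%%)  H3=%d (%.1f%%)\n",
              x$T, x$H1, 100 * x$fractions["H1"], x$H2, 100 * x$fractions["H2"],
              x$H3, 100 * x$fractions["H3"]))
  invisible(x)
}

#' Genome mapping rate at coverage/identity threshold pairs
#'
#' Fraction of transcripts with at least one genome alignment passing both
#' thresholds. The default pairs are full-length (98/98) and near-full-length
#' (90/98) coverage/identity.
#'
#' @param rec Alignment record table.
#' @param queries Full transcript universe; defaults to the ids in `rec`.
#' @param pairs List of c(min_cov, min_id) pairs.
#' @return Data frame with `min_cov`, `min_id` and `rate`.
#' @export
mapping_rate <- function(rec, queries = unique(rec$query_id),
                         pairs = list(c(0.98, 0.98), c(0.90, 0.98))) {
  rows <- lapply(pairs, function(p) {
    passing <- filter_alignments(rec, p[1L], p[2L])
    data.frame(min_cov = p[1L], min_id = p[2L],
               rate = if (length(queries))
                 sum(queries %in% passing$query_id) / length(queries)
               else NA_real_)
  })
  do.call(rbind, rows)
}

#' Assembly length statistics
#'
#' N50 is the largest length L such that the summed length of all sequences
#' at least L long reaches half of the total length.
#'
#' @param x Numeric vector of sequence lengths, or a character vector of
#'   sequences.
#' @return List with `n`, `mean`, `min`, `max` and `N50`.
#' @export
length_stats <- function(x) {
  lens <- if (is.character(x)) nchar(x) else as.numeric(x)
  if (!length(lens)) stop("length statistics undefined for an empty set")
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1L]]
  list(n = length(lens), mean = mean(lens), min = min(lens),
       max = max(lens), N50 = n50)
}

#' GC content of nucleotide sequences
#'
#' (G+C)/(A+C+G+T); ambiguity codes are excluded from the denominator and U
#' is treated as T.
#'
#' @param seq Character vector of DNA/RNA sequences.
#' @return Numeric vector of GC fractions (NaN for sequences without
#'   unambiguous bases).
#' @export
gc_content <- function(seq) {
  dna <- Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(seq)))
  freq <- Biostrings::letterFrequency(dna, letters = c("A", "C", "G", "T"))
  unname((freq[, "G"] + freq[, "C"]) / rowSums(freq))
}

#' Rarefaction curve of transcript richness
#'
#' Expected number of distinct transcripts observed when subsampling reads.
#' The analytic method uses the hypergeometric expectation
#' E\[S(n)\] = sum_i (1 - choose(N - c_i, n) / choose(N, n)); the Monte Carlo
#' method averages the observed richness over `n_reps` subsamples without
#' replacement. When more transcripts than `subsample_transcripts` are
#' present, that many are first drawn uniformly at random (seeded), following
#' the usual practice of rarefying a random transcript subset.
#'
#' @param counts Named integer vector of per-transcript read counts.
#' @param sample_sizes Read counts at which to evaluate the curve.
#' @param method `"analytic"` or `"montecarlo"`.
#' @param n_reps Number of Monte Carlo replicates.
#' @param seed Integer seed for transcript subsampling and Monte Carlo draws.
#' @param subsample_transcripts Transcript subset size, default 1000.
#' @return Object of class `rarefaction_curve`: data frame `curve`
#'   (`sample_size`, `expected_richness`), plus `method`, `n_reps`, `seed`.
#' @export
rarefaction_curve <- function(counts, sample_sizes,
                              method = c("analytic", "montecarlo"),
                              n_reps = 100L, seed = NULL,
                              subsample_transcripts = 1000L) {
  method <- match.arg(method)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (!is.null(seed)) set.seed(seed)
  if (length(counts) > subsample_transcripts)
    counts <- counts[sample(length(counts), subsample_transcripts)]
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(sample_sizes > N))
    stop("sample size exceeds the total read count (", N, ")")
  richness <- if (method == "analytic") {
    vapply(sample_sizes, function(n) {
      miss <- exp(lchoose(N - counts, n) - lchoose(N, n))
      miss[N - counts < n] <- 0
      sum(1 - miss)
    }, numeric(1))
  } else {
    pool <- rep(seq_along(counts), counts)
    vapply(sample_sizes, function(n) {
      mean(vapply(seq_len(n_reps),
                  function(r) length(unique(sample(pool, n))), numeric(1)))
    }, numeric(1))
  }
  structure(list(curve = data.frame(sample_size = sample_sizes,
                                    expected_richness = richness),
                 method = method,
                 n_reps = if (method == "montecarlo") n_reps else NA_integer_,
                 seed = seed,
                 n_transcripts = length(counts), total_reads = N),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat("rarefaction curve (", x$method, "): ", nrow(x$curve), " points, ",
      x$n_transcripts, " transcripts, ", x$total_reads, " reads\n", sep = "")
  print(utils::head(x$curve))
  invisible(x)
}

#' @export
plot.rarefaction_curve <- function(x, ...) {
  plot(x$curve$sample_size, x$curve$expected_richness, type = "b",
       xlab = "reads subsampled", ylab = "expected distinct transcripts", ...)
  invisible(x)
}
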