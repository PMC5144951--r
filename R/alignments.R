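# Spliced transcript-to-genome alignments: PAF parsing, CIGAR-derived exon
# chains, query coverage and percent identity. Coordinates are 0-based
# half-open throughout (the PAF convention).

CIGAR_OPS <- c("M", "=", "X", "I", "D", "N")

#' Parse a PAF file of spliced transcript-to-genome alignments
#'
#' Reads minimap2/GMAP-style PAF with at least the 12 standard columns.
#' The `cg:Z:` tag, when present, supplies the CIGAR used to derive exon
#' chains; records without it are flagged span-only (usable for coverage and
#' identity, not for exon-level analysis).
#'
#' @param path Path to a PAF file, or a character vector of PAF lines.
#' @return A data frame with one row per alignment record: `query_id`,
#'   `query_len`, `q_start`, `q_end`, `strand`, `target_id`, `target_len`,
#'   `t_start`, `t_end`, `n_match`, `block_len`, `mapq`, `cigar` (NA when
#'   absent) and `span_only`.
#' @export
parse_paf <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop("malformed PAF line ", bad, ": expected >= 12 columns, got ", nf[bad])
  }
  cigar <- vapply(fields, function(f) {
    tag <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
    if (length(tag)) sub("^cg:Z:", "", tag[1L]) else NA_character_
  }, character(1))
  col <- function(i) vapply(fields, `[[`, character(1), i)
  rec <- data.frame(
    query_id   = col(1),
    query_len  = as.integer(col(2)),
    q_start    = as.integer(col(3)),
    q_end      = as.integer(col(4)),
    strand     = col(5),
    target_id  = col(6),
    target_len = as.integer(col(7)),
    t_start    = as.integer(col(8)),
    t_end      = as.integer(col(9)),
    n_match    = as.integer(col(10)),
    block_len  = as.integer(col(11)),
    mapq       = as.integer(col(12)),
    cigar      = cigar,
    span_only  = is.na(cigar),
    stringsAsFactors = FALSE
  )
  validate_paf(rec)
  rec
}

empty_paf <- function() {
  data.frame(query_id = character(), query_len = integer(),
             q_start = integer(), q_end = integer(), strand = character(),
             target_id = character(), target_len = integer(),
             t_start = integer(), t_end = integer(), n_match = integer(),
             block_len = integer(), mapq = integer(), cigar = character(),
             span_only = logical(), stringsAsFactors = FALSE)
}

validate_paf <- function(rec) {
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) stop("malformed PAF line ", i[1L], ": ", msg)
  }
  bad(is.na(rec$query_len) | is.na(rec$q_start) | is.na(rec$q_end),
      "non-numeric coordinate field")
  bad(!(rec$strand %in% c("+", "-")), "strand must be + or -")
  bad(rec$q_start >= rec$q_end | rec$q_end > rec$query_len,
      "query interval violates 0 <= q_start < q_end <= query_len")
  bad(rec$t_start >= rec$t_end, "target interval violates t_start < t_end")
  bad(rec$n_match > rec$block_len, "n_match exceeds block_len")
  has_cg <- !is.na(rec$cigar)
  if (any(has_cg)) {
    for (i in which(has_cg)) {
      ops <- parse_cigar(rec$cigar[i])
      qc <- sum(ops$len[ops$op %in% c("M", "=", "X", "I")])
      tc <- sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
      if (qc != rec$q_end[i] - rec$q_start[i])
        stop("malformed PAF line ", i,
             ": CIGAR query-consuming ops (", qc, ") != q_end - q_start (",
             rec$q_end[i] - rec$q_start[i], ")")
      if (tc != rec$t_end[i] - rec$t_start[i])
        stop("malformed PAF line ", i,
             ": CIGAR target-consuming ops (", tc, ") != t_end - t_start (",
             rec$t_end[i] - rec$t_start[i], ")")
    }
  }
  invisible(rec)
}

#' Write alignment records as PAF
#'
#' @param rec Alignment records as returned by [parse_paf()].
#' @param path Output file path.
#' @export
write_paf <- function(rec, path) {
  base <- cbind(rec$query_id, rec$query_len, rec$q_start, rec$q_end,
                rec$strand, rec$target_id, rec$target_len, rec$t_start,
                rec$t_end, rec$n_match, rec$block_len, rec$mapq)
  lines <- apply(base, 1L, paste, collapse = "\t")
  has_cg <- !is.na(rec$cigar)
  lines[has_cg] <- paste0(lines[has_cg], "\tcg:Z:", rec$cigar[has_cg])
  writeLines(lines, path)
  invisible(path)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("([0-9]+)([A-Z=])", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(cigar))
    stop("unparseable CIGAR string: ", cigar)
  op <- substring(toks, nchar(toks))
  if (!all(op %in% CIGAR_OPS))
    stop("unsupported CIGAR operation(s): ",
         paste(setdiff(op, CIGAR_OPS), collapse = ", "))
  list(len = as.integer(sub(".$", "", toks)), op = op)
}

#' Derive the exon chain of a spliced alignment
#'
#' Splits the alignment's CIGAR on `N` (intron) operations. `M`, `=`, `X` and
#' `D` consume target bases within exons; adjacent exons are separated by
#' exactly the `N` lengths.
#'
#' @param rec A single alignment record (one-row data frame or list) with a
#'   CIGAR, or the full record table together with `i` selecting the row.
#' @param i Optional row index when `rec` has several rows.
#' @return An object of class `exon_chain`: list with `scaffold`, `strand`,
#'   `exons` (two-column matrix of 0-based half-open intervals) and `introns`.
#' @export
exon_chain <- function(rec, i = 1L) {
  cigar <- rec$cigar[i]
  if (is.na(cigar)) stop("record is span-only (no CIGAR); cannot derive exon chain")
  ops <- parse_cigar(cigar)
  if (ops$op[1L] == "N" || ops$op[length(ops$op)] == "N")
    stop("CIGAR has an N operation at a terminus; an intron cannot flank an alignment")
  exons_from_ops(ops, rec$t_start[i], rec$target_id[i], rec$strand[i])
}

exons_from_ops <- function(ops, t_start, scaffold, strand) {
  target_use <- ifelse(ops$op %in% c("M", "=", "X", "D"), ops$len,
                ifelse(ops$op == "N", ops$len, 0L))
  is_n <- ops$op == "N"
  pos <- t_start
  starts <- integer(0); ends <- integer(0)
  ex_start <- t_start
  for (k in seq_along(ops$op)) {
    if (is_n[k]) {
      starts <- c(starts, ex_start); ends <- c(ends, pos)
      pos <- pos + ops$len[k]
      ex_start <- pos
    } else {
      pos <- pos + target_use[k]
    }
  }
  starts <- c(starts, ex_start); ends <- c(ends, pos)
  new_exon_chain(cbind(start = starts, end = ends), scaffold, strand)
}

#' Construct an exon chain from explicit intervals
#'
#' @param exons Two-column matrix (or coercible) of sorted, disjoint 0-based
#'   half-open exon intervals.
#' @param scaffold Scaffold identifier.
#' @param strand `"+"` or `"-"`.
#' @return An `exon_chain` object; introns are derived as the inter-exon gaps.
#' @export
new_exon_chain <- function(exons, scaffold, strand) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 2L] <= exons[, 1L])) stop("exon of non-positive length")
  if (nrow(exons) > 1L && any(diff(exons[, 1L]) <= 0))
    stop("exons must be sorted and disjoint")
  n <- nrow(exons)
  introns <- if (n > 1L)
    cbind(start = exons[-n, 2L], end = exons[-1L, 1L])
  else
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  structure(list(scaffold = scaffold, strand = strand,
                 exons = exons, introns = introns),
            class = "exon_chain")
}

#' @export
print.exon_chain <- function(x, ...) {
  cat("exon chain on ", x$scaffold, " (", x$strand, "): ",
      paste(sprintf("[%d,%d)", x$exons[, 1L], x$exons[, 2L]), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Sum of exon lengths of a chain
#' @param chain An `exon_chain`.
#' @export
exonic_length <- function(chain) {
  sum(chain$exons[, 2L] - chain$exons[, 1L])
}

#' Exon chains for all CIGAR-bearing records
#'
#' @param rec Alignment record table.
#' @return A list of `exon_chain` objects, `NULL` for span-only records.
#' @export
exon_chains <- function(rec) {
  lapply(seq_len(nrow(rec)), function(i) {
    if (is.na(rec$cigar[i])) NULL else exon_chain(rec, i)
  })
}

#' Query coverage of an alignment
#'
#' Fraction of the query covered by the aligned span:
#' `(q_end - q_start) / query_len`.
#'
#' @param rec Alignment record table.
#' @return Numeric vector in \[0, 1\].
#' @export
query_coverage <- function(rec) {
  stopifnot(all(rec$q_start < rec$q_end), all(rec$q_end <= rec$query_len))
  (rec$q_end - rec$q_start) / rec$query_len
}

#' Percent identity of an alignment
#'
#' Matching bases over alignment columns (`n_match / block_len`, PAF columns
#' 10/11), so indels count against identity.
#'
#' @param rec Alignment record table.
#' @return Numeric vector in \[0, 1\].
#' @export
percent_identity <- function(rec) {
  if (any(rec$block_len == 0L)) stop("percent identity undefined for block_len = 0")
  rec$n_match / rec$block_len
}

#' Filter alignments on coverage and identity
#'
#' Keeps records with `query_coverage >= min_cov` and
#' `percent_identity >= min_id` (both thresholds inclusive); input order is
#' preserved.
#'
#' @param rec Alignment record table.
#' @param min_cov Minimum query coverage in \[0, 1\].
#' @param min_id Minimum percent identity in \[0, 1\].
#' @export
filter_alignments <- function(rec, min_cov, min_id) {
  stopifnot(min_cov >= 0, min_cov <= 1, min_id >= 0, min_id <= 1)
  if (nrow(rec) == 0L) return(rec)
  keep <- query_coverage(rec) >= min_cov & percent_identity(rec) >= min_id
  rec[keep, , drop = FALSE]
}
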