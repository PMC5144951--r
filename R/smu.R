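# Single-mapping-unit (SMU) analysis: mapping-status classification, SMU
# construction from a reference transcript set, strand-aware exon-overlap
# assignment of per-technology members, longest-variant and
# coverage-improvement statistics, nonredundant splice-variant counts and
# library specificity.

#' Classify transcripts by mapping status
#'
#' A transcript is a single mapping unit (SMU) when, after filtering
#' alignments at the given coverage/identity thresholds, it retains exactly
#' one genomic location; `unmapped` when it retains none; `multi` when it
#' retains two or more. The partition is exhaustive over the query universe,
#' including transcripts with no alignment record at all.
#'
#' @param rec Alignment record table (see [parse_paf()]).
#' @param min_cov,min_id Filtering thresholds in \[0, 1\]; defaults 1.0 and
#'   0.90 (full-coverage, 90 percent identity).
#' @param queries Character vector naming the full transcript universe;
#'   defaults to the distinct query ids present in `rec`.
#' @return Data frame with `query_id`, `status` (`unmapped`/`smu`/`multi`)
#'   and `n_loci`.
#' @export
classify_mapping_status <- function(rec, min_cov = 1.0, min_id = 0.90,
                                    queries = unique(rec$query_id)) {
  passing <- filter_alignments(rec, min_cov, min_id)
  n_loci <- table(factor(passing$query_id, levels = queries))
  n <- as.integer(n_loci)
  data.frame(query_id = queries,
             status = ifelse(n == 0L, "unmapped", ifelse(n == 1L, "smu", "multi")),
             n_loci = n,
             stringsAsFactors = FALSE)
}

#' Build SMUs from mapping statuses
#'
#' One SMU per transcript classified `smu`; its locus is the span of the
#' transcript's exon chain. Overlapping SMUs are deliberately not merged:
#' each reference transcript defines its own SMU.
#'
#' @param status Output of [classify_mapping_status()].
#' @param rec The reference alignment record table the statuses were derived
#'   from.
#' @param min_cov,min_id The thresholds used for status classification.
#' @return A list of class `smu_set`; each element has `smu_id`, `locus`
#'   (scaffold, start, end, strand), `reference_transcript`, `chain`
#'   (reference `exon_chain`) and an empty `members` list.
#' @export
build_smus <- function(status, rec, min_cov = 1.0, min_id = 0.90) {
  passing <- filter_alignments(rec, min_cov, min_id)
  ids <- status$query_id[status$status == "smu"]
  smus <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    i <- which(passing$query_id == ids[k])
    stopifnot(length(i) == 1L)
    chain <- exon_chain(passing, i)
    smus[[k]] <- list(
      smu_id = sprintf("SMU_%05d", k),
      locus = list(scaffold = chain$scaffold,
                   start = chain$exons[1L, 1L],
                   end = chain$exons[nrow(chain$exons), 2L],
                   strand = chain$strand),
      reference_transcript = ids[k],
      chain = chain,
      members = list())
  }
  structure(smus, class = "smu_set")
}

#' @export
print.smu_set <- function(x, ...) {
  techs <- unique(unlist(lapply(x, function(s) names(s$members))))
  cat("smu_set: ", length(x), " SMUs",
      if (length(techs)) paste0("; member technologies: ",
                                paste(techs, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

intron_key <- function(chain) {
  if (nrow(chain$introns) == 0L) return("")
  paste(chain$introns[, 1L], chain$introns[, 2L], sep = "-", collapse = ";")
}

#' Assign per-technology member transcripts to SMUs
#'
#' A transcript is a member of an SMU when it aligns on the same scaffold and
#' strand and its exons overlap the SMU reference transcript's exons by at
#' least 1 bp (exon-level, not span-level, so a transcript falling entirely
#' within a reference intron is not a member). Technology records are
#' filtered at the same thresholds as the reference set.
#'
#' @param smus An `smu_set` from [build_smus()].
#' @param tech_records Named list mapping technology label to an alignment
#'   record table.
#' @param min_cov,min_id Filtering thresholds.
#' @return The `smu_set` with `members` populated (per technology: a list
#'   with `query_id`, `exonic_len`, `intron_key` and `chains`), plus an
#'   attribute `coverage` giving per-technology counts and fractions of SMUs
#'   with at least one member.
#' @export
assign_members <- function(smus, tech_records, min_cov = 1.0, min_id = 0.90) {
  if (is.null(names(tech_records)) || any(!nzchar(names(tech_records))))
    stop("tech_records must be a named list of alignment tables")
  n_smu <- length(smus)
  ref_gr <- smu_exon_granges(smus)

  for (tech in names(tech_records)) {
    filt <- filter_alignments(tech_records[[tech]], min_cov, min_id)
    chains <- exon_chains(filt)
    ok <- !vapply(chains, is.null, logical(1))
    filt <- filt[ok, , drop = FALSE]
    chains <- chains[ok]
    hit_pairs <- if (nrow(filt)) {
      mem_gr <- record_exon_granges(chains)
      ov <- GenomicRanges::findOverlaps(mem_gr, ref_gr)
      unique(data.frame(
        rec = S4Vectors::mcols(mem_gr)$rec[S4Vectors::queryHits(ov)],
        smu = S4Vectors::mcols(ref_gr)$smu[S4Vectors::subjectHits(ov)]))
    } else data.frame(rec = integer(0), smu = integer(0))

    for (k in seq_len(n_smu)) {
      ridx <- hit_pairs$rec[hit_pairs$smu == k]
      if (!length(ridx)) next
      smus[[k]]$members[[tech]] <- list(
        query_id = filt$query_id[ridx],
        exonic_len = vapply(chains[ridx], exonic_length, numeric(1)),
        intron_key = vapply(chains[ridx], intron_key, character(1)),
        chains = chains[ridx])
    }
  }

  cov <- t(vapply(names(tech_records), function(tech) {
    n <- sum(vapply(smus, function(s) !is.null(s$members[[tech]]), logical(1)))
    c(count = n, fraction = if (n_smu) n / n_smu else NA_real_)
  }, numeric(2)))
  attr(smus, "coverage") <- data.frame(technology = names(tech_records),
                                       count = cov[, "count"],
                                       fraction = cov[, "fraction"],
                                       row.names = NULL)
  smus
}

exon_granges <- function(chains, idx_name) {
  n_ex <- vapply(chains, function(ch) nrow(ch$exons), integer(1))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(vapply(chains, `[[`, character(1), "scaffold"), n_ex),
    ranges = IRanges::IRanges(
      start = unlist(lapply(chains, function(ch) ch$exons[, 1L] + 1L)),
      end = unlist(lapply(chains, function(ch) ch$exons[, 2L]))),
    strand = rep(vapply(chains, `[[`, character(1), "strand"), n_ex))
  S4Vectors::mcols(gr)[[idx_name]] <- rep(seq_along(chains), n_ex)
  gr
}

smu_exon_granges <- function(smus) {
  exon_granges(lapply(smus, `[[`, "chain"), "smu")
}

record_exon_granges <- function(chains) {
  exon_granges(chains, "rec")
}

#' Longest splice variant per technology at one SMU
#'
#' The length of a splice variant is the sum of its exon lengths. The best
#' set is the argmax over technologies with at least one member; ties are
#' recorded, not broken.
#'
#' @param smu One element of an `smu_set` with members assigned.
#' @return List with `longest` (named numeric, nt, per technology present),
#'   `best` (character vector of best technologies) and `unique_best`.
#' @export
longest_variant_stats <- function(smu) {
  techs <- names(smu$members)
  if (!length(techs))
    return(list(longest = stats::setNames(numeric(0), character(0)),
                best = character(0), unique_best = FALSE))
  longest <- vapply(smu$members, function(m) max(m$exonic_len), numeric(1))
  best <- names(longest)[longest == max(longest)]
  list(longest = longest, best = best, unique_best = length(best) == 1L)
}

#' Coverage improvement of the best technology at one SMU
#'
#' When a single technology provides the longest splice variant, its
#' improvement over each other technology present is the difference of the
#' summed exon lengths of the respective longest variants. Ties are skipped
#' with a warning (improvement is defined only where one technology performs
#' best); an SMU with a single technology yields an empty map.
#'
#' @param smu One element of an `smu_set` with members assigned.
#' @return Named numeric vector (nt); names are the other technologies.
#'   Attribute `best` carries the best technology.
#' @export
coverage_improvement <- function(smu) {
  st <- longest_variant_stats(smu)
  if (length(st$longest) <= 1L)
    return(structure(stats::setNames(numeric(0), character(0)),
                     best = st$best))
  if (!st$unique_best) {
    warning("tie for best technology at ", smu$smu_id,
            "; coverage improvement skipped")
    return(structure(stats::setNames(numeric(0), character(0)),
                     best = st$best))
  }
  others <- setdiff(names(st$longest), st$best)
  impr <- st$longest[st$best] - st$longest[others]
  structure(stats::setNames(as.numeric(impr), others), best = st$best)
}

#' Nonredundant splice variants of one technology at one SMU
#'
#' Members are collapsed by identical intron chain (the ordered list of
#' intron intervals); terminal coordinates are ignored, so length variants of
#' one splice structure count once, and all intron-less members form a single
#' variant class.
#'
#' @param smu One element of an `smu_set` with members assigned.
#' @param tech Technology label.
#' @return Integer count of distinct intron chains (0 when no member).
#' @export
nonredundant_variants <- function(smu, tech) {
  m <- smu$members[[tech]]
  if (is.null(m)) return(0L)
  length(unique(m$intron_key))
}

#' Mean splice variants per SMU after outlier removal
#'
#' Removes values outside the Tukey fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR),
#' with quartiles computed by linear interpolation (quantile type 7), then
#' averages the remainder.
#'
#' @param counts Numeric vector of per-SMU variant counts.
#' @param outlier_rule `"tukey"` (default) or `"none"`.
#' @export
mean_variants_per_smu <- function(counts, outlier_rule = c("tukey", "none")) {
  outlier_rule <- match.arg(outlier_rule)
  if (!length(counts)) stop("mean of an empty count vector is undefined")
  if (outlier_rule == "tukey") {
    q <- stats::quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    keep <- counts >= q[1L] - 1.5 * iqr & counts <= q[2L] + 1.5 * iqr
    counts <- counts[keep]
  }
  mean(counts)
}

#' Library-specific and shared gene products from a cluster table
#'
#' A cluster is library-specific when all of its member transcripts come from
#' one library. Transcripts in clusters spanning several libraries are
#' counted as shared.
#'
#' @param cluster_table Data frame with columns `transcript_id`, `cluster_id`
#'   and `library`.
#' @return List with `specific_clusters` (named integer per library),
#'   `specific_transcripts` (named integer per library),
#'   `shared_clusters` and `shared_transcripts`.
#' @export
library_specificity <- function(cluster_table) {
  libs <- sort(unique(cluster_table$library))
  out <- list(specific_clusters = stats::setNames(integer(length(libs)), libs),
              specific_transcripts = stats::setNames(integer(length(libs)), libs),
              shared_clusters = 0L, shared_transcripts = 0L)
  if (!nrow(cluster_table)) return(out)
  by_cluster <- split(cluster_table$library, cluster_table$cluster_id)
  for (members in by_cluster) {
    u <- unique(members)
    if (length(u) == 1L) {
      out$specific_clusters[u] <- out$specific_clusters[u] + 1L
      out$specific_transcripts[u] <- out$specific_transcripts[u] + length(members)
    } else {
      out$shared_clusters <- out$shared_clusters + 1L
      out$shared_transcripts <- out$shared_transcripts + length(members)
    }
  }
  out
}

#' Per-SMU, per-technology report table
#'
#' @param smus An `smu_set` with members assigned.
#' @return Data frame with one row per SMU x technology present: longest
#'   variant length, whether the technology is (uniquely) best, its coverage
#'   improvement entries, and its nonredundant variant count.
#' @export
smu_report <- function(smus) {
  rows <- list()
  for (s in smus) {
    st <- longest_variant_stats(s)
    impr <- if (st$unique_best) coverage_improvement(s) else numeric(0)
    for (tech in names(s$members)) {
      rows[[length(rows) + 1L]] <- data.frame(
        smu_id = s$smu_id,
        technology = tech,
        n_members = length(s$members[[tech]]$query_id),
        longest = unname(st$longest[tech]),
        is_best = tech %in% st$best,
        unique_best = st$unique_best && tech %in% st$best,
        improvement_over = if (st$unique_best && !tech %in% st$best)
          unname(impr[tech]) else NA_real_,
        nonredundant = nonredundant_variants(s, tech),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
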