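# Synthetic study generator: a multi-scaffold genome, multi-isoform gene
# models, technology-specific transcript sets with exact truth alignments
# (PAF with N CIGAR ops) and truth labels, a protein database, and
# negative-binomial read counts. Everything is deterministic for a fixed
# seed, so downstream stages can be tested against known truth without any
# external data.

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random multi-scaffold genome
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc_target / 2, so realized GC
#' converges on the target (within about two percentage points for scaffolds
#' of 10 kb and above).
#'
#' @param n_scaffolds Number of scaffolds (>= 1).
#' @param scaffold_length Length of each scaffold in nt (>= 1000).
#' @param gc_target Target GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return Named character vector of scaffold sequences
#'   (`scaffold_1`, ...).
#' @export
generate_genome <- function(n_scaffolds, scaffold_length, gc_target = 0.42,
                            seed = 1L) {
  if (n_scaffolds < 1L) stop("n_scaffolds must be >= 1")
  if (scaffold_length < 1000L) stop("scaffold_length must be >= 1000")
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must be in (0, 1)")
  set.seed(seed)
  prob <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
            (1 - gc_target) / 2)
  seqs <- vapply(seq_len(n_scaffolds), function(i)
    paste(sample(BASES, scaffold_length, replace = TRUE, prob = prob),
          collapse = ""), character(1))
  stats::setNames(seqs, paste0("scaffold_", seq_len(n_scaffolds)))
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param type `"DNA"` or `"AA"`.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @param type `"DNA"` or `"AA"`.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

ISOFORM_TYPES <- c("identical", "alt_start", "premature_stop",
                   "intron_retention", "exon_skipping")

# A random stop-free CDS of the given length (multiple of 3): ATG + interior
# codons with in-frame stops patched out + TAA.
random_cds <- function(len, gc_target) {
  stopifnot(len %% 3 == 0, len >= 9)
  prob <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
            (1 - gc_target) / 2)
  b <- sample(BASES, len, replace = TRUE, prob = prob)
  b[1:3] <- c("A", "T", "G")
  b[(len - 2):len] <- c("T", "A", "A")
  starts <- seq(4L, len - 5L, by = 3L)
  codons <- paste0(b[starts], b[starts + 1L], b[starts + 2L])
  bad <- which(codons %in% c("TAA", "TAG", "TGA"))
  b[starts[bad]] <- "C"
  paste(b, collapse = "")
}

derive_isoform <- function(exons, type, strand) {
  n <- nrow(exons)
  switch(type,
    identical = exons,
    alt_start = {
      delta <- sample(10:60, 1L)
      if (strand == "+") exons[1L, 1L] <- exons[1L, 1L] + delta
      else exons[n, 2L] <- exons[n, 2L] - delta
      exons
    },
    premature_stop = {
      delta <- sample(10:60, 1L)
      if (strand == "+") exons[n, 2L] <- exons[n, 2L] - delta
      else exons[1L, 1L] <- exons[1L, 1L] + delta
      exons
    },
    intron_retention = {
      k <- sample(n - 1L, 1L)
      merged <- rbind(c(exons[k, 1L], exons[k + 1L, 2L]))
      out <- rbind(exons[seq_len(k - 1L), , drop = FALSE], merged,
                   exons[seq_len(n)[-seq_len(k + 1L)], , drop = FALSE])
      out
    },
    exon_skipping = {
      internal <- seq(2L, n - 1L)
      k <- internal[sample(length(internal), 1L)]
      exons[-k, , drop = FALSE]
    },
    stop("unknown isoform type: ", type))
}

#' Generate multi-isoform gene models on a genome
#'
#' Genes are placed without overlap; each carries a reference isoform (a
#' stop-free CDS spliced over 3-5 exons) plus `extra_isoforms` alternative
#' isoforms drawn from `isoform_menu` (identical, alternative start,
#' premature stop, intron retention, exon skipping). A fraction of genes is
#' duplicated onto a second locus with identical sequence so that their
#' transcripts become multi-mappers. The genome is patched with the designed
#' exonic sequence and returned alongside the models.
#'
#' @param genome Named character vector of scaffolds (see
#'   [generate_genome()]).
#' @param n_genes Number of genes.
#' @param isoform_menu Named probability vector over the isoform types.
#' @param dup_fraction Fraction of genes duplicated (copy_number 2); the
#'   duplicate count is `floor(dup_fraction * n_genes)`.
#' @param seed Integer seed.
#' @param extra_isoforms Alternative isoforms per gene (default 2).
#' @param exon_len,intron_len Length ranges (nt) for exons and introns.
#' @param gc_target GC used for CDS base composition.
#' @return List of class `gene_models`: `models` (per gene: `gene_id`,
#'   `scaffold`, `strand`, `isoforms` list of exon matrices,
#'   `isoform_types`, `copy_number`, `dup` locus or NULL, `cds`),
#'   `genome` (patched) and `truth_isoforms` (data frame).
#' @export
generate_gene_models <- function(genome, n_genes,
                                 isoform_menu = c(identical = 0.2,
                                                  alt_start = 0.25,
                                                  premature_stop = 0.25,
                                                  intron_retention = 0.2,
                                                  exon_skipping = 0.1),
                                 dup_fraction = 0, seed = 1L,
                                 extra_isoforms = 2L,
                                 exon_len = c(120L, 400L),
                                 intron_len = c(60L, 300L),
                                 gc_target = 0.42) {
  stopifnot(all(names(isoform_menu) %in% ISOFORM_TYPES),
            abs(sum(isoform_menu) - 1) < 1e-8,
            dup_fraction >= 0, dup_fraction <= 1)
  set.seed(seed)
  gap <- 500L
  n_dup <- as.integer(floor(dup_fraction * n_genes))
  dup_genes <- if (n_dup > 0L) sort(sample(n_genes, n_dup)) else integer(0)

  cursor <- stats::setNames(rep(gap, length(genome)), names(genome))
  scaf_len <- nchar(genome)
  place <- function(span) {
    for (sc in names(genome)) {
      if (cursor[sc] + span + gap <= scaf_len[sc]) {
        start <- cursor[sc]
        cursor[sc] <<- cursor[sc] + span + gap
        return(list(scaffold = sc, start = start))
      }
    }
    stop("insufficient scaffold space to place gene of span ", span)
  }

  models <- vector("list", n_genes)
  truth <- list()
  for (g in seq_len(n_genes)) {
    n_ex <- sample(3:5, 1L)
    widths <- sample(seq(exon_len[1L], exon_len[2L]), n_ex, replace = TRUE)
    total <- sum(widths)
    widths[n_ex] <- widths[n_ex] + (3L - total %% 3L) %% 3L
    gaps <- sample(seq(intron_len[1L], intron_len[2L]), n_ex - 1L,
                   replace = TRUE)
    span <- sum(widths) + sum(gaps)
    loc <- place(span)
    starts <- loc$start + cumsum(c(0L, widths[-n_ex] + gaps))
    exons <- cbind(start = starts, end = starts + widths)
    strand <- sample(c("+", "-"), 1L)
    gene_id <- sprintf("gene_%03d", g)

    cds <- random_cds(sum(widths), gc_target)
    genomic_exonic <- if (strand == "+") cds else revcomp(cds)
    off <- 0L
    for (e in seq_len(n_ex)) {
      w <- widths[e]
      substr(genome[[loc$scaffold]], exons[e, 1L] + 1L, exons[e, 2L]) <-
        substr(genomic_exonic, off + 1L, off + w)
      off <- off + w
    }

    types <- if (extra_isoforms > 0L)
      sample(names(isoform_menu), extra_isoforms, replace = TRUE,
             prob = isoform_menu) else character(0)
    isoforms <- c(list(exons), lapply(types, derive_isoform, exons = exons,
                                      strand = strand))
    iso_types <- c("identical", types)

    dup <- NULL
    if (g %in% dup_genes) {
      dloc <- place(span)
      substr(genome[[dloc$scaffold]], dloc$start + 1L, dloc$start + span) <-
        substr(genome[[loc$scaffold]], loc$start + 1L, loc$start + span)
      dup <- list(scaffold = dloc$scaffold, shift = dloc$start - loc$start)
    }

    models[[g]] <- list(gene_id = gene_id, scaffold = loc$scaffold,
                        strand = strand, isoforms = isoforms,
                        isoform_types = iso_types,
                        copy_number = if (is.null(dup)) 1L else 2L,
                        dup = dup, cds = cds)
    truth[[g]] <- data.frame(gene_id = gene_id,
                             isoform_index = seq_along(isoforms),
                             type = iso_types, stringsAsFactors = FALSE)
  }
  structure(list(models = models, genome = genome,
                 truth_isoforms = do.call(rbind, truth)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models: ", length(x$models), " genes on ",
      length(x$genome), " scaffolds; ",
      sum(vapply(x$models, function(m) m$copy_number, integer(1)) == 2L),
      " duplicated\n", sep = "")
  invisible(x)
}

#' Write gene models as GFF3 (1-based closed coordinates)
#' @param gm A `gene_models` object.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(gm, path) {
  rows <- list()
  for (m in gm$models) {
    span <- range(unlist(lapply(m$isoforms, function(e) c(e[, 1L], e[, 2L]))))
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = m$scaffold, start = span[1L] + 1L, end = span[2L],
      strand = m$strand, type = "gene", ID = m$gene_id, Parent = NA)
    for (i in seq_along(m$isoforms)) {
      ex <- m$isoforms[[i]]
      tid <- paste0(m$gene_id, ".", i)
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = m$scaffold, start = ex[1L, 1L] + 1L,
        end = ex[nrow(ex), 2L], strand = m$strand, type = "mRNA",
        ID = tid, Parent = m$gene_id)
      for (e in seq_len(nrow(ex)))
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = m$scaffold, start = ex[e, 1L] + 1L, end = ex[e, 2L],
          strand = m$strand, type = "exon",
          ID = paste0(tid, ".exon", e), Parent = tid)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA_character_,
                                        df$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Technology simulation profile
#'
#' Bundles the parameters of one sequencing technology: characteristic
#' transcript length (used as a soft cap emulating assembly fragmentation),
#' truncation probabilities, per-base substitution and indel rates, mean
#' isoform sampling depth per gene, and per-transcript read depth for the
#' counts table.
#'
#' @param name Technology label.
#' @param mean_len,len_sd Characteristic assembled-transcript length (nt);
#'   transcripts longer than a draw from N(mean_len, len_sd) get their
#'   alignment clipped to it. Use a large `mean_len` to disable.
#' @param truncation_5p_prob,truncation_3p_prob Probability of a clipped
#'   (unaligned) 5'/3' flank of `trunc_frac` of the transcript.
#' @param subst_rate,indel_rate Per-base error rates in \[0, 1).
#' @param isoforms_per_gene Mean Poisson isoform draws per gene.
#' @param depth Mean reads per transcript (negative binomial).
#' @param trunc_frac Clipped fraction per truncation event, default 0.10.
#' @param dispersion Negative-binomial dispersion, default 0.3.
#' @export
tech_profile <- function(name, mean_len = 1e6, len_sd = 0,
                         truncation_5p_prob = 0, truncation_3p_prob = 0,
                         subst_rate = 0, indel_rate = 0,
                         isoforms_per_gene = 1, depth = 10,
                         trunc_frac = 0.10, dispersion = 0.3) {
  rates <- c(truncation_5p_prob, truncation_3p_prob, subst_rate, indel_rate)
  stopifnot(all(rates >= 0), all(rates < 1), mean_len > 0,
            isoforms_per_gene >= 1 || isoforms_per_gene > 0, depth >= 0)
  structure(list(name = name, mean_len = mean_len, len_sd = len_sd,
                 truncation_5p_prob = truncation_5p_prob,
                 truncation_3p_prob = truncation_3p_prob,
                 subst_rate = subst_rate, indel_rate = indel_rate,
                 isoforms_per_gene = isoforms_per_gene, depth = depth,
                 trunc_frac = trunc_frac, dispersion = dispersion),
            class = "tech_profile")
}

#' Default study profiles for the three technologies
#'
#' Qualitative contrasts, not calibrated constants: `hiseq` is deep and
#' accurate but fragmented; `miseq` similar with lower depth; `pacbio` is
#' long and isoform-rich but noisy and shallow. Isoform sampling depths
#' (1.6 / 1.5 / 3.7) mirror the per-SMU splice-variant means typical of this
#' kind of short- vs long-read comparison.
#' @export
default_tech_profiles <- function() {
  list(
    hiseq = tech_profile("hiseq", mean_len = 1600, len_sd = 400,
                         truncation_5p_prob = 0.25, truncation_3p_prob = 0.25,
                         subst_rate = 0.004, indel_rate = 0.001,
                         isoforms_per_gene = 1.6, depth = 300),
    miseq = tech_profile("miseq", mean_len = 1700, len_sd = 450,
                         truncation_5p_prob = 0.25, truncation_3p_prob = 0.25,
                         subst_rate = 0.003, indel_rate = 0.001,
                         isoforms_per_gene = 1.5, depth = 60),
    pacbio = tech_profile("pacbio", mean_len = 4000, len_sd = 800,
                          truncation_5p_prob = 0.05, truncation_3p_prob = 0.05,
                          subst_rate = 0.02, indel_rate = 0.03,
                          isoforms_per_gene = 3.7, depth = 12))
}

# Remove k query/target bases from the low or high genomic side of a chain.
trim_chain <- function(exons, k, side = c("low", "high")) {
  side <- match.arg(side)
  while (k > 0L && nrow(exons) > 0L) {
    i <- if (side == "low") 1L else nrow(exons)
    w <- exons[i, 2L] - exons[i, 1L]
    if (k >= w) {
      exons <- exons[-i, , drop = FALSE]
      k <- k - w
    } else {
      if (side == "low") exons[i, 1L] <- exons[i, 1L] + k
      else exons[i, 2L] <- exons[i, 2L] - k
      k <- 0L
    }
  }
  if (nrow(exons) == 0L) stop("chain trimmed to nothing")
  exons
}

spliced_seq <- function(genome, scaffold, exons, strand) {
  parts <- vapply(seq_len(nrow(exons)), function(e)
    substr(genome[[scaffold]], exons[e, 1L] + 1L, exons[e, 2L]), character(1))
  g <- paste(parts, collapse = "")
  if (strand == "+") g else revcomp(g)
}

# Per-base error simulation over a trimmed chain, walking the target forward.
# Returns the target-oriented aligned query sequence, the CIGAR (with N ops
# between exons) and the match/block bookkeeping. Indels are single-base;
# substitutions and indels leave the exon chain itself untouched (D consumes
# target inside an exon).
sim_alignment_ops <- function(genome, scaffold, exons, subst_rate, indel_rate) {
  n_ex <- nrow(exons)
  tokens <- character(0)
  qparts <- character(0)
  n_match <- 0L; n_block <- 0L
  for (e in seq_len(n_ex)) {
    seq_e <- substr(genome[[scaffold]], exons[e, 1L] + 1L, exons[e, 2L])
    b <- strsplit(seq_e, "", fixed = TRUE)[[1]]
    n <- length(b)
    if (subst_rate == 0 && indel_rate == 0) {
      tokens <- c(tokens, paste0(n, "M"))
      qparts <- c(qparts, seq_e)
      n_match <- n_match + n; n_block <- n_block + n
    } else {
      u <- stats::runif(n)
      del <- u < indel_rate / 2
      sub <- !del & u < indel_rate / 2 + subst_rate
      ins <- stats::runif(n) < indel_rate / 2
      qb <- b
      if (any(sub))
        qb[sub] <- vapply(b[sub], function(x)
          sample(setdiff(BASES, x), 1L), character(1))
      slot_op <- character(2L * n)
      slot_q <- character(2L * n)
      odd <- seq(1L, 2L * n, by = 2L)
      slot_op[odd] <- ifelse(del, "D", "M")
      slot_q[odd] <- ifelse(del, "", qb)
      if (any(ins)) {
        slot_op[odd[ins] + 1L] <- "I"
        slot_q[odd[ins] + 1L] <- sample(BASES, sum(ins), replace = TRUE)
      }
      ops <- slot_op[nzchar(slot_op)]
      r <- rle(ops)
      tokens <- c(tokens, paste0(r$lengths, r$values))
      qparts <- c(qparts, paste(slot_q, collapse = ""))
      n_match <- n_match + sum(!del & !sub)
      n_block <- n_block + n + sum(ins)
    }
    if (e < n_ex)
      tokens <- c(tokens, paste0(exons[e + 1L, 1L] - exons[e, 2L], "N"))
  }
  list(cigar = paste(tokens, collapse = ""),
       query_target_oriented = paste(qparts, collapse = ""),
       n_match = n_match, block_len = n_block)
}

#' Simulate a technology-specific transcript set with truth alignments
#'
#' For each gene, isoforms are sampled (Poisson draws with replacement then
#' deduplicated per gene/isoform, or exhaustively, or the reference isoform
#' only), spliced sequences are extracted, truncation clips the alignment
#' flanks, and per-base substitutions/indels are applied over the aligned
#' region. The truth PAF carries the exact exon chain (with `N` CIGAR
#' operations) of each transcript; duplicated genes yield one record per
#' locus, making their transcripts multi-mappers.
#'
#' @param gm A `gene_models` object.
#' @param profile A [tech_profile()].
#' @param seed Integer seed.
#' @param sampling `"poisson"` (default), `"exhaustive"` (every isoform
#'   once) or `"reference"` (reference isoform only; used for the combined
#'   reference transcript set).
#' @return List with `transcripts` (named character vector), `paf` (truth
#'   alignment records) and `truth` (per-transcript table: ids, technology,
#'   locus, variant type).
#' @export
simulate_transcript_set <- function(gm, profile, seed = 1L,
                                    sampling = c("poisson", "exhaustive",
                                                 "reference")) {
  sampling <- match.arg(sampling)
  set.seed(seed)
  seqs <- character(0)
  paf_rows <- list()
  truth_rows <- list()
  for (m in gm$models) {
    n_iso <- length(m$isoforms)
    picks <- switch(sampling,
      poisson = {
        k <- stats::rpois(1L, profile$isoforms_per_gene)
        if (k == 0L) integer(0) else unique(sample(n_iso, k, replace = TRUE))
      },
      exhaustive = seq_len(n_iso),
      reference = 1L)
    for (iso in picks) {
      exons <- m$isoforms[[iso]]
      full_seq <- spliced_seq(gm$genome, m$scaffold, exons, m$strand)
      slen <- nchar(full_seq)

      clip5 <- if (stats::runif(1) < profile$truncation_5p_prob)
        as.integer(round(profile$trunc_frac * slen)) else 0L
      clip3 <- if (stats::runif(1) < profile$truncation_3p_prob)
        as.integer(round(profile$trunc_frac * slen)) else 0L
      cap <- as.integer(round(stats::rnorm(1, profile$mean_len,
                                           profile$len_sd)))
      min_aligned <- 100L
      excess <- (slen - clip5 - clip3) - max(cap, min_aligned)
      if (excess > 0L) {
        if (stats::runif(1) < 0.5) clip5 <- clip5 + excess
        else clip3 <- clip3 + excess
      }
      if (slen - clip5 - clip3 < min_aligned) {
        over <- min_aligned - (slen - clip5 - clip3)
        take5 <- min(clip5, over)
        clip5 <- clip5 - take5
        clip3 <- max(0L, clip3 - (over - take5))
      }

      lowk <- if (m$strand == "+") clip5 else clip3
      highk <- if (m$strand == "+") clip3 else clip5
      chain <- exons
      if (lowk > 0L) chain <- trim_chain(chain, lowk, "low")
      if (highk > 0L) chain <- trim_chain(chain, highk, "high")

      sim <- sim_alignment_ops(gm$genome, m$scaffold, chain,
                               profile$subst_rate, profile$indel_rate)
      aligned_q <- if (m$strand == "+") sim$query_target_oriented
                   else revcomp(sim$query_target_oriented)
      query <- paste0(substr(full_seq, 1L, clip5), aligned_q,
                      substr(full_seq, slen - clip3 + 1L, slen))
      qlen <- nchar(query)
      q_start <- clip5
      q_end <- clip5 + nchar(aligned_q)

      tid <- sprintf("%s|%s.%d", profile$name, m$gene_id, iso)
      seqs[tid] <- query

      loci <- list(list(scaffold = m$scaffold, shift = 0L))
      if (!is.null(m$dup))
        loci <- c(loci, list(m$dup))
      for (loc in loci) {
        paf_rows[[length(paf_rows) + 1L]] <- data.frame(
          query_id = tid, query_len = qlen, q_start = q_start, q_end = q_end,
          strand = m$strand, target_id = loc$scaffold,
          target_len = nchar(gm$genome[[loc$scaffold]]),
          t_start = chain[1L, 1L] + loc$shift,
          t_end = chain[nrow(chain), 2L] + loc$shift,
          n_match = sim$n_match, block_len = sim$block_len, mapq = 60L,
          cigar = sim$cigar, span_only = FALSE, stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = m$gene_id, isoform_index = iso,
        technology = profile$name, scaffold = m$scaffold,
        start = chain[1L, 1L], end = chain[nrow(chain), 2L],
        strand = m$strand, variant_type = m$isoform_types[iso],
        copy_number = m$copy_number, stringsAsFactors = FALSE)
    }
  }
  list(transcripts = seqs,
       paf = if (length(paf_rows)) do.call(rbind, paf_rows) else empty_paf(),
       truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
         data.frame())
}

#' Simulate the protein database implied by the gene models
#'
#' One protein per gene: the translation of the reference isoform's CDS
#' (stop trimmed). The truth hit table gives, per isoform, the expected
#' query and target coverage fractions of a hit against that protein,
#' derived from the exonic overlap with the reference isoform (about 1.0/1.0
#' for full-length reference isoforms).
#'
#' @param gm A `gene_models` object.
#' @return List with `proteins` (named character vector, ids `pro_<gene>`) and
#'   `truth_hits` (data frame `gene_id`, `isoform_index`, `qcov`, `tcov`).
#' @export
simulate_protein_db <- function(gm) {
  if (!length(gm$models))
    return(list(proteins = stats::setNames(character(0), character(0)),
                truth_hits = data.frame()))
  proteins <- character(0)
  rows <- list()
  for (m in gm$models) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(m$cds)))
    proteins[paste0("pro_", m$gene_id)] <- sub("\\*$", "", aa)
    ref <- m$isoforms[[1L]]
    for (i in seq_along(m$isoforms)) {
      shared <- exonic_intersection(m$isoforms[[i]], ref)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = m$gene_id, isoform_index = i,
        qcov = shared / sum(m$isoforms[[i]][, 2L] - m$isoforms[[i]][, 1L]),
        tcov = shared / sum(ref[, 2L] - ref[, 1L]),
        stringsAsFactors = FALSE)
    }
  }
  list(proteins = proteins, truth_hits = do.call(rbind, rows))
}

exonic_intersection <- function(a, b) {
  total <- 0L
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a[i, 2L], b[, 2L]) - pmax(a[i, 1L], b[, 1L])
    total <- total + sum(ov[ov > 0L])
  }
  total
}

#' Simulate per-transcript read counts
#'
#' Counts are negative binomial with mean `profile$depth` and dispersion
#' `profile$dispersion` (variance mu + dispersion * mu^2).
#'
#' @param transcript_ids Character vector of transcript ids.
#' @param profile A [tech_profile()].
#' @param seed Integer seed.
#' @return Data frame `transcript_id`, `count`.
#' @export
simulate_read_counts <- function(transcript_ids, profile, seed = 1L) {
  set.seed(seed)
  n <- length(transcript_ids)
  counts <- if (profile$depth == 0) rep(0L, n)
    else stats::rnbinom(n, mu = profile$depth, size = 1 / profile$dispersion)
  data.frame(transcript_id = transcript_ids, count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Build a protein hit table from simulated transcripts
#'
#' Emits, for each simulated transcript, its expected local-alignment hit
#' against the protein of its source gene: the aligned spans follow from the
#' exonic overlap between the transcript's aligned chain and the gene's
#' reference isoform (the CDS). Transcripts whose aligned chain shares no
#' exonic sequence with the CDS produce no hit.
#'
#' @param sim Output of [simulate_transcript_set()].
#' @param gm The `gene_models` object.
#' @return Hit table in the layout of [read_hit_table()].
#' @export
simulate_protein_hits <- function(sim, gm) {
  by_gene <- stats::setNames(gm$models,
                             vapply(gm$models, `[[`, character(1), "gene_id"))
  chains <- exon_chains(sim$paf)
  first_rec <- match(sim$truth$transcript_id, sim$paf$query_id)
  rows <- list()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    m <- by_gene[[tr$gene_id]]
    ref <- m$isoforms[[1L]]
    chain <- chains[[first_rec[i]]]
    shared <- exonic_intersection(chain$exons, ref)
    if (shared <= 0L) next
    prot_len <- nchar(m$cds) / 3L - 1L
    t_aln <- if (shared == nchar(m$cds)) prot_len else
      min(prot_len, max(1L, floor(shared / 3L)))
    qlen <- sim$paf$query_len[first_rec[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = tr$transcript_id, query_len = qlen,
      target_id = paste0("pro_", tr$gene_id), target_len = prot_len,
      q_start = 0L, q_end = min(qlen, shared),
      t_start = 0L, t_end = as.integer(t_aln),
      e_value = 1e-30, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(query_id = character(0), query_len = integer(0),
                      target_id = character(0), target_len = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      e_value = numeric(0)))
  do.call(rbind, rows)
}

#' Plant miRNA precursor candidates with known verdicts
#'
#' Builds hairpin-like precursor candidates around known mature sequences:
#' each candidate carries a mature copy with the requested number of
#' mismatches, a loop, the reverse complement of the mature (the star arm)
#' and random flanks, plus an MFE value chosen so that the candidate's MFEI
#' equals `mfei_target`.
#'
#' @param known_matures Data frame with `family` and `sequence`.
#' @param plan Data frame with one row per candidate: `family`,
#'   `mismatches`, `mfei_target`, `length` (total precursor nt).
#' @param seed Integer seed.
#' @return Candidate table suitable for [filter_precursors()].
#' @export
simulate_mirna_candidates <- function(known_matures, plan, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    fam <- plan$family[i]
    mat <- norm_rna(known_matures$sequence[known_matures$family == fam][1L])
    mb <- strsplit(mat, "")[[1]]
    if (plan$mismatches[i] > 0L) {
      pos <- sample(length(mb), plan$mismatches[i])
      mb[pos] <- vapply(mb[pos], function(x)
        sample(setdiff(BASES, x), 1L), character(1))
    }
    mature <- paste(mb, collapse = "")
    star <- revcomp(mature)
    loop <- paste(sample(BASES, 8L, replace = TRUE), collapse = "")
    core <- paste0(mature, loop, star)
    flank_total <- max(0L, plan$length[i] - nchar(core))
    f5 <- flank_total %/% 2L
    f3 <- flank_total - f5
    seqs <- paste0(paste(sample(BASES, f5, replace = TRUE), collapse = ""),
                   core,
                   paste(sample(BASES, f3, replace = TRUE), collapse = ""))
    gc <- gc_content(seqs)
    mfe <- plan$mfei_target[i] * gc * nchar(seqs)
    rows[[i]] <- data.frame(
      precursor_id = sprintf("pre_%03d", i),
      source_transcript_id = sprintf("src_%03d", i),
      sequence = seqs, mature_start = f5, mature_end = f5 + nchar(mature),
      mfe = mfe, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
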