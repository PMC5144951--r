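test_that("genome generation honors dimensions, GC target and determinism", {
  g <- generate_genome(3, 10000, gc_target = 0.5, seed = 7)
  expect_length(g, 3L)
  expect_true(all(nchar(g) == 10000L))

  big <- generate_genome(1, 100000, gc_target = 0.5, seed = 1)
  expect_gte(gc_content(big), 0.48)
  expect_lte(gc_content(big), 0.52)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(generate_genome(2, 5000, 0.4, seed = 99), f1)
  write_fasta(generate_genome(2, 5000, 0.4, seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(read_fasta(f1), generate_genome(2, 5000, 0.4, seed = 99))

  expect_error(generate_genome(0, 10000), "n_scaffolds")
  expect_error(generate_genome(1, 10), "scaffold_length")
  expect_error(generate_genome(1, 10000, gc_target = 1.2), "gc_target")
})

test_that("gene models obey the isoform menu and duplication rounding", {
  g <- generate_genome(3, 50000, seed = 2)
  ident <- generate_gene_models(g, 10, isoform_menu = c(identical = 1),
                                seed = 3)
  for (m in ident$models)
    expect_equal(length(unique(vapply(m$isoforms, function(e)
      paste(e, collapse = ","), character(1)))), 1L)

  ir <- generate_gene_models(g, 5, isoform_menu = c(intron_retention = 1),
                             seed = 4, extra_isoforms = 1L)
  labels <- ir$truth_isoforms$type[ir$truth_isoforms$isoform_index > 1]
  expect_equal(labels, rep("intron_retention", 5))

  dup <- generate_gene_models(g, 10, dup_fraction = 0.2, seed = 1)
  expect_equal(sum(vapply(dup$models, `[[`, integer(1), "copy_number") == 2L),
               2L)
  expect_error(generate_gene_models(generate_genome(1, 1000, seed = 1), 50),
               "insufficient")
})

test_that("alternative isoforms classify to their planted event at zero noise", {
  g <- generate_genome(4, 100000, seed = 20)
  gm <- generate_gene_models(g, 40, seed = 21)
  for (m in gm$models) {
    ref <- new_exon_chain(m$isoforms[[1]], m$scaffold, m$strand)
    for (i in seq_along(m$isoforms)[-1]) {
      cand <- new_exon_chain(m$isoforms[[i]], m$scaffold, m$strand)
      expect_identical(classify_variant(cand, ref)$labels,
                       m$isoform_types[i])
    }
  }
})

test_that("zero-noise transcripts equal their spliced isoform sequence", {
  g <- generate_genome(2, 60000, seed = 5)
  gm <- generate_gene_models(g, 8, seed = 6)
  sim <- simulate_transcript_set(gm, tech_profile("clean"), seed = 7,
                                 sampling = "exhaustive")
  expect_equal(length(sim$transcripts), nrow(sim$truth))
  rec <- sim$paf
  expect_true(all(rec$q_start == 0L))
  expect_true(all(query_coverage(rec) == 1))
  expect_true(all(percent_identity(rec) == 1))
  # sequence check against the (gene-patched) genome for a few transcripts
  chains <- exon_chains(rec)
  for (i in seq_len(min(6, nrow(rec)))) {
    ch <- chains[[i]]
    parts <- vapply(seq_len(nrow(ch$exons)), function(e)
      substr(gm$genome[[ch$scaffold]], ch$exons[e, 1] + 1, ch$exons[e, 2]),
      character(1))
    spliced <- paste(parts, collapse = "")
    if (ch$strand == "-")
      spliced <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(spliced)))
    expect_identical(unname(sim$transcripts[rec$query_id[i]]), spliced)
  }
})

test_that("forced truncation clips the truth alignment, not the transcript", {
  g <- generate_genome(2, 60000, seed = 5)
  gm <- generate_gene_models(g, 8, seed = 6)
  prof <- tech_profile("trunc", truncation_5p_prob = 0.999)
  sim <- simulate_transcript_set(gm, prof, seed = 8, sampling = "reference")
  expect_true(all(sim$paf$q_start > 0L))
  expect_true(all(query_coverage(sim$paf) < 1))
  # the truth PAF stays internally consistent (validated on parse)
  tmp <- tempfile(); write_paf(sim$paf, tmp)
  expect_silent(parse_paf(tmp))
})

test_that("exhaustive sampling emits every isoform; duplicated genes multi-map", {
  g <- generate_genome(3, 80000, seed = 30)
  gm <- generate_gene_models(g, 10, dup_fraction = 0.2, seed = 31,
                             extra_isoforms = 2L)
  sim <- simulate_transcript_set(gm, tech_profile("clean"), seed = 32,
                                 sampling = "exhaustive")
  expect_equal(nrow(sim$truth), 30L)  # 10 genes x 3 isoforms
  st <- classify_mapping_status(sim$paf, queries = sim$truth$transcript_id)
  dup_tx <- sim$truth$transcript_id[sim$truth$copy_number == 2L]
  expect_true(all(st$status[st$query_id %in% dup_tx] == "multi"))
  expect_true(all(st$status[!st$query_id %in% dup_tx] == "smu"))
})

test_that("protein database translates the reference CDS", {
  g <- generate_genome(2, 60000, seed = 40)
  gm <- generate_gene_models(g, 5, seed = 41)
  pd <- simulate_protein_db(gm)
  expect_length(pd$proteins, 5L)
  cds_len <- vapply(gm$models, function(m) nchar(m$cds), numeric(1))
  expect_equal(unname(nchar(pd$proteins)), unname(cds_len / 3 - 1))
  expect_false(any(grepl("\\*", pd$proteins)))
  ref_rows <- pd$truth_hits[pd$truth_hits$isoform_index == 1, ]
  expect_true(all(ref_rows$qcov == 1 & ref_rows$tcov == 1))
  alt <- pd$truth_hits[pd$truth_hits$isoform_index > 1, ]
  expect_true(all(alt$qcov > 0 & alt$tcov <= 1))

  none <- simulate_protein_db(structure(list(models = list(), genome = NULL),
                                        class = "gene_models"))
  expect_length(none$proteins, 0L)
})

test_that("read counts are deterministic with the stated NB moments", {
  prof <- tech_profile("t", depth = 50)
  ids <- paste0("t", 1:1000)
  c1 <- simulate_read_counts(ids, prof, seed = 3)
  c2 <- simulate_read_counts(ids, prof, seed = 3)
  expect_identical(c1, c2)
  # mean within 3 SE: var = mu + disp * mu^2
  se <- sqrt((50 + 0.3 * 50^2) / 1000)
  expect_lt(abs(mean(c1$count) - 50), 3 * se)
  zero <- simulate_read_counts(ids[1:10], tech_profile("z", depth = 0), 1)
  expect_true(all(zero$count == 0L))
})

test_that("gene models export well-formed 1-based GFF3", {
  g <- generate_genome(2, 50000, seed = 50)
  gm <- generate_gene_models(g, 4, seed = 51)
  tmp <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(gm, tmp)
  lines <- readLines(tmp)
  expect_true(any(grepl("gff-version 3", lines)))
  body <- lines[!startsWith(lines, "#")]
  types <- vapply(strsplit(body, "\t"), `[[`, character(1), 3)
  expect_equal(sum(types == "gene"), 4L)
  expect_equal(sum(types == "mRNA"), 12L)
  # first exon of gene 1 starts 1 beyond its 0-based coordinate
  m <- gm$models[[1]]
  exon1 <- body[grepl(paste0(m$gene_id, "\\.1\\.exon1;"), body) |
                  grepl(paste0("ID=", m$gene_id, "\\.1\\.exon1"), body)][1]
  start_field <- as.integer(strsplit(exon1, "\t")[[1]][4])
  expect_equal(start_field, unname(m$isoforms[[1]][1, 1]) + 1L)
})
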