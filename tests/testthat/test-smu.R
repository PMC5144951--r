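test_that("mapping status partitions queries exhaustively", {
  rec <- parse_paf(c(
    simple_paf_record("smu1", 1000, ts = 0),
    simple_paf_record("multi1", 800, ts = 5000),
    simple_paf_record("multi1", 800, ts = 20000),
    simple_paf_record("multi1", 800, ts = 40000),
    simple_paf_record("low_id", 900, ts = 60000, id_frac = 0.85)))
  st <- classify_mapping_status(rec, queries = c("smu1", "multi1", "low_id",
                                                 "never_aligned"))
  expect_equal(st$status[st$query_id == "smu1"], "smu")
  expect_equal(st$status[st$query_id == "multi1"], "multi")
  expect_equal(st$n_loci[st$query_id == "multi1"], 3L)
  expect_equal(st$status[st$query_id == "low_id"], "unmapped")
  expect_equal(st$status[st$query_id == "never_aligned"], "unmapped")
  expect_equal(nrow(st), 4L)
  expect_equal(sum(table(st$status)), 4L)
})

test_that("partition conservation holds on random inputs at any threshold pair", {
  set.seed(202)
  n_q <- 300L
  lines <- unlist(lapply(seq_len(n_q), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(character(0))
    vapply(seq_len(k), function(j)
      simple_paf_record(paste0("q", i), sample(300:1500, 1),
                        ts = sample(1:5e5, 1),
                        id_frac = stats::runif(1, 0.8, 1),
                        cov = sample(c(1, 0.9, 0.8), 1)), character(1))
  }))
  rec <- parse_paf(lines)
  queries <- paste0("q", seq_len(n_q))
  for (thr in list(c(1, 0.9), c(0.9, 0.98), c(0.5, 0.5), c(0, 0))) {
    st <- classify_mapping_status(rec, thr[1], thr[2], queries = queries)
    expect_equal(nrow(st), n_q)
    expect_equal(sum(st$status == "unmapped") + sum(st$status == "smu") +
                   sum(st$status == "multi"), n_q)
    expect_true(all((st$status == "smu") == (st$n_loci == 1L)))
    expect_true(all((st$status == "unmapped") == (st$n_loci == 0L)))
  }
})

test_that("build_smus makes one SMU per smu query and never merges overlapping loci", {
  rec <- parse_paf(c(
    paf_line("a", 500, 0, 500, "+", "s1", 1e6, 100, 700, 500, 500,
             cg = "200M100N300M"),
    paf_line("b", 400, 0, 400, "+", "s1", 1e6, 150, 550, 400, 400,
             cg = "400M"),
    paf_line("c", 300, 0, 300, "+", "s2", 1e6, 0, 300, 300, 300,
             cg = "300M")))
  st <- classify_mapping_status(rec)
  smus <- build_smus(st, rec)
  expect_equal(length(smus), 3L)
  loci <- vapply(smus, function(s) s$locus$scaffold, character(1))
  expect_equal(sort(loci), c("s1", "s1", "s2"))
  # overlapping a/b remain distinct SMUs
  expect_equal(length(unique(vapply(smus, `[[`, character(1),
                                    "reference_transcript"))), 3L)

  none <- classify_mapping_status(empty <- rec[0, ], queries = character(0))
  expect_equal(length(build_smus(none, empty)), 0L)
})

test_that("member assignment needs same strand and exon-level overlap", {
  ref <- parse_paf(paf_line("ref", 500, 0, 500, "+", "s1", 1e6, 100, 700,
                            500, 500, cg = "200M100N300M"))
  st <- classify_mapping_status(ref)
  smus <- build_smus(st, ref)

  tech <- parse_paf(c(
    # identical chain: member
    paf_line("same", 500, 0, 500, "+", "s1", 1e6, 100, 700, 500, 500,
             cg = "200M100N300M"),
    # same span, opposite strand: excluded
    paf_line("anti", 500, 0, 500, "-", "s1", 1e6, 100, 700, 500, 500,
             cg = "200M100N300M"),
    # falls entirely inside the reference intron: excluded
    paf_line("intronic", 80, 0, 80, "+", "s1", 1e6, 310, 390, 80, 80,
             cg = "80M"),
    # 1 bp exonic overlap: member
    paf_line("edge", 2, 0, 2, "+", "s1", 1e6, 299, 399, 2, 2,
             cg = "1M98N1M")))
  smus <- assign_members(smus, list(techA = tech))
  m <- smus[[1]]$members$techA
  expect_setequal(m$query_id, c("same", "edge"))
  cov <- attr(smus, "coverage")
  expect_equal(cov$count, 1)
  expect_equal(cov$fraction, 1)
})

test_that("longest-variant statistics and coverage improvement match direct differences", {
  smu <- list(smu_id = "SMU_1",
              members = list(
                A = list(query_id = "a", exonic_len = c(700, 1000),
                         intron_key = c("", ""), chains = list()),
                B = list(query_id = "b", exonic_len = 600,
                         intron_key = "", chains = list()),
                C = list(query_id = "c", exonic_len = 250,
                         intron_key = "", chains = list())))
  st <- longest_variant_stats(smu)
  expect_equal(st$longest, c(A = 1000, B = 600, C = 250))
  expect_equal(st$best, "A")
  expect_true(st$unique_best)
  impr <- coverage_improvement(smu)
  expect_equal(impr[["B"]], 400)
  expect_equal(impr[["C"]], 750)
  expect_equal(attr(impr, "best"), "A")
  # internal consistency: improvements are exactly pairwise differences
  expect_equal(unname(impr[c("B", "C")]),
               unname(st$longest["A"] - st$longest[c("B", "C")]))

  tie <- list(smu_id = "SMU_2",
              members = list(A = list(exonic_len = 500, query_id = "a",
                                      intron_key = "", chains = list()),
                             B = list(exonic_len = 500, query_id = "b",
                                      intron_key = "", chains = list())))
  ts <- longest_variant_stats(tie)
  expect_setequal(ts$best, c("A", "B"))
  expect_false(ts$unique_best)
  expect_warning(ti <- coverage_improvement(tie), "tie")
  expect_length(ti, 0L)

  solo <- list(smu_id = "SMU_3",
               members = list(C = list(exonic_len = 300, query_id = "c",
                                       intron_key = "", chains = list())))
  expect_equal(longest_variant_stats(solo)$best, "C")
  expect_length(coverage_improvement(solo), 0L)
})

test_that("nonredundant variants collapse by intron chain only", {
  smu <- list(members = list(
    A = list(query_id = c("x", "y", "z"),
             exonic_len = c(500, 450, 400),
             intron_key = c("100-200", "100-200", "100-200"),
             chains = list()),
    B = list(query_id = c("u", "v"),
             exonic_len = c(300, 280),
             intron_key = c("100-200", ""),
             chains = list())))
  expect_equal(nonredundant_variants(smu, "A"), 1L)
  expect_equal(nonredundant_variants(smu, "B"), 2L)
  expect_equal(nonredundant_variants(smu, "C"), 0L)
})

test_that("mean variants per SMU uses Tukey fences with interpolated quartiles", {
  expect_equal(mean_variants_per_smu(c(1, 2, 2, 3, 40)), 2.0)
  expect_equal(mean_variants_per_smu(c(2, 2, 2)), 2.0)
  expect_equal(mean_variants_per_smu(5), 5.0)
  expect_equal(mean_variants_per_smu(c(1, 2, 2, 3, 40), "none"), 9.6)
  expect_error(mean_variants_per_smu(numeric(0)), "empty")
})

test_that("library specificity separates single-library clusters from shared ones", {
  tab <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
    cluster_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    library = c("LibA", "LibA", "LibA", "LibB", "LibB", "LibB"),
    stringsAsFactors = FALSE)
  out <- library_specificity(tab)
  expect_equal(unname(out$specific_clusters["LibA"]), 1L)
  expect_equal(unname(out$specific_clusters["LibB"]), 1L)
  expect_equal(out$shared_clusters, 1L)
  expect_equal(out$shared_transcripts, 2L)

  zero <- library_specificity(tab[0, ])
  expect_equal(zero$shared_transcripts, 0L)
})
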