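mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], query_len = as.integer(r[[2]]),
               target_id = r[[3]], target_len = as.integer(r[[4]]),
               q_start = as.integer(r[[5]]), q_end = as.integer(r[[6]]),
               t_start = as.integer(r[[7]]), t_end = as.integer(r[[8]]),
               e_value = as.numeric(r[[9]]), stringsAsFactors = FALSE)))
}

test_that("H categories follow reciprocal 70% coverage of transcript and protein", {
  hits <- mk_hits(
    list("q_h2", 100, "p1", 200, 0, 80, 0, 90, 1e-20),    # 0.80 / 0.45
    list("q_h3", 150, "p2", 120, 0, 150, 0, 120, 1e-30),  # 1.00 / 1.00
    list("q_h1", 100, "p3", 100, 0, 30, 0, 30, 1e-10))    # 0.30 / 0.30
  s <- score_hits(hits, queries = c("q_h2", "q_h3", "q_h1", "q_none"))
  expect_equal(s$T, 4L)
  expect_equal(s$H1, 3L)
  expect_equal(s$H2, 2L)
  expect_equal(s$H3, 1L)
  pq <- stats::setNames(s$per_query$category, s$per_query$query_id)
  expect_equal(unname(pq[c("q_h2", "q_h3", "q_h1", "q_none")]),
               c("H2", "H3", "H1", "none"))
})

test_that("the best hit is chosen by e-value, then by coverage product", {
  hits <- mk_hits(
    list("q", 100, "weak", 100, 0, 100, 0, 100, 1e-5),
    list("q", 100, "strong", 100, 0, 30, 0, 30, 1e-40))
  s <- score_hits(hits)
  expect_equal(s$per_query$category, "H1")  # strong e-value, weak coverage
  tie <- mk_hits(
    list("q", 100, "small", 100, 0, 60, 0, 60, 1e-40),
    list("q", 100, "big", 100, 0, 90, 0, 90, 1e-40))
  # the higher coverage product wins the tie: 0.9/0.9 reaches H3, 0.6 would not
  expect_equal(score_hits(tie)$per_query$category, "H3")
})

test_that("zero-length queries are rejected with a warning", {
  hits <- mk_hits(list("ok", 100, "p", 100, 0, 100, 0, 100, 1e-10))
  hits0 <- hits
  hits0$query_len <- 0L
  hits0$q_start <- 0L; hits0$q_end <- 0L
  expect_warning(s <- score_hits(rbind(hits, hits0[0, ])), NA)
  expect_warning(score_hits(hits0, queries = "ok"), "rejected")
})

test_that("H ordering holds on fuzzed hit tables", {
  set.seed(303)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    qlen <- sample(50:500, n, replace = TRUE)
    tlen <- sample(50:500, n, replace = TRUE)
    qa <- vapply(qlen, function(l) sort(sample(0:l, 2)), numeric(2))
    ta <- vapply(tlen, function(l) sort(sample(0:l, 2)), numeric(2))
    ok <- qa[1, ] < qa[2, ] & ta[1, ] < ta[2, ]
    hits <- data.frame(query_id = paste0("q", sample(n, n, replace = TRUE)),
                       query_len = qlen, target_id = "p", target_len = tlen,
                       q_start = qa[1, ], q_end = qa[2, ],
                       t_start = ta[1, ], t_end = ta[2, ],
                       e_value = 10^-sample(5:50, n, replace = TRUE),
                       stringsAsFactors = FALSE)[ok, ]
    if (!nrow(hits)) next
    s <- score_hits(hits, queries = paste0("q", 1:n))
    expect_true(s$H3 <= s$H2 && s$H2 <= s$H1 && s$H1 <= s$T)
  }
})

test_that("mapping rate counts queries passing both thresholds and is monotone", {
  rec <- parse_paf(c(
    simple_paf_record("full", 1000, id_frac = 0.99),
    simple_paf_record("short", 1000, ts = 5000, id_frac = 0.99, cov = 0.93),
    simple_paf_record("noisy", 1000, ts = 10000, id_frac = 0.92)))
  r <- mapping_rate(rec, queries = c("full", "short", "noisy", "missing"))
  expect_equal(r$rate[r$min_cov == 0.98], 1 / 4)   # only "full"
  expect_equal(r$rate[r$min_cov == 0.90], 2 / 4)   # "full" + "short"
  degenerate <- mapping_rate(rec, queries = c("full", "short", "noisy", "missing"),
                             pairs = list(c(0, 0)))
  expect_equal(degenerate$rate, 3 / 4)
  # monotone nonincreasing in each threshold
  grid <- mapping_rate(rec, queries = c("full", "short", "noisy"),
                       pairs = list(c(0.5, 0.9), c(0.9, 0.9), c(0.9, 0.95),
                                    c(0.98, 0.95)))
  expect_true(all(diff(grid$rate) <= 0))
})

test_that("length statistics use the cumulative-half N50 convention", {
  s <- length_stats(c(3, 3, 2, 2, 2))
  expect_equal(s$N50, 3)
  expect_equal(s$mean, 2.4)
  expect_equal(length_stats(500)$N50, 500)
  expect_equal(length_stats(c("ACGT", "ACGTACGT"))$max, 8)
  expect_error(length_stats(numeric(0)), "empty")
})

test_that("GC content excludes ambiguity codes and accepts RNA", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("AAAA"), 0.0)
  expect_equal(gc_content("ACGN"), 2 / 3)
  expect_equal(gc_content("acgu"), 0.5)
  expect_equal(gc_content(c("GGCC", "ATAT")), c(1, 0))
})

test_that("analytic rarefaction matches exact enumeration and saturates", {
  counts <- c(A = 2L, B = 1L)
  r1 <- rarefaction_curve(counts, 1)
  expect_equal(r1$curve$expected_richness, 1.0)
  r2 <- rarefaction_curve(counts, 2)
  expect_equal(r2$curve$expected_richness, 5 / 3)
  r3 <- rarefaction_curve(counts, 3)
  expect_equal(r3$curve$expected_richness, 2.0)
  expect_error(rarefaction_curve(counts, 4), "exceeds")
  # nondecreasing curve
  set.seed(9)
  cv <- stats::setNames(rpois(40, 5), paste0("t", 1:40))
  cv[1] <- 0L
  curve <- rarefaction_curve(cv, c(1, 5, 20, 50, sum(cv)))
  expect_true(all(diff(curve$curve$expected_richness) >= -1e-9))
  expect_lte(max(curve$curve$expected_richness), sum(cv > 0))
})

test_that("analytic rarefaction agrees with vegan and with Monte Carlo", {
  skip_if_not_installed("vegan")
  set.seed(77)
  counts <- stats::setNames(rpois(30, 8) + 1L, paste0("t", 1:30))
  N <- sum(counts)
  sizes <- c(5L, 25L, 100L, as.integer(N))
  mine <- rarefaction_curve(counts, sizes)$curve$expected_richness
  veg <- vapply(sizes, function(n)
    unname(suppressWarnings(vegan::rarefy(t(as.matrix(counts)), n))[1]),
    numeric(1))
  expect_equal(mine, veg, tolerance = 1e-8)

  n_reps <- 3000L
  mc <- rarefaction_curve(counts, sizes, method = "montecarlo",
                          n_reps = n_reps, seed = 5)
  # within 3 SE of the analytic expectation (richness SD is < sqrt(S))
  se <- sqrt(length(counts)) / sqrt(n_reps)
  expect_true(all(abs(mc$curve$expected_richness - mine) <= 3 * se + 1e-9))
})

test_that("transcript subsampling bounds the rarefaction universe deterministically", {
  set.seed(4)
  counts <- stats::setNames(rpois(200, 5) + 1L, paste0("t", 1:200))
  a <- rarefaction_curve(counts, c(10, 50), seed = 42,
                         subsample_transcripts = 50)
  b <- rarefaction_curve(counts, c(10, 50), seed = 42,
                         subsample_transcripts = 50)
  expect_identical(a$curve, b$curve)
  expect_equal(a$n_transcripts, 50L)
  expect_lte(max(a$curve$expected_richness), 50)
})

test_that("hit tables read in both 12- and 14-column dialects", {
  row12 <- paste("q1", "p1", 98.5, 80, 1, 0, 1, 80, 1, 80, 1e-30, 150,
                 sep = "\t")
  f12 <- tempfile(); writeLines(row12, f12)
  lens <- data.frame(id = c("q1", "p1"), length = c(100L, 90L))
  h <- read_hit_table(f12, lengths = lens)
  expect_equal(h$q_start, 0L)
  expect_equal(h$q_end, 80L)
  expect_equal(h$query_len, 100L)
  expect_error(read_hit_table(f12), "sidecar")

  row14 <- paste(row12, 100, 90, sep = "\t")
  f14 <- tempfile(); writeLines(row14, f14)
  expect_equal(read_hit_table(f14), h)
  # reversed target coordinates are normalized
  rev14 <- paste("q1", "p1", 98.5, 80, 1, 0, 1, 80, 80, 1, 1e-30, 150,
                 100, 90, sep = "\t")
  frev <- tempfile(); writeLines(rev14, frev)
  expect_equal(read_hit_table(frev)$t_start, 0L)
})
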