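# Brute-force splice-variant oracle: classifies a candidate exon chain
# against a reference chain by enumerating explicit base-position sets and
# interval relations, independently of the package's coordinate-arithmetic
# classifier. Also enumerates all exon chains on a coordinate grid.

bf_positions <- function(exons) {
  unlist(lapply(seq_len(nrow(exons)),
                function(i) seq.int(exons[i, 1], exons[i, 2] - 1L)))
}

bf_introns <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(list())
  lapply(seq_len(n - 1L),
         function(i) seq.int(exons[i, 2], exons[i + 1L, 1] - 1L))
}

bf_classify <- function(ce, re, strand = "+") {
  cpos <- bf_positions(ce); rpos <- bf_positions(re)
  ci <- bf_introns(ce); ri <- bf_introns(re)
  if (setequal(cpos, rpos))
    return(list(labels = "identical", n_ret = 0L, n_skip = 0L))
  shared <- seq.int(max(min(cpos), min(rpos)), min(max(cpos), max(rpos)))
  ref_exons <- lapply(seq_len(nrow(re)),
                      function(i) seq.int(re[i, 1], re[i, 2] - 1L))

  # candidate introns
  skipping <- logical(length(ci))
  n_skip <- 0L
  c_unexplained <- FALSE
  for (j in seq_along(ci)) {
    if (any(vapply(ri, setequal, logical(1), y = ci[[j]]))) next
    inside <- vapply(ref_exons, function(e) all(e %in% ci[[j]]), logical(1))
    if (any(inside)) {
      skipping[j] <- TRUE
      n_skip <- n_skip + sum(inside)
      next
    }
    if (!any(ci[[j]] %in% shared)) next
    c_unexplained <- TRUE
  }

  # reference introns
  n_ret <- 0L
  r_unexplained <- FALSE
  for (j in seq_along(ri)) {
    if (any(vapply(ci, setequal, logical(1), y = ri[[j]]))) next
    if (all(ri[[j]] %in% cpos)) { n_ret <- n_ret + 1L; next }
    if (!any(ri[[j]] %in% shared)) next
    if (any(vapply(which(skipping), function(k) all(ri[[j]] %in% ci[[k]]),
                   logical(1)))) next
    r_unexplained <- TRUE
  }

  labels <- character(0)
  if (n_ret > 0L) labels <- c(labels, "intron_retention")
  if (n_skip > 0L) labels <- c(labels, "exon_skipping")
  lo_differs <- min(cpos) != min(rpos)
  hi_differs <- max(cpos) != max(rpos)
  if (strand == "+") {
    if (lo_differs) labels <- c(labels, "alt_start")
    if (hi_differs) labels <- c(labels, "premature_stop")
  } else {
    if (hi_differs) labels <- c(labels, "alt_start")
    if (lo_differs) labels <- c(labels, "premature_stop")
  }
  if (c_unexplained || r_unexplained) labels <- c(labels, "complex")
  if (!length(labels)) labels <- "complex"
  list(labels = labels, n_ret = n_ret, n_skip = n_skip)
}

# All exon chains with up to max_exons exons whose boundaries lie on `grid`.
enumerate_chains <- function(grid, max_exons = 3L) {
  chains <- list()
  for (k in seq_len(max_exons)) {
    combos <- utils::combn(length(grid), 2L * k)
    for (j in seq_len(ncol(combos)))
      chains[[length(chains) + 1L]] <-
        matrix(grid[combos[, j]], ncol = 2L, byrow = TRUE)
  }
  chains
}

# Random exon chain for property-style tests.
random_chain_matrix <- function(n_exons, min_w = 1L, max_w = 50L,
                                max_gap = 50L) {
  w <- sample(min_w:max_w, n_exons, replace = TRUE)
  g <- if (n_exons > 1L) sample(1L:max_gap, n_exons - 1L, replace = TRUE)
       else integer(0)
  starts <- cumsum(c(sample(0:20, 1L), w[-n_exons] + g))
  cbind(starts, starts + w)
}
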