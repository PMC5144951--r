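# End-to-end orchestration: simulate a study, align-parse, SMU analysis,
# variant classification, completeness metrics and rarefaction, with
# machine-readable outputs (per-stage TSVs plus summary.json). All
# randomness flows from the single seed in the run configuration.

#' Default run configuration
#'
#' Study conditions of the built-in synthetic comparison: a 1 Mb genome in
#' five scaffolds, 120 multi-isoform genes (10 percent duplicated), the three
#' default technology profiles, SMU thresholds of 100 percent coverage and 90
#' percent identity, completeness threshold 0.70, and mapping-rate pairs
#' 98/98 and 90/98.
#' @export
default_run_config <- function() {
  list(seed = 1L,
       n_scaffolds = 5L, scaffold_length = 200000L, gc_target = 0.42,
       n_genes = 120L, extra_isoforms = 2L,
       isoform_menu = c(identical = 0.2, alt_start = 0.25,
                        premature_stop = 0.25, intron_retention = 0.2,
                        exon_skipping = 0.1),
       dup_fraction = 0.1,
       profiles = default_tech_profiles(),
       min_cov = 1.0, min_id = 0.90,
       hit_cov = 0.70,
       mapping_pairs = list(c(0.98, 0.98), c(0.90, 0.98)),
       rarefaction_points = 8L,
       outdir = NULL)
}

#' Read a run configuration from YAML
#'
#' Fields omitted from the file keep their defaults; profile entries are
#' converted with [tech_profile()].
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), raw)
  if (!is.null(raw$isoform_menu)) cfg$isoform_menu <- unlist(raw$isoform_menu)
  if (!is.null(raw$mapping_pairs))
    cfg$mapping_pairs <- lapply(raw$mapping_pairs, unlist)
  if (!is.null(raw$profiles))
    cfg$profiles <- lapply(stats::setNames(names(raw$profiles),
                                           names(raw$profiles)),
                           function(nm) do.call(tech_profile,
                                                c(list(name = nm),
                                                  raw$profiles[[nm]])))
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$min_cov >= 0, cfg$min_cov <= 1, cfg$min_id >= 0,
            cfg$min_id <= 1, cfg$hit_cov > 0, cfg$hit_cov <= 1)
  techs <- names(cfg$profiles)
  if (is.null(techs) || anyDuplicated(techs) || any(!nzchar(techs)))
    stop("technology labels must be unique and nonempty")
  invisible(cfg)
}

#' Run the full synthetic technology comparison
#'
#' Simulates the study defined by the configuration, then runs every
#' evaluation stage: mapping-status classification and SMU construction from
#' the reference transcript set, per-technology member assignment,
#' longest-variant / coverage-improvement / nonredundant-variant statistics,
#' splice-variant classification of members against SMU references, H1/H2/H3
#' completeness scoring, mapping rates, length and GC statistics, rarefaction
#' curves and library specificity. When `config$outdir` is set, per-stage
#' TSVs, `summary.json` and a run log are written there.
#'
#' @param config A configuration list (see [default_run_config()]) or a path
#'   to a YAML file.
#' @return (Invisibly) a list with `summary` (the machine-readable summary),
#'   `smus`, `smu_table`, `variant_calls` and the simulated inputs.
#' @export
run_comparison <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  # list-valued fields are replaced wholesale, never merged element-wise
  for (field in c("profiles", "mapping_pairs", "isoform_menu"))
    if (!is.null(config[[field]])) cfg[[field]] <- config[[field]]
  cfg <- validate_config(cfg)
  techs <- names(cfg$profiles)

  genome <- generate_genome(cfg$n_scaffolds, cfg$scaffold_length,
                            cfg$gc_target, seed = cfg$seed)
  gm <- generate_gene_models(genome, cfg$n_genes, cfg$isoform_menu,
                             cfg$dup_fraction, seed = cfg$seed + 1L,
                             extra_isoforms = cfg$extra_isoforms,
                             gc_target = cfg$gc_target)
  ref <- simulate_transcript_set(gm, tech_profile("reference"),
                                 seed = cfg$seed + 2L, sampling = "reference")
  sims <- lapply(seq_along(techs), function(i)
    simulate_transcript_set(gm, cfg$profiles[[i]], seed = cfg$seed + 10L + i))
  names(sims) <- techs

  # SMU stage on the reference set
  status <- classify_mapping_status(ref$paf, cfg$min_cov, cfg$min_id,
                                    queries = names(ref$transcripts))
  smus <- build_smus(status, ref$paf, cfg$min_cov, cfg$min_id)
  smus <- assign_members(smus, lapply(sims, `[[`, "paf"),
                         cfg$min_cov, cfg$min_id)
  coverage <- attr(smus, "coverage")
  smu_table <- smu_report(smus)

  # Best-technology statistics over SMUs covered by every technology
  all_tech <- vapply(smus, function(s) all(techs %in% names(s$members)),
                     logical(1))
  best_counts <- stats::setNames(integer(length(techs)), techs)
  unique_best_counts <- stats::setNames(integer(length(techs)), techs)
  improvements <- list()
  nonred <- stats::setNames(vector("list", length(techs)), techs)
  for (s in smus[all_tech]) {
    st <- longest_variant_stats(s)
    for (tech in st$best) best_counts[tech] <- best_counts[tech] + 1L
    if (st$unique_best) {
      unique_best_counts[st$best] <- unique_best_counts[st$best] + 1L
      impr <- coverage_improvement(s)
      for (other in names(impr))
        improvements[[length(improvements) + 1L]] <- data.frame(
          best = st$best, other = other, improvement = unname(impr[other]),
          stringsAsFactors = FALSE)
    }
    for (tech in techs)
      nonred[[tech]] <- c(nonred[[tech]], nonredundant_variants(s, tech))
  }
  improvements <- if (length(improvements)) do.call(rbind, improvements)
    else data.frame(best = character(0), other = character(0),
                    improvement = numeric(0))
  mean_variants <- vapply(nonred, function(v)
    if (length(v)) mean_variants_per_smu(v) else NA_real_, numeric(1))

  # Variant classification of members against their SMU reference chain
  calls <- list()
  per_tech_calls <- stats::setNames(vector("list", length(techs)), techs)
  for (s in smus) {
    for (tech in names(s$members)) {
      mem <- s$members[[tech]]
      for (i in seq_along(mem$chains)) {
        cl <- classify_variant(mem$chains[[i]], s$chain,
                               candidate_id = mem$query_id[i],
                               reference_id = s$reference_transcript)
        calls[[length(calls) + 1L]] <- cl
        per_tech_calls[[tech]] <- c(per_tech_calls[[tech]], list(cl))
      }
    }
  }
  variant_summary <- summarize_variant_types(calls)
  variant_by_tech <- lapply(per_tech_calls, summarize_variant_types)

  # Completeness, mapping rates, sequence statistics, rarefaction
  completeness <- lapply(techs, function(tech) {
    hits <- simulate_protein_hits(sims[[tech]], gm)
    score_hits(hits, cfg$hit_cov, queries = names(sims[[tech]]$transcripts))
  })
  names(completeness) <- techs
  rates <- lapply(techs, function(tech)
    mapping_rate(sims[[tech]]$paf, queries = names(sims[[tech]]$transcripts),
                 pairs = cfg$mapping_pairs))
  names(rates) <- techs
  seq_stats <- lapply(techs, function(tech) {
    s <- sims[[tech]]$transcripts
    c(length_stats(s), list(gc = mean(gc_content(s))))
  })
  names(seq_stats) <- techs
  counts <- lapply(seq_along(techs), function(i)
    simulate_read_counts(names(sims[[i]]$transcripts), cfg$profiles[[i]],
                         seed = cfg$seed + 100L + i))
  names(counts) <- techs
  rarefaction <- lapply(techs, function(tech) {
    cv <- stats::setNames(counts[[tech]]$count, counts[[tech]]$transcript_id)
    N <- sum(cv)
    if (N == 0L) return(NULL)
    sizes <- unique(pmax(1L, round(seq(1L, N,
                                       length.out = cfg$rarefaction_points))))
    rarefaction_curve(cv, sizes, method = "analytic", seed = cfg$seed)
  })
  names(rarefaction) <- techs

  # Library specificity: clusters keyed by source gene, libraries = techs
  cluster_table <- do.call(rbind, lapply(techs, function(tech)
    data.frame(transcript_id = sims[[tech]]$truth$transcript_id,
               cluster_id = sims[[tech]]$truth$gene_id,
               library = tech, stringsAsFactors = FALSE)))
  specificity <- library_specificity(cluster_table)

  summary <- list(
    seed = cfg$seed,
    n_genes = cfg$n_genes,
    technologies = techs,
    mapping_status = as.list(table(status$status)),
    n_smus = length(smus),
    smu_coverage = stats::setNames(
      lapply(seq_len(nrow(coverage)), function(i)
        list(count = coverage$count[i], fraction = coverage$fraction[i])),
      coverage$technology),
    n_smus_all_technologies = sum(all_tech),
    best_counts = as.list(best_counts),
    unique_best_counts = as.list(unique_best_counts),
    mean_improvement = if (nrow(improvements))
      lapply(split(improvements$improvement,
                   paste(improvements$best, improvements$other, sep = "_over_")),
             mean) else list(),
    mean_variants_per_smu = as.list(mean_variants),
    variant_types = c(as.list(variant_summary$counts),
                      list(length_variant = variant_summary$length_variant,
                           total = variant_summary$total)),
    completeness = lapply(completeness, function(x)
      list(T = x$T, H1 = x$H1, H2 = x$H2, H3 = x$H3,
           fractions = as.list(x$fractions))),
    mapping_rates = lapply(rates, function(r)
      stats::setNames(as.list(r$rate),
                      sprintf("cov%.2f_id%.2f", r$min_cov, r$min_id))),
    sequence_stats = seq_stats,
    rarefaction = lapply(rarefaction, function(r)
      if (is.null(r)) NULL else list(sample_sizes = r$curve$sample_size,
                                     expected_richness = r$curve$expected_richness)),
    library_specificity = list(
      specific_clusters = as.list(specificity$specific_clusters),
      shared_transcripts = specificity$shared_transcripts))

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(df, name)
      utils::write.table(df, file.path(cfg$outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    tsv(status, "mapping_status.tsv")
    tsv(smu_table, "smu_table.tsv")
    vt <- do.call(rbind, lapply(techs, function(tech) {
      v <- variant_by_tech[[tech]]
      data.frame(technology = tech, label = names(v$counts),
                 count = as.integer(v$counts), stringsAsFactors = FALSE)
    }))
    tsv(vt, "variant_types.tsv")
    tsv(do.call(rbind, lapply(techs, function(tech)
      cbind(technology = tech, rates[[tech]]))), "mapping_rates.tsv")
    tsv(do.call(rbind, lapply(techs, function(tech)
      data.frame(technology = tech, T = completeness[[tech]]$T,
                 H1 = completeness[[tech]]$H1, H2 = completeness[[tech]]$H2,
                 H3 = completeness[[tech]]$H3))), "completeness.tsv")
    raref_df <- do.call(rbind, lapply(techs, function(tech) {
      r <- rarefaction[[tech]]
      if (is.null(r)) return(NULL)
      cbind(technology = tech, r$curve)
    }))
    if (!is.null(raref_df)) tsv(raref_df, "rarefaction.tsv")
    for (tech in techs) tsv(counts[[tech]], paste0("counts_", tech, ".tsv"))
    jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log <- c(paste("run_comparison at", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             paste("seed:", cfg$seed),
             paste("technologies:", paste(techs, collapse = ", ")),
             paste("n_genes:", cfg$n_genes),
             paste("thresholds: min_cov", cfg$min_cov, "min_id", cfg$min_id,
                   "hit_cov", cfg$hit_cov))
    writeLines(log, file.path(cfg$outdir, "run_log.txt"))
  }

  invisible(list(summary = summary, smus = smus, smu_table = smu_table,
                 variant_calls = calls, status = status, genome = gm$genome,
                 gene_models = gm, reference = ref, simulations = sims,
                 counts = counts, rarefaction = rarefaction))
}
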