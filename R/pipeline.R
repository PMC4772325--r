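#' Simulate a complete synthetic sorted-population study
#'
#' Convenience wrapper chaining [generate_lineage()], [generate_truth()],
#' [generate_markers()], [simulate_sort_counts()], [simulate_pwm_library()],
#' [generate_sequences()] and [generate_timeseries()] with one master seed
#' (stage seeds are derived deterministically from it).
#'
#' @param n_cells Terminal cells in the lineage.
#' @param n_genes Genes.
#' @param n_patterns Tissue-restricted expression patterns (= planted
#'   coexpression clusters, each with a planted regulator motif).
#' @param n_markers Overlapping sort markers.
#' @param noise_sd Per-entry expression noise, log2 units.
#' @param purity Sort purity.
#' @param depth Reads per sample.
#' @param replicates Biological replicates per single-marker sort.
#' @param n_decoys Decoy motifs added to the PWM library.
#' @param upstream_len Promoter length (bp).
#' @param n_timepoints Whole-embryo time-series points.
#' @param fold Member-tissue expression fold.
#' @param seed Master integer seed.
#' @param ... Passed on to [simulate_sort_counts()].
#' @return A list of class `popseq_simulation` with elements `lineage`,
#'   `truth`, `markers`, `study` (counts + scheme), `pwms`, `rules`, `seqs`,
#'   `timeseries`, and `params`.
#' @export
simulate_study <- function(n_cells = 500, n_genes = 2000, n_patterns = 12,
                           n_markers = 14, noise_sd = 0.25, heritable_sd = 0.1,
                           purity = 0.9,
                           depth = 2e6, replicates = 1, n_decoys = n_patterns,
                           upstream_len = 3000, n_timepoints = 21, fold = 16,
                           seed = 1L, ...) {
  seed <- as.integer(seed)
  lineage <- generate_lineage(n_cells, n_tissues = min(n_patterns, n_cells),
                              seed = seed)
  truth <- generate_truth(lineage, n_genes, n_patterns = n_patterns,
                          fold = fold, noise_sd = noise_sd,
                          heritable_sd = heritable_sd, seed = seed + 1L)
  markers <- generate_markers(lineage, n_markers, seed = seed + 2L)
  study <- simulate_sort_counts(truth, markers, purity = purity, depth = depth,
                                replicates = replicates, seed = seed + 3L, ...)
  pwms <- simulate_pwm_library(n_patterns + n_decoys,
                               tfs = truth$patterns$regulator, seed = seed + 4L)
  # scale the planted-distance bands with the promoter length (defaults
  # assume 3 kb promoters)
  bands <- lapply(list(c(50, 900), c(1050, 1900), c(2050, 2900)), function(b) {
    pmax(round(b * upstream_len / 3000), c(10, 60))
  })
  rules <- default_regulation_rules(truth, pwms, distance_bands = bands)
  seqs <- generate_sequences(truth, pwms, rules, upstream_len = upstream_len,
                             seed = seed + 5L)
  ts <- generate_timeseries(truth, n_timepoints = n_timepoints)
  structure(
    list(lineage = lineage, truth = truth, markers = markers, study = study,
         pwms = pwms, rules = rules, seqs = seqs, timeseries = ts,
         params = list(n_cells = n_cells, n_genes = n_genes,
                       n_patterns = n_patterns, n_markers = n_markers,
                       noise_sd = noise_sd, purity = purity, depth = depth,
                       replicates = replicates, upstream_len = upstream_len,
                       fold = fold, seed = seed)),
    class = "popseq_simulation"
  )
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulates a study (or takes one), then runs quantification, enrichment,
#' calling, clustering, specificity, term enrichment against the planted
#' pattern gene sets, motif scanning / presence / cluster enrichment /
#' regulator linking, ChIP enrichment, deconvolution with leave-one-out
#' cross-validation, and the singlet-gating reconstruction check.  All result
#' tables (and the resolved parameters) are written as TSV/YAML under
#' `outdir`; rerunning with the same seed reproduces them byte for byte.
#'
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @param seed Master seed.
#' @param sim An existing `popseq_simulation` (otherwise one is generated
#'   from `...`).
#' @param k Cluster count (defaults to the number of planted patterns).
#' @param call_cutoff Enrichment call cutoff (log2).
#' @param pseudocount Enrichment pseudocount (RPM).
#' @param scan_p PWM scan reporting threshold.
#' @param q_motif Motif-cluster significance threshold on q.
#' @param ... Passed to [simulate_study()] when `sim` is NULL.
#' @return A list of class `popseq_pipeline` with all stage results and a
#'   `summary` tibble of stage-level counts.
#' @export
run_pipeline <- function(outdir = NULL, seed = 1L, sim = NULL, k = NULL,
                         call_cutoff = 2, pseudocount = 3, scan_p = 1e-3,
                         q_motif = 1e-3, ...) {
  if (is.null(sim)) sim <- simulate_study(seed = seed, ...)
  k <- k %||% sim$params$n_patterns
  expr <- compute_rpm(sim$study$counts, sim$study$gene_classes)
  detected <- detect_expressed(expr)
  enr <- enrichment_matrix(expr, sim$study$scheme, pseudocount = pseudocount,
                           include_singlet = TRUE)
  calls <- call_enriched_depleted(enr, cutoff = call_cutoff)
  keep <- intersect(detected$any_sample, rownames(enr$values))
  clust <- suppressWarnings(
    hierarchical_cluster(enr$values[keep, , drop = FALSE], k = k)
  )
  spec <- cluster_specificity(clust, expr, enr)
  truth_sets <- split(sim$truth$genes$gene, sim$truth$genes$pattern)
  cluster_sets <- split(clust$assignment$gene, clust$assignment$cluster)
  terms <- term_enrichment(truth_sets, cluster_sets, universe = keep)
  hits <- scan_pwm_set(sim$seqs, sim$pwms, p_threshold = scan_p)
  presence <- gene_hit_presence(hits)
  motif_res <- motif_cluster_enrichment(presence, clust, universe = keep,
                                        q_threshold = q_motif)
  chip_res <- chip_cluster_enrichment(sim$seqs$peaks, clust, universe = keep,
                                      promoter_len = sim$seqs$upstream_len,
                                      q_threshold = q_motif)
  tf_map <- tibble::tibble(
    tf = vapply(sim$pwms, `[[`, "", "tf"),
    motif = names(sim$pwms)
  )
  links <- suppressWarnings(
    link_regulators(enr, clust, motif_res, tf_map, q_threshold = q_motif)
  )
  membership <- build_membership(sim$markers, sim$study$scheme)
  dbl_pos <- sim$study$scheme$experiments$experiment[
    sim$study$scheme$experiments$sign1 == "+" &
      !is.na(sim$study$scheme$experiments$sign2) &
      sim$study$scheme$experiments$sign2 == "+"
  ]
  fold_values <- 2^enr$values[keep, rownames(membership), drop = FALSE]
  loo <- loo_crossvalidate(fold_values, membership, exclude_from_fit = dbl_pos)
  recon <- reconstruction_check(expr, sim$study$scheme, pseudocount = pseudocount)
  ts_spec <- temporal_specificity(sim$timeseries,
                                  sd_cutoff = sd_cutoff_default(sim$timeseries))
  temporal <- fraction_temporal_profile(enr, ts_spec)

  summary <- tibble::tibble(
    n_genes = nrow(expr$rpm),
    n_samples = ncol(expr$rpm),
    n_detected = length(detected$any_sample),
    n_called_ge1 = calls$summary$n_genes_ge1,
    n_clusters = clust$k,
    n_specific_clusters = sum(spec$specific),
    n_significant_terms = sum(terms$significant),
    n_significant_motif_pairs = sum(motif_res$significant),
    n_candidate_regulators = sum(links$candidate),
    mean_loo_r = mean(loo$r, na.rm = TRUE),
    reconstruction_p = recon$p_improvement
  )
  out <- structure(
    list(sim = sim, expr = expr, detected = detected, enr = enr, calls = calls,
         clustering = clust, specificity = spec, terms = terms, hits = hits,
         motif_enrichment = motif_res, chip_enrichment = chip_res,
         links = links, membership = membership, loo = loo,
         reconstruction = recon, temporal = temporal, summary = summary,
         params = c(sim$params, list(k = k, call_cutoff = call_cutoff,
                                     pseudocount = pseudocount,
                                     scan_p = scan_p, q_motif = q_motif))),
    class = "popseq_pipeline"
  )
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

# half the time-series span: flags genes confined to roughly one
# developmental half as time-specific
sd_cutoff_default <- function(ts) diff(range(ts$time)) / 4

write_pipeline <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_matrix_tsv(x$sim$study$counts, p("counts.tsv"))
  write_gene_classes(x$sim$study$gene_classes, p("gene_classes.tsv"))
  write_matrix_tsv(round(x$expr$rpm, 4), p("rpm.tsv"))
  write_matrix_tsv(round(x$enr$values, 4), p("enrichment.tsv"))
  readr::write_tsv(x$calls$calls, p("calls.tsv"))
  readr::write_tsv(x$clustering$assignment, p("clusters.tsv"))
  write_matrix_tsv(round(x$clustering$centroids, 4), p("centroids.tsv"))
  readr::write_tsv(x$specificity, p("cluster_stats.tsv"))
  readr::write_tsv(x$terms, p("term_enrichment.tsv"))
  readr::write_tsv(x$motif_enrichment, p("motif_enrichment.tsv"))
  readr::write_tsv(x$chip_enrichment, p("chip_enrichment.tsv"))
  readr::write_tsv(x$links, p("regulator_links.tsv"))
  write_matrix_tsv(round(x$membership, 6), p("membership.tsv"))
  readr::write_tsv(x$loo, p("loo.tsv"))
  readr::write_tsv(x$summary, p("summary.tsv"))
  write_scheme_yaml(x$sim$study$scheme, p("scheme.yaml"))
  write_lineage_tsv(x$sim$lineage, p("lineage.tsv"))
  yaml::write_yaml(x$params, p("config.yaml"))
  invisible(outdir)
}

#' @export
print.popseq_pipeline <- function(x, ...) {
  cat("popseq pipeline run\n")
  print(as.data.frame(x$summary))
  invisible(x)
}
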