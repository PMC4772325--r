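#' Upper-tail hypergeometric test
#'
#' Exact probability of drawing at least `k` annotated genes when `n` genes
#' are drawn without replacement from a universe of `N` genes of which `K`
#' are annotated: `P[X >= k]`.
#'
#' @param k Observed overlap (vectorized).
#' @param K Annotated-set size.
#' @param n Number of draws (target-set size).
#' @param N Universe size.
#' @return Numeric p-value(s).
#' @examples
#' hypergeom_test(4, 5, 4, 10)  # 5 / choose(10, 4)
#' @export
hypergeom_test <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | k > pmin(K, n) | K > N | n > N
  if (any(bad)) stop_invalid("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Term enrichment of target gene sets by hypergeometric test
#'
#' One upper-tail hypergeometric test per (term, target) pair over a common
#' gene universe, with BH correction across all tests in the call (one family
#' per invocation).  Fold = (k/n) / (K/N).
#'
#' @param sets Named list: term id -> character vector of gene ids.
#' @param targets Named list: target id (cluster or fraction) -> gene set.
#' @param universe Character vector of universe gene ids; targets must be
#'   subsets.  Sets are intersected with the universe.
#' @param fdr Significance threshold on q.
#' @return Tibble (`term`, `target`, `k`, `K`, `n`, `N`, `fold`, `p`, `q`,
#'   `significant`).
#' @export
term_enrichment <- function(sets, targets, universe, fdr = 0.05) {
  if (length(universe) == 0) stop_invalid("empty universe")
  if (!all(unlist(targets) %in% universe)) {
    stop_invalid("targets must be subsets of the universe")
  }
  sets <- lapply(sets, intersect, universe)
  N <- length(universe)
  grid <- tidyr::expand_grid(term = names(sets), target = names(targets))
  res <- purrr::pmap_dfr(grid, function(term, target) {
    K <- length(sets[[term]])
    n <- length(targets[[target]])
    k <- length(intersect(sets[[term]], targets[[target]]))
    tibble::tibble(
      term = term, target = target, k = k, K = K, n = n, N = N,
      fold = if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
      p = if (K > 0 && n > 0) hypergeom_test(k, K, n, N) else 1
    )
  })
  res$q <- bh_fdr(res$p)
  res$significant <- res$q < fdr
  res
}

#' Temporal specificity of genes from a whole-embryo time series
#'
#' Computes, per gene, the weighted mean and SD of time, treating a
#' nonnegative transform of the temporal profile as weights over timepoints;
#' genes with SD below `sd_cutoff` are flagged time-specific.  The default
#' `"zscore"` weighting uses the positive part of the per-gene standardized
#' log profile - the times at which the gene is *enriched* relative to its own
#' baseline - so a tissue-restricted gene is not diluted by the embryo-wide
#' expression it shares with every gene.  `"standardized"` (divide by the
#' per-gene max) and `"raw"` weight by expression itself; all three are
#' invariant to rescaling a profile by a positive constant.
#'
#' @param ts A `popseq_timeseries` (or list with `values` genes x timepoints
#'   and `time`).
#' @param sd_cutoff SD cutoff in minutes below which a gene is time-specific.
#' @param weights `"zscore"`, `"standardized"`, or `"raw"`.
#' @return Tibble (`gene`, `mean_time`, `sd_time`, `time_specific`).  Genes
#'   with no positive weight (all-zero or constant profiles) get `NA`
#'   statistics and are unflagged.
#' @export
temporal_specificity <- function(ts, sd_cutoff,
                                 weights = c("zscore", "standardized", "raw")) {
  weights <- match.arg(weights)
  v <- ts$values
  t <- ts$time
  if (any(v < 0)) stop_invalid("temporal profiles must be nonnegative")
  if (weights == "zscore") {
    lv <- log2(1 + v)
    mu <- rowMeans(lv)
    sg <- apply(lv, 1, sd)
    v <- pmax((lv - mu) / ifelse(sg > 0, sg, 1), 0)
    v[sg == 0, ] <- 0
  } else if (weights == "standardized") {
    mx <- apply(v, 1, max)
    v <- v / ifelse(mx > 0, mx, 1)
  }
  tot <- unname(rowSums(v))
  mean_time <- ifelse(tot > 0, as.vector(v %*% t) / tot, NA_real_)
  ex2 <- ifelse(tot > 0, as.vector(v %*% t^2) / tot, NA_real_)
  sd_time <- sqrt(pmax(ex2 - mean_time^2, 0))
  tibble::tibble(
    gene = rownames(v),
    mean_time = mean_time,
    sd_time = sd_time,
    time_specific = !is.na(sd_time) & sd_time < sd_cutoff
  )
}

#' Mean enrichment of time-specific genes by temporal bin
#'
#' Bins time-specific genes by their mean expression time into `n_bins`
#' equal-width bins and reports each experiment's mean enrichment per bin,
#' plus a Spearman rank trend test of bin index against mean enrichment
#' (positive trend = the fraction enriches late genes).
#'
#' @param enr A `popseq_enrichment` or matrix.
#' @param temporal Output of [temporal_specificity()].
#' @param n_bins Number of equal-width time bins.
#' @return A list: `profile` (tibble `experiment`, `bin`, `mid_time`,
#'   `mean_enrichment`, `n_genes`) and `trend` (tibble `experiment`, `rho`,
#'   `p`; `NA` when fewer than two bins).
#' @export
fraction_temporal_profile <- function(enr, temporal, n_bins = 5) {
  v <- enr_matrix(enr)
  flagged <- temporal[temporal$time_specific & temporal$gene %in% rownames(v), ]
  if (nrow(flagged) == 0) stop_invalid("no flagged time-specific genes")
  rng <- range(flagged$mean_time)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  gene_bin <- cut(flagged$mean_time, breaks, include.lowest = TRUE, labels = FALSE)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  bin_genes <- lapply(seq_len(n_bins), function(b) flagged$gene[gene_bin == b])
  profile <- purrr::map_dfr(colnames(v), function(e) {
    tibble::tibble(
      experiment = e, bin = seq_len(n_bins), mid_time = mids,
      mean_enrichment = vapply(bin_genes, function(g) {
        if (length(g) == 0) NA_real_ else mean(v[g, e])
      }, 0),
      n_genes = lengths(bin_genes)
    )
  })
  trend <- profile |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(
      rho = if (sum(!is.na(.data$mean_enrichment)) >= 2 &&
                sd(.data$mean_enrichment, na.rm = TRUE) > 0) {
        cor(.data$bin, .data$mean_enrichment, method = "spearman",
            use = "complete.obs")
      } else NA_real_,
      p = if (sum(!is.na(.data$mean_enrichment)) >= 3 &&
              sd(.data$mean_enrichment, na.rm = TRUE) > 0) {
        suppressWarnings(cor.test(.data$bin, .data$mean_enrichment,
                                  method = "spearman")$p.value)
      } else NA_real_,
      .groups = "drop"
    )
  list(profile = profile, trend = trend)
}
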