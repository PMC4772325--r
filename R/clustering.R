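#' Correlation distance between two enrichment profiles
#'
#' `1 - Pearson r`, in `[0, 2]`.
#'
#' @param a,b Numeric vectors of equal length >= 2 with nonzero variance.
#' @return Distance scalar.
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) {
    stop_invalid("profiles must have equal length >= 2")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    abort("undefined-distance: zero-variance profile",
          class = "popseq_undefined_distance")
  }
  1 - cor(a, b)
}

#' Hierarchical coexpression clustering of enrichment profiles
#'
#' Agglomerative complete-linkage clustering on correlation distance
#' (1 - Pearson r) between per-gene enrichment profiles, cut to `k` clusters
#' or at height `h`.  Genes with zero-variance (all-equal) profiles have no
#' defined correlation and are excluded with a warning; they are
#' non-differential by construction and reported in `excluded`.
#'
#' @param enr A `popseq_enrichment` or genes x experiments matrix.
#' @param k Number of clusters (exactly one of `k`, `h`).
#' @param h Cut height in correlation-distance units.
#' @return A list of class `popseq_clustering`: `assignment` (tibble `gene`,
#'   `cluster`), `clusters` (named integer vector), `centroids` (clusters x
#'   experiments mean enrichment), `hclust`, `sizes`, `excluded`, `k`, `h`.
#' @export
hierarchical_cluster <- function(enr, k = NULL, h = NULL) {
  v <- enr_matrix(enr)
  if (is.null(k) == is.null(h)) stop_invalid("give exactly one of `k` or `h`")
  vars <- apply(v, 1, sd)
  excluded <- rownames(v)[vars == 0]
  if (length(excluded) > 0) {
    warn(sprintf("%d zero-variance profile(s) excluded from clustering",
                 length(excluded)))
    v <- v[vars > 0, , drop = FALSE]
  }
  if (nrow(v) < 2) stop_invalid("need >= 2 genes with non-constant profiles")
  if (!is.null(k) && k > nrow(v)) {
    stop_invalid("`k` (%d) exceeds the number of clusterable genes (%d)", k, nrow(v))
  }
  d <- as.dist(1 - cor(t(v)))
  hc <- hclust(d, method = "complete")
  cl <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = h)
  cl <- setNames(as.integer(cl), rownames(v))
  centroids <- rowsum(v, cl) / as.vector(table(cl))
  rownames(centroids) <- sprintf("C%03d", as.integer(rownames(centroids)))
  structure(
    list(
      assignment = tibble::tibble(gene = names(cl),
                                  cluster = sprintf("C%03d", cl)),
      clusters = setNames(sprintf("C%03d", cl), names(cl)),
      centroids = centroids,
      hclust = hc,
      sizes = table(sprintf("C%03d", cl)),
      excluded = excluded,
      k = if (!is.null(k)) as.integer(k) else length(unique(cl)),
      h = h
    ),
    class = "popseq_clustering"
  )
}

#' @export
print.popseq_clustering <- function(x, ...) {
  cat(sprintf("popseq clustering: %d genes in %d clusters (complete linkage, correlation distance)\n",
              nrow(x$assignment), x$k))
  invisible(x)
}

#' Choose the tree cut that maximizes regulator detection
#'
#' Scores each candidate cluster count by the number of motif-cluster pairs
#' significant at `q_threshold` (via [motif_cluster_enrichment()] over the
#' presence table and cutoff grid) and returns the best clustering; ties go to
#' the smallest cluster count.
#'
#' @param enr A `popseq_enrichment` or matrix.
#' @param candidate_k Integer vector of candidate cluster counts.
#' @param presence Output of [gene_hit_presence()].
#' @param universe Gene universe for the hypergeometric tests.
#' @param q_threshold Significance threshold on BH q-values.
#' @return A list: `clustering` (the chosen `popseq_clustering`) and `scores`
#'   (tibble `k`, `n_significant`).
#' @export
select_cut <- function(enr, candidate_k, presence, universe, q_threshold = 1e-3) {
  if (length(candidate_k) < 1) stop_invalid("empty candidate list")
  candidate_k <- sort(unique(as.integer(candidate_k)))
  fits <- lapply(candidate_k, function(k) hierarchical_cluster(enr, k = k))
  scores <- vapply(fits, function(f) {
    res <- motif_cluster_enrichment(presence, f, universe,
                                    q_threshold = q_threshold)
    sum(res$q < q_threshold, na.rm = TRUE)
  }, 0)
  best <- which(scores == max(scores))[1]      # candidates sorted: ties -> smallest k
  list(
    clustering = fits[[best]],
    scores = tibble::tibble(k = candidate_k, n_significant = scores)
  )
}

#' Per-cluster specificity statistics and flags
#'
#' For each cluster: the mean over member genes of log2(1 + max-over-samples
#' RPM) and the mean absolute enrichment over genes x experiments.  The
#' specificity flag requires both to be strictly above their cutoffs,
#' separating tissue-specific clusters from low-expression or non-differential
#' ones.
#'
#' @param clustering A `popseq_clustering`.
#' @param expr A `popseq_expression` or RPM matrix.
#' @param enr A `popseq_enrichment` or matrix.
#' @param abs_enr_cutoff Cutoff on mean |enrichment| (default 0.2).
#' @param log_expr_cutoff Cutoff on mean log2(1 + max RPM) (default 4).
#' @return Tibble (`cluster`, `size`, `mean_log_expr`, `mean_abs_enr`,
#'   `specific`).
#' @export
cluster_specificity <- function(clustering, expr, enr,
                                abs_enr_cutoff = 0.2, log_expr_cutoff = 4) {
  stopifnot(inherits(clustering, "popseq_clustering"))
  rpm <- rpm_matrix(expr)
  v <- enr_matrix(enr)
  cl <- clustering$clusters
  gene_log_expr <- log2(1 + apply(rpm[names(cl), , drop = FALSE], 1, max))
  gene_abs_enr <- rowMeans(abs(v[names(cl), , drop = FALSE]))
  tibble::tibble(
    cluster = names(clustering$sizes),
    size = as.integer(clustering$sizes),
    mean_log_expr = as.vector(tapply(gene_log_expr, cl, mean)[names(clustering$sizes)]),
    mean_abs_enr = as.vector(tapply(gene_abs_enr, cl, mean)[names(clustering$sizes)]),
  ) |>
    dplyr::mutate(specific = .data$mean_log_expr > log_expr_cutoff &
                    .data$mean_abs_enr > abs_enr_cutoff)
}

#' Rank genes by enrichment-profile similarity to a query gene
#'
#' All other genes ranked by decreasing Pearson correlation with the query's
#' enrichment profile; ties broken by gene id.
#'
#' @param enr A `popseq_enrichment` or matrix.
#' @param gene Query gene id.
#' @param top_n Number of genes to return (the full ranking if larger).
#' @return Tibble (`gene`, `r`).
#' @export
coexpression_query <- function(enr, gene, top_n = 50) {
  v <- enr_matrix(enr)
  if (!gene %in% rownames(v)) {
    abort(sprintf("not-found: gene '%s' absent from enrichment matrix", gene),
          class = "popseq_not_found")
  }
  q <- v[gene, ]
  if (sd(q) == 0) stop_invalid("query gene has a constant profile")
  keep <- setdiff(rownames(v), gene)
  vv <- v[keep, , drop = FALSE]
  ok <- apply(vv, 1, sd) > 0
  r <- as.vector(cor(q, t(vv[ok, , drop = FALSE])))
  out <- tibble::tibble(gene = keep[ok], r = r)
  out <- out[order(-out$r, out$gene), ]
  head(out, min(top_n, nrow(out)))
}
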