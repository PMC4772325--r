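#' Concordance between fraction cell composition and gene-set enrichment
#'
#' For every (tissue, experiment) pair: x = log2 of the pseudocounted ratio of
#' the tissue's cell proportion in the fraction to its overall proportion
#' (cell-level tissue enrichment, from the membership matrix); y = mean
#' enrichment of the tissue's marker gene set in the experiment.  If sorting
#' worked, fractions capturing a tissue's cells should also enrich that
#' tissue's genes, giving a positive correlation over all points.
#'
#' @param membership Experiments x cells membership matrix
#'   ([build_membership()]); rows sum to 1.
#' @param tissue_sets Named list: tissue -> gene id set.
#' @param enr A `popseq_enrichment` or matrix (columns = experiments of the
#'   membership rows).
#' @param cell_tissues Named character vector cell id -> tissue.
#' @param pseudo Pseudo-proportion added to both proportions before the log
#'   ratio.
#' @return A list: `points` (tibble `tissue`, `experiment`, `x`, `y`), `r`,
#'   `p` (Pearson test; `NA` with fewer than 3 points).
#' @export
tissue_composition_concordance <- function(membership, tissue_sets, enr,
                                           cell_tissues, pseudo = 0.01) {
  v <- enr_matrix(enr)
  exps <- intersect(rownames(membership), colnames(v))
  if (length(exps) == 0) stop_invalid("no shared experiments")
  tissues <- intersect(names(tissue_sets), unique(cell_tissues[colnames(membership)]))
  tissues <- tissues[vapply(tissues, function(t) {
    sum(cell_tissues[colnames(membership)] == t, na.rm = TRUE) > 0
  }, TRUE)]
  if (length(tissues) == 0) stop_invalid("no usable tissues")
  overall <- vapply(tissues, function(t) {
    mean(cell_tissues[colnames(membership)] == t, na.rm = TRUE)
  }, 0)
  points <- purrr::map_dfr(tissues, function(t) {
    in_t <- cell_tissues[colnames(membership)] == t
    purrr::map_dfr(exps, function(e) {
      prop <- sum(membership[e, in_t]) / sum(membership[e, ])
      genes <- intersect(tissue_sets[[t]], rownames(v))
      tibble::tibble(
        tissue = t, experiment = e,
        x = log2((prop + pseudo) / (overall[[t]] + pseudo)),
        y = if (length(genes) > 0) mean(v[genes, e]) else NA_real_
      )
    })
  })
  ok <- stats::complete.cases(points[, c("x", "y")])
  r <- p <- NA_real_
  if (sum(ok) >= 3 && sd(points$x[ok]) > 0 && sd(points$y[ok]) > 0) {
    ct <- cor.test(points$x[ok], points$y[ok])
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(points = points, r = r, p = p)
}

#' Co-clustering enrichment of a gene-pair network
#'
#' How often do two genes linked in an external network fall in the same
#' coexpression cluster, compared with random relabelings?  Fold = observed
#' co-clustered edge count over the mean count under `n_shuffles` shuffles of
#' the cluster labels; empirical p = (1 + #shuffles >= observed) /
#' (1 + n_shuffles).
#'
#' @param edges Two-column data frame / tibble of gene pairs.
#' @param clustering A `popseq_clustering`.
#' @param n_shuffles Number of label shuffles.
#' @param seed Integer seed.
#' @return A list: `observed`, `expected` (shuffle mean), `fold`, `p`,
#'   `n_edges` (usable edges), `analytic_expected` (closed-form expected
#'   co-cluster count for a random pair).
#' @export
network_coclustering <- function(edges, clustering, n_shuffles = 1000, seed = 1L) {
  stopifnot(inherits(clustering, "popseq_clustering"))
  cl <- clustering$clusters
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  keep <- a %in% names(cl) & b %in% names(cl) & a != b
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) stop_invalid("no usable edges (both endpoints clustered)")
  ia <- match(a, names(cl)); ib <- match(b, names(cl))
  observed <- sum(cl[ia] == cl[ib])
  sizes <- as.integer(clustering$sizes)
  G <- length(cl)
  analytic <- length(a) * sum(sizes * (sizes - 1)) / (G * (G - 1))
  shuffled <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      perm <- cl[sample.int(G)]
      sum(perm[ia] == perm[ib])
    }, 0L)
  })
  expected <- mean(shuffled)
  list(
    observed = observed, expected = expected,
    fold = observed / max(expected, .Machine$double.eps),
    p = (1 + sum(shuffled >= observed)) / (1 + n_shuffles),
    n_edges = length(a),
    analytic_expected = analytic,
    shuffle_sd = sd(shuffled)
  )
}

#' Concordance of motif-cluster links with yeast one-hybrid interactions
#'
#' Of the (TF, cluster) pairs called by motif enrichment, what proportion is
#' supported by a Y1H interaction with that TF as prey and a bait gene inside
#' the cluster?  The baseline shuffles the TF labels of the motif-cluster
#' pairs.
#'
#' @param y1h_edges Two-column data frame: TF id, bait (promoter) gene id.
#' @param motif_cluster_hits Two-column data frame: TF id, cluster id.
#' @param clustering A `popseq_clustering`.
#' @param n_shuffles Number of TF-label shuffles.
#' @param seed Integer seed.
#' @return A list: `proportion_supported`, `baseline` (shuffle mean),
#'   `fold`, `n_pairs`.
#' @export
y1h_concordance <- function(y1h_edges, motif_cluster_hits, clustering,
                            n_shuffles = 1000, seed = 1L) {
  stopifnot(inherits(clustering, "popseq_clustering"))
  if (nrow(motif_cluster_hits) == 0) stop_invalid("no motif-cluster pairs")
  cl <- clustering$clusters
  baits_by_tf <- split(as.character(y1h_edges[[2]]), as.character(y1h_edges[[1]]))
  tfs <- as.character(motif_cluster_hits[[1]])
  clusters <- as.character(motif_cluster_hits[[2]])
  supported <- function(tfv) {
    vapply(seq_along(tfv), function(i) {
      baits <- baits_by_tf[[tfv[i]]]
      !is.null(baits) && any(cl[intersect(baits, names(cl))] == clusters[i])
    }, TRUE)
  }
  prop <- mean(supported(tfs))
  baseline <- with_seed(seed, {
    mean(vapply(seq_len(n_shuffles), function(i) {
      mean(supported(sample(tfs)))
    }, 0))
  })
  list(
    proportion_supported = prop, baseline = baseline,
    fold = prop / max(baseline, .Machine$double.eps),
    n_pairs = length(tfs)
  )
}

#' Expression correlation of noncoding RNAs with their genomic neighbors
#'
#' For each lincRNA, the nearest coding gene by interval-midpoint distance
#' (ties toward the smaller start coordinate); for each ancRNA, the coding
#' gene it overlaps on the opposite strand; for coding genes, the adjacent
#' (nearest other) coding gene.  Correlation is Pearson r of log(1 + RPM)
#' profiles across samples; the per-class summary reports the mean r and a
#' one-sample Wilcoxon signed-rank p against zero.
#'
#' @param expr A `popseq_expression` or RPM matrix.
#' @param coords Tibble with `gene`, `chrom`, `start`, `end`, `strand`.
#' @param classes Named character vector gene -> class.
#' @param include_coding Also compute adjacent coding-coding pairs (can be
#'   slow for large gene sets).
#' @return A list: `pairs` (tibble `gene`, `neighbor`, `class`, `r`),
#'   `summary` (tibble `class`, `n`, `mean_r`, `p`), `n_excluded` (pairs
#'   dropped for constant profiles).
#' @export
neighbor_correlation <- function(expr, coords, classes, include_coding = TRUE) {
  rpm <- log1p(rpm_matrix(expr))
  coords <- coords[coords$gene %in% rownames(rpm), , drop = FALSE]
  cls <- classes[coords$gene]
  mid <- (coords$start + coords$end) / 2
  coding <- which(cls == "coding")
  if (length(coding) == 0) stop_invalid("no coding genes in coordinates")
  nearest_coding <- function(i, exclude = i) {
    cand <- setdiff(coding, exclude)
    d <- abs(mid[cand] - mid[i])
    cand[order(d, coords$start[cand])][1]
  }
  rows <- list()
  for (i in which(cls == "lincRNA")) {
    rows[[length(rows) + 1L]] <- c(i, nearest_coding(i), "lincRNA")
  }
  for (i in which(cls == "ancRNA")) {
    ov <- coding[coords$chrom[coding] == coords$chrom[i] &
                   coords$start[coding] < coords$end[i] &
                   coords$end[coding] > coords$start[i] &
                   coords$strand[coding] != coords$strand[i]]
    if (length(ov) > 0) rows[[length(rows) + 1L]] <- c(i, ov[1], "ancRNA")
  }
  if (include_coding) {
    for (i in coding) {
      rows[[length(rows) + 1L]] <- c(i, nearest_coding(i), "coding")
    }
  }
  if (length(rows) == 0) stop_invalid("no neighbor pairs found")
  rows <- do.call(rbind, rows)
  g <- coords$gene[as.integer(rows[, 1])]
  nb <- coords$gene[as.integer(rows[, 2])]
  const <- apply(rpm[g, , drop = FALSE], 1, sd) == 0 |
    apply(rpm[nb, , drop = FALSE], 1, sd) == 0
  r <- rep(NA_real_, length(g))
  r[!const] <- vapply(which(!const), function(j) cor(rpm[g[j], ], rpm[nb[j], ]), 0)
  pairs <- tibble::tibble(gene = g, neighbor = nb, class = rows[, 3], r = r)
  summary <- pairs |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      n = dplyr::n(), mean_r = mean(.data$r),
      p = if (dplyr::n() >= 3 && sd(.data$r) > 0) {
        suppressWarnings(wilcox.test(.data$r, mu = 0)$p.value)
      } else NA_real_,
      .groups = "drop"
    )
  list(pairs = pairs, summary = summary, n_excluded = sum(const))
}
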