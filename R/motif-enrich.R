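#' Collapse redundant motifs by matrix similarity
#'
#' Pairwise similarity between two PWMs is the maximum, over ungapped offsets
#' and both orientations, of the mean per-aligned-column Pearson correlation
#' of the probability columns (at least `min_overlap` aligned columns).
#' Motifs are single-linkage clustered at PCC distance (1 - similarity) below
#' `pcc_distance_threshold`, and the lexicographically first motif id of each
#' cluster is kept as representative.
#'
#' @param pwms A `popseq_pwm_list`.
#' @param pcc_distance_threshold Distance below which motifs are merged
#'   (default 0.01).
#' @param min_overlap Minimum aligned columns when sliding.
#' @return A list: `representatives` (a `popseq_pwm_list`), `mapping` (tibble
#'   `motif`, `representative`).
#' @export
motif_similarity_dedup <- function(pwms, pcc_distance_threshold = 0.01,
                                   min_overlap = 4) {
  n <- length(pwms)
  if (n < 1) stop_invalid("need at least one motif")
  ids <- names(pwms)
  rep_id <- ids
  if (n > 1) {
    # union-find over pairs within the distance threshold (single linkage)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        s <- pwm_similarity(pwms[[i]], pwms[[j]], min_overlap)
        if (1 - s < pcc_distance_threshold) {
          parent[max(find(i), find(j))] <- min(find(i), find(j))
        }
      }
    }
    comp <- vapply(seq_len(n), find, 0L)
    rep_id <- vapply(comp, function(c) min(ids[comp == c]), "")
  }
  reps <- pwms[unique(rep_id)]
  class(reps) <- "popseq_pwm_list"
  list(
    representatives = reps,
    mapping = tibble::tibble(motif = ids, representative = rep_id)
  )
}

#' Similarity of two PWMs (max mean column correlation over alignments)
#'
#' @param a,b `popseq_pwm` objects.
#' @param min_overlap Minimum aligned columns.
#' @return Similarity in `[-1, 1]`.
#' @export
pwm_similarity <- function(a, b, min_overlap = 4) {
  ma <- a$matrix
  best <- -Inf
  for (mb in list(b$matrix, pwm_revcomp(b$matrix))) {
    La <- ncol(ma); Lb <- ncol(mb)
    for (off in (-Lb + min_overlap):(La - min_overlap)) {
      ia <- max(1, off + 1):min(La, off + Lb)
      ib <- ia - off
      cc <- vapply(seq_along(ia), function(t) {
        x <- ma[, ia[t]]; y <- mb[, ib[t]]
        if (sd(x) == 0 || sd(y) == 0) return(0)
        cor(x, y)
      }, 0)
      best <- max(best, mean(cc))
    }
  }
  best
}

#' Default cutoff grid for motif/ChIP enrichment
#'
#' Distances upstream of the TSS (bp), conservation minima, and score minima
#' in -10*log10(p) units.
#'
#' @param distance,conservation,score Grid axis values (ascending).
#' @return A list of class `popseq_grid`.
#' @export
default_grid <- function(distance = c(1000, 2000, 3000),
                         conservation = c(0, 0.5, 0.7, 0.9),
                         score = c(30, 35, 40)) {
  if (any(lengths(list(distance, conservation, score)) == 0)) {
    stop_invalid("grid axes must be nonempty")
  }
  structure(list(distance = sort(distance), conservation = sort(conservation),
                 score = sort(score)),
            class = "popseq_grid")
}

#' Per-gene motif presence across a cutoff grid
#'
#' A (motif, gene) pair is present in grid cell (D, C, S) when some hit has
#' distance <= D, conservation >= C, and -10*log10(p) >= S.  Presence is
#' therefore antitone in each cutoff: a hit passing a stricter cell passes all
#' looser cells.
#'
#' @param hits A `popseq_hits` tibble from [scan_pwm_set()].
#' @param grid A `popseq_grid`.
#' @return Tibble (`motif`, `gene`, `distance_cut`, `conservation_cut`,
#'   `score_cut`) with one row per present (motif, gene, cell).
#' @export
gene_hit_presence <- function(hits, grid = default_grid()) {
  stopifnot(inherits(grid, "popseq_grid"))
  hs <- -10 * log10(pmax(hits$p, .Machine$double.xmin))
  cons <- ifelse(is.na(hits$conservation), 0, hits$conservation)
  cells <- tidyr::expand_grid(
    distance_cut = grid$distance,
    conservation_cut = grid$conservation,
    score_cut = grid$score
  )
  purrr::pmap_dfr(cells, function(distance_cut, conservation_cut, score_cut) {
    pass <- hits$distance <= distance_cut & cons >= conservation_cut &
      hs >= score_cut
    if (!any(pass)) return(NULL)
    dplyr::distinct(tibble::tibble(
      motif = hits$motif[pass], gene = hits$gene[pass],
      distance_cut = distance_cut, conservation_cut = conservation_cut,
      score_cut = score_cut
    ))
  })
}

#' Motif-cluster hypergeometric enrichment over the cutoff grid
#'
#' For every (motif, cluster, grid cell): upper-tail hypergeometric test of
#' the overlap between the cluster's genes and the genes where the motif is
#' present at that cell, over the detected-gene universe.  BH correction is
#' applied jointly across all motif x cluster x cell tests; for each
#' motif-cluster pair the minimum-p cell is reported.
#'
#' @param presence Output of [gene_hit_presence()].
#' @param clustering A `popseq_clustering`.
#' @param universe Character vector of universe gene ids.
#' @param q_threshold Significance threshold on q (the headline analysis uses
#'   a very strict 1e-10 on deep data; recovery simulations use 1e-3).
#' @return Tibble (`motif`, `cluster`, `distance_cut`, `conservation_cut`,
#'   `score_cut`, `k`, `K`, `n`, `N`, `fold`, `p`, `q`, `significant`), one
#'   row per motif-cluster pair (its best cell), with the full per-cell table
#'   in attribute `"all_cells"`.
#' @export
motif_cluster_enrichment <- function(presence, clustering, universe,
                                     q_threshold = 1e-10) {
  stopifnot(inherits(clustering, "popseq_clustering"))
  if (length(universe) == 0) stop_invalid("empty universe")
  cl <- clustering$clusters
  cl <- cl[names(cl) %in% universe]
  if (length(cl) == 0) stop_invalid("clustering and universe do not overlap")
  N <- length(universe)
  cluster_sets <- split(names(cl), cl)
  pres <- presence[presence$gene %in% universe, , drop = FALSE]
  if (nrow(pres) == 0) {
    empty <- tibble::tibble(
      motif = character(), cluster = character(), distance_cut = double(),
      conservation_cut = double(), score_cut = double(), k = integer(),
      K = integer(), n = integer(), N = integer(), fold = double(),
      p = double(), q = double(), significant = logical()
    )
    attr(empty, "all_cells") <- empty
    return(empty)
  }
  key <- paste(pres$motif, pres$distance_cut, pres$conservation_cut,
               pres$score_cut, sep = "\r")
  fg_sets <- split(pres$gene, key)
  meta <- pres[!duplicated(key), c("motif", "distance_cut", "conservation_cut",
                                   "score_cut")]
  meta_key <- key[!duplicated(key)]
  cl_names <- names(cluster_sets)
  n_cl <- lengths(cluster_sets)
  nm <- nrow(meta)
  # overlap counts k for every (foreground set, cluster) at once
  kmat <- t(vapply(meta_key, function(mk) {
    tab <- table(factor(cl[fg_sets[[mk]]], levels = cl_names))
    as.integer(tab)
  }, integer(length(cl_names))))
  Kvec <- lengths(fg_sets)[meta_key]
  all_rows <- tibble::tibble(
    motif = rep(meta$motif, each = length(cl_names)),
    cluster = rep(cl_names, nm),
    distance_cut = rep(meta$distance_cut, each = length(cl_names)),
    conservation_cut = rep(meta$conservation_cut, each = length(cl_names)),
    score_cut = rep(meta$score_cut, each = length(cl_names)),
    k = as.integer(t(kmat)),
    K = rep(unname(Kvec), each = length(cl_names)),
    n = rep(unname(n_cl), nm),
    N = N
  )
  all_rows$fold <- (all_rows$k / all_rows$n) / (all_rows$K / all_rows$N)
  all_rows$p <- hypergeom_test(all_rows$k, all_rows$K, all_rows$n, all_rows$N)
  all_rows$q <- bh_fdr(all_rows$p)
  all_rows$significant <- all_rows$q < q_threshold
  best <- all_rows |>
    dplyr::group_by(.data$motif, .data$cluster) |>
    dplyr::arrange(.data$p, dplyr::desc(.data$score_cut),
                   dplyr::desc(.data$conservation_cut), .data$distance_cut,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  attr(best, "all_cells") <- all_rows
  best
}

#' ChIP-peak-cluster enrichment over the distance grid
#'
#' A gene is bound by a TF when one of the TF's peaks (BED `name` field)
#' overlaps the gene's upstream window of D bp, for each D in the distance
#' grid; the score/conservation components are not used.  Peaks are
#' promoter-relative (`chrom` = gene id, TSS at `promoter_len`).
#' Hypergeometric + BH as for motifs, reporting each (TF, cluster) pair's
#' best distance.
#'
#' @param peaks BED6-style tibble (`chrom` = gene id, `start`, `end`, `name` =
#'   TF id).
#' @param clustering A `popseq_clustering`.
#' @param universe Character vector of universe gene ids.
#' @param promoter_len Promoter length (TSS coordinate); scalar or named
#'   per-gene.
#' @param distances Distance grid (bp).
#' @param q_threshold Significance threshold on q.
#' @return As [motif_cluster_enrichment()], with `motif` replaced by `tf`.
#' @export
chip_cluster_enrichment <- function(peaks, clustering, universe, promoter_len,
                                    distances = c(1000, 2000, 3000),
                                    q_threshold = 1e-3) {
  if (!all(c("chrom", "start", "end", "name") %in% names(peaks))) {
    stop_invalid("`peaks` must have chrom/start/end/name columns")
  }
  plen <- if (length(promoter_len) == 1) {
    setNames(rep(promoter_len, length(unique(peaks$chrom))), unique(peaks$chrom))
  } else {
    promoter_len
  }
  # peak distance from TSS = promoter_len - end (TSS-proximal edge)
  pres <- purrr::map_dfr(distances, function(D) {
    pass <- peaks$end > plen[peaks$chrom] - D & peaks$start < plen[peaks$chrom]
    if (!any(pass)) return(NULL)
    dplyr::distinct(tibble::tibble(
      motif = peaks$name[pass], gene = peaks$chrom[pass],
      distance_cut = D, conservation_cut = 0, score_cut = 0
    ))
  })
  out <- motif_cluster_enrichment(pres, clustering, universe, q_threshold)
  names(out)[names(out) == "motif"] <- "tf"
  out$conservation_cut <- out$score_cut <- NULL
  out
}

#' Positional and conservation bias of a motif's instances in a cluster
#'
#' Two-sided Mann-Whitney rank tests comparing (a) hit distances from the TSS
#' and (b) hit conservation between instances near in-cluster genes and
#' instances near out-of-cluster genes.  Direction is the sign of the median
#' difference ("nearer"/"further", "more_conserved"/"less_conserved").
#'
#' @param hits A `popseq_hits` tibble.
#' @param motif Motif id to test.
#' @param cluster_genes,other_genes Gene id sets.
#' @return Tibble (`metric`, `p`, `direction`, `n_in`, `n_out`); `NA` rows
#'   when either side is empty.
#' @export
positional_conservation_bias <- function(hits, motif, cluster_genes, other_genes) {
  h <- hits[hits$motif == motif, , drop = FALSE]
  hin <- h[h$gene %in% cluster_genes, , drop = FALSE]
  hout <- h[h$gene %in% other_genes, , drop = FALSE]
  one <- function(metric, xin, xout, less, more) {
    if (length(xin) == 0 || length(xout) == 0 || all(is.na(xin)) || all(is.na(xout))) {
      return(tibble::tibble(metric = metric, p = NA_real_,
                            direction = NA_character_,
                            n_in = length(xin), n_out = length(xout)))
    }
    p <- suppressWarnings(wilcox.test(xin, xout, exact = FALSE)$p.value)
    d <- median(xin, na.rm = TRUE) - median(xout, na.rm = TRUE)
    tibble::tibble(
      metric = metric, p = p,
      direction = if (d < 0) less else if (d > 0) more else "none",
      n_in = length(xin), n_out = length(xout)
    )
  }
  dplyr::bind_rows(
    one("distance", hin$distance, hout$distance, "nearer", "further"),
    one("conservation", hin$conservation, hout$conservation,
        "less_conserved", "more_conserved")
  )
}

#' Link candidate transcriptional regulators to clusters
#'
#' A (TF, cluster) pair is a candidate regulator link when the TF gene's own
#' enrichment profile correlates with the cluster centroid above `r_threshold`
#' AND one of the TF's motifs is enriched in the cluster below `q_threshold`.
#'
#' @param enr A `popseq_enrichment` or matrix (contains the TF genes' rows).
#' @param clustering A `popseq_clustering`.
#' @param motif_results Best-cell table from [motif_cluster_enrichment()].
#' @param tf_to_motif Tibble (`tf`, `motif`) mapping TF gene ids to motif ids.
#' @param r_threshold Correlation threshold (default 0.7, exclusive).
#' @param q_threshold Motif-enrichment q threshold (default 0.001).
#' @return Tibble (`tf`, `cluster`, `r`, `q`, `candidate`), one row per
#'   (TF, cluster) with a tested motif; TFs absent from `enr` are skipped
#'   with a warning.
#' @export
link_regulators <- function(enr, clustering, motif_results, tf_to_motif,
                            r_threshold = 0.7, q_threshold = 0.001) {
  v <- enr_matrix(enr)
  stopifnot(inherits(clustering, "popseq_clustering"))
  tfs <- unique(tf_to_motif$tf)
  absent <- setdiff(tfs, rownames(v))
  if (length(absent) > 0) {
    warn(sprintf("%d TF(s) absent from expression data skipped: %s",
                 length(absent), paste(head(absent, 5), collapse = ", ")))
    tfs <- setdiff(tfs, absent)
  }
  res <- dplyr::inner_join(tf_to_motif, motif_results, by = "motif") |>
    dplyr::filter(.data$tf %in% tfs) |>
    dplyr::group_by(.data$tf, .data$cluster) |>
    dplyr::summarise(q = min(.data$q, Inf), .groups = "drop")
  cent <- clustering$centroids[, colnames(v), drop = FALSE]
  res$r <- vapply(seq_len(nrow(res)), function(i) {
    prof <- v[res$tf[i], ]
    if (sd(prof) == 0) return(NA_real_)
    cor(prof, cent[res$cluster[i], ])
  }, 0)
  res$candidate <- !is.na(res$r) & res$r > r_threshold & res$q < q_threshold
  res[, c("tf", "cluster", "r", "q", "candidate")]
}
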