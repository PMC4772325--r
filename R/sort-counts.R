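#' Simulate sorted-fraction RNA-seq counts and the matching sort scheme
#'
#' For each marker, the positive fraction is a purity-weighted mixture of the
#' mean profile of member cells and of the complement (contamination drawn
#' from the complement's mean profile, matching how re-sort purity is
#' measured); the negative fraction is the complementary mixture.  An
#' "ungated" sample (all cells, with a configurable over-weighting of one
#' designated tissue emulating cell types depleted by singlet gating) and a
#' "singlet" sample (all cells, unweighted) are always emitted.  The
#' designated double-reporter marker pair contributes four samples (++, +-,
#' -+, --).  Read counts are multinomial at the requested depth, so column
#' sums equal `depth` exactly.
#'
#' @param truth A `popseq_truth`.
#' @param markers A `popseq_markers` over the same lineage.
#' @param purity Sort purity in (0, 1]; scalar or per-marker named vector.
#' @param depth Reads per sample (multinomial size).
#' @param replicates Number of biological replicates per single-marker sort.
#' @param n_singlet_control Number of markers (taken from the end of the
#'   marker list) sorted without a matched negative; their experiments use the
#'   singlet sample as control.
#' @param ungated_bias Weight multiplier for `bias_tissue` cells in the
#'   ungated sample (default 3).
#' @param bias_tissue Tissue over-represented among ungated cells; defaults to
#'   the first tissue ("hypodermis-like").
#' @param include_double Emit the double-reporter strain's four gated samples
#'   (set `FALSE` for schemes of single-marker fractions only, e.g. when
#'   studying how accuracy scales with the number of fractions).
#' @param seed Integer seed.
#'
#' @return A list of class `popseq_study`: `counts` (genes x samples integer
#'   matrix), `scheme` (a `popseq_scheme`), `mixtures` (expected per-sample
#'   mixture profiles, linear units, for oracle checks), and `gene_classes`.
#' @export
simulate_sort_counts <- function(truth, markers, purity = 0.9, depth = 2e6,
                                 replicates = 1, n_singlet_control = 2,
                                 ungated_bias = 3, bias_tissue = NULL,
                                 include_double = TRUE, seed = 1L) {
  stopifnot(inherits(truth, "popseq_truth"), inherits(markers, "popseq_markers"))
  if (any(purity <= 0) || any(purity > 1)) {
    stop_invalid("`purity` must lie in (0, 1]")
  }
  expr <- truth$expr
  cells <- colnames(expr)
  leaves <- lineage_leaves(truth$lineage)
  if (is.null(bias_tissue)) bias_tissue <- sort(unique(leaves$tissue))[1]
  ids <- names(markers$members)
  pur <- if (length(purity) == 1) setNames(rep(purity, length(ids)), ids) else purity[ids]

  mean_profile <- function(set) {
    if (length(set) == 0) {
      stop_invalid("degenerate-fraction: empty cell set")
    }
    rowMeans(expr[, set, drop = FALSE])
  }
  mix_for <- function(set, p) {
    comp <- setdiff(cells, set)
    if (length(set) == 0 || length(comp) == 0) {
      stop_invalid("degenerate-fraction: marker fraction or its complement is empty")
    }
    p * mean_profile(set) + (1 - p) * mean_profile(comp)
  }

  mixtures <- list()
  scheme_rows <- list()
  singlet_markers <- if (n_singlet_control > 0) {
    tail(setdiff(ids, markers$double_pair), n_singlet_control)
  } else {
    character()
  }
  for (m in ids) {
    mem <- markers$members[[m]]
    for (r in seq_len(replicates)) {
      tag <- if (replicates > 1) sprintf("_r%d", r) else ""
      pos_s <- sprintf("%s_pos%s", m, tag)
      mixtures[[pos_s]] <- mix_for(mem, pur[[m]])
      if (m %in% singlet_markers) {
        ctrl_policy <- "singlet"; ctrl_s <- "singlet"
      } else {
        ctrl_policy <- "matched_negative"
        ctrl_s <- sprintf("%s_neg%s", m, tag)
        mixtures[[ctrl_s]] <- mix_for(setdiff(cells, mem), pur[[m]])
      }
      scheme_rows[[length(scheme_rows) + 1L]] <- tibble::tibble(
        experiment = pos_s, positive_sample = pos_s,
        control_policy = ctrl_policy, control_sample = ctrl_s,
        marker1 = m, sign1 = "+", marker2 = NA_character_, sign2 = NA_character_,
        kind = markers$kinds[[m]], replicate_group = m,
        purity = pur[[m]],
        positive_fraction = length(mem) / length(cells)
      )
    }
  }
  # double-reporter strain: four gated quadrants, controls = double negative
  dp <- markers$double_pair
  if (include_double) {
    A <- markers$members[[dp[1]]]; B <- markers$members[[dp[2]]]
    quads <- list(
      pp = intersect(A, B), pn = setdiff(A, B),
      np = setdiff(B, A), nn = setdiff(cells, union(A, B))
    )
    dbl_p <- mean(pur[dp])
    dbl_id <- paste(dp, collapse = ".")
    for (q in names(quads)) {
      s <- sprintf("%s_%s", dbl_id, q)
      mixtures[[s]] <- mix_for(quads[[q]], dbl_p)
    }
    for (q in c("pp", "pn", "np")) {
      scheme_rows[[length(scheme_rows) + 1L]] <- tibble::tibble(
        experiment = sprintf("%s_%s", dbl_id, q),
        positive_sample = sprintf("%s_%s", dbl_id, q),
        control_policy = "double_negative",
        control_sample = sprintf("%s_nn", dbl_id),
        marker1 = dp[1], sign1 = if (substr(q, 1, 1) == "p") "+" else "-",
        marker2 = dp[2], sign2 = if (substr(q, 2, 2) == "p") "+" else "-",
        kind = "double", replicate_group = dbl_id,
        purity = dbl_p,
        positive_fraction = length(quads[[q]]) / length(cells)
      )
    }
  }
  # ungated (tissue-biased) and singlet (unweighted) whole-embryo samples
  w <- ifelse(leaves$tissue == bias_tissue, ungated_bias, 1)
  mixtures[["ungated"]] <- as.vector(expr %*% w) / sum(w)
  mixtures[["singlet"]] <- rowMeans(expr)

  mix <- do.call(cbind, mixtures)
  rownames(mix) <- rownames(expr)
  counts <- with_seed(seed, {
    apply(mix, 2, function(p) rmultinom(1, size = depth, prob = p / sum(p)))
  })
  dimnames(counts) <- dimnames(mix)

  scheme <- structure(
    list(
      experiments = dplyr::bind_rows(scheme_rows),
      singlet_sample = "singlet",
      ungated_sample = "ungated",
      double_pair = dp,
      bias_tissue = bias_tissue
    ),
    class = "popseq_scheme"
  )
  structure(
    list(
      counts = counts, scheme = scheme, mixtures = mix,
      gene_classes = setNames(truth$genes$class, truth$genes$gene)
    ),
    class = "popseq_study"
  )
}

#' @export
print.popseq_scheme <- function(x, ...) {
  cat(sprintf(
    "popseq sort scheme: %d experiments (%d matched-negative, %d singlet-control, %d double-gated)\n",
    nrow(x$experiments),
    sum(x$experiments$control_policy == "matched_negative"),
    sum(x$experiments$control_policy == "singlet"),
    sum(x$experiments$control_policy == "double_negative")
  ))
  invisible(x)
}

#' @export
print.popseq_study <- function(x, ...) {
  cat(sprintf("popseq study: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$scheme)
  invisible(x)
}
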