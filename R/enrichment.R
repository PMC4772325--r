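#' Pseudocounted log2 enrichment
#'
#' `log2((pseudocount + pos) / (pseudocount + neg))`.  The pseudocount
#' (default 3 RPM) bounds the enrichment of genes with very low read support,
#' giving a conservative estimate; a gene absent from both fractions scores 0.
#' Vectorized and antisymmetric under argument swap.
#'
#' @param pos_rpm,neg_rpm Nonnegative RPM values (recycled).
#' @param pseudocount Positive pseudocount in RPM (default 3).
#' @return Numeric vector of log2 enrichments.
#' @examples
#' log2_enrichment(13, 1)   # log2(16/4) = 2
#' @export
log2_enrichment <- function(pos_rpm, neg_rpm, pseudocount = 3) {
  if (any(pos_rpm < 0, na.rm = TRUE) || any(neg_rpm < 0, na.rm = TRUE)) {
    stop_invalid("RPM inputs must be nonnegative")
  }
  if (pseudocount <= 0) stop_invalid("`pseudocount` must be positive")
  log2((pseudocount + pos_rpm) / (pseudocount + neg_rpm))
}

#' Per-experiment enrichment matrix under the scheme's control policies
#'
#' For every experiment in the sort scheme, computes [log2_enrichment()] of
#' the positive sample against the control named by the experiment's policy:
#' its matched negative fraction, the singlet sample (for sorts without a
#' matched negative; flagged conservative, since any gated fraction is a
#' subset of the singlets), or the double-negative sample of the
#' double-reporter strain.
#'
#' @param expr A `popseq_expression` or RPM matrix.
#' @param scheme A `popseq_scheme`.
#' @param pseudocount Pseudocount in RPM.
#' @param include_singlet Append the singlet-vs-ungated column as a
#'   pseudo-experiment named `"singlet"` (see [singlet_enrichment()]).
#' @return A list of class `popseq_enrichment`: `values` (genes x experiments),
#'   `scheme`, `pseudocount`, `conservative` (named logical per experiment).
#' @export
enrichment_matrix <- function(expr, scheme, pseudocount = 3,
                              include_singlet = FALSE) {
  stopifnot(inherits(scheme, "popseq_scheme"))
  rpm <- rpm_matrix(expr)
  ex <- scheme$experiments
  need <- unique(c(ex$positive_sample, ex$control_sample))
  missing <- setdiff(need, colnames(rpm))
  if (length(missing) > 0) {
    bad <- ex$experiment[ex$positive_sample %in% missing | ex$control_sample %in% missing]
    abort(sprintf("missing-sample: sample(s) %s (experiment(s) %s) absent from expression matrix",
                  paste(missing, collapse = ", "), paste(bad, collapse = ", ")),
          class = "popseq_missing_sample")
  }
  values <- vapply(seq_len(nrow(ex)), function(i) {
    log2_enrichment(rpm[, ex$positive_sample[i]], rpm[, ex$control_sample[i]],
                    pseudocount)
  }, numeric(nrow(rpm)))
  dimnames(values) <- list(rownames(rpm), ex$experiment)
  conservative <- setNames(ex$control_policy == "singlet", ex$experiment)
  if (include_singlet) {
    values <- cbind(values, singlet = singlet_enrichment(expr, scheme, pseudocount))
    conservative <- c(conservative, singlet = FALSE)
  }
  structure(
    list(values = values, scheme = scheme, pseudocount = pseudocount,
         conservative = conservative),
    class = "popseq_enrichment"
  )
}

#' @export
print.popseq_enrichment <- function(x, ...) {
  cat(sprintf("popseq enrichment: %d genes x %d experiments (pseudocount %g RPM)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Call enriched / depleted genes at a log2 cutoff
#'
#' A gene is enriched in an experiment when its enrichment is at least
#' `cutoff` log2 units (4-fold at the default cutoff of 2) and depleted at or
#' below `-cutoff`; boundaries are inclusive.
#'
#' @param enr A `popseq_enrichment` or enrichment matrix.
#' @param cutoff Positive log2 cutoff (default 2).
#' @return A list: `calls` (tibble `gene`, `experiment`, `call`), and
#'   `summary` (tibble with the number of genes called in >= 1 and >= 2
#'   experiments).
#' @export
call_enriched_depleted <- function(enr, cutoff = 2) {
  if (cutoff <= 0) stop_invalid("`cutoff` must be positive")
  v <- enr_matrix(enr)
  call <- matrix("neither", nrow(v), ncol(v), dimnames = dimnames(v))
  call[v >= cutoff] <- "enriched"
  call[v <= -cutoff] <- "depleted"
  n_called <- rowSums(call != "neither")
  calls <- tibble::tibble(
    gene = rep(rownames(v), ncol(v)),
    experiment = rep(colnames(v), each = nrow(v)),
    call = as.vector(call)
  )
  list(
    calls = calls,
    matrix = call,
    summary = tibble::tibble(
      n_genes_ge1 = sum(n_called >= 1),
      n_genes_ge2 = sum(n_called >= 2)
    )
  )
}

#' Replicate concordance of enrichment columns
#'
#' Pearson correlation over all genes, plus call accuracy: among genes called
#' enriched or depleted in replicate A at `cutoff`, the fraction whose
#' enrichment in replicate B has the same sign (B is thresholded at zero, the
#' weakest faithful reading of predicting the replicate's direction; set
#' `b_cutoff` to require B to pass a cutoff too).
#'
#' @param enr_a,enr_b Numeric enrichment vectors of equal length (>= 3).
#' @param cutoff Call cutoff applied to A.
#' @param b_cutoff Threshold B must exceed in absolute value (default 0).
#' @return Tibble with `r`, `accuracy`, `n_called`.
#' @export
replicate_concordance <- function(enr_a, enr_b, cutoff = 2, b_cutoff = 0) {
  if (length(enr_a) != length(enr_b) || length(enr_a) < 3) {
    stop_invalid("columns must have equal length >= 3")
  }
  if (sd(enr_a) == 0 || sd(enr_b) == 0) {
    abort("undefined-correlation: zero variance in an enrichment column",
          class = "popseq_undefined_correlation")
  }
  called <- abs(enr_a) >= cutoff
  acc <- if (any(called)) {
    mean(sign(enr_b[called]) == sign(enr_a[called]) & abs(enr_b[called]) >= b_cutoff)
  } else {
    NA_real_
  }
  tibble::tibble(r = cor(enr_a, enr_b), accuracy = acc, n_called = sum(called))
}

#' Singlet-vs-ungated enrichment column
#'
#' log2 enrichment of the singlet sample over the ungated sample per gene;
#' genes depleted here are preferentially expressed in cell types lost to
#' singlet gating (clumping-prone cells).  Appended to the enrichment matrix
#' as a pseudo-experiment by `enrichment_matrix(include_singlet = TRUE)`.
#'
#' @inheritParams enrichment_matrix
#' @return Named numeric vector over genes.
#' @export
singlet_enrichment <- function(expr, scheme, pseudocount = 3) {
  stopifnot(inherits(scheme, "popseq_scheme"))
  rpm <- rpm_matrix(expr)
  need <- c(scheme$singlet_sample, scheme$ungated_sample)
  if (!all(need %in% colnames(rpm))) {
    abort(sprintf("missing-sample: %s",
                  paste(setdiff(need, colnames(rpm)), collapse = ", ")),
          class = "popseq_missing_sample")
  }
  log2_enrichment(rpm[, scheme$singlet_sample], rpm[, scheme$ungated_sample],
                  pseudocount)
}

#' Reconstruction of the ungated profile from sorted fractions
#'
#' For each matched-negative experiment, the combined profile
#' `w * positive + (1 - w) * negative` (w = the fraction of cells that are
#' positive, from the scheme unless `weights` is given) is compared with the
#' ungated sample by Pearson correlation of log(1 + RPM).  With
#' `correct_for_singlet`, the ungated column is first rescaled per gene by the
#' pseudocounted singlet/ungated ratio, removing the expression signature of
#' cell types lost to singlet gating; a paired one-sided Wilcoxon signed-rank
#' test asks whether correction improves the similarity across experiments.
#'
#' @inheritParams enrichment_matrix
#' @param weights Optional named per-experiment positive-cell proportions in
#'   (0, 1).
#' @param correct_for_singlet Compute corrected similarities as well.
#' @return A list: `table` (tibble `experiment`, `r_uncorrected`,
#'   `r_corrected`), `p_improvement` (one-sided paired Wilcoxon p, or `NA` if
#'   fewer than two experiments), `n_experiments`.
#' @export
reconstruction_check <- function(expr, scheme, weights = NULL,
                                 correct_for_singlet = TRUE, pseudocount = 3) {
  stopifnot(inherits(scheme, "popseq_scheme"))
  rpm <- rpm_matrix(expr)
  ex <- scheme$experiments
  ex <- ex[ex$control_policy == "matched_negative", , drop = FALSE]
  if (nrow(ex) == 0) stop_invalid("no matched-negative experiments in scheme")
  w <- if (is.null(weights)) setNames(ex$positive_fraction, ex$experiment) else weights
  if (any(w <= 0 | w >= 1)) stop_invalid("weights must lie in (0, 1)")
  ung <- rpm[, scheme$ungated_sample]
  sing <- rpm[, scheme$singlet_sample]
  ung_corr <- ung * (pseudocount + sing) / (pseudocount + ung)
  rows <- lapply(seq_len(nrow(ex)), function(i) {
    comb <- w[[ex$experiment[i]]] * rpm[, ex$positive_sample[i]] +
      (1 - w[[ex$experiment[i]]]) * rpm[, ex$control_sample[i]]
    tibble::tibble(
      experiment = ex$experiment[i],
      r_uncorrected = cor(log1p(comb), log1p(ung)),
      r_corrected = if (correct_for_singlet) cor(log1p(comb), log1p(ung_corr)) else NA_real_
    )
  })
  table <- dplyr::bind_rows(rows)
  p <- NA_real_
  if (correct_for_singlet && nrow(table) >= 2 &&
      any(table$r_corrected != table$r_uncorrected)) {
    p <- wilcox.test(table$r_corrected, table$r_uncorrected, paired = TRUE,
                     alternative = "greater", exact = FALSE)$p.value
  }
  list(table = table, p_improvement = p, n_experiments = nrow(table))
}
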