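#' Reads-per-million normalization with class exclusion
#'
#' Normalizes each sample to one million reads over the included genes:
#' `RPM(g, s) = 1e6 * count(g, s) / sum(count(g', s))`, where the denominator
#' runs over genes whose class is not excluded (ribosomal and mitochondrial
#' RNA by default).  Excluded-class genes still receive an RPM value against
#' the same denominator but are flagged, so included genes sum to exactly one
#' million per sample.
#'
#' @param counts Genes x samples count matrix (or data frame with a gene id
#'   first column); nonnegative integers.
#' @param gene_classes Named character vector gene id -> class (coding,
#'   lincRNA, ancRNA, rRNA, mito).  Genes without a class are treated as
#'   included.
#' @param excluded_classes Classes omitted from the normalization denominator.
#' @return A list of class `popseq_expression`: `rpm` (genes x samples),
#'   `gene_classes`, `excluded` (logical per gene), `excluded_classes`.
#' @examples
#' m <- matrix(c(2, 8), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' compute_rpm(m)$rpm
#' @export
compute_rpm <- function(counts, gene_classes = NULL,
                        excluded_classes = c("rRNA", "mito")) {
  m <- as_gene_matrix(counts, "counts")
  if (any(m < 0)) stop_invalid("counts must be nonnegative")
  cls <- rep(NA_character_, nrow(m))
  if (!is.null(gene_classes)) {
    cls <- unname(gene_classes[rownames(m)])
  }
  excluded <- !is.na(cls) & cls %in% excluded_classes
  denom <- colSums(m[!excluded, , drop = FALSE])
  if (any(denom == 0)) {
    abort(sprintf("degenerate-sample: no included reads in sample(s) %s",
                  paste(colnames(m)[denom == 0], collapse = ", ")),
          class = "popseq_degenerate_sample")
  }
  rpm <- sweep(m, 2, denom, "/") * 1e6
  structure(
    list(rpm = rpm, gene_classes = setNames(cls, rownames(m)),
         excluded = setNames(excluded, rownames(m)),
         excluded_classes = excluded_classes),
    class = "popseq_expression"
  )
}

#' @export
print.popseq_expression <- function(x, ...) {
  cat(sprintf("popseq expression: %d genes x %d samples (RPM; %d genes excluded from denominator)\n",
              nrow(x$rpm), ncol(x$rpm), sum(x$excluded)))
  invisible(x)
}

#' Detected (expressed) genes at an RPM threshold
#'
#' A gene is detected in a sample when its RPM is at least `threshold`
#' (inclusive boundary).  The any-sample set is the union over samples.
#'
#' @param expr A `popseq_expression` or RPM matrix.
#' @param threshold Detection threshold in RPM (default 1).
#' @return A list: `by_sample` (named list of gene id vectors), `any_sample`
#'   (character vector), and `table` (tibble `gene`, `n_samples`).
#' @export
detect_expressed <- function(expr, threshold = 1) {
  if (threshold < 0) stop_invalid("`threshold` must be nonnegative")
  rpm <- rpm_matrix(expr)
  hit <- rpm >= threshold
  by_sample <- lapply(seq_len(ncol(rpm)), function(j) rownames(rpm)[hit[, j]])
  names(by_sample) <- colnames(rpm)
  n <- rowSums(hit)
  list(
    by_sample = by_sample,
    any_sample = rownames(rpm)[n > 0],
    table = tibble::tibble(gene = rownames(rpm), n_samples = unname(n))
  )
}
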