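#' Build the experiments-by-cells membership matrix
#'
#' Each experiment's row gives the expected capture weight of every terminal
#' cell in that fraction: `purity * 1[members]/|members| + (1 - purity) *
#' 1[complement]/|complement|`, so rows sum to one.  Positive, negative and
#' double-gated quadrant fractions are derived from the scheme's marker signs
#' (set intersection / difference / complement).  Columns can optionally be
#' aggregated to tissues, which conditions the unmixing problem when there are
#' far fewer fractions than cells.
#'
#' @param markers A `popseq_markers`.
#' @param scheme A `popseq_scheme` (its `purity` column is used unless
#'   `purity` is supplied).
#' @param purity Scalar or per-experiment named vector in (0, 1].
#' @param tissues Optional named character vector cell -> tissue; when given,
#'   columns are summed within tissues.
#' @return Experiments x cells (or tissues) numeric matrix with attribute
#'   `"purity"`.
#' @export
build_membership <- function(markers, scheme, purity = NULL, tissues = NULL) {
  stopifnot(inherits(markers, "popseq_markers"), inherits(scheme, "popseq_scheme"))
  cells <- markers$cells
  ex <- scheme$experiments
  pur <- if (is.null(purity)) {
    setNames(ex$purity, ex$experiment)
  } else if (length(purity) == 1) {
    setNames(rep(purity, nrow(ex)), ex$experiment)
  } else {
    purity
  }
  if (any(pur <= 0 | pur > 1)) stop_invalid("`purity` must lie in (0, 1]")
  rows <- t(vapply(seq_len(nrow(ex)), function(i) {
    set <- fraction_cells(markers, ex[i, ])
    comp <- setdiff(cells, set)
    if (length(set) == 0) {
      stop_invalid("degenerate-fraction: experiment %s captures no cells",
                   ex$experiment[i])
    }
    p <- pur[[ex$experiment[i]]]
    row <- setNames(numeric(length(cells)), cells)
    row[set] <- p / length(set)
    if (length(comp) > 0) {
      row[comp] <- (1 - p) / length(comp)
    } else if (p < 1) {
      stop_invalid("degenerate-fraction: experiment %s has an empty complement",
                   ex$experiment[i])
    }
    row
  }, numeric(length(cells))))
  rownames(rows) <- ex$experiment
  if (!is.null(tissues)) {
    grp <- factor(tissues[cells], levels = unique(tissues[cells]))
    rows <- t(rowsum(t(rows), grp))
    colnames(rows) <- levels(grp)
  }
  attr(rows, "purity") <- pur
  rows
}

# terminal cells captured by an experiment's gate
fraction_cells <- function(markers, ex_row) {
  cells <- markers$cells
  m1 <- markers$members[[ex_row$marker1]]
  set <- if (ex_row$sign1 == "+") m1 else setdiff(cells, m1)
  if (!is.na(ex_row$marker2)) {
    m2 <- markers$members[[ex_row$marker2]]
    s2 <- if (ex_row$sign2 == "+") m2 else setdiff(cells, m2)
    set <- intersect(set, s2)
  }
  set
}

#' Per-cell expression estimates by pseudoinverse unmixing
#'
#' Solves `values = membership %*% x` per gene with the Moore-Penrose
#' pseudoinverse, giving the minimum-norm least-squares estimate of the
#' per-cell (or per-tissue) values.  The unmixed quantity is whatever is
#' passed in; linear fold-enrichment (2^log2-enrichment) is the conventional
#' choice, available via [deconvolve_enrichment()].
#'
#' @param values Genes x experiments matrix (or a numeric vector for one
#'   gene); columns must match the membership rows.
#' @param membership Experiments x cells matrix from [build_membership()].
#' @return A list of class `popseq_deconvolution`: `estimates` (genes x
#'   cells), `rank`, `condition` (ratio of extreme positive singular values).
#' @export
deconvolve <- function(values, membership) {
  if (is.vector(values)) values <- matrix(values, 1, dimnames = list("gene", names(values)))
  if (ncol(values) != nrow(membership)) {
    stop_invalid("values have %d experiments but membership has %d rows",
                 ncol(values), nrow(membership))
  }
  if (!is.null(colnames(values)) && !is.null(rownames(membership))) {
    values <- values[, rownames(membership), drop = FALSE]
  }
  sv <- svd(membership)$d
  tol <- max(dim(membership)) * max(sv) * .Machine$double.eps
  pinv <- MASS::ginv(membership)
  est <- values %*% t(pinv)
  colnames(est) <- colnames(membership)
  structure(
    list(
      estimates = est,
      rank = sum(sv > tol),
      condition = max(sv) / min(sv[sv > tol])
    ),
    class = "popseq_deconvolution"
  )
}

#' Unmix fold-enrichment values from an enrichment matrix
#'
#' @param enr A `popseq_enrichment`.
#' @param membership Experiments x cells matrix.
#' @param scale `"fold"` (2^enrichment, the default), `"log2"`, or
#'   `"expression"` is not rescaled here - pass RPM through [deconvolve()].
#' @return A `popseq_deconvolution`.
#' @export
deconvolve_enrichment <- function(enr, membership, scale = c("fold", "log2")) {
  scale <- match.arg(scale)
  v <- enr_matrix(enr)
  v <- v[, rownames(membership), drop = FALSE]
  if (scale == "fold") v <- 2^v
  deconvolve(v, membership)
}

#' @export
print.popseq_deconvolution <- function(x, ...) {
  cat(sprintf("popseq deconvolution: %d genes x %d cells (rank %d, condition %.3g)\n",
              nrow(x$estimates), ncol(x$estimates), x$rank, x$condition))
  invisible(x)
}

#' Leave-one-out cross-validation of the unmixing
#'
#' Each experiment in turn is held out; the remaining rows (minus any
#' permanently excluded experiments, e.g. the double-positive sort) are used
#' to estimate per-cell values, and the held-out experiment's values are
#' predicted as its membership row applied to the estimates.  Reported per
#' held-out experiment: Pearson r between predicted and observed values
#' across genes.
#'
#' @param values Genes x experiments matrix.
#' @param membership Experiments x cells matrix.
#' @param exclude_from_fit Experiment ids never used for fitting (still
#'   predicted).
#' @return Tibble (`experiment`, `r`, `n_fit`, `excluded_from_fit`).  `r` is
#'   `NA` when either vector is constant.
#' @export
loo_crossvalidate <- function(values, membership, exclude_from_fit = character()) {
  if (nrow(membership) < 3) stop_invalid("need >= 3 experiments")
  exps <- rownames(membership)
  values <- values[, exps, drop = FALSE]
  purrr::map_dfr(exps, function(e) {
    fit <- setdiff(exps, union(e, exclude_from_fit))
    if (length(fit) < 2) stop_invalid("fewer than 2 rows left after exclusion")
    est <- deconvolve(values[, fit, drop = FALSE],
                      membership[fit, , drop = FALSE])$estimates
    pred <- as.vector(est %*% membership[e, ])
    obs <- values[, e]
    r <- if (sd(pred) == 0 || sd(obs) == 0) NA_real_ else cor(pred, obs)
    tibble::tibble(experiment = e, r = r, n_fit = length(fit),
                   excluded_from_fit = e %in% exclude_from_fit)
  })
}
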