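# Internal helpers shared across modules.

# Run an expression with a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce counts/expression input to a numeric matrix with gene rownames.
# Accepts a matrix with rownames, or a data frame whose first column is the
# gene id.
as_gene_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    return(m)
  }
  if (!is.matrix(x)) {
    abort(sprintf("`%s` must be a matrix or data frame", arg),
          class = "popseq_invalid_argument")
  }
  if (is.null(rownames(x))) {
    abort(sprintf("`%s` must have gene ids as rownames", arg),
          class = "popseq_invalid_argument")
  }
  storage.mode(x) <- "double"
  x
}

# Extract the RPM matrix from a popseq_expression object or pass a matrix
# through.
rpm_matrix <- function(expr) {
  if (inherits(expr, "popseq_expression")) return(expr$rpm)
  as_gene_matrix(expr, "expr")
}

# Extract the enrichment value matrix from popseq_enrichment or a matrix.
enr_matrix <- function(enr) {
  if (inherits(enr, "popseq_enrichment")) return(enr$values)
  as_gene_matrix(enr, "enr")
}

stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "popseq_invalid_argument")
}
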