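#' Generate ground-truth per-cell expression for a synthetic study
#'
#' Assigns genes to expression patterns (tissue-restricted, ubiquitous, or
#' unstructured noise), draws per-cell abundances with multiplicative lognormal
#' noise, and lays gene models on a single synthetic chromosome.  A small
#' fraction of genes are long intergenic noncoding RNAs (lincRNA) placed next
#' to a coding gene with the same pattern, or antisense noncoding RNAs (ancRNA)
#' overlapping a coding gene on the opposite strand; rRNA and mitochondrial
#' genes are included so RPM exclusion rules can be exercised.
#'
#' Each tissue-restricted pattern designates one of its member genes as the
#' pattern's regulator transcription factor; motif-planting and
#' regulator-linking tests use that assignment as truth.
#'
#' @param lineage A `popseq_lineage` from [generate_lineage()].
#' @param n_genes Total number of genes.
#' @param n_patterns Number of tissue-restricted patterns (each pattern's
#'   member tissues are one or more lineage tissues).  A ubiquitous pattern and
#'   an unstructured noise pattern are always present in addition.
#' @param fold Expression fold of a pattern gene in member-tissue cells versus
#'   elsewhere (default 16).
#' @param noise_sd Per-entry (gene x cell) independent multiplicative noise SD
#'   in log2 units.
#' @param heritable_sd Per-division SD (log2 units) of a lineage random walk
#'   added to each gene's log expression: sister cells inherit their parent's
#'   deviation and drift apart, giving cell-level structure finer than the
#'   tissue blocks (what finer sort fractions can resolve).  Set to 0 for
#'   purely tissue-block truth.
#' @param prop_ubiquitous,prop_noise Fractions of genes assigned to the
#'   ubiquitous and noise patterns.
#' @param prop_linc,prop_anc Fractions of genes that are lincRNA / ancRNA.
#' @param n_rrna,n_mito Counts of rRNA and mitochondrial genes.
#' @param seed Integer seed.
#'
#' @return A list of class `popseq_truth`:
#'   * `expr`: genes x terminal-cells abundance matrix (arbitrary linear units);
#'   * `genes`: tibble (`gene`, `class`, `chrom`, `start`, `end` (0-based
#'     half-open), `strand`, `pattern`, `partner` for linc/ancRNA);
#'   * `patterns`: tibble (`pattern`, `tissues` list-column, `regulator`);
#'   * `lineage`: the input lineage.
#' @export
generate_truth <- function(lineage, n_genes, n_patterns = 12, fold = 16,
                           noise_sd = 0.25, heritable_sd = 0.1,
                           prop_ubiquitous = 0.2,
                           prop_noise = 0.05, prop_linc = 0.02, prop_anc = 0.01,
                           n_rrna = 3, n_mito = 3, seed = 1L) {
  stopifnot(inherits(lineage, "popseq_lineage"))
  if (n_genes < n_patterns) {
    stop_invalid("`n_genes` (%d) must be at least `n_patterns` (%d)",
                 n_genes, n_patterns)
  }
  leaves <- lineage_leaves(lineage)
  tissues <- sort(unique(leaves$tissue))
  if (n_patterns < 1) stop_invalid("`n_patterns` must be >= 1")
  with_seed(seed, {
    n_genes <- as.integer(n_genes)
    n_patterns <- as.integer(n_patterns)
    gene <- sprintf("g%05d", seq_len(n_genes))

    # pattern table: each pattern owns 1 tissue (cycled) when patterns <=
    # tissues, otherwise a random pair of tissues
    pat_id <- sprintf("P%02d", seq_len(n_patterns))
    pat_tissues <- lapply(seq_len(n_patterns), function(i) {
      if (n_patterns <= length(tissues)) {
        tissues[i]
      } else {
        sort(sample(tissues, 2L))
      }
    })

    # gene classes
    n_special <- n_rrna + n_mito
    n_linc <- round(prop_linc * n_genes)
    n_anc <- round(prop_anc * n_genes)
    n_regular <- n_genes - n_special - n_linc - n_anc
    if (n_regular < n_patterns) stop_invalid("`n_genes` too small for class mix")
    class <- c(
      rep("coding", n_regular),
      rep("lincRNA", n_linc),
      rep("ancRNA", n_anc),
      rep("rRNA", n_rrna),
      rep("mito", n_mito)
    )

    # pattern assignment for regular coding genes
    n_ubi <- round(prop_ubiquitous * n_regular)
    n_noise <- round(prop_noise * n_regular)
    n_pat_genes <- n_regular - n_ubi - n_noise
    pattern <- c(
      pat_id[(seq_len(n_pat_genes) - 1L) %% n_patterns + 1L],
      rep("ubiquitous", n_ubi),
      rep("noise", n_noise)
    )
    # linc/ancRNA copy the pattern of a coding partner
    partner <- rep(NA_character_, n_genes)
    pool <- seq_len(n_pat_genes)        # coding pattern genes
    nc_partner <- sample(pool, n_linc + n_anc, replace = n_linc + n_anc > length(pool))
    pattern <- c(pattern, pattern[nc_partner], rep("ubiquitous", n_special))
    partner[n_regular + seq_len(n_linc + n_anc)] <- gene[nc_partner]

    # per-cell abundance
    base <- rlnorm(n_genes, meanlog = log(10), sdlog = 1)
    base[class %in% c("rRNA", "mito")] <- 500
    member <- matrix(FALSE, n_genes, nrow(leaves))
    for (i in seq_len(n_patterns)) {
      member[pattern == pat_id[i], leaves$tissue %in% pat_tissues[[i]]] <- TRUE
    }
    member[pattern == "ubiquitous", ] <- TRUE
    expr <- matrix(base, n_genes, nrow(leaves)) * ifelse(member, fold, 1)
    is_noise <- pattern == "noise"
    if (any(is_noise)) {
      expr[is_noise, ] <- base[is_noise] *
        2^matrix(rnorm(sum(is_noise) * nrow(leaves), sd = 2), sum(is_noise))
    }
    if (noise_sd > 0) {
      expr <- expr * 2^matrix(rnorm(length(expr), sd = noise_sd), n_genes)
    }
    if (heritable_sd > 0) {
      # lineage random walk: each gene's log deviation drifts down the tree
      idx_parent <- match(lineage$parent, lineage$cell)
      W <- matrix(0, n_genes, nrow(lineage))
      for (i in seq_len(nrow(lineage))[-1]) {      # children follow parents
        W[, i] <- W[, idx_parent[i]] + rnorm(n_genes, sd = heritable_sd)
      }
      expr <- expr * 2^W[, match(leaves$cell, lineage$cell), drop = FALSE]
    }
    dimnames(expr) <- list(gene, leaves$cell)

    # coordinates: cursor layout on one synthetic chromosome, 0-based
    # half-open; linc/ancRNA are emitted beside/inside their partner
    ord <- c(sample(seq_len(n_regular)), n_regular + n_linc + n_anc + seq_len(n_special))
    start <- end <- integer(n_genes)
    strand <- rep("+", n_genes)
    cursor <- 3000L
    linc_of <- which(class == "lincRNA")
    anc_of <- which(class == "ancRNA")
    linc_by_partner <- split(linc_of, partner[linc_of])
    anc_by_partner <- split(anc_of, partner[anc_of])
    for (i in ord) {
      len <- 1000L
      start[i] <- cursor
      end[i] <- cursor + len
      strand[i] <- sample(c("+", "-"), 1L)
      g <- gene[i]
      for (j in anc_by_partner[[g]] %||% integer()) {  # antisense, overlapping
        start[j] <- start[i] + 200L
        end[j] <- end[i] - 200L
        strand[j] <- if (strand[i] == "+") "-" else "+"
      }
      cursor <- end[i] + 500L
      for (j in linc_by_partner[[g]] %||% integer()) { # nearest neighbour
        start[j] <- cursor
        end[j] <- cursor + 600L
        strand[j] <- sample(c("+", "-"), 1L)
        cursor <- end[j] + 500L
      }
      cursor <- cursor + 2500L
    }

    genes <- tibble::tibble(
      gene = gene, class = class, chrom = "chrS",
      start = start, end = end, strand = strand,
      pattern = pattern, partner = partner
    )
    regulator <- vapply(pat_id, function(p) gene[which(pattern == p)[1L]], "")
    patterns <- tibble::tibble(
      pattern = pat_id, tissues = pat_tissues, regulator = regulator
    )
    structure(
      list(expr = expr, genes = genes, patterns = patterns, lineage = lineage),
      class = "popseq_truth"
    )
  })
}

#' @export
print.popseq_truth <- function(x, ...) {
  cat(sprintf(
    "popseq truth: %d genes x %d terminal cells, %d tissue patterns\n",
    nrow(x$expr), ncol(x$expr), nrow(x$patterns)
  ))
  invisible(x)
}
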