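# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy an enrichment matrix into long form
#'
#' @param x A `popseq_enrichment`.
#' @param ... Unused.
#' @return Tibble (`gene`, `experiment`, `enrichment`).
#' @export
tidy.popseq_enrichment <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "experiment",
                        values_to = "enrichment")
}

#' @rdname tidy.popseq_enrichment
#' @return `glance`: one-row tibble with dimensions and pseudocount.
#' @export
glance.popseq_enrichment <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$values), n_experiments = ncol(x$values),
    pseudocount = x$pseudocount,
    n_conservative = sum(x$conservative)
  )
}

#' Tidy a clustering into its gene assignment
#'
#' @param x A `popseq_clustering`.
#' @param ... Unused.
#' @return The assignment tibble (`gene`, `cluster`).
#' @export
tidy.popseq_clustering <- function(x, ...) x$assignment

#' @rdname tidy.popseq_clustering
#' @return `glance`: one-row tibble (`n_genes`, `k`, `n_excluded`,
#'   `max_cluster_size`).
#' @export
glance.popseq_clustering <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$assignment), k = x$k,
    n_excluded = length(x$excluded),
    max_cluster_size = max(as.integer(x$sizes))
  )
}

#' Tidy deconvolution estimates into long form
#'
#' @param x A `popseq_deconvolution`.
#' @param ... Unused.
#' @return Tibble (`gene`, `cell`, `estimate`).
#' @export
tidy.popseq_deconvolution <- function(x, ...) {
  tibble::as_tibble(x$estimates, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cell", values_to = "estimate")
}

#' @rdname tidy.popseq_deconvolution
#' @return `glance`: one-row tibble (`rank`, `condition`, dimensions).
#' @export
glance.popseq_deconvolution <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$estimates), n_cells = ncol(x$estimates),
    rank = x$rank, condition = x$condition
  )
}

#' Heatmap of cluster centroid enrichment profiles
#'
#' @param object A `popseq_clustering`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.popseq_clustering <- function(object, ...) {
  df <- tibble::as_tibble(object$centroids, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "experiment",
                        values_to = "enrichment")
  ggplot(df, aes(.data$experiment, .data$cluster, fill = .data$enrichment)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "sort experiment", y = "cluster",
         fill = "mean log2\nenrichment") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Distribution of enrichment values per experiment
#'
#' @param object A `popseq_enrichment`.
#' @param cutoff Call cutoff drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.popseq_enrichment <- function(object, cutoff = 2, ...) {
  df <- tidy.popseq_enrichment(object)
  ggplot(df, aes(.data$enrichment)) +
    geom_histogram(bins = 60, fill = "grey40") +
    geom_vline(xintercept = c(-cutoff, cutoff), linetype = "dashed") +
    facet_wrap(~experiment) +
    labs(x = "log2 enrichment (positive vs control)", y = "genes") +
    theme_minimal()
}

#' Leave-one-out prediction accuracy per held-out experiment
#'
#' @param loo Tibble from [loo_crossvalidate()].
#' @return A ggplot.
#' @export
plot_loo <- function(loo) {
  ggplot(loo, aes(stats::reorder(.data$experiment, .data$r), .data$r,
                  fill = .data$excluded_from_fit)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Pearson r (predicted vs observed)",
         fill = "excluded\nfrom fit") +
    theme_minimal()
}

#' Mean enrichment of time-specific genes by temporal bin
#'
#' @param temporal Output of [fraction_temporal_profile()].
#' @return A ggplot.
#' @export
plot_temporal_profile <- function(temporal) {
  ggplot(temporal$profile,
         aes(.data$mid_time, .data$mean_enrichment, group = .data$experiment)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dotted") +
    facet_wrap(~experiment) +
    labs(x = "mean expression time (min)", y = "mean log2 enrichment") +
    theme_minimal()
}
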