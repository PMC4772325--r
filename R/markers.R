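#' Generate overlapping reporter marker sets over a lineage
#'
#' Each marker labels the union of 1-3 lineage subtrees, so memberships are
#' lineage-contiguous and markers overlap heavily (as fluorescent reporter
#' strains do), rather than partitioning the cells.  One base subtree per
#' marker is drawn from a partition of the tree so that the union of all
#' markers covers every terminal cell; extra random subtrees create overlap.
#' One designated pair of markers is guaranteed a nonempty intersection and is
#' used for the simulated double-reporter strain.
#'
#' @param lineage A `popseq_lineage`.
#' @param n_markers Number of markers (>= 2).
#' @param max_extra Maximum number of extra subtrees added per marker (0-2 by
#'   default, giving 1-3 subtrees per marker).
#' @param seed Integer seed.
#'
#' @return A list of class `popseq_markers`: `members` (named list of terminal
#'   cell ids per marker), `table` (long tibble `marker`, `cell`), `kinds`
#'   (reporter kind per marker), `double_pair` (two marker ids), `overlap`
#'   (tibble of pairwise overlap counts) and `mean_overlap`.
#' @export
generate_markers <- function(lineage, n_markers = 14, max_extra = 2, seed = 1L) {
  stopifnot(inherits(lineage, "popseq_lineage"))
  if (n_markers < 2) stop_invalid("`n_markers` must be >= 2")
  n_markers <- as.integer(n_markers)
  leaves <- lineage_leaves(lineage)$cell
  subtrees <- lineage_subtrees(lineage)
  # candidate subtrees: at most 40% of leaves, at least 1
  sizes <- lengths(subtrees)
  cand <- names(subtrees)[sizes <= max(1L, floor(0.4 * length(leaves)))]
  with_seed(seed, {
    # base partition: split the root into n_markers subtrees (largest-first),
    # guaranteeing coverage
    base <- partition_subtrees(lineage, min(n_markers, length(leaves)))
    if (length(base) < n_markers) {
      base <- c(base, sample(base, n_markers - length(base), replace = TRUE))
    }
    base <- sample(base)     # shuffle assignment to markers
    ids <- sprintf("m%02d", seq_len(n_markers))
    members <- vector("list", n_markers)
    for (i in seq_len(n_markers)) {
      extra <- sample(0:max_extra, 1L)
      picks <- if (extra > 0) sample(cand, extra) else character()
      mem <- sort(unique(c(base[[i]], unlist(subtrees[picks], use.names = FALSE))))
      # strict subset of all terminal cells
      while (length(mem) >= length(leaves) && length(picks) > 0) {
        picks <- picks[-length(picks)]
        mem <- sort(unique(c(base[[i]], unlist(subtrees[picks], use.names = FALSE))))
      }
      members[[i]] <- mem
    }
    names(members) <- ids
    # designated double pair: prefer a pair whose four gating quadrants
    # (++, +-, -+, --) are all nonempty; otherwise repair markers 1 and 2 by
    # adding single leaves (a leaf is a one-cell subtree)
    quad_ok <- function(a, b) {
      length(intersect(a, b)) > 0 && length(setdiff(a, b)) > 0 &&
        length(setdiff(b, a)) > 0 && length(setdiff(leaves, union(a, b))) > 0
    }
    # among valid pairs, take the one with the smallest intersection: the
    # double reporter emulates two distinct expression patterns that share a
    # limited set of cells
    double_pair <- NULL
    best_ov <- Inf
    for (p in utils::combn(seq_len(n_markers), 2, simplify = FALSE)) {
      if (quad_ok(members[[p[1]]], members[[p[2]]])) {
        ov <- length(intersect(members[[p[1]]], members[[p[2]]]))
        if (ov < best_ov) {
          best_ov <- ov
          double_pair <- ids[p]
        }
      }
    }
    if (is.null(double_pair)) {
      if (length(intersect(members[[1]], members[[2]])) == 0) {
        members[[1]] <- sort(unique(c(members[[1]], sample(members[[2]], 1L))))
      }
      if (length(setdiff(members[[1]], members[[2]])) == 0) {
        members[[1]] <- sort(unique(c(
          members[[1]], sample(setdiff(leaves, members[[2]]), 1L)
        )))
      }
      if (length(setdiff(members[[2]], members[[1]])) == 0) {
        members[[2]] <- sort(unique(c(
          members[[2]], sample(setdiff(leaves, members[[1]]), 1L)
        )))
      }
      if (!quad_ok(members[[1]], members[[2]])) {
        stop_invalid("degenerate-fraction: could not form a double-marker pair")
      }
      double_pair <- ids[1:2]
    }
    kinds <- sample(c("translational", "promoter-fusion"), n_markers, replace = TRUE)
    ov <- t(utils::combn(ids, 2))
    overlap <- tibble::tibble(
      marker_a = ov[, 1], marker_b = ov[, 2],
      n_overlap = apply(ov, 1, function(p) {
        length(intersect(members[[p[1]]], members[[p[2]]]))
      })
    )
    structure(
      list(
        members = members,
        table = tibble::tibble(
          marker = rep(ids, lengths(members)),
          cell = unlist(members, use.names = FALSE)
        ),
        kinds = setNames(kinds, ids),
        double_pair = double_pair,
        overlap = overlap,
        mean_overlap = mean(overlap$n_overlap),
        cells = leaves
      ),
      class = "popseq_markers"
    )
  })
}

# Partition terminal cells into k lineage-contiguous subtree leaf sets.
partition_subtrees <- function(lineage, k) {
  idx_parent <- match(lineage$parent, lineage$cell)
  children <- split(which(!is.na(idx_parent)), idx_parent[!is.na(idx_parent)])
  ls <- leaf_sets(idx_parent, lineage$terminal)
  roots <- which(is.na(idx_parent))
  while (length(roots) < k) {
    splittable <- roots[lengths(ls[roots]) > 1L]
    pick <- splittable[which.max(lengths(ls[splittable]))]
    roots <- c(setdiff(roots, pick), children[[as.character(pick)]])
  }
  lapply(roots, function(r) lineage$cell[ls[[r]]])
}

#' Construct a marker set from explicit member lists
#'
#' For designed sorting schemes (e.g. a marker covering exactly the
#' early-born cells).  Members must be nonempty strict subsets of `cells`.
#'
#' @param members Named list of terminal-cell id vectors.
#' @param cells All terminal cell ids.
#' @param kinds Reporter kind per marker (recycled).
#' @param double_pair Two marker ids for the double-reporter strain (defaults
#'   to the first two markers).
#' @return A `popseq_markers`.
#' @export
as_markers <- function(members, cells, kinds = "translational",
                       double_pair = names(members)[1:2]) {
  stopifnot(length(members) >= 1, !is.null(names(members)))
  members <- lapply(members, function(m) sort(unique(as.character(m))))
  bad <- vapply(members, function(m) {
    length(m) == 0 || length(m) >= length(cells) || !all(m %in% cells)
  }, TRUE)
  if (any(bad)) {
    stop_invalid("marker member sets must be nonempty strict subsets of `cells`: %s",
                 paste(names(members)[bad], collapse = ", "))
  }
  ids <- names(members)
  ov <- if (length(ids) >= 2) {
    pairs <- t(utils::combn(ids, 2))
    tibble::tibble(
      marker_a = pairs[, 1], marker_b = pairs[, 2],
      n_overlap = apply(pairs, 1, function(p) {
        length(intersect(members[[p[1]]], members[[p[2]]]))
      })
    )
  } else {
    tibble::tibble(marker_a = character(), marker_b = character(),
                   n_overlap = integer())
  }
  structure(
    list(
      members = members,
      table = tibble::tibble(marker = rep(ids, lengths(members)),
                             cell = unlist(members, use.names = FALSE)),
      kinds = setNames(rep_len(kinds, length(ids)), ids),
      double_pair = double_pair,
      overlap = ov,
      mean_overlap = if (nrow(ov)) mean(ov$n_overlap) else NA_real_,
      cells = cells
    ),
    class = "popseq_markers"
  )
}

#' @export
print.popseq_markers <- function(x, ...) {
  cat(sprintf(
    "popseq markers: %d markers over %d cells; mean pairwise overlap %.1f cells\n",
    length(x$members), length(x$cells), x$mean_overlap
  ))
  invisible(x)
}
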