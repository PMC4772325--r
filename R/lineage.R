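#' Generate a synthetic embryonic cell lineage
#'
#' Builds a random binary cell lineage with `n_terminal` leaves, uniform
#' division times, and tissue labels assigned to whole subtrees so that every
#' tissue is lineage-contiguous (the property that makes overlapping reporter
#' fractions informative).
#'
#' @param n_terminal Number of terminal cells (leaves); at least 2.
#' @param total_time Total developmental time in minutes; terminal cells
#'   persist until this time.
#' @param n_tissues Number of tissue labels; each tissue is the leaf set of one
#'   subtree.  Defaults to 12 or `n_terminal`, whichever is smaller.
#' @param terminal_lifespan Minutes a terminal cell's expression window stays
#'   open after its birth (capped at `total_time`); gives tissues distinct
#'   temporal extents so whole-embryo time series show stage structure.
#' @param seed Integer seed; identical seeds give identical trees.
#'
#' @return A tibble of class `popseq_lineage` with one row per cell and columns
#'   `cell`, `parent` (`NA` for the root), `birth`, `end` (minutes),
#'   `terminal`, and `tissue` (`NA` for internal cells).
#' @examples
#' lin <- generate_lineage(16, seed = 1)
#' table(lineage_leaves(lin)$tissue)
#' @export
generate_lineage <- function(n_terminal, total_time = 400, n_tissues = min(12L, n_terminal),
                             terminal_lifespan = total_time * 0.4, seed = 1L) {
  if (!is.numeric(n_terminal) || n_terminal < 2) {
    stop_invalid("`n_terminal` must be at least 2")
  }
  n_terminal <- as.integer(n_terminal)
  n_tissues <- as.integer(n_tissues)
  if (n_tissues < 1 || n_tissues > n_terminal) {
    stop_invalid("`n_tissues` must be between 1 and `n_terminal`")
  }
  with_seed(seed, {
    n_nodes <- 2L * n_terminal - 1L
    parent <- rep(NA_integer_, n_nodes)
    n <- 1L                      # nodes created so far; node 1 is the root
    leaves <- 1L
    while (length(leaves) < n_terminal) {
      i <- leaves[sample.int(length(leaves), 1L)]
      kids <- c(n + 1L, n + 2L)
      parent[kids] <- i
      n <- n + 2L
      leaves <- c(setdiff(leaves, i), kids)
    }
    is_leaf <- !(seq_len(n_nodes) %in% parent)
    # Division times: a steady division clock assigned in depth-first order,
    # so each clade's divisions occupy a contiguous time block and tissues
    # form successive developmental waves (early- and late-born tissues).
    children <- split(which(!is.na(parent)), parent[!is.na(parent)])
    n_splits <- n_terminal - 1L
    dfs <- integer(0)
    stack <- 1L
    while (length(stack) > 0) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!is_leaf[i]) {
        dfs <- c(dfs, i)
        stack <- c(stack, rev(children[[as.character(i)]]))
      }
    }
    split_at <- rep(NA_real_, n_nodes)
    split_at[dfs] <- seq_len(n_splits) * (0.85 * total_time) / n_splits
    birth <- numeric(n_nodes)
    birth[!is.na(parent)] <- split_at[parent[!is.na(parent)]]
    end <- ifelse(is_leaf, pmin(birth + terminal_lifespan, total_time), split_at)

    # Tissues: split the tree into n_tissues subtrees, largest-first.
    children <- split(which(!is.na(parent)), parent[!is.na(parent)])
    leafset <- leaf_sets(parent, is_leaf)
    roots <- 1L
    while (length(roots) < n_tissues) {
      sizes <- lengths(leafset[roots])
      splittable <- roots[sizes > 1L]
      pick <- splittable[which.max(lengths(leafset[splittable]))]
      roots <- c(setdiff(roots, pick), children[[as.character(pick)]])
    }
    tissue <- rep(NA_character_, n_nodes)
    for (i in seq_along(roots)) {
      tissue[leafset[[roots[i]]]] <- sprintf("T%02d", i)
    }
    tissue[!is_leaf] <- NA_character_

    ids <- sprintf("c%04d", seq_len(n_nodes))
    out <- tibble::tibble(
      cell = ids,
      parent = ifelse(is.na(parent), NA_character_, ids[parent]),
      birth = birth,
      end = end,
      terminal = is_leaf,
      tissue = tissue
    )
    class(out) <- c("popseq_lineage", class(out))
    out
  })
}

# leaf set (node indices) under every node, bottom-up
leaf_sets <- function(parent, is_leaf) {
  n <- length(parent)
  out <- vector("list", n)
  for (i in n:1) {                      # children always have larger index
    if (is_leaf[i]) {
      out[[i]] <- i
    }
  }
  for (i in n:2) {
    p <- parent[i]
    out[[p]] <- c(out[[p]], out[[i]])
  }
  out
}

#' Terminal cells of a lineage
#'
#' @param lineage A `popseq_lineage` tibble.
#' @return The rows of `lineage` with `terminal == TRUE`.
#' @export
lineage_leaves <- function(lineage) {
  lineage[lineage$terminal, , drop = FALSE]
}

# Named list: for every internal or leaf node, the terminal cell ids beneath
# it (a leaf's set is itself).  Used for marker construction.
lineage_subtrees <- function(lineage) {
  idx <- match(lineage$parent, lineage$cell)
  ls <- leaf_sets(idx, lineage$terminal)
  setNames(lapply(ls, function(i) lineage$cell[i]), lineage$cell)
}
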