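#' Simulate a library of position weight matrices
#'
#' Draws `n_motifs` sharp PWMs with mutually distinct consensus words (no two
#' consensi equal or reverse complements of each other).  The first
#' `length(tfs)` motifs are assigned the given transcription-factor ids;
#' remaining motifs get synthetic TF ids and serve as decoys.
#'
#' @param n_motifs Number of motifs.
#' @param length Motif length in bp.
#' @param info Probability mass on the consensus base at each position.
#' @param tfs Optional character vector of TF gene ids for the first motifs.
#' @param seed Integer seed.
#' @return A list of class `popseq_pwm_list`; each element is a `popseq_pwm`:
#'   list(`id`, `tf`, `matrix` (4 x L probability matrix, rows ACGT),
#'   `background` (length-4 named)).
#' @export
simulate_pwm_library <- function(n_motifs, length = 8, info = 0.95,
                                 tfs = character(), seed = 1L) {
  stopifnot(n_motifs >= 1, length >= 3, info > 0.25, info <= 1)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    consensi <- character()
    tries <- 0L
    while (base::length(consensi) < n_motifs) {
      tries <- tries + 1L
      if (tries > 5e4) stop_invalid("could not draw %d mutually dissimilar consensi of length %d",
                                    n_motifs, length)
      w <- paste(sample(bases, length, replace = TRUE), collapse = "")
      if (all(vapply(consensi, word_dissimilar, TRUE, b = w))) {
        consensi <- c(consensi, w)
      }
    }
    pwms <- lapply(seq_len(n_motifs), function(i) {
      cons <- strsplit(consensi[i], "")[[1]]
      m <- matrix((1 - info) / 3, 4, length, dimnames = list(bases, NULL))
      m[cbind(match(cons, bases), seq_len(length))] <- info
      tf <- if (i <= base::length(tfs)) tfs[i] else sprintf("decoyTF%02d", i)
      structure(
        list(id = sprintf("M%03d", i), tf = tf, matrix = m,
             background = setNames(rep(0.25, 4), bases)),
        class = "popseq_pwm"
      )
    })
    names(pwms) <- vapply(pwms, `[[`, "", "id")
    structure(pwms, class = "popseq_pwm_list")
  })
}

# TRUE when two consensus words are dissimilar in every ungapped alignment
# and orientation: any overlap of >= 6 bases has >= 3 mismatches, any overlap
# of 4-5 bases has >= 2.  Keeps decoy motifs from rediscovering planted
# instances (the redundancy that motif dedup addresses in real libraries).
word_dissimilar <- function(a, b) {
  xa <- strsplit(a, "")[[1]]
  for (bb in c(b, unname(revcomp_string(b)))) {
    xb <- strsplit(bb, "")[[1]]
    for (off in -(length(xb) - 4):(length(xa) - 4)) {
      ia <- max(1, off + 1):min(length(xa), off + length(xb))
      ib <- ia - off
      o <- length(ia)
      matches <- sum(xa[ia] == xb[ib])
      if (o >= 7 && matches > o - 3) return(FALSE)
      if (o == 6 && matches > 4) return(FALSE)
      if (o < 6 && matches > o - 1) return(FALSE)
    }
  }
  TRUE
}

revcomp_string <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, ""))
}

#' Consensus word of a PWM
#' @param pwm A `popseq_pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)], collapse = "")
}

#' Default planted-regulation rules for a synthetic truth
#'
#' Maps tissue pattern `i` to motif `i` of the library, with distance bands,
#' conservation levels and ChIP-peak flags cycled over the grid the enrichment
#' analysis searches.  The motif's TF is the pattern's regulator gene.  Motifs
#' beyond the number of patterns are decoys (recorded in the `decoys`
#' attribute).
#'
#' @param truth A `popseq_truth`.
#' @param pwms A `popseq_pwm_list` with at least as many motifs as patterns.
#' @param distance_bands List of `c(min, max)` upstream-distance bands (bp),
#'   cycled across patterns.
#' @param conservation_levels Conservation score of planted instances, cycled.
#' @param peak Logical; emit a ChIP peak over planted instances.
#' @return Tibble (`pattern`, `motif`, `tf`, `dist_min`, `dist_max`,
#'   `conservation`, `peak`) of class `popseq_rules`, with attribute `decoys`.
#' @export
default_regulation_rules <- function(truth, pwms,
                                     distance_bands = list(c(50, 900), c(1050, 1900), c(2050, 2900)),
                                     conservation_levels = c(0.8, 0.9, 0.95),
                                     peak = TRUE) {
  stopifnot(inherits(truth, "popseq_truth"))
  np <- nrow(truth$patterns)
  if (length(pwms) < np) stop_invalid("need at least %d motifs", np)
  bands <- distance_bands[(seq_len(np) - 1L) %% length(distance_bands) + 1L]
  rules <- tibble::tibble(
    pattern = truth$patterns$pattern,
    motif = names(pwms)[seq_len(np)],
    tf = truth$patterns$regulator,
    dist_min = vapply(bands, `[`, 0, 1),
    dist_max = vapply(bands, `[`, 0, 2),
    conservation = conservation_levels[(seq_len(np) - 1L) %% length(conservation_levels) + 1L],
    peak = peak
  )
  attr(rules, "decoys") <- setdiff(names(pwms), rules$motif)
  class(rules) <- c("popseq_rules", class(rules))
  rules
}

#' Generate promoter sequences with planted motifs, conservation and peaks
#'
#' Emits an i.i.d. background promoter (upstream) sequence per gene, with the
#' consensus of each pattern's motif planted at a distance drawn from the
#' rule's band, on a random strand, for every gene of the pattern.  A per-base
#' conservation track is low-background everywhere and elevated to the rule's
#' level over planted instances; ChIP peaks (named by the rule's TF) are
#' emitted over planted instances when flagged.
#'
#' Coordinates of the conservation and peak tracks are promoter-relative: the
#' "chromosome" is the gene id and position `upstream_len` is the TSS (the
#' sequence reads 5' to 3' into the gene).  A window ending at the last base
#' is at distance 1 from the TSS.
#'
#' @param truth A `popseq_truth`.
#' @param pwms A `popseq_pwm_list`.
#' @param rules Planted-regulation rules, e.g. [default_regulation_rules()].
#' @param upstream_len Promoter length in bp; must cover the largest rule
#'   distance band.
#' @param gc Background GC content.
#' @param background_conservation Range (min, max) of the per-gene background
#'   conservation level.
#' @param seed Integer seed.
#' @return A list of class `popseq_sequences`: `sequences`
#'   (`Biostrings::DNAStringSet`, one per gene), `conservation` (tibble
#'   `chrom`, `start`, `end`, `score`; 0-based half-open), `peaks` (BED6-style
#'   tibble `chrom`, `start`, `end`, `name` = TF id, `score`, `strand`),
#'   `planted` (truth tibble of planted instances), `rules`, `upstream_len`.
#' @export
generate_sequences <- function(truth, pwms, rules = default_regulation_rules(truth, pwms),
                               upstream_len = 3000, gc = 0.36,
                               background_conservation = c(0.02, 0.3),
                               seed = 1L) {
  stopifnot(inherits(truth, "popseq_truth"))
  if (!all(rules$motif %in% names(pwms))) {
    stop_invalid("rule references unknown motif: %s",
                 paste(setdiff(rules$motif, names(pwms)), collapse = ", "))
  }
  if (upstream_len < max(rules$dist_max)) {
    stop_invalid("`upstream_len` must cover the largest rule distance band")
  }
  genes <- truth$genes$gene
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(genes, function(g) {
      paste(sample(bases, upstream_len, replace = TRUE, prob = probs), collapse = "")
    }, "")
    bg_cons <- runif(length(genes), background_conservation[1], background_conservation[2])
    planted <- list()
    for (i in seq_len(nrow(rules))) {
      targets <- genes[truth$genes$pattern == rules$pattern[i]]
      if (length(targets) == 0) next
      pwm <- pwms[[rules$motif[i]]]
      cons_word <- pwm_consensus(pwm)
      L <- nchar(cons_word)
      for (g in targets) {
        d <- sample(seq(rules$dist_min[i], min(rules$dist_max[i], upstream_len - L + 1)), 1L)
        s <- upstream_len - d - L + 2L      # 1-based window start
        strand <- sample(c("+", "-"), 1L)
        word <- if (strand == "+") cons_word else revcomp_string(cons_word)
        substr(seqs[[g]], s, s + L - 1L) <- word
        planted[[length(planted) + 1L]] <- tibble::tibble(
          pattern = rules$pattern[i], motif = rules$motif[i], tf = rules$tf[i],
          gene = g, distance = d, strand = strand,
          start = s - 1L, end = s + L - 1L,      # 0-based half-open
          conservation = rules$conservation[i], peak = rules$peak[i]
        )
      }
    }
    planted <- if (length(planted)) dplyr::bind_rows(planted) else
      tibble::tibble(pattern = character(), motif = character(), tf = character(),
                     gene = character(), distance = integer(), strand = character(),
                     start = integer(), end = integer(),
                     conservation = double(), peak = logical())

    # conservation track: per-gene background interval, overridden over
    # planted windows
    cons <- lapply(seq_along(genes), function(j) {
      g <- genes[j]
      pl <- planted[planted$gene == g, , drop = FALSE]
      if (nrow(pl) == 0) {
        return(tibble::tibble(chrom = g, start = 0L, end = upstream_len,
                              score = bg_cons[j]))
      }
      pl <- pl[order(pl$start), , drop = FALSE]
      starts <- c(0L, pl$end)
      ends <- c(pl$start, upstream_len)
      bg <- tibble::tibble(chrom = g, start = starts, end = ends, score = bg_cons[j])
      hi <- tibble::tibble(chrom = g, start = pl$start, end = pl$end,
                           score = pl$conservation)
      out <- dplyr::bind_rows(bg[bg$end > bg$start, ], hi)
      out[order(out$start), ]
    })
    conservation <- dplyr::bind_rows(cons)

    pk <- planted[planted$peak, , drop = FALSE]
    peaks <- tibble::tibble(
      chrom = pk$gene,
      start = pmax(0L, pk$start - 50L),
      end = pmin(upstream_len, pk$end + 50L),
      name = unname(pk$tf), score = 1000L, strand = "."
    )
    structure(
      list(
        sequences = Biostrings::DNAStringSet(seqs),
        conservation = conservation,
        peaks = peaks,
        planted = planted,
        rules = rules,
        upstream_len = upstream_len
      ),
      class = "popseq_sequences"
    )
  })
}

#' Whole-embryo expression time series from lineage truth
#'
#' Expression of gene g at time t is the sum of per-cell abundance over
#' terminal cells alive at t (birth <= t <= end), so genes restricted to
#' late-born tissues peak late and a ubiquitous gene's profile is proportional
#' to the number of live terminal cells.
#'
#' @param truth A `popseq_truth`.
#' @param lineage The lineage (defaults to the one inside `truth`).
#' @param n_timepoints Number of equally spaced timepoints (>= 3).
#' @return A list of class `popseq_timeseries`: `values` (genes x timepoints
#'   matrix) and `time` (minutes).
#' @export
generate_timeseries <- function(truth, lineage = truth$lineage, n_timepoints = 21) {
  stopifnot(inherits(truth, "popseq_truth"))
  if (n_timepoints < 3) stop_invalid("`n_timepoints` must be >= 3")
  leaves <- lineage_leaves(lineage)
  times <- seq(0, max(leaves$end), length.out = n_timepoints)
  alive <- outer(leaves$birth, times, `<=`) & outer(leaves$end, times, `>=`)
  values <- truth$expr[, leaves$cell, drop = FALSE] %*% (alive * 1)
  colnames(values) <- sprintf("t%03d", round(times))
  structure(list(values = values, time = times), class = "popseq_timeseries")
}
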