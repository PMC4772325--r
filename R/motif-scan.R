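# PWM scanning with exact score p-values.
#
# Scores are log2 odds against the background, quantized to a common integer
# grid (bin width = score range / n_bins).  The null distribution of the
# quantized window score over i.i.d. background sequence is computed exactly
# by dynamic programming (convolution across motif positions), and the
# p-value of a window is the tail mass at its quantized score.  Using the
# same quantization for the null and for observed windows makes the DP
# distribution exact for the score actually used, so it matches brute-force
# enumeration over all 4^L words.

# log-odds matrix with a probability floor applied (then renormalized)
pwm_log_odds <- function(pwm, floor = 1e-3) {
  m <- pwm$matrix
  m <- m + floor
  m <- sweep(m, 2, colSums(m), "/")
  log2(m / pwm$background)
}

# quantized integer score matrix + bin width
pwm_quantize <- function(lo, n_bins = 1e4) {
  rng <- sum(apply(lo, 2, max)) - sum(apply(lo, 2, min))
  delta <- max(rng, .Machine$double.eps) / n_bins
  list(q = round(lo / delta), delta = delta)
}

# Exact null distribution of the quantized score under the background.
# Returns function(score_int) -> P[S >= score_int].
pwm_null_tail <- function(q, background) {
  offset <- sum(apply(q, 2, min))
  width <- sum(apply(q, 2, max)) - offset
  dist <- numeric(width + 1)        # index i -> score offset + i - 1
  dist[1] <- 1
  pos_in_use <- 0L
  for (j in seq_len(ncol(q))) {
    newdist <- numeric(width + 1)
    qj <- q[, j] - min(q[, j])
    for (b in 1:4) {
      s <- qj[b]
      idx <- seq_len(pos_in_use + 1L)
      newdist[idx + s] <- newdist[idx + s] + dist[idx] * background[b]
    }
    pos_in_use <- pos_in_use + max(qj)
    dist <- newdist
  }
  tail_mass <- rev(cumsum(rev(dist)))
  ext <- c(1, tail_mass, 0)       # index 1 = below range, last = above range
  len <- length(tail_mass)
  function(score_int) {
    i <- score_int - offset + 2L  # into ext
    i[i < 1L] <- 1L
    i[i > len + 2L] <- len + 2L
    ext[i]
  }
}

# reverse-complement of a PWM probability matrix (rows ACGT)
pwm_revcomp <- function(m) {
  m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Scan promoter sequences with a PWM, with exact score p-values
#'
#' Scores every window on both strands with the PWM's log2-odds against its
#' background, computes the exact p-value of each score under the null of
#' i.i.d. background sequence (dynamic programming over quantized scores), and
#' reports windows with `p <= p_threshold`.  Windows containing N are
#' skipped.  The reported `distance` is the bp from the window's TSS-proximal
#' edge to the TSS, taking the end of each promoter sequence as the TSS (a
#' window ending at the last base has distance 1).  If a conservation track is
#' supplied (promoter-relative bedGraph intervals: `chrom` = gene id,
#' 0-based half-open), each hit carries the mean per-base conservation over
#' its window.
#'
#' @param sequences A `Biostrings::DNAStringSet` (one promoter per gene, names
#'   = gene ids), a named character vector, or a `popseq_sequences` object.
#' @param pwm A `popseq_pwm`.
#' @param p_threshold Report hits with score p-value at or below this.
#' @param conservation Optional conservation tibble (`chrom`, `start`, `end`,
#'   `score`); taken from `sequences` when it is a `popseq_sequences`.
#' @param n_bins Score-quantization bins for the DP (default 1e4).
#' @param floor Probability floor added to PWM entries before log-odds.
#' @return Tibble of class `popseq_hits`: `motif`, `gene`, `distance`,
#'   `strand`, `score` (log2 odds), `p`, `conservation`.
#' @export
scan_pwm <- function(sequences, pwm, p_threshold = 1e-3, conservation = NULL,
                     n_bins = 1e4, floor = 1e-3) {
  stopifnot(inherits(pwm, "popseq_pwm"))
  if (p_threshold <= 0 || p_threshold > 1) {
    stop_invalid("`p_threshold` must lie in (0, 1]")
  }
  if (inherits(sequences, "popseq_sequences")) {
    if (is.null(conservation)) conservation <- sequences$conservation
    sequences <- sequences$sequences
  }
  enc <- if (inherits(sequences, "popseq_encoded")) {
    sequences
  } else {
    seqs <- setNames(as.character(sequences), names(sequences))
    if (is.null(names(seqs))) stop_invalid("sequences must be named by gene id")
    encode_sequences(seqs)
  }

  lo <- pwm_log_odds(pwm, floor)
  qz <- pwm_quantize(lo, n_bins)
  tail_fun <- pwm_null_tail(qz$q, pwm$background)
  L <- ncol(lo)

  hit_rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") qz$q else pwm_revcomp(qz$q)
    sc <- window_scores(enc, q)
    keep <- which(!is.na(sc))
    if (length(keep) == 0) next
    p <- tail_fun(sc[keep])
    sel <- keep[p <= p_threshold]
    if (length(sel) == 0) next
    gene_idx <- enc$gene_of[sel]
    # window [pos, pos + L - 1] within the gene's promoter (1-based)
    pos <- sel - enc$offset[gene_idx]
    dist <- unname(enc$len)[gene_idx] - (pos + L - 1L) + 1L
    ok <- dist >= 1L & pos >= 1L
    hit_rows[[strand]] <- tibble::tibble(
      motif = pwm$id,
      gene = enc$genes[gene_idx[ok]],
      distance = dist[ok],
      strand = strand,
      score = (sc[sel] * qz$delta)[ok],
      p = tail_fun(sc[sel])[ok],
      start0 = (pos[ok] - 1L),
      end0 = pos[ok] + L - 1L
    )
  }
  hits <- if (length(hit_rows)) dplyr::bind_rows(hit_rows) else
    tibble::tibble(motif = character(), gene = character(), distance = integer(),
                   strand = character(), score = double(), p = double(),
                   start0 = integer(), end0 = integer())
  hits$conservation <- if (!is.null(conservation) && nrow(hits) > 0) {
    mean_conservation(conservation, hits$gene, hits$start0, hits$end0,
                      setNames(enc$len, enc$genes))
  } else {
    rep(NA_real_, nrow(hits))
  }
  hits <- hits[order(hits$gene, hits$distance, hits$strand), ]
  hits$start0 <- hits$end0 <- NULL
  class(hits) <- c("popseq_hits", class(hits))
  hits
}

#' Scan a whole PWM library
#'
#' @param sequences See [scan_pwm()].
#' @param pwms A `popseq_pwm_list`.
#' @inheritParams scan_pwm
#' @return Row-bound `popseq_hits` tibble over all motifs.
#' @export
scan_pwm_set <- function(sequences, pwms, p_threshold = 1e-3,
                         conservation = NULL, n_bins = 1e4, floor = 1e-3) {
  if (inherits(sequences, "popseq_sequences")) {
    if (is.null(conservation)) conservation <- sequences$conservation
    sequences <- sequences$sequences
  }
  # encode once for the whole library scan
  enc <- encode_sequences(setNames(as.character(sequences), names(sequences)))
  out <- purrr::map_dfr(pwms, scan_pwm, sequences = enc,
                        p_threshold = p_threshold, conservation = conservation,
                        n_bins = n_bins, floor = floor)
  class(out) <- unique(c("popseq_hits", class(out)))
  out
}

# Concatenate promoters (separated by NA sentinels) into one integer vector.
encode_sequences <- function(seqs) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop_invalid("sequence alphabet outside {A,C,G,T,N} in: %s",
                 paste(head(names(seqs)[bad], 3), collapse = ", "))
  }
  lens <- nchar(seqs)
  n <- length(seqs)
  sep <- 1L                                    # one NA between genes
  total <- sum(lens) + sep * n
  code <- rep(NA_integer_, total)
  gene_of <- rep(NA_integer_, total)
  offset <- integer(n)
  cursor <- 0L
  lookup <- setNames(1:4, c("A", "C", "G", "T"))
  for (i in seq_len(n)) {
    x <- lookup[strsplit(seqs[[i]], "")[[1]]]
    code[cursor + seq_along(x)] <- unname(x)   # non-ACGT -> NA
    gene_of[cursor + seq_along(x)] <- i
    offset[i] <- cursor
    cursor <- cursor + lens[i] + sep
  }
  code0 <- code
  code0[is.na(code0)] <- 1L
  structure(
    list(code = code, code0 = code0, cumna = cumsum(is.na(code)),
         gene_of = gene_of, offset = offset,
         genes = names(seqs), len = lens),
    class = "popseq_encoded"
  )
}

# Quantized window scores at every start position (NA where the window
# crosses a boundary or contains N).
window_scores <- function(enc, q) {
  L <- ncol(q)
  n <- length(enc$code0)
  if (n < L) return(numeric(0))
  m <- n - L + 1
  q <- unname(q)
  sc <- q[, 1][enc$code0[1:m]]
  for (j in 2:L) {
    sc <- sc + q[, j][enc$code0[j:(m + j - 1)]]
  }
  # window contains an N or crosses a gene boundary iff any NA inside
  n_na <- enc$cumna[L:n] - c(0, enc$cumna[1:(m - 1)])
  sc[n_na > 0] <- NA
  sc
}

# Mean conservation over windows, from per-gene interval tracks.
mean_conservation <- function(track, genes, start0, end0, lens) {
  ug <- unique(genes)
  cums <- lapply(ug, function(g) {
    tr <- track[track$chrom == g, , drop = FALSE]
    len <- lens[[g]]
    base <- numeric(len)
    if (nrow(tr) > 0) {
      for (i in seq_len(nrow(tr))) {
        a <- max(tr$start[i] + 1L, 1L); b <- min(tr$end[i], len)
        if (b >= a) base[a:b] <- tr$score[i]
      }
    }
    cumsum(c(0, base))
  })
  names(cums) <- ug
  vapply(seq_along(genes), function(i) {
    cs <- cums[[genes[i]]]
    a <- start0[i] + 1L; b <- end0[i]
    (cs[b + 1L] - cs[a]) / (b - a + 1L)
  }, 0)
}

#' Read PWMs from MEME minimal motif format
#'
#' Parses the MEME minimal text format (`MOTIF` blocks with letter-probability
#' matrices) into a `popseq_pwm_list`.  The alternate name on the MOTIF line,
#' when present, is taken as the TF id.
#'
#' @param path File path.
#' @return A `popseq_pwm_list`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- setNames(rep(0.25, 4), c("A", "C", "G", "T"))
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) > 0) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    bg <- setNames(as.numeric(tok[c(2, 4, 6, 8)]), tok[c(1, 3, 5, 7)])[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop_invalid("no MOTIF blocks in %s", path)
  pwms <- lapply(seq_along(starts), function(i) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    id <- hdr[2]
    tf <- if (length(hdr) >= 3) hdr[3] else id
    j <- starts[i]
    while (j <= length(lines) && !grepl("^letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines)) stop_invalid("motif %s lacks a letter-probability matrix", id)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1):(j + w)]
    m <- vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                numeric(4))
    dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
    structure(
      list(id = id, tf = tf, matrix = m, background = bg),
      class = "popseq_pwm"
    )
  })
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  structure(pwms, class = "popseq_pwm_list")
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms A `popseq_pwm_list`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$background
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg["A"], bg["C"], bg["G"], bg["T"]),
    ""
  )
  for (p in pwms) {
    out <- c(out,
             sprintf("MOTIF %s %s", p$id, p$tf),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     ncol(p$matrix)),
             apply(p$matrix, 2, function(col) sprintf(" %.8f %.8f %.8f %.8f",
                                                      col[1], col[2], col[3], col[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
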