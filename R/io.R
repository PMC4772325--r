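# Readers and writers for the interchange formats: genes x samples TSV,
# class sidecar TSV, sort-scheme YAML, lineage TSV, GMT gene sets, FASTA
# promoters (Biostrings), and BED6 / bedGraph tracks (rtracklayer).  All
# genomic intervals are 0-based half-open internally (BED native).

#' Write / read a genes-by-samples matrix as TSV
#'
#' TSV with a one-line header; first column `gene`, remaining columns are
#' sample (or experiment) ids.
#'
#' @param m Numeric matrix with gene rownames.
#' @param path File path.
#' @return `write_matrix_tsv`: `path` invisibly; `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  as_gene_matrix(as.data.frame(df))
}

#' Write / read a gene-class sidecar TSV (`gene`, `class`)
#'
#' @param classes Named character vector gene -> class.
#' @param path File path.
#' @return `write_gene_classes`: `path` invisibly; `read_gene_classes`: named
#'   character vector.
#' @export
write_gene_classes <- function(classes, path) {
  readr::write_tsv(tibble::tibble(gene = names(classes), class = unname(classes)),
                   path)
  invisible(path)
}

#' @rdname write_gene_classes
#' @export
read_gene_classes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  setNames(df$class, df$gene)
}

#' Write / read a sort scheme as YAML
#'
#' @param scheme A `popseq_scheme`.
#' @param path File path.
#' @return `write_scheme_yaml`: `path` invisibly; `read_scheme_yaml`: a
#'   `popseq_scheme`.
#' @export
write_scheme_yaml <- function(scheme, path) {
  stopifnot(inherits(scheme, "popseq_scheme"))
  obj <- list(
    singlet_sample = scheme$singlet_sample,
    ungated_sample = scheme$ungated_sample,
    double_pair = as.list(scheme$double_pair),
    bias_tissue = scheme$bias_tissue,
    experiments = purrr::transpose(as.list(scheme$experiments))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_scheme_yaml
#' @export
read_scheme_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  ex <- purrr::map_dfr(obj$experiments, function(e) {
    tibble::as_tibble(lapply(e, function(v) if (is.null(v)) NA else v))
  })
  structure(
    list(
      experiments = ex,
      singlet_sample = obj$singlet_sample,
      ungated_sample = obj$ungated_sample,
      double_pair = unlist(obj$double_pair),
      bias_tissue = obj$bias_tissue
    ),
    class = "popseq_scheme"
  )
}

#' Write / read a lineage as TSV
#'
#' Columns `cell`, `parent`, `birth`, `end`, `terminal`, `tissue`.
#'
#' @param lineage A `popseq_lineage`.
#' @param path File path.
#' @return `write_lineage_tsv`: `path` invisibly; `read_lineage_tsv`: a
#'   `popseq_lineage`.
#' @export
write_lineage_tsv <- function(lineage, path) {
  readr::write_tsv(as.data.frame(lineage), path)
  invisible(path)
}

#' @rdname write_lineage_tsv
#' @export
read_lineage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          cell = "c", parent = "c", tissue = "c",
                          birth = "d", end = "d", terminal = "l"
                        ))
  out <- tibble::as_tibble(df)
  class(out) <- c("popseq_lineage", class(out))
  out
}

#' Write / read gene sets in GMT format
#'
#' One set per line: term, description, then member genes, tab-separated.
#' Reading uses `fgsea::gmtPathways()` and rejects duplicate term ids.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @return `write_gmt`: `path` invisibly; `read_gmt`: named list.
#' @export
write_gmt <- function(sets, path) {
  if (anyDuplicated(names(sets))) {
    stop_invalid("duplicate term id(s): %s",
                 paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  terms <- vapply(strsplit(readLines(path), "\t"), `[`, "", 1)
  dup <- unique(terms[duplicated(terms)])
  if (length(dup) > 0) {
    stop_invalid("duplicate term id(s) in %s: %s", path, paste(dup, collapse = ", "))
  }
  fgsea::gmtPathways(path)
}

#' Write / read promoter sequences as FASTA
#'
#' @param sequences A named `Biostrings::DNAStringSet` or character vector.
#' @param path File path.
#' @return `write_fasta`: `path` invisibly; `read_fasta`: a `DNAStringSet`.
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

# tibble (chrom, start, end, ...) -> GRanges (0-based half-open in, 1-based in
# GRanges)
track_to_granges <- function(df) {
  if (any(df$start >= df$end)) {
    bad <- which(df$start >= df$end)[1]
    stop_invalid("interval with start >= end at row %d (%s:%d-%d)",
                 bad, df$chrom[bad], df$start[bad], df$end[bad])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  gr
}

granges_to_track <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Write / read a bedGraph conservation track
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `score`.
#'
#' @param track Tibble with `chrom`, `start`, `end`, `score`.
#' @param path File path.
#' @return `write_bedgraph`: `path` invisibly; `read_bedgraph`: the tibble.
#' @export
write_bedgraph <- function(track, path) {
  gr <- track_to_granges(track)
  gr$score <- track$score
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- granges_to_track(gr)
  out$score <- gr$score
  out
}

#' Write / read BED6 peaks
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `name` (TF id),
#' `score`, `strand`.
#'
#' @param peaks BED6-style tibble.
#' @param path File path.
#' @return `write_bed`: `path` invisibly; `read_bed`: the tibble.
#' @export
write_bed <- function(peaks, path) {
  gr <- track_to_granges(peaks)
  gr$name <- peaks$name
  gr$score <- peaks$score %||% 0
  GenomicRanges::strand(gr) <- ifelse(peaks$strand %in% c("+", "-"), peaks$strand, "*")
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_track(gr)
  out$name <- gr$name
  out$score <- if (is.null(gr$score)) 0 else gr$score
  st <- as.character(GenomicRanges::strand(gr))
  out$strand <- ifelse(st == "*", ".", st)
  out
}
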