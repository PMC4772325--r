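test_that("DP score p-values equal brute-force enumeration over all words", {
  for (L in c(3, 5)) {
    pwm <- simulate_pwm_library(1, length = L, info = 0.9, seed = L)[[1]]
    lo <- popseq:::pwm_log_odds(pwm, 1e-3)
    qz <- popseq:::pwm_quantize(lo, 1e4)
    tail_fun <- popseq:::pwm_null_tail(qz$q, pwm$background)
    scores <- sort(unique(as.vector(qz$q %*% diag(ncol(qz$q)))))
    probe <- unique(c(sum(apply(qz$q, 2, min)), sum(apply(qz$q, 2, max)),
                      round(seq(sum(apply(qz$q, 2, min)),
                                sum(apply(qz$q, 2, max)), length.out = 25))))
    expect_equal(tail_fun(probe), pwm_enum_tail(pwm, probe), tolerance = 1e-12,
                 info = sprintf("L=%d", L))
  }
})

test_that("a near-indicator motif gives p(max score) = 1/64", {
  bases <- c("A", "C", "G", "T")
  m <- matrix(0.001, 4, 3, dimnames = list(bases, NULL))
  m[cbind(c(1, 3, 4), 1:3)] <- 0.997
  pwm <- structure(list(id = "ind", tf = "ind", matrix = m,
                        background = setNames(rep(0.25, 4), bases)),
                   class = "popseq_pwm")
  qz <- popseq:::pwm_quantize(popseq:::pwm_log_odds(pwm, 1e-3), 1e4)
  tail_fun <- popseq:::pwm_null_tail(qz$q, pwm$background)
  max_score <- sum(apply(qz$q, 2, max))
  expect_equal(tail_fun(max_score), 1 / 64, tolerance = 1e-12)
})

test_that("scanning finds a planted consensus with the correct distance and strand", {
  pwm <- simulate_pwm_library(1, length = 6, info = 0.97, seed = 9)[[1]]
  cons <- pwm_consensus(pwm)
  bg <- strrep("A", 40)
  seqs <- c(gX = paste0(bg, cons, strrep("C", 10)))   # ends 10 bp before TSS
  hits <- scan_pwm(seqs, pwm, p_threshold = 1e-3)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$gene, "gX")
  expect_equal(hits$strand, "+")
  expect_equal(hits$distance, 11L)        # window end at base 46 of 56
  # reverse-complement sequence: same hit on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[[1]])))
  hits_rc <- scan_pwm(c(gX = rc), pwm, p_threshold = 1e-3)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$score, hits$score, tolerance = 1e-9)
  # no above-threshold window in pure background
  expect_equal(nrow(scan_pwm(c(g0 = strrep("A", 60)), pwm, 1e-3)), 0)
  # windows containing N are skipped, others still reported
  withN <- c(gN = paste0(strrep("N", 6), bg, cons))
  expect_equal(nrow(scan_pwm(withN, pwm, 1e-3)), 1)
  expect_invalid(scan_pwm(c(bad = "ACGTXZ"), pwm))
})

test_that("hit conservation averages the per-base track over the window", {
  pwm <- simulate_pwm_library(1, length = 4, info = 0.97, seed = 2)[[1]]
  cons <- pwm_consensus(pwm)
  seqs <- c(g1 = paste0(strrep("A", 16), cons))
  track <- tibble::tibble(chrom = "g1", start = c(0L, 16L), end = c(16L, 20L),
                          score = c(0.1, 0.9))
  hits <- scan_pwm(seqs, pwm, p_threshold = 1e-2, conservation = track)
  expect_equal(hits$conservation[hits$distance == 1], 0.9)
})

test_that("motif similarity collapses duplicates and keeps distinct motifs", {
  pwms <- simulate_pwm_library(3, length = 8, seed = 4)
  dup <- pwms[[1]]
  dup$id <- "M000"                        # lexicographically first
  lib <- c(pwms, list(M000 = dup))
  class(lib) <- "popseq_pwm_list"
  res <- motif_similarity_dedup(lib)
  expect_equal(sort(res$mapping$representative[res$mapping$motif %in% c("M001", "M000")]),
               c("M000", "M000"))          # merged, first id kept
  expect_equal(length(res$representatives), 3)
  expect_equal(pwm_similarity(pwms[[1]], pwms[[1]]), 1, tolerance = 1e-12)
})

test_that("shifted-motif similarity matches a brute-force offset oracle", {
  bases <- c("A", "C", "G", "T")
  flat <- rep(0.25, 4)
  colA <- c(0.85, 0.05, 0.05, 0.05); colC <- c(0.05, 0.85, 0.05, 0.05)
  colG <- c(0.05, 0.05, 0.85, 0.05)
  mk <- function(cols) {
    m <- do.call(cbind, cols); rownames(m) <- bases
    structure(list(id = "x", tf = "x", matrix = m,
                   background = setNames(flat, bases)), class = "popseq_pwm")
  }
  a <- mk(list(colA, colC, colG, flat))
  b <- mk(list(flat, colA, colC, colG))   # a shifted right by one
  # oracle: enumerate every ungapped offset and orientation by hand
  oracle <- -Inf
  for (mb in list(b$matrix, popseq:::pwm_revcomp(b$matrix))) {
    for (off in -(4 - 4):(4 - 4)) oracle <- max(oracle, {
      cc <- vapply(1:4, function(t) {
        x <- a$matrix[, t]; y <- mb[, t]
        if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)
      }, 0)
      mean(cc)
    })
  }
  # with min_overlap = 4 only the zero offset is allowed for L = 4
  expect_equal(pwm_similarity(a, b, min_overlap = 4), oracle, tolerance = 1e-12)
  # allowing shorter overlaps discovers the shifted alignment (3 perfect cols)
  expect_gt(pwm_similarity(a, b, min_overlap = 3), oracle)
})

test_that("grid presence follows the cutoff definitions and is monotone", {
  hits <- tibble::tibble(
    motif = "M1", gene = "g1", distance = 1500L, strand = "+",
    score = 10, p = 10^(-3.6), conservation = 0.8
  )
  pres <- gene_hit_presence(hits, default_grid())
  at <- function(d, c, s) {
    nrow(pres[pres$distance_cut == d & pres$conservation_cut == c &
                pres$score_cut == s, ])
  }
  expect_equal(at(2000, 0.7, 35), 1)
  expect_equal(at(1000, 0.7, 35), 0)     # too far
  expect_equal(at(2000, 0.9, 35), 0)     # not conserved enough
  expect_equal(at(2000, 0.7, 40), 0)     # score too weak
  # no hits, no presence
  expect_equal(nrow(gene_hit_presence(hits[0, ], default_grid())), 0)
  # monotone: presence at a stricter cell implies presence at looser cells
  set.seed(12)
  rhits <- tibble::tibble(
    motif = sample(c("A", "B"), 40, TRUE), gene = sample(sprintf("g%d", 1:8), 40, TRUE),
    distance = sample(100:3500, 40), strand = "+",
    score = 10, p = 10^(-runif(40, 2.5, 5)), conservation = runif(40)
  )
  pres_r <- gene_hit_presence(rhits, default_grid())
  grid <- default_grid()
  key <- function(df) paste(df$motif, df$gene, df$distance_cut,
                            df$conservation_cut, df$score_cut)
  have <- key(pres_r)
  for (i in seq_len(nrow(pres_r))) {
    row <- pres_r[i, ]
    for (d in grid$distance[grid$distance >= row$distance_cut]) {
      for (cc in grid$conservation[grid$conservation <= row$conservation_cut]) {
        for (s in grid$score[grid$score <= row$score_cut]) {
          expect_true(paste(row$motif, row$gene, d, cc, s) %in% have)
        }
      }
    }
  }
})

test_that("motif-cluster enrichment has the right degenerate behavior", {
  genes <- sprintf("g%02d", 1:40)
  cl <- list(clusters = setNames(rep(c("C001", "C002"), each = 20), genes),
             sizes = table(rep(c("C001", "C002"), each = 20)))
  class(cl) <- "popseq_clustering"
  everywhere <- tidyr::expand_grid(motif = "M1", gene = genes,
                                   distance_cut = 1000, conservation_cut = 0,
                                   score_cut = 30)
  res <- motif_cluster_enrichment(everywhere, cl, genes)
  expect_true(all(res$p == 1))
  one_cluster <- everywhere[everywhere$gene %in% genes[1:20], ]
  one_cluster$motif <- "M2"
  res2 <- motif_cluster_enrichment(dplyr::bind_rows(everywhere, one_cluster),
                                   cl, genes)
  best <- res2[which.min(res2$p), ]
  expect_equal(best$motif, "M2")
  expect_equal(best$cluster, "C001")
})

test_that("ChIP peaks bind genes through upstream windows by distance", {
  genes <- sprintf("g%02d", 1:30)
  cl <- list(clusters = setNames(rep(c("C001", "C002", "C003"), each = 10), genes),
             sizes = table(rep(c("C001", "C002", "C003"), each = 10)))
  class(cl) <- "popseq_clustering"
  plen <- 3000
  peaks <- tibble::tibble(
    chrom = genes[1:10], start = plen - 600, end = plen - 400,
    name = "TF1", score = 1000, strand = "."
  )
  res <- chip_cluster_enrichment(peaks, cl, genes, promoter_len = plen)
  expect_equal(res$cluster[which.min(res$p)], "C001")
  # a peak 2500 bp upstream binds only at the 3 kb distance
  far <- tibble::tibble(chrom = "g01", start = plen - 2600, end = plen - 2450,
                        name = "TF2", score = 0, strand = ".")
  res_far <- chip_cluster_enrichment(far, cl, genes, promoter_len = plen)
  expect_true(all(res_far$distance_cut[res_far$tf == "TF2" & res_far$k > 0] == 3000))
  expect_invalid(chip_cluster_enrichment(far[, 1:2], cl, genes, plen))
})

test_that("positional and conservation bias tests detect planted shifts", {
  set.seed(7)
  hits <- tibble::tibble(
    motif = "M1",
    gene = c(sprintf("in%02d", 1:50), sprintf("out%02d", 1:50)),
    distance = c(sample(1:500, 50, TRUE), sample(1:3000, 50, TRUE)),
    strand = "+", score = 10, p = 1e-4,
    conservation = c(rep(0.9, 50), rep(0.1, 50))
  )
  res <- positional_conservation_bias(hits, "M1", sprintf("in%02d", 1:50),
                                      sprintf("out%02d", 1:50))
  d <- res[res$metric == "distance", ]
  expect_lt(d$p, 0.01)
  expect_equal(d$direction, "nearer")
  cc <- res[res$metric == "conservation", ]
  expect_lt(cc$p, 1e-10)
  expect_equal(cc$direction, "more_conserved")
  # identical samples on both sides: no signal
  same <- positional_conservation_bias(hits, "M1", hits$gene, hits$gene)
  expect_gt(same$p[1], 0.9)
  # empty side: not applicable
  na_res <- positional_conservation_bias(hits, "M1", character(), hits$gene)
  expect_true(all(is.na(na_res$p)))
})

test_that("regulator links require both coexpression and motif enrichment", {
  cent <- rbind(C001 = c(3, -1, 0, 2), C002 = c(-2, 2, 1, -1))
  colnames(cent) <- paste0("e", 1:4)
  cl <- list(clusters = setNames(rep(c("C001", "C002"), 2), sprintf("g%d", 1:4)),
             centroids = cent)
  class(cl) <- "popseq_clustering"
  v <- rbind(tfHi = cent["C001", ] + c(1e-4, 0, 0, 0),
             tfLo = c(1, 1.2, 0.9, 1.1))
  colnames(v) <- paste0("e", 1:4)
  motif_res <- tibble::tibble(
    motif = c("mHi", "mLo", "mQ"), cluster = "C001",
    q = c(1e-5, 1e-5, 0.01)
  )
  tf_map <- tibble::tibble(tf = c("tfHi", "tfLo", "tfHi"),
                           motif = c("mHi", "mLo", "mQ"))
  res <- link_regulators(v, cl, motif_res, tf_map)
  expect_true(res$candidate[res$tf == "tfHi"])        # r ~ 1, q = 1e-5
  expect_false(res$candidate[res$tf == "tfLo"])       # r below 0.7
  res_q <- link_regulators(v, cl, motif_res[3, ], tf_map[3, ])
  expect_false(res_q$candidate[1])                    # q = 0.01 too weak
  expect_warning(
    link_regulators(v, cl, motif_res, tibble::tibble(tf = "ghost", motif = "mHi")),
    "absent"
  )
})

test_that("MEME minimal format round-trips", {
  pwms <- simulate_pwm_library(3, length = 6, tfs = c("tfA", "tfB"), seed = 5)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), names(pwms))
  expect_equal(vapply(back, `[[`, "", "tf"), vapply(pwms, `[[`, "", "tf"))
  for (i in seq_along(pwms)) {
    expect_equal(back[[i]]$matrix, pwms[[i]]$matrix, tolerance = 1e-5)
  }
})
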