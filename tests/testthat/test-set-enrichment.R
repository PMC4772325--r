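test_that("hypergeometric upper tail matches enumeration on small universes", {
  expect_equal(hypergeom_test(4, 5, 4, 10), 5 / choose(10, 4))
  expect_equal(hypergeom_test(0, 3, 2, 8), 1)       # P(X >= 0)
  expect_equal(hypergeom_test(2, 2, 5, 5), 1)       # certain when K = N... n
  for (N in c(5, 8)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
      expect_equal(hypergeom_test(k, K, n, N), hyper_oracle(k, K, n, N),
                   tolerance = 1e-12,
                   info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
  expect_invalid(hypergeom_test(3, 2, 5, 10))
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_invalid(bh_fdr(c(0.5, 1.2)))
})

test_that("term enrichment flags matching sets and is BH-corrected per call", {
  universe <- sprintf("g%02d", 1:30)
  sets <- list(A = universe[1:10], B = universe[11:20], C = universe[25:30])
  targets <- list(t1 = universe[1:10], t2 = universe[21:24])
  res <- term_enrichment(sets, targets, universe)
  r_at <- function(term, target) res[res$term == term & res$target == target, ]
  expect_equal(r_at("A", "t1")$p, min(res$p))        # identical set/target
  expect_true(r_at("A", "t1")$significant)
  expect_equal(r_at("C", "t2")$fold, 0)              # disjoint
  expect_equal(r_at("C", "t2")$p, 1)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
  expect_invalid(term_enrichment(sets, targets, character()))
  expect_invalid(term_enrichment(sets, list(bad = "nope"), universe))
})

test_that("term enrichment p-values are uniform under the null", {
  set.seed(21)
  universe <- sprintf("g%03d", 1:200)
  frac <- replicate(10, {
    sets <- lapply(1:8, function(i) sample(universe, 25))
    names(sets) <- paste0("S", 1:8)
    targets <- lapply(1:6, function(i) sample(universe, 20))
    names(targets) <- paste0("T", 1:6)
    mean(term_enrichment(sets, targets, universe)$p < 0.05)
  })
  # binomial 99% bounds for 10 x 48 tests at 0.05 (discreteness makes the
  # test conservative, so the upper bound is what matters)
  expect_lt(mean(frac), 0.05 + 2.58 * sqrt(0.05 * 0.95 / (10 * 48)))
})

test_that("temporal statistics follow the weighted formulas", {
  ts <- list(values = rbind(one = c(0, 5, 0), two = c(3, 0, 3),
                            zero = c(0, 0, 0)),
             time = c(0, 100, 200))
  res <- temporal_specificity(ts, sd_cutoff = 10, weights = "raw")
  expect_equal(res$mean_time[res$gene == "one"], 100)
  expect_equal(res$sd_time[res$gene == "one"], 0)
  expect_true(res$time_specific[res$gene == "one"])
  expect_equal(res$mean_time[res$gene == "two"], 100)     # (0+200)/2
  expect_equal(res$sd_time[res$gene == "two"], 100)       # |t2-t1|/2
  expect_true(is.na(res$mean_time[res$gene == "zero"]))
  expect_false(res$time_specific[res$gene == "zero"])
  # uniform profile: sd of the uniform weighting over timepoints
  ts2 <- list(values = rbind(u = c(1, 1, 1, 1, 1)), time = seq(0, 400, 100))
  res2 <- temporal_specificity(ts2, sd_cutoff = 100, weights = "raw")
  expect_equal(res2$sd_time, sqrt(mean((ts2$time - 200)^2)))
  expect_false(res2$time_specific)
  # invariance to positive rescaling of a profile
  ts3 <- list(values = ts$values * 17, time = ts$time)
  res3 <- temporal_specificity(ts3, sd_cutoff = 10, weights = "raw")
  expect_equal(res3$mean_time, res$mean_time)
  expect_equal(res3$sd_time, res$sd_time)
})

test_that("temporal binning yields flat profiles for uninformative experiments", {
  temporal <- tibble::tibble(gene = sprintf("g%02d", 1:20),
                             mean_time = seq(10, 200, 10),
                             sd_time = 5, time_specific = TRUE)
  v <- matrix(1.5, 20, 2, dimnames = list(temporal$gene, c("e1", "e2")))
  ftp <- fraction_temporal_profile(v, temporal, n_bins = 4)
  expect_true(all(ftp$profile$mean_enrichment == 1.5))
  expect_true(all(is.na(ftp$trend$rho)))       # zero variance across bins
  one_bin <- fraction_temporal_profile(v, temporal, n_bins = 1)
  expect_true(all(is.na(one_bin$trend$rho)))   # trend not applicable
})

test_that("tissue-composition concordance finds planted structure and not noise", {
  sim <- tiny_sim(13)
  expr <- compute_rpm(sim$study$counts, sim$study$gene_classes)
  enr <- enrichment_matrix(expr, sim$study$scheme)
  M <- build_membership(sim$markers, sim$study$scheme)
  leaves <- lineage_leaves(sim$lineage)
  cell_tissues <- setNames(leaves$tissue, leaves$cell)
  pat_tissue <- setNames(
    vapply(sim$truth$patterns$tissues, `[`, "", 1),
    sim$truth$patterns$pattern
  )
  tissue_sets <- lapply(split(sim$truth$genes$gene, pat_tissue[sim$truth$genes$pattern]),
                        identity)
  res <- tissue_composition_concordance(M, tissue_sets, enr, cell_tissues)
  expect_gt(res$r, 0.3)
  expect_lt(res$p, 0.01)
  # random gene sets: no relationship on average
  set.seed(99)
  rs <- replicate(10, {
    rand_sets <- lapply(tissue_sets, function(s) sample(rownames(enr$values), length(s)))
    tissue_composition_concordance(M, rand_sets, enr, cell_tissues)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("network co-clustering calibrates against shuffles and the closed form", {
  sim <- tiny_sim(2)
  expr <- compute_rpm(sim$study$counts, sim$study$gene_classes)
  enr <- enrichment_matrix(expr, sim$study$scheme)
  cl <- suppressWarnings(hierarchical_cluster(enr$values[1:150, ], k = 6))
  genes <- names(cl$clusters)
  # edges entirely within clusters
  within <- do.call(rbind, lapply(split(genes, cl$clusters), function(g) {
    if (length(g) < 2) return(NULL)
    cbind(g[1], g[2])
  }))
  res_w <- network_coclustering(as.data.frame(within), cl, n_shuffles = 200, seed = 4)
  expect_gt(res_w$fold, 1)
  expect_equal(res_w$p, 1 / 201)
  # random edges: fold near 1 and shuffle mean near the closed form
  set.seed(5)
  rand <- data.frame(a = sample(genes, 400, TRUE), b = sample(genes, 400, TRUE))
  res_r <- network_coclustering(rand, cl, n_shuffles = 400, seed = 6)
  expect_gt(res_r$fold, 0.7)
  expect_lt(res_r$fold, 1.4)
  expect_lt(abs(res_r$expected - res_r$analytic_expected),
            3 * res_r$shuffle_sd / sqrt(400) + 3 * sqrt(res_r$analytic_expected))
  expect_invalid(network_coclustering(data.frame(a = "x", b = "y"), cl))
})

test_that("Y1H concordance is 1 with full support and 0 with no interactions", {
  cl <- list(clusters = setNames(rep(c("C001", "C002"), each = 3),
                                 sprintf("g%d", 1:6)))
  class(cl) <- "popseq_clustering"
  hits <- data.frame(tf = c("tfA", "tfB"), cluster = c("C001", "C002"))
  y1h_full <- data.frame(tf = c("tfA", "tfB"), bait = c("g1", "g5"))
  res <- y1h_concordance(y1h_full, hits, cl, n_shuffles = 50, seed = 1)
  expect_equal(res$proportion_supported, 1)
  res0 <- y1h_concordance(y1h_full[0, ], hits, cl, n_shuffles = 50, seed = 1)
  expect_equal(res0$proportion_supported, 0)
  expect_invalid(y1h_concordance(y1h_full, hits[0, ], cl))
})

test_that("neighbor correlation pairs noncoding genes with the right partners", {
  coords <- tibble::tibble(
    gene = c("c1", "c2", "linc", "anc"),
    chrom = "chr1",
    start = c(1000, 9000, 2600, 1200), end = c(2000, 10000, 3200, 1700),
    strand = c("+", "+", "+", "-")
  )
  classes <- c(c1 = "coding", c2 = "coding", linc = "lincRNA", anc = "ancRNA")
  rpm <- rbind(c1 = c(1, 5, 20, 3), c2 = c(9, 2, 4, 8),
               linc = c(2, 10, 40, 6),     # duplicates c1's shape
               anc = c(9, 2, 4, 8))
  colnames(rpm) <- paste0("s", 1:4)
  res <- neighbor_correlation(rpm, coords, classes)
  linc_row <- res$pairs[res$pairs$class == "lincRNA", ]
  expect_equal(linc_row$neighbor, "c1")              # nearest by midpoint
  expect_equal(linc_row$r, cor(log1p(c(1, 5, 20, 3)), log1p(c(2, 10, 40, 6))))
  anc_row <- res$pairs[res$pairs$class == "ancRNA", ]
  expect_equal(anc_row$neighbor, "c1")               # opposite-strand overlap
  # equidistant neighbors: tie broken toward the smaller start coordinate
  coords2 <- tibble::tibble(
    gene = c("a", "b", "l"), chrom = "chr1",
    start = c(0, 2000, 1000), end = c(500, 2500, 1500), strand = "+"
  )
  classes2 <- c(a = "coding", b = "coding", l = "lincRNA")
  rpm2 <- matrix(runif(12), 3, 4, dimnames = list(c("a", "b", "l"), paste0("s", 1:4)))
  res2 <- neighbor_correlation(rpm2, coords2, classes2, include_coding = FALSE)
  expect_equal(res2$pairs$neighbor[res2$pairs$gene == "l"], "a")
})
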