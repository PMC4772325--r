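test_that("correlation distance matches its definition", {
  expect_equal(correlation_distance(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_equal(correlation_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  expect_equal(correlation_distance(a, b), 1 - cor(a, b))
  expect_error(correlation_distance(c(1, 1, 1), c(1, 2, 3)),
               class = "popseq_undefined_distance")
  expect_invalid(correlation_distance(1:3, 1:4))
})

test_that("identical-profile pairs are recovered and singletons are allowed", {
  m <- rbind(g1 = c(1, 2, 3, 1), g2 = c(2, 4, 6, 2),
             g3 = c(5, 1, 0, 4), g4 = c(10, 2, 0, 8))
  cl <- hierarchical_cluster(m, k = 2)
  expect_equal(cl$clusters[["g1"]], cl$clusters[["g2"]])
  expect_equal(cl$clusters[["g3"]], cl$clusters[["g4"]])
  expect_false(cl$clusters[["g1"]] == cl$clusters[["g3"]])
  all_single <- hierarchical_cluster(m, k = 4)
  expect_equal(length(unique(all_single$clusters)), 4)
  expect_invalid(hierarchical_cluster(m, k = 5))
  expect_invalid(hierarchical_cluster(m))             # neither k nor h
})

test_that("zero-variance profiles are excluded with a warning", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(3, 2, 1), g3 = c(2, 2, 2), g4 = c(0, 1, 0))
  expect_warning(cl <- hierarchical_cluster(m, k = 2), "zero-variance")
  expect_equal(cl$excluded, "g3")
  expect_false("g3" %in% cl$assignment$gene)
})

test_that("complete linkage bounds within-cluster distance by the cut height", {
  sim <- tiny_sim(2)
  expr <- compute_rpm(sim$study$counts, sim$study$gene_classes)
  enr <- enrichment_matrix(expr, sim$study$scheme)
  v <- enr$values[1:120, ]
  h <- 0.6
  cl <- suppressWarnings(hierarchical_cluster(v, h = h))
  d <- as.matrix(1 - cor(t(v[cl$assignment$gene, ])))
  for (cn in unique(cl$clusters)) {
    g <- names(cl$clusters)[cl$clusters == cn]
    if (length(g) > 1) expect_lte(max(d[g, g]), h + 1e-12)
  }
})

test_that("centroids equal member-profile means and row order does not matter", {
  sim <- tiny_sim(2)
  expr <- compute_rpm(sim$study$counts, sim$study$gene_classes)
  enr <- enrichment_matrix(expr, sim$study$scheme)
  v <- enr$values[1:100, ]
  cl <- suppressWarnings(hierarchical_cluster(v, k = 5))
  for (cn in rownames(cl$centroids)) {
    g <- names(cl$clusters)[cl$clusters == cn]
    expect_equal(unname(cl$centroids[cn, ]),
                 unname(colMeans(v[g, , drop = FALSE])), tolerance = 1e-12)
  }
  # permuting gene rows permutes labels but not memberships
  set.seed(1)
  perm <- sample(nrow(v))
  cl2 <- suppressWarnings(hierarchical_cluster(v[perm, ], k = 5))
  same <- outer(cl$clusters[rownames(v)], cl$clusters[rownames(v)], "==")
  same2 <- outer(cl2$clusters[rownames(v)], cl2$clusters[rownames(v)], "==")
  expect_true(all(same == same2))
})

test_that("cluster specificity applies strict cutoffs", {
  rpm <- rbind(lo1 = c(0, 0), lo2 = c(0, 0), hi1 = c(400, 2), hi2 = c(500, 1))
  colnames(rpm) <- c("s1", "s2")
  enr <- rbind(lo1 = c(0.2, 0.2), lo2 = c(0.2, 0.2),
               hi1 = c(3, -3), hi2 = c(2.5, -2))
  colnames(enr) <- c("e1", "e2")
  cl <- list(
    clusters = setNames(c("C001", "C001", "C002", "C002"), rownames(rpm)),
    sizes = table(c("C001", "C001", "C002", "C002"))
  )
  class(cl) <- "popseq_clustering"
  spec <- cluster_specificity(cl, rpm, enr)
  expect_false(spec$specific[spec$cluster == "C001"])   # |enr| = 0.2 exactly
  expect_true(spec$specific[spec$cluster == "C002"])
})

test_that("coexpression queries rank by correlation with ties on gene id", {
  m <- rbind(q = c(1, 2, 3, 4), dup = c(2, 4, 6, 8),
             anti = c(4, 3, 2, 1), zz = c(1, 2, 3, 5), aa = c(1, 2, 3, 5))
  res <- coexpression_query(m, "q", top_n = 10)
  expect_equal(res$gene[1], "dup")
  expect_equal(res$r[1], 1)
  expect_equal(nrow(res), 4)                       # full ranking returned
  expect_equal(res$gene[res$r == res$r[2]][1], "aa")  # tie -> gene id order
  expect_error(coexpression_query(m, "missing"), class = "popseq_not_found")
})

test_that("select_cut returns the single candidate and breaks ties to fewer clusters", {
  sim <- tiny_sim(2)
  expr <- compute_rpm(sim$study$counts, sim$study$gene_classes)
  enr <- enrichment_matrix(expr, sim$study$scheme)
  v <- enr$values[1:100, ]
  universe <- rownames(v)
  empty_pres <- tibble::tibble(motif = character(), gene = character(),
                               distance_cut = double(), conservation_cut = double(),
                               score_cut = double())
  res1 <- suppressWarnings(select_cut(v, 4, empty_pres, universe))
  expect_equal(res1$clustering$k, 4L)
  # no motif signal: all scores zero, smallest k wins
  res <- suppressWarnings(select_cut(v, c(6, 3, 9), empty_pres, universe))
  expect_equal(res$clustering$k, 3L)
  expect_true(all(res$scores$n_significant == 0))
  expect_invalid(select_cut(v, integer(), empty_pres, universe))
})
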