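test_that("the pseudocounted enrichment formula is exact", {
  expect_equal(log2_enrichment(13, 1, 3), 2)          # log2(16/4)
  expect_equal(log2_enrichment(7.3, 7.3, 5), 0)
  expect_equal(log2_enrichment(0, 0, 3), 0)
  expect_invalid(log2_enrichment(-1, 2))
  expect_invalid(log2_enrichment(1, 2, pseudocount = 0))
})

test_that("enrichment is antisymmetric, bounded and monotone", {
  set.seed(31)
  a <- runif(500, 0, 1e4); b <- runif(500, 0, 1e4)
  expect_equal(log2_enrichment(a, b), -log2_enrichment(b, a))
  bound <- log2((3 + pmax(a, b)) / 3)
  expect_true(all(abs(log2_enrichment(a, b)) <= bound + 1e-12))
  # strictly increasing in pos, decreasing in neg
  expect_true(all(diff(log2_enrichment(sort(a), 5)) > 0))
  expect_true(all(diff(log2_enrichment(5, sort(a))) < 0))
})

test_that("the enrichment matrix honors per-experiment control policies", {
  rpm <- cbind(p1 = c(40, 1), n1 = c(1, 40), singlet = c(10, 10),
               ungated = c(10, 10))
  rownames(rpm) <- c("gA", "gB")
  scheme <- structure(list(
    experiments = tibble::tibble(
      experiment = c("e_neg", "e_sing"), positive_sample = c("p1", "p1"),
      control_policy = c("matched_negative", "singlet"),
      control_sample = c("n1", "singlet"),
      marker1 = "m", sign1 = "+", marker2 = NA_character_, sign2 = NA_character_,
      kind = "translational", replicate_group = "m", purity = 0.9,
      positive_fraction = 0.3
    ),
    singlet_sample = "singlet", ungated_sample = "ungated",
    double_pair = NULL, bias_tissue = NULL
  ), class = "popseq_scheme")
  enr <- enrichment_matrix(rpm, scheme)
  expect_equal(enr$values["gA", "e_neg"], log2(43 / 4))
  expect_equal(enr$values["gA", "e_sing"], log2(43 / 13))
  expect_false(enr$values["gA", "e_neg"] == enr$values["gA", "e_sing"])
  expect_true(enr$conservative[["e_sing"]])
  # singlet control equal to the matched negative gives identical columns
  rpm2 <- rpm; rpm2[, "singlet"] <- rpm2[, "n1"]
  enr2 <- enrichment_matrix(rpm2, scheme)
  expect_equal(unname(enr2$values[, "e_neg"]), unname(enr2$values[, "e_sing"]))
  # missing samples raise a classed error naming the experiment
  expect_error(enrichment_matrix(rpm[, 1:2], scheme),
               class = "popseq_missing_sample")
})

test_that("call boundaries are inclusive and summaries count genes", {
  m <- matrix(c(2, -2, 1.99, 0, 2.5, 2.2), 2, 3,
              dimnames = list(c("g1", "g2"), c("e1", "e2", "e3")))
  calls <- call_enriched_depleted(m)
  expect_equal(calls$matrix["g1", "e1"], "enriched")
  expect_equal(calls$matrix["g2", "e1"], "depleted")
  expect_equal(calls$matrix["g1", "e2"], "neither")
  expect_equal(calls$summary$n_genes_ge1, 2)
  expect_equal(calls$summary$n_genes_ge2, 2)   # g1 in e1+e3, g2 in e1+e3
  expect_invalid(call_enriched_depleted(m, cutoff = 0))
})

test_that("replicate concordance matches its definitional oracle", {
  expect_equal(replicate_concordance(c(3, -3, 1), c(3, -3, 1)),
               tibble::tibble(r = 1, accuracy = 1, n_called = 2L))
  neg <- replicate_concordance(c(3, -3, 1), -c(3, -3, 1))
  expect_equal(neg$r, -1)
  expect_equal(neg$accuracy, 0)
  a <- c(3, -3, 0, 1); b <- c(2.5, -1, 0, -1)
  res <- replicate_concordance(a, b)
  expect_equal(res$accuracy, 1)                # both called genes sign-match
  expect_equal(res$r, cor(a, b))
  expect_error(replicate_concordance(c(1, 1, 1), c(1, 2, 3)),
               class = "popseq_undefined_correlation")
})

test_that("singlet enrichment is zero without gating bias and negative for the biased tissue", {
  sim <- tiny_sim(13)
  expr <- compute_rpm(sim$study$counts, sim$study$gene_classes)
  se <- singlet_enrichment(expr, sim$study$scheme)
  # genes of the ungated-overweighted tissue are singlet-depleted
  bias_pat <- sim$truth$patterns$pattern[vapply(
    sim$truth$patterns$tissues, function(t) sim$study$scheme$bias_tissue %in% t, TRUE
  )]
  bias_genes <- sim$truth$genes$gene[sim$truth$genes$pattern %in% bias_pat]
  other <- sim$truth$genes$gene[grepl("^P", sim$truth$genes$pattern) &
                                  !(sim$truth$genes$pattern %in% bias_pat)]
  expect_lt(mean(se[bias_genes]), 0)
  expect_lt(mean(se[bias_genes]), mean(se[other]))
  # no bias at all: singlet equals ungated in expectation
  rpm <- cbind(s = c(5, 5), singlet = c(7, 1), ungated = c(7, 1))
  rownames(rpm) <- c("a", "b")
  sch <- structure(list(singlet_sample = "singlet", ungated_sample = "ungated"),
                   class = "popseq_scheme")
  expect_equal(unname(singlet_enrichment(rpm, sch)), c(0, 0))
})

test_that("reconstruction check reports improvement only when correction helps", {
  sim <- tiny_sim(13)
  expr <- compute_rpm(sim$study$counts, sim$study$gene_classes)
  rec <- reconstruction_check(expr, sim$study$scheme)
  expect_true(all(c("r_uncorrected", "r_corrected") %in% names(rec$table)))
  expect_lt(rec$p_improvement, 0.5)      # simulator plants a gating bias
  # single experiment: Wilcoxon not applicable
  sch1 <- sim$study$scheme
  sch1$experiments <- sch1$experiments[
    sch1$experiments$control_policy == "matched_negative", ][1, ]
  rec1 <- reconstruction_check(expr, sch1)
  expect_true(is.na(rec1$p_improvement))
})
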