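test_that("Fisher exact: known tables", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1)$p, 1)
  r <- fisher_exact_2x2(5, 0, 0, 5)
  expect_equal(r$p, 2 / choose(10, 5))
  expect_equal(r$odds_ratio, Inf)
  # zero margin: single possible table
  z <- fisher_exact_2x2(0, 0, 3, 4)
  expect_equal(z$p, 1)
  expect_true(z$undefined_or)
  # sample odds ratio, not the conditional MLE
  expect_equal(fisher_exact_2x2(6, 2, 3, 9)$odds_ratio, 6 * 9 / (2 * 3))
  expect_equal(fisher_exact_2x2(0, 3, 2, 1)$odds_ratio, 0)
  expect_true(is.nan(fisher_exact_2x2(0, 3, 0, 4)$odds_ratio))
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher exact agrees with enumeration oracle and stats::fisher.test", {
  set.seed(14)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    got <- fisher_exact_2x2(tab)
    expect_equal(got$p, oracle_fisher_p(tab[1, 1], tab[1, 2],
                                        tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12, info = paste(tab, collapse = ","))
    if (!got$undefined_or)
      expect_equal(got$p, stats::fisher.test(tab)$p.value,
                   tolerance = 1e-9)
  }
})

test_that("Holm adjustment: worked example and invariants", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(20)
  expect_equal(holm_adjust(p[perm]), adj[perm])
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("phase enrichment detects planted presence imbalance", {
  set.seed(3)
  genes <- sprintf("g%03d", 1:300)
  labels <- setNames(rep(c("magenta", "navy", "arrhythmic"), each = 100),
                     genes)
  present <- ifelse(labels == "magenta", runif(300) < 0.8,
                    runif(300) < 0.2)
  hits <- data.frame(gene_id = genes, motif = "RORE",
                     count = as.integer(present), present = present)
  enr <- phase_enrichment(labels, hits)
  expect_s3_class(enr, "enrichment_result")
  mag <- enr[enr$bin == "magenta", ]
  expect_lt(mag$p_holm, 0.001)
  expect_gt(mag$odds_ratio, 1)
  # margins consistent
  expect_equal(mag$a + mag$b, 100)
  expect_equal(mag$c + mag$d, 200)
  # arrhythmic-only background shrinks the comparison set
  enr2 <- phase_enrichment(labels, hits, background = "arrhythmic")
  expect_equal(enr2$c[enr2$bin == "magenta"] +
                 enr2$d[enr2$bin == "magenta"], 100)
})

test_that("empty focal bin is flagged with p = 1", {
  genes <- c("a", "b", "c")
  labels <- setNames(c("navy", "navy", "arrhythmic"), genes)
  hits <- data.frame(gene_id = genes, motif = "RORE", count = 1,
                     present = TRUE)
  expect_warning(
    enr <- phase_enrichment(labels, hits,
                            focal_bins = c("navy", "magenta")),
    "no genes")
  expect_equal(enr$p[enr$bin == "magenta"], 1)
  expect_true(enr$empty_bin[enr$bin == "magenta"])
})

test_that("per-motif Holm families adjust within motif only", {
  genes <- sprintf("g%d", 1:40)
  labels <- setNames(rep(c("magenta", "arrhythmic"), each = 20), genes)
  set.seed(4)
  hits <- rbind(
    data.frame(gene_id = genes, motif = "m1",
               present = runif(40) < 0.5),
    data.frame(gene_id = genes, motif = "m2",
               present = runif(40) < 0.5))
  hits$count <- as.integer(hits$present)
  e_all <- phase_enrichment(labels, hits, family = "all")
  e_pm <- phase_enrichment(labels, hits, family = "per_motif")
  # one test per family here, so per-motif adjustment is the identity
  expect_equal(e_pm$p_holm, e_pm$p)
  expect_equal(e_all$p_holm, holm_adjust(e_all$p))
})

test_that("overlap statistics match direct enumeration on small sets", {
  uni <- letters[1:20]
  expect_equal(dual_period_overlap(letters[1:5], letters[6:10],
                                   uni)$proportion, 0)
  expect_equal(dual_period_overlap(letters[1:4], letters[1:8],
                                   uni)$proportion, 1)
  ov <- dual_period_overlap(letters[1:6], letters[4:12], uni)
  expect_equal(ov$n_intersect, 3)
  expect_equal(ov$proportion, 0.5)
  expect_equal(ov$p_hyper,
               stats::phyper(2, 9, 11, 6, lower.tail = FALSE))
  # hypergeometric tail by enumeration: P(X >= 3)
  enum <- sum(vapply(3:6, function(k)
    choose(9, k) * choose(11, 6 - k) / choose(20, 6), 0))
  expect_equal(ov$p_hyper, enum, tolerance = 1e-12)

  em <- dual_period_overlap(character(0), letters[1:3], uni)
  expect_true(em$empty_circadian)
  expect_true(is.na(em$proportion))
  expect_error(dual_period_overlap(c("zz"), letters[1:3], uni),
               "subsets")
})

test_that("per-bin overlap proportions are computed within bins", {
  uni <- sprintf("g%d", 1:30)
  bins <- setNames(rep(c("magenta", "gray"), each = 10), uni[1:20])
  circ <- uni[1:20]
  dev <- c(uni[1:5], uni[11:12])
  ov <- dual_period_overlap(circ, dev, uni, bins = bins)
  pb <- ov$per_bin
  expect_equal(pb$proportion[pb$bin == "magenta"], 0.5)
  expect_equal(pb$proportion[pb$bin == "gray"], 0.2)
})

test_that("shuffle null is deterministic and calibrated on null data", {
  sim <- simulate_expression(design_circadian(seed = 10), 60,
                             frac_rhythmic = 0)
  n1 <- shuffle_null(sim, period_min = 20, period_max = 28,
                     n_shuffles = 3, seed = 2, n_perm = 99)
  n2 <- shuffle_null(sim, period_min = 20, period_max = 28,
                     n_shuffles = 3, seed = 2, n_perm = 99)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(3L, 3L))
  # observed null data sits inside the shuffled count range at q < 0.30
  tab <- rhythm_test(sim, period_min = 20, period_max = 28,
                     n_perm = 99, seed = 2)
  obs <- sum(tab$q < 0.30)
  expect_lte(obs, max(n1[, "0.30"]) + 5)
})

test_that("identical conditions show no systematic rhythm loss", {
  sim <- simulate_expression(design_knockdown(seed = 15), 60,
                             frac_rhythmic = 0.5)
  cc <- compare_conditions(sim, condition_a = "mock",
                           condition_b = "auxin",
                           period_min = 20, period_max = 28,
                           n_perm = 99, seed = 1)
  # both conditions carry the same planted signal; loss is only
  # threshold noise
  expect_lte(length(cc$lost), 0.2 * max(1, length(cc$rhythmic_a)))
  expect_equal(nrow(cc$counts), 2)
  expect_error(compare_conditions(sim, condition_a = "mock",
                                  condition_b = "zz", period_min = 20,
                                  period_max = 28, n_perm = 99),
               "missing condition")
})
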