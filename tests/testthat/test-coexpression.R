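test_that("spearman correlation reproduces hand and oracle values", {
  # hand rank formula: rho = 1 - 6*6/(3*8) = -0.5
  s <- spearman_rho(c(1, 2, 3), c(3, 1, 2))
  expect_equal(s$rho, -0.5)
  # monotone transform of x has rho 1
  x <- c(2, 9, 4, 7, 1, 5)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  # oracle agreement on random untied vectors
  set.seed(23)
  for (rep in 1:200) {
    a <- rnorm(26); b <- rnorm(26)
    expect_equal(spearman_rho(a, b)$rho, oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  # constant vector: undefined, flagged
  u <- spearman_rho(rep(1, 10), rnorm(10))
  expect_true(is.na(u$rho))
  expect_equal(u$method, "undefined")
  expect_error(spearman_rho(1:2, 2:1), "n >= 3")
})

test_that("exact permutation p-values match full enumeration", {
  set.seed(29)
  for (n in c(5, 6, 7)) {
    for (rep in 1:5) {
      x <- rnorm(n); y <- rnorm(n)
      s <- spearman_rho(x, y, method = "exact")
      expect_equal(s$pvalue, oracle_spearman_p(x, y), tolerance = 1e-12)
    }
  }
  # the cached null distribution is a proper probability distribution
  d <- spearman_null_distribution(8)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_true(all(diff(d$S) > 0))
  # ties force the approximation and exact mode refuses them
  expect_error(spearman_rho(c(1, 1, 2, 3, 4), 1:5, method = "exact"), "untied")
  expect_equal(spearman_rho(c(1, 1, 2, 3, 4), 1:5)$method, "approx")
  # large n uses the t-approximation and stays calibrated-ish under the null
  s <- spearman_rho(rnorm(26), rnorm(26))
  expect_equal(s$method, "approx")
  expect_true(s$pvalue >= 0 && s$pvalue <= 1)
})

test_that("BH adjustment follows the step-up trace and its true properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # monotone in the input ordering, bounded by [p, 1]
    expect_true(all(q[order(p)] == cummax(q[order(p)])))
    expect_true(all(q >= p - 1e-15 & q <= 1))
  }
})

mk_pairs <- function(lnc, mrna, distance = 1000) {
  data.frame(lnc_id = lnc, mrna_id = mrna, pair_class = "divergent",
             distance = distance, retained = TRUE, stringsAsFactors = FALSE)
}

test_that("correlate_pairs applies the significance rule over one BH family", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:60), biotype = "lincRNA")
  planted <- data.frame(gene_a = genes$gene_id[1:5], gene_b = genes$gene_id[6:10],
                        target_rho = 0.9)
  weak <- data.frame(gene_a = genes$gene_id[11:15], gene_b = genes$gene_id[16:20],
                     target_rho = 0.3)
  ex <- generate_expression(genes, planted_pairs = rbind(planted, weak),
                            noise_cv = 0.2, seed = 41)
  pairs <- rbind(mk_pairs(planted$gene_a, planted$gene_b),
                 mk_pairs(weak$gene_a, weak$gene_b),
                 mk_pairs(genes$gene_id[21:30], genes$gene_id[31:40]))
  cps <- correlate_pairs(pairs, ex$matrix)
  expect_equal(nrow(cps), 20L)
  expect_equal(cps$padj, bh_adjust(cps$pvalue))
  expect_true(all(cps$padj >= cps$pvalue))
  expect_equal(cps$significant, abs(cps$rho) > 0.5 & cps$padj < 0.05)
  # strong planted pairs recovered, weak ones rejected by the |rho| gate
  expect_true(all(cps$significant[1:5]))
  expect_true(all(abs(cps$rho[6:10]) < 0.75))
  smry <- attr(cps, "summary")
  expect_equal(smry$n_tested, 20L)
  expect_equal(smry$n_significant, sum(cps$significant))
})

test_that("pairs with unusable expression are dropped with reasons", {
  mat <- rbind(a = c(1, 2, 3, 4, 5, 6), b = c(2, 1, 4, 3, 6, 5),
               c = rep(0, 6), d = rep(7, 6))
  colnames(mat) <- paste0("t", 1:6)
  pairs <- mk_pairs(c("a", "c", "d"), c("b", "b", "b"))
  cps <- correlate_pairs(pairs, mat)
  expect_equal(nrow(cps), 1L)
  dropped <- attr(cps, "dropped")
  expect_setequal(dropped$lnc_id, c("c", "d"))
  expect_setequal(dropped$reason, c("not_expressed", "constant_vector"))
  expect_error(correlate_pairs(mk_pairs("a", "zz"), mat), "missing from")
})

test_that("distance profile, rank-sum and partner ranks follow definitions", {
  cps <- data.frame(
    lnc_id = c("l1", "l1", "l2", "l3"),
    mrna_id = c("m1", "m2", "m3", "m4"),
    pair_class = "divergent", retained = TRUE,
    distance = c(100, 300, 500, 10000),
    rho = c(0.95, 0.92, 0.6, 0.3),
    pvalue = c(1e-6, 1e-6, 1e-3, 0.4),
    padj = c(1e-5, 1e-5, 1e-2, 0.5),
    significant = c(TRUE, TRUE, TRUE, FALSE))
  prof <- distance_correlation_profile(cps)
  expect_equal(prof$bins$mean_distance[prof$bins$bin == "(0.9,1]"], 200)
  expect_equal(prof$bins$mean_distance[prof$bins$bin == "(0.5,0.7]"], 500)
  expect_false("(0.7,0.9]" %in% prof$bins$bin)   # empty bins are absent

  # identical samples give a one-tailed rank-sum p of 0.5
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3), "greater")$p.value, 0.5)

  # best partner at rank 2 by distance
  pr <- partner_rank_analysis(data.frame(
    lnc_id = "l", mrna_id = c("near", "far"), distance = c(1e4, 2e5),
    rho = c(0.6, 0.9), significant = TRUE))
  expect_equal(pr$best_partner, "far")
  expect_equal(pr$best_rank, 2L)
  expect_true(pr$best_is_not_nearest)
  # single-partner lncRNAs are excluded
  pr1 <- partner_rank_analysis(data.frame(
    lnc_id = "l", mrna_id = "m", distance = 1, rho = 0.9, significant = TRUE))
  expect_equal(nrow(pr1), 0L)
})

test_that("distance-decaying correlation yields a negative trend", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:120), biotype = "lincRNA")
  rho_target <- seq(0.95, 0.55, length.out = 30)
  planted <- data.frame(gene_a = genes$gene_id[1:30],
                        gene_b = genes$gene_id[61:90],
                        target_rho = rho_target)
  ex <- generate_expression(genes, planted_pairs = planted, noise_cv = 0.2,
                            seed = 53)
  # distance grows as the planted correlation falls
  pairs <- mk_pairs(planted$gene_a, planted$gene_b,
                    distance = 1e4 + (0.95 - rho_target) * 2e6)
  cps <- correlate_pairs(pairs, ex$matrix)
  prof <- distance_correlation_profile(cps)
  expect_lt(prof$trend_rho, 0)
})
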