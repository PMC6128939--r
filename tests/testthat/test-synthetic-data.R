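test_that("generators are pure functions of (config, seed)", {
  g1 <- generate_annotation(n_mrna = 15, n_lincrna = 10, n_antisense = 3,
                            n_divergent = 2, n_convergent = 2, seed = 5)
  g2 <- generate_annotation(n_mrna = 15, n_lincrna = 10, n_antisense = 3,
                            n_divergent = 2, n_convergent = 2, seed = 5)
  f1 <- tempfile(); f2 <- tempfile()
  write_gtf(g1$annotation, f1); write_gtf(g2$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))

  ex1 <- generate_expression(g1$annotation, seed = 6)
  ex2 <- generate_expression(g2$annotation, seed = 6)
  expect_identical(ex1$matrix, ex2$matrix)
  expect_false(identical(
    ex1$matrix, generate_expression(g1$annotation, seed = 7)$matrix))

  t1 <- generate_te_landscape(g1$chrom_lengths, seed = 8)
  t2 <- generate_te_landscape(g1$chrom_lengths, seed = 8)
  b1 <- tempfile(); b2 <- tempfile()
  write_bed(t1$tes, b1); write_bed(t2$tes, b2)
  expect_identical(readLines(b1), readLines(b2))

  p1 <- generate_ortholog_panel(n_per_stratum = 10, seed = 9)
  p2 <- generate_ortholog_panel(n_per_stratum = 10, seed = 9)
  expect_identical(p1$expr_a, p2$expr_a)

  c1 <- generate_conservation_track(c(chr1 = 10000), seed = 10)
  c2 <- generate_conservation_track(c(chr1 = 10000), seed = 10)
  expect_identical(as.numeric(c1$track$chr1), as.numeric(c2$track$chr1))

  # the generators restore the caller's RNG state
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_annotation(n_mrna = 2, n_lincrna = 1,
                                               n_antisense = 0, n_divergent = 0,
                                               n_convergent = 0, seed = 99))
  expect_identical(runif(1), before)
})

test_that("annotation generator respects quotas and degenerate configs", {
  gen <- generate_annotation(n_mrna = 20, n_lincrna = 15, n_antisense = 5,
                             n_divergent = 4, n_convergent = 3, seed = 13)
  g <- genes(gen$annotation)
  expect_equal(sum(g$biotype == "mRNA"), 20L)
  expect_equal(sum(g$biotype == "lincRNA"), 15L)
  expect_equal(sum(g$biotype == "antisense"), 5L)
  expect_equal(sum(gen$truth$planted_class == "divergent", na.rm = TRUE), 4L)
  expect_equal(sum(gen$truth$planted_class == "convergent", na.rm = TRUE), 3L)
  # empty annotation
  empty <- generate_annotation(n_mrna = 0, n_lincrna = 0, n_antisense = 0,
                               n_divergent = 0, n_convergent = 0, seed = 1)
  expect_equal(nrow(genes(empty$annotation)), 0L)
  # infeasible packing is rejected with advice
  expect_error(generate_annotation(n_chroms = 1, chrom_length = 1e5,
                                   n_mrna = 50, n_lincrna = 50, seed = 1),
               "chrom_length")
  expect_error(generate_annotation(n_mrna = 2, n_antisense = 5, seed = 1),
               "n_antisense")
})

test_that("expression generator hits planted regimes and validates input", {
  genes <- data.frame(gene_id = c("a", "b", "c", "d"), biotype = "lincRNA")
  expect_error(generate_expression(
    genes, planted_specific = data.frame(gene_id = "zz", tissue = "testis",
                                         fold = 50), seed = 1),
    "unknown gene")
  expect_error(generate_expression(
    genes, planted_pairs = data.frame(gene_a = "a", gene_b = "b",
                                      target_rho = 1.5), seed = 1),
    "target_rho")

  # near-zero noise, no planting: every gene's tau tends to 0
  ex <- generate_expression(genes, noise_cv = 1e-6, seed = 2)
  tau <- compute_tau(ex$matrix, floor_tpm = 0)
  expect_true(all(tau$tau < 1e-4))

  # biotype offset: lncRNA baselines ~20x below mRNA on average
  many <- data.frame(gene_id = sprintf("g%04d", 1:2000),
                     biotype = rep(c("mRNA", "lincRNA"), 1000))
  exm <- generate_expression(many, seed = 3)
  tr <- exm$truth$genes
  ratio <- mean(tr$baseline_tpm[tr$biotype == "mRNA"]) /
    mean(tr$baseline_tpm[tr$biotype == "lincRNA"])
  expect_gt(ratio, 10); expect_lt(ratio, 40)
  # truth records every planted attribute without regeneration
  expect_true(all(c("gene_id", "biotype", "baseline_tpm", "regime",
                    "specific_tissue", "fold") %in% names(tr)))
})

test_that("ortholog panel strata hit their copula targets", {
  expect_error(generate_ortholog_panel(k = 2), "k >= 4")
  panel <- generate_ortholog_panel(n_per_stratum = 60, k = 11, seed = 17)
  rho <- vapply(seq_len(nrow(panel$orthologs)), function(i) {
    cor(rank(panel$expr_a[panel$orthologs$gene_a[i], ]),
        rank(panel$expr_b[panel$orthologs$gene_b[i], ]))
  }, 0)
  by_stratum <- split(rho, panel$truth$stratum)
  # at k = 11 a true-null |rho| has expectation ~ sqrt(2/pi)/sqrt(k-1) = 0.25
  expect_lt(mean(abs(by_stratum$divergent)), 0.3)
  expect_lt(abs(mean(by_stratum$divergent)), 0.12)
  expect_gt(mean(by_stratum$high), 0.75)
  expect_gt(mean(by_stratum$intermediate), 0.3)
  expect_lt(mean(by_stratum$intermediate), 0.7)
})

test_that("TE landscape respects coverage, enrichment and depletion", {
  cl <- c(chr1 = 1e6, chr2 = 1e6)
  land <- generate_te_landscape(cl, coverage = 0.3, seed = 19)
  gf <- genome_te_fraction(land$tes, cl)
  frac <- gf$fraction[gf$te_class == "any"]
  expect_gt(frac, 0.2); expect_lt(frac, 0.35)
  # empty mix
  none <- generate_te_landscape(cl, families = default_te_families()[0, ], seed = 1)
  expect_equal(nrow(none$tes), 0L)
  # depletion thins background copies inside the named regions
  regions <- data.frame(chrom = "chr1", start = seq(0, 9e5, by = 1e5),
                        end = seq(0, 9e5, by = 1e5) + 5e4)
  dep <- generate_te_landscape(cl, coverage = 0.3,
                               depletion = list(list(regions = regions,
                                                     keep_prob = 0.1)),
                               seed = 19)
  inside <- overlap_length(regions, dep$tes)
  inside_bg <- overlap_length(regions, land$tes)
  expect_lt(inside, 0.4 * inside_bg)
  expect_error(generate_te_landscape(
    cl, enrichment = list(family = "SINEC_Cf",
                          regions = regions, factor = 0.5), seed = 1),
    ">= 1")
})

test_that("conservation track elevates exon scores by biotype", {
  gen <- generate_annotation(n_mrna = 30, n_lincrna = 30, n_antisense = 0,
                             n_divergent = 0, n_convergent = 0, seed = 23)
  ct <- generate_conservation_track(gen$chrom_lengths, ann = gen$annotation,
                                    exon_means = c(mRNA = 0.4, lincRNA = 0.1,
                                                   antisense = 0.1),
                                    seed = 24)
  sc <- gene_conservation_score(gen$annotation, ct$track)
  g <- genes(gen$annotation)
  sc$biotype <- g$biotype[match(sc$gene_id, g$gene_id)]
  cmp <- compare_score_distributions(sc[sc$biotype == "mRNA", ],
                                     sc[sc$biotype == "lincRNA", ],
                                     alternative = "greater")
  expect_lt(cmp$p.value, 0.01)
  expect_equal(ct$truth$intended_mean[ct$truth$biotype == "mRNA"][1], 0.4)
})

test_that("truth files round-trip through JSON", {
  gen <- generate_annotation(n_mrna = 6, n_lincrna = 4, n_antisense = 2,
                             n_divergent = 1, n_convergent = 1, seed = 29)
  f <- tempfile(fileext = ".json")
  write_truth(gen$truth, f)
  back <- read_truth(f)
  expect_equal(back$gene_id, gen$truth$gene_id)
  expect_equal(back$planted_class, gen$truth$planted_class)
})
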