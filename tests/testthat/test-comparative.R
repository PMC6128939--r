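test_that("replicate averaging is a per-gene arithmetic mean", {
  mat <- cbind(s1 = c(2, 1), s2 = c(4, 3), s3 = c(10, 0))
  rownames(mat) <- c("g1", "g2")
  out <- average_replicates(mat, c("liver", "liver", "lung"))
  expect_equal(out[, "liver"], c(g1 = 3, g2 = 2))
  expect_equal(out[, "lung"], c(g1 = 10, g2 = 0))
  # single replicate unchanged
  expect_equal(average_replicates(mat[, 1, drop = FALSE], "liver")[, 1],
               mat[, 1])
  # random agreement with an explicit loop
  set.seed(61)
  m <- matrix(rlnorm(8 * 6), 8, 6, dimnames = list(paste0("g", 1:8), paste0("s", 1:6)))
  tiss <- c("a", "b", "a", "c", "b", "a")
  got <- average_replicates(m, tiss)
  for (t in unique(tiss)) {
    for (g in rownames(m)) {
      expect_equal(got[g, t], mean(m[g, tiss == t]))
    }
  }
  # list-of-matrices form with a gene-set mismatch error
  l <- list(m, m + 1)
  expect_equal(average_replicates(l), m + 0.5)
  l2 <- list(m, m[c(2:8, 1), ])
  expect_error(average_replicates(l2), "disagree")
})

test_that("conservation classes partition the p-value axis", {
  expect_equal(conservation_classify(0.01), "high")
  expect_equal(conservation_classify(0.10), "intermediate")
  expect_equal(conservation_classify(0.60), "divergent")
  # boundaries: p = 0.05 is intermediate, p = 0.2 divergent (half-open bins)
  expect_equal(conservation_classify(c(0.05, 0.2)), c("intermediate", "divergent"))
  expect_equal(conservation_classify(NA), "unscored")
  p_grid <- seq(0, 1, by = 0.001)
  cls <- conservation_classify(p_grid)
  expect_true(all(cls %in% c("high", "intermediate", "divergent")))
  expect_equal(sum(table(cls)), length(p_grid))
})

test_that("ortholog classification uses exact small-sample p-values", {
  panel <- generate_ortholog_panel(n_per_stratum = 40, k = 11, seed = 71)
  cls <- classify_orthologs(panel$orthologs, panel$expr_a, panel$expr_b)
  expect_true(all(cls$conservation_class %in%
                    c("high", "intermediate", "divergent")))
  tab <- table(panel$truth$stratum, cls$conservation_class)
  expect_equal(unname(which.max(tab["high", ])),
               unname(which(colnames(tab) == "high")))
  # spot-check one pair against a direct exact computation
  s <- spearman_rho(panel$expr_a[cls$gene_a[1], ],
                    panel$expr_b[cls$gene_b[1], ], method = "exact")
  expect_equal(cls$pvalue[1], s$pvalue)
  expect_equal(cls$rho[1], s$rho)
})

test_that("per-gene conservation medians match a flatten-and-sort oracle", {
  ann <- gene_annotation(data.frame(
    gene_id = "g", transcript_id = c("t", "t"), chrom = "chr1",
    start = c(10, 20), end = c(13, 22), strand = "+", biotype = "lincRNA"))
  # constant track: median is the constant
  track <- structure(list(chr1 = S4Vectors::Rle(0.3, 100)),
                     class = "conservation_track")
  sc <- gene_conservation_score(ann, track)
  expect_equal(sc$median_score, 0.3)
  expect_equal(sc$n_bases, 5L)

  # explicit values: bases 11..13 and 21..22 (1-based) of the track
  v <- rep(NA_real_, 100)
  v[11:13] <- c(0.1, 0.3, 0.2); v[21:22] <- c(0.9, 0.5)
  track2 <- structure(list(chr1 = S4Vectors::Rle(v)), class = "conservation_track")
  sc2 <- gene_conservation_score(ann, track2)
  expect_equal(sc2$median_score, median(c(0.1, 0.3, 0.2, 0.9, 0.5)))
  # even count: mean of the two middle values
  v[13] <- NA
  track3 <- structure(list(chr1 = S4Vectors::Rle(v)), class = "conservation_track")
  sc3 <- gene_conservation_score(ann, track3)
  expect_equal(sc3$n_bases, 4L)
  expect_equal(sc3$median_score, mean(sort(c(0.1, 0.3, 0.9, 0.5))[2:3]))

  # duplicate transcripts do not change the projection or the median
  ann2 <- gene_annotation(rbind(ann$exons,
                                transform(ann$exons, transcript_id = "t2")))
  expect_equal(gene_conservation_score(ann2, track2), sc2)

  # unscored projection flagged
  ann3 <- gene_annotation(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "chr1",
    start = 50, end = 60, strand = "+", biotype = "lincRNA"))
  sc4 <- gene_conservation_score(ann3, track3)
  expect_true(is.na(sc4$median_score))
  expect_equal(sc4$n_bases, 0L)

  # random track vs oracle
  set.seed(73)
  vv <- runif(500)
  trackr <- structure(list(chr1 = S4Vectors::Rle(vv)), class = "conservation_track")
  iv <- rand_intervals(6, 500, max_len = 40)
  annr <- gene_annotation(data.frame(
    gene_id = "g", transcript_id = paste0("t", 1:6), chrom = "chr1",
    start = iv$start, end = iv$end, strand = "+", biotype = "lincRNA"))
  scr <- gene_conservation_score(annr, trackr)
  covered <- which(mask_of(iv$start, iv$end, 500))
  expect_equal(scr$median_score, median(vv[covered]))
  expect_equal(scr$n_bases, length(covered))
})

test_that("rank-sum comparisons match exact enumeration on small sets", {
  a <- c(1.2, 3.4, 0.5); b <- c(2.2, 4.1, 5.0, 6.3)
  got <- rank_sum_test(a, b, alternative = "less", method = "exact")$p.value
  # enumerate all assignments of ranks to group a
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[1:3]) - 3 * 4 / 2
  combs <- combn(7, 3)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]) - 6)
  expect_equal(got, mean(w_all <= w_obs), tolerance = 1e-12)
  # identical sets: two-tailed normal-approximation p of 1
  expect_equal(compare_score_distributions(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # a clear shift is detected one-tailed
  set.seed(79)
  x <- rnorm(100); y <- rnorm(100) + 2
  expect_lt(compare_score_distributions(y, x, alternative = "greater")$p.value,
            1e-10)
})

test_that("conservation tracks round-trip through bedGraph", {
  cl <- c(chr1 = 4000, chr2 = 3000)
  gen <- generate_annotation(n_chroms = 2, chrom_length = 50000, n_mrna = 4,
                             n_lincrna = 3, n_antisense = 1, n_divergent = 1,
                             n_convergent = 1, slot_size = 10000, seed = 83)
  ct <- generate_conservation_track(gen$chrom_lengths, ann = gen$annotation,
                                    seed = 84)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(ct$track, f)
  back <- read_conservation_track(f, gen$chrom_lengths)
  for (chr in names(gen$chrom_lengths)) {
    expect_equal(as.numeric(back[[chr]]), as.numeric(ct$track[[chr]]),
                 tolerance = 1e-6)
  }
  # scores from the written file agree with in-memory scores
  s1 <- gene_conservation_score(gen$annotation, ct$track)
  s2 <- gene_conservation_score(gen$annotation, back)
  expect_equal(s2$median_score, s1$median_score, tolerance = 1e-6)
})
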