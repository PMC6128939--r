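test_that("exon projection merges overlapping and touching exons", {
  ann <- gene_annotation(data.frame(
    gene_id = "g", transcript_id = c("t1", "t1", "t2"), chrom = "chr1",
    start = c(100, 300, 150), end = c(200, 400, 250), strand = "+",
    biotype = "mRNA"))
  proj <- project_exons(ann)
  expect_equal(proj$start, c(100, 300))
  expect_equal(proj$end, c(250, 400))
  expect_equal(unname(projection_lengths(proj)), 250)

  # touching intervals merge under half-open semantics
  ann2 <- gene_annotation(data.frame(
    gene_id = "g", transcript_id = c("t1", "t2"), chrom = "chr1",
    start = c(100, 200), end = c(200, 300), strand = "+", biotype = "mRNA"))
  proj2 <- project_exons(ann2)
  expect_equal(nrow(proj2), 1L)
  expect_equal(c(proj2$start, proj2$end), c(100, 300))

  # single exon is its own projection
  ann3 <- gene_annotation(data.frame(
    gene_id = "g", transcript_id = "t1", chrom = "chr1",
    start = 100, end = 200, strand = "+", biotype = "mRNA"))
  expect_equal(unname(projection_lengths(project_exons(ann3))), 100)
})

test_that("projection is idempotent and matches a per-base mask oracle", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    iv <- rand_intervals(n, 10000)
    ann <- gene_annotation(data.frame(
      gene_id = "g", transcript_id = paste0("t", seq_len(n)),
      chrom = "chr1", start = iv$start, end = iv$end, strand = "+",
      biotype = "lincRNA"))
    proj <- project_exons(ann)
    oracle <- mask_to_intervals(mask_of(iv$start, iv$end, 10000))
    expect_equal(proj$start, oracle$start)
    expect_equal(proj$end, oracle$end)
    # idempotence: projecting the projection returns it unchanged
    ann_p <- gene_annotation(data.frame(
      gene_id = "g", transcript_id = paste0("p", seq_len(nrow(proj))),
      chrom = "chr1", start = proj$start, end = proj$end, strand = "+",
      biotype = "lincRNA"))
    expect_equal(project_exons(ann_p)[, c("start", "end")],
                 proj[, c("start", "end")])
  }
})

test_that("promoter windows are strand-aware, clipped and flagged", {
  mk <- function(start, end, strand) gene_annotation(data.frame(
    gene_id = "g", transcript_id = "t", chrom = "chr1",
    start = start, end = end, strand = strand, biotype = "mRNA"))
  p <- promoter_regions(mk(10000, 12000, "+"), 5000, c(chr1 = 20000))
  expect_equal(c(p$start, p$end), c(5000, 10000))
  p <- promoter_regions(mk(10000, 12000, "-"), 5000, c(chr1 = 20000))
  expect_equal(c(p$start, p$end), c(12000, 17000))
  # clipped at the chromosome start
  p <- promoter_regions(mk(2000, 4000, "+"), 5000, c(chr1 = 20000))
  expect_equal(c(p$start, p$end), c(0, 2000))
  expect_false(p$degenerate)
  # fully clipped -> degenerate
  p <- promoter_regions(mk(100, 4000, "-"), 5000, c(chr1 = 4000))
  expect_true(p$degenerate)
  expect_error(promoter_regions(mk(100, 4000, "+"), 5000, c(chr1 = 3000)),
               "beyond chromosome end")
  expect_error(promoter_regions(mk(100, 4000, "+"), 5000, c(chr2 = 9000)),
               "missing chromosome")
})

test_that("overlap_length projects its inputs and matches brute force", {
  a <- data.frame(chrom = "chr1", start = 100, end = 250)
  expect_equal(overlap_length(a, data.frame(chrom = "chr1", start = 200, end = 300)), 50)
  # internally overlapping b is projected first: shared bases count once,
  # so adding [240,260) inside [200,300) changes nothing
  b <- data.frame(chrom = "chr1", start = c(200, 240), end = c(300, 260))
  expect_equal(overlap_length(a, b), 50)
  expect_equal(overlap_length(a, data.frame(chrom = "chr1", start = 300, end = 400)), 0)
  expect_equal(overlap_length(a, data.frame(chrom = "chr2", start = 100, end = 250)), 0)

  set.seed(7)
  for (rep in 1:200) {
    a <- rand_intervals(sample(1:12, 1), 2000)
    b <- rand_intervals(sample(1:12, 1), 2000)
    got <- overlap_length(a, b)
    want <- sum(mask_of(a$start, a$end, 2000) & mask_of(b$start, b$end, 2000))
    expect_identical(got, as.numeric(want))
    # symmetry after projection
    expect_identical(overlap_length(b, a), got)
  }
})

test_that("annotation invariants are enforced at construction", {
  base <- data.frame(gene_id = "g", transcript_id = "t", chrom = "chr1",
                     start = 10, end = 20, strand = "+", biotype = "mRNA")
  expect_error(gene_annotation(transform(base, end = 10)), "must be > start")
  expect_error(gene_annotation(transform(base, start = -5)), ">= 0")
  expect_error(gene_annotation(transform(base, strand = ".")), "strand")
  expect_error(gene_annotation(transform(base, biotype = "pseudogene")), "biotype")
  # overlapping exons within one transcript
  two <- rbind(base, transform(base, start = 15, end = 30))
  expect_error(gene_annotation(two), "overlapping exons")
  # inconsistent strand across a gene's exons
  two2 <- rbind(base, transform(base, start = 30, end = 40, strand = "-"))
  expect_error(gene_annotation(two2), "inconsistent")
})

test_that("GTF round-trips preserve gene models exactly", {
  gen <- generate_annotation(n_mrna = 12, n_lincrna = 8, n_antisense = 3,
                             n_divergent = 2, n_convergent = 2, seed = 42)
  f1 <- tempfile(fileext = ".gtf"); f2 <- tempfile(fileext = ".gtf")
  write_gtf(gen$annotation, f1)
  back <- read_gtf(f1)
  expect_equal(genes(back)[order(genes(back)$gene_id), ],
               genes(gen$annotation)[order(genes(gen$annotation)$gene_id), ],
               ignore_attr = TRUE)
  srt <- function(e) {
    e <- e[order(e$gene_id, e$transcript_id, e$start), ]
    rownames(e) <- NULL
    e[, sort(names(e))]
  }
  expect_equal(srt(back$exons), srt(gen$annotation$exons))
  # write -> read -> write is byte-stable
  write_gtf(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("TE tables read from rmsk TSV and class/family BED", {
  rmsk <- tempfile(fileext = ".tsv")
  writeLines(c(
    "genoName\tgenoStart\tgenoEnd\trepClass\trepFamily",
    "chr1\t100\t280\tSINE\tSINEC_Cf",
    "chr1\t500\t900\tLINE\tL1_Cf",
    "chr2\t10\t60\tSimple_repeat\t(TA)n"), rmsk)
  tes <- read_te_table(rmsk)
  expect_equal(nrow(tes), 2L)             # non-major classes dropped
  expect_equal(attr(tes, "n_dropped"), 1L)
  expect_equal(tes$te_family, c("SINEC_Cf", "L1_Cf"))

  bed <- tempfile(fileext = ".bed")
  write_bed(tes, bed)
  back <- read_te_table(bed)
  expect_equal(back[, c("chrom", "start", "end", "te_class", "te_family")],
               tes[, c("chrom", "start", "end", "te_class", "te_family")],
               ignore_attr = TRUE)
  expect_error(te_records(data.frame(chrom = "chr1", start = 1, end = 5,
                                     te_class = "ALU", te_family = "x")),
               "unknown TE class")
})
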