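#' The 26-tissue panel used by the synthetic generators
#'
#' A panel of 26 tissues grouped by anatomical system (nervous,
#' integumental, digestive, musculoskeletal systems, testis, and unmapped
#' single tissues), including the 11 tissues of [matched_tissues()].
#'
#' @return data.frame `tissue`, `system`.
#' @export
dog_tissues <- function() {
  data.frame(
    tissue = c(
      "brain", "cerebellum", "cortex", "olfactory_bulb", "spinal_cord",
      "skin", "footpad", "nose", "lip", "ear", "mammary_gland",
      "gut_colon", "stomach",
      "heart", "muscle",
      "testis",
      "adrenal_gland", "bladder", "blood", "kidney", "liver", "lung",
      "ovary", "pancreas", "spleen", "thyroid"
    ),
    system = c(
      rep("nervous", 5), rep("integumental", 6), rep("digestive", 2),
      rep("musculoskeletal", 2), "testis", rep("unmapped", 10)
    ),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# annotation generator

.make_exons <- function(span_start, span_end, max_exons = 10L) {
  len <- span_end - span_start
  n_ex <- sample.int(min(max_exons, max(1L, len %/% 300L)), 1L)
  if (n_ex == 1L) {
    ex <- data.frame(start = span_start, end = span_end)
  } else {
    n_seg <- 2L * n_ex - 1L # exons and introns alternate, exons at both ends
    w <- stats::runif(n_seg, 0.5, 1.5)
    w <- pmax(50L, floor(w / sum(w) * len))
    w[n_seg] <- len - sum(w[-n_seg]) # absorb rounding in last exon
    if (w[n_seg] < 50L) { # fall back to a single exon on tiny spans
      ex <- data.frame(start = span_start, end = span_end)
    } else {
      edge <- span_start + cumsum(c(0L, w))
      ex <- data.frame(start = edge[seq(1, n_seg, by = 2)],
                       end = edge[seq(2, n_seg + 1, by = 2)])
    }
  }
  n_ex <- nrow(ex)
  n_tx <- sample.int(3L, 1L)
  tx <- list(seq_len(n_ex))
  if (n_tx > 1L && n_ex > 1L) {
    for (t in seq_len(n_tx - 1L)) {
      i <- sample.int(n_ex, 1L); j <- sample(i:n_ex, 1L)
      tx[[t + 1L]] <- i:j
    }
  }
  do.call(rbind, lapply(seq_along(tx), function(t) {
    data.frame(transcript_id = sprintf("tx%d", t),
               start = ex$start[tx[[t]]], end = ex$end[tx[[t]]])
  }))
}

#' Generate a synthetic gene annotation with planted pair geometries
#'
#' Lays out non-overlapping gene loci on evenly sized slots along the
#' synthetic chromosomes. Antisense genes are planted inside an mRNA
#' locus on the opposite strand with guaranteed exonic overlap; quotas of
#' lincRNAs are planted immediately adjacent to an mRNA in head-to-head
#' (divergent) or tail-to-tail (convergent) orientation at controlled
#' gaps. Gene models have 1-10 exons and 1-3 transcripts. Fully
#' deterministic given the seed.
#'
#' @param n_chroms,chrom_length number and length (bp) of chromosomes.
#' @param n_mrna,n_lincrna,n_antisense gene counts per biotype.
#' @param n_divergent,n_convergent lincRNA quotas planted in divergent /
#'   convergent geometry (drawn from the lincRNA count).
#' @param slot_size locus slot size in bp.
#' @param seed RNG seed.
#' @return list with `annotation` (a [gene_annotation()]), `chrom_lengths`
#'   (named vector) and `truth` (per-gene planted attributes: data.frame
#'   `gene_id`, `biotype`, `planted_class`, `partner`).
#' @export
generate_annotation <- function(n_chroms = 2, chrom_length = 2.5e6,
                                n_mrna = 80, n_lincrna = 60, n_antisense = 10,
                                n_divergent = 10, n_convergent = 10,
                                slot_size = 25000, seed = 1) {
  stopifnot(n_mrna >= 0, n_lincrna >= 0, n_antisense >= 0,
            n_divergent >= 0, n_convergent >= 0)
  if (n_antisense > n_mrna) stop("n_antisense cannot exceed n_mrna")
  if (n_divergent + n_convergent > min(n_mrna, n_lincrna)) {
    stop("planted divergent + convergent quotas exceed available genes")
  }
  slots_per_chrom <- floor(chrom_length / slot_size)
  if (n_mrna + n_lincrna > n_chroms * slots_per_chrom) {
    stop("infeasible packing: increase chrom_length or n_chroms")
  }
  chrom_lengths <- stats::setNames(rep(chrom_length, n_chroms),
                                   sprintf("chr%d", seq_len(n_chroms)))
  with_seed(seed, {
    # units: paired (divergent/convergent lincRNA + mRNA, two adjacent
    # slots on one chromosome) and singles
    units <- c(rep("div", n_divergent), rep("conv", n_convergent),
               rep("mrna", n_mrna - n_divergent - n_convergent),
               rep("linc", n_lincrna - n_divergent - n_convergent))
    units <- sample(units)
    exon_rows <- list()
    truth <- list()
    id_counter <- c(mrna = 0L, linc = 0L, anti = 0L)
    mrna_slots <- list() # slot info for later antisense planting
    chrom_i <- 1L; slot_i <- 1L
    next_slot <- function() {
      if (slot_i > slots_per_chrom) { chrom_i <<- chrom_i + 1L; slot_i <<- 1L }
      if (chrom_i > n_chroms) stop("infeasible packing: increase chrom_length")
      s <- list(chrom = names(chrom_lengths)[chrom_i],
                start = (slot_i - 1L) * slot_size)
      slot_i <<- slot_i + 1L
      s
    }
    place_gene <- function(slot, strand, min_len, max_len, at = "random") {
      len <- round(stats::runif(1, min_len, max_len))
      margin <- 500L
      lo <- slot$start + margin
      hi <- slot$start + slot_size - margin - len
      start <- switch(at,
        random = round(stats::runif(1, lo, hi)),
        right = slot$start + slot_size - round(stats::runif(1, 500, 5000)) - len,
        left = slot$start + round(stats::runif(1, 500, 5000))
      )
      c(start = start, end = start + len)
    }
    add_gene <- function(prefix, biotype, chrom, strand, span, single_exon = FALSE) {
      key <- c(MRNA = "mrna", LINC = "linc", ANTI = "anti")[[prefix]]
      id_counter[key] <<- id_counter[key] + 1L
      gid <- sprintf("%s_%04d", prefix, id_counter[key])
      ex <- if (single_exon) {
        data.frame(transcript_id = "tx1", start = span[["start"]], end = span[["end"]])
      } else {
        .make_exons(span[["start"]], span[["end"]])
      }
      ex$gene_id <- gid; ex$chrom <- chrom; ex$strand <- strand; ex$biotype <- biotype
      ex$transcript_id <- paste(gid, ex$transcript_id, sep = ".")
      exon_rows[[length(exon_rows) + 1L]] <<- ex
      gid
    }
    for (u in units) {
      if (u %in% c("div", "conv")) {
        # pair needs two adjacent slots on the same chromosome
        if (slot_i == slots_per_chrom) {
          s <- next_slot() # burn the chromosome-final slot with a single
          span <- place_gene(s, NULL, 500, 5000)
          gid <- add_gene("LINC", "lincRNA", s$chrom, sample(c("+", "-"), 1), span)
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = gid, biotype = "lincRNA",
            planted_class = NA_character_, partner = NA_character_)
        }
        s1 <- next_slot(); s2 <- next_slot()
        lnc_strand <- if (u == "div") "-" else "+"
        mrna_strand <- if (u == "div") "+" else "-"
        lnc_span <- place_gene(s1, lnc_strand, 500, 5000, at = "right")
        mrna_span <- place_gene(s2, mrna_strand, 2000, 15000, at = "left")
        lid <- add_gene("LINC", "lincRNA", s1$chrom, lnc_strand, lnc_span)
        mid <- add_gene("MRNA", "mRNA", s2$chrom, mrna_strand, mrna_span)
        mrna_slots[[mid]] <- list(chrom = s2$chrom)
        cls <- if (u == "div") "divergent" else "convergent"
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = lid, biotype = "lincRNA", planted_class = cls, partner = mid)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = mid, biotype = "mRNA", planted_class = NA_character_,
          partner = NA_character_)
      } else if (u == "mrna") {
        s <- next_slot()
        span <- place_gene(s, NULL, 2000, 15000)
        gid <- add_gene("MRNA", "mRNA", s$chrom, sample(c("+", "-"), 1), span)
        mrna_slots[[gid]] <- list(chrom = s$chrom)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, biotype = "mRNA",
          planted_class = NA_character_, partner = NA_character_)
      } else {
        s <- next_slot()
        span <- place_gene(s, NULL, 500, 5000)
        gid <- add_gene("LINC", "lincRNA", s$chrom, sample(c("+", "-"), 1), span)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = gid, biotype = "lincRNA",
          planted_class = NA_character_, partner = NA_character_)
      }
    }
    exons <- do.call(rbind, exon_rows)
    # plant antisense genes inside randomly chosen mRNA loci: a single-exon
    # gene nested in the host's longest exon on the opposite strand, so
    # span overlap and exonic overlap both hold by construction
    hosts <- sample(names(mrna_slots), n_antisense)
    for (mid in hosts) {
      hex <- exons[exons$gene_id == mid, , drop = FALSE]
      widths <- hex$end - hex$start
      k <- which.max(widths)
      ex_len <- widths[k]
      len <- max(100L, min(ex_len - 2L, round(stats::runif(1, 300, 2000))))
      start <- hex$start[k] + sample.int(ex_len - len, 1L) - 1L
      strand <- if (hex$strand[1] == "+") "-" else "+"
      gid <- add_gene("ANTI", "antisense", hex$chrom[1], strand,
                      c(start = start, end = start + len), single_exon = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gid, biotype = "antisense",
        planted_class = "antisense_exonic", partner = mid)
    }
    exons <- do.call(rbind, exon_rows)
    ann <- if (!is.null(exons) && nrow(exons)) {
      gene_annotation(exons[, c("gene_id", "transcript_id", "chrom",
                                "start", "end", "strand", "biotype")])
    } else {
      gene_annotation(data.frame(gene_id = character(), transcript_id = character(),
                                 chrom = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 biotype = character()))
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(), biotype = character(),
                 planted_class = character(), partner = character())
    rownames(truth_df) <- NULL
    list(annotation = ann, chrom_lengths = chrom_lengths,
         truth = truth_df, seed = seed)
  })
}

# ---------------------------------------------------------------------------
# expression generator

# Pearson correlation on the latent Gaussian scale that induces a target
# Spearman correlation under a Gaussian copula.
.copula_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic expression matrix with planted structure
#'
#' Draws log-normal baseline expression per gene (lncRNA baselines lower
#' than mRNA by `lnc_factor`, default 20x) and multiplicative log-normal
#' noise with coefficient of variation `noise_cv`. On top of that it can
#' plant: tissue-specific genes (high in one tissue, background elsewhere,
#' below the usual 1-TPM floor), co-expressed gene pairs (both members
#' driven by a shared per-tissue latent factor whose weight is chosen
#' analytically, via the Gaussian-copula inversion
#' `rho_pearson = 2 sin(pi rho_spearman / 6)`, to hit a target Spearman
#' correlation in expectation), and anatomical-system tissue blocks
#' (per-gene random loadings shared by the tissues of a block, which make
#' within-block tissues correlate).
#'
#' @param genes a [gene_annotation()] or data.frame `gene_id`, `biotype`.
#' @param tissues tissue names (default the 26-tissue panel).
#' @param planted_specific optional data.frame `gene_id`, `tissue`, `fold`:
#'   tissue-specific genes at `fold` times the off-tissue background.
#' @param planted_pairs optional data.frame `gene_a`, `gene_b`,
#'   `target_rho` (Spearman target in `[0, 0.99]`).
#' @param noise_cv coefficient of variation of multiplicative noise.
#' @param base_meanlog,base_sdlog log-normal baseline for mRNA mean TPM.
#' @param lnc_factor lncRNA baselines are this factor below mRNA.
#' @param broad_min_tpm baseline above which a non-planted gene is
#'   recorded as regime `broad` in the truth (below: `low`).
#' @param specific_background_tpm off-tissue background of planted
#'   specific genes.
#' @param tissue_blocks optional data.frame `tissue`, `block` planting
#'   shared latent profiles per block.
#' @param block_sd standard deviation of the per-gene block loadings.
#' @param seed RNG seed.
#' @return list `matrix` (genes x tissues TPM), `truth` (list with `genes`
#'   data.frame: `gene_id`, `biotype`, `baseline_tpm`, `regime`,
#'   `specific_tissue`, `fold`; and `pairs` data.frame).
#' @export
generate_expression <- function(genes, tissues = dog_tissues()$tissue,
                                planted_specific = NULL, planted_pairs = NULL,
                                noise_cv = 0.2,
                                base_meanlog = log(30), base_sdlog = 1,
                                lnc_factor = 20, broad_min_tpm = 5,
                                specific_background_tpm = 0.1,
                                tissue_blocks = NULL, block_sd = 1,
                                seed = 1) {
  stopifnot(noise_cv > 0)
  if (inherits(genes, "gene_annotation")) genes <- genes(genes)
  .check_columns(genes, c("gene_id", "biotype"), "gene table")
  ng <- nrow(genes); nt <- length(tissues)
  if (anyDuplicated(tissues)) stop("duplicated tissue names")
  check_ids <- function(ids, what) {
    bad <- setdiff(ids, genes$gene_id)
    if (length(bad)) stop("unknown gene id(s) in ", what, ": ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(planted_specific)) {
    .check_columns(planted_specific, c("gene_id", "tissue", "fold"), "planted_specific")
    check_ids(planted_specific$gene_id, "planted_specific")
    bad_t <- setdiff(planted_specific$tissue, tissues)
    if (length(bad_t)) stop("unknown tissue(s) in planted_specific: ",
                            paste(bad_t, collapse = ", "))
  }
  if (!is.null(planted_pairs)) {
    .check_columns(planted_pairs, c("gene_a", "gene_b", "target_rho"), "planted_pairs")
    check_ids(c(planted_pairs$gene_a, planted_pairs$gene_b), "planted_pairs")
    if (any(planted_pairs$target_rho < 0 | planted_pairs$target_rho > 0.99)) {
      stop("target_rho must lie in [0, 0.99]")
    }
  }
  sigma <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    meanlog <- base_meanlog - ifelse(genes$biotype == "mRNA", 0, log(lnc_factor))
    baseline <- stats::rlnorm(ng, meanlog, base_sdlog)
    logx <- matrix(stats::rnorm(ng * nt, 0, sigma), ng, nt,
                   dimnames = list(genes$gene_id, tissues))
    logx <- logx + log(baseline)

    pair_ids <- if (is.null(planted_pairs)) character(0) else
      unique(c(planted_pairs$gene_a, planted_pairs$gene_b))
    spec_ids <- if (is.null(planted_specific)) character(0) else
      planted_specific$gene_id
    plain <- !(genes$gene_id %in% c(pair_ids, spec_ids))

    if (!is.null(tissue_blocks)) {
      .check_columns(tissue_blocks, c("tissue", "block"), "tissue_blocks")
      for (b in unique(tissue_blocks$block)) {
        cols <- tissue_blocks$tissue[tissue_blocks$block == b]
        loading <- stats::rnorm(ng, 0, block_sd) * plain
        logx[, cols] <- logx[, cols] + loading
      }
    }

    pairs_truth <- NULL
    if (!is.null(planted_pairs)) {
      alpha <- sigma * sqrt(.copula_pearson(planted_pairs$target_rho) /
                              (1 - .copula_pearson(planted_pairs$target_rho)))
      for (i in seq_len(nrow(planted_pairs))) {
        z <- stats::rnorm(nt)
        for (g in c(planted_pairs$gene_a[i], planted_pairs$gene_b[i])) {
          logx[g, ] <- log(baseline[match(g, genes$gene_id)]) + alpha[i] * z +
            stats::rnorm(nt, 0, sigma)
        }
      }
      pairs_truth <- cbind(planted_pairs, latent_weight = alpha)
    }

    if (!is.null(planted_specific)) {
      for (i in seq_len(nrow(planted_specific))) {
        g <- planted_specific$gene_id[i]
        mu <- rep(log(specific_background_tpm), nt)
        mu[match(planted_specific$tissue[i], tissues)] <-
          log(specific_background_tpm * planted_specific$fold[i])
        logx[g, ] <- mu + stats::rnorm(nt, 0, sigma)
      }
    }

    mat <- exp(logx)
    regime <- ifelse(genes$gene_id %in% spec_ids, "specific",
                     ifelse(genes$gene_id %in% pair_ids, "pair",
                            ifelse(baseline >= broad_min_tpm, "broad", "low")))
    truth_genes <- data.frame(
      gene_id = genes$gene_id, biotype = genes$biotype,
      baseline_tpm = baseline, regime = regime,
      specific_tissue = NA_character_, fold = NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(planted_specific)) {
      idx <- match(planted_specific$gene_id, truth_genes$gene_id)
      truth_genes$specific_tissue[idx] <- planted_specific$tissue
      truth_genes$fold[idx] <- planted_specific$fold
    }
    list(matrix = mat,
         truth = list(genes = truth_genes, pairs = pairs_truth,
                      noise_cv = noise_cv, seed = seed))
  })
}

# ---------------------------------------------------------------------------
# TE landscape generator

#' Default synthetic TE family mix
#'
#' Family weights and typical copy lengths loosely shaped like a canine
#' repeat landscape: SINEC_Cf-dominated SINEs, long L1-type LINEs,
#' ERVL-type LTRs and DNA transposons.
#'
#' @return data.frame `te_family`, `te_class`, `weight` (bp share of TE
#'   coverage), `mean_len` (bp).
#' @export
default_te_families <- function() {
  data.frame(
    te_family = c("SINEC_Cf", "SINEC_old", "L1_Cf", "L2", "LTR_ERVL",
                  "LTR_other", "hAT_Charlie", "TcMar_Tigger"),
    te_class = c("SINE", "SINE", "LINE", "LINE", "LTR", "LTR", "DNA", "DNA"),
    weight = c(0.25, 0.05, 0.30, 0.10, 0.08, 0.07, 0.08, 0.07),
    mean_len = c(180, 180, 3000, 800, 500, 450, 300, 300),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic transposable-element landscape
#'
#' Places background TE copies uniformly along the chromosomes so that the
#' expected genome coverage and per-family bp shares match the requested
#' mix, then optionally plants extra copies of one family inside named
#' regions (e.g. promoters of tissue-specific lncRNAs) so the expected
#' per-region content fraction of that family is raised by a given factor
#' over background.
#'
#' @param chrom_lengths named chromosome lengths.
#' @param families family mix as in [default_te_families()].
#' @param coverage target genome-wide TE coverage fraction before merging.
#' @param enrichment optional list with elements `family` (name),
#'   `regions` (interval data.frame `chrom`, `start`, `end`, optionally
#'   `gene_id`) and `factor` (>= 1, scalar or one value per region row).
#' @param depletion optional list of lists, each with `regions` (interval
#'   data.frame) and `keep_prob` in `[0, 1]`: background copies
#'   overlapping the regions are retained with that probability, which
#'   emulates purifying selection against TE insertions (strong in coding
#'   exons, weaker in lncRNA exons).
#' @param seed RNG seed.
#' @return list `tes` (a [te_records()] table sorted by position) and
#'   `truth` (the generating configuration).
#' @export
generate_te_landscape <- function(chrom_lengths, families = default_te_families(),
                                  coverage = 0.35, enrichment = NULL,
                                  depletion = NULL, seed = 1) {
  .check_columns(families, c("te_family", "te_class", "weight", "mean_len"),
                 "families")
  if (!is.null(enrichment)) {
    stopifnot(is.list(enrichment),
              all(c("family", "regions", "factor") %in% names(enrichment)))
    if (any(enrichment$factor < 1)) stop("enrichment factors must be >= 1")
    if (!enrichment$family %in% families$te_family) {
      stop("enrichment family not in the family mix")
    }
  }
  genome_bp <- sum(as.numeric(chrom_lengths))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(families))) {
      target_bp <- coverage * families$weight[i] * genome_bp
      n <- max(0L, round(target_bp / families$mean_len[i]))
      if (n == 0L) next
      chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                      prob = chrom_lengths / genome_bp)
      len <- pmax(50L, round(stats::rnorm(n, families$mean_len[i],
                                          0.3 * families$mean_len[i])))
      start <- floor(stats::runif(n, 0, chrom_lengths[chrom] - len))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = start + len,
        te_class = families$te_class[i], te_family = families$te_family[i],
        stringsAsFactors = FALSE
      )
    }
    if (!is.null(depletion) && length(rows)) {
      bg <- do.call(rbind, rows)
      rows <- list()
      keep <- rep(TRUE, nrow(bg))
      bg_gr <- .as_granges(bg, ignore_strand = TRUE)
      for (dep in depletion) {
        stopifnot(all(c("regions", "keep_prob") %in% names(dep)),
                  dep$keep_prob >= 0, dep$keep_prob <= 1)
        hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
          bg_gr, .as_granges(dep$regions, ignore_strand = TRUE),
          ignore.strand = TRUE)))
        drop <- hit[stats::runif(length(hit)) > dep$keep_prob]
        keep[drop] <- FALSE
      }
      rows[[1L]] <- bg[keep, , drop = FALSE]
    }
    if (!is.null(enrichment)) {
      fam <- enrichment$family
      fi <- match(fam, families$te_family)
      f_bg <- coverage * families$weight[fi]
      reg <- enrichment$regions
      .check_columns(reg, c("chrom", "start", "end"), "enrichment regions")
      fac <- rep_len(enrichment$factor, nrow(reg))
      for (r in seq_len(nrow(reg))) {
        width <- reg$end[r] - reg$start[r]
        if (width <= 0) next
        m <- stats::rpois(1L, (fac[r] - 1) * f_bg * width / families$mean_len[fi])
        if (m == 0L) next
        len <- pmax(50L, round(stats::rnorm(m, families$mean_len[fi],
                                            0.3 * families$mean_len[fi])))
        start <- floor(stats::runif(m, reg$start[r], pmax(reg$start[r] + 1,
                                                          reg$end[r] - len)))
        end <- pmin(start + len, chrom_lengths[[reg$chrom[r]]])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = reg$chrom[r], start = start, end = end,
          te_class = families$te_class[fi], te_family = fam,
          stringsAsFactors = FALSE
        )
      }
    }
    tes <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 te_class = character(), te_family = character())
    tes <- tes[order(tes$chrom, tes$start, tes$end, tes$te_family), , drop = FALSE]
    rownames(tes) <- NULL
    list(tes = te_records(tes),
         truth = list(coverage = coverage, families = families,
                      enrichment = enrichment, depletion = depletion,
                      seed = seed))
  })
}

# ---------------------------------------------------------------------------
# ortholog panel generator

#' Generate a synthetic 1:1 ortholog panel with conservation strata
#'
#' Produces pairs of matched-tissue expression vectors whose rank
#' correlation is targeted per stratum through a Gaussian copula: latent
#' bivariate normal samples with Pearson correlation
#' `2 sin(pi rho_s / 6)` are transformed monotonically to TPM-like
#' values, which preserves the Spearman correlation.
#'
#' @param n_per_stratum pairs per stratum.
#' @param k number of matched tissues (>= 4).
#' @param strata named numeric vector of target Spearman correlations.
#' @param tissues tissue names; defaults to [matched_tissues()] when
#'   `k == 11`.
#' @param biotype biotype recorded in the ortholog map.
#' @param seed RNG seed.
#' @return list `orthologs` (`gene_a`, `gene_b`, `biotype`), `expr_a`,
#'   `expr_b` (genes x k TPM matrices), `truth` (`gene_a`, `stratum`,
#'   `target_rho`).
#' @export
generate_ortholog_panel <- function(n_per_stratum = 200, k = 11,
                                    strata = c(high = 0.9, intermediate = 0.5,
                                               divergent = 0.0),
                                    tissues = NULL, biotype = "lincRNA",
                                    seed = 1) {
  if (k < 4) stop("need k >= 4 matched tissues")
  if (is.null(tissues)) {
    tissues <- if (k == 11) matched_tissues() else sprintf("tissue%02d", seq_len(k))
  }
  stopifnot(length(tissues) == k)
  with_seed(seed, {
    rows <- list(); ea <- list(); eb <- list()
    for (s in names(strata)) {
      rho_p <- .copula_pearson(strata[[s]])
      for (i in seq_len(n_per_stratum)) {
        za <- stats::rnorm(k)
        zb <- rho_p * za + sqrt(1 - rho_p^2) * stats::rnorm(k)
        ga <- sprintf("DOG_%s_%04d", s, i)
        gb <- sprintf("HUM_%s_%04d", s, i)
        ea[[ga]] <- exp(1 + 1.2 * za)
        eb[[gb]] <- exp(1 + 1.2 * zb)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = ga, gene_b = gb, biotype = biotype, stratum = s,
          target_rho = strata[[s]], stringsAsFactors = FALSE
        )
      }
    }
    truth <- do.call(rbind, rows)
    expr_a <- do.call(rbind, ea); colnames(expr_a) <- tissues
    expr_b <- do.call(rbind, eb); colnames(expr_b) <- tissues
    list(
      orthologs = truth[, c("gene_a", "gene_b", "biotype")],
      expr_a = expr_a, expr_b = expr_b,
      truth = truth[, c("gene_a", "gene_b", "stratum", "target_rho")],
      seed = seed
    )
  })
}

# ---------------------------------------------------------------------------
# conservation track generator

#' Generate a synthetic per-base conservation track
#'
#' Draws windowed Gaussian background scores along each chromosome and
#' raises the mean inside the exon projections of annotated genes by a
#' per-biotype offset (so e.g. mRNA exons score higher than lncRNA
#' exons). Returned as a run-length encoded per-base score map.
#'
#' @param chrom_lengths named chromosome lengths.
#' @param ann optional [gene_annotation()] whose exons get elevated means.
#' @param exon_means named per-biotype mean scores inside exons.
#' @param background_mean,background_sd background window score
#'   distribution.
#' @param window window size in bp for background score draws.
#' @param seed RNG seed.
#' @return list `track` (a `conservation_track`) and `truth` (data.frame
#'   `gene_id`, `biotype`, `intended_mean`).
#' @export
generate_conservation_track <- function(chrom_lengths, ann = NULL,
                                        exon_means = c(mRNA = 0.4,
                                                       lincRNA = 0.15,
                                                       antisense = 0.15),
                                        background_mean = 0,
                                        background_sd = 0.3,
                                        window = 25, seed = 1) {
  stopifnot(all(is.finite(exon_means)), window >= 1)
  with_seed(seed, {
    track <- lapply(names(chrom_lengths), function(chr) {
      L <- chrom_lengths[[chr]]
      n_win <- ceiling(L / window)
      vals <- stats::rnorm(n_win, background_mean, background_sd)
      lens <- rep(window, n_win)
      lens[n_win] <- L - (n_win - 1) * window
      S4Vectors::Rle(vals, lens)
    })
    names(track) <- names(chrom_lengths)
    truth <- NULL
    if (!is.null(ann)) {
      proj <- project_exons(ann)
      bt <- genes(ann)$biotype[match(proj$gene_id, genes(ann)$gene_id)]
      delta <- exon_means[bt] - background_mean
      gr <- GenomicRanges::GRanges(
        proj$chrom, IRanges::IRanges(proj$start + 1L, proj$end),
        seqinfo = GenomeInfoDb::Seqinfo(names(chrom_lengths),
                                        unname(chrom_lengths))
      )
      cov <- GenomicRanges::coverage(gr, weight = unname(delta))
      for (chr in names(track)) {
        if (chr %in% names(cov)) {
          track[[chr]] <- track[[chr]] + cov[[chr]]
        }
      }
      g <- genes(ann)
      truth <- data.frame(gene_id = g$gene_id, biotype = g$biotype,
                          intended_mean = unname(exon_means[g$biotype]),
                          stringsAsFactors = FALSE)
    }
    list(track = structure(track, class = "conservation_track"),
         truth = truth, seed = seed)
  })
}

#' Write a synthetic-truth object as JSON
#'
#' @param truth any truth list/data.frame from the generators.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a truth JSON written by [write_truth()]
#'
#' @param path JSON file path.
#' @return the truth object (data.frames restored column-wise).
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path)
}
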