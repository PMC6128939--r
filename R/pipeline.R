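#' Pipeline configuration
#'
#' Collects every tunable threshold of the staged analysis plus the
#' simulation layout, validates ranges, and fixes the single seed from
#' which all stage randomness derives. The configuration is serialized
#' into the output directory for provenance when `simulate` runs.
#'
#' @param outdir output/working directory for stage artifacts.
#' @param seed top-level RNG seed.
#' @param floor_tpm tau expression floor (TPM).
#' @param tau_threshold tissue-specificity cut-off.
#' @param expressed_tpm "expressed" threshold (strict, TPM).
#' @param rho_threshold,padj_threshold co-expression significance rule.
#' @param window lncRNA:mRNA pairing window (bp).
#' @param promoter_size promoter window (bp).
#' @param conservation_cuts p-value cut-offs for the conservation classes.
#' @param lambda1,lambda2,ncomp ridge CCA parameters.
#' @param simulate named list overriding simulation defaults (gene counts,
#'   chromosome layout, planted structure sizes, noise).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1,
                            floor_tpm = 1, tau_threshold = 0.95,
                            expressed_tpm = 1,
                            rho_threshold = 0.5, padj_threshold = 0.05,
                            window = 1e6, promoter_size = 5000,
                            conservation_cuts = c(0.05, 0.2),
                            lambda1 = 0.1, lambda2 = 0.1, ncomp = 3,
                            simulate = list()) {
  stopifnot(
    floor_tpm >= 0, tau_threshold >= 0, tau_threshold <= 1,
    expressed_tpm >= 0, rho_threshold >= 0, rho_threshold <= 1,
    padj_threshold > 0, padj_threshold <= 1, window > 0, promoter_size > 0,
    length(conservation_cuts) == 2L, conservation_cuts[1] < conservation_cuts[2],
    lambda1 >= 0, lambda2 >= 0, ncomp >= 1
  )
  sim <- utils::modifyList(list(
    n_chroms = 2, chrom_length = 2.5e6,
    n_mrna = 80, n_lincrna = 60, n_antisense = 10,
    n_divergent = 10, n_convergent = 10,
    n_specific = 20, specific_fold = 50, noise_cv = 0.2,
    pair_rho = 0.8, n_coexpr_pairs = 8,
    te_coverage = 0.35, te_enrich_family = "SINEC_Cf", te_enrich_factor = 5,
    n_ortholog_per_stratum = 100,
    block_sd = 1
  ), simulate)
  structure(list(
    outdir = outdir, seed = as.integer(seed),
    floor_tpm = floor_tpm, tau_threshold = tau_threshold,
    expressed_tpm = expressed_tpm,
    rho_threshold = rho_threshold, padj_threshold = padj_threshold,
    window = window, promoter_size = promoter_size,
    conservation_cuts = conservation_cuts,
    lambda1 = lambda1, lambda2 = lambda2, ncomp = ncomp,
    simulate = sim
  ), class = "pipeline_config")
}

.pipeline_path <- function(cfg, file) file.path(cfg$outdir, file)

.require_artifacts <- function(cfg, files, needed_stage) {
  missing <- files[!file.exists(vapply(files, function(f) .pipeline_path(cfg, f), ""))]
  if (length(missing)) {
    stop(sprintf("missing artifact(s) %s: run stage '%s' first",
                 paste(missing, collapse = ", "), needed_stage))
  }
}

.stage_log <- function(cfg, stage, msg) {
  message(sprintf("[lncscape %s seed=%d] %s", stage, cfg$seed, msg))
}

#' Run a pipeline stage
#'
#' Stages: `simulate` (generate all synthetic inputs and the truth file),
#' `tau` (specificity scores and per-tissue proportions), `cluster`
#' (tissue correlation matrices and dendrograms per biotype), `te` (TE
#' content of exons/promoters, genome fractions, ridge CCA versus tissue
#' expression), `pairs` (positional lncRNA:mRNA pair classification),
#' `coexpr` (pair correlation, BH, distance and partner-rank analyses),
#' `conserve` (ortholog conservation classes and per-gene conservation
#' scores), `report` (aggregate summary JSON), or `all`. Stages are
#' idempotent and re-runnable from persisted upstream artifacts; a
#' missing prerequisite raises an error naming the stage to run first.
#'
#' @param stage stage name (see above).
#' @param config a [pipeline_config()].
#' @return invisibly, the paths of the artifacts written by the stage.
#' @export
run_stage <- function(stage = c("all", "simulate", "tau", "cluster", "te",
                                "pairs", "coexpr", "conserve", "report"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  if (stage == "all") {
    out <- unlist(lapply(c("simulate", "tau", "cluster", "te", "pairs",
                           "coexpr", "conserve", "report"),
                         run_stage, config = config))
    return(invisible(out))
  }
  fun <- switch(stage,
    simulate = .stage_simulate, tau = .stage_tau, cluster = .stage_cluster,
    te = .stage_te, pairs = .stage_pairs, coexpr = .stage_coexpr,
    conserve = .stage_conserve, report = .stage_report
  )
  invisible(fun(config))
}

.stage_simulate <- function(cfg) {
  sim <- cfg$simulate
  .stage_log(cfg, "simulate", sprintf("R %s; generating synthetic inputs",
                                      getRversion()))
  gen <- generate_annotation(
    n_chroms = sim$n_chroms, chrom_length = sim$chrom_length,
    n_mrna = sim$n_mrna, n_lincrna = sim$n_lincrna,
    n_antisense = sim$n_antisense, n_divergent = sim$n_divergent,
    n_convergent = sim$n_convergent, seed = cfg$seed + 1L
  )
  ann <- gen$annotation
  g <- genes(ann)
  tissues_df <- dog_tissues()

  # planted tissue-specific lncRNAs: testis-skewed, like real panels
  lnc_plain <- g$gene_id[g$biotype == "lincRNA" &
                           is.na(gen$truth$planted_class[match(g$gene_id, gen$truth$gene_id)])]
  spec <- NULL
  n_spec <- min(sim$n_specific, length(lnc_plain))
  if (n_spec > 0) {
    spec_ids <- with_seed(cfg$seed + 11L, sample(lnc_plain, n_spec))
    spec_tissue <- with_seed(cfg$seed + 12L, ifelse(
      stats::runif(n_spec) < 0.5, "testis",
      sample(tissues_df$tissue, n_spec, replace = TRUE)))
    spec <- data.frame(gene_id = spec_ids, tissue = spec_tissue,
                       fold = sim$specific_fold, stringsAsFactors = FALSE)
  }
  # planted co-expressed pairs: a subset of the planted divergent pairs
  div <- gen$truth[!is.na(gen$truth$planted_class) &
                     gen$truth$planted_class == "divergent", , drop = FALSE]
  pairs <- NULL
  if (nrow(div) > 0 && sim$n_coexpr_pairs > 0) {
    take <- utils::head(div, sim$n_coexpr_pairs)
    pairs <- data.frame(gene_a = take$gene_id, gene_b = take$partner,
                        target_rho = sim$pair_rho, stringsAsFactors = FALSE)
  }
  blocks <- tissues_df[tissues_df$system %in%
                         c("nervous", "integumental", "musculoskeletal",
                           "digestive"), ]
  names(blocks) <- c("tissue", "block")
  expr <- generate_expression(
    ann, tissues = tissues_df$tissue, planted_specific = spec,
    planted_pairs = pairs, noise_cv = sim$noise_cv,
    tissue_blocks = blocks, block_sd = sim$block_sd,
    seed = cfg$seed + 2L
  )
  promo <- promoter_regions(ann, size = cfg$promoter_size,
                            chrom_lengths = gen$chrom_lengths)
  enr <- NULL
  if (!is.null(spec)) {
    enr_regions <- promo[promo$gene_id %in% spec$gene_id & !promo$degenerate, ]
    if (nrow(enr_regions)) {
      enr <- list(family = sim$te_enrich_family, regions = enr_regions,
                  factor = sim$te_enrich_factor)
    }
  }
  depl <- list(
    list(regions = project_exons(filter_biotype(ann, "mRNA")), keep_prob = 0.2),
    list(regions = project_exons(filter_biotype(ann, "lncRNA")), keep_prob = 0.6)
  )
  te <- generate_te_landscape(gen$chrom_lengths, coverage = sim$te_coverage,
                              enrichment = enr, depletion = depl,
                              seed = cfg$seed + 3L)
  panel <- generate_ortholog_panel(n_per_stratum = sim$n_ortholog_per_stratum,
                                   k = 11, seed = cfg$seed + 4L)
  cons <- generate_conservation_track(gen$chrom_lengths, ann = ann,
                                      seed = cfg$seed + 5L)

  paths <- c(
    annotation = .pipeline_path(cfg, "annotation.gtf"),
    expression = .pipeline_path(cfg, "expression.tsv"),
    te = .pipeline_path(cfg, "te.bed"),
    chrom_lengths = .pipeline_path(cfg, "chrom_lengths.tsv"),
    ortho_map = .pipeline_path(cfg, "ortholog_map.tsv"),
    ortho_a = .pipeline_path(cfg, "ortholog_expr_dog.tsv"),
    ortho_b = .pipeline_path(cfg, "ortholog_expr_human.tsv"),
    track = .pipeline_path(cfg, "conservation.bedgraph"),
    truth = .pipeline_path(cfg, "truth.json"),
    config = .pipeline_path(cfg, "config.json")
  )
  write_gtf(ann, paths[["annotation"]])
  write_expression_matrix(expr$matrix, paths[["expression"]])
  write_bed(te$tes, paths[["te"]])
  data.table::fwrite(data.frame(chrom = names(gen$chrom_lengths),
                                length = unname(gen$chrom_lengths)),
                     paths[["chrom_lengths"]], sep = "\t")
  data.table::fwrite(panel$orthologs, paths[["ortho_map"]], sep = "\t")
  write_expression_matrix(panel$expr_a, paths[["ortho_a"]])
  write_expression_matrix(panel$expr_b, paths[["ortho_b"]])
  write_bedgraph(cons$track, paths[["track"]])
  write_truth(list(annotation = gen$truth, expression = expr$truth,
                   te = list(coverage = sim$te_coverage,
                             enrich_family = sim$te_enrich_family,
                             enrich_factor = sim$te_enrich_factor,
                             enriched_genes = if (is.null(spec)) character(0) else spec$gene_id),
                   orthologs = panel$truth,
                   conservation = cons$truth),
              paths[["truth"]])
  cfg_out <- unclass(cfg)
  jsonlite::write_json(cfg_out, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .stage_log(cfg, "simulate", "done")
  paths
}

.read_inputs <- function(cfg) {
  cl <- data.table::fread(.pipeline_path(cfg, "chrom_lengths.tsv"),
                          data.table = FALSE)
  list(
    ann = read_gtf(.pipeline_path(cfg, "annotation.gtf")),
    mat = read_expression_matrix(.pipeline_path(cfg, "expression.tsv")),
    chrom_lengths = stats::setNames(cl$length, cl$chrom)
  )
}

.stage_tau <- function(cfg) {
  .require_artifacts(cfg, c("expression.tsv", "annotation.gtf"), "simulate")
  inp <- .read_inputs(cfg)
  g <- genes(inp$ann)
  tau <- compute_tau(inp$mat, floor_tpm = cfg$floor_tpm)
  tau$biotype <- g$biotype[match(tau$gene_id, g$gene_id)]
  calls <- call_tissue_specific(tau, threshold = cfg$tau_threshold)
  props <- do.call(rbind, lapply(c("lncRNA", "mRNA"), function(grp) {
    ids <- if (grp == "mRNA") g$gene_id[g$biotype == "mRNA"] else
      g$gene_id[g$biotype %in% c("lincRNA", "antisense")]
    p <- per_tissue_specific_proportion(
      inp$mat[ids, , drop = FALSE],
      calls[calls$gene_id %in% ids, , drop = FALSE],
      threshold = cfg$expressed_tpm)
    p$biotype_group <- grp
    p
  }))
  paths <- c(tau = .pipeline_path(cfg, "tau.tsv"),
             props = .pipeline_path(cfg, "tissue_specific_proportions.tsv"))
  write_tau_table(calls, paths[["tau"]])
  data.table::fwrite(props, paths[["props"]], sep = "\t")
  .stage_log(cfg, "tau", sprintf("%d genes scored", nrow(calls)))
  paths
}

.stage_cluster <- function(cfg) {
  .require_artifacts(cfg, c("expression.tsv", "annotation.gtf"), "simulate")
  inp <- .read_inputs(cfg)
  g <- genes(inp$ann)
  paths <- character(0)
  for (grp in c("lncRNA", "mRNA")) {
    ids <- if (grp == "mRNA") g$gene_id[g$biotype == "mRNA"] else
      g$gene_id[g$biotype %in% c("lincRNA", "antisense")]
    corr <- tissue_spearman_matrix(inp$mat, gene_ids = ids)
    clust <- cluster_tissues(corr)
    p1 <- .pipeline_path(cfg, sprintf("tissue_correlation_%s.tsv", grp))
    p2 <- .pipeline_path(cfg, sprintf("dendrogram_%s.tsv", grp))
    p3 <- .pipeline_path(cfg, sprintf("dendrogram_%s.nwk", grp))
    write_correlation_matrix(corr, p1)
    data.table::fwrite(clust$merges, p2, sep = "\t")
    writeLines(dendrogram_newick(clust), p3)
    paths <- c(paths, p1, p2, p3)
  }
  .stage_log(cfg, "cluster", "tissue dendrograms written")
  paths
}

.stage_te <- function(cfg) {
  .require_artifacts(cfg, c("annotation.gtf", "te.bed", "chrom_lengths.tsv",
                            "expression.tsv"), "simulate")
  inp <- .read_inputs(cfg)
  tes <- read_te_table(.pipeline_path(cfg, "te.bed"))
  lnc <- filter_biotype(inp$ann, "lncRNA")
  mrna <- filter_biotype(inp$ann, "mRNA")

  profiles <- list(); aggregates <- list()
  for (grp in c("lncRNA", "mRNA")) {
    ann_g <- if (grp == "mRNA") mrna else lnc
    for (reg in c("exon_projection", "promoter")) {
      tc <- te_content(ann_g, tes, region = reg,
                       promoter_size = cfg$promoter_size,
                       chrom_lengths = inp$chrom_lengths)
      tc$biotype_group <- grp
      agg <- attr(tc, "aggregate"); agg$biotype_group <- grp
      profiles[[paste(grp, reg)]] <- tc
      aggregates[[paste(grp, reg)]] <- agg
    }
  }
  prof <- do.call(rbind, profiles)
  agg <- do.call(rbind, aggregates)
  rownames(prof) <- rownames(agg) <- NULL
  gtf <- genome_te_fraction(tes, inp$chrom_lengths)

  # ridge CCA: lncRNA tissue expression (log TPM) vs TE content features
  Y <- te_feature_matrix(profiles[["lncRNA exon_projection"]],
                         profiles[["lncRNA promoter"]])
  X <- log_tpm(inp$mat[rownames(Y), , drop = FALSE])
  keep_x <- apply(X, 2, stats::sd) > 0
  keep_y <- apply(Y, 2, stats::sd) > 0
  fit <- rcc(X[, keep_x, drop = FALSE], Y[, keep_y, drop = FALSE],
             lambda1 = cfg$lambda1, lambda2 = cfg$lambda2, ncomp = cfg$ncomp)

  paths <- c(profiles = .pipeline_path(cfg, "te_profiles.tsv"),
             aggregate = .pipeline_path(cfg, "te_aggregate.tsv"),
             genome = .pipeline_path(cfg, "genome_te_fraction.tsv"),
             cors = .pipeline_path(cfg, "rcc_correlations.tsv"),
             cross = .pipeline_path(cfg, "rcc_cross_correlation.tsv"))
  data.table::fwrite(prof, paths[["profiles"]], sep = "\t")
  data.table::fwrite(agg, paths[["aggregate"]], sep = "\t")
  data.table::fwrite(gtf, paths[["genome"]], sep = "\t")
  data.table::fwrite(data.frame(component = seq_along(fit$cor), cor = fit$cor),
                     paths[["cors"]], sep = "\t")
  cross <- data.frame(tissue = rownames(fit$cross_cor), fit$cross_cor,
                      check.names = FALSE)
  data.table::fwrite(cross, paths[["cross"]], sep = "\t")
  .stage_log(cfg, "te", sprintf("first canonical correlation %.3f", fit$cor[1]))
  paths
}

.stage_pairs <- function(cfg) {
  .require_artifacts(cfg, "annotation.gtf", "simulate")
  ann <- read_gtf(.pipeline_path(cfg, "annotation.gtf"))
  pairs <- classify_pairs(find_pairs(ann, window = cfg$window), ann)
  path <- .pipeline_path(cfg, "pairs.tsv")
  write_pair_table(pairs, path)
  .stage_log(cfg, "pairs", sprintf("%d pairs, %d retained",
                                   nrow(pairs), sum(pairs$retained)))
  c(pairs = path)
}

.stage_coexpr <- function(cfg) {
  .require_artifacts(cfg, "pairs.tsv", "pairs")
  .require_artifacts(cfg, "expression.tsv", "simulate")
  pairs <- data.table::fread(.pipeline_path(cfg, "pairs.tsv"), data.table = FALSE)
  mat <- read_expression_matrix(.pipeline_path(cfg, "expression.tsv"))
  cps <- correlate_pairs(pairs, mat, rho_threshold = cfg$rho_threshold,
                         padj_threshold = cfg$padj_threshold)
  summary <- attr(cps, "summary")
  sig <- cps[cps$significant, , drop = FALSE]
  paths <- c(coexpr = .pipeline_path(cfg, "coexpression.tsv"),
             summary = .pipeline_path(cfg, "coexpr_summary.json"),
             mrna_ids = .pipeline_path(cfg, "significant_mrna_ids.txt"),
             dist = .pipeline_path(cfg, "distance_profile.tsv"),
             ranks = .pipeline_path(cfg, "partner_ranks.tsv"))
  write_pair_table(cps, paths[["coexpr"]])
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(sort(unique(sig$mrna_id)), paths[["mrna_ids"]])
  if (nrow(sig)) {
    prof <- distance_correlation_profile(cps)
    data.table::fwrite(prof$bins, paths[["dist"]], sep = "\t")
  } else {
    data.table::fwrite(data.frame(bin = character(), n = integer(),
                                  mean_distance = numeric()),
                       paths[["dist"]], sep = "\t")
  }
  data.table::fwrite(partner_rank_analysis(cps), paths[["ranks"]], sep = "\t")
  .stage_log(cfg, "coexpr", sprintf("%d/%d pairs significant",
                                    summary$n_significant, summary$n_tested))
  paths
}

.stage_conserve <- function(cfg) {
  .require_artifacts(cfg, c("ortholog_map.tsv", "ortholog_expr_dog.tsv",
                            "ortholog_expr_human.tsv", "conservation.bedgraph",
                            "annotation.gtf", "chrom_lengths.tsv"), "simulate")
  inp <- .read_inputs(cfg)
  ortho <- read_ortholog_map(.pipeline_path(cfg, "ortholog_map.tsv"))
  ea <- read_expression_matrix(.pipeline_path(cfg, "ortholog_expr_dog.tsv"))
  eb <- read_expression_matrix(.pipeline_path(cfg, "ortholog_expr_human.tsv"))
  cls <- classify_orthologs(ortho, ea, eb, cuts = cfg$conservation_cuts)
  track <- read_conservation_track(.pipeline_path(cfg, "conservation.bedgraph"),
                                   inp$chrom_lengths)
  scores <- gene_conservation_score(inp$ann, track)
  g <- genes(inp$ann)
  scores$biotype <- g$biotype[match(scores$gene_id, g$gene_id)]
  cmp <- compare_score_distributions(
    scores[scores$biotype != "mRNA", ],
    scores[scores$biotype == "mRNA", ],
    alternative = "two.sided")
  paths <- c(classes = .pipeline_path(cfg, "ortholog_classes.tsv"),
             scores = .pipeline_path(cfg, "conservation_scores.tsv"),
             cmp = .pipeline_path(cfg, "conservation_comparison.json"))
  data.table::fwrite(cls, paths[["classes"]], sep = "\t")
  data.table::fwrite(scores, paths[["scores"]], sep = "\t")
  jsonlite::write_json(cmp, paths[["cmp"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .stage_log(cfg, "conserve", sprintf("%d ortholog pairs classified", nrow(cls)))
  paths
}

.stage_report <- function(cfg) {
  .require_artifacts(cfg, c("tau.tsv", "tissue_specific_proportions.tsv"), "tau")
  .require_artifacts(cfg, c("te_aggregate.tsv", "genome_te_fraction.tsv",
                            "rcc_correlations.tsv"), "te")
  .require_artifacts(cfg, "pairs.tsv", "pairs")
  .require_artifacts(cfg, "coexpr_summary.json", "coexpr")
  .require_artifacts(cfg, c("ortholog_classes.tsv",
                            "conservation_comparison.json"), "conserve")
  inp <- .read_inputs(cfg)
  g <- genes(inp$ann)
  lnc_ids <- g$gene_id[g$biotype %in% c("lincRNA", "antisense")]
  mrna_ids <- g$gene_id[g$biotype == "mRNA"]
  tau <- data.table::fread(.pipeline_path(cfg, "tau.tsv"), data.table = FALSE)
  agg <- data.table::fread(.pipeline_path(cfg, "te_aggregate.tsv"),
                           data.table = FALSE)
  gtf <- data.table::fread(.pipeline_path(cfg, "genome_te_fraction.tsv"),
                           data.table = FALSE)
  cors <- data.table::fread(.pipeline_path(cfg, "rcc_correlations.tsv"),
                            data.table = FALSE)
  pairs <- data.table::fread(.pipeline_path(cfg, "pairs.tsv"), data.table = FALSE)
  coexpr <- jsonlite::fromJSON(.pipeline_path(cfg, "coexpr_summary.json"))
  cls <- data.table::fread(.pipeline_path(cfg, "ortholog_classes.tsv"),
                           data.table = FALSE)
  cons_cmp <- jsonlite::fromJSON(.pipeline_path(cfg, "conservation_comparison.json"))

  frac_expressed <- function(ids) {
    expressed_fraction(inp$mat[ids, , drop = FALSE],
                       threshold = cfg$expressed_tpm)$fraction
  }
  spec_frac <- function(ids) {
    sub <- tau[tau$gene_id %in% ids, ]
    expressed <- sub$gene_id[!is.na(sub$tau)]
    if (!length(expressed)) return(0)
    mean(sub$is_specific[!is.na(sub$tau)])
  }
  summary <- list(
    n_genes = list(lncRNA = length(lnc_ids), mRNA = length(mrna_ids)),
    expressed_fraction = list(lncRNA = frac_expressed(lnc_ids),
                              mRNA = frac_expressed(mrna_ids)),
    tissue_specific_fraction = list(lncRNA = spec_frac(lnc_ids),
                                    mRNA = spec_frac(mrna_ids)),
    exonic_te_fraction = list(
      lncRNA = agg$fraction[agg$biotype_group == "lncRNA" &
                              agg$region == "exon_projection" &
                              agg$te_class == "any"],
      mRNA = agg$fraction[agg$biotype_group == "mRNA" &
                            agg$region == "exon_projection" &
                            agg$te_class == "any"]),
    genome_te_fraction = gtf$fraction[gtf$te_class == "any"],
    first_canonical_correlation = cors$cor[1],
    pair_counts = as.list(table(pairs$pair_class[pairs$retained])),
    coexpression = coexpr,
    conservation_classes = as.list(table(cls$conservation_class)),
    conservation_wilcoxon_p = cons_cmp$p.value,
    seed = cfg$seed
  )
  path <- .pipeline_path(cfg, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  .stage_log(cfg, "report", "summary written")
  c(summary = path)
}
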