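#' Average replicate libraries per tissue
#'
#' Collapses a genes x samples TPM matrix to genes x tissues by taking the
#' arithmetic mean of each gene over a tissue's replicate columns. Also
#' accepts a list of replicate matrices sharing dimnames, which are
#' averaged element-wise.
#'
#' @param mat genes x samples matrix, or a list of genes x tissues
#'   matrices (one per replicate).
#' @param sample_tissues character vector mapping each column of `mat` to
#'   a tissue (ignored for the list form).
#' @return genes x tissues matrix of mean TPM.
#' @export
average_replicates <- function(mat, sample_tissues = NULL) {
  if (is.list(mat) && !is.data.frame(mat)) {
    ref <- dimnames(mat[[1]])
    for (m in mat[-1]) {
      if (!identical(rownames(m), ref[[1]])) stop("replicate matrices disagree on gene set")
      if (!identical(colnames(m), ref[[2]])) stop("replicate matrices disagree on tissues")
    }
    return(Reduce(`+`, mat) / length(mat))
  }
  if (is.null(sample_tissues) || length(sample_tissues) != ncol(mat)) {
    stop("sample_tissues must map every column to a tissue")
  }
  tissues <- unique(sample_tissues)
  out <- vapply(tissues, function(t) {
    rowMeans(mat[, sample_tissues == t, drop = FALSE])
  }, numeric(nrow(mat)))
  rownames(out) <- rownames(mat)
  out
}

#' The matched dog:human tissue panel
#'
#' The eleven tissues for which bulk RNA-seq can be matched one-to-one
#' between the canine multi-tissue panel and human ENCODE tissue data.
#'
#' @return character vector of 11 tissue names.
#' @export
matched_tissues <- function() {
  c("adrenal_gland", "gut_colon", "heart", "liver", "lung", "muscle",
    "ovary", "pancreas", "skin", "spleen", "testis")
}

#' Classify expression conservation from a correlation p-value
#'
#' Orthologue pairs are binned by the (exact permutation) p-value of the
#' Spearman correlation of their matched-tissue expression vectors:
#' `high` for `p < 0.05`, `intermediate` for `0.05 <= p < 0.2`,
#' `divergent` for `p >= 0.2` (the boundary `p = 0.2` falls in the
#' divergent bin; the bins are half-open and exhaustive). Undefined
#' correlations give class `unscored`.
#'
#' @param pvalue numeric vector of p-values (NA allowed).
#' @param cuts length-2 increasing cut-offs (default `c(0.05, 0.2)`).
#' @return character vector of classes.
#' @export
conservation_classify <- function(pvalue, cuts = c(0.05, 0.2)) {
  stopifnot(length(cuts) == 2L, cuts[1] < cuts[2])
  ifelse(is.na(pvalue), "unscored",
         ifelse(pvalue < cuts[1], "high",
                ifelse(pvalue < cuts[2], "intermediate", "divergent")))
}

#' Correlate and classify 1:1 orthologue pairs
#'
#' For every orthologue pair, computes the Spearman correlation of the two
#' species' expression vectors over the matched tissue panel (exact
#' permutation p-value by default at small k) and assigns an
#' expression-conservation class via [conservation_classify()].
#'
#' @param orthologs data.frame `gene_a`, `gene_b`, `biotype`.
#' @param mat_a,mat_b expression matrices for species A and B with the
#'   paired genes in rows and the same ordered tissue columns.
#' @param tissues tissue panel to use (default: the common columns, in
#'   `mat_a` order).
#' @param cuts conservation p-value cut-offs.
#' @param p_method p-value route passed to [spearman_rho()].
#' @return `orthologs` with `rho`, `pvalue`, `conservation_class` added.
#' @export
classify_orthologs <- function(orthologs, mat_a, mat_b, tissues = NULL,
                               cuts = c(0.05, 0.2), p_method = "auto") {
  .check_columns(orthologs, c("gene_a", "gene_b"), "ortholog map")
  if (is.null(tissues)) tissues <- intersect(colnames(mat_a), colnames(mat_b))
  if (length(tissues) < 4L) stop("need >= 4 matched tissues")
  missing_a <- setdiff(orthologs$gene_a, rownames(mat_a))
  missing_b <- setdiff(orthologs$gene_b, rownames(mat_b))
  if (length(missing_a) || length(missing_b)) {
    stop("ortholog gene(s) missing from expression matrices: ",
         paste(utils::head(c(missing_a, missing_b), 10), collapse = ", "))
  }
  res <- mapply(function(a, b) {
    s <- spearman_rho(mat_a[a, tissues], mat_b[b, tissues], method = p_method)
    c(s$rho, s$pvalue)
  }, orthologs$gene_a, orthologs$gene_b)
  orthologs$rho <- res[1, ]
  orthologs$pvalue <- res[2, ]
  orthologs$conservation_class <- conservation_classify(orthologs$pvalue, cuts = cuts)
  orthologs
}

#' Read a per-base conservation-score track
#'
#' Reads a bedGraph or wiggle file into a run-length encoded per-base
#' score map (one numeric Rle per chromosome; bases without a score are
#' `NA`).
#'
#' @param path bedGraph (`.bedgraph`/`.bg`) or wiggle (`.wig`) file.
#' @param chrom_lengths named chromosome lengths.
#' @return named list of [S4Vectors::Rle] score vectors, classed
#'   `conservation_track`.
#' @export
read_conservation_track <- function(path, chrom_lengths) {
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  track <- lapply(names(chrom_lengths), function(chr) {
    S4Vectors::Rle(NA_real_, chrom_lengths[[chr]])
  })
  names(track) <- names(chrom_lengths)
  chroms <- as.character(GenomicRanges::seqnames(gr))
  for (chr in unique(chroms)) {
    if (!chr %in% names(track)) stop("track chromosome not in chrom_lengths: ", chr)
    sub <- gr[chroms == chr]
    sub <- sub[order(GenomicRanges::start(sub))]
    s0 <- GenomicRanges::start(sub) - 1L # 0-based starts
    e <- GenomicRanges::end(sub)
    if (any(s0[-1] < e[-length(e)])) stop("overlapping score intervals on ", chr)
    # interleave NA gap runs with scored runs, then the trailing gap
    L <- chrom_lengths[[chr]]
    gap <- s0 - c(0L, e[-length(e)])
    lens <- as.vector(rbind(gap, e - s0))
    vals <- as.vector(rbind(NA_real_, sub$score))
    lens <- c(lens, L - e[length(e)])
    vals <- c(vals, NA_real_)
    keep <- lens > 0L
    track[[chr]] <- S4Vectors::Rle(vals[keep], lens[keep])
  }
  structure(track, class = "conservation_track")
}

#' Write a conservation track as bedGraph
#'
#' Runs of equal score are written as single bedGraph intervals (0-based
#' half-open); `NA` runs are skipped. Deterministic output.
#'
#' @param track a `conservation_track` (list of per-chromosome Rle).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chr in names(track)) {
    v <- track[[chr]]
    ends <- cumsum(S4Vectors::runLength(v))
    starts <- ends - S4Vectors::runLength(v)
    vals <- S4Vectors::runValue(v)
    keep <- !is.na(vals)
    if (!any(keep)) next
    writeLines(sprintf("%s\t%s\t%s\t%s", chr, .fmt_int(starts[keep]),
                       .fmt_int(ends[keep]),
                       formatC(vals[keep], format = "g", digits = 10)), con)
  }
  invisible(path)
}

#' Median conservation score per gene
#'
#' Projects each gene's exons onto the genome and takes the median of the
#' per-base conservation scores inside the projection. Bases without a
#' score are skipped; genes with no scored base get `NA` (flagged by
#' `n_bases = 0`). The even-count median is the mean of the two middle
#' values.
#'
#' @param ann a [gene_annotation()].
#' @param track a `conservation_track` from [read_conservation_track()]
#'   or [generate_conservation_track()].
#' @return data.frame `gene_id`, `median_score`, `n_bases` (scored bases),
#'   `projected_length`.
#' @export
gene_conservation_score <- function(ann, track) {
  proj <- project_exons(ann)
  lens <- projection_lengths(proj)
  ids <- names(lens)
  med <- rep(NA_real_, length(ids)); nb <- integer(length(ids))
  for (k in seq_along(ids)) {
    sub <- proj[proj$gene_id == ids[k], , drop = FALSE]
    vals <- unlist(lapply(seq_len(nrow(sub)), function(i) {
      chr <- sub$chrom[i]
      if (!chr %in% names(track)) return(numeric(0))
      as.numeric(track[[chr]][(sub$start[i] + 1L):sub$end[i]])
    }))
    vals <- vals[!is.na(vals)]
    nb[k] <- length(vals)
    if (nb[k] > 0L) med[k] <- stats::median(vals)
  }
  data.frame(gene_id = ids, median_score = med, n_bases = nb,
             projected_length = as.integer(lens),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare two sets of per-gene conservation scores
#'
#' Two-sample Wilcoxon rank-sum comparison of median conservation scores
#' between two gene sets (e.g. syntenic lncRNAs versus syntenic mRNAs).
#' Thin wrapper over [rank_sum_test()] that drops unscored genes first.
#'
#' @param scores_a,scores_b outputs of [gene_conservation_score()] (or
#'   bare numeric vectors).
#' @param alternative,method passed to [rank_sum_test()].
#' @return list `statistic`, `p.value`, `n_a`, `n_b`.
#' @export
compare_score_distributions <- function(scores_a, scores_b,
                                        alternative = "two.sided",
                                        method = "normal") {
  pick <- function(s) {
    if (is.data.frame(s)) s <- s$median_score
    s[!is.na(s)]
  }
  a <- pick(scores_a); b <- pick(scores_b)
  ht <- rank_sum_test(a, b, alternative = alternative, method = method)
  c(ht, list(n_a = length(a), n_b = length(b)))
}

#' Read a 1:1 ortholog map
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `biotype`.
#' @return data.frame.
#' @export
read_ortholog_map <- function(path) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  .check_columns(tab, c("gene_a", "gene_b", "biotype"), "ortholog map")
  tab
}
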