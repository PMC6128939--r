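#' Transposable-element content of exon projections or promoters
#'
#' For each gene, computes the fraction of its region (exon projection or
#' 5'-upstream promoter window) covered by each TE family and each TE
#' class. TEs of a family (or class) are merged before counting so that
#' overlapping copies contribute each base once; strand is ignored.
#' Degenerate (fully clipped) promoters are excluded.
#'
#' @param ann a [gene_annotation()].
#' @param tes a [te_records()] table.
#' @param region `"exon_projection"` or `"promoter"`.
#' @param promoter_size promoter window size in bp (promoter region only).
#' @param chrom_lengths named chromosome lengths (required for promoters).
#' @return data.frame with one row per gene x (family or class):
#'   `gene_id`, `region`, `level` (`"family"`/`"class"`), `te_class`,
#'   `te_family` (`NA` on class rows), `overlap_bp`, `region_length`,
#'   `fraction`. Attribute `aggregate` holds the gene-set totals: overall
#'   and per-class overlapped bp over total region bp.
#' @export
te_content <- function(ann, tes, region = c("exon_projection", "promoter"),
                       promoter_size = 5000, chrom_lengths = NULL) {
  region <- match.arg(region)
  stopifnot(inherits(ann, "gene_annotation"))
  tes <- te_records(tes)
  if (region == "exon_projection") {
    regions <- project_exons(ann)
  } else {
    if (is.null(chrom_lengths)) stop("promoter regions require chrom_lengths")
    regions <- promoter_regions(ann, size = promoter_size, chrom_lengths = chrom_lengths)
    regions <- regions[!regions$degenerate, , drop = FALSE]
  }
  gene_len <- tapply(regions$end - regions$start, regions$gene_id, sum)
  gene_ids <- names(gene_len)

  groups <- unique(tes[, c("te_class", "te_family")])
  groups <- groups[order(groups$te_class, groups$te_family), , drop = FALSE]
  classes <- sort(unique(tes$te_class))

  per_gene_bp <- function(sub) {
    if (!nrow(sub)) return(setNames(numeric(length(gene_ids)), gene_ids))
    gr <- GenomicRanges::reduce(.as_granges(sub, ignore_strand = TRUE))
    bp <- .per_region_overlap(regions, gr)
    out <- tapply(bp, regions$gene_id, sum)
    setNames(as.numeric(out)[match(gene_ids, names(out))], gene_ids)
  }

  rows <- list()
  for (i in seq_len(nrow(groups))) {
    sub <- tes[tes$te_family == groups$te_family[i] &
                 tes$te_class == groups$te_class[i], , drop = FALSE]
    bp <- per_gene_bp(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_ids, region = region, level = "family",
      te_class = groups$te_class[i], te_family = groups$te_family[i],
      overlap_bp = bp, region_length = as.numeric(gene_len),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  for (cl in classes) {
    bp <- per_gene_bp(tes[tes$te_class == cl, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_ids, region = region, level = "class",
      te_class = cl, te_family = NA_character_,
      overlap_bp = bp, region_length = as.numeric(gene_len),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  out$fraction <- ifelse(out$region_length > 0, out$overlap_bp / out$region_length, 0)

  # gene-set aggregate: all TEs jointly (projected) and per class
  total_len <- sum(gene_len)
  all_bp <- sum(per_gene_bp(tes))
  agg <- data.frame(
    region = region,
    te_class = c("any", classes),
    overlap_bp = c(all_bp, vapply(classes, function(cl) {
      sum(per_gene_bp(tes[tes$te_class == cl, , drop = FALSE]))
    }, 0)),
    region_bp = total_len,
    stringsAsFactors = FALSE, row.names = NULL
  )
  agg$fraction <- ifelse(agg$region_bp > 0, agg$overlap_bp / agg$region_bp, 0)
  attr(out, "aggregate") <- agg
  out
}

#' Genome-wide TE fraction per class
#'
#' Fraction of the genome covered by each TE class (and by any TE), with
#' overlapping copies merged before counting.
#'
#' @param tes a [te_records()] table.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return data.frame `te_class` (including `"any"`), `bp`, `genome_bp`,
#'   `fraction`.
#' @export
genome_te_fraction <- function(tes, chrom_lengths) {
  tes <- te_records(tes)
  missing <- setdiff(unique(tes$chrom), names(chrom_lengths))
  if (length(missing)) {
    stop("chrom_lengths missing chromosome(s): ", paste(missing, collapse = ", "))
  }
  if (any(tes$end > chrom_lengths[tes$chrom])) {
    stop("TE interval beyond chromosome end")
  }
  genome_bp <- sum(as.numeric(chrom_lengths))
  proj_bp <- function(sub) {
    if (!nrow(sub)) return(0)
    sum(as.numeric(GenomicRanges::width(
      GenomicRanges::reduce(.as_granges(sub, ignore_strand = TRUE))
    )))
  }
  classes <- sort(unique(tes$te_class))
  out <- data.frame(
    te_class = c("any", classes),
    bp = c(proj_bp(tes), vapply(classes, function(cl) {
      proj_bp(tes[tes$te_class == cl, , drop = FALSE])
    }, 0)),
    genome_bp = genome_bp,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$fraction <- out$bp / out$genome_bp
  out
}

#' Per-gene TE feature matrix
#'
#' Reshapes family-level [te_content()] output (one or more regions) into a
#' gene x feature numeric matrix of overlap fractions, with features named
#' `family_region` (e.g. `SINEC_Cf_promoter`). This is the Y block for
#' [rcc()].
#'
#' @param ... one or more family-level long tables from [te_content()].
#' @return numeric matrix, genes in rows, TE features in columns.
#' @export
te_feature_matrix <- function(...) {
  tabs <- list(...)
  long <- do.call(rbind, lapply(tabs, function(t) t[t$level == "family", ]))
  long$feature <- paste(long$te_family, long$region, sep = "_")
  genes <- sort(unique(long$gene_id))
  feats <- unique(long$feature)
  mat <- matrix(0, length(genes), length(feats), dimnames = list(genes, feats))
  mat[cbind(match(long$gene_id, genes), match(long$feature, feats))] <- long$fraction
  mat
}

#' Ridge-regularized canonical correlation analysis
#'
#' Finds pairs of linear combinations `(X a, Y b)` maximising
#' `a' Cov(X,Y) b / sqrt(a' (Cov(X) + lambda1 I) a * b' (Cov(Y) + lambda2 I) b)`.
#' With `lambda1 = lambda2 = 0` this is classical CCA (requires full-rank
#' covariances); positive ridge penalties make the problem well-posed when
#' features outnumber observations or are collinear. Solved by whitening
#' the regularized covariances (symmetric inverse square roots via
#' eigendecomposition) and taking the SVD of the whitened cross-covariance.
#'
#' Alongside the canonical correlations and loadings, the function returns
#' the cross-correlation table used for clustered image maps: with
#' canonical variates `U = Xc A`, `V = Yc B` and `Z = (U + V)/2`,
#' `cross_cor = cor(X, Z) %*% t(cor(Y, Z))` over the retained components.
#'
#' @param X,Y numeric matrices with matched rows (e.g. genes), columns are
#'   the two variable blocks (tissue expression; TE features).
#' @param lambda1,lambda2 non-negative ridge penalties (default 0.1).
#' @param ncomp number of components to retain (default 3).
#' @param center,scale centre/unit-scale columns first (defaults `TRUE`).
#' @return object of class `rcc_result`: list with `cor` (non-increasing
#'   canonical correlations in `[0, 1]`), `xcoef`, `ycoef` (loadings),
#'   `variates` (list `U`, `V`), `cross_cor` (X-variables x Y-variables),
#'   `lambda`, `ncomp`.
#' @export
rcc <- function(X, Y, lambda1 = 0.1, lambda2 = 0.1, ncomp = 3,
                center = TRUE, scale = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (lambda1 < 0 || lambda2 < 0) stop("ridge penalties must be >= 0")
  n <- nrow(X)
  if (n < 3L) stop("need >= 3 observations")
  Xc <- base::scale(X, center = center, scale = scale)
  Yc <- base::scale(Y, center = center, scale = scale)
  if (anyNA(Xc) || anyNA(Yc)) stop("constant column (zero variance) in X or Y")
  Cxx <- stats::cov(Xc) + diag(lambda1, ncol(X))
  Cyy <- stats::cov(Yc) + diag(lambda2, ncol(Y))
  Cxy <- stats::cov(Xc, Yc)
  isqrt <- function(C, lambda, block) {
    e <- eigen(C, symmetric = TRUE)
    tol <- max(dim(C)) * .Machine$double.eps * max(abs(e$values))
    if (min(e$values) < tol) {
      stop(sprintf(
        "covariance of %s is rank-deficient at lambda = %g; use a positive ridge penalty",
        block, lambda))
    }
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  Kx <- isqrt(Cxx, lambda1, "X")
  Ky <- isqrt(Cyy, lambda2, "Y")
  sv <- svd(Kx %*% Cxy %*% Ky)
  ncomp <- min(ncomp, length(sv$d))
  d <- pmin(pmax(sv$d[seq_len(ncomp)], 0), 1)
  xcoef <- Kx %*% sv$u[, seq_len(ncomp), drop = FALSE]
  ycoef <- Ky %*% sv$v[, seq_len(ncomp), drop = FALSE]
  rownames(xcoef) <- colnames(X); rownames(ycoef) <- colnames(Y)
  U <- Xc %*% xcoef
  V <- Yc %*% ycoef
  Z <- (U + V) / 2
  cross <- stats::cor(Xc, Z) %*% t(stats::cor(Yc, Z))
  dimnames(cross) <- list(colnames(X), colnames(Y))
  structure(list(
    cor = d, xcoef = xcoef, ycoef = ycoef,
    variates = list(U = U, V = V),
    cross_cor = cross,
    lambda = c(lambda1 = lambda1, lambda2 = lambda2),
    ncomp = ncomp
  ), class = "rcc_result")
}

#' @export
print.rcc_result <- function(x, ...) {
  cat(sprintf("rcc_result: %d component(s), lambda = (%g, %g)\n",
              x$ncomp, x$lambda[1], x$lambda[2]))
  cat("canonical correlations:", paste(sprintf("%.4f", x$cor), collapse = ", "), "\n")
  invisible(x)
}

#' log10(TPM + 1) transform
#'
#' Standard log-scale transform for TPM expression ahead of correlation or
#' canonical-correlation analyses.
#'
#' @param mat non-negative expression matrix.
#' @return transformed matrix of the same shape.
#' @export
log_tpm <- function(mat) {
  if (any(mat < 0)) stop("negative expression values")
  log10(mat + 1)
}
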