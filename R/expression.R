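#' Read a gene-by-tissue expression matrix
#'
#' Expects a TSV with gene ids in the first column and one column of TPM
#' values per tissue. Values must be numeric, non-negative and complete;
#' gene ids and tissue names must be unique.
#'
#' @param path TSV file path.
#' @return numeric matrix, genes in rows (rownames), tissues in columns.
#' @export
read_expression_matrix <- function(path) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (ncol(tab) < 3L) stop("expression matrix needs a gene column and >= 2 tissues")
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values")
  if (anyNA(mat)) stop("missing expression values")
  if (any(mat < 0)) stop("negative expression values")
  if (anyDuplicated(ids)) stop("duplicated gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicated tissue names")
  rownames(mat) <- ids
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix with gene rownames and tissue colnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Tau tissue-specificity score
#'
#' For a gene expressed over `n >= 2` tissues with TPM values `x_i`, tau is
#' `sum(1 - x_i / max(x_i)) / (n - 1)`: 1 for a gene expressed in a single
#' tissue, 0 for a uniformly expressed gene. Values below `floor_tpm` are
#' floored to 0 before scoring (stringency floor); a gene whose floored
#' vector is all zero is "not expressed" and gets `tau = NA`.
#'
#' @param x numeric matrix (genes x tissues, TPM) or a single named vector.
#' @param floor_tpm expression floor in TPM (default 1).
#' @return data.frame with one row per gene: `gene_id`, `tau`, `n_used`
#'   (number of tissues scored), `max_tissue` (tissue of maximal floored
#'   expression; ties broken by column order and flagged in `max_tie`),
#'   `max_tpm` (maximal raw TPM), `ratio_first_second` (floored max over
#'   floored second max; `Inf` when the second is 0).
#' @examples
#' compute_tau(c(liver = 8, lung = 2, skin = 0), floor_tpm = 1)
#' @export
compute_tau <- function(x, floor_tpm = 1) {
  if (is.null(dim(x))) {
    x <- matrix(x, nrow = 1, dimnames = list("gene", names(x)))
  }
  n <- ncol(x)
  if (n < 2L) stop("tau requires >= 2 tissues")
  if (anyNA(x)) stop("missing expression values")
  if (any(x < 0)) stop("negative expression values")
  if (is.null(colnames(x))) colnames(x) <- paste0("tissue", seq_len(n))
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))
  xf <- x
  xf[xf < floor_tpm] <- 0
  mx <- apply(xf, 1L, max)
  second <- apply(xf, 1L, function(v) sort(v, decreasing = TRUE)[2L])
  expressed <- mx > 0
  tau <- rep(NA_real_, nrow(x))
  tau[expressed] <- rowSums(1 - xf[expressed, , drop = FALSE] / mx[expressed]) / (n - 1)
  which_max <- max.col(xf, ties.method = "first")
  n_at_max <- rowSums(xf == mx)
  data.frame(
    gene_id = rownames(x),
    tau = tau,
    n_used = n,
    max_tissue = ifelse(expressed, colnames(x)[which_max], NA_character_),
    max_tie = expressed & n_at_max > 1L,
    max_tpm = apply(x, 1L, max),
    ratio_first_second = ifelse(expressed, ifelse(second > 0, mx / second, Inf), NA_real_),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Call tissue-specific genes from tau scores
#'
#' A gene is tissue-specific when its tau reaches the threshold (inclusive
#' by default: `tau >= threshold`); specific genes are assigned to their
#' tissue of maximal expression. Genes with undefined tau are never called.
#'
#' @param tau_result output of [compute_tau()].
#' @param threshold tau cut-off (default 0.95).
#' @param inclusive if `TRUE` (default) the boundary `tau == threshold`
#'   counts as specific; set `FALSE` for a strict comparison.
#' @return the input with columns `is_specific` and `specific_tissue` added.
#' @export
call_tissue_specific <- function(tau_result, threshold = 0.95, inclusive = TRUE) {
  .check_columns(tau_result, c("tau", "max_tissue"), "tau result")
  spec <- if (inclusive) tau_result$tau >= threshold else tau_result$tau > threshold
  spec[is.na(spec)] <- FALSE
  tau_result$is_specific <- spec
  tau_result$specific_tissue <- ifelse(spec, tau_result$max_tissue, NA_character_)
  tau_result
}

#' Tau on a tissue subset
#'
#' Recomputes tau restricted to a subset of tissues (e.g. specificity
#' within nervous-system tissues only). Equivalent to slicing the matrix
#' columns and calling [compute_tau()].
#'
#' @param mat expression matrix (genes x tissues).
#' @param tissues character vector (>= 2) of tissue names to keep.
#' @param floor_tpm expression floor, as in [compute_tau()].
#' @return a tau result data.frame over the subset.
#' @export
subset_tau <- function(mat, tissues, floor_tpm = 1) {
  unknown <- setdiff(tissues, colnames(mat))
  if (length(unknown)) {
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "),
         "; valid tissues: ", paste(colnames(mat), collapse = ", "))
  }
  if (length(tissues) < 2L) stop("tissue subset must contain >= 2 tissues")
  compute_tau(mat[, tissues, drop = FALSE], floor_tpm = floor_tpm)
}

#' Fraction of genes expressed anywhere
#'
#' A gene counts as expressed when its maximum TPM over tissues strictly
#' exceeds `threshold`.
#'
#' @param mat expression matrix.
#' @param threshold TPM threshold (default 1).
#' @return list with `fraction` (scalar) and `expressed` (named logical
#'   per gene).
#' @export
expressed_fraction <- function(mat, threshold = 1) {
  stopifnot(threshold >= 0)
  flags <- apply(mat, 1L, max) > threshold
  list(fraction = mean(flags), expressed = flags)
}

#' Per-tissue proportion of tissue-specific genes
#'
#' For each tissue, the number of genes specific to it divided by the
#' number of genes expressed in it (TPM strictly above `threshold`).
#' Tissues with no expressed genes get proportion 0 and are flagged.
#'
#' @param mat expression matrix the calls were computed on.
#' @param calls output of [call_tissue_specific()] on the same matrix.
#' @param threshold TPM threshold defining "expressed in tissue".
#' @return data.frame `tissue`, `n_specific`, `n_expressed`, `proportion`,
#'   `no_expressed` flag.
#' @export
per_tissue_specific_proportion <- function(mat, calls, threshold = 1) {
  .check_columns(calls, c("gene_id", "is_specific", "specific_tissue"), "calls")
  if (!all(calls$gene_id %in% rownames(mat))) {
    stop("calls contain genes absent from the matrix")
  }
  tissues <- colnames(mat)
  sub <- mat[calls$gene_id, , drop = FALSE]
  n_expressed <- colSums(sub > threshold)
  n_specific <- vapply(tissues, function(t) {
    sum(calls$is_specific & calls$specific_tissue == t, na.rm = TRUE)
  }, 0L)
  prop <- ifelse(n_expressed > 0, n_specific / n_expressed, 0)
  data.frame(
    tissue = tissues,
    n_specific = as.integer(n_specific),
    n_expressed = as.integer(n_expressed),
    proportion = prop,
    no_expressed = n_expressed == 0,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a tau/specificity result table as TSV
#'
#' @param tau_result output of [compute_tau()] or [call_tissue_specific()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tau_table <- function(tau_result, path) {
  data.table::fwrite(tau_result, path, sep = "\t")
  invisible(path)
}
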