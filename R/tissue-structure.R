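#' Pairwise Spearman correlation between tissues
#'
#' Computes all pairwise Spearman correlations between tissue columns over
#' a gene set, typically restricted to one biotype. By default genes with
#' no expression in any tissue are removed first (all-zero rows carry no
#' rank information).
#'
#' @param mat expression matrix (genes x tissues, TPM).
#' @param gene_ids optional character vector restricting the gene universe
#'   (e.g. all lncRNAs); defaults to all rows.
#' @param drop_unexpressed drop genes whose max TPM is 0 (default `TRUE`).
#' @return symmetric tissue x tissue correlation matrix (unit diagonal).
#' @export
tissue_spearman_matrix <- function(mat, gene_ids = NULL, drop_unexpressed = TRUE) {
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, rownames(mat))
    if (length(missing)) stop("unknown gene id(s): ", paste(missing, collapse = ", "))
    mat <- mat[gene_ids, , drop = FALSE]
  }
  if (drop_unexpressed) {
    mat <- mat[apply(mat, 1L, max) > 0, , drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("need >= 2 tissues")
  if (nrow(mat) < 3L) stop("need >= 3 genes after filtering")
  const <- apply(mat, 2L, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    stop("constant expression column(s), Spearman undefined: ",
         paste(colnames(mat)[const], collapse = ", "))
  }
  stats::cor(mat, method = "spearman")
}

#' Complete-linkage clustering of tissues
#'
#' Tissues are clustered by hierarchical agglomerative clustering with
#' complete linkage on Euclidean distances between the rows of the tissue
#' correlation matrix (the correlation matrix is treated as the feature
#' table, reproducing the common `hclust(dist(cor_matrix))` idiom). Rows
#' are put in lexicographic tissue order first so the result does not
#' depend on input column order and ties break deterministically.
#'
#' @param corr symmetric tissue correlation matrix from
#'   [tissue_spearman_matrix()].
#' @return list with `hclust` (the stats::hclust tree), `merges` (a
#'   data.frame trace: step, member labels of the two merged clusters,
#'   height) and `order` (leaf order as tissue names).
#' @export
cluster_tissues <- function(corr) {
  if (!isTRUE(all.equal(rownames(corr), colnames(corr)))) {
    stop("corr must be a labelled square matrix")
  }
  ord <- order(rownames(corr))
  corr <- corr[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::dist(corr, method = "euclidean"), method = "complete")
  labels <- hc$labels
  members <- vector("list", nrow(hc$merge))
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       cluster_a = character(nrow(hc$merge)),
                       cluster_b = character(nrow(hc$merge)),
                       height = hc$height,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hc$merge))) {
    get_members <- function(j) if (j < 0) labels[-j] else members[[j]]
    a <- get_members(hc$merge[i, 1]); b <- get_members(hc$merge[i, 2])
    members[[i]] <- c(a, b)
    merges$cluster_a[i] <- paste(sort(a), collapse = ",")
    merges$cluster_b[i] <- paste(sort(b), collapse = ",")
  }
  list(hclust = hc, merges = merges, order = labels[hc$order])
}

#' Dendrogram as a Newick string
#'
#' @param clustering output of [cluster_tissues()].
#' @return single Newick string (with branch lengths from merge heights).
#' @export
dendrogram_newick <- function(clustering) {
  ape::write.tree(ape::as.phylo(clustering$hclust))
}

#' Cut a tissue dendrogram into k groups
#'
#' @param clustering output of [cluster_tissues()].
#' @param k number of groups.
#' @return named integer vector of group memberships per tissue.
#' @export
cut_tissue_clusters <- function(clustering, k) {
  stats::cutree(clustering$hclust, k = k)
}

#' Write a tissue correlation matrix as TSV
#'
#' @param corr correlation matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(corr, path) {
  df <- data.frame(tissue = rownames(corr), corr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
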