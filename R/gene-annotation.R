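#' Gene annotation container
#'
#' Bundles a set of gene models: each gene has a stable `gene_id`, a
#' chromosome, a strand, a biotype (`mRNA`, `lincRNA` or `antisense`) and one
#' or more transcripts, each a set of non-overlapping exons. All coordinates
#' in the public interface are 0-based half-open (BED convention); GTF I/O
#' converts from/to 1-based inclusive coordinates.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (`+`/`-`) and `biotype`.
#' @return An object of class `gene_annotation` with elements `exons` (the
#'   validated exon table) and `genes` (one row per gene: `gene_id`, `chrom`,
#'   `strand`, `biotype`, `span_start`, `span_end`).
#' @examples
#' ann <- gene_annotation(data.frame(
#'   gene_id = "g1", transcript_id = "t1", chrom = "chr1",
#'   start = c(100, 300), end = c(200, 400), strand = "+", biotype = "mRNA"
#' ))
#' genes(ann)
#' @export
gene_annotation <- function(exons) {
  .check_columns(exons, c("gene_id", "transcript_id", "chrom", "start",
                          "end", "strand", "biotype"), "exon table")
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start < 0L)) stop("exon start must be >= 0")
  if (any(exons$end <= exons$start)) stop("exon end must be > start")
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  bad_bt <- setdiff(unique(exons$biotype), c("mRNA", "lincRNA", "antisense"))
  if (length(bad_bt)) {
    stop("unknown biotype(s): ", paste(bad_bt, collapse = ", "),
         " (expected mRNA, lincRNA, antisense)")
  }
  # per-gene consistency: single chrom, strand, biotype
  per_gene <- unique(exons[, c("gene_id", "chrom", "strand", "biotype")])
  if (anyDuplicated(per_gene$gene_id)) {
    dup <- unique(per_gene$gene_id[duplicated(per_gene$gene_id)])
    stop("gene(s) with inconsistent chrom/strand/biotype across exons: ",
         paste(dup, collapse = ", "))
  }
  # exons within a transcript must not overlap each other
  key <- paste(exons$gene_id, exons$transcript_id, sep = "\r")
  ord <- order(key, exons$start)
  ek <- key[ord]; es <- exons$start[ord]; ee <- exons$end[ord]
  same <- ek[-1] == ek[-length(ek)]
  if (any(same & es[-1] < ee[-length(ee)])) {
    stop("overlapping exons within a transcript")
  }
  span <- do.call(rbind, lapply(split(seq_len(nrow(exons)), exons$gene_id), function(i) {
    data.frame(span_start = min(exons$start[i]), span_end = max(exons$end[i]))
  }))
  genes <- per_gene[match(rownames(span), per_gene$gene_id), ]
  genes$span_start <- span$span_start
  genes$span_end <- span$span_end
  rownames(genes) <- NULL
  structure(list(exons = exons, genes = genes), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes (%s), %d exon rows on %d chromosome(s)\n",
              nrow(x$genes),
              paste(sprintf("%s=%d", names(table(x$genes$biotype)),
                            as.integer(table(x$genes$biotype))), collapse = ", "),
              nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Per-gene summary table of an annotation
#'
#' @param ann a [gene_annotation()] object.
#' @return data.frame with one row per gene (`gene_id`, `chrom`, `strand`,
#'   `biotype`, `span_start`, `span_end`), 0-based half-open span.
#' @export
genes <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  ann$genes
}

#' Subset an annotation by biotype
#'
#' `lncRNA` is accepted as shorthand for the union of `lincRNA` and
#' `antisense`.
#'
#' @param ann a [gene_annotation()].
#' @param biotypes character vector of biotypes to keep.
#' @return a [gene_annotation()] restricted to the selected genes.
#' @export
filter_biotype <- function(ann, biotypes) {
  stopifnot(inherits(ann, "gene_annotation"))
  if ("lncRNA" %in% biotypes) {
    biotypes <- union(setdiff(biotypes, "lncRNA"), c("lincRNA", "antisense"))
  }
  keep <- ann$genes$gene_id[ann$genes$biotype %in% biotypes]
  gene_annotation(ann$exons[ann$exons$gene_id %in% keep, , drop = FALSE])
}
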