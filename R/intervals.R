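#' Project exons onto the genome
#'
#' For each gene, takes the union of all exon intervals across its
#' transcripts and merges them into a sorted set of pairwise-disjoint
#' intervals. Touching intervals (one's end equal to the next's start, in
#' half-open coordinates) are merged, so the projection of a projection is
#' itself. This per-gene "exon projection" is the unit on which
#' transposable-element content and conservation scores are computed.
#'
#' @param ann a [gene_annotation()].
#' @param gene_ids optional character vector restricting the projection to a
#'   subset of genes.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open), sorted by gene then start; intervals are
#'   disjoint within each gene.
#' @seealso [projection_lengths()] for per-gene total projected length.
#' @export
project_exons <- function(ann, gene_ids = NULL) {
  stopifnot(inherits(ann, "gene_annotation"))
  ex <- ann$exons
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, ex$gene_id)
    if (length(missing)) stop("unknown gene id(s): ", paste(missing, collapse = ", "))
    ex <- ex[ex$gene_id %in% gene_ids, , drop = FALSE]
  }
  if (!nrow(ex)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer()))
  }
  gr <- .as_granges(ex)
  red <- GenomicRanges::reduce(S4Vectors::split(gr, ex$gene_id))
  flat <- unlist(red, use.names = TRUE)
  out <- .from_granges(flat, extra = data.frame(gene_id = names(flat)))
  out <- out[, c("gene_id", "chrom", "strand", "start", "end")]
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total projected length per gene
#'
#' @param projection output of [project_exons()].
#' @return named integer vector of summed interval lengths per `gene_id`.
#' @export
projection_lengths <- function(projection) {
  .check_columns(projection, c("gene_id", "start", "end"), "projection")
  len <- tapply(projection$end - projection$start, projection$gene_id, sum)
  out <- as.integer(len)
  names(out) <- names(len)
  out
}

#' Strand-aware promoter windows
#'
#' The promoter of a gene is the fixed-size window immediately upstream of
#' the gene span's 5' boundary: `[span_start - size, span_start)` on the
#' `+` strand and `[span_end, span_end + size)` on the `-` strand, clipped
#' to `[0, chrom_length)`. Windows that vanish entirely after clipping are
#' flagged `degenerate` and should be excluded from content fractions.
#'
#' @param ann a [gene_annotation()].
#' @param size window size in bp (default 5000).
#' @param chrom_lengths named numeric vector of chromosome lengths covering
#'   every chromosome in the annotation.
#' @return data.frame `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `degenerate` (0-based half-open; degenerate rows have `start == end`).
#' @export
promoter_regions <- function(ann, size = 5000, chrom_lengths) {
  stopifnot(inherits(ann, "gene_annotation"), size > 0)
  g <- ann$genes
  missing <- setdiff(unique(g$chrom), names(chrom_lengths))
  if (length(missing)) {
    stop("chrom_lengths missing chromosome(s): ", paste(missing, collapse = ", "))
  }
  len <- unname(chrom_lengths[g$chrom])
  if (any(g$span_end > len)) {
    bad <- g$gene_id[g$span_end > len]
    stop("gene span beyond chromosome end: ", paste(bad, collapse = ", "))
  }
  plus <- g$strand == "+"
  start <- ifelse(plus, g$span_start - size, g$span_end)
  end <- ifelse(plus, g$span_start, g$span_end + size)
  start <- pmax(start, 0)
  end <- pmin(end, len)
  end <- pmax(end, start) # fully clipped windows collapse to zero length
  data.frame(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    start = as.integer(start), end = as.integer(end),
    degenerate = end <= start,
    stringsAsFactors = FALSE
  )
}

#' Total overlap between two interval sets
#'
#' Counts the number of bases covered by both `a` and the projection of
#' `b`. `b` is merged (projected) first so that internally overlapping
#' intervals contribute each base once; `a` is also merged, which is a
#' no-op when `a` is already a projection. Strand is ignored; intervals on
#' different chromosomes contribute nothing.
#'
#' @param a,b interval data.frames with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return total overlapping bases (numeric scalar).
#' @export
overlap_length <- function(a, b) {
  .check_columns(a, c("chrom", "start", "end"), "a")
  .check_columns(b, c("chrom", "start", "end"), "b")
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  a <- a[a$chrom %in% shared, , drop = FALSE]
  b <- b[b$chrom %in% shared, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) return(0)
  ga <- GenomicRanges::reduce(.as_granges(a, ignore_strand = TRUE))
  gb <- GenomicRanges::reduce(.as_granges(b, ignore_strand = TRUE))
  sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(ga, gb))))
}

# Per-region overlap with a (projected) subject interval set. `regions` is an
# interval data.frame carrying an `id` column; returns bp of overlap per id,
# in the order of `regions` rows. Used for per-gene TE-family content.
.per_region_overlap <- function(regions, subject_gr) {
  gr <- .as_granges(regions, ignore_strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, subject_gr, ignore.strand = TRUE)
  out <- numeric(length(gr))
  if (length(hits)) {
    inter <- GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(hits)], subject_gr[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE
    )
    w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
    out[as.integer(names(w))] <- as.numeric(w)
  }
  out
}
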