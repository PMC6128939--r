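#' Find lncRNA:mRNA pairs within a genomic window
#'
#' Emits every (lncRNA, mRNA) pair on the same chromosome whose gene-span
#' gap is at most `window` bp (gap measured between the closest span
#' boundaries; 0 for overlapping or touching spans). A lncRNA may appear
#' in many pairs.
#'
#' @param ann a [gene_annotation()] containing both biotypes.
#' @param window maximum span gap in bp (default 1e6).
#' @return data.frame `lnc_id`, `mrna_id`, `chrom`, `distance` (bp gap),
#'   `overlapping` (logical span overlap).
#' @export
find_pairs <- function(ann, window = 1e6) {
  stopifnot(inherits(ann, "gene_annotation"))
  g <- ann$genes
  lnc <- g[g$biotype %in% c("lincRNA", "antisense"), , drop = FALSE]
  mrna <- g[g$biotype == "mRNA", , drop = FALSE]
  if (!nrow(lnc) || !nrow(mrna)) {
    return(data.frame(lnc_id = character(), mrna_id = character(),
                      chrom = character(), distance = numeric(),
                      overlapping = logical()))
  }
  gl <- GenomicRanges::GRanges(lnc$chrom,
                               IRanges::IRanges(lnc$span_start + 1L, lnc$span_end))
  gm <- GenomicRanges::GRanges(mrna$chrom,
                               IRanges::IRanges(mrna$span_start + 1L, mrna$span_end))
  hits <- GenomicRanges::findOverlaps(gl, gm, maxgap = window, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  gap <- pmax(0,
              pmax(lnc$span_start[qi], mrna$span_start[si]) -
                pmin(lnc$span_end[qi], mrna$span_end[si]))
  out <- data.frame(
    lnc_id = lnc$gene_id[qi],
    mrna_id = mrna$gene_id[si],
    chrom = lnc$chrom[qi],
    distance = as.numeric(gap),
    overlapping = lnc$span_start[qi] < mrna$span_end[si] &
      mrna$span_start[si] < lnc$span_end[qi],
    stringsAsFactors = FALSE
  )
  out <- out[out$distance <= window, , drop = FALSE]
  out <- out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positionally classify lncRNA:mRNA pairs
#'
#' Applies the retained-subclass rules used for co-expression inference:
#'
#' * `antisense_exonic`: spans overlap, strands differ, and the exon
#'   projections of the two genes intersect by at least 1 bp;
#' * `divergent`: disjoint spans, opposite strands, facing boundaries are
#'   both 5' ends (head-to-head);
#' * `convergent`: disjoint spans, opposite strands, facing boundaries are
#'   both 3' ends (tail-to-tail);
#' * everything else (same-strand pairs, intron-only antisense overlap) is
#'   `excluded` and not retained.
#'
#' @param pairs output of [find_pairs()].
#' @param ann the [gene_annotation()] the pairs were derived from.
#' @return `pairs` with columns `pair_class` and `retained` added.
#' @export
classify_pairs <- function(pairs, ann) {
  .check_columns(pairs, c("lnc_id", "mrna_id", "overlapping"), "pairs")
  g <- ann$genes
  rownames(g) <- g$gene_id
  lg <- g[pairs$lnc_id, ]; mg <- g[pairs$mrna_id, ]
  opposite <- lg$strand != mg$strand
  cls <- rep("excluded", nrow(pairs))

  ov <- which(pairs$overlapping & opposite)
  if (length(ov)) {
    proj <- project_exons(ann, gene_ids = unique(c(pairs$lnc_id[ov], pairs$mrna_id[ov])))
    exonic <- vapply(ov, function(i) {
      overlap_length(proj[proj$gene_id == pairs$lnc_id[i], , drop = FALSE],
                     proj[proj$gene_id == pairs$mrna_id[i], , drop = FALSE]) >= 1
    }, logical(1))
    cls[ov[exonic]] <- "antisense_exonic"
  }

  dj <- which(!pairs$overlapping & opposite)
  if (length(dj)) {
    # for disjoint genes, the left gene faces with its right edge (3' on +,
    # 5' on -) and the right gene with its left edge (5' on +, 3' on -);
    # with opposite strands the two facing ends are necessarily both-5' or
    # both-3'
    lnc_left <- lg$span_end[dj] <= mg$span_start[dj]
    left_strand <- ifelse(lnc_left, lg$strand[dj], mg$strand[dj])
    right_strand <- ifelse(lnc_left, mg$strand[dj], lg$strand[dj])
    stopifnot(all(left_strand != right_strand))
    cls[dj] <- ifelse(left_strand == "-", "divergent", "convergent")
  }

  pairs$pair_class <- cls
  pairs$retained <- cls %in% c("antisense_exonic", "divergent", "convergent")
  pairs
}

#' Write a classified pair table as TSV
#'
#' @param pairs output of [classify_pairs()] (or [correlate_pairs()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  data.table::fwrite(pairs, path, sep = "\t")
  invisible(path)
}
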