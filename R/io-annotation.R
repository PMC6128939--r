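#' Read a gene annotation from GTF
#'
#' Exon features are grouped into transcripts by `transcript_id` and into
#' genes by `gene_id`; the gene biotype is taken from a configurable
#' attribute key. GTF's 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path GTF file path.
#' @param biotype_attr attribute key carrying the gene biotype
#'   (default `"gene_biotype"`).
#' @return a [gene_annotation()].
#' @export
read_gtf <- function(path, biotype_attr = "gene_biotype") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  for (col in c("gene_id", "transcript_id", biotype_attr)) {
    if (!col %in% names(mc)) stop("GTF lacks required attribute: ", col)
  }
  gene_annotation(data.frame(
    gene_id = mc$gene_id,
    transcript_id = mc$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = mc[[biotype_attr]],
    stringsAsFactors = FALSE
  ))
}

#' Write a gene annotation as GTF
#'
#' Emits one `exon` feature per exon with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes, converting back to GTF's 1-based inclusive
#' coordinates. Output is deterministic (sorted by chrom, start, gene,
#' transcript), so identical annotations yield byte-identical files.
#'
#' @param ann a [gene_annotation()].
#' @param path output file path.
#' @param biotype_attr attribute key to write the biotype under.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path, biotype_attr = "gene_biotype") {
  stopifnot(inherits(ann, "gene_annotation"))
  ex <- ann$exons
  ex <- ex[order(ex$chrom, ex$start, ex$gene_id, ex$transcript_id), , drop = FALSE]
  lines <- sprintf(
    "%s\tlncscape\texon\t%s\t%s\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; %s \"%s\";",
    ex$chrom, .fmt_int(ex$start + 1L), .fmt_int(ex$end), ex$strand,
    ex$gene_id, ex$transcript_id, biotype_attr, ex$biotype
  )
  writeLines(lines, path)
  invisible(path)
}

#' Transposable-element records
#'
#' Validates a table of TE copies. Strand is ignored throughout TE overlap
#' computations (RepeatMasker convention); only the four major classes are
#' admitted.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `te_class` (one of `DNA`, `LTR`, `LINE`, `SINE`) and
#'   `te_family`.
#' @return the validated data.frame, classed `te_records`.
#' @export
te_records <- function(df) {
  .check_columns(df, c("chrom", "start", "end", "te_class", "te_family"), "TE table")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 0L) || any(df$end <= df$start)) {
    stop("TE intervals must satisfy 0 <= start < end")
  }
  bad <- setdiff(unique(df$te_class), c("DNA", "LTR", "LINE", "SINE"))
  if (length(bad)) {
    stop("unknown TE class(es): ", paste(bad, collapse = ", "))
  }
  class(df) <- c("te_records", "data.frame")
  df
}

#' Read a RepeatMasker-style TE table or TE BED file
#'
#' Accepts either a UCSC `rmsk` TSV (header with `genoName`, `genoStart`,
#' `genoEnd`, `repClass` and `repFamily` or `repName`; `genoStart` is
#' 0-based) or a headerless BED6 whose name field packs `class/family`.
#' Records outside the four major classes (DNA, LTR, LINE, SINE) are
#' dropped; the number dropped is attached as attribute `n_dropped`.
#'
#' @param path input file path.
#' @return a [te_records()] table.
#' @export
read_te_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("genoName", first)) {
    tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
    fam_col <- if ("repFamily" %in% names(tab)) "repFamily" else "repName"
    .check_columns(tab, c("genoName", "genoStart", "genoEnd", "repClass", fam_col),
                   "rmsk table")
    df <- data.frame(
      chrom = tab$genoName, start = tab$genoStart, end = tab$genoEnd,
      te_class = tab$repClass, te_family = tab[[fam_col]],
      stringsAsFactors = FALSE
    )
  } else {
    tab <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
    if (ncol(tab) < 4L) stop("TE BED requires at least 4 columns (BED6 with class/family name)")
    parts <- strsplit(as.character(tab[[4]]), "/", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("TE BED name field must be 'class/family'")
    }
    df <- data.frame(
      chrom = as.character(tab[[1]]), start = tab[[2]], end = tab[[3]],
      te_class = vapply(parts, `[`, "", 1L),
      te_family = vapply(parts, `[`, "", 2L),
      stringsAsFactors = FALSE
    )
  }
  keep <- df$te_class %in% c("DNA", "LTR", "LINE", "SINE")
  out <- te_records(df[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write intervals as BED
#'
#' Exports projections, promoters or TE records in BED format (0-based
#' half-open, as stored). For [te_records()] the name field is written as
#' `class/family`, round-tripping through [read_te_table()].
#'
#' @param x interval data.frame (`chrom`, `start`, `end`, optionally
#'   `gene_id`/`strand`, or a [te_records()] table).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  .check_columns(x, c("chrom", "start", "end"), "interval table")
  name <- if (inherits(x, "te_records")) {
    paste(x$te_class, x$te_family, sep = "/")
  } else if ("gene_id" %in% names(x)) {
    x$gene_id
  } else {
    "."
  }
  strand <- if ("strand" %in% names(x)) x$strand else "."
  lines <- sprintf("%s\t%s\t%s\t%s\t0\t%s",
                   x$chrom, .fmt_int(x$start), .fmt_int(x$end), name, strand)
  writeLines(lines, path)
  invisible(path)
}
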