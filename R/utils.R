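# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All generators route randomness
# through this so that outputs are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Interval data.frame (chrom/start/end, 0-based half-open) -> GRanges
# (1-based closed). Strand is carried when present unless ignore_strand.
.as_granges <- function(df, ignore_strand = FALSE) {
  strand <- if (!ignore_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

# GRanges -> interval data.frame in 0-based half-open coordinates.
.from_granges <- function(gr, extra = NULL) {
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) out <- cbind(out, extra)
  out
}

.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Format genomic coordinates without scientific notation (file writers).
.fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

# Session-level cache (exact Spearman null distributions etc.).
.lncscape_cache <- new.env(parent = emptyenv())
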