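# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (per-base masks, exhaustive enumeration,
# direct formulas) and share no code with the implementation paths they
# check.

# per-base boolean mask of a set of 0-based half-open intervals on [0, L)
mask_of <- function(starts, ends, L) {
  m <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) m[(starts[i] + 1):ends[i]] <- TRUE
  }
  m
}

# intervals (sorted, disjoint) back from a mask
mask_to_intervals <- function(m) {
  r <- rle(m)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(start = start[r$values], end = end[r$values])
}

# direct evaluation of the tau formula
oracle_tau <- function(x, floor_tpm = 0) {
  x[x < floor_tpm] <- 0
  if (max(x) == 0) return(NA_real_)
  sum(1 - x / max(x)) / (length(x) - 1)
}

# quadratic-time rank-then-Pearson Spearman
oracle_spearman <- function(x, y) {
  r <- function(v) vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  }, 0)
  rx <- r(x); ry <- r(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

# exact two-sided Spearman p by full enumeration (untied data)
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  s_obs <- sum((rx - ry)^2)
  s_all <- vapply(all_perms(n), function(p) sum((rx - p)^2), 0)
  min(1, 2 * min(mean(s_all <= s_obs), mean(s_all >= s_obs)))
}

# classical CCA canonical correlations via the QR route (independent of the
# covariance-whitening implementation)
oracle_cca_cor <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  qx <- qr(Xc); qy <- qr(Yc)
  svd(t(qr.Q(qx)[, seq_len(qx$rank)]) %*% qr.Q(qy)[, seq_len(qy$rank)])$d
}

# step-up BH by the textbook trace
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# random interval set on a chromosome of length L
rand_intervals <- function(n, L, max_len = 400) {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(L - l, 1L) - 1L, 0L)
  data.frame(chrom = "chr1", start = start, end = start + len)
}

# small two-biotype annotation used by several I/O and pairing tests
toy_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("m1", "m1", "m1", "m2", "l1", "l1", "a1"),
    transcript_id = c("m1.t1", "m1.t1", "m1.t2", "m2.t1", "l1.t1", "l1.t1", "a1.t1"),
    chrom = c(rep("chr1", 6), "chr1"),
    start = c(1000, 3000, 1000, 20000, 9000, 9800, 1100),
    end = c(1600, 3600, 2200, 26000, 9500, 10200, 1500),
    strand = c("+", "+", "+", "-", "+", "+", "-"),
    biotype = c("mRNA", "mRNA", "mRNA", "mRNA", "lincRNA", "lincRNA", "antisense"),
    stringsAsFactors = FALSE
  ))
}
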