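#' Exact null distribution of the Spearman rank statistic
#'
#' Distribution of `S = sum((rank(x) - rank(y))^2)` under the permutation
#' null for `n` untied observations. Computed by a subset dynamic program
#' over `T = sum(i * perm(i))` (with `S = 2 * (sum(i^2) - T)`), which
#' enumerates all `n!` permutations in `O(2^n * n * sum(i^2))` time.
#' Results are cached per `n` for the session.
#'
#' @param n number of observations (2..12; the exact route is intended for
#'   small samples such as 11 matched tissues).
#' @return data.frame `S` (achievable values) and `prob`.
#' @export
spearman_null_distribution <- function(n) {
  stopifnot(n >= 2L, n <= 12L)
  key <- paste0("spearman_null_", n)
  if (!is.null(.lncscape_cache[[key]])) return(.lncscape_cache[[key]])
  tmax <- sum((1:n)^2)
  nmask <- bitwShiftL(1L, n)
  cnt <- matrix(0, nmask, tmax + 1L)
  cnt[1L, 1L] <- 1
  popcount <- function(m) sum(bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L))
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (mask in seq_len(nmask - 1L)) {
    i <- popcount(mask) # position being filled
    row <- numeric(tmax + 1L)
    for (j in which(bitwAnd(mask, bits) > 0L)) {
      prev <- mask - bits[j]
      shift <- i * j
      idx <- (shift + 1L):(tmax + 1L)
      row[idx] <- row[idx] + cnt[prev + 1L, seq_len(tmax + 1L - shift)]
    }
    cnt[mask + 1L, ] <- row
  }
  counts <- cnt[nmask, ]
  t_vals <- which(counts > 0) - 1L
  s_vals <- 2 * (tmax - t_vals)
  ord <- order(s_vals)
  out <- data.frame(S = s_vals[ord], prob = counts[t_vals + 1L][ord] / factorial(n))
  .lncscape_cache[[key]] <- out
  out
}

#' Spearman correlation with exact or approximate p-value
#'
#' Average-rank Spearman correlation with a two-sided p-value computed
#' from the exact permutation distribution of the rank statistic for
#' `n <= exact_limit` untied samples, and from the t-approximation
#' (`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df) otherwise or
#' in the presence of ties.
#'
#' @param x,y aligned numeric vectors (`n >= 3`).
#' @param method `"auto"` (exact when possible, default), `"exact"` or
#'   `"approx"`.
#' @param exact_limit largest `n` for the exact route (default 12).
#' @return list `rho`, `pvalue`, `n`, `method` (method actually used;
#'   `"undefined"` with `rho = NA` when either vector is constant).
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(4, 3, 2, 1))
#' @export
spearman_rho <- function(x, y, method = c("auto", "exact", "approx"),
                         exact_limit = 12L) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3 points")
  if (anyNA(x) || anyNA(y)) stop("missing values")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, pvalue = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  use_exact <- (method == "exact") ||
    (method == "auto" && n <= exact_limit && !ties)
  if (method == "exact" && (ties || n > exact_limit)) {
    stop("exact p-value requires untied data and n <= ", exact_limit)
  }
  if (use_exact) {
    s <- sum((rx - ry)^2)
    dist <- spearman_null_distribution(n)
    p <- 2 * min(sum(dist$prob[dist$S <= s]), sum(dist$prob[dist$S >= s]))
    p <- min(p, 1)
    used <- "exact"
  } else {
    r <- min(max(rho, -1), 1)
    if (abs(r) == 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    used <- "approx"
  }
  list(rho = rho, pvalue = p, n = n, method = used)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over one family of p-values,
#' returned in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (same order as input).
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
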