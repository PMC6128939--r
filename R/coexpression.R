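#' Correlate classified pairs over tissue expression
#'
#' Computes Spearman correlation and p-value for each retained pair over
#' the tissue expression vectors, adjusts p-values once over all tested
#' pairs (a single Benjamini-Hochberg family across classes), and flags
#' significant co-expression by the rule `|rho| > rho_threshold` and
#' `padj < padj_threshold`.
#'
#' Pairs are dropped before testing (with a reason code, attached as
#' attribute `dropped`) when either member is absent a retained class,
#' never expressed above `expression_floor`, or has a constant expression
#' vector (undefined rank correlation).
#'
#' @param pairs classified pairs from [classify_pairs()]; only rows with
#'   `retained == TRUE` are tested.
#' @param mat expression matrix containing every paired gene.
#' @param rho_threshold absolute-correlation cut-off (default 0.5, strict).
#' @param padj_threshold adjusted-p cut-off (default 0.05, strict).
#' @param expression_floor drop pairs whose either member has max TPM at
#'   or below this floor (default 0).
#' @param p_method p-value route passed to [spearman_rho()].
#' @return data.frame of tested pairs with `rho`, `pvalue`, `padj`,
#'   `significant` added; attributes `dropped` (reason table) and
#'   `summary` (counts by class and rho sign among significant pairs).
#' @export
correlate_pairs <- function(pairs, mat, rho_threshold = 0.5,
                            padj_threshold = 0.05, expression_floor = 0,
                            p_method = "auto") {
  .check_columns(pairs, c("lnc_id", "mrna_id", "pair_class", "retained"), "pairs")
  pairs <- pairs[pairs$retained, , drop = FALSE]
  ids <- unique(c(pairs$lnc_id, pairs$mrna_id))
  missing <- setdiff(ids, rownames(mat))
  if (length(missing)) {
    stop("gene(s) missing from expression matrix: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
  }
  maxes <- apply(mat[ids, , drop = FALSE], 1L, max)
  consts <- apply(mat[ids, , drop = FALSE], 1L, function(v) length(unique(v)) == 1L)
  unexpr <- names(maxes)[maxes <= expression_floor]
  constant <- names(consts)[consts]
  reason <- rep(NA_character_, nrow(pairs))
  reason[pairs$lnc_id %in% constant | pairs$mrna_id %in% constant] <- "constant_vector"
  reason[pairs$lnc_id %in% unexpr | pairs$mrna_id %in% unexpr] <- "not_expressed"
  dropped <- pairs[!is.na(reason), , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!is.na(reason)]
  tested <- pairs[is.na(reason), , drop = FALSE]

  if (nrow(tested)) {
    res <- mapply(function(a, b) {
      s <- spearman_rho(mat[a, ], mat[b, ], method = p_method)
      c(s$rho, s$pvalue)
    }, tested$lnc_id, tested$mrna_id)
    tested$rho <- res[1, ]
    tested$pvalue <- res[2, ]
    tested$padj <- bh_adjust(tested$pvalue)
    tested$significant <- abs(tested$rho) > rho_threshold &
      tested$padj < padj_threshold
  } else {
    tested$rho <- numeric(0); tested$pvalue <- numeric(0)
    tested$padj <- numeric(0); tested$significant <- logical(0)
  }
  rownames(tested) <- NULL

  sig <- tested[tested$significant, , drop = FALSE]
  summary <- list(
    n_tested = nrow(tested),
    n_dropped = nrow(dropped),
    n_significant = nrow(sig),
    by_class = as.list(table(sig$pair_class)),
    n_positive = sum(sig$rho > 0),
    n_negative = sum(sig$rho < 0),
    n_distinct_lnc = length(unique(sig$lnc_id))
  )
  attr(tested, "dropped") <- dropped
  attr(tested, "summary") <- summary
  tested
}

#' Distance profile of co-expressed pairs
#'
#' Bins significant pairs by `|rho|` and reports the mean pair distance per
#' bin, together with a Spearman trend statistic between `|rho|` and
#' distance over all significant pairs (negative when stronger
#' co-expression implies closer pairs). Empty bins are omitted.
#'
#' @param cps output of [correlate_pairs()].
#' @param breaks increasing `|rho|` bin edges (default
#'   `c(0.5, 0.7, 0.9, 1)`, left-open right-closed).
#' @return list `bins` (data.frame `bin`, `n`, `mean_distance`),
#'   `trend_rho`, `trend_p`.
#' @export
distance_correlation_profile <- function(cps, breaks = c(0.5, 0.7, 0.9, 1)) {
  sig <- cps[cps$significant, , drop = FALSE]
  if (!nrow(sig)) stop("no significant pairs")
  ar <- abs(sig$rho)
  bin <- cut(ar, breaks = breaks)
  keep <- !is.na(bin)
  bins <- do.call(rbind, lapply(levels(bin), function(lv) {
    d <- sig$distance[keep & bin == lv]
    if (!length(d)) return(NULL)
    data.frame(bin = lv, n = length(d), mean_distance = mean(d),
               stringsAsFactors = FALSE)
  }))
  trend <- spearman_rho(ar, sig$distance, method = "approx")
  list(bins = bins, trend_rho = trend$rho, trend_p = trend$pvalue)
}

#' Rank-sum comparison of two distance (or score) sets
#'
#' Two-sample Wilcoxon rank-sum test, by default the normal approximation
#' with tie correction and no continuity correction (so identical samples
#' give a one-tailed p of 0.5), optionally the exact distribution.
#'
#' @param a,b numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (a shifted right of b) or
#'   `"less"`.
#' @param method `"normal"` (default) or `"exact"`.
#' @return list `statistic` (W, rank-sum of `a` relative to `b`), `p.value`.
#' @export
rank_sum_test <- function(a, b, alternative = c("two.sided", "greater", "less"),
                          method = c("normal", "exact")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ht <- stats::wilcox.test(a, b, alternative = alternative,
                           exact = method == "exact", correct = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Nearest- versus best-partner analysis per lncRNA
#'
#' For every lncRNA with at least two significantly co-expressed mRNA
#' partners, orders the partners by genomic distance and reports the
#' distance rank of the partner with the largest `|rho|`. A flag marks
#' lncRNAs whose best-correlated partner is not the nearest gene.
#'
#' @param cps output of [correlate_pairs()].
#' @return data.frame `lnc_id`, `n_partners`, `best_partner`, `best_rho`,
#'   `best_rank` (distance rank of the best partner), `best_is_not_nearest`.
#' @export
partner_rank_analysis <- function(cps) {
  sig <- cps[cps$significant, , drop = FALSE]
  keep <- names(which(table(sig$lnc_id) >= 2L))
  rows <- lapply(keep, function(id) {
    sub <- sig[sig$lnc_id == id, , drop = FALSE]
    sub <- sub[order(sub$distance, sub$mrna_id), , drop = FALSE]
    best <- which.max(abs(sub$rho))
    data.frame(
      lnc_id = id, n_partners = nrow(sub),
      best_partner = sub$mrna_id[best], best_rho = sub$rho[best],
      best_rank = best, best_is_not_nearest = best > 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(lnc_id = character(), n_partners = integer(),
               best_partner = character(), best_rho = numeric(),
               best_rank = integer(), best_is_not_nearest = logical())
  }
  rownames(out) <- NULL
  out
}
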