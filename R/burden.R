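#' Per-individual variant burden
#'
#' Counts, for every sample, either the number of variant sites at which it
#' carries at least one alternative allele (`"carrier"`, the default: the
#' "number of variants in each individual") or the total number of
#' alternative alleles (`"allele"`). Missing genotypes contribute 0.
#'
#' @param gm Filtered [genotype_matrix()].
#' @param mode `"carrier"` or `"allele"`.
#' @return Object of class `burden_profile`: data frame with columns
#'   `sample`, `group`, `burden`; the counting mode is kept as an attribute.
#' @export
per_individual_burden <- function(gm, mode = c("carrier", "allele")) {
  mode <- match.arg(mode)
  b <- if (mode == "carrier") {
    colSums(gm$dosages >= 1L, na.rm = TRUE)
  } else {
    colSums(gm$dosages, na.rm = TRUE)
  }
  out <- data.frame(sample = colnames(gm$dosages),
                    group = gm$groups,
                    burden = as.integer(b),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("burden_profile", "data.frame")
  out
}

#' Bin per-individual burdens into a 2xK group-by-interval table
#'
#' With `edges = NULL`, uses `n_bins` equal-width intervals spanning the
#' observed burden range (all identical burdens collapse into the first
#' bin). Intervals are `[e_i, e_{i+1})` with the last interval closed;
#' burdens outside explicit edges are assigned to the nearest terminal bin
#' with a warning.
#'
#' @param profile A [per_individual_burden()] result (or any data frame
#'   with `group` and `burden` columns).
#' @param edges Strictly increasing numeric vector of K+1 interval edges,
#'   or `NULL` for automatic equal-width bins.
#' @param n_bins Number of automatic bins (K >= 2); default 5.
#' @return Object of class `burden_bins`: list with `table` (2xK counts,
#'   rows = groups), `edges`, and `midpoints`.
#' @export
bin_burden <- function(profile, edges = NULL, n_bins = 5) {
  groups <- sort(unique(profile$group))
  if (is.null(edges)) {
    if (n_bins < 2) abort_usage("at least 2 bins required")
    lo <- min(profile$burden); hi <- max(profile$burden)
    edges <- if (lo == hi) lo + 0:n_bins else
      seq(lo, hi, length.out = n_bins + 1)
  }
  if (any(diff(edges) <= 0)) abort_usage("edges must be strictly increasing")
  k <- length(edges) - 1L
  if (k < 2L) abort_usage("at least 2 bins required")
  idx <- findInterval(profile$burden, edges, rightmost.closed = TRUE)
  if (any(idx < 1L) || any(idx > k)) {
    warning("burden outside bin range; assigned to nearest terminal bin")
    idx <- pmin(pmax(idx, 1L), k)
  }
  tab <- matrix(0L, nrow = length(groups), ncol = k,
                dimnames = list(groups, paste0("bin", seq_len(k))))
  for (g in seq_along(groups)) {
    tt <- tabulate(idx[profile$group == groups[g]], nbins = k)
    tab[g, ] <- tt
  }
  structure(list(table = tab, edges = edges,
                 midpoints = (edges[-1] + edges[-length(edges)]) / 2),
            class = "burden_bins")
}

#' Chi-squared test for linear trend on a 2xK table
#'
#' Cochran-Armitage-type trend statistic with column scores: with group
#' indicator g (0/1 by row) and score s per column, the statistic is
#' `chi2 = N * r^2` where r is the Pearson correlation of (g, s) over all N
#' individuals; the p-value comes from the chi-squared distribution with
#' 1 degree of freedom. The statistic is invariant under affine score
#' transformations. Degenerate inputs (all samples in one group or one bin,
#' or constant scores) return chi2 = 0, p = 1, flagged.
#'
#' @param x A [bin_burden()] result or a 2xK integer matrix.
#' @param scores Numeric score per column; default: bin midpoints when `x`
#'   is a `burden_bins`, column ranks `1:K` for a bare matrix.
#' @return Object of class `trend_test`: list with `chi2`, `df = 1`,
#'   `p.value`, `scores`, `edges` (or `NULL`), `table`, `degenerate`.
#' @export
chi2_linear_trend <- function(x, scores = NULL) {
  if (inherits(x, "burden_bins")) {
    tab <- x$table
    if (is.null(scores)) scores <- x$midpoints
    edges <- x$edges
  } else {
    tab <- as.matrix(x)
    if (is.null(scores)) scores <- seq_len(ncol(tab))
    edges <- NULL
  }
  if (nrow(tab) != 2L) abort_usage("trend test expects a 2-row table")
  if (length(scores) != ncol(tab)) {
    abort_usage("need one score per column")
  }
  N <- sum(tab)
  if (N == 0) abort_usage("empty table")
  res <- list(chi2 = 0, df = 1L, p.value = 1, scores = scores,
              edges = edges, table = tab, degenerate = TRUE)
  class(res) <- "trend_test"
  if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2L) return(res)
  cw <- colSums(tab)
  s_mean <- sum(cw * scores) / N
  s_var <- sum(cw * (scores - s_mean)^2) / N
  g_mean <- sum(tab[2, ]) / N
  g_var <- g_mean * (1 - g_mean)
  if (s_var == 0 || g_var == 0) return(res)
  cov_gs <- sum(tab[2, ] * scores) / N - g_mean * s_mean
  r <- cov_gs / sqrt(s_var * g_var)
  chi2 <- N * r^2
  res$chi2 <- chi2
  res$p.value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  res$degenerate <- FALSE
  res
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("chi-squared linear trend: chi2 = %.4g, df = 1, p = %.4g%s\n",
              x$chi2, x$p.value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Gene-set burden analysis
#'
#' Composes the gene-set stage: per-individual burden, interval binning,
#' and the chi-squared linear-trend test, restricted to the two compared
#' groups. Also reports the per-group percentage of individuals per bin
#' (the published figure's layout) and a Wilcoxon rank-sum test on the raw
#' (unbinned) burdens as a sensitivity check.
#'
#' @param gm Filtered [genotype_matrix()].
#' @param groups The two group labels to compare.
#' @param mode Burden counting mode; see [per_individual_burden()].
#' @param edges,n_bins,scores Binning and scoring controls; see
#'   [bin_burden()] and [chi2_linear_trend()].
#' @return List with `trend` (a `trend_test`), `profile`, `bins`,
#'   `percent_table` (groups x bins, rows summing to 100), and
#'   `wilcoxon_p`.
#' @export
run_gene_set_level <- function(gm, groups, mode = "carrier",
                               edges = NULL, n_bins = 5, scores = NULL) {
  keep <- colnames(gm$dosages)[gm$groups %in% groups]
  if (length(keep) == 0L) abort_usage("no samples in the selected groups")
  sub <- subset_samples(gm, keep)
  profile <- per_individual_burden(sub, mode = mode)
  bins <- bin_burden(profile, edges = edges, n_bins = n_bins)
  trend <- chi2_linear_trend(bins, scores = scores)
  pct <- sweep(bins$table, 1, rowSums(bins$table), "/") * 100
  pct[is.nan(pct)] <- 0
  w <- split(profile$burden, profile$group)
  wilcoxon_p <- if (length(w) == 2L &&
                    all(lengths(w) > 0)) {
    suppressWarnings(wilcox.test(w[[1]], w[[2]], exact = FALSE)$p.value)
  } else NA_real_
  list(trend = trend, profile = profile, bins = bins,
       percent_table = pct, wilcoxon_p = wilcoxon_p)
}
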