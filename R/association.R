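#' Two-sided Fisher exact p-values for 2x2 tables (vectorized)
#'
#' Conditional on both margins, the first cell follows a hypergeometric
#' distribution; the two-sided p-value sums the probabilities of all tables
#' whose probability does not exceed that of the observed table (relative
#' tolerance 1e-7, matching the usual probability-mass convention).
#' Tables with a zero row or column margin are degenerate and return p = 1.
#'
#' @param a,b,c,d Equal-length integer vectors: per-table cell counts
#'   `[[a, b], [c, d]]`.
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher22_pvalue <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]
    c1 <- a[i] + c[i]; c2 <- b[i] + d[i]
    if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
      out[i] <- 1
      next
    }
    N <- r1 + r2
    lo <- max(0L, c1 - r2); hi <- min(r1, c1)
    x <- lo:hi
    dens <- stats::dhyper(x, r1, r2, c1)
    p_obs <- dens[a[i] - lo + 1L]
    out[i] <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  }
  out
}

#' Two-sided Fisher exact p-value for a 2xK table (Freeman-Halton)
#'
#' Enumerates every table with the observed margins, computing each table's
#' conditional probability from log-factorials, and sums those no more
#' probable than the observed table. The enumeration grid runs over the two
#' columns with the smallest support, so cost scales with the product of
#' the two smallest of `min(row1, col_j)`.
#'
#' @param tab Integer matrix with 2 rows and K >= 2 columns.
#' @return Two-sided exact p-value in (0, 1].
#' @export
fisher2xk_pvalue <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L)
  if (ncol(tab) == 2L) {
    return(fisher22_pvalue(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  }
  stopifnot(ncol(tab) == 3L)
  r <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(r == 0L) || sum(cs > 0L) < 2L) return(1)
  # drop empty columns: they contribute nothing to the distribution
  if (any(cs == 0L)) {
    return(fisher2xk_pvalue(tab[, cs > 0L, drop = FALSE]))
  }
  # reorder columns so the free grid indices have the smallest supports
  supp <- pmin(r[1], cs)
  ord <- order(supp)
  tab <- tab[, ord, drop = FALSE]
  cs <- cs[ord]
  r1 <- r[1]
  lf <- lfactorial(0:N)
  const <- lf[r[1] + 1L] + lf[r[2] + 1L] + sum(lf[cs + 1L]) - lf[N + 1L]
  a11 <- 0:min(r1, cs[1])
  a12 <- 0:min(r1, cs[2])
  t1 <- lf[a11 + 1L] + lf[cs[1] - a11 + 1L]
  t2 <- lf[a12 + 1L] + lf[cs[2] - a12 + 1L]
  a13 <- outer(a11, a12, function(x, y) r1 - x - y)
  valid <- a13 >= 0L & a13 <= cs[3]
  logp <- matrix(-Inf, length(a11), length(a12))
  idx <- which(valid)
  a13v <- a13[idx]
  logp[idx] <- const - (outer(t1, t2, "+")[idx] +
                          lf[a13v + 1L] + lf[cs[3] - a13v + 1L])
  p_obs <- logp[tab[1, 1] + 1L, tab[1, 2] + 1L]
  probs <- exp(logp[idx])
  min(1, sum(probs[probs <= exp(p_obs) * (1 + 1e-7)]))
}

#' Fisher exact test on a contingency table
#'
#' Dispatches to the 2x2 hypergeometric tail summation or the 2x3
#' Freeman-Halton enumeration. Degenerate tables (a zero row or column
#' margin) return p = 1 with a flag instead of an error, so callers can
#' exclude them from multiple-testing families.
#'
#' @param tab 2x2 or 2x3 integer matrix.
#' @return List with `p.value`, `degenerate` (logical), and `method`.
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))          # p = 1
#' fisher_exact(rbind(c(9, 99), c(18, 34)))        # allele-level table
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L || !ncol(tab) %in% c(2L, 3L)) {
    abort_usage("fisher_exact expects a 2x2 or 2x3 table")
  }
  if (any(tab < 0)) abort_data("negative cell count")
  degenerate <- any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2L
  p <- if (degenerate) 1 else fisher2xk_pvalue(tab)
  list(p.value = p, degenerate = degenerate,
       method = if (ncol(tab) == 2L) "fisher-2x2" else "freeman-halton-2x3")
}

# Per-group allele and genotype count summaries for all variants at once.
group_counts <- function(gm, group) {
  cols <- gm$groups == group
  if (!any(cols)) abort_usage(sprintf("group label absent: %s", group))
  d <- gm$dosages[, cols, drop = FALSE]
  called <- unname(rowSums(!is.na(d)))
  alt <- unname(rowSums(d, na.rm = TRUE))
  list(alt = alt, called = called, ref = 2L * called - alt,
       g0 = unname(rowSums(d == 0L, na.rm = TRUE)),
       g1 = unname(rowSums(d == 1L, na.rm = TRUE)),
       g2 = unname(rowSums(d == 2L, na.rm = TRUE)))
}

#' Allele-level contingency table for one variant
#'
#' Per group: alternative-allele count (sum of dosages, missing dropped)
#' against reference-allele count (2 x called - alt).
#'
#' @param gm A [genotype_matrix()].
#' @param key Variant key string.
#' @param groups The two group labels (rows of the table).
#' @return 2x2 integer matrix, rows = groups, columns = ref/alt.
#' @export
allele_table <- function(gm, key, groups) {
  i <- match(key, gm$variants$key)
  if (is.na(i)) abort_usage(sprintf("variant not in matrix: %s", key))
  tab <- t(vapply(groups, function(g) {
    gc <- group_counts(gm, g)
    c(ref = gc$ref[i], alt = gc$alt[i])
  }, numeric(2)))
  storage.mode(tab) <- "integer"
  rownames(tab) <- groups
  tab
}

#' Genotype-level contingency table for one variant
#'
#' Per group: counts of hom-ref / het / hom-alt genotypes (missing dropped).
#'
#' @inheritParams allele_table
#' @return 2x3 integer matrix, rows = groups.
#' @export
genotype_table <- function(gm, key, groups) {
  i <- match(key, gm$variants$key)
  if (is.na(i)) abort_usage(sprintf("variant not in matrix: %s", key))
  tab <- t(vapply(groups, function(g) {
    gc <- group_counts(gm, g)
    c(hom_ref = gc$g0[i], het = gc$g1[i], hom_alt = gc$g2[i])
  }, numeric(3)))
  storage.mode(tab) <- "integer"
  rownames(tab) <- groups
  tab
}

#' Pooled per-gene contingency tables
#'
#' The gene-level tables are the elementwise sums of the per-variant tables
#' over every variant assigned to the gene, i.e. variant-sample observations
#' are stacked. The pooled alternative-allele frequency per group is pooled
#' alt over pooled total alleles.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param gene Gene symbol.
#' @param assignment Variant-to-gene data frame (`key`, `gene`).
#' @param groups The two group labels.
#' @return List with `allele` (2x2), `genotype` (2x3), `n_variants`, and
#'   `freq` (named per-group pooled alt-allele fraction).
#' @export
gene_pooled_tables <- function(gm, gene, assignment, groups) {
  keys <- assignment$key[assignment$gene == gene]
  keys <- intersect(keys, gm$variants$key)
  if (length(keys) == 0L) {
    abort_usage(sprintf("gene %s has no variants in the matrix", gene))
  }
  idx <- match(keys, gm$variants$key)
  allele <- matrix(0L, 2, 2, dimnames = list(groups, c("ref", "alt")))
  geno <- matrix(0L, 2, 3,
                 dimnames = list(groups, c("hom_ref", "het", "hom_alt")))
  freq <- setNames(numeric(2), groups)
  for (g in seq_along(groups)) {
    gc <- group_counts(gm, groups[g])
    allele[g, ] <- c(sum(gc$ref[idx]), sum(gc$alt[idx]))
    geno[g, ] <- c(sum(gc$g0[idx]), sum(gc$g1[idx]), sum(gc$g2[idx]))
    tot <- sum(allele[g, ])
    freq[g] <- if (tot > 0) allele[g, "alt"] / tot else NA_real_
  }
  storage.mode(allele) <- "integer"
  storage.mode(geno) <- "integer"
  list(allele = allele, genotype = geno, n_variants = length(keys),
       freq = freq)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, mapped back to the
#' input order; `q >= p` holds for every element.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort_data("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Shared scaffolding for variant- and gene-level result frames: applies BH
# separately within the allele-level and genotype-level families, excluding
# degenerate (untestable) units from each family.
finalize_results <- function(df, groups, level, fdr_alpha) {
  df$q_allele <- rep(NA_real_, nrow(df))
  df$q_genotype <- rep(NA_real_, nrow(df))
  ok_a <- !df$untestable_allele
  ok_g <- !df$untestable_genotype
  df$q_allele[ok_a] <- bh_fdr(df$p_allele[ok_a])
  df$q_genotype[ok_g] <- bh_fdr(df$p_genotype[ok_g])
  df$significant_allele <- !is.na(df$q_allele) & df$q_allele < fdr_alpha
  df$significant_genotype <- !is.na(df$q_genotype) & df$q_genotype < fdr_alpha
  attr(df, "groups") <- groups
  attr(df, "level") <- level
  attr(df, "fdr_alpha") <- fdr_alpha
  attr(df, "family_sizes") <- c(allele = sum(ok_a), genotype = sum(ok_g))
  df
}

#' Per-variant association tests
#'
#' For every variant: two-sided Fisher exact p at the allele level (2x2
#' ref/alt counts) and the genotype level (2x3 genotype counts), with BH
#' q-values computed separately within each family. Degenerate tables (a
#' group with no called genotypes, or a monomorphic site) are flagged
#' untestable and excluded from the BH families.
#'
#' @param gm Filtered [genotype_matrix()].
#' @param groups The two group labels to compare.
#' @param fdr_alpha FDR significance threshold; default 0.05.
#' @param tests Which test families to compute (`"allele"`, `"genotype"`,
#'   or both); a family not computed gets p = NA and is flagged
#'   untestable.
#' @return Data frame with one row per variant: `unit` (variant key),
#'   `level = "variant"`, `n_variants = 1`, per-group pooled frequencies,
#'   p/q at both levels, untestable and significance flags. Attributes:
#'   `groups`, `level`, `fdr_alpha`, `family_sizes`.
#' @export
run_variant_level <- function(gm, groups, fdr_alpha = 0.05,
                              tests = c("allele", "genotype")) {
  tests <- match.arg(tests, several.ok = TRUE)
  g1 <- group_counts(gm, groups[1])
  g2 <- group_counts(gm, groups[2])
  nv <- n_variants(gm)
  unt_allele <- g1$called == 0L | g2$called == 0L |
    (g1$alt + g2$alt) == 0L | (g1$ref + g2$ref) == 0L
  p_allele <- rep(1, nv)
  if ("allele" %in% tests) {
    idx <- which(!unt_allele)
    p_allele[idx] <- fisher22_pvalue(g1$ref[idx], g1$alt[idx],
                                     g2$ref[idx], g2$alt[idx])
  } else {
    p_allele <- rep(NA_real_, nv)
    unt_allele <- rep(TRUE, nv)
  }
  p_geno <- rep(1, nv)
  unt_geno <- logical(nv)
  if ("genotype" %in% tests) {
    for (i in seq_len(nv)) {
      tab <- rbind(c(g1$g0[i], g1$g1[i], g1$g2[i]),
                   c(g2$g0[i], g2$g1[i], g2$g2[i]))
      fe <- fisher_exact(tab)
      p_geno[i] <- fe$p.value
      unt_geno[i] <- fe$degenerate
    }
  } else {
    p_geno <- rep(NA_real_, nv)
    unt_geno <- rep(TRUE, nv)
  }
  df <- data.frame(
    unit = gm$variants$key,
    level = rep("variant", nv),
    n_variants = rep(1L, nv),
    freq_group1 = ifelse(g1$called > 0, g1$alt / (2 * g1$called), NA_real_),
    freq_group2 = ifelse(g2$called > 0, g2$alt / (2 * g2$called), NA_real_),
    p_allele = p_allele,
    p_genotype = p_geno,
    untestable_allele = unt_allele,
    untestable_genotype = unt_geno,
    stringsAsFactors = FALSE
  )
  finalize_results(df, groups, "variant", fdr_alpha)
}

#' Per-gene pooled association tests
#'
#' Pools per-variant allele and genotype tables within each gene that has at
#' least one surviving assigned variant, tests each pooled table with the
#' Fisher exact test, and applies BH separately within the gene-allele and
#' gene-genotype families. The BH family is the set of genes with testable
#' pooled tables, not the full panel.
#'
#' @inheritParams run_variant_level
#' @param assignment Variant-to-gene data frame (`key`, `gene`), typically
#'   from [apply_filter_cascade()].
#' @return Data frame with one row per tested gene (columns as in
#'   [run_variant_level()], `unit` = gene symbol, `n_variants` = pooled
#'   variant count).
#' @export
run_gene_level <- function(gm, assignment, groups, fdr_alpha = 0.05) {
  assignment <- assignment[assignment$key %in% gm$variants$key, ,
                           drop = FALSE]
  genes <- sort(unique(assignment$gene))
  rows <- lapply(genes, function(gene) {
    pt <- gene_pooled_tables(gm, gene, assignment, groups)
    fa <- fisher_exact(pt$allele)
    fg <- fisher_exact(pt$genotype)
    data.frame(
      unit = gene, level = "gene", n_variants = pt$n_variants,
      freq_group1 = pt$freq[1], freq_group2 = pt$freq[2],
      p_allele = fa$p.value, p_genotype = fg$p.value,
      untestable_allele = fa$degenerate, untestable_genotype = fg$degenerate,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(unit = character(), level = character(),
                     n_variants = integer(), freq_group1 = numeric(),
                     freq_group2 = numeric(), p_allele = numeric(),
                     p_genotype = numeric(), untestable_allele = logical(),
                     untestable_genotype = logical(),
                     stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  finalize_results(df, groups, "gene", fdr_alpha)
}
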