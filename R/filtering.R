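#' Restrict a genotype matrix to panel gene regions
#'
#' Keeps variants whose 1-based position falls inside at least one panel
#' interval and records the variant-to-gene assignment. Panel intervals are
#' 0-based half-open (BED), so a variant at 1-based position p is contained
#' in `[start, end)` iff `p - 1 \in [start, end)`, i.e. `start < p <= end`.
#' A variant overlapping several genes is kept once in the matrix but is
#' assigned to every overlapping gene.
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [gene_panel()].
#' @return A list with `matrix` (the restricted `genotype_matrix`),
#'   `assignment` (data frame `key`, `gene`; one row per variant-gene pair),
#'   and `excluded` (character vector of keys outside all panel intervals).
#' @export
filter_by_regions <- function(gm, panel) {
  if (n_variants(gm) == 0L) {
    return(list(matrix = gm,
                assignment = data.frame(key = character(),
                                        gene = character(),
                                        stringsAsFactors = FALSE),
                excluded = character(0)))
  }
  v_gr <- GenomicRanges::GRanges(
    seqnames = gm$variants$chrom,
    ranges = IRanges::IRanges(start = gm$variants$pos,
                              end = gm$variants$pos)
  )
  hits <- GenomicRanges::findOverlaps(v_gr, panel$gr)
  vi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  assignment <- unique(data.frame(
    key = gm$variants$key[vi],
    gene = S4Vectors::mcols(panel$gr)$gene[gi],
    stringsAsFactors = FALSE
  ))
  keep <- sort(unique(vi))
  excluded <- gm$variants$key[setdiff(seq_len(n_variants(gm)), keep)]
  list(matrix = subset_variants(gm, keep),
       assignment = assignment[order(assignment$gene, assignment$key), ,
                               drop = FALSE],
       excluded = excluded)
}

#' Remove group-exclusive variants
#'
#' Drops variants whose alternative allele is carried by samples of only one
#' of the two compared groups. Requiring at least one carrier in each group
#' protects the downstream tests from between-cohort allele-calling
#' artifacts. A missing genotype does not count as carrying the allele.
#'
#' @param gm A [genotype_matrix()].
#' @param groups Character vector of the two group labels to compare.
#' @return List with `matrix` (retained variants) and `excluded` (data frame
#'   `key`, `reason = "group-exclusive"`).
#' @export
shared_presence_filter <- function(gm, groups) {
  stopifnot(length(groups) == 2L)
  if (!all(groups %in% gm$groups)) {
    abort_usage(sprintf("group label not present in matrix: %s",
                        setdiff(groups, gm$groups)[1]))
  }
  present_in <- function(label) {
    cols <- gm$groups == label
    rowSums(gm$dosages[, cols, drop = FALSE] >= 1L, na.rm = TRUE) > 0L
  }
  keep <- present_in(groups[1]) & present_in(groups[2])
  excluded <- data.frame(
    key = gm$variants$key[!keep],
    reason = if (any(!keep)) "group-exclusive" else character(0),
    stringsAsFactors = FALSE
  )
  list(matrix = subset_variants(gm, which(keep)), excluded = excluded)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test for departure from Hardy-Weinberg
#' genotype proportions. Conditional on the observed allele counts, the
#' number of heterozygotes has a known distribution over all configurations
#' with the same parity; the p-value sums the probabilities of every
#' configuration no more probable than the observed one. This is robust at
#' the small sample sizes typical of exome cohorts, where the chi-squared
#' approximation is not.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (missing genotypes must
#'   be excluded upstream).
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_pvalue(5, 0, 5)   # strong heterozygote deficit
#' hwe_exact_pvalue(25, 50, 25) # perfect HWE proportions
#' @export
hwe_exact_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) {
    abort_data("genotype counts must be non-negative")
  }
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) abort_data("at least one called genotype required")
  na <- min(2L * n_hom_ref + n_het, 2L * n_hom_alt + n_het) # minor alleles
  if (na == 0L) return(1)
  h <- seq.int(na %% 2L, na, by = 2L)
  # log P(het = h | n, na) up to a constant; hom-minor = (na-h)/2
  logp <- h * log(2) - lfactorial(h) - lfactorial((na - h) / 2) -
    lfactorial(n - (na + h) / 2)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, h)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Genotype counts per variant for a set of sample columns (NA dropped).
genotype_count_matrix <- function(gm, cols) {
  d <- gm$dosages[, cols, drop = FALSE]
  cbind(
    hom_ref = rowSums(d == 0L, na.rm = TRUE),
    het = rowSums(d == 1L, na.rm = TRUE),
    hom_alt = rowSums(d == 2L, na.rm = TRUE)
  )
}

#' Hardy-Weinberg filter
#'
#' Removes variants whose exact HWE p-value (computed on the configured
#' population, missing genotypes dropped per variant) falls below `alpha`.
#' Variants with no called genotypes in the population are retained with
#' p = 1 (nothing to test).
#'
#' @param gm A [genotype_matrix()].
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @param population Group labels forming the test population; default all
#'   groups in the matrix (combined case + control).
#' @return List with `matrix` (retained variants) and `excluded` (data frame
#'   `key`, `reason = "hwe"`, `p`).
#' @export
hwe_filter <- function(gm, alpha = 0.05, population = unique(gm$groups)) {
  if (!(alpha > 0 && alpha < 1)) abort_usage("alpha must be in (0, 1)")
  cols <- gm$groups %in% population
  if (!any(cols)) abort_usage("HWE population selects no samples")
  counts <- genotype_count_matrix(gm, cols)
  p <- vapply(seq_len(nrow(counts)), function(i) {
    if (sum(counts[i, ]) == 0L) return(1)
    hwe_exact_pvalue(counts[i, 1], counts[i, 2], counts[i, 3])
  }, numeric(1))
  keep <- p >= alpha
  excluded <- data.frame(
    key = gm$variants$key[!keep],
    reason = if (any(!keep)) "hwe" else character(0),
    p = p[!keep],
    stringsAsFactors = FALSE
  )
  list(matrix = subset_variants(gm, which(keep)), excluded = excluded,
       p = setNames(p, gm$variants$key))
}

#' Filter report ledger
#'
#' Stage-wise variant counts for the filtering cascade, satisfying
#' `n_final = n_after_shared - n_hwe_excluded` by construction.
#'
#' @param n_input,n_after_region,n_after_shared,n_hwe_excluded,n_final
#'   Stage counts.
#' @param excluded Data frame with columns `key`, `stage`, `reason` and
#'   optionally `p` for HWE exclusions.
#' @return Object of class `filter_report`.
#' @export
filter_report <- function(n_input, n_after_region, n_after_shared,
                          n_hwe_excluded, n_final, excluded) {
  stopifnot(n_final == n_after_shared - n_hwe_excluded,
            n_after_region <= n_input,
            n_after_shared <= n_after_region,
            n_final <= n_after_shared)
  structure(
    list(n_input = n_input, n_after_region = n_after_region,
         n_after_shared = n_after_shared, n_hwe_excluded = n_hwe_excluded,
         n_final = n_final, excluded = excluded),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "filter_report:\n",
    "  input variants:        %d\n",
    "  after region filter:   %d\n",
    "  after shared-presence: %d\n",
    "  HWE-excluded:          %d\n",
    "  final:                 %d\n"),
    x$n_input, x$n_after_region, x$n_after_shared,
    x$n_hwe_excluded, x$n_final))
  invisible(x)
}

#' Serialize a filter report to JSON
#'
#' @param report A [filter_report()].
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
filter_report_json <- function(report, path = NULL) {
  obj <- report[c("n_input", "n_after_region", "n_after_shared",
                  "n_hwe_excluded", "n_final")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Run the full filtering cascade
#'
#' Applies, in order: panel-region restriction, shared-presence filter,
#' and Hardy-Weinberg filter. The order is fixed; the report records
#' stage-wise counts.
#'
#' @param gm Joined cohort [genotype_matrix()].
#' @param panel A [gene_panel()].
#' @param groups The two group labels compared (case, control).
#' @param hwe_alpha HWE exclusion threshold; default 0.05.
#' @param hwe_population Groups forming the HWE test population; default
#'   all samples in `gm`.
#' @return List with `matrix` (final filtered matrix), `assignment`
#'   (variant-to-gene map restricted to surviving variants), and `report`
#'   (a [filter_report()]).
#' @export
apply_filter_cascade <- function(gm, panel, groups,
                                 hwe_alpha = 0.05,
                                 hwe_population = unique(gm$groups)) {
  reg <- filter_by_regions(gm, panel)
  shr <- shared_presence_filter(reg$matrix, groups)
  hwe <- hwe_filter(shr$matrix, alpha = hwe_alpha,
                    population = hwe_population)
  excluded <- rbind(
    data.frame(key = reg$excluded,
               stage = rep("region", length(reg$excluded)),
               reason = rep("outside-panel", length(reg$excluded)),
               p = rep(NA_real_, length(reg$excluded)),
               stringsAsFactors = FALSE),
    data.frame(key = shr$excluded$key,
               stage = rep("shared", nrow(shr$excluded)),
               reason = shr$excluded$reason,
               p = rep(NA_real_, nrow(shr$excluded)),
               stringsAsFactors = FALSE),
    data.frame(key = hwe$excluded$key,
               stage = rep("hwe", nrow(hwe$excluded)),
               reason = hwe$excluded$reason,
               p = hwe$excluded$p,
               stringsAsFactors = FALSE)
  )
  report <- filter_report(
    n_input = n_variants(gm),
    n_after_region = n_variants(reg$matrix),
    n_after_shared = n_variants(shr$matrix),
    n_hwe_excluded = nrow(hwe$excluded),
    n_final = n_variants(hwe$matrix),
    excluded = excluded
  )
  final_keys <- hwe$matrix$variants$key
  assignment <- reg$assignment[reg$assignment$key %in% final_keys, ,
                               drop = FALSE]
  rownames(assignment) <- NULL
  list(matrix = hwe$matrix, assignment = assignment, report = report)
}
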