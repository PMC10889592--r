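#' Build the replication set from discovery results
#'
#' Candidate genes are the discovery genes significant at the configured FDR
#' in the allele family, the genotype family, or either (default "either":
#' published gene lists carry genes significant in only one family).
#' Candidate variants are the surviving variants assigned to those genes;
#' `panel_present` keeps the candidates carried by at least one reference
#' panel individual (dosage >= 1; missing does not count).
#'
#' @param gene_results Data frame from [run_gene_level()].
#' @param assignment Variant-to-gene map (`key`, `gene`) restricted to
#'   surviving discovery variants.
#' @param gm_panel Reference-panel [genotype_matrix()].
#' @param fdr_alpha Candidate-gene FDR threshold; default 0.05.
#' @param rule `"either"`, `"allele"`, or `"genotype"`.
#' @return Object of class `replication_set`: list with `candidate_genes`,
#'   `candidate_variants` (keys), `panel_present` (keys), `fdr_alpha`,
#'   `rule`.
#' @export
build_replication_set <- function(gene_results, assignment, gm_panel,
                                  fdr_alpha = 0.05,
                                  rule = c("either", "allele", "genotype")) {
  rule <- match.arg(rule)
  sig_a <- !is.na(gene_results$q_allele) & gene_results$q_allele < fdr_alpha
  sig_g <- !is.na(gene_results$q_genotype) &
    gene_results$q_genotype < fdr_alpha
  sig <- switch(rule, either = sig_a | sig_g, allele = sig_a,
                genotype = sig_g)
  candidate_genes <- sort(gene_results$unit[sig])
  candidate_variants <- sort(unique(
    assignment$key[assignment$gene %in% candidate_genes]))
  present_keys <- character(0)
  if (length(candidate_variants) > 0 && n_variants(gm_panel) > 0) {
    in_panel <- intersect(candidate_variants, gm_panel$variants$key)
    if (length(in_panel) > 0) {
      d <- gm_panel$dosages[in_panel, , drop = FALSE]
      carried <- rowSums(d >= 1L, na.rm = TRUE) > 0L
      present_keys <- in_panel[carried]
    }
  }
  structure(
    list(candidate_genes = candidate_genes,
         candidate_variants = candidate_variants,
         panel_present = sort(present_keys),
         fdr_alpha = fdr_alpha, rule = rule),
    class = "replication_set"
  )
}

#' @export
print.replication_set <- function(x, ...) {
  cat(sprintf(
    "replication_set: %d candidate genes, %d candidate variants, %d present in panel\n",
    length(x$candidate_genes), length(x$candidate_variants),
    length(x$panel_present)))
  invisible(x)
}

#' Re-test candidate genes against the reference panel
#'
#' Runs the same pooled gene-level machinery as discovery, comparing the
#' case cohort against the reference panel over panel-present variants
#' only, with BH applied within the candidate-gene family. Genes losing
#' all their variants to panel absence are dropped (recorded in the
#' `dropped_genes` attribute).
#'
#' @param repl A [build_replication_set()] result.
#' @param gm_case Case cohort [genotype_matrix()] (must contain the
#'   candidate variants).
#' @param gm_panel Reference-panel [genotype_matrix()].
#' @param assignment Variant-to-gene map (`key`, `gene`).
#' @param fdr_alpha Replication FDR threshold; default 0.05.
#' @return Gene-level results data frame (as [run_gene_level()]) comparing
#'   case vs panel groups; empty data frame when nothing is testable.
#' @export
run_replication <- function(repl, gm_case, gm_panel, assignment,
                            fdr_alpha = 0.05) {
  case_label <- unique(gm_case$groups)
  panel_label <- unique(gm_panel$groups)
  if (length(case_label) != 1L || length(panel_label) != 1L) {
    abort_usage("case and panel matrices must each carry a single group")
  }
  keys <- repl$panel_present
  keys <- intersect(keys, gm_case$variants$key)
  asg <- assignment[assignment$key %in% keys &
                      assignment$gene %in% repl$candidate_genes, ,
                    drop = FALSE]
  empty <- run_gene_level(
    genotype_matrix(gm_case$variants[0, , drop = FALSE],
                    gm_case$dosages[0, , drop = FALSE],
                    sample_groups(gm_case)),
    assignment[0, , drop = FALSE],
    groups = c(case_label, panel_label), fdr_alpha = fdr_alpha)
  if (length(keys) == 0L || nrow(asg) == 0L) {
    attr(empty, "dropped_genes") <- repl$candidate_genes
    return(empty)
  }
  sub_case <- subset_variants(gm_case, keys)
  sub_panel <- subset_variants(gm_panel, keys)
  merged <- genotype_matrix(
    sub_case$variants[, c("chrom", "pos", "ref", "alt")],
    cbind(sub_case$dosages, sub_panel$dosages),
    c(sample_groups(sub_case), sample_groups(sub_panel))
  )
  res <- run_gene_level(merged, asg, groups = c(case_label, panel_label),
                        fdr_alpha = fdr_alpha)
  attr(res, "dropped_genes") <- setdiff(repl$candidate_genes,
                                        unique(asg$gene))
  res
}
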