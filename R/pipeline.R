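#' Pipeline configuration
#'
#' Collects paths and analysis knobs for an end-to-end run. Can be built
#' directly or loaded from a YAML file with [read_pipeline_config()]; the
#' resolved configuration is persisted as JSON next to the outputs so any
#' run can be reproduced.
#'
#' @param case_vcf,control_vcf Cohort VCF paths.
#' @param panel_bed Gene panel path (BED-like, 4 columns).
#' @param out_dir Output directory.
#' @param panel_vcf Optional reference-panel VCF for replication.
#' @param case_label,control_label,panel_label Group labels.
#' @param hwe_alpha HWE exclusion threshold.
#' @param hwe_population `"all"`, `"case"`, or `"control"`: samples the HWE
#'   test is computed on.
#' @param fdr_alpha FDR significance threshold for all three levels.
#' @param burden_mode,burden_bins,burden_edges,burden_scores Gene-set
#'   burden controls; see [run_gene_set_level()].
#' @param candidate_rule Rule selecting replication candidates; see
#'   [build_replication_set()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(case_vcf, control_vcf, panel_bed, out_dir,
                            panel_vcf = NULL,
                            case_label = "AFF", control_label = "OP",
                            panel_label = "REF",
                            hwe_alpha = 0.05, hwe_population = "all",
                            fdr_alpha = 0.05,
                            burden_mode = "carrier", burden_bins = 5,
                            burden_edges = NULL, burden_scores = NULL,
                            candidate_rule = "either") {
  if (!(hwe_alpha > 0 && hwe_alpha < 1) ||
      !(fdr_alpha > 0 && fdr_alpha < 1)) {
    abort_usage("alphas must lie in (0, 1)")
  }
  structure(
    list(case_vcf = case_vcf, control_vcf = control_vcf,
         panel_vcf = panel_vcf, panel_bed = panel_bed, out_dir = out_dir,
         case_label = case_label, control_label = control_label,
         panel_label = panel_label,
         hwe_alpha = hwe_alpha, hwe_population = hwe_population,
         fdr_alpha = fdr_alpha,
         burden_mode = burden_mode, burden_bins = burden_bins,
         burden_edges = burden_edges, burden_scores = burden_scores,
         candidate_rule = candidate_rule),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file with keys matching the `pipeline_config()`
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("config not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort_usage(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

resolved_config_json <- function(config, path) {
  obj <- unclass(config)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

hwe_population_groups <- function(config) {
  switch(config$hwe_population,
         all = c(config$case_label, config$control_label),
         case = config$case_label,
         control = config$control_label,
         abort_usage(sprintf("unknown hwe_population: %s",
                             config$hwe_population)))
}

discovery_artifacts <- c(
  "resolved_config.json", "filter_report.json", "excluded_variants.tsv",
  "variant_level.tsv", "gene_level.tsv", "gene_set_trend.json",
  "burden_bins.tsv", "summary.json", "replication.tsv"
)

write_burden_tsv <- function(gs, path) {
  bins <- gs$bins
  k <- ncol(bins$table)
  rows <- do.call(rbind, lapply(rownames(bins$table), function(g) {
    data.frame(
      group = g,
      bin = sprintf("[%g,%g%s", bins$edges[seq_len(k)],
                    bins$edges[-1], c(rep(")", k - 1), "]")),
      n_individuals = as.integer(bins$table[g, ]),
      pct_individuals = gs$percent_table[g, ],
      stringsAsFactors = FALSE
    )
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the discovery analysis
#'
#' Executes the full discovery pipeline in the published order: read both
#' cohort VCFs, full-join them, restrict to panel regions, remove
#' group-exclusive variants, apply the exact-HWE filter, then test at the
#' variant, gene, and gene-set levels. All tabular and JSON artifacts are
#' written under `config$out_dir`; stage counts are logged via `message()`.
#' Partial outputs are removed if a stage fails.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return List with `matrix` (final filtered matrix), `assignment`,
#'   `report` ([filter_report()]), `variant_results`, `gene_results`,
#'   `gene_set` (see [run_gene_set_level()]), and `config`.
#' @export
run_discovery <- function(config, quiet = FALSE) {
  for (p in c(config$case_vcf, config$control_vcf, config$panel_bed)) {
    if (!file.exists(p)) abort_usage(sprintf("input not found: %s", p))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  on_fail <- function() {
    unlink(file.path(config$out_dir, discovery_artifacts))
  }
  tryCatch({
    resolved_config_json(config, file.path(config$out_dir,
                                           "resolved_config.json"))
    gm_case <- read_cohort_vcf(config$case_vcf, config$case_label)
    gm_ctrl <- read_cohort_vcf(config$control_vcf, config$control_label)
    say("read %d case and %d control variants",
        n_variants(gm_case), n_variants(gm_ctrl))
    gm <- full_join_cohorts(list(gm_case, gm_ctrl))
    panel <- read_gene_panel(config$panel_bed)
    groups <- c(config$case_label, config$control_label)
    casc <- apply_filter_cascade(gm, panel, groups,
                                 hwe_alpha = config$hwe_alpha,
                                 hwe_population = hwe_population_groups(config))
    rpt <- casc$report
    say("filter ledger: %d joined -> %d in panel -> %d shared; %d HWE-excluded -> %d final",
        rpt$n_input, rpt$n_after_region, rpt$n_after_shared,
        rpt$n_hwe_excluded, rpt$n_final)
    filter_report_json(rpt, file.path(config$out_dir, "filter_report.json"))
    write.table(rpt$excluded,
                file.path(config$out_dir, "excluded_variants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    vres <- run_variant_level(casc$matrix, groups, config$fdr_alpha)
    gres <- run_gene_level(casc$matrix, casc$assignment, groups,
                           config$fdr_alpha)
    say("variant level: %d tested, %d FDR-significant (allele)",
        nrow(vres), sum(vres$significant_allele))
    say("gene level: %d genes tested, %d FDR-significant (either family)",
        nrow(gres), sum(gres$significant_allele | gres$significant_genotype))
    write_results_table(vres, file.path(config$out_dir, "variant_level.tsv"))
    write_results_table(gres, file.path(config$out_dir, "gene_level.tsv"))

    gs <- run_gene_set_level(casc$matrix, groups,
                             mode = config$burden_mode,
                             edges = config$burden_edges,
                             n_bins = config$burden_bins,
                             scores = config$burden_scores)
    say("gene set: chi2 trend = %.4g, p = %.4g",
        gs$trend$chi2, gs$trend$p.value)
    writeLines(jsonlite::toJSON(
      list(chi2 = gs$trend$chi2, df = gs$trend$df, p = gs$trend$p.value,
           edges = gs$trend$edges, mode = config$burden_mode,
           wilcoxon_p = gs$wilcoxon_p),
      auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(config$out_dir, "gene_set_trend.json"))
    write_burden_tsv(gs, file.path(config$out_dir, "burden_bins.tsv"))

    list(matrix = casc$matrix, assignment = casc$assignment, report = rpt,
         variant_results = vres, gene_results = gres, gene_set = gs,
         config = config)
  }, error = function(e) {
    on_fail()
    stop(e)
  })
}

#' Run discovery plus reference-panel replication
#'
#' After [run_discovery()], reads the reference-panel VCF, builds the
#' candidate replication set from the gene-level discovery results, and
#' re-tests the candidate genes against the panel over panel-present
#' variants. Writes `replication.tsv` and a `summary.json` listing
#' discovery- and replication-significant genes.
#'
#' @inheritParams run_discovery
#' @return The [run_discovery()] list, extended with `replication_set`,
#'   `replication_results`, and `summary`.
#' @export
run_full <- function(config, quiet = FALSE) {
  if (is.null(config$panel_vcf)) {
    abort_usage("run_full requires a panel_vcf in the configuration")
  }
  if (!file.exists(config$panel_vcf)) {
    abort_usage(sprintf("input not found: %s", config$panel_vcf))
  }
  disc <- run_discovery(config, quiet = quiet)
  say <- function(...) if (!quiet) message(sprintf(...))
  gm_panel <- read_cohort_vcf(config$panel_vcf, config$panel_label)
  repl <- build_replication_set(disc$gene_results, disc$assignment,
                                gm_panel, fdr_alpha = config$fdr_alpha,
                                rule = config$candidate_rule)
  say("replication: %d candidate genes, %d/%d candidate variants present in panel",
      length(repl$candidate_genes), length(repl$panel_present),
      length(repl$candidate_variants))
  gm_case <- subset_samples(
    disc$matrix, colnames(disc$matrix$dosages)[
      disc$matrix$groups == config$case_label])
  rres <- run_replication(repl, gm_case, gm_panel, disc$assignment,
                          fdr_alpha = config$fdr_alpha)
  write_results_table(rres, file.path(config$out_dir, "replication.tsv"))
  disc_sig <- disc$gene_results$unit[disc$gene_results$significant_allele |
                                       disc$gene_results$significant_genotype]
  repl_sig <- rres$unit[rres$significant_allele | rres$significant_genotype]
  summary <- list(
    n_final_variants = disc$report$n_final,
    discovery_significant_genes = disc_sig,
    candidate_genes = repl$candidate_genes,
    n_candidate_variants = length(repl$candidate_variants),
    n_panel_present = length(repl$panel_present),
    replication_significant_genes = repl_sig,
    fdr_alpha = config$fdr_alpha,
    gene_family_sizes = as.list(attr(disc$gene_results, "family_sizes"))
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(config$out_dir, "summary.json"))
  say("replicated genes: %s",
      if (length(repl_sig)) paste(repl_sig, collapse = ", ") else "none")
  c(disc, list(replication_set = repl, replication_results = rres,
               summary = summary))
}
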