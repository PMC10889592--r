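#' Published gene-level effect profile
#'
#' The per-group pooled alternative-allele frequencies and variant counts
#' reported for the twelve genes that reached gene-level significance in
#' the motivating AFF study (control = osteoporotic cohort). The default
#' simulation uses these as the data-generating frequencies for those
#' genes, so a default run emulates a cohort with the published structure.
#'
#' @return Data frame with columns `gene`, `n_variants`, `control_freq`,
#'   `case_freq`.
#' @export
aff_effect_profile <- function() {
  data.frame(
    gene = c("ACAN", "AKAP13", "APC", "ARHGEF3", "CYP2D6", "NBN",
             "NOTCH2", "P4HB", "PITX2", "SPP1", "SUCO", "UGT1A8"),
    n_variants = c(16L, 21L, 7L, 6L, 10L, 3L, 7L, 3L, 2L, 3L, 5L, 37L),
    control_freq = c(0.47, 0.41, 0.61, 0.29, 0.20, 0.20,
                     0.23, 0.19, 0.08, 0.37, 0.23, 0.27),
    case_freq = c(0.59, 0.34, 0.68, 0.37, 0.27, 0.44,
                  0.32, 0.26, 0.35, 0.44, 0.42, 0.27),
    stringsAsFactors = FALSE
  )
}

#' Default simulated gene table
#'
#' Loads the shipped synthetic 457-gene bone-panel fixture and assigns
#' per-gene variant counts: 3 variants per gene (so the shared-variant
#' count lands near the scale of a real panel-restricted exome cohort),
#' except the published effect genes, which get their reported counts.
#'
#' @return Data frame `gene`, `chrom`, `start`, `end`, `n_variants`.
#' @export
default_gene_table <- function() {
  bed <- system.file("extdata", "bone_panel_457_synthetic.bed",
                     package = "affburden", mustWork = TRUE)
  panel <- read_gene_panel(bed)
  iv <- panel$intervals
  # one interval per gene in the shipped fixture
  iv <- iv[!duplicated(iv$gene), , drop = FALSE]
  prof <- aff_effect_profile()
  nv <- rep(3L, nrow(iv))
  m <- match(iv$gene, prof$gene)
  nv[!is.na(m)] <- prof$n_variants[m[!is.na(m)]]
  data.frame(gene = iv$gene, chrom = iv$chrom, start = iv$start,
             end = iv$end, n_variants = nv, stringsAsFactors = FALSE)
}

#' Auto-generated gene table for scenario configs
#'
#' Lays out `n_genes` non-overlapping synthetic genes along chromosome 1.
#'
#' @param n_genes Number of genes.
#' @param variants_per_gene Variants simulated per gene.
#' @param width Gene interval width in bp.
#' @return Data frame `gene`, `chrom`, `start`, `end`, `n_variants`.
#' @export
sim_gene_table <- function(n_genes, variants_per_gene, width = 20000L) {
  start <- 1000000L + (seq_len(n_genes) - 1L) * (width + 10000L)
  data.frame(
    gene = sprintf("SIMG%03d", seq_len(n_genes)),
    chrom = "1",
    start = start,
    end = start + width,
    n_variants = variants_per_gene,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines a seeded synthetic study: two exome cohorts and a reference
#' panel genotyped over a gene panel, with configurable effect genes,
#' Hardy-Weinberg-violating variants, group-exclusive variants, missing
#' genotypes, and a global case burden inflation. Defaults emulate the
#' motivating study's conditions: 13 cases vs 27 controls, a 107-sample
#' reference panel, the 457-gene bone panel with ~3 variants per gene,
#' 176 HWE-distorted variants, and the published 12-gene effect profile.
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_case,n_control,n_panel Cohort sizes.
#' @param genes Gene table (`gene`, `chrom`, `start`, `end`,
#'   `n_variants`); default [default_gene_table()].
#' @param base_freq_range Range of the uniform law for per-variant base
#'   alternative-allele frequencies.
#' @param gene_base_freq Named numeric: fixed base (control) frequency for
#'   all variants of the named genes, overriding the uniform draw.
#' @param effect_genes Named numeric: absolute case-group alternative-allele
#'   frequency for the named genes (must lie in (0, 1)).
#' @param n_hwe_violators Number of variants drawn from an
#'   inbreeding-distorted genotype law (in all groups).
#' @param hwe_inbreeding_f Inbreeding coefficient F of the distorted law:
#'   hom-ref `(1-f)^2 + F f (1-f)`, het `2 f (1-f) (1-F)`, hom-alt
#'   `f^2 + F f (1-f)`. F = 0 recovers HWE.
#' @param n_group_exclusive Length-2 integer (case, control): number of
#'   extra variants carried only in that cohort.
#' @param missing_rate Per-call missing-genotype probability in the two
#'   cohorts (the reference panel is emitted complete).
#' @param burden_shift Multiplier on the case-group allele frequency of all
#'   non-effect-gene variants (clipped to (0.001, 0.999)); values > 1
#'   inflate the case carrier burden across the whole gene set.
#' @param n_panel_absent Number of otherwise-null variants forced absent
#'   from the reference panel (frequency 0 there).
#' @param group_labels Named character: labels for case, control, panel.
#' @param ensure_shared If `TRUE`, guarantee at least one called carrier of
#'   every non-exclusive variant in each cohort (and of every exclusive
#'   variant in its own cohort) so the simulator's truth table matches the
#'   shared-presence filter exactly.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_case = 13L, n_control = 27L, n_panel = 107L,
                       genes = default_gene_table(),
                       base_freq_range = c(0.05, 0.5),
                       gene_base_freq = setNames(
                         aff_effect_profile()$control_freq,
                         aff_effect_profile()$gene),
                       effect_genes = setNames(
                         aff_effect_profile()$case_freq,
                         aff_effect_profile()$gene),
                       n_hwe_violators = 176L,
                       hwe_inbreeding_f = 0.6,
                       n_group_exclusive = c(50L, 50L),
                       missing_rate = 0.02,
                       burden_shift = 1.06,
                       n_panel_absent = 25L,
                       group_labels = c(case = "AFF", control = "OP",
                                        panel = "REF"),
                       ensure_shared = TRUE) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "chrom", "start", "end", "n_variants") %in%
                  names(genes)))
  if (n_case < 1 || n_control < 1 || n_panel < 0) {
    abort_usage("cohort sizes must be positive (panel may be 0)")
  }
  if (length(n_group_exclusive) == 1L) {
    n_group_exclusive <- rep(n_group_exclusive, 2L)
  }
  if (length(effect_genes) > 0) {
    if (is.null(names(effect_genes)) ||
        !all(names(effect_genes) %in% genes$gene)) {
      abort_usage("effect_genes must be named after panel genes")
    }
    if (any(effect_genes <= 0 | effect_genes >= 1)) {
      abort_usage("effect-gene case frequencies must lie in (0, 1)")
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort_usage("missing_rate must lie in [0, 1)")
  }
  if (burden_shift <= 0) abort_usage("burden_shift must be positive")
  if (hwe_inbreeding_f < 0 || hwe_inbreeding_f > 1) {
    abort_usage("hwe_inbreeding_f must lie in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), n_case = as.integer(n_case),
         n_control = as.integer(n_control), n_panel = as.integer(n_panel),
         genes = genes, base_freq_range = base_freq_range,
         gene_base_freq = gene_base_freq, effect_genes = effect_genes,
         n_hwe_violators = as.integer(n_hwe_violators),
         hwe_inbreeding_f = hwe_inbreeding_f,
         n_group_exclusive = as.integer(n_group_exclusive),
         missing_rate = missing_rate, burden_shift = burden_shift,
         n_panel_absent = as.integer(n_panel_absent),
         group_labels = group_labels, ensure_shared = ensure_shared),
    class = "sim_config"
  )
}

clip_freq <- function(f) pmin(pmax(f, 0.001), 0.999)

# Draw an nv x ns dosage matrix: HWE rows are binomial(2, f); distorted
# rows use the inbreeding-parameterized genotype law.
draw_dosages <- function(nv, ns, f, distorted, inbreeding_f) {
  if (nv == 0L) return(matrix(integer(), 0, ns))
  d <- matrix(rbinom(nv * ns, 2L, rep(f, ns)), nrow = nv)
  if (any(distorted) && inbreeding_f > 0) {
    rows <- which(distorted)
    fd <- f[rows]
    p0 <- (1 - fd)^2 + inbreeding_f * fd * (1 - fd)
    p1 <- 2 * fd * (1 - fd) * (1 - inbreeding_f)
    u <- matrix(runif(length(rows) * ns), nrow = length(rows))
    d[rows, ] <- (u >= p0) + (u >= p0 + p1)
  }
  storage.mode(d) <- "integer"
  d
}

force_carrier <- function(d, rows) {
  # guarantee >= 1 called carrier in each listed row of dosage matrix d
  for (i in rows) {
    x <- d[i, ]
    if (any(!is.na(x) & x >= 1L)) next
    j <- which(!is.na(x))
    if (length(j) == 0L) j <- seq_along(x)
    d[i, sample(j, 1L)] <- 1L
  }
  d
}

#' Simulate case, control and panel genotype matrices
#'
#' Draws the full synthetic study in memory: variant placement within gene
#' intervals, per-variant group frequencies (base, effect-gene, burden
#' shift), HWE-distorted and group-exclusive variants, missingness, and
#' ground-truth labels. Cohort matrices contain only variants with at
#' least one called carrier in that cohort (the cohort's "call set"), so
#' joining them exercises the homozygous-reference imputation of
#' [full_join_cohorts()].
#'
#' @param config A [sim_config()].
#' @return List with `case`, `control`, `panel` ([genotype_matrix()]
#'   objects), `panel_genes` (a [gene_panel()]), and `truth` (class
#'   `simulation_truth`: effect-gene labels, HWE-violator /
#'   group-exclusive / panel-absent keys, and realized per-group
#'   frequencies recounted from the emitted matrices).
#' @export
simulate_matrices <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- config$genes
  labels <- config$group_labels

  place_variants <- function(gene_rows, counts) {
    pieces <- lapply(seq_along(gene_rows), function(k) {
      g <- genes[gene_rows[k], ]
      n <- counts[k]
      span <- g$end - g$start
      if (n > span) abort_usage(sprintf("gene %s too short for %d variants",
                                        g$gene, n))
      pos <- g$start + sort(sample.int(span, n))
      bases <- c("A", "C", "G", "T")
      alt_of <- matrix(c("C", "G", "T", "A", "G", "T",
                         "A", "C", "T", "A", "C", "G"),
                       nrow = 4, byrow = TRUE)
      ref_i <- sample.int(4L, n, replace = TRUE)
      ref <- bases[ref_i]
      alt <- alt_of[cbind(ref_i, sample.int(3L, n, replace = TRUE))]
      data.frame(gene = g$gene, chrom = g$chrom, pos = pos,
                 ref = ref, alt = alt, stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  }

  shared <- place_variants(seq_len(nrow(genes)), genes$n_variants)
  shared$type <- "null"
  shared$type[shared$gene %in% names(config$effect_genes)] <- "effect"

  n_excl <- config$n_group_exclusive
  excl <- NULL
  if (sum(n_excl) > 0) {
    gene_rows <- sample.int(nrow(genes), sum(n_excl), replace = TRUE)
    excl <- place_variants(gene_rows, rep(1L, sum(n_excl)))
    excl$type <- rep(c("excl_case", "excl_control"), n_excl)
  }
  vt <- rbind(shared, excl)
  vt <- vt[!duplicated(variant_key(vt$chrom, vt$pos, vt$ref, vt$alt)), ,
           drop = FALSE]
  vt$key <- variant_key(vt$chrom, vt$pos, vt$ref, vt$alt)

  # base (control-side) frequency
  vt$f_base <- runif(nrow(vt), config$base_freq_range[1],
                     config$base_freq_range[2])
  if (length(config$gene_base_freq) > 0) {
    m <- match(vt$gene, names(config$gene_base_freq))
    vt$f_base[!is.na(m)] <- config$gene_base_freq[m[!is.na(m)]]
  }

  # HWE violators: sampled among plain null shared variants
  null_idx <- which(vt$type == "null")
  n_viol <- min(config$n_hwe_violators, length(null_idx))
  viol_idx <- if (n_viol > 0) sort(sample(null_idx, n_viol)) else integer(0)
  vt$hwe_violator <- seq_len(nrow(vt)) %in% viol_idx

  # panel-absent variants: among remaining plain nulls
  rest <- setdiff(null_idx, viol_idx)
  n_absent <- min(config$n_panel_absent, length(rest))
  absent_idx <- if (n_absent > 0) sort(sample(rest, n_absent)) else integer(0)
  vt$panel_absent <- seq_len(nrow(vt)) %in% absent_idx

  # group frequencies
  vt$f_control <- vt$f_base
  vt$f_case <- clip_freq(vt$f_base * config$burden_shift)
  eff <- vt$type == "effect"
  vt$f_case[eff] <- config$effect_genes[vt$gene[eff]]
  vt$f_panel <- vt$f_control
  vt$f_control[vt$type == "excl_case"] <- 0
  vt$f_case[vt$type == "excl_control"] <- 0
  vt$f_panel[vt$panel_absent] <- 0

  nv <- nrow(vt)
  d_case <- draw_dosages(nv, config$n_case, vt$f_case, vt$hwe_violator,
                         config$hwe_inbreeding_f)
  d_ctrl <- draw_dosages(nv, config$n_control, vt$f_control,
                         vt$hwe_violator, config$hwe_inbreeding_f)
  d_panel <- draw_dosages(nv, config$n_panel, vt$f_panel, vt$hwe_violator,
                          config$hwe_inbreeding_f)

  # exclusive variants carry no alt allele outside their cohort
  d_case[vt$f_case == 0, ] <- 0L
  d_ctrl[vt$f_control == 0, ] <- 0L
  d_panel[vt$f_panel == 0, ] <- 0L

  if (config$missing_rate > 0) {
    d_case[matrix(runif(length(d_case)) < config$missing_rate,
                  nrow = nv)] <- NA_integer_
    d_ctrl[matrix(runif(length(d_ctrl)) < config$missing_rate,
                  nrow = nv)] <- NA_integer_
  }

  if (config$ensure_shared) {
    shared_rows <- which(vt$type %in% c("null", "effect"))
    d_case <- force_carrier(d_case, shared_rows)
    d_ctrl <- force_carrier(d_ctrl, shared_rows)
    d_case <- force_carrier(d_case, which(vt$type == "excl_case"))
    d_ctrl <- force_carrier(d_ctrl, which(vt$type == "excl_control"))
  }

  sample_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  mk <- function(d, prefix, n, label) {
    ids <- sample_ids(prefix, n)
    colnames(d) <- ids
    carried <- rowSums(d >= 1L, na.rm = TRUE) > 0L
    gm <- genotype_matrix(vt[carried, c("chrom", "pos", "ref", "alt")],
                          d[carried, , drop = FALSE],
                          setNames(rep(label, n), ids))
    ord <- variant_order(gm$variants)
    subset_variants(gm, ord)
  }
  gm_case <- mk(d_case, "CASE", config$n_case, labels[["case"]])
  gm_ctrl <- mk(d_ctrl, "CTRL", config$n_control, labels[["control"]])
  gm_panel <- mk(d_panel, "PANEL", config$n_panel, labels[["panel"]])

  realized <- function(d) {
    called <- rowSums(!is.na(d))
    alt <- rowSums(d, na.rm = TRUE)
    ifelse(called > 0, alt / (2 * called), NA_real_)
  }
  truth <- structure(
    list(
      effect_gene_labels = setNames(genes$gene %in%
                                      names(config$effect_genes),
                                    genes$gene),
      hwe_violator_keys = vt$key[vt$hwe_violator],
      group_exclusive_keys = list(
        case = vt$key[vt$type == "excl_case"],
        control = vt$key[vt$type == "excl_control"]
      ),
      panel_absent_keys = vt$key[vt$panel_absent],
      generating_freqs = data.frame(
        key = vt$key, gene = vt$gene, type = vt$type, f_base = vt$f_base,
        f_case = vt$f_case, f_control = vt$f_control, f_panel = vt$f_panel,
        stringsAsFactors = FALSE
      ),
      realized_freqs = data.frame(
        key = vt$key, gene = vt$gene, type = vt$type,
        f_case = realized(d_case), f_control = realized(d_ctrl),
        f_panel = realized(d_panel), stringsAsFactors = FALSE
      ),
      alt_counts = data.frame(
        key = vt$key,
        case = rowSums(d_case, na.rm = TRUE),
        control = rowSums(d_ctrl, na.rm = TRUE),
        panel = rowSums(d_panel, na.rm = TRUE),
        stringsAsFactors = FALSE
      )
    ),
    class = "simulation_truth"
  )
  panel_bed <- genes[, c("chrom", "start", "end", "gene")]
  list(case = gm_case, control = gm_ctrl, panel = gm_panel,
       panel_genes = gene_panel(panel_bed), truth = truth,
       config = config)
}

#' Write a genotype matrix as a VCF 4.2 file
#'
#' Emits a minimal standards-conformant VCF with contig headers and GT-only
#' genotype fields. No timestamps are written, so output is byte-identical
#' for identical input.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param phased If `TRUE`, genotypes use the `|` separator (heterozygotes
#'   as `0|1`), as in reference-panel releases.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path, phased = FALSE) {
  sep <- if (phased) "|" else "/"
  gt_code <- c(paste0("0", sep, "0"), paste0("0", sep, "1"),
               paste0("1", sep, "1"))
  chroms <- unique(gm$variants$chrom)
  chroms <- chroms[order(chrom_rank(chroms))]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=affburden-simulator",
    sprintf("##contig=<ID=%s,length=%d>", chroms, CHROM_LENGTHS[chroms]),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gm$dosages)), collapse = "\t")
  )
  body <- character(0)
  if (n_variants(gm) > 0) {
    gts <- matrix(gt_code[gm$dosages + 1L], nrow = n_variants(gm))
    gts[is.na(gm$dosages)] <- "./."
    body <- paste(gm$variants$chrom, gm$variants$pos, ".",
                  gm$variants$ref, gm$variants$alt, ".", "PASS", ".", "GT",
                  apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a study and write its files
#'
#' Runs [simulate_matrices()] and writes `case.vcf`, `control.vcf`,
#' `panel.vcf` (phased), `panel.bed` (the gene panel, BED 0-based
#' half-open) and `truth.json` into `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (named file paths) and `truth`.
#' @export
simulate_cohorts <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_matrices(config)
  paths <- list(
    case_vcf = file.path(dir, "case.vcf"),
    control_vcf = file.path(dir, "control.vcf"),
    panel_vcf = file.path(dir, "panel.vcf"),
    panel_bed = file.path(dir, "panel.bed"),
    truth_json = file.path(dir, "truth.json")
  )
  write_vcf(sim$case, paths$case_vcf, phased = FALSE)
  write_vcf(sim$control, paths$control_vcf, phased = FALSE)
  write_vcf(sim$panel, paths$panel_vcf, phased = TRUE)
  bed <- config$genes[, c("chrom", "start", "end", "gene")]
  write.table(bed, paths$panel_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  truth_out <- sim$truth
  class(truth_out) <- NULL
  writeLines(jsonlite::toJSON(truth_out, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             paths$truth_json)
  list(paths = paths, truth = sim$truth)
}

#' Canned null-scenario configurations
#'
#' Replicated configurations with no effect genes, no burden shift, no HWE
#' distortion and no injected exclusives, used for type-I-error and
#' null-distribution checks. Replicate seeds are distinct and derived from
#' `seed`.
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed.
#' @param n_case,n_control Cohort sizes (defaults match the motivating
#'   study's 13 vs 27).
#' @param n_genes,variants_per_gene Panel shape.
#' @param ... Further overrides passed to [sim_config()].
#' @return List of `sim_config` objects.
#' @export
make_null_scenario <- function(n_reps, seed = 1L, n_case = 13L,
                               n_control = 27L, n_genes = 50L,
                               variants_per_gene = 40L, ...) {
  base <- (abs(seed) %% 1000000L)
  lapply(seq_len(n_reps), function(i) {
    sim_config(
      seed = base * 1000L + i,
      n_case = n_case, n_control = n_control, n_panel = 0L,
      genes = sim_gene_table(n_genes, variants_per_gene),
      gene_base_freq = setNames(numeric(0), character(0)),
      effect_genes = setNames(numeric(0), character(0)),
      n_hwe_violators = 0L, n_group_exclusive = c(0L, 0L),
      missing_rate = 0, burden_shift = 1, n_panel_absent = 0L,
      ensure_shared = FALSE, ...
    )
  })
}

#' Canned power-scenario configurations
#'
#' Replicated configurations with injected gene effects (and optionally a
#' case burden shift), used for recovery and trend-power checks. A shift
#' of `case_freq == control_freq` with `burden_shift = 1` degenerates to
#' the null scenario.
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed.
#' @param n_case,n_control Cohort sizes.
#' @param n_genes,variants_per_gene Panel shape.
#' @param n_effect_genes Number of genes given the case-frequency shift.
#' @param control_freq,case_freq Data-generating frequencies for effect
#'   genes (control-side frequency also fixes the effect genes' base
#'   frequency, so power is attributable to the injected shift alone).
#' @param burden_shift Case-frequency multiplier on all other variants.
#' @param n_panel Reference-panel size (0 to skip panel simulation).
#' @param ... Further overrides passed to [sim_config()].
#' @return List of `sim_config` objects.
#' @export
make_power_scenario <- function(n_reps, seed = 1L, n_case = 200L,
                                n_control = 200L, n_genes = 20L,
                                variants_per_gene = 5L,
                                n_effect_genes = 2L,
                                control_freq = 0.2, case_freq = 0.4,
                                burden_shift = 1, n_panel = 0L, ...) {
  genes <- sim_gene_table(n_genes, variants_per_gene)
  eff_names <- genes$gene[seq_len(n_effect_genes)]
  base <- (abs(seed) %% 1000000L)
  lapply(seq_len(n_reps), function(i) {
    sim_config(
      seed = base * 1000L + i,
      n_case = n_case, n_control = n_control, n_panel = n_panel,
      genes = genes,
      gene_base_freq = setNames(rep(control_freq, n_effect_genes),
                                eff_names),
      effect_genes = setNames(rep(case_freq, n_effect_genes), eff_names),
      n_hwe_violators = 0L, n_group_exclusive = c(0L, 0L),
      missing_rate = 0, burden_shift = burden_shift, n_panel_absent = 0L,
      ensure_shared = FALSE, ...
    )
  })
}
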