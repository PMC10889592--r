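#' Read a cohort VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (single- or multi-sample) and converts its GT fields
#' into an alternative-allele dosage matrix. Multi-allelic records are split
#' into one biallelic row per alternative allele, with per-sample dosage
#' counting only that allele. Genotypes containing any missing allele
#' (`./.`, `.`, or half-calls like `1/.`) become missing (`NA`). Phased
#' separators (`|`) are accepted and collapsed; the pipeline treats
#' genotypes as unphased. Chromosome names are normalized by stripping a
#' `"chr"` prefix; records on contigs other than 1-22, X, Y, MT are dropped
#' with a warning.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param group_label Group label assigned to every sample in this file.
#' @return A [genotype_matrix()] with variants sorted by
#'   (chrom, pos, ref, alt).
#' @export
read_cohort_vcf <- function(path, group_label) {
  if (!file.exists(path)) abort_usage(sprintf("VCF not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, "##fileformat=VCF")) {
    abort_format(sprintf(
      "parse error in %s at line 1: missing ##fileformat=VCF header", path))
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort_format(sprintf("parse error in %s: %s",
                                             path, conditionMessage(e)))
  )
  gt_part <- vcf@gt
  if (is.null(gt_part) || ncol(gt_part) < 2L) {
    abort_data(sprintf("no sample genotype columns in %s", path))
  }
  samples <- colnames(gt_part)[-1L]
  groups <- setNames(rep(group_label, length(samples)), samples)

  if (nrow(vcf@fix) == 0L) {
    return(genotype_matrix(
      data.frame(chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      matrix(integer(), nrow = 0, ncol = length(samples),
             dimnames = list(NULL, samples)),
      groups
    ))
  }
  if (any(!grepl("(^|:)GT(:|$)", gt_part[, "FORMAT"]))) {
    abort_data(sprintf("record without GT format field in %s", path))
  }

  chrom <- normalize_chrom(vcf@fix[, "CHROM"])
  keep <- chrom %in% CHROM_LEVELS
  if (!all(keep)) {
    warning(sprintf("dropping %d record(s) on unsupported contig(s): %s",
                    sum(!keep),
                    paste(unique(chrom[!keep]), collapse = ", ")))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = length(samples),
                                     dimnames = list(NULL, samples))
  chrom <- chrom[keep]
  pos <- as.integer(vcf@fix[keep, "POS"])
  ref <- toupper(vcf@fix[keep, "REF"])
  alt_field <- toupper(vcf@fix[keep, "ALT"])
  gt <- gt[keep, , drop = FALSE]

  # Decode each distinct GT string once: allele index pairs, NA if any "."
  decode_gt <- function(strings) {
    u <- unique(strings[!is.na(strings)])
    parsed <- lapply(strsplit(u, "[/|]"), function(a) {
      if (any(a == ".")) return(NULL)
      suppressWarnings(as.integer(a))
    })
    names(parsed) <- u
    parsed
  }
  codebook <- decode_gt(as.vector(gt))

  out_chrom <- character(); out_pos <- integer()
  out_ref <- character(); out_alt <- character()
  rows <- list()
  for (i in seq_along(pos)) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    alleles_by_sample <- codebook[gt[i, ]]
    for (k in seq_along(alts)) {
      if (alts[k] %in% c(".", "*")) next
      dos <- vapply(seq_along(samples), function(j) {
        a <- alleles_by_sample[[j]]
        if (is.null(a) || anyNA(a)) return(MISSING_GT)
        sum(a == k)
      }, integer(1))
      out_chrom <- c(out_chrom, chrom[i]); out_pos <- c(out_pos, pos[i])
      out_ref <- c(out_ref, ref[i]); out_alt <- c(out_alt, alts[k])
      rows[[length(rows) + 1L]] <- dos
    }
  }
  dos_mat <- if (length(rows)) do.call(rbind, rows) else
    matrix(integer(), nrow = 0, ncol = length(samples))
  colnames(dos_mat) <- samples
  variants <- data.frame(chrom = out_chrom, pos = out_pos,
                         ref = out_ref, alt = out_alt,
                         stringsAsFactors = FALSE)
  ord <- variant_order(variants)
  genotype_matrix(variants[ord, , drop = FALSE],
                  dos_mat[ord, , drop = FALSE], groups)
}

#' Read a BED-like gene panel file
#'
#' Expects a tab-separated file with columns chrom, start, end, gene in
#' BED convention (0-based, half-open intervals). Intervals of the same gene
#' that overlap or touch are merged.
#'
#' @param path Path to the panel file.
#' @return An object of class `gene_panel`: a list with `intervals`
#'   (data frame chrom/start/end/gene, 0-based half-open, merged) and
#'   `gr` (the same intervals as a 1-based `GRanges` with a `gene` column).
#' @export
read_gene_panel <- function(path) {
  if (!file.exists(path)) abort_usage(sprintf("panel file not found: %s", path))
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) abort_format(sprintf("cannot read panel file %s: %s",
                                             path, conditionMessage(e)))
  )
  if (ncol(df) < 4L) {
    abort_format("panel file needs 4 columns (chrom, start, end, gene); gene column missing")
  }
  df <- df[, 1:4]
  names(df) <- c("chrom", "start", "end", "gene")
  gene_panel(df)
}

#' @rdname read_gene_panel
#' @param intervals Data frame with columns `chrom`, `start`, `end`, `gene`
#'   (0-based half-open intervals).
#' @export
gene_panel <- function(intervals) {
  df <- intervals
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$gene <- as.character(df$gene)
  if (anyNA(df$start) || anyNA(df$end)) {
    abort_format("non-numeric interval bounds in panel")
  }
  bad <- df$start >= df$end | df$start < 0
  if (any(bad)) {
    abort_data(sprintf("invalid interval for gene %s: [%d, %d)",
                       df$gene[bad][1], df$start[bad][1], df$end[bad][1]))
  }
  keep <- df$chrom %in% CHROM_LEVELS
  if (!all(keep)) {
    warning(sprintf("dropping %d panel interval(s) on unsupported contig(s)",
                    sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) abort_data("empty gene panel")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    gene = df$gene
  )
  # Merge overlapping/adjacent intervals within each gene.
  by_gene <- GenomicRanges::split(gr, S4Vectors::mcols(gr)$gene)
  merged <- GenomicRanges::reduce(by_gene)
  flat <- unlist(merged, use.names = TRUE)
  S4Vectors::mcols(flat)$gene <- names(flat)
  names(flat) <- NULL
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1L,
    end = GenomicRanges::end(flat),
    gene = S4Vectors::mcols(flat)$gene,
    stringsAsFactors = FALSE
  )
  out <- out[order(chrom_rank(out$chrom), out$start, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(intervals = out, gr = flat), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel: %d genes, %d intervals\n",
              length(unique(x$intervals$gene)), nrow(x$intervals)))
  invisible(x)
}

#' @rdname read_gene_panel
#' @param panel A `gene_panel`.
#' @export
panel_genes <- function(panel) sort(unique(panel$intervals$gene))

#' Full join of cohort genotype matrices
#'
#' Merges cohorts called on the same capture into one matrix over the union
#' of variant keys. A variant absent from a cohort's call set is imputed as
#' homozygous reference (dosage 0) for that cohort's samples -- the
#' downstream shared-presence filter guards against the callability
#' artifacts this could otherwise hide.
#'
#' @param matrices List of [genotype_matrix()] objects with disjoint
#'   sample IDs.
#' @return A `genotype_matrix` over the union of variant keys, sorted by
#'   (chrom, pos, ref, alt).
#' @export
full_join_cohorts <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  all_samples <- unlist(lapply(matrices, function(m) colnames(m$dosages)))
  if (anyDuplicated(all_samples)) {
    abort_data(sprintf("duplicate sample ID across cohorts: %s",
                       all_samples[duplicated(all_samples)][1]))
  }
  var_union <- do.call(rbind, lapply(matrices, function(m)
    m$variants[, c("chrom", "pos", "ref", "alt", "key")]))
  var_union <- var_union[!duplicated(var_union$key), , drop = FALSE]
  var_union <- var_union[variant_order(var_union), , drop = FALSE]

  dos <- matrix(0L, nrow = nrow(var_union), ncol = length(all_samples),
                dimnames = list(var_union$key, all_samples))
  groups <- character(0)
  for (m in matrices) {
    idx <- match(m$variants$key, var_union$key)
    dos[idx, colnames(m$dosages)] <- m$dosages
    groups <- c(groups, sample_groups(m))
  }
  genotype_matrix(var_union[, c("chrom", "pos", "ref", "alt")], dos, groups)
}

#' Write an association results table
#'
#' Renders variant- or gene-level association results as a TSV mirroring the
#' published table layout: unit, number of variants, per-group pooled
#' alternative-allele frequency (integer percent), raw Fisher p-values and
#' BH q-values for the allele-level and genotype-level tests.
#'
#' @param results A results data frame from [run_variant_level()] or
#'   [run_gene_level()] (all rows must share one analysis level).
#' @param path Output file path.
#' @return Invisibly, the data frame as written.
#' @export
write_results_table <- function(results, path) {
  lv <- unique(results$level)
  if (length(lv) > 1L) abort_usage("results mix analysis levels")
  groups <- attr(results, "groups")
  if (is.null(groups)) groups <- c("group1", "group2")
  out <- data.frame(
    unit = results$unit,
    n_variants = as.integer(results$n_variants),
    stringsAsFactors = FALSE
  )
  out[[paste0("freq_pct_", groups[1])]] <- round(100 * results$freq_group1)
  out[[paste0("freq_pct_", groups[2])]] <- round(100 * results$freq_group2)
  fmt_p <- function(p) ifelse(is.na(p), "NA", sprintf("%.6g", p))
  out$p_allele <- fmt_p(results$p_allele)
  out$p_genotype <- fmt_p(results$p_genotype)
  out$q_allele <- fmt_p(results$q_allele)
  out$q_genotype <- fmt_p(results$q_genotype)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
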