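#' Genotype matrix container
#'
#' The pipeline's central data structure: a variants x samples matrix of
#' alternative-allele dosages (0, 1, 2, or `NA` for missing genotypes),
#' together with the variant keys and a group label per sample. Dosage is the
#' number of alternative alleles carried at a biallelic site; multi-allelic
#' records are split into biallelic rows upstream, so every row is identified
#' by a unique `chrom:pos:ref:alt` key.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per biallelic variant).
#' @param dosages Integer matrix, `nrow(variants)` rows by one column per
#'   sample, values in `{0, 1, 2, NA}`. Column names are sample IDs.
#' @param groups Named character vector mapping every sample ID to its group
#'   label (e.g. `"AFF"`, `"OP"`, `"REF"`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `variants` (data frame, including a `key` column), `dosages`
#'   (integer matrix with variant keys as row names), and `groups`.
#' @examples
#' v <- data.frame(chrom = "1", pos = 1000L, ref = "A", alt = "G")
#' d <- matrix(c(0L, 1L), nrow = 1, dimnames = list(NULL, c("s1", "s2")))
#' gm <- genotype_matrix(v, d, c(s1 = "AFF", s2 = "OP"))
#' n_variants(gm)
#' @export
genotype_matrix <- function(variants, dosages, groups) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  variants <- data.frame(
    chrom = as.character(variants$chrom),
    pos = as.integer(variants$pos),
    ref = toupper(as.character(variants$ref)),
    alt = toupper(as.character(variants$alt)),
    stringsAsFactors = FALSE
  )
  if (any(variants$pos < 1L)) abort_data("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) {
    abort_data("ref and alt alleles must differ")
  }
  variants$key <- variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt)
  if (anyDuplicated(variants$key)) {
    abort_data(sprintf("duplicate variant key: %s",
                       variants$key[duplicated(variants$key)][1]))
  }
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != nrow(variants)) {
    abort_data("dosage matrix rows must match number of variants")
  }
  samples <- colnames(dosages)
  if (is.null(samples) && ncol(dosages) > 0) {
    abort_data("dosage matrix must have sample IDs as column names")
  }
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) abort_data("dosages must be 0, 1, 2 or NA")
  if (!all(samples %in% names(groups))) {
    abort_data("every sample needs a group label")
  }
  groups <- groups[samples]
  rownames(dosages) <- variants$key
  structure(
    list(variants = variants, dosages = dosages,
         groups = as.character(setNames(groups, samples))),
    class = "genotype_matrix"
  )
}

#' @rdname genotype_matrix
#' @param gm A `genotype_matrix`.
#' @export
n_variants <- function(gm) nrow(gm$dosages)

#' @rdname genotype_matrix
#' @export
n_samples <- function(gm) ncol(gm$dosages)

#' @rdname genotype_matrix
#' @export
sample_groups <- function(gm) setNames(gm$groups, colnames(gm$dosages))

#' @export
print.genotype_matrix <- function(x, ...) {
  grp <- table(x$groups)
  cat(sprintf("genotype_matrix: %d variants x %d samples (%s)\n",
              n_variants(x), n_samples(x),
              paste(sprintf("%s=%d", names(grp), grp), collapse = ", ")))
  invisible(x)
}

#' Subset a genotype matrix by variants or samples
#'
#' @param gm A `genotype_matrix`.
#' @param keys Character vector of variant keys to keep (order preserved),
#'   or a logical/integer row index.
#' @return A `genotype_matrix` restricted to the selected rows.
#' @export
subset_variants <- function(gm, keys) {
  if (is.character(keys)) {
    idx <- match(keys, gm$variants$key)
    if (anyNA(idx)) abort_usage(sprintf("variant not in matrix: %s",
                                        keys[is.na(idx)][1]))
  } else {
    idx <- seq_len(n_variants(gm))[keys]
  }
  genotype_matrix(gm$variants[idx, , drop = FALSE],
                  gm$dosages[idx, , drop = FALSE],
                  sample_groups(gm))
}

#' @rdname subset_variants
#' @param samples Character vector of sample IDs to keep.
#' @export
subset_samples <- function(gm, samples) {
  if (!all(samples %in% colnames(gm$dosages))) {
    abort_usage("unknown sample ID in selection")
  }
  genotype_matrix(gm$variants,
                  gm$dosages[, samples, drop = FALSE],
                  sample_groups(gm)[samples])
}
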