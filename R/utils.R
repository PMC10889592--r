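#' @importFrom stats p.adjust pchisq rbinom runif setNames wilcox.test
#' @importFrom utils read.table write.table
NULL

# Accepted contigs, in canonical sort order.
CHROM_LEVELS <- c(as.character(1:22), "X", "Y", "MT")

# Approximate GRCh37 contig lengths, used only for VCF ##contig headers.
CHROM_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566,
  "MT" = 16569
)

MISSING_GT <- NA_integer_

condition_error <- function(class, msg) {
  stop(structure(
    class = c(class, "affburden_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_usage <- function(msg) condition_error("affburden_usage_error", msg)
abort_data <- function(msg) condition_error("affburden_data_error", msg)
abort_format <- function(msg) condition_error("affburden_format_error", msg)

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix and maps `"M"` to `"MT"`.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @keywords internal
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x[x == "M"] <- "MT"
  x
}

chrom_rank <- function(x) match(x, CHROM_LEVELS)

#' Build variant key strings
#'
#' A variant key is `chrom:pos:ref:alt`, unique within a genotype matrix.
#'
#' @param chrom,pos,ref,alt Vectors of the four key components.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Canonical variant ordering: (chrom rank, pos, ref, alt).
variant_order <- function(variants) {
  order(chrom_rank(variants$chrom), variants$pos, variants$ref, variants$alt)
}
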