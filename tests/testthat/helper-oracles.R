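# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately use different formulations from the package
# implementations (choose()/factorial() products and recurrences rather
# than dhyper()/lfactorial grids).

# Two-sided Fisher 2x2 by hypergeometric enumeration with choose().
oracle_fisher22 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  dens <- choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  pobs <- dens[a - lo + 1]
  min(1, sum(dens[dens <= pobs * (1 + 1e-7)]))
}

# Freeman-Halton 2x3 by full table enumeration with factorial products.
oracle_fisher23 <- function(tab) {
  r <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  stopifnot(N <= 170)
  const <- prod(factorial(r)) * prod(factorial(cs)) / factorial(N)
  prob_of <- function(m) const / prod(factorial(m))
  pobs <- prob_of(tab)
  total <- 0
  for (a11 in 0:min(r[1], cs[1])) {
    for (a12 in 0:min(r[1] - a11, cs[2])) {
      a13 <- r[1] - a11 - a12
      if (a13 > cs[3]) next
      m <- rbind(c(a11, a12, a13), cs - c(a11, a12, a13))
      pr <- prob_of(m)
      if (pr <= pobs * (1 + 1e-7)) total <- total + pr
    }
  }
  min(1, total)
}

# Exact HWE by the heterozygote-count recurrence (distinct route from the
# package's direct log-factorial formula).
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (na == 0) return(1)
  h0 <- na %% 2
  hs <- seq(h0, na, by = 2)
  vals <- numeric(length(hs))
  vals[1] <- 1
  if (length(hs) > 1) {
    for (k in 2:length(hs)) {
      h <- hs[k]
      hm_prev <- (na - (h - 2)) / 2          # hom-minor at h-2
      hM_prev <- n - (na + (h - 2)) / 2      # hom-major at h-2
      vals[k] <- vals[k - 1] * 4 * hm_prev * hM_prev / (h * (h - 1))
    }
  }
  probs <- vals / sum(vals)
  pobs <- probs[match(n_het, hs)]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Textbook BH step-up: q_(k) = min_{i >= k} p_(i) * m / i.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[k] <- min(ps[k:m] * m / (k:m))
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Brute-force per-sample tally of allele / genotype tables.
oracle_allele_table <- function(gm, key, groups) {
  i <- match(key, gm$variants$key)
  tab <- matrix(0L, 2, 2, dimnames = list(groups, c("ref", "alt")))
  for (g in 1:2) {
    for (s in which(gm$groups == groups[g])) {
      d <- gm$dosages[i, s]
      if (is.na(d)) next
      tab[g, "alt"] <- tab[g, "alt"] + d
      tab[g, "ref"] <- tab[g, "ref"] + (2L - d)
    }
  }
  tab
}

oracle_genotype_table <- function(gm, key, groups) {
  i <- match(key, gm$variants$key)
  tab <- matrix(0L, 2, 3,
                dimnames = list(groups, c("hom_ref", "het", "hom_alt")))
  for (g in 1:2) {
    for (s in which(gm$groups == groups[g])) {
      d <- gm$dosages[i, s]
      if (is.na(d)) next
      tab[g, d + 1L] <- tab[g, d + 1L] + 1L
    }
  }
  tab
}

# Minimal VCF writer for hand-built fixtures.
write_test_vcf <- function(path, samples, records,
                           contigs = c("1", "2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=249250621>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Small ready-made genotype matrix: 3 variants, 2 groups.
tiny_gm <- function() {
  v <- data.frame(chrom = c("1", "1", "2"), pos = c(100L, 200L, 50L),
                  ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  d <- rbind(c(1L, 2L, 0L, 0L, 1L),
             c(0L, 1L, NA, 1L, 0L),
             c(2L, 0L, 1L, NA, NA))
  colnames(d) <- paste0("s", 1:5)
  genotype_matrix(v, d, setNames(c("AFF", "AFF", "OP", "OP", "OP"),
                                 paste0("s", 1:5)))
}
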