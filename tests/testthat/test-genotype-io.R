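test_that("GT fields are decoded into dosages with missing handling", {
  p <- tempfile(fileext = ".vcf")
  write_test_vcf(p, c("sA", "sB", "sC"), c(
    vcf_record("1", 1000, "A", "G", c("0/1", "1/1", "./."))
  ))
  gm <- read_cohort_vcf(p, "AFF")
  expect_equal(n_variants(gm), 1L)
  expect_identical(unname(gm$dosages[1, ]), c(1L, 2L, NA))
  expect_identical(gm$variants$key, "1:1000:A:G")
  expect_true(all(gm$groups == "AFF"))
})

test_that("multi-allelic records split into biallelic rows conserving dosage", {
  p <- tempfile(fileext = ".vcf")
  write_test_vcf(p, c("sA", "sB", "sC"), c(
    vcf_record("1", 2000, "C", "T,G", c("1/2", "0|2", "1/.")),
    vcf_record("2", 10, "G", "A,T", c("2/2", "0/0", "1|1"))
  ))
  gm <- read_cohort_vcf(p, "AFF")
  expect_equal(n_variants(gm), 4L)
  expect_setequal(gm$variants$key,
                  c("1:2000:C:T", "1:2000:C:G", "2:10:G:A", "2:10:G:T"))
  d <- gm$dosages
  # 1/2: one T and one G allele; phased 0|2 collapses; half-call -> NA
  expect_identical(unname(d["1:2000:C:T", ]), c(1L, 0L, NA))
  expect_identical(unname(d["1:2000:C:G", ]), c(1L, 1L, NA))
  # per-sample alt totals conserved across the split rows
  orig_tot <- c(sA = 2L, sB = 1L, sC = NA)
  expect_identical(d["1:2000:C:T", "sC"] + d["1:2000:C:G", "sC"], NA_integer_)
  expect_identical(unname(d["1:2000:C:T", c("sA", "sB")] +
                            d["1:2000:C:G", c("sA", "sB")]), c(2L, 1L))
  expect_identical(unname(d["2:10:G:A", ] + d["2:10:G:T", ]),
                   c(2L, 0L, 2L))
})

test_that("header-only VCF yields an empty matrix with header samples", {
  p <- tempfile(fileext = ".vcf")
  write_test_vcf(p, c("x1", "x2"), character(0))
  gm <- read_cohort_vcf(p, "OP")
  expect_equal(n_variants(gm), 0L)
  expect_identical(colnames(gm$dosages), c("x1", "x2"))
})

test_that("malformed or GT-less VCFs raise informative errors", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "1\t2\t3"), p)
  expect_error(read_cohort_vcf(p, "AFF"), "line 1",
               class = "affburden_format_error")
  p2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tDP\t10"
  ), p2)
  expect_error(read_cohort_vcf(p2, "AFF"), "GT",
               class = "affburden_data_error")
})

test_that("unsupported contigs are dropped with a warning", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "GL000201.1\t5\t.\tC\tT\t.\tPASS\t.\tGT\t1/1"
  ), p)
  expect_warning(gm <- read_cohort_vcf(p, "AFF"), "contig")
  expect_identical(gm$variants$key, "1:100:A:G")  # chr prefix stripped
})

test_that("gene panel intervals are merged per gene and validated", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("1\t100\t200\tGENEA", "1\t150\t250\tGENEA",
               "2\t10\t90\tGENEB"), p)
  panel <- read_gene_panel(p)
  iv <- panel$intervals
  a <- iv[iv$gene == "GENEA", ]
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$start, a$end), c(100L, 250L))

  p2 <- tempfile(fileext = ".bed")
  writeLines("1\t200\t100\tG", p2)
  expect_error(read_gene_panel(p2), "invalid interval",
               class = "affburden_data_error")

  p3 <- tempfile(fileext = ".bed")
  writeLines("1\t100\t200", p3)
  expect_error(read_gene_panel(p3), "gene column",
               class = "affburden_format_error")
})

test_that("shipped synthetic bone panel has 457 genes", {
  bed <- system.file("extdata", "bone_panel_457_synthetic.bed",
                     package = "affburden")
  panel <- read_gene_panel(bed)
  expect_length(panel_genes(panel), 457L)
})

test_that("full join unions keys and imputes cohort-absent variants as 0", {
  vA <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G")
  vB <- data.frame(chrom = "1", pos = 200L, ref = "C", alt = "T")
  dA <- matrix(c(1L, 2L), 1, dimnames = list(NULL, c("a1", "a2")))
  dB <- matrix(c(1L), 1, dimnames = list(NULL, "b1"))
  gmA <- genotype_matrix(vA, dA, c(a1 = "AFF", a2 = "AFF"))
  gmB <- genotype_matrix(vB, dB, c(b1 = "OP"))
  j <- full_join_cohorts(list(gmA, gmB))
  expect_setequal(j$variants$key, c("1:100:A:G", "1:200:C:T"))
  expect_identical(unname(j$dosages["1:100:A:G", "b1"]), 0L)
  expect_identical(unname(j$dosages["1:200:C:T", c("a1", "a2")]), c(0L, 0L))
  expect_identical(sample_groups(j)[["b1"]], "OP")

  # idempotence on identical key sets
  gmB2 <- genotype_matrix(vA, dB, c(b1 = "OP"))
  expect_equal(n_variants(full_join_cohorts(list(gmA, gmB2))), 1L)

  # sample collision
  gmB3 <- genotype_matrix(vB, matrix(1L, 1, dimnames = list(NULL, "a1")),
                          c(a1 = "OP"))
  expect_error(full_join_cohorts(list(gmA, gmB3)), "duplicate sample",
               class = "affburden_data_error")
})

test_that("full join key set equals the brute-force union over simulated cohorts", {
  cfg <- sim_config(seed = 11, genes = sim_gene_table(6, 4),
                    gene_base_freq = setNames(numeric(0), character(0)),
                    effect_genes = setNames(numeric(0), character(0)),
                    n_hwe_violators = 0L, n_group_exclusive = c(3L, 3L),
                    missing_rate = 0.05, n_panel_absent = 0L,
                    n_case = 8L, n_control = 10L, n_panel = 12L)
  sim <- simulate_matrices(cfg)
  j <- full_join_cohorts(list(sim$case, sim$control, sim$panel))
  expect_setequal(j$variants$key,
                  union(union(sim$case$variants$key,
                              sim$control$variants$key),
                        sim$panel$variants$key))
  # simulated genes all sit on chromosome 1: join output must be pos-sorted
  expect_false(is.unsorted(j$variants$pos))
})

test_that("multi-sample read equals split per-sample reads joined", {
  cfg <- sim_config(seed = 12, genes = sim_gene_table(4, 5),
                    gene_base_freq = setNames(numeric(0), character(0)),
                    effect_genes = setNames(numeric(0), character(0)),
                    n_hwe_violators = 0L, n_group_exclusive = c(0L, 0L),
                    missing_rate = 0.1, n_panel_absent = 0L,
                    n_case = 6L, n_control = 4L, n_panel = 0L)
  sim <- simulate_matrices(cfg)
  multi <- tempfile(fileext = ".vcf")
  write_vcf(sim$case, multi)
  gm_multi <- read_cohort_vcf(multi, "AFF")

  per_sample <- lapply(colnames(sim$case$dosages), function(s) {
    sub <- subset_samples(sim$case, s)
    keep <- is.na(sub$dosages[, 1]) | sub$dosages[, 1] >= 1L
    sub <- subset_variants(sub, which(keep))
    f <- tempfile(fileext = ".vcf")
    write_vcf(sub, f)
    read_cohort_vcf(f, "AFF")
  })
  gm_join <- full_join_cohorts(per_sample)
  keys <- gm_multi$variants$key
  # same keys, same dosages, same missingness pattern
  expect_setequal(gm_join$variants$key, keys)
  d1 <- gm_multi$dosages[keys, colnames(gm_multi$dosages)]
  d2 <- gm_join$dosages[keys, colnames(gm_multi$dosages)]
  expect_identical(d1, d2)
})

test_that("results tables round-trip through disk", {
  gm <- tiny_gm()
  res <- run_variant_level(gm, c("AFF", "OP"))
  p <- tempfile(fileext = ".tsv")
  written <- write_results_table(res, p)
  expect_equal(ncol(written), 8L)
  back <- read.delim(p, stringsAsFactors = FALSE)
  expect_identical(back$n_variants, as.integer(res$n_variants))
  expect_equal(back$p_allele, signif(res$p_allele, 6), tolerance = 1e-6)
  expect_equal(back$q_genotype, signif(res$q_genotype, 6), tolerance = 1e-6)

  empty <- res[0, ]
  attr(empty, "groups") <- attr(res, "groups")
  p2 <- tempfile(fileext = ".tsv")
  write_results_table(empty, p2)
  expect_length(readLines(p2), 1L)  # header only

  mixed <- res
  mixed$level[1] <- "gene"
  expect_error(write_results_table(mixed, tempfile()),
               class = "affburden_usage_error")
})
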