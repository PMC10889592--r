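test_that("allele and genotype tables match the per-sample tally", {
  gm <- tiny_gm()
  groups <- c("AFF", "OP")
  # hand-checked: AFF dosages [1,2], OP [0,0,1] at variant 1
  t1 <- allele_table(gm, "1:100:A:G", groups)
  expect_identical(unname(t1["AFF", ]), c(1L, 3L))
  expect_identical(unname(t1["OP", ]), c(5L, 1L))
  g1 <- genotype_table(gm, "1:100:A:G", groups)
  expect_identical(unname(g1["AFF", ]), c(0L, 1L, 1L))
  expect_identical(unname(g1["OP", ]), c(2L, 1L, 0L))
  for (k in gm$variants$key) {
    expect_identical(allele_table(gm, k, groups),
                     oracle_allele_table(gm, k, groups))
    expect_identical(genotype_table(gm, k, groups),
                     oracle_genotype_table(gm, k, groups))
  }
  expect_error(allele_table(gm, "9:9:A:G", groups),
               class = "affburden_usage_error")
})

test_that("random matrices agree with the tally oracle", {
  set.seed(41)
  for (rep in 1:10) {
    nv <- 8; ns <- 12
    d <- matrix(sample(c(0:2, NA), nv * ns, replace = TRUE), nv, ns)
    colnames(d) <- paste0("s", 1:ns)
    v <- data.frame(chrom = "1", pos = seq_len(nv) * 10L, ref = "A",
                    alt = "C")
    gm <- genotype_matrix(v, d, setNames(rep(c("AFF", "OP"), each = ns / 2),
                                         colnames(d)))
    k <- sample(gm$variants$key, 1)
    expect_identical(allele_table(gm, k, c("AFF", "OP")),
                     oracle_allele_table(gm, k, c("AFF", "OP")))
    expect_identical(genotype_table(gm, k, c("AFF", "OP")),
                     oracle_genotype_table(gm, k, c("AFF", "OP")))
  }
})

test_that("Fisher 2x2 equals enumeration and the stats oracle", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  # allele counts reconstructed from a published two-variant gene:
  # 9/108 alt alleles (8%) in controls vs 18/52 (35%) in cases
  tab <- rbind(c(9, 99), c(18, 34))
  expect_equal(round(100 * 9 / 108), 8)
  expect_equal(round(100 * 18 / 52), 35)
  p <- fisher_exact(tab)$p.value
  expect_equal(p, oracle_fisher22(9, 99, 18, 34), tolerance = 1e-10)
  expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  set.seed(42)
  for (i in 1:150) {
    t <- matrix(rpois(4, sample(3:15, 1)), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    p1 <- fisher22_pvalue(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
    expect_equal(p1, oracle_fisher22(t[1, 1], t[1, 2], t[2, 1], t[2, 2]),
                 tolerance = 1e-10)
    expect_equal(p1, stats::fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("Freeman-Halton 2x3 equals full enumeration and the stats oracle", {
  set.seed(43)
  for (i in 1:150) {
    t <- matrix(rpois(6, sample(2:7, 1)), 2)
    if (sum(t) == 0 || any(rowSums(t) == 0) || sum(colSums(t) > 0) < 2) next
    p1 <- fisher2xk_pvalue(t)
    expect_equal(p1, oracle_fisher23(t), tolerance = 1e-10)
    expect_equal(p1, stats::fisher.test(t)$p.value, tolerance = 1e-9)
  }
})

test_that("degenerate tables are flagged with p = 1", {
  fe <- fisher_exact(rbind(c(0, 0), c(3, 4)))
  expect_equal(fe$p.value, 1)
  expect_true(fe$degenerate)
  fe2 <- fisher_exact(rbind(c(0, 3, 2), c(0, 1, 4)))
  expect_false(fe2$degenerate)  # zero column dropped, still testable
  fe3 <- fisher_exact(rbind(c(5, 0, 0), c(3, 0, 0)))
  expect_true(fe3$degenerate)
})

test_that("BH q-values follow the step-up definition", {
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(44)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_false(is.unsorted(q[order(p)]))
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 0)), class = "affburden_data_error")
})

test_that("gene pooling is additive over constituent variants", {
  v <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G")
  d <- rbind(c(1L, 2L, 0L, 0L), c(1L, 2L, 0L, 0L))
  colnames(d) <- paste0("s", 1:4)
  gm <- genotype_matrix(v, d, setNames(c("AFF", "AFF", "OP", "OP"),
                                       colnames(d)))
  asg <- data.frame(key = gm$variants$key, gene = "G1")
  pt <- gene_pooled_tables(gm, "G1", asg, c("AFF", "OP"))
  expect_equal(pt$n_variants, 2L)
  expect_identical(unname(pt$allele["AFF", ]), c(2L, 6L))
  expect_equal(unname(pt$freq["AFF"]), 6 / 8)
  # additivity against the per-variant tables
  sum_allele <- allele_table(gm, "1:100:A:G", c("AFF", "OP")) +
    allele_table(gm, "1:200:A:G", c("AFF", "OP"))
  expect_identical(pt$allele, sum_allele)
  sum_geno <- genotype_table(gm, "1:100:A:G", c("AFF", "OP")) +
    genotype_table(gm, "1:200:A:G", c("AFF", "OP"))
  expect_identical(pt$genotype, sum_geno)
  # single-variant gene: pooled equals per-variant
  asg1 <- data.frame(key = "1:100:A:G", gene = "G2")
  pt1 <- gene_pooled_tables(gm, "G2", asg1, c("AFF", "OP"))
  expect_identical(pt1$allele, allele_table(gm, "1:100:A:G", c("AFF", "OP")))
  expect_error(gene_pooled_tables(gm, "NONE", asg, c("AFF", "OP")),
               class = "affburden_usage_error")
})

test_that("pooled gene tables match a concatenated brute-force tally", {
  cfg <- sim_config(seed = 45, genes = sim_gene_table(3, 6),
                    gene_base_freq = setNames(numeric(0), character(0)),
                    effect_genes = setNames(numeric(0), character(0)),
                    n_hwe_violators = 0L, n_group_exclusive = c(0L, 0L),
                    missing_rate = 0.05, n_panel_absent = 0L,
                    n_case = 7L, n_control = 9L, n_panel = 0L)
  sim <- simulate_matrices(cfg)
  gm <- full_join_cohorts(list(sim$case, sim$control))
  reg <- filter_by_regions(gm, sim$panel_genes)
  for (gene in unique(reg$assignment$gene)) {
    pt <- gene_pooled_tables(reg$matrix, gene, reg$assignment,
                             c("AFF", "OP"))
    keys <- reg$assignment$key[reg$assignment$gene == gene]
    brute <- Reduce(`+`, lapply(keys, oracle_allele_table,
                                gm = reg$matrix,
                                groups = c("AFF", "OP")))
    expect_identical(pt$allele, brute)
  }
})

test_that("variant-level results: q = p for a single variant, untestables sidelined", {
  v <- data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G")
  d <- rbind(c(1L, 2L, 0L, 1L),
             c(1L, 0L, NA, NA))   # OP entirely missing: untestable
  colnames(d) <- paste0("s", 1:4)
  gm <- genotype_matrix(v, d, setNames(c("AFF", "AFF", "OP", "OP"),
                                       colnames(d)))
  res <- run_variant_level(gm, c("AFF", "OP"))
  r2 <- res[res$unit == "1:200:A:G", ]
  expect_true(r2$untestable_allele && r2$untestable_genotype)
  expect_true(is.na(r2$q_allele))
  r1 <- res[res$unit == "1:100:A:G", ]
  # BH family has a single member: q equals p
  expect_equal(r1$q_allele, r1$p_allele)
  expect_equal(attr(res, "family_sizes")[["allele"]], 1L)
})

test_that("gene-level results carry pooled frequencies and per-family FDR", {
  gm <- tiny_gm()
  asg <- data.frame(key = gm$variants$key,
                    gene = c("G1", "G1", "G2"))
  res <- run_gene_level(gm, asg, c("AFF", "OP"))
  expect_setequal(res$unit, c("G1", "G2"))
  g1 <- res[res$unit == "G1", ]
  pt <- gene_pooled_tables(gm, "G1", asg, c("AFF", "OP"))
  expect_equal(g1$freq_group1, unname(pt$freq["AFF"]))
  expect_equal(g1$freq_group2, unname(pt$freq["OP"]))
  expect_equal(g1$n_variants, 2L)
  # two testable genes: BH with m = 2
  expect_equal(sort(res$q_allele),
               sort(oracle_bh(res$p_allele)), tolerance = 1e-12)
  # single-gene family: q equals p
  res1 <- run_gene_level(gm, asg[asg$gene == "G1", ], c("AFF", "OP"))
  expect_equal(res1$q_allele, res1$p_allele)
  expect_equal(res1$q_genotype, res1$p_genotype)
})
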