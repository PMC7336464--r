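test_that("simulation is fully deterministic under a seed", {
  cfg <- sim_config(n_samples = 40, n_snps = 300, n_genes = 20,
                    n_local_eqtl = 4, n_distant_eqtl = 2, seed = 7)
  a <- simulate_drought_study(cfg)
  b <- simulate_drought_study(cfg)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$annotation, b$annotation)
  expect_identical(lapply(a$expression, `[[`, "abundance"),
                   lapply(b$expression, `[[`, "abundance"))
  expect_identical(as.numeric(a$phenotype), as.numeric(b$phenotype))
  expect_identical(a$truth, b$truth)
})

test_that("fst -> 0 limit collapses subpopulation differentiation", {
  cfg <- sim_config(n_samples = 30, n_snps = 400, n_genes = 10,
                    n_local_eqtl = 0, n_distant_eqtl = 0, fst = 1e-4,
                    seed = 5)
  geno <- simulate_genotypes(cfg)
  # per-SNP allele-frequency variance across subpopulations
  freq <- vapply(seq_len(n_snps(geno$genotypes)), function(j) {
    g <- geno$genotypes$calls[, j]
    vapply(split(g, geno$subpop), function(v)
      mean(v, na.rm = TRUE) / 2, numeric(1))
  }, numeric(3))
  # with fst ~ 0 the three subpop frequencies agree up to sampling noise
  # of 10 samples each; compare to a strongly structured panel
  cfg2 <- sim_config(n_samples = 30, n_snps = 400, n_genes = 10,
                     n_local_eqtl = 0, n_distant_eqtl = 0, fst = 0.3,
                     seed = 5)
  geno2 <- simulate_genotypes(cfg2)
  freq2 <- vapply(seq_len(n_snps(geno2$genotypes)), function(j) {
    g <- geno2$genotypes$calls[, j]
    vapply(split(g, geno2$subpop), function(v)
      mean(v, na.rm = TRUE) / 2, numeric(1))
  }, numeric(3))
  expect_lt(mean(apply(freq, 2, var)), 0.5 * mean(apply(freq2, 2, var)))
})

test_that("LD decays with distance on the configured scale", {
  cfg <- sim_config(n_samples = 150, n_snps = 1500, n_genes = 10,
                    n_local_eqtl = 0, n_distant_eqtl = 0,
                    ld_decay_bp = 1600, missing_rate = 0, het_rate = 0,
                    seed = 17)
  geno <- simulate_genotypes(cfg)
  g <- dosage_imputed(geno$genotypes)
  keep <- which(apply(g, 2, var) > 0)
  g <- g[, keep]; pos <- geno$genotypes$snps$pos[keep]
  r2 <- cor(g)^2
  d <- abs(outer(pos, pos, "-"))
  ut <- upper.tri(r2)
  near <- r2[ut & d < 1600 & d > 0]
  far <- r2[ut & d > 16000]
  expect_gt(mean(near), mean(far))
  expect_gt(mean(near), 0.3)     # usable local tagging
  expect_lt(mean(far), 0.1)
})

test_that("a planted local effect explains its configured variance share", {
  cfg <- sim_config(n_samples = 500, n_snps = 600, n_genes = 20,
                    n_local_eqtl = 5, n_distant_eqtl = 0,
                    effect_r2_range = c(0.3, 0.3), frac_static = 1,
                    missing_rate = 0, het_rate = 0, seed = 23)
  sim <- simulate_drought_study(cfg)
  tr <- sim$truth$effects
  dose <- dosage_imputed(sim$genotypes)
  r2 <- vapply(seq_len(nrow(tr)), function(i) {
    z <- dose[, tr$snp[i]]
    x <- log(sim$expression$WW$abundance[tr$gene[i], ])
    cor(z, x)^2
  }, numeric(1))
  expect_true(all(abs(r2 - 0.3) < 0.05))
})

test_that("zero effects and zero noise reduce to the baseline", {
  cfg <- sim_config(n_samples = 20, n_snps = 200, n_genes = 8,
                    n_local_eqtl = 0, n_distant_eqtl = 0,
                    n_hidden_factors = 0, noise_sd = 1e-12,
                    condition_shift_sd = 0, frac_responsive = 0,
                    seed = 3)
  sim <- simulate_drought_study(cfg)
  ab <- sim$expression$WW$abundance
  # every sample identical per gene (only the baseline survives)
  expect_lt(max(apply(log(ab), 1, sd)), 1e-10)
})

test_that("ledger bookkeeping distinguishes static and dynamic effects", {
  cfg <- sim_config(n_samples = 50, n_snps = 500, n_genes = 25,
                    n_local_eqtl = 8, n_distant_eqtl = 4,
                    frac_static = 0.5, seed = 31)
  sim <- simulate_drought_study(cfg)
  tr <- sim$truth$effects
  conds <- strsplit(tr$conditions, ",")
  n_active <- lengths(conds)
  expect_true(all(n_active >= 1 & n_active <= 3))
  # every planted effect appears exactly once per (kind, gene)
  expect_false(anyDuplicated(tr[c("kind", "gene")]) > 0)
  # causal SNPs and genes exist in their containers
  expect_true(all(tr$snp %in% sim$genotypes$snps$snp_id))
  expect_true(all(tr$gene %in% sim$annotation$gene_id))
  reg <- tr$regulator[tr$kind == "distant"]
  expect_true(all(reg %in% sim$annotation$gene_id[sim$annotation$is_tf]))
  # local causal SNPs lie within 20 kb of their gene
  pos <- setNames(sim$genotypes$snps$pos, sim$genotypes$snps$snp_id)
  loc <- tr[tr$kind == "local", ]
  ann <- sim$annotation
  for (i in seq_len(nrow(loc))) {
    gi <- match(loc$gene[i], ann$gene_id)
    expect_gte(pos[loc$snp[i]], ann$start[gi] - 20000)
    expect_lte(pos[loc$snp[i]], ann$end[gi] + 20000)
  }
})

test_that("per-gene variance decomposes close to the configured budget", {
  cfg <- sim_config(n_samples = 600, n_snps = 400, n_genes = 12,
                    n_local_eqtl = 6, n_distant_eqtl = 0,
                    effect_r2_range = c(0.35, 0.35), frac_static = 1,
                    n_hidden_factors = 8, factor_sd = 0.4,
                    noise_sd = 0.5, missing_rate = 0, het_rate = 0,
                    seed = 41)
  sim <- simulate_drought_study(cfg)
  tr <- sim$truth$effects
  dose <- dosage_imputed(sim$genotypes)
  for (i in seq_len(nrow(tr))) {
    x <- log(sim$expression$WW$abundance[tr$gene[i], ])
    z <- dose[, tr$snp[i]]
    genetic <- var(tr$beta[i] * z)
    share <- genetic / var(x)
    expect_lt(abs(share - 0.35), 0.1 * 1 + 0.035)  # within 10% rel. + mc
  }
})

test_that("phenotype is driven by its causal genes as recorded", {
  # single causal gene, no noise: perfect rank agreement
  cfg <- sim_config(n_samples = 60, n_snps = 300, n_genes = 10,
                    n_local_eqtl = 2, n_distant_eqtl = 0,
                    n_phenotype_genes = 1, phenotype_effects = 0.7,
                    pheno_noise_sd = 0, n_hidden_factors = 0, seed = 19)
  sim <- simulate_drought_study(cfg)
  g <- sim$truth$phenotype$gene
  es <- inverse_normal_transform(quantile_normalize(sim$expression$WS2))
  x <- es$transformed[g, names(sim$phenotype)]
  expect_equal(abs(cor(x, as.numeric(sim$phenotype),
                       method = "spearman")), 1)
})

test_that("a known mediation coefficient is recovered by OLS", {
  cfg <- sim_config(n_samples = 300, n_snps = 300, n_genes = 10,
                    n_local_eqtl = 0, n_distant_eqtl = 0,
                    n_phenotype_genes = 1, phenotype_effects = 0.5,
                    noise_sd = 0.3, seed = 29)
  sim <- simulate_drought_study(cfg)
  tp <- sim$truth$phenotype
  es <- inverse_normal_transform(quantile_normalize(sim$expression$WS2))
  x <- es$transformed[tp$gene, names(sim$phenotype)]
  fit <- summary(lm(as.numeric(sim$phenotype) ~ x))
  expect_lt(abs(fit$coefficients["x", 1] - tp$effect),
            2 * fit$coefficients["x", 2])
})

test_that("with no causal genes the phenotype is uncorrelated with expression", {
  cfg <- sim_config(n_samples = 200, n_snps = 300, n_genes = 15,
                    n_local_eqtl = 0, n_distant_eqtl = 0,
                    n_phenotype_genes = 1, phenotype_effects = 0,
                    noise_sd = 0.5, seed = 37)
  sim <- simulate_drought_study(cfg)
  es <- inverse_normal_transform(quantile_normalize(sim$expression$WS2))
  y <- as.numeric(sim$phenotype)
  r <- apply(es$transformed[, names(sim$phenotype)], 1,
             function(x) cor(x, y))
  expect_true(all(abs(r) < 3 / sqrt(length(y))))
})

test_that("simulation writes a complete on-disk study", {
  cfg <- sim_config(n_samples = 15, n_snps = 120, n_genes = 8,
                    n_local_eqtl = 2, n_distant_eqtl = 1, seed = 53)
  sim <- simulate_drought_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  suppressMessages(vt <- read_vcf(file.path(dir, "genotypes.vcf")))
  expect_identical(unname(vt$calls), unname(sim$genotypes$calls))
  ann <- read_gff3(file.path(dir, "genes.gff3"))
  expect_identical(ann$gene_id, sim$annotation$gene_id)
  expect_identical(ann$is_tf, sim$annotation$is_tf)
  ww <- read_matrix(file.path(dir, "expression_WW.tsv"))
  expect_identical(ww, sim$expression$WW$abundance)
  ph <- read_phenotype(file.path(dir, "phenotype.tsv"))
  expect_equal(as.numeric(ph), as.numeric(sim$phenotype))
})
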