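# Synthetic-data generators: determinism and ground-truth recovery

test_that("all generators are bit-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 40, n_snps = 60, n_causal = 4, seed = 1)
  g1 <- gen_genotypes(cfg); g2 <- gen_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$meta, g2$meta)
  p1 <- gen_phenotype_direct(cfg, g1); p2 <- gen_phenotype_direct(cfg, g2)
  expect_identical(p1$phenotype$y, p2$phenotype$y)
  v1 <- gen_vasculature(cfg, p1$phenotype$genetic_value)
  v2 <- gen_vasculature(cfg, p2$phenotype$genetic_value)
  expect_identical(v1$points, v2$points)
  m1 <- gen_mr_summary(30, 0.2, seed = 5)
  m2 <- gen_mr_summary(30, 0.2, seed = 5)
  expect_identical(m1$forward, m2$forward)
  a1 <- gen_annotations_and_sets(30, 3, 5, seed = 2)
  a2 <- gen_annotations_and_sets(30, 3, 5, seed = 2)
  expect_identical(a1$annotation, a2$annotation)
  expect_identical(a1$expression, a2$expression)
  # a different seed changes the draw
  expect_false(identical(gen_genotypes(sim_config(n_subjects = 40,
                                                  n_snps = 60,
                                                  seed = 2))$dosage,
                         g1$dosage))
})

test_that("ld_rho = 0 gives independent SNPs; ld_rho = 0.9 matches the
           copula's Monte-Carlo adjacent r2", {
  cfg0 <- sim_config(n_subjects = 10000, n_snps = 40, ld_block_size = 10,
                     ld_rho = 0, seed = 3, rare_fraction = 0)
  g0 <- gen_genotypes(cfg0)
  adj <- vapply(seq_len(39), function(j) {
    if (g0$meta$block[j] != g0$meta$block[j + 1]) return(NA_real_)
    cor(g0$dosage[, j], g0$dosage[, j + 1])^2
  }, 0)
  expect_lt(mean(adj, na.rm = TRUE), 0.01)

  cfg9 <- sim_config(n_subjects = 5000, n_snps = 40, ld_block_size = 10,
                     ld_rho = 0.9, seed = 3, rare_fraction = 0)
  g9 <- gen_genotypes(cfg9)
  adj9 <- vapply(seq_len(39), function(j) {
    if (g9$meta$block[j] != g9$meta$block[j + 1]) return(NA_real_)
    cor(g9$dosage[, j], g9$dosage[, j + 1])^2
  }, 0)
  # brute-force Monte-Carlo of the same copula at large n
  set.seed(99)
  nmc <- 1e6
  r2_mc <- replicate(8, {
    maf1 <- runif(1, 0.05, 0.5); maf2 <- runif(1, 0.05, 0.5)
    z1 <- rnorm(nmc); z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(nmc)
    w1 <- rnorm(nmc); w2 <- 0.9 * w1 + sqrt(1 - 0.81) * rnorm(nmc)
    d1 <- (z1 < qnorm(maf1)) + (w1 < qnorm(maf1))
    d2 <- (z2 < qnorm(maf2)) + (w2 < qnorm(maf2))
    cor(d1, d2)^2
  })
  mean_obs <- mean(adj9, na.rm = TRUE)
  se <- sqrt(var(adj9, na.rm = TRUE) / sum(!is.na(adj9)) +
               var(r2_mc) / length(r2_mc))
  expect_lt(abs(mean_obs - mean(r2_mc)), 3 * se + 0.02)
})

test_that("zero amplitude gives straight vessels with DF = 1", {
  cfg <- sim_config(n_subjects = 5, n_snps = 10, n_causal = 2, seed = 4)
  seg <- gen_vasculature(cfg, rep(0, 5), amplitude_override = 0)
  dfs <- vapply(seg$points, distance_factor, 0)
  expect_true(all(abs(dfs - 1) < 1e-12))
})

test_that("median DF increases strictly with the waviness amplitude", {
  cfg <- sim_config(n_subjects = 8, n_snps = 10, n_causal = 2, seed = 4)
  med <- vapply(c(0, 0.015, 0.03), function(a) {
    seg <- gen_vasculature(cfg, rep(0, 8), amplitude_override = a)
    median(vapply(seg$points, distance_factor, 0))
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("phenotype generator hits its heritability target", {
  # h2 = 0: phenotype independent of causal dosages
  cfg0 <- sim_config(n_subjects = 500, n_snps = 100, n_causal = 10,
                     h2_target = 0, seed = 6)
  g <- gen_genotypes(cfg0)
  p <- gen_phenotype_direct(cfg0, g)
  expect_identical(length(p$truth$causal_betas), 0L)
  expect_equal(p$truth$realized_h2, 0)

  # variance share of the genetic component near 0.5 over repeated seeds
  h2s <- vapply(1:20, function(s) {
    cfg <- sim_config(n_subjects = 400, n_snps = 100, n_causal = 50,
                      h2_target = 0.5, seed = s)
    gg <- gen_genotypes(cfg)
    gen_phenotype_direct(cfg, gg)$truth$realized_h2
  }, 0)
  expect_lt(abs(mean(h2s) - 0.5), 3 * sd(h2s) / sqrt(20) + 0.01)

  # ground truth is recomputable from betas and standardized dosages
  cfg <- sim_config(n_subjects = 300, n_snps = 50, n_causal = 5,
                    h2_target = 0.3, seed = 7)
  gg <- gen_genotypes(cfg)
  pp <- gen_phenotype_direct(cfg, gg)
  X <- scale(gg$dosage[, pp$truth$causal_snp_ids])
  g_re <- as.numeric(X %*% pp$truth$causal_betas)
  expect_equal(var(g_re), cfg$h2_target, tolerance = 1e-6)
  expect_equal(var(g_re) / var(pp$phenotype$genetic_value +
                                 (pp$phenotype$y - pp$phenotype$genetic_value -
                                    cfg$age_beta * (pp$phenotype$age - 56) / 8 -
                                    cfg$sex_beta * pp$phenotype$sex)),
               pp$truth$realized_h2, tolerance = 1e-6)
})

test_that("single causal SNP with beta 1 and no noise equals the
           standardized dosage", {
  cfg <- sim_config(n_subjects = 200, n_snps = 20, n_causal = 1,
                    h2_target = 1 - 1e-12, seed = 8, age_beta = 0,
                    sex_beta = 0)
  g <- gen_genotypes(cfg)
  p <- gen_phenotype_direct(cfg, g)
  x <- as.numeric(scale(g$dosage[, p$truth$causal_snp_ids]))
  expect_equal(cor(abs(p$phenotype$y), abs(x)), 1, tolerance = 1e-5)
})

test_that("MR generator: null, recovery and filtering hooks", {
  null <- gen_mr_summary(100, 0, seed = 10)
  iv <- select_instruments(null$forward)
  est <- ivw_estimate(iv)
  expect_lt(abs(est$beta), 3 * est$se)
  eff <- gen_mr_summary(100, 0.3, seed = 11)
  est2 <- ivw_estimate(select_instruments(eff$forward))
  expect_lt(abs(est2$beta - 0.3), 3 * est2$se)
  # ambiguous alleles and sub-threshold p-values are present to filter
  fw <- eff$forward
  expect_gt(sum((fw$EA == "A" & fw$RA == "T") |
                  (fw$EA == "T" & fw$RA == "A") |
                  (fw$EA == "C" & fw$RA == "G") |
                  (fw$EA == "G" & fw$RA == "C")), 0)
  expect_gt(sum(fw$p_exp >= 5e-8), 0)
})

test_that("annotation generator: fusion boundary gaps, empty set lists,
           plantable catalogue", {
  ann <- gen_annotations_and_sets(60, 4, 6, seed = 12,
                                  gap_choices = c(150000, 250000))
  fused <- fuse_genes(ann$annotation)
  keep <- ann$annotation[ann$annotation$biotype %in%
                           c("protein_coding", "lincRNA"), ]
  expect_identical(nrow(fused), nrow(keep))  # all gaps >= 100 kb: identity
  empty <- gen_annotations_and_sets(10, 0, 3, seed = 13, planted_set = NA)
  expect_identical(length(empty$sets), 0L)
  pool <- sprintf("rs%04d", 1:50)
  withpool <- gen_annotations_and_sets(10, 1, 3, seed = 14,
                                       snp_pool = pool)
  expect_true(all(withpool$catalogue$SNP %in% pool))
})
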