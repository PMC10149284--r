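# SNP QC, normalization, per-SNP association and diagnostics

test_that("SNP filter applies the MAF and info rules", {
  meta <- data.table::data.table(
    snp = paste0("s", 1:6),
    freq = c(0.5, 0.0004, 0.3, 0.9997, 0.2, 0.1),
    info = rep(1.0, 6))
  out <- filter_snps(meta)
  expect_identical(nrow(out$kept), 4L)
  expect_setequal(out$log$snp, c("s2", "s4"))
  # info strictly below 0.3 is excluded, 0.3 itself survives
  meta2 <- data.table::data.table(snp = c("a", "b"), freq = c(0.2, 0.2),
                                  info = c(0.29, 0.30))
  expect_identical(filter_snps(meta2)$kept$snp, "b")
  # zero thresholds are the identity
  expect_identical(nrow(filter_snps(meta, 0, 0)$kept), 6L)
  expect_error(filter_snps(data.table::data.table(snp = "x")), "columns")
})

test_that("inverse normal transform: closed-form quantiles, monotonicity,
           ties, idempotence up to ranks", {
  out <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(out, qnorm(c(1, 3, 5) / 6))
  expect_equal(out[2], 0)
  x <- rnorm(50)
  tx <- inverse_normal_transform(x)
  expect_identical(order(x), order(tx))
  expect_lt(abs(mean(tx)), 1e-6 * 50)
  ties <- inverse_normal_transform(c(5, 1, 5, 3))
  expect_equal(ties[1], ties[3])
  expect_equal(inverse_normal_transform(tx), tx, tolerance = 1e-12)
  expect_error(inverse_normal_transform(rep(2, 5)), "all-ties")
  expect_error(inverse_normal_transform(1), "at least 2")
})

test_that("PC selection keeps correlated PCs at rate alpha for null ones", {
  set.seed(21)
  n <- 2000
  y <- rnorm(n)
  pcs <- cbind(y + rnorm(n, 0, 0.1), rnorm(n), rnorm(n))
  sel <- select_covariate_pcs(y, pcs)
  expect_true(1 %in% sel)
  # null PCs selected with probability ~ alpha
  hits <- mean(replicate(200, {
    length(select_covariate_pcs(rnorm(500), cbind(rnorm(500)))) > 0
  }))
  expect_lt(abs(hits - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
  expect_identical(select_covariate_pcs(y, pcs, alpha = 1), 1:3)
  expect_warning(select_covariate_pcs(y, cbind(rep(1, n))), "zero variance")
})

test_that("run_gwas equals the naive per-SNP lm fit on a 50x20 instance", {
  set.seed(22)
  n <- 50; m <- 20
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(NULL, paste0("s", 1:m)))
  cov <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- rnorm(n) + 0.3 * G[, 1] + 0.2 * cov[, "age"]
  res <- run_gwas(y, G, covariates = cov)
  for (j in c(1, 5, 20)) {
    fit <- summary(lm(y ~ G[, j] + cov))$coefficients[2, ]
    expect_equal(res$BETA[j], unname(fit[1]), tolerance = 1e-8)
    expect_equal(res$SE[j], unname(fit[2]), tolerance = 1e-8)
    # normal rather than t reference for p
    z <- unname(fit[1] / fit[2])
    expect_equal(res$P[j], 2 * pnorm(-abs(z)), tolerance = 1e-10)
  }
  expect_true(all(res$N == n))
})

test_that("phenotype equal to dosage gives beta 1 with vanishing p", {
  set.seed(23)
  G <- matrix(rbinom(400, 2, 0.4), 200, 2,
              dimnames = list(NULL, c("a", "b")))
  res <- run_gwas(as.numeric(G[, 1]), G)
  expect_equal(res$BETA[1], 1, tolerance = 1e-12)
  expect_lt(res$P[1], 1e-100)
  expect_gt(res$NEG_LOG10_P[1], 100)
})

test_that("type-I error is nominal on permuted phenotypes and
           confounder adjustment removes bias", {
  sim <- make_small_sim(seed = 31, n = 400, m = 1000)
  set.seed(31)
  y_perm <- sample(sim$phen$phenotype$y)
  res <- run_gwas(y_perm, sim$geno)
  pv <- res$P[is.finite(res$P)]  # monomorphic rare SNPs yield NA
  frac <- mean(pv < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(pv)))

  # age drives both the phenotype and a batch correlated with dosage
  set.seed(32)
  n <- 2000
  age <- rnorm(n)
  g <- rbinom(n, 2, plogis(-0.5 + 0.8 * age))  # dosage tied to age
  y <- 0.8 * age + rnorm(n)                    # age drives y; g does not
  G1 <- matrix(g, ncol = 1, dimnames = list(NULL, "snp1"))
  unadj <- run_gwas(y, G1)
  adj <- run_gwas(y, G1, covariates = cbind(age = age))
  expect_gt(abs(unadj$BETA / unadj$SE), 5)      # biased without adjustment
  expect_lt(abs(adj$BETA), 3 * adj$SE)          # unbiased with it
})

test_that("collinear covariates raise a named singularity error", {
  set.seed(24)
  G <- matrix(rbinom(100, 2, 0.3), 50, 2,
              dimnames = list(NULL, c("a", "b")))
  cov <- cbind(x1 = rnorm(50))
  cov <- cbind(cov, x2 = 2 * cov[, 1])
  expect_error(run_gwas(rnorm(50), G, covariates = cov), "collinear.*x2")
})

test_that("genomic diagnostics: null calibration and scale equivariance", {
  set.seed(25)
  z <- rnorm(50000)
  assoc <- data.table::data.table(BETA = z, SE = 1)
  d <- genomic_diagnostics(assoc)
  expect_lt(abs(d$lambda_gc - 1), 0.03)
  expect_lt(abs(d$mean_chi2 - 1), 0.03)
  const <- data.table::data.table(BETA = rep(sqrt(qchisq(0.5, 1)), 200),
                                  SE = 1)
  expect_equal(genomic_diagnostics(const)$lambda_gc, 1)
  doubled <- data.table::data.table(BETA = z * sqrt(2), SE = 1)
  expect_equal(genomic_diagnostics(doubled)$lambda_gc,
               2 * d$lambda_gc, tolerance = 1e-10)
  expect_error(genomic_diagnostics(assoc[1:50]), "at least 100")
})

test_that("Bonferroni thresholds reproduce the protocol constants", {
  expect_equal(bonferroni_threshold(0.05, 1e6), 5e-8)
  expect_equal(bonferroni_threshold(0.05, 25489), 0.05 / 25489)
  expect_equal(bonferroni_threshold(0.05, 25489), 1.9616e-6,
               tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 54), 0.05 / 54)
  expect_equal(bonferroni_threshold(0.05, 54), 9.259e-4, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
})
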