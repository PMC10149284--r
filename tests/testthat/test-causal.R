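# Instrument selection, IVW MR, catalogue overlap, disease association

test_that("instrument selection drops ambiguous, weak and non-autosomal
           SNPs and prunes by r2 like the brute-force oracle", {
  d <- data.table::data.table(
    SNP = paste0("s", 1:5), CHR = c(1L, 1L, 23L, 2L, 2L),
    EA = c("A", "A", "A", "C", "G"), RA = c("G", "T", "G", "T", "T"),
    beta_exp = 0.2, se_exp = 0.01,
    p_exp = c(1e-10, 1e-10, 1e-10, 6e-8, 1e-9),
    beta_out = 0.05, se_out = 0.01, p_out = 0.01)
  sel <- select_instruments(d)
  # s2 ambiguous (A/T), s3 chromosome 23, s4 p above 5e-8
  expect_setequal(sel$SNP, c("s1", "s5"))

  set.seed(71)
  n <- 800
  base <- rbinom(n, 2, 0.4)
  panel <- cbind(
    i1 = base,
    i2 = ifelse(runif(n) < 0.9, base, rbinom(n, 2, 0.4)),  # high r2 w/ i1
    i3 = rbinom(n, 2, 0.4),
    i4 = rbinom(n, 2, 0.4),
    i5 = ifelse(runif(n) < 0.9, base, rbinom(n, 2, 0.4)))
  dd <- data.table::data.table(
    SNP = paste0("i", 1:5), CHR = 1L, EA = "A", RA = "G",
    beta_exp = 0.2, se_exp = 0.01,
    p_exp = c(1e-12, 1e-11, 1e-10, 1e-9, 1e-8) * c(1, 10, 1, 1, 1),
    beta_out = 0.05, se_out = 0.01, p_out = 0.01)
  sel2 <- select_instruments(dd, panel, r2_max = 0.01)
  # brute-force greedy over the r2 matrix in ascending-p order
  r2 <- cor(panel)^2
  ord <- order(dd$p_exp, dd$SNP)
  keep <- character(0)
  for (s in dd$SNP[ord]) {
    if (all(r2[s, keep] < 0.01)) keep <- c(keep, s)
  }
  expect_identical(sel2$SNP, keep)
  expect_error(select_instruments(d[2]), "no instruments")
})

test_that("IVW reduces to the Wald ratio for one instrument and behaves
           at the null", {
  one <- data.table::data.table(beta_exp = 0.5, beta_out = 0.1,
                                se_out = 0.05)
  est <- ivw_estimate(one)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  expect_identical(est$n_instruments, 1L)
  zero <- data.table::data.table(beta_exp = c(0.2, -0.4),
                                 beta_out = c(0, 0), se_out = 0.05)
  expect_equal(ivw_estimate(zero)$beta, 0)
  expect_error(ivw_estimate(data.table::data.table(beta_exp = 0,
                                                   beta_out = 1,
                                                   se_out = 1)),
               "undefined")
})

test_that("IVW is invariant under per-instrument allele recoding", {
  set.seed(72)
  d <- data.table::data.table(beta_exp = rnorm(20, 0, 0.2),
                              beta_out = rnorm(20, 0, 0.05),
                              se_out = 0.05)
  base <- ivw_estimate(d)
  flip <- data.table::copy(d)
  idx <- sample(20, 8)
  flip[idx, `:=`(beta_exp = -beta_exp, beta_out = -beta_out)]
  flipped <- ivw_estimate(flip)
  expect_equal(base$beta, flipped$beta, tolerance = 1e-12)
  expect_equal(base$se, flipped$se, tolerance = 1e-12)
})

test_that("simulated causal effects are recovered in the right direction", {
  mr <- gen_mr_summary(100, 0.3, seed = 73, se_outcome = 0.005)
  res <- bidirectional_mr(mr$forward, mr$reverse)
  fwd <- res[[1]]; rev <- res[[2]]
  expect_lt(abs(fwd$beta - 0.3), 3 * fwd$se)
  expect_lt(abs(rev$beta), 3 * rev$se)
  # swapping datasets swaps the estimates with their labels
  res2 <- bidirectional_mr(mr$reverse, mr$forward,
                           labels = c("rev", "fwd"))
  expect_equal(res2[["rev"]]$beta, rev$beta)
  expect_equal(res2[["fwd"]]$beta, fwd$beta)
})

test_that("catalogue overlap: exact matches, proxy threshold boundary,
           trait counting, and the brute-force double loop", {
  set.seed(74)
  n <- 600
  g1 <- rbinom(n, 2, 0.4)
  g2 <- ifelse(runif(n) < 0.97, g1, rbinom(n, 2, 0.4))  # r2 > 0.8
  g3 <- ifelse(runif(n) < 0.60, g1, rbinom(n, 2, 0.4))  # r2 < 0.8
  panel <- cbind(lead1 = g1, prox = g2, weak = g3, lead2 = rbinom(n, 2, 0.3))
  r2 <- cor(panel)^2
  expect_gt(r2["lead1", "prox"], 0.8); expect_lt(r2["lead1", "weak"], 0.8)
  leads <- data.table::data.table(SNP = c("lead1", "lead2"))
  cat_tab <- data.table::data.table(
    SNP = c("lead2", "prox", "weak", "other"),
    TRAIT = c("bp", "bp", "bp", "lipid"),
    MAPPED_GENE = c("G1", "G2", "G3", "G4"))
  ov <- catalogue_overlap(leads, cat_tab, panel, min_count = 1)
  expect_true(any(ov$overlaps$lead_snp == "lead2" &
                    ov$overlaps$r2 == 1))             # exact match
  expect_true(any(ov$overlaps$catalogue_snp == "prox"))  # proxy
  expect_false(any(ov$overlaps$catalogue_snp == "weak"))
  expect_identical(ov$trait_counts[trait == "bp", n_shared], 2L)
  # brute-force double loop over all (lead, catalogue) pairs
  bf <- 0
  for (l in leads$SNP) for (k in seq_len(nrow(cat_tab))) {
    cs <- cat_tab$SNP[k]
    hit <- (l == cs) ||
      (cs %in% colnames(panel) && r2[l, cs] > 0.8)
    bf <- bf + hit
  }
  expect_identical(nrow(ov$overlaps), as.integer(bf))
  # min_count filters traits
  ov5 <- catalogue_overlap(leads, cat_tab, panel, min_count = 5)
  expect_identical(nrow(ov5$trait_counts), 0L)
})

test_that("disease association: null, slope recovery and separation", {
  set.seed(75)
  n <- 4000
  ph <- rnorm(n)
  null_status <- rbinom(n, 1, 0.3)
  d0 <- disease_association(ph, null_status)
  expect_lt(abs(d0$beta), 3 * d0$se)
  status <- rbinom(n, 1, plogis(-1 + 0.25 * ph))
  d1 <- disease_association(ph, status)
  expect_lt(abs(d1$beta - 0.25), 3 * d1$se)
  expect_error(disease_association(ph, rep(0, n)), "degenerate")
  sep <- c(rep(0, 20), rep(1, 20))
  expect_error(disease_association(c(rnorm(20, -10), rnorm(20, 10)), sep),
               "separation")
})

test_that("Cohen's d matches hand arithmetic and is antisymmetric", {
  expect_equal(cohens_d(c(2, 4), c(0, 2)), sqrt(2))
  x <- rnorm(30); y <- rnorm(30, 0.5)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled")
})
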