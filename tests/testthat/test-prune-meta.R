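# LD pruning, meta-analysis, BH replication, concordance

test_that("pruning keeps SNP pairs that are distant OR weakly correlated", {
  set.seed(51)
  n <- 500
  g1 <- rbinom(n, 2, 0.3)
  g2 <- ifelse(runif(n) < 0.7, g1, rbinom(n, 2, 0.3))  # r2 ~ 0.5
  g3 <- rbinom(n, 2, 0.3)                               # r2 ~ 0
  panel <- cbind(a = g1, b = g2, c = g3)
  mk <- function(snp, chr, bp, p) data.table::data.table(
    SNP = snp, CHR = chr, BP = bp, P = p)
  # correlated but > 500 kb apart: both kept
  far <- rbind(mk("a", 1, 1e6, 1e-10), mk("b", 1, 1e6 + 600001, 1e-9))
  expect_identical(nrow(ld_prune(far, panel)), 2L)
  # close but r2 < 0.1: both kept
  near_indep <- rbind(mk("a", 1, 1e6, 1e-10), mk("c", 1, 1e6 + 1e4, 1e-9))
  expect_identical(nrow(ld_prune(near_indep, panel)), 2L)
  # close and correlated: the more significant wins
  near_dep <- rbind(mk("b", 1, 1e6 + 1e4, 1e-9), mk("a", 1, 1e6, 1e-10))
  out <- ld_prune(near_dep, panel)
  expect_identical(out$SNP, "a")
  expect_warning(ld_prune(mk("zz", 1, 1, 1e-9), panel), "absent")
})

test_that("pruning matches the brute-force greedy oracle on a 10-SNP
           block and is order-invariant", {
  cfg <- sim_config(n_subjects = 600, n_snps = 10, n_causal = 2,
                    ld_block_size = 5, ld_rho = 0.85, seed = 52,
                    rare_fraction = 0, spacing_bp = 2e5)
  g <- gen_genotypes(cfg)
  set.seed(52)
  assoc <- data.table::data.table(SNP = g$meta$snp, CHR = g$meta$chr,
                                  BP = g$meta$pos,
                                  P = runif(10, 1e-12, 1e-6))
  r2mat <- cor(g$dosage)^2
  oracle <- prune_oracle(as.data.frame(assoc), r2mat, 0.1, 5e5)
  out <- ld_prune(assoc, g$dosage)
  expect_identical(out$SNP, oracle)
  shuffled <- assoc[sample(nrow(assoc))]
  expect_identical(ld_prune(shuffled, g$dosage)$SNP, oracle)
})

test_that("inverse-variance meta-analysis arithmetic and symmetry", {
  a <- data.table::data.table(SNP = "s", EA = "A", RA = "G", BETA = 0.1,
                              SE = 0.1, N = 100L)
  b <- data.table::data.table(SNP = "s", EA = "A", RA = "G", BETA = 0.3,
                              SE = 0.1, N = 100L)
  m <- meta_analyze(a, b)
  expect_equal(m$BETA, 0.2)
  expect_equal(m$SE, 0.1 / sqrt(2), tolerance = 1e-10)
  # symmetry
  m2 <- meta_analyze(b, a)
  expect_equal(m$BETA, m2$BETA)
  expect_equal(m$SE, m2$SE)
  # identical studies halve the variance
  mm <- meta_analyze(a, a)
  expect_equal(mm$BETA, a$BETA)
  expect_equal(mm$SE, a$SE / sqrt(2))
  expect_lte(mm$SE, min(a$SE, a$SE))
  # one uninformative study leaves the other unchanged
  wide <- data.table::data.table(SNP = "s", EA = "A", RA = "G",
                                 BETA = 5, SE = 1e6, N = 10L)
  m3 <- meta_analyze(a, wide)
  expect_equal(m3$BETA, a$BETA, tolerance = 1e-6)
  expect_equal(m3$SE, a$SE, tolerance = 1e-6)
})

test_that("meta-analysis aligns swapped and strand-flipped alleles and
           drops ambiguous ones", {
  a <- data.table::data.table(SNP = c("s1", "s2", "s3", "s4"),
                              EA = c("A", "A", "A", "A"),
                              RA = c("G", "G", "G", "T"),
                              BETA = c(0.2, 0.2, 0.2, 0.2),
                              SE = rep(0.1, 4), N = rep(50L, 4))
  b <- data.table::data.table(SNP = c("s1", "s2", "s3", "s4"),
                              EA = c("G", "T", "C", "T"),
                              RA = c("A", "C", "T", "A"),
                              BETA = c(-0.2, 0.2, -0.2, 0.2),
                              SE = rep(0.1, 4), N = rep(50L, 4))
  m <- meta_analyze(a, b)
  # s1 swapped (sign flip), s2 strand-flipped (kept), s3 strand+swap
  # (sign flip), s4 palindromic swapped (ambiguous, dropped)
  expect_setequal(m$SNP, c("s1", "s2", "s3"))
  expect_equal(m$BETA, rep(0.2, 3))
  expect_identical(attr(m, "dropped"), "s4")
})

test_that("BH replication follows the step-up rule and agrees with
           p.adjust", {
  p <- c(a = 0.001, b = 0.002, c = 0.9, d = 0.95)
  expect_setequal(bh_replicate(p, 0.1), c("a", "b"))
  expect_identical(length(bh_replicate(rep(1, 4), 0.1)), 0L)
  expect_identical(bh_replicate(c(x = 0.04), 0.05), "x")
  set.seed(53)
  pr <- runif(200)^1.5
  names(pr) <- paste0("p", seq_along(pr))
  mine <- bh_replicate(pr, 0.2)
  ref <- names(pr)[p.adjust(pr, "BH") <= 0.2]
  expect_setequal(mine, ref)
  expect_identical(bh_replicate(numeric(0), 0.1), integer(0))
})

test_that("effect-size concordance: exact, negated and sampled cases", {
  d <- data.table::data.table(SNP = paste0("s", 1:10), EA = "A", RA = "G",
                              BETA = c(seq(-0.5, -0.1, 0.1), seq(0.1, 0.5, 0.1)))
  same <- effect_size_concordance(d, d)
  expect_equal(same$r, 1)
  expect_identical(same$n_same_sign, 10L)
  neg <- data.table::copy(d)[, BETA := -BETA]
  opp <- effect_size_concordance(d, neg)
  expect_equal(opp$r, -1)
  expect_identical(opp$n_same_sign, 0L)
  set.seed(54)
  n <- 150
  b1 <- rnorm(n); b2 <- 0.4 * b1 + sqrt(1 - 0.16) * rnorm(n)
  dd <- data.table::data.table(SNP = paste0("r", 1:n), EA = "A", RA = "G",
                               BETA = b1)
  rr <- data.table::copy(dd)[, BETA := b2]
  est <- effect_size_concordance(dd, rr)
  expect_lt(abs(est$r - 0.4), 3 / sqrt(n))
  expect_error(effect_size_concordance(d[1:2], d[1:2]), "at least 3")
})
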