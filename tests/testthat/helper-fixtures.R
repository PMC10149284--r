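# shared small fixtures, built once per test run

# circular arc sampled at n points: radius r, angle theta
arc_points <- function(theta, r = 1, n = 1000, phase = 0) {
  a <- seq(phase, phase + theta, length.out = n)
  cbind(x = r * cos(a), y = r * sin(a))
}

# closed form for the distance factor of a circular arc
arc_df <- function(theta) theta / (2 * sin(theta / 2))

# brute-force greedy LD pruning oracle: mirrors the documented rule with
# an independent, direct implementation over a precomputed r2 matrix
prune_oracle <- function(assoc, r2mat, r2_max, dist_bp) {
  ord <- order(assoc$P, assoc$CHR, assoc$BP, assoc$SNP)
  assoc <- assoc[ord, ]
  r2mat <- r2mat[ord, ord, drop = FALSE]
  alive <- rep(TRUE, nrow(assoc))
  leads <- character(0)
  for (i in seq_len(nrow(assoc))) {
    if (!alive[i]) next
    leads <- c(leads, assoc$SNP[i])
    for (j in seq_len(nrow(assoc))) {
      if (j <= i || !alive[j]) next
      same_chr <- assoc$CHR[j] == assoc$CHR[i]
      near <- same_chr && abs(assoc$BP[j] - assoc$BP[i]) <= dist_bp
      if (near && r2mat[i, j] >= r2_max) alive[j] <- FALSE
    }
  }
  leads
}

# tiny deterministic genotype fixture shared across association tests
make_small_sim <- function(seed = 42, n = 300, m = 200) {
  cfg <- sim_config(n_subjects = n, n_snps = m, n_causal = 5, seed = seed)
  geno <- gen_genotypes(cfg)
  phen <- gen_phenotype_direct(cfg, geno)
  list(cfg = cfg, geno = geno, phen = phen)
}

mpmath_available <- function() {
  Sys.which("python") != "" &&
    system2("python", c("-c", shQuote("import mpmath")), stdout = FALSE,
            stderr = FALSE) == 0
}

# multiple-precision oracle for the weighted chi-squared tail (mpmath)
mpmath_neglog10 <- function(weights, t, digits = 50) {
  script <- system.file("tools", "wsumchi2_oracle.py", package = "tortgwas")
  out <- system2("python", c(script, digits, format(t, digits = 17),
                             format(weights, digits = 17)),
                 stdout = TRUE)
  out[length(out)]
}
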