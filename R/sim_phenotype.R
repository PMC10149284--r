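#' Generate an additive polygenic phenotype with known ground truth
#'
#' Chooses `n_causal` causal SNPs (one per LD block while blocks last, so
#' causal signals are spread over the genome), draws their effects, scales
#' the genetic score so its empirical variance equals `h2_target`, and adds
#' age/sex confounder effects plus Gaussian noise of variance
#' `1 - h2_target`. The returned ground truth records the causal SNPs,
#' their betas on the standardized-dosage scale, and the realized
#' heritability var(g) / var(g + e) computed from the noiseless components.
#'
#' @param cfg a [sim_config()].
#' @param genotypes output of [gen_genotypes()].
#' @param equal_effects if `TRUE` all causal SNPs get effects of equal
#'   magnitude (random sign); otherwise effects are standard normal before
#'   rescaling.
#' @return List with `phenotype` (data.table: `subject`, `y`, `age`, `sex`,
#'   `genetic_value`) and `truth` (list: `causal_snp_ids`, `causal_betas`,
#'   `realized_h2`, `h2_target`).
#' @export
gen_phenotype_direct <- function(cfg, genotypes, equal_effects = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$h2_target >= 1) stop("h2_target must be < 1")
  set.seed(substream_seed(cfg$seed, "phenotype"))
  n <- cfg$n_subjects
  meta <- genotypes$meta
  G <- genotypes$dosage
  stopifnot(nrow(G) == n)

  nc <- cfg$n_causal
  causal <- integer(0)
  if (nc > 0) {
    blocks <- unique(meta$block)
    # one causal SNP per block while distinct blocks last; common SNPs only
    common <- which(meta$maf_true >= 0.01)
    picked <- integer(0)
    use_blocks <- sample(blocks, min(nc, length(blocks)))
    for (blk in use_blocks) {
      cand <- intersect(which(meta$block == blk), common)
      if (length(cand) > 0) picked <- c(picked, sample(cand, 1))
    }
    extra <- nc - length(picked)
    if (extra > 0) {
      pool <- setdiff(common, picked)
      picked <- c(picked, sample(pool, min(extra, length(pool))))
    }
    causal <- sort(picked)
  }

  g <- rep(0, n)
  betas <- numeric(0)
  if (length(causal) > 0 && cfg$h2_target > 0) {
    X <- scale(G[, causal, drop = FALSE])
    betas <- if (equal_effects) sample(c(-1, 1), length(causal), TRUE)
             else stats::rnorm(length(causal))
    g_raw <- as.numeric(X %*% betas)
    sc <- sqrt(cfg$h2_target) / stats::sd(g_raw)
    betas <- betas * sc
    g <- g_raw * sc
  }
  e <- stats::rnorm(n, 0, sqrt(1 - cfg$h2_target))
  age <- stats::rnorm(n, 56, 8)
  sex <- stats::rbinom(n, 1, 0.54)  # 1 = female
  y <- g + e + cfg$age_beta * (age - 56) / 8 + cfg$sex_beta * sex
  realized_h2 <- if (stats::var(g + e) > 0) stats::var(g) / stats::var(g + e)
                 else 0
  subj <- sprintf("S%05d", seq_len(n))
  list(
    phenotype = data.table::data.table(subject = subj, y = y, age = age,
                                       sex = sex, genetic_value = g),
    truth = list(causal_snp_ids = meta$snp[causal], causal_betas = betas,
                 realized_h2 = realized_h2, h2_target = cfg$h2_target)
  )
}

#' Generate binary disease status driven by a standardized phenotype
#'
#' Status is drawn from a logistic model
#' \eqn{logit P(D=1) = b_0 + b_1 z + b_{age} (age-56)/8 + b_{sex} sex}
#' where z is the standardized phenotype; used to exercise the
#' phenotype-disease association stage with known slope.
#'
#' @param phenotype data.table with `subject`, `y`, `age`, `sex`.
#' @param slope log-odds per SD of phenotype (default 0.19, the order of
#'   the hypertension association reported for arterial tortuosity).
#' @param prevalence approximate disease prevalence (controls the
#'   intercept).
#' @param age_lor,sex_lor log-odds for standardized age and female sex.
#' @param seed integer seed.
#' @return data.table `subject`, `status` (0/1).
#' @export
gen_disease_status <- function(phenotype, slope = 0.19, prevalence = 0.3,
                               age_lor = 0.4, sex_lor = -0.1, seed = 1) {
  set.seed(substream_seed(seed, "disease"))
  z <- as.numeric(scale(phenotype$y))
  lin <- stats::qlogis(prevalence) + slope * z +
    age_lor * (phenotype$age - 56) / 8 + sex_lor * phenotype$sex
  status <- stats::rbinom(length(z), 1, stats::plogis(lin))
  data.table::data.table(subject = phenotype$subject, status = status)
}
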