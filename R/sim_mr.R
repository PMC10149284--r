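#' Generate two-sample summary statistics for Mendelian randomization
#'
#' Simulates per-SNP effects for an exposure and an outcome trait with a
#' known causal effect of the exposure on the outcome. Instrument effects
#' on the exposure are drawn from a two-component mixture (mostly strong,
#' some sub-threshold, to exercise the p < 5e-8 selection); outcome effects
#' are `causal_effect` times the exposure effect plus noise at the stated
#' standard error. A fraction of SNPs gets strand-ambiguous (A/T or C/G)
#' alleles and a small fraction is placed on a non-autosomal chromosome,
#' both of which instrument selection must remove. The reverse-direction
#' table uses an independent instrument set with its own (default zero)
#' causal effect of the outcome on the exposure.
#'
#' @param n_instruments number of candidate instruments per direction.
#' @param causal_effect true effect of exposure on outcome.
#' @param seed integer seed.
#' @param reverse_effect true effect of outcome on exposure (reverse
#'   direction), default 0.
#' @param se_exposure,se_outcome per-SNP standard errors.
#' @param strong_fraction fraction of instruments with genome-wide
#'   significant exposure effects.
#' @param ambiguous_fraction fraction of strand-ambiguous SNPs.
#' @param nonauto_fraction fraction of SNPs placed on chromosome 23.
#' @return List of two data.tables (`forward`, `reverse`) with columns
#'   `SNP`, `CHR`, `EA`, `RA`, `beta_exp`, `se_exp`, `p_exp`, `beta_out`,
#'   `se_out`, `p_out`, and `truth` (list with the causal effects).
#' @export
gen_mr_summary <- function(n_instruments, causal_effect, seed = 1,
                           reverse_effect = 0, se_exposure = 0.01,
                           se_outcome = 0.01, strong_fraction = 0.8,
                           ambiguous_fraction = 0.15,
                           nonauto_fraction = 0.05) {
  stopifnot(n_instruments >= 1)
  set.seed(substream_seed(seed, "mr"))
  one_direction <- function(effect, tag) {
    k <- n_instruments
    strong <- stats::runif(k) < strong_fraction
    beta_x <- ifelse(strong,
                     sample(c(-1, 1), k, TRUE) * stats::runif(k, 0.1, 0.3),
                     stats::rnorm(k, 0, se_exposure))
    se_x <- rep(se_exposure, k)
    p_x <- 2 * stats::pnorm(-abs(beta_x / se_x))
    beta_y <- effect * beta_x + stats::rnorm(k, 0, se_outcome)
    se_y <- rep(se_outcome, k)
    p_y <- 2 * stats::pnorm(-abs(beta_y / se_y))
    amb <- stats::runif(k) < ambiguous_fraction
    pal <- list(c("A", "T"), c("C", "G"))
    reg <- list(c("A", "G"), c("A", "C"), c("C", "T"), c("G", "T"))
    alleles <- lapply(seq_len(k), function(j) {
      a <- if (amb[j]) pal[[sample.int(2, 1)]] else reg[[sample.int(4, 1)]]
      if (stats::runif(1) < 0.5) rev(a) else a
    })
    chr <- ifelse(stats::runif(k) < nonauto_fraction, 23L,
                  sample.int(22, k, replace = TRUE))
    data.table::data.table(
      SNP = sprintf("rs9%s%05d", tag, seq_len(k)), CHR = chr,
      EA = vapply(alleles, `[`, "", 1), RA = vapply(alleles, `[`, "", 2),
      beta_exp = beta_x, se_exp = se_x, p_exp = p_x,
      beta_out = beta_y, se_out = se_y, p_out = p_y)
  }
  list(forward = one_direction(causal_effect, "F"),
       reverse = one_direction(reverse_effect, "R"),
       truth = list(causal_effect = causal_effect,
                    reverse_effect = reverse_effect))
}
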