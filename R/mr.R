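#' Select Mendelian-randomization instruments from exposure summary stats
#'
#' Keeps autosomal SNPs with exposure p-value below `p_max` (default the
#' genome-wide 5e-8), removes strand-ambiguous (A/T, C/G) variants whose
#' orientation cannot be resolved from the alleles, and greedily prunes
#' the survivors to pairwise r-squared below `r2_max` (default 0.01) in
#' order of ascending p-value.
#'
#' @param sumstats table with `SNP`, `CHR`, `EA`, `RA`, `beta_exp`,
#'   `se_exp`, `p_exp` (the [gen_mr_summary()] layout).
#' @param panel optional dosage matrix with SNP-named columns for LD
#'   pruning; `NULL` treats instruments as independent (no pruning).
#' @param p_max exposure significance threshold.
#' @param r2_max pairwise r-squared ceiling among instruments.
#' @return The selected rows, p-ascending. Errors if none survive.
#' @export
select_instruments <- function(sumstats, panel = NULL, p_max = 5e-8,
                               r2_max = 0.01) {
  d <- data.table::as.data.table(sumstats)
  d <- d[CHR %in% 1:22]
  d <- d[p_exp < p_max]
  amb <- (d$EA == "A" & d$RA == "T") | (d$EA == "T" & d$RA == "A") |
    (d$EA == "C" & d$RA == "G") | (d$EA == "G" & d$RA == "C")
  d <- d[!amb]
  data.table::setorder(d, p_exp, SNP)
  if (!is.null(panel) && nrow(d) > 1) {
    if (is.list(panel) && !is.matrix(panel)) panel <- panel$dosage
    have <- d$SNP %in% colnames(panel)
    if (!all(have)) {
      warning(sprintf("%d instrument(s) absent from panel; excluded",
                      sum(!have)))
      d <- d[have]
    }
    if (nrow(d) > 1) {
      Z <- scale(panel[, d$SNP, drop = FALSE])
      n <- nrow(Z)
      keep <- logical(nrow(d))
      for (i in seq_len(nrow(d))) {
        acc <- which(keep)
        if (length(acc) == 0) { keep[i] <- TRUE; next }
        r2 <- as.numeric(crossprod(Z[, i], Z[, acc, drop = FALSE]) /
                           (n - 1))^2
        keep[i] <- all(r2 < r2_max)
      }
      d <- d[keep]
    }
  }
  if (nrow(d) == 0) stop("no instruments survive selection")
  d[]
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effects IVW with first-order weights:
#' \eqn{\hat\beta = \sum \beta_X \beta_Y / se_Y^2 / \sum \beta_X^2/se_Y^2}
#' and \eqn{se = (\sum \beta_X^2 / se_Y^2)^{-1/2}}, the precision-weighted
#' average of the per-instrument Wald ratios
#' \eqn{\beta_Y/\beta_X}. With a single instrument this reduces to the
#' Wald ratio exactly. Optionally inflates the variance by the
#' multiplicative random-effects factor when the heterogeneity
#' \eqn{\chi^2} per df exceeds 1.
#'
#' @param dataset table with `beta_exp`, `beta_out`, `se_out` (alleles
#'   already harmonized: both betas on the same effect allele).
#' @param random_effects if `TRUE`, multiply the squared SE by
#'   max(Q/(k-1), 1).
#' @param direction label stored in the result.
#' @return List with `beta`, `se`, `p`, `n_instruments`, `direction`.
#' @export
ivw_estimate <- function(dataset, random_effects = FALSE,
                         direction = "exposure->outcome") {
  d <- data.table::as.data.table(dataset)
  stopifnot(nrow(d) >= 1, all(d$se_out > 0))
  if (all(d$beta_exp == 0)) stop("undefined estimate: all exposure effects 0")
  w <- d$beta_exp^2 / d$se_out^2
  beta <- sum(d$beta_exp * d$beta_out / d$se_out^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (random_effects && nrow(d) > 1) {
    qstat <- sum((d$beta_out - beta * d$beta_exp)^2 / d$se_out^2)
    se <- se * sqrt(max(qstat / (nrow(d) - 1), 1))
  }
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)),
       n_instruments = nrow(d), direction = direction)
}

#' Bidirectional two-sample Mendelian randomization
#'
#' Runs instrument selection and the IVW estimate in both directions of a
#' trait pair.
#'
#' @param forward summary table for exposure -> outcome (exposure columns
#'   are the instruments' trait).
#' @param reverse summary table for outcome -> exposure.
#' @param panel optional LD panel for instrument pruning.
#' @param p_max,r2_max instrument selection parameters.
#' @param labels direction labels, length 2.
#' @return List of two [ivw_estimate()] results, named by `labels`.
#' @export
bidirectional_mr <- function(forward, reverse, panel = NULL, p_max = 5e-8,
                             r2_max = 0.01,
                             labels = c("exposure->outcome",
                                        "outcome->exposure")) {
  fw <- select_instruments(forward, panel, p_max, r2_max)
  rv <- select_instruments(reverse, panel, p_max, r2_max)
  res <- list(ivw_estimate(fw, direction = labels[1]),
              ivw_estimate(rv, direction = labels[2]))
  names(res) <- labels
  res
}

#' Cohen's d standardized mean difference
#'
#' \eqn{d = (\bar x_A - \bar x_B) / s_p} with the pooled standard
#' deviation using the \eqn{n_A + n_B - 2} denominator.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return Scalar d.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sqrt(sp2)
}
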