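#' SNP quality-control filter on MAF and imputation quality
#'
#' Keeps SNPs whose minor allele frequency `min(freq, 1 - freq)` is at
#' least `maf_min` and whose imputation info score is at least `info_min`.
#' Defaults follow the association protocol: MAF floor 5e-4 (chosen so a
#' biobank-scale sample still carries dozens of minor alleles) and info
#' floor 0.3.
#'
#' @param meta SNP metadata table with `freq` and `info` columns.
#' @param maf_min minimum minor allele frequency (SNPs strictly below are
#'   removed).
#' @param info_min minimum info score (SNPs strictly below are removed).
#' @return List with `kept` (filtered table) and `log` (data.table of
#'   excluded SNPs and the rule each violated).
#' @export
filter_snps <- function(meta, maf_min = 5e-4, info_min = 0.3) {
  meta <- data.table::as.data.table(meta)
  if (!all(c("freq", "info") %in% names(meta))) {
    stop("metadata must have 'freq' and 'info' columns")
  }
  maf <- pmin(meta$freq, 1 - meta$freq)
  bad_maf <- maf < maf_min
  bad_info <- meta$info < info_min
  reason <- ifelse(bad_maf & bad_info, "maf;info",
                   ifelse(bad_maf, "maf", ifelse(bad_info, "info", "")))
  log <- data.table::data.table(snp = meta$snp[reason != ""],
                                reason = reason[reason != ""])
  list(kept = meta[reason == ""], log = log)
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard normal quantiles
#' \eqn{\Phi^{-1}((rank - 0.5)/n)} with ties receiving the average rank.
#' Order is preserved and the result has mean near zero.
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return Transformed vector of the same length (`NA`s preserved).
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 2) stop("need at least 2 non-missing values")
  if (length(unique(v)) == 1) stop("all values identical: all-ties error")
  r <- rank(v)
  out <- values
  out[ok] <- stats::qnorm((r - 0.5) / length(v))
  out
}

#' Select genotype principal components correlated with the phenotype
#'
#' Returns the indices of PCs whose two-sided Pearson correlation test
#' with the phenotype has p < alpha; only such PCs enter the association
#' model as covariates.
#'
#' @param phenotype numeric vector.
#' @param pcs numeric matrix, one PC per column.
#' @param alpha significance level (default 0.05).
#' @return Integer vector of selected column indices.
#' @export
select_covariate_pcs <- function(phenotype, pcs, alpha = 0.05) {
  pcs <- as.matrix(pcs)
  stopifnot(nrow(pcs) == length(phenotype), alpha > 0, alpha <= 1)
  sel <- logical(ncol(pcs))
  for (j in seq_len(ncol(pcs))) {
    if (stats::sd(pcs[, j]) == 0) {
      warning(sprintf("PC %d has zero variance; skipped", j))
      next
    }
    if (alpha >= 1) { sel[j] <- TRUE; next }
    sel[j] <- stats::cor.test(phenotype, pcs[, j])$p.value < alpha
  }
  which(sel)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of (effective) independent tests.
#' @return `alpha / n_tests`. With the conventional 1 million independent
#'   SNPs this gives the genome-wide 5e-8 threshold.
#' @examples
#' bonferroni_threshold(0.05, 1e6)    # 5e-8
#' bonferroni_threshold(0.05, 25489)  # ~2.0e-6, gene-based tests
#' bonferroni_threshold(0.05, 54)     # ~9.2e-4, tissues
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}
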