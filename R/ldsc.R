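#' Per-SNP LD scores from a genotype reference panel
#'
#' The LD score of SNP j is \eqn{\ell_j = \sum_k r^2_{jk}} over SNPs k
#' within `window_bp` on the same chromosome (including itself, r2 = 1).
#' Squared correlations are adjusted for sampling noise with the standard
#' unbiased correction \eqn{r^2_{adj} = r^2 - (1 - r^2)/(n - 2)}.
#'
#' @param panel dosage matrix (individuals x SNPs) or [gen_genotypes()]
#'   output.
#' @param meta SNP metadata with `snp`, `chr`, `pos` (taken from the
#'   generator output when available).
#' @param window_bp window radius in base pairs (default 1e6).
#' @return data.table `snp`, `chr`, `pos`, `ld_score`.
#' @export
ld_scores <- function(panel, meta = NULL, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be positive")
  if (is.list(panel) && !is.matrix(panel)) {
    if (is.null(meta)) meta <- panel$meta
    panel <- panel$dosage
  }
  G <- as.matrix(panel)
  n <- nrow(G)
  if (n < 100) stop("reference panel should have at least 100 individuals")
  meta <- data.table::as.data.table(meta)
  stopifnot(ncol(G) == nrow(meta))
  Z <- scale(G)
  sd0 <- attr(Z, "scaled:scale") == 0
  if (any(sd0)) Z[, sd0] <- 0  # monomorphic SNPs contribute nothing
  ell <- numeric(ncol(G))
  chunk <- 256L
  for (cc in unique(meta$chr)) {
    idx <- which(meta$chr == cc)
    pos <- meta$pos[idx]
    starts <- seq(1, length(idx), by = chunk)
    for (s in starts) {
      j <- idx[s:min(s + chunk - 1, length(idx))]
      lo <- min(meta$pos[j]) - window_bp
      hi <- max(meta$pos[j]) + window_bp
      k <- idx[pos >= lo & pos <= hi]
      r <- crossprod(Z[, j, drop = FALSE], Z[, k, drop = FALSE]) / (n - 1)
      r2 <- r^2
      r2 <- r2 - (1 - r2) / (n - 2)
      # zero out pairs outside the per-SNP window
      dist_ok <- abs(outer(meta$pos[j], meta$pos[k], "-")) <= window_bp
      ell[j] <- rowSums(r2 * dist_ok)
    }
  }
  data.table::data.table(snp = meta$snp, chr = meta$chr, pos = meta$pos,
                         ld_score = ell)
}

#' SNP heritability by LD score regression
#'
#' Regresses per-SNP association \eqn{\chi^2_j = (\beta_j/se_j)^2} on LD
#' scores: under a polygenic model
#' \eqn{E[\chi^2_j] = 1 + n h^2 \ell_j / m} (plus an intercept shift from
#' confounding), so the weighted-least-squares slope estimates
#' \eqn{n h^2 / m} and the intercept should be near 1 in the absence of
#' stratification. Weights are \eqn{1/\max(\ell_j, 1)} with one
#' reweighting iteration by the fitted variance factor
#' \eqn{(1 + n \hat h^2 \ell_j / m)^2}. Standard errors come from a
#' delete-one block jackknife over `n_blocks` contiguous SNP blocks.
#'
#' @param assoc association table (needs `BETA`, `SE`, `SNP`).
#' @param ld data.table from [ld_scores()] (needs `snp`, `ld_score`).
#' @param n GWAS sample size.
#' @param m number of SNPs the heritability is spread over (default:
#'   number of matched SNPs).
#' @param n_blocks jackknife blocks (default 200).
#' @return List with `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `lambda_gc`, `mean_chi2`, `ratio` ((intercept-1)/(mean_chi2-1), NA
#'   when mean_chi2 <= 1), `n`, `m`.
#' @export
ldsc_heritability <- function(assoc, ld, n, m = NULL, n_blocks = 200) {
  assoc <- data.table::as.data.table(assoc)
  ld <- data.table::as.data.table(ld)
  dt <- merge(assoc[, .(SNP, BETA, SE)], ld[, .(SNP = snp, ld_score)],
              by = "SNP", sort = FALSE)
  dt <- dt[is.finite(BETA) & is.finite(SE) & SE > 0]  # drop monomorphic
  if (nrow(dt) < n_blocks) {
    stop(sprintf("need at least %d matched SNPs for the jackknife",
                 n_blocks))
  }
  if (is.null(m)) m <- nrow(dt)
  chi2 <- (dt$BETA / dt$SE)^2
  ell <- dt$ld_score

  fit_wls <- function(keep) {
    x <- ell[keep]; y <- chi2[keep]
    w <- 1 / pmax(x, 1)
    f <- stats::lm.wfit(cbind(1, x), y, w)
    slope <- f$coefficients[2]
    h2 <- slope * m / n
    w2 <- w / pmax(1 + (n * max(h2, 0) / m) * x, 0.1)^2
    f2 <- stats::lm.wfit(cbind(1, x), y, w2)
    c(intercept = unname(f2$coefficients[1]),
      h2 = unname(f2$coefficients[2]) * m / n)
  }
  full <- fit_wls(rep(TRUE, nrow(dt)))
  blocks <- cut(seq_len(nrow(dt)), breaks = n_blocks, labels = FALSE)
  jk <- vapply(seq_len(n_blocks), function(bk) fit_wls(blocks != bk),
               numeric(2))
  jk_se <- sqrt((n_blocks - 1) / n_blocks *
                  rowSums((jk - rowMeans(jk))^2))
  mean_chi2 <- mean(chi2)
  list(h2 = unname(full["h2"]), h2_se = unname(jk_se["h2"]),
       intercept = unname(full["intercept"]),
       intercept_se = unname(jk_se["intercept"]),
       lambda_gc = stats::median(chi2) / stats::qchisq(0.5, 1),
       mean_chi2 = mean_chi2,
       ratio = if (mean_chi2 > 1) (unname(full["intercept"]) - 1) /
                 (mean_chi2 - 1) else NA_real_,
       n = n, m = m)
}
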