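#' Per-SNP linear association with joint covariate adjustment
#'
#' For every SNP, fits ordinary least squares of the phenotype on the
#' dosage plus covariates (age, sex, selected genotype PCs, ...) and
#' reports the dosage effect, its standard error, and a two-sided p-value
#' from the normal approximation (the GWAS convention; at small n this is
#' slightly anticonservative relative to the t reference).
#'
#' The covariates enter the model jointly. Computation uses the
#' Frisch-Waugh-Lovell projection — phenotype and dosages are residualized
#' on the intercept-augmented covariates once, then each SNP needs a
#' single inner product — which reproduces the joint fit exactly,
#' including the residual degrees of freedom `n - p - 2`.
#'
#' @param phenotype numeric vector (already transformed as desired).
#' @param genotypes dosage matrix, subjects x SNPs (column names = SNP
#'   ids), or the list returned by [gen_genotypes()].
#' @param covariates optional numeric matrix/data.frame of covariates
#'   (no intercept column; one is added internally).
#' @param meta SNP metadata (`snp`, `chr`, `pos`, `ea`, `ra`, `freq`);
#'   taken from `genotypes$meta` when a generator result is passed.
#' @return data.table of association records with columns `CHR`, `SNP`,
#'   `BP`, `EA`, `RA`, `FREQ`, `BETA`, `SE`, `P`, `N` and `NEG_LOG10_P`
#'   (computed in log space, exact beyond the double underflow of P).
#' @export
run_gwas <- function(phenotype, genotypes, covariates = NULL, meta = NULL) {
  if (is.list(genotypes) && !is.matrix(genotypes)) {
    if (is.null(meta)) meta <- genotypes$meta
    genotypes <- genotypes$dosage
  }
  G <- as.matrix(genotypes)
  n <- length(phenotype)
  stopifnot(nrow(G) == n)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  cc <- stats::complete.cases(phenotype, X)
  y <- phenotype[cc]; X <- X[cc, , drop = FALSE]; G <- G[cc, , drop = FALSE]
  n <- length(y)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("collinear covariates: %s", paste(bad, collapse = ", ")))
  }
  y_r <- stats::resid(stats::lm.fit(X, y))
  G_r <- G - X %*% qr.coef(qrX, G)
  gg <- colSums(G_r^2)
  gy <- as.numeric(crossprod(G_r, y_r))
  df <- n - ncol(X) - 1
  beta <- ifelse(gg > 0, gy / gg, NA_real_)
  rss <- sum(y_r^2) - ifelse(gg > 0, beta^2 * gg, 0)
  se <- sqrt(pmax(rss, 0) / df / gg)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  nl10 <- -(stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) +
              log(2)) / log(10)
  ids <- colnames(G)
  if (is.null(meta)) {
    meta <- data.table::data.table(snp = ids, chr = NA_integer_,
                                   pos = NA_integer_, ea = NA_character_,
                                   ra = NA_character_,
                                   freq = colMeans(G) / 2)
  }
  meta <- data.table::as.data.table(meta)
  m <- meta[match(ids, meta$snp)]
  data.table::data.table(
    CHR = m$chr, SNP = ids, BP = m$pos, EA = m$ea, RA = m$ra,
    FREQ = m$freq, BETA = beta, SE = se, P = p, N = n,
    NEG_LOG10_P = nl10)
}

#' Genomic-control and mean-chi-squared inflation diagnostics
#'
#' \eqn{\lambda_{GC}} is the median association \eqn{\chi^2 = (\beta/se)^2}
#' divided by the null median of \eqn{\chi^2_1}
#' (`qchisq(0.5, 1)` = 0.4549364...); values near 1 indicate no inflation.
#'
#' @param assoc association table from [run_gwas()] (or any table with
#'   `BETA` and `SE`).
#' @return List with `lambda_gc`, `mean_chi2`, `n_snps`.
#' @export
genomic_diagnostics <- function(assoc) {
  chi2 <- (assoc$BETA / assoc$SE)^2
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) < 100) stop("need at least 100 SNPs for diagnostics")
  list(lambda_gc = stats::median(chi2) / stats::qchisq(0.5, 1),
       mean_chi2 = mean(chi2), n_snps = length(chi2))
}
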