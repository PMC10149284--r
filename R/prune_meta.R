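#' LD pruning of significant SNPs to independent lead SNPs
#'
#' Greedy selection in order of ascending p-value (ties broken by
#' chromosome, position, SNP id): the most significant remaining SNP is
#' accepted as a lead, and every remaining SNP that is BOTH within
#' `dist_bp` of it AND has dosage r-squared at least `r2_max` with it is
#' discarded. Two SNPs therefore count as independent if their r2 is below
#' the threshold OR they are farther apart than `dist_bp` (different
#' chromosomes are always far apart).
#'
#' @param assoc significant association records (`SNP`, `CHR`, `BP`, `P`).
#' @param panel dosage matrix with SNP-named columns (or [gen_genotypes()]
#'   output) used to estimate r-squared.
#' @param r2_max r-squared threshold (default 0.1).
#' @param dist_bp distance threshold in bases (default 5e5).
#' @return data.table of lead SNPs (rows of `assoc`) with a `LOCUS_ID`
#'   column numbering the loci in acceptance order.
#' @export
ld_prune <- function(assoc, panel, r2_max = 0.1, dist_bp = 5e5) {
  assoc <- data.table::as.data.table(assoc)
  if (nrow(assoc) == 0) return(cbind(assoc, LOCUS_ID = integer(0)))
  if (is.list(panel) && !is.matrix(panel)) panel <- panel$dosage
  missing <- setdiff(assoc$SNP, colnames(panel))
  if (length(missing) > 0) {
    warning(sprintf("%d SNP(s) absent from the panel; excluded: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")))
    assoc <- assoc[!SNP %in% missing]
    if (nrow(assoc) == 0) return(cbind(assoc, LOCUS_ID = integer(0)))
  }
  data.table::setorder(assoc, P, CHR, BP, SNP)
  Z <- scale(panel[, assoc$SNP, drop = FALSE])
  n <- nrow(Z)
  active <- rep(TRUE, nrow(assoc))
  lead <- integer(0)
  for (i in seq_len(nrow(assoc))) {
    if (!active[i]) next
    lead <- c(lead, i)
    cand <- which(active)
    cand <- cand[cand > i]
    if (length(cand) == 0) next
    near <- cand[assoc$CHR[cand] == assoc$CHR[i] &
                   abs(assoc$BP[cand] - assoc$BP[i]) <= dist_bp]
    if (length(near) == 0) next
    r2 <- as.numeric(crossprod(Z[, i], Z[, near, drop = FALSE]) / (n - 1))^2
    active[near[r2 >= r2_max]] <- FALSE
  }
  out <- assoc[lead]
  out[, LOCUS_ID := seq_len(.N)]
  out[]
}

#' Inverse-variance-weighted meta-analysis of two studies
#'
#' Records are matched by SNP id and allele-aligned first: when the
#' studies' effect alleles are swapped the second study's beta changes
#' sign; strand flips are resolved through allele complements, except for
#' strand-ambiguous (A/T, C/G) pairs whose complement equals a swap —
#' those keep their stated orientation when alleles match directly and are
#' dropped otherwise, as are all unalignable records. The combined effect
#' is \eqn{\beta = (\beta_A/se_A^2 + \beta_B/se_B^2)/(1/se_A^2 + 1/se_B^2)}
#' with \eqn{se = (1/se_A^2 + 1/se_B^2)^{-1/2}}.
#'
#' @param a,b association tables (`SNP`, `EA`, `RA`, `BETA`, `SE`, and
#'   optionally `FREQ`, `N`).
#' @return data.table of combined records (columns as `a` plus updated
#'   `BETA`, `SE`, `P`, `N`); attribute `"dropped"` lists unalignable SNPs.
#' @export
meta_analyze <- function(a, b) {
  a <- data.table::as.data.table(a); b <- data.table::as.data.table(b)
  m <- merge(a, b, by = "SNP", suffixes = c("_a", "_b"))
  comp <- function(x) chartr("ACGT", "TGCA", x)
  same <- m$EA_a == m$EA_b & m$RA_a == m$RA_b
  swapped <- m$EA_a == m$RA_b & m$RA_a == m$EA_b
  flip_same <- m$EA_a == comp(m$EA_b) & m$RA_a == comp(m$RA_b)
  flip_swap <- m$EA_a == comp(m$RA_b) & m$RA_a == comp(m$EA_b)
  palindromic <- m$EA_b == comp(m$RA_b)
  sign_b <- rep(NA_real_, nrow(m))
  sign_b[flip_swap & !palindromic] <- -1
  sign_b[flip_same & !palindromic] <- 1
  sign_b[swapped & !palindromic] <- -1
  sign_b[same] <- 1  # direct match, incl. palindromic as stated
  dropped <- m$SNP[is.na(sign_b)]
  m <- m[!is.na(sign_b)]
  sign_b <- sign_b[!is.na(sign_b)]
  wa <- 1 / m$SE_a^2; wb <- 1 / m$SE_b^2
  beta <- (m$BETA_a * wa + sign_b * m$BETA_b * wb) / (wa + wb)
  se <- 1 / sqrt(wa + wb)
  out <- data.table::data.table(
    SNP = m$SNP, EA = m$EA_a, RA = m$RA_a,
    BETA = beta, SE = se, P = 2 * stats::pnorm(-abs(beta / se)),
    N = if (all(c("N_a", "N_b") %in% names(m))) m$N_a + m$N_b else NA_integer_)
  if (all(c("CHR_a", "BP_a") %in% names(m))) {
    out[, `:=`(CHR = m$CHR_a, BP = m$BP_a)]
  }
  data.table::setattr(out, "dropped", dropped)
  out[]
}

#' Benjamini-Hochberg replication of candidate SNPs
#'
#' Applies the step-up false-discovery-rate rule to the replication
#' p-values of the discovery-significant candidates: with ordered p-values
#' \eqn{p_{(1)} \le ... \le p_{(m)}}, the largest k with
#' \eqn{p_{(k)} \le k \cdot fdr / m} determines the replicated set.
#'
#' @param p named (or unnamed) vector of replication p-values of the
#'   candidates.
#' @param fdr target false discovery rate.
#' @return Indices (or names, if `p` is named) of replicated entries, in
#'   ascending p order; empty when none replicate.
#' @export
bh_replicate <- function(p, fdr = 0.05) {
  if (length(p) == 0) return(integer(0))
  stopifnot(all(p > 0 & p <= 1), fdr > 0, fdr < 1)
  o <- order(p)
  m <- length(p)
  ok <- p[o] <= seq_len(m) * fdr / m
  k <- if (any(ok)) max(which(ok)) else 0
  res <- o[seq_len(k)]
  if (!is.null(names(p))) names(p)[res] else res
}

#' Effect-size concordance between discovery and replication
#'
#' Pearson correlation of the allele-aligned effect estimates, its
#' two-sided t-test p-value (n - 2 df), and the number of SNPs whose
#' effect has the same sign in both studies.
#'
#' @param discovery,replication association tables with `SNP`, `EA`, `RA`,
#'   `BETA`.
#' @return List with `r`, `p`, `n_same_sign`, `n`.
#' @export
effect_size_concordance <- function(discovery, replication) {
  a <- data.table::as.data.table(discovery)
  b <- data.table::as.data.table(replication)
  m <- merge(a[, .(SNP, EA, RA, BETA)], b[, .(SNP, EA, RA, BETA)],
             by = "SNP", suffixes = c("_a", "_b"))
  comp <- function(x) chartr("ACGT", "TGCA", x)
  sgn <- rep(NA_real_, nrow(m))
  sgn[(m$EA_a == m$RA_b & m$RA_a == m$EA_b) |
        (m$EA_a == comp(m$RA_b) & m$RA_a == comp(m$EA_b))] <- -1
  sgn[(m$EA_a == m$EA_b & m$RA_a == m$RA_b) |
        (m$EA_a == comp(m$EA_b) & m$RA_a == comp(m$RA_b))] <- 1
  m <- m[!is.na(sgn)]
  sgn <- sgn[!is.na(sgn)]
  if (nrow(m) < 3) stop("need at least 3 matched SNPs")
  bb <- sgn * m$BETA_b
  ct <- stats::cor.test(m$BETA_a, bb)
  list(r = unname(ct$estimate), p = ct$p.value,
       n_same_sign = sum(sign(m$BETA_a) == sign(bb)), n = nrow(m))
}
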