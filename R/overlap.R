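#' Overlap of lead SNPs with a disease-variant catalogue
#'
#' Reports exact id matches (r2 recorded as 1) and LD-proxy matches: a
#' lead SNP counts as shared with a catalogue SNP when their panel
#' r-squared exceeds `r2_proxy` (default 0.8). Per-trait counts aggregate
#' distinct lead SNPs, and only traits reaching `min_count` shared
#' associations are reported in the count table.
#'
#' @param leads lead-SNP table (`SNP`; ignored columns pass through).
#' @param catalogue table with `SNP`, `TRAIT`, `MAPPED_GENE`.
#' @param panel optional dosage matrix with SNP-named columns covering
#'   both lead and catalogue SNPs; `NULL` restricts to exact matches.
#' @param r2_proxy proxy threshold (strictly greater-than).
#' @param min_count minimum shared associations for the per-trait table.
#' @return List with `overlaps` (data.table `lead_snp`, `catalogue_snp`,
#'   `r2`, `trait`, `mapped_gene`) and `trait_counts` (`trait`, `n_shared`,
#'   filtered at `min_count`).
#' @export
catalogue_overlap <- function(leads, catalogue, panel = NULL,
                              r2_proxy = 0.8, min_count = 5) {
  leads <- data.table::as.data.table(leads)
  catalogue <- data.table::as.data.table(catalogue)
  if (is.list(panel) && !is.matrix(panel)) panel <- panel$dosage
  rows <- list()
  for (i in seq_len(nrow(leads))) {
    ls <- leads$SNP[i]
    exact <- catalogue[SNP == ls]
    if (nrow(exact) > 0) {
      rows[[length(rows) + 1]] <- data.table::data.table(
        lead_snp = ls, catalogue_snp = ls, r2 = 1,
        trait = exact$TRAIT, mapped_gene = exact$MAPPED_GENE)
    }
    if (!is.null(panel)) {
      if (!ls %in% colnames(panel)) next  # exact-match only for this SNP
      others <- catalogue[SNP != ls & SNP %in% colnames(panel)]
      if (nrow(others) == 0) next
      z1 <- as.numeric(scale(panel[, ls]))
      Z <- scale(panel[, unique(others$SNP), drop = FALSE])
      r2 <- as.numeric(crossprod(z1, Z) / (nrow(Z) - 1))^2
      names(r2) <- colnames(Z)
      hit <- others[r2[others$SNP] > r2_proxy]
      if (nrow(hit) > 0) {
        rows[[length(rows) + 1]] <- data.table::data.table(
          lead_snp = ls, catalogue_snp = hit$SNP, r2 = r2[hit$SNP],
          trait = hit$TRAIT, mapped_gene = hit$MAPPED_GENE)
      }
    }
  }
  overlaps <- data.table::rbindlist(rows)
  if (nrow(overlaps) == 0) {
    overlaps <- data.table::data.table(lead_snp = character(0),
                                       catalogue_snp = character(0),
                                       r2 = numeric(0), trait = character(0),
                                       mapped_gene = character(0))
  }
  counts <- overlaps[, .(n_shared = data.table::uniqueN(lead_snp)),
                     by = .(trait)]
  counts <- counts[n_shared >= min_count]
  data.table::setorder(counts, -n_shared)
  list(overlaps = overlaps, trait_counts = counts)
}

#' Association between a tortuosity phenotype and disease status
#'
#' Logistic regression of binary disease status on the standardized
#' phenotype, adjusting for age and sex; the reported beta is the log-odds
#' per phenotype standard deviation.
#'
#' @param phenotype numeric vector (standardized internally).
#' @param status binary 0/1 disease status.
#' @param age,sex optional covariates.
#' @return List with `beta`, `se`, `p`, `n_cases`, `n_controls`.
#' @export
disease_association <- function(phenotype, status, age = NULL, sex = NULL) {
  stopifnot(length(status) == length(phenotype),
            all(status %in% c(0, 1)))
  if (sum(status) == 0 || sum(status) == length(status)) {
    stop("degenerate outcome: zero cases or zero controls")
  }
  z <- as.numeric(scale(phenotype))
  df <- data.frame(status = status, z = z)
  form <- status ~ z
  if (!is.null(age)) { df$age <- age; form <- stats::update(form, . ~ . + age) }
  if (!is.null(sex)) { df$sex <- sex; form <- stats::update(form, . ~ . + sex) }
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("separation: fitted probabilities numerically 0 or 1")
      }
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients["z", ]
  list(beta = unname(co[1]), se = unname(co[2]),
       p = unname(co[4]), n_cases = sum(status),
       n_controls = sum(1 - status))
}
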