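#' Rank-based gene-set enrichment from gene scores
#'
#' Gene significance is reduced to ranks (rank 1 = most significant gene),
#' made uniform as \eqn{u_i = (rank_i - 0.5)/G} over all G scored genes,
#' transformed to 1-df chi-squared variables
#' \eqn{q_i = F^{-1}_{\chi^2_1}(1 - u_i)}, summed over the m member genes
#' of the set, and tested against a chi-squared distribution with m
#' degrees of freedom. Because only ranks enter, genes with extremely
#' inflated p-values cannot dominate — a deliberately conservative choice
#' for highly powered scans.
#'
#' @param scores data.table with `gene` and `neg_log10_p_raw` (or
#'   `neg_log10_p`) for all scored (fusion) genes.
#' @param members character vector of member gene ids (subset of the
#'   scored genes; unscored members are dropped with a message).
#' @return List with `p`, `statistic`, `df` (members used), `n_scored`.
#' @export
rank_enrichment <- function(scores, members) {
  scores <- data.table::as.data.table(scores)
  sc <- if ("neg_log10_p_raw" %in% names(scores)) scores$neg_log10_p_raw
        else scores$neg_log10_p
  G <- nrow(scores)
  stopifnot(G >= 1, length(members) >= 1)
  miss <- setdiff(members, scores$gene)
  if (length(miss) > 0) {
    message(sprintf("%d member gene(s) unscored; excluded", length(miss)))
    members <- setdiff(members, miss)
  }
  if (length(members) == 0) stop("no scored member genes in the set")
  rk <- rank(-sc)  # rank 1 = most significant
  u <- (rk - 0.5) / G
  q <- stats::qchisq(u, df = 1, lower.tail = FALSE)
  idx <- match(members, scores$gene)
  tstat <- sum(q[idx])
  m <- length(idx)
  list(p = stats::pchisq(tstat, df = m, lower.tail = FALSE),
       statistic = tstat, df = m, n_scored = G)
}

#' Score a GMT collection of gene sets
#'
#' @param scores scored-gene table (see [rank_enrichment()]).
#' @param sets named list of member vectors (e.g. from [read_gmt()]).
#' @return data.table `set`, `df`, `statistic`, `p`, sorted by p.
#' @export
enrich_gene_sets <- function(scores, sets) {
  res <- lapply(names(sets), function(nm) {
    r <- tryCatch(suppressMessages(rank_enrichment(scores, sets[[nm]])),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.table::data.table(set = nm, df = r$df, statistic = r$statistic,
                           p = r$p)
  })
  out <- data.table::rbindlist(res)
  if (nrow(out) > 0) data.table::setorder(out, p)
  out
}

#' Tissue-wide expression enrichment of a gene set
#'
#' For each tissue, the expression of every gene is ranked (descending:
#' the most expressed gene gets rank 1, ties get average ranks), made
#' uniform, transformed to 1-df chi-squared variables and summed over the
#' set members, giving a chi-squared test with as many degrees of freedom
#' as there are (fusion) genes in the set. Tissues with
#' p < alpha / n_tissues are flagged (Bonferroni; with the reference
#' 54-tissue atlas and alpha 0.05 the threshold is 9.26e-4).
#'
#' @param expression numeric matrix genes x tissues (rownames = gene ids).
#' @param members character vector of set member gene ids.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @return data.table `tissue`, `df`, `statistic`, `p`, `significant`;
#'   attribute `"threshold"` holds the Bonferroni threshold.
#' @export
tissue_enrichment <- function(expression, members, alpha = 0.05) {
  expression <- as.matrix(expression)
  stopifnot(!is.null(rownames(expression)), ncol(expression) >= 1)
  if (any(expression < 0)) stop("expression values must be nonnegative")
  members <- intersect(members, rownames(expression))
  if (length(members) == 0) stop("no set member present in the matrix")
  G <- nrow(expression)
  thr <- bonferroni_threshold(alpha, ncol(expression))
  idx <- match(members, rownames(expression))
  res <- lapply(seq_len(ncol(expression)), function(tj) {
    e <- expression[, tj]
    if (stats::sd(e) == 0) {
      warning(sprintf("tissue %s has constant expression (tie-heavy ranks)",
                      colnames(expression)[tj]))
    }
    rk <- rank(-e)  # rank 1 = most expressed
    u <- (rk - 0.5) / G
    q <- stats::qchisq(u, df = 1, lower.tail = FALSE)
    tstat <- sum(q[idx])
    m <- length(idx)
    p <- stats::pchisq(tstat, df = m, lower.tail = FALSE)
    data.table::data.table(tissue = colnames(expression)[tj], df = m,
                           statistic = tstat, p = p,
                           significant = p < thr)
  })
  out <- data.table::rbindlist(res)
  data.table::setattr(out, "threshold", thr)
  out
}

#' Expression of fusion genes from member-gene expression
#'
#' The expression of a fusion gene is the sum of its members' values in
#' each tissue (merged entities pool their transcripts).
#'
#' @param expression genes x tissues matrix.
#' @param fusion fusion table from [fuse_genes()].
#' @return Matrix fusion-genes x tissues.
#' @export
fusion_expression <- function(expression, fusion) {
  expression <- as.matrix(expression)
  rows <- lapply(seq_len(nrow(fusion)), function(i) {
    mem <- intersect(fusion$members[[i]], rownames(expression))
    if (length(mem) == 0) return(rep(NA_real_, ncol(expression)))
    colSums(expression[mem, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- fusion$gene
  colnames(out) <- colnames(expression)
  out[stats::complete.cases(out), , drop = FALSE]
}
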