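#' Assign SNPs to genes by a padded window around the gene body
#'
#' A SNP belongs to a gene iff it lies on the same chromosome within
#' `window_bp` of the gene body: positions in
#' \[min(TSS,TES) - window_bp, max(TSS,TES) + window_bp\]. A SNP may
#' belong to several (overlapping or nearby) genes. With the default
#' symmetric 50-kb pad the window is identical for + and - strand genes; a
#' strand-aware mode anchors the pads at the TSS and the TES instead
#' (`before_tss_bp` upstream of the TSS, `after_tes_bp` downstream of the
#' TES), which coincides with the symmetric window when both pads are
#' equal.
#'
#' @param annotation gene table (`gene`, `chr`, `start`, `end`, `strand`,
#'   `tss`, `tes`, optionally `biotype`). Only `protein_coding` and
#'   `lincRNA` biotypes are retained when the column is present.
#' @param snp_meta SNP table (`snp`, `chr`, `pos`).
#' @param window_bp symmetric pad in bases (default 50000).
#' @return data.table mapping `gene` to `snp` (one row per pair), with
#'   `chr` and `pos`.
#' @export
assign_snps_to_genes <- function(annotation, snp_meta, window_bp = 5e4) {
  annotation <- data.table::as.data.table(annotation)
  snp_meta <- data.table::as.data.table(snp_meta)
  if ("biotype" %in% names(annotation)) {
    annotation <- annotation[biotype %in% c("protein_coding", "lincRNA")]
  }
  unknown <- setdiff(unique(snp_meta$chr), unique(annotation$chr))
  if (length(unknown) > 0) {
    warning(sprintf("SNPs on chromosome(s) %s match no gene; skipped",
                    paste(unknown, collapse = ", ")))
  }
  res <- lapply(seq_len(nrow(annotation)), function(i) {
    lo <- min(annotation$start[i], annotation$end[i]) - window_bp
    hi <- max(annotation$start[i], annotation$end[i]) + window_bp
    hit <- snp_meta[chr == annotation$chr[i] & pos >= lo & pos <= hi]
    if (nrow(hit) == 0) return(NULL)
    data.table::data.table(gene = annotation$gene[i], snp = hit$snp,
                           chr = hit$chr, pos = hit$pos)
  })
  data.table::rbindlist(res)
}

#' Fuse genes closer than a gap threshold into fusion genes
#'
#' Genes on the same chromosome whose body intervals are separated by
#' fewer than `gap_bp` intervening bases (overlapping genes included) are
#' merged transitively into a single "fusion gene" spanning the union of
#' the member bodies, absorbing co-association and co-expression of close
#' neighbours. SNP windows are then recomputed on the fused span.
#'
#' @param annotation gene table as in [assign_snps_to_genes()].
#' @param gap_bp fusion distance (default 100000; genes strictly less
#'   than 100 kb apart are fused).
#' @return data.table with `gene` (fusion id: member ids joined by "_"),
#'   `members` (list column), `n_members`, `chr`, `start`, `end`.
#' @export
fuse_genes <- function(annotation, gap_bp = 1e5) {
  ann <- data.table::as.data.table(annotation)
  if ("biotype" %in% names(ann)) {
    ann <- ann[biotype %in% c("protein_coding", "lincRNA")]
  }
  data.table::setorder(ann, chr, start, end)
  out <- list()
  for (cc in unique(ann$chr)) {
    a <- ann[chr == cc]
    grp <- integer(nrow(a))
    g <- 1L
    grp[1] <- g
    run_end <- a$end[1]
    if (nrow(a) > 1) {
      for (i in 2:nrow(a)) {
        gap <- a$start[i] - run_end - 1L  # intervening bases
        if (gap < gap_bp) {
          grp[i] <- g
          run_end <- max(run_end, a$end[i])
        } else {
          g <- g + 1L
          grp[i] <- g
          run_end <- a$end[i]
        }
      }
    }
    f <- a[, .(members = list(gene), n_members = .N,
               start = min(start), end = max(end)), by = .(grp)]
    f[, `:=`(chr = cc, gene = vapply(members, paste, "", collapse = "_"))]
    out[[length(out) + 1]] <- f[, .(gene, members, n_members, chr,
                                    start, end)]
  }
  data.table::rbindlist(out)
}

#' LD-aware gene score from SNP p-values
#'
#' The SNP p-values in the gene window are transformed to 1-df
#' chi-squared quantiles and summed: \eqn{T = \sum_i q_i} with
#' \eqn{q_i = F^{-1}_{\chi^2_1}(1 - p_i)}. Under the null, T is
#' distributed as a weighted sum of independent chi-squared(1) variables
#' whose weights are the eigenvalues of the SNP-SNP correlation matrix
#' ("eigen-SNPs"), and the gene p-value is its upper tail at T, evaluated
#' by [weighted_chi2_sf()]. The reported \eqn{-\log_{10} p} is capped at
#' `cap` (default 100, i.e. p = 1e-100) with a flag; the uncapped value is
#' retained.
#'
#' @param p_values per-SNP p-values in the gene window (all in (0, 1\]).
#' @param ld correlation matrix of the same SNPs from a reference panel
#'   (positive semidefinite up to -1e-8 eigenvalue tolerance). A scalar 1
#'   (or 1x1 matrix) for a single SNP.
#' @param precision_digits requested digits for the tail evaluation
#'   (default 15, the fast backend; raise above 15 for quadruple
#'   precision).
#' @param cap cap on the reported -log10 p.
#' @param ridge diagonal regularization added to the LD matrix before the
#'   eigen-decomposition; the spectrum is rescaled afterwards so its sum
#'   equals the SNP count (trace preservation).
#' @return List with `n_snps`, `statistic` (T), `neg_log10_p` (capped),
#'   `neg_log10_p_raw`, `p`, `capped`, `spectrum`.
#' @export
score_gene <- function(p_values, ld, precision_digits = 15, cap = 100,
                       ridge = 1e-6) {
  if (length(p_values) == 0) return(NULL)
  stopifnot(all(p_values > 0 & p_values <= 1))
  k <- length(p_values)
  tstat <- sum(stats::qchisq(p_values, df = 1, lower.tail = FALSE))
  if (k == 1) {
    ev <- 1
  } else {
    C <- as.matrix(ld)
    stopifnot(nrow(C) == k, ncol(C) == k)
    C <- C + diag(ridge, k)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8)) stop("LD matrix not positive semidefinite")
    ev <- pmax(ev, 0)
    ev <- ev * (k / sum(ev))  # restore trace = n_snps
  }
  sf <- weighted_chi2_sf(ev, tstat, precision_digits = precision_digits,
                         stop_below = 10^(-(cap + 10)))
  raw <- sf$neg_log10_p
  capped <- sf$stopped_below || raw > cap
  list(n_snps = k, statistic = tstat,
       neg_log10_p = min(raw, cap), neg_log10_p_raw = raw,
       p = sf$p, capped = capped, spectrum = ev)
}

#' Score every gene (or fusion gene) from association results
#'
#' Maps SNPs to (fusion) genes, extracts each gene's SNP p-values and the
#' reference-panel LD among those SNPs, and applies [score_gene()].
#'
#' @param assoc association table (`SNP`, `P`).
#' @param mapping gene-to-SNP mapping from [assign_snps_to_genes()].
#' @param panel reference dosage matrix with SNP-named columns (or
#'   [gen_genotypes()] output).
#' @param precision_digits,cap,ridge passed to [score_gene()].
#' @return data.table `gene`, `n_snps`, `statistic`, `neg_log10_p`,
#'   `neg_log10_p_raw`, `capped`.
#' @export
score_genes <- function(assoc, mapping, panel, precision_digits = 15,
                        cap = 100, ridge = 1e-6) {
  assoc <- data.table::as.data.table(assoc)
  mapping <- data.table::as.data.table(mapping)
  if (is.list(panel) && !is.matrix(panel)) panel <- panel$dosage
  p_of <- stats::setNames(assoc$P, assoc$SNP)
  genes <- unique(mapping$gene)
  res <- lapply(genes, function(gn) {
    snps <- mapping[gene == gn, snp]
    snps <- snps[snps %in% names(p_of) & snps %in% colnames(panel)]
    if (length(snps) == 0) return(NULL)
    ld <- if (length(snps) > 1) stats::cor(panel[, snps, drop = FALSE]) else 1
    s <- score_gene(p_of[snps], ld, precision_digits = precision_digits,
                    cap = cap, ridge = ridge)
    data.table::data.table(gene = gn, n_snps = s$n_snps,
                           statistic = s$statistic,
                           neg_log10_p = s$neg_log10_p,
                           neg_log10_p_raw = s$neg_log10_p_raw,
                           capped = s$capped)
  })
  data.table::rbindlist(res)
}
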