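#' Default end-to-end pipeline configuration
#'
#' All stage parameters with the protocol defaults: MAF floor 5e-4, info
#' floor 0.3, genome-wide threshold 5e-8 (with the per-analysis
#' Bonferroni option), pruning r2 < 0.1 within 500 kb, 50-kb gene
#' windows, 100-kb gene fusion, instrument selection p < 5e-8 with
#' r2 < 0.01, proxy overlap r2 > 0.8, and the 1e-100 gene-score cap.
#'
#' @param seed master seed; every stage draws from substreams of it.
#' @param ... overrides for any [sim_config()] or threshold field.
#' @return A named list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    sim = sim_config(seed = seed),
    maf_min = 5e-4, info_min = 0.3,
    alpha_gw = 0.05, n_tests_gw = 1e6,      # -> 5e-8
    prune_r2 = 0.1, prune_dist_bp = 5e5,
    gene_window_bp = 5e4, fusion_gap_bp = 1e5,
    score_cap = 100, precision_digits = 15,
    mr_p_max = 5e-8, mr_r2_max = 0.01,
    proxy_r2 = 0.8, overlap_min_count = 5,
    replication_fdr = 0.1,
    n_genes = 120, n_sets = 12, n_tissues = 54,
    pc_alpha = 0.05, seed = seed)
  dots <- list(...)
  sim_fields <- names(formals(sim_config))
  for (nm in names(dots)) {
    if (nm %in% sim_fields) {
      cfg$sim[[nm]] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Run the full synthetic analysis chain
#'
#' Simulates genotypes, phenotype and vasculature; phenotypes the vessel
#' centerlines (QC + aggregation); runs the SNP-filtered,
#' covariate-adjusted GWAS on the inverse-normal-transformed measured
#' phenotype; computes inflation diagnostics and LD-score-regression
#' heritability; prunes to lead SNPs; scores fusion genes; runs gene-set
#' and tissue enrichment; bidirectional IVW Mendelian randomization; and
#' the disease-catalogue overlap. Every stage logs input/surviving counts.
#'
#' @param config list from [default_config()].
#' @param out_dir optional directory for stage artifacts (TSV/JSON).
#' @param measure tortuosity measure driving the GWAS (default `"DF"`).
#' @param vessel_class vessel class for the association phenotype.
#' @return List with every stage's outputs plus `log` (a data.table of
#'   stage, n_in, n_out, rule) and `report` (character vector).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         measure = "DF", vessel_class = "combined") {
  log <- list()
  note <- function(stage, n_in, n_out, rule) {
    log[[length(log) + 1]] <<- data.table::data.table(
      stage = stage, n_in = n_in, n_out = n_out, rule = rule)
  }
  sim <- config$sim

  geno <- gen_genotypes(sim)
  phen_direct <- gen_phenotype_direct(sim, geno)
  segments <- gen_vasculature(sim, phen_direct$phenotype$genetic_value)
  note("simulate", sim$n_subjects, nrow(segments),
       "synthetic genotypes + vasculature")

  ph <- compute_phenotypes(segments, measures = measure,
                           classes = vessel_class)
  note("image_qc", nrow(ph$qc), sum(ph$qc$pass),
       "length and vessel-count bounds")
  vc <- vessel_class; ms <- measure
  phen <- ph$phenotypes[ph$phenotypes$vessel_class == vc &
                          ph$phenotypes$measure == ms]
  note("aggregate", sim$n_subjects, nrow(phen),
       "median per image, earliest timepoint, mean of eyes")

  flt <- filter_snps(geno$meta, config$maf_min, config$info_min)
  note("filter_snps", nrow(geno$meta), nrow(flt$kept),
       sprintf("maf >= %g & info >= %g", config$maf_min, config$info_min))

  cov <- phen_direct$phenotype[match(phen$subject, subject)]
  y <- inverse_normal_transform(phen$value)
  keep_subj <- match(phen$subject, phen_direct$phenotype$subject)
  G <- geno$dosage[keep_subj, flt$kept$snp, drop = FALSE]
  covariates <- cbind(age = cov$age, sex = cov$sex)
  assoc <- run_gwas(y, G, covariates = covariates, meta = flt$kept)
  note("gwas", ncol(G), nrow(assoc), "per-SNP OLS, joint covariates")

  diag <- genomic_diagnostics(assoc)
  ld <- ld_scores(G, flt$kept)
  h2 <- ldsc_heritability(assoc, ld, n = nrow(G),
                          n_blocks = min(200, max(10, nrow(assoc) %/% 10)))

  thr <- bonferroni_threshold(config$alpha_gw, config$n_tests_gw)
  sig <- assoc[P < thr]
  leads <- ld_prune(sig, G, config$prune_r2, config$prune_dist_bp)
  note("ld_prune", nrow(sig), nrow(leads),
       sprintf("r2 < %g or > %g bp apart", config$prune_r2,
               config$prune_dist_bp))

  ann <- gen_annotations_and_sets(config$n_genes, config$n_sets,
                                  config$n_tissues, seed = config$seed,
                                  snp_pool = if (nrow(leads) > 0)
                                    c(leads$SNP,
                                      sample(flt$kept$snp,
                                             min(50, nrow(flt$kept))))
                                  else flt$kept$snp)
  fusion <- fuse_genes(ann$annotation, config$fusion_gap_bp)
  # map SNPs onto the fusion-gene genome: reuse SNP positions scaled onto
  # the annotation's coordinate range per chromosome
  snp_meta <- remap_snps(flt$kept, ann$annotation)
  mapping <- assign_snps_to_genes(
    fusion[, .(gene, chr, start, end, strand = "+", tss = start,
               tes = end)],
    snp_meta, config$gene_window_bp)
  gs <- score_genes(assoc, mapping, G,
                    precision_digits = config$precision_digits,
                    cap = config$score_cap)
  note("genescore", data.table::uniqueN(mapping$gene), nrow(gs),
       sprintf("sum of chi2, %d kb windows", config$gene_window_bp / 1000))

  enr <- if (length(ann$sets) > 0) {
    fusion_sets <- lapply(ann$sets, function(mem) {
      unique(fusion$gene[vapply(fusion$members,
                                function(m) any(m %in% mem), TRUE)])
    })
    enrich_gene_sets(gs, fusion_sets)
  } else data.table::data.table()

  fexpr <- fusion_expression(ann$expression, fusion)
  tort_set <- if (nrow(gs) > 0) {
    gthr <- bonferroni_threshold(0.05, nrow(gs))
    sig_genes <- gs[neg_log10_p_raw > -log10(gthr), gene]
    if (length(sig_genes) < 3) gs[order(-neg_log10_p_raw)][1:min(10, .N),
                                                           gene]
    else sig_genes
  } else character(0)
  tis <- if (length(tort_set) > 0 &&
             any(tort_set %in% rownames(fexpr))) {
    tissue_enrichment(fexpr, tort_set)
  } else data.table::data.table()

  mr_data <- gen_mr_summary(100, causal_effect = -0.05,
                            seed = config$seed)
  mr <- bidirectional_mr(mr_data$forward, mr_data$reverse,
                         p_max = config$mr_p_max,
                         r2_max = config$mr_r2_max,
                         labels = c("exposure->tortuosity",
                                    "tortuosity->exposure"))

  ov <- catalogue_overlap(leads, ann$catalogue, G,
                          r2_proxy = config$proxy_r2,
                          min_count = config$overlap_min_count)

  dis <- gen_disease_status(phen_direct$phenotype[keep_subj],
                            seed = config$seed)
  da <- disease_association(phen$value, dis$status,
                            age = cov$age, sex = cov$sex)

  log <- data.table::rbindlist(log)
  out <- list(config = config, genotypes = geno,
              phenotype_direct = phen_direct, phenotypes = ph,
              annotations = ann,
              assoc = assoc, diagnostics = diag, heritability = h2,
              leads = leads, gene_scores = gs, set_enrichment = enr,
              tissue_enrichment = tis, mr = mr, overlap = ov,
              disease = da, log = log)
  out$report <- pipeline_report(out)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sumstats(assoc[, -"NEG_LOG10_P"], file.path(out_dir,
                                                      "sumstats.tsv"))
    if (nrow(leads) > 0) {
      write_sumstats(leads[, -"NEG_LOG10_P"], file.path(out_dir,
                                                        "leads.tsv"))
    }
    write_diagnostics(h2, file.path(out_dir, "diagnostics.json"))
    data.table::fwrite(gs, file.path(out_dir, "gene_scores.tsv"),
                       sep = "\t")
    writeLines(out$report, file.path(out_dir, "report.txt"))
  }
  out
}

#' Text report for a pipeline run
#'
#' @param res [run_pipeline()] result.
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(res) {
  lines <- c("== tortuosity pipeline report ==", "", "-- stage ledger --")
  for (i in seq_len(nrow(res$log))) {
    lines <- c(lines, sprintf("%-12s %6d -> %6d  (%s)", res$log$stage[i],
                              res$log$n_in[i], res$log$n_out[i],
                              res$log$rule[i]))
  }
  h <- res$heritability
  lines <- c(lines, "", "-- diagnostics --",
             sprintf("lambda_GC %.3f  mean_chi2 %.3f", h$lambda_gc,
                     h$mean_chi2),
             sprintf("h2_SNP %.3f (SE %.3f)  intercept %.3f (SE %.3f)",
                     h$h2, h$h2_se, h$intercept, h$intercept_se),
             "", sprintf("-- lead SNPs (%d) --", nrow(res$leads)))
  if (nrow(res$leads) > 0) {
    top <- utils::head(res$leads, 10)
    lines <- c(lines, sprintf("%s chr%s:%d beta %.3f -log10P %.1f",
                              top$SNP, top$CHR, top$BP, top$BETA,
                              top$NEG_LOG10_P))
  }
  if (nrow(res$gene_scores) > 0) {
    top <- utils::head(res$gene_scores[order(-neg_log10_p_raw)], 5)
    lines <- c(lines, "", "-- top genes --",
               sprintf("%s  -log10P %s", top$gene,
                       ifelse(top$capped, "> 100",
                              sprintf("%.1f", top$neg_log10_p))))
  }
  if (nrow(res$tissue_enrichment) > 0) {
    sig <- res$tissue_enrichment[significant == TRUE]
    lines <- c(lines, "", sprintf("-- enriched tissues (%d) --", nrow(sig)),
               if (nrow(sig) > 0) sprintf("%s p=%.2e", sig$tissue, sig$p))
  }
  for (d in res$mr) {
    lines <- c(lines, sprintf("MR %s: beta %.3f (se %.3f) p %.3g, %d IVs",
                              d$direction, d$beta, d$se, d$p,
                              d$n_instruments))
  }
  lines <- c(lines, sprintf("disease assoc: beta %.3f p %.3g",
                            res$disease$beta, res$disease$p))
  lines
}

#' Rescale SNP positions onto a gene annotation's coordinate range
#'
#' The genotype and annotation generators tile their chromosomes
#' independently; this helper rescales SNP positions per chromosome onto
#' the annotation's span so that gene windows overlap SNPs. It is
#' plumbing for the synthetic pipeline, not a biological operation.
#'
#' @param snp_meta SNP table with `chr`, `pos`.
#' @param annotation gene table with `chr`, `start`, `end`.
#' @return The SNP table with rescaled `pos`.
#' @export
remap_snps <- function(snp_meta, annotation) {
  snp_meta <- data.table::as.data.table(snp_meta)
  ann_rng <- annotation[, .(lo = min(start), hi = max(end)), by = .(chr)]
  out <- data.table::copy(snp_meta)
  for (cc in unique(out$chr)) {
    rng <- ann_rng[chr == cc]
    if (nrow(rng) == 0) next
    j <- which(out$chr == cc)
    p <- out$pos[j]
    out$pos[j] <- as.integer(rng$lo + (p - min(p)) /
                               max(max(p) - min(p), 1) * (rng$hi - rng$lo))
  }
  out
}
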