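#!/usr/bin/env Rscript
# Stage 5 — Mendelian randomization, disease-variant overlap, disease
# association.
#
# Simulates two-sample summary statistics with a known causal effect of
# an exposure (think LDL) on tortuosity, selects instruments
# (autosomal, p < 5e-8, strand-unambiguous, r2 < 0.01), estimates the
# causal effect by fixed-effect IVW in both directions, intersects the
# GWAS lead SNPs with a toy disease catalogue (exact ids plus r2 > 0.8
# proxies), and fits the logistic disease model on the direct phenotype.

suppressMessages(library(tortgwas))
dat <- "results/data"
out <- "results/causal"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1

mr_data <- gen_mr_summary(100, causal_effect = -0.05, seed = seed)
write_mr(mr_data$forward, file.path(out, "mr_forward.tsv"))
write_mr(mr_data$reverse, file.path(out, "mr_reverse.tsv"))
mr <- bidirectional_mr(read_mr(file.path(out, "mr_forward.tsv")),
                       read_mr(file.path(out, "mr_reverse.tsv")),
                       labels = c("exposure->tortuosity",
                                  "tortuosity->exposure"))
for (e in mr) {
  cat(sprintf("MR %s: beta %.4f (se %.4f), p %.3g, %d instruments\n",
              e$direction, e$beta, e$se, e$p, e$n_instruments))
}
cat(sprintf("(simulated truth: forward %.2f, reverse %.2f)\n",
            mr_data$truth$causal_effect, mr_data$truth$reverse_effect))

dosage <- as.matrix(data.table::fread(file.path(dat, "dosages.tsv")))
leads_path <- "results/gwas/leads.tsv"
if (file.exists(leads_path)) {
  leads <- read_sumstats(leads_path)
  ann <- gen_annotations_and_sets(150, 12, 54, seed = seed,
                                  snp_pool = c(leads$SNP,
                                               colnames(dosage)[1:50]))
  write_catalogue(ann$catalogue, file.path(out, "catalogue.tsv"))
  ov <- catalogue_overlap(leads, read_catalogue(file.path(out,
                                                          "catalogue.tsv")),
                          dosage, min_count = 1)
  data.table::fwrite(ov$overlaps, file.path(out, "overlap.tsv"),
                     sep = "\t")
  cat(sprintf("catalogue overlap: %d record(s), %d trait(s)\n",
              nrow(ov$overlaps), nrow(ov$trait_counts)))
}

cov <- data.table::fread(file.path(dat, "covariates.tsv"))
dis <- gen_disease_status(cov, slope = 0.19, seed = seed)
da <- disease_association(cov$y, dis$status, age = cov$age,
                          sex = cov$sex)
cat(sprintf("disease association: log-odds %.3f (se %.3f), p %.3g\n",
            da$beta, da$se, da$p))
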