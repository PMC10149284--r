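#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates a 400-subject synthetic cohort with known ground truth:
# genotypes in LD blocks (MAF spectrum with a rare tail and an
# imputation-quality column), an additive tortuosity trait at h2 = 0.25
# with age/sex confounding, and the fundus-image vessel centerlines whose
# waviness is coupled to the genetic value. The heritability is split over
# four loci so that the desk-scale cohort still has discovery power (a
# biobank-scale architecture would leave every locus undetectable here).
# Everything downstream reads only the files written here.

suppressMessages(library(tortgwas))
seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_subjects = 400, n_snps = 2000, n_causal = 4,
                  h2_target = 0.25, seed = seed,
                  ld_rho_range = c(0.3, 0.98))
geno <- gen_genotypes(cfg)
phen <- gen_phenotype_direct(cfg, geno)
segments <- gen_vasculature(cfg, phen$phenotype$genetic_value)

write_centerlines(segments, file.path(out, "centerlines.jsonl"))
data.table::fwrite(data.table::as.data.table(geno$dosage),
                   file.path(out, "dosages.tsv"), sep = "\t")
data.table::fwrite(geno$meta, file.path(out, "snp_meta.tsv"), sep = "\t")
data.table::fwrite(phen$phenotype, file.path(out, "covariates.tsv"),
                   sep = "\t")
jsonlite::write_json(
  list(seed = seed, n_subjects = cfg$n_subjects, n_snps = cfg$n_snps,
       causal_snps = phen$truth$causal_snp_ids,
       realized_h2 = phen$truth$realized_h2),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d subjects, %d SNPs, %d vessel segments\n",
            cfg$n_subjects, cfg$n_snps, nrow(segments)))
cat(sprintf("realized h2 of the direct trait: %.4f\n",
            phen$truth$realized_h2))
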