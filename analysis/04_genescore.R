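#!/usr/bin/env Rscript
# Stage 4 — gene scores, gene-set enrichment, tissue expression.
#
# Generates the toy gene annotation (with gaps straddling the 100-kb
# fusion boundary), fuses nearby genes, maps the filtered SNPs into 50-kb
# windows around each fusion gene, aggregates SNP p-values into
# LD-aware sum-of-chi-squared gene scores (tails evaluated to far below
# 1e-100, reported capped at -log10 p = 100), and runs the rank-based
# gene-set and tissue-expression enrichments.

suppressMessages(library(tortgwas))
dat <- "results/data"
out <- "results/genescore"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1

dosage <- as.matrix(data.table::fread(file.path(dat, "dosages.tsv")))
meta <- data.table::fread(file.path(dat, "snp_meta.tsv"))
assoc <- read_sumstats("results/gwas/sumstats.tsv")

ann <- gen_annotations_and_sets(n_genes = 150, n_sets = 12,
                                n_tissues = 54, seed = seed,
                                snp_pool = assoc$SNP)
write_annotation(ann$annotation, file.path(out, "annotation.tsv"))
write_gmt(ann$sets, file.path(out, "sets.gmt"))
write_expression(ann$expression, file.path(out, "expression.tsv"))

fusion <- fuse_genes(ann$annotation)
cat(sprintf("genes: %d -> %d fusion genes\n", nrow(ann$annotation),
            nrow(fusion)))

# place SNPs onto the annotation's coordinate range so windows overlap
snp_meta <- remap_snps(meta[snp %in% assoc$SNP], ann$annotation)
mapping <- assign_snps_to_genes(
  fusion[, .(gene, chr, start, end, strand = "+", tss = start,
             tes = end)], snp_meta)
gs <- score_genes(assoc, mapping, dosage)
data.table::fwrite(gs, file.path(out, "gene_scores.tsv"), sep = "\t")
top <- head(gs[order(-neg_log10_p_raw)], 5)
cat("top genes:\n")
print(top[, .(gene, n_snps, neg_log10_p, capped)])

fusion_sets <- lapply(ann$sets, function(mem) {
  unique(fusion$gene[vapply(fusion$members,
                            function(m) any(m %in% mem), TRUE)])
})
enr <- enrich_gene_sets(gs, fusion_sets)
data.table::fwrite(enr, file.path(out, "set_enrichment.tsv"), sep = "\t")

# tissue enrichment of the planted set (ground truth: tissue01)
te <- tissue_enrichment(ann$expression, ann$sets[[ann$planted$set]])
data.table::fwrite(te, file.path(out, "tissue_enrichment.tsv"),
                   sep = "\t")
cat(sprintf("planted tissue %s: p = %.3g (threshold %.3g); %d tissue(s) flagged\n",
            ann$planted$tissue, te[tissue == ann$planted$tissue, p],
            attr(te, "threshold"), sum(te$significant)))
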