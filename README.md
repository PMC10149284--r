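# tortgwas

Retinal vessel tortuosity is a heritable, clinically informative trait:
how much a vessel winds is measured from fundus images and can be tested
for genetic association like any quantitative phenotype. `tortgwas`
implements that whole chain as a tested R package for methodologists who
want to exercise, validate or extend each stage without access to
biobank data: every input is generated synthetically with known ground
truth, so recovery of planted signals is checkable end to end.

The chain:

1. **Phenotyping** — from vessel centerlines: the distance factor
   `DF = s(C) / chord(C)` (arc length over endpoint chord; 1 for a
   straight vessel) and six curvature-integral measures
   (`tau2 = ∫|κ|ds`, `tau3 = ∫κ²ds`, plus length- and chord-normalized
   variants `tau4..tau7`); artery/vein calling from the signed
   pixel-label difference; image QC on total vasculature length and
   vessel count; aggregation median-per-image → earliest timepoint per
   eye → mean over eyes.
2. **Association** — SNP QC (MAF ≥ 5e-4, imputation info ≥ 0.3),
   rank-based inverse normal transform, per-SNP OLS with joint
   age/sex/PC covariates, genomic-control diagnostics, SNP heritability
   by LD-score regression (`E[χ²_j] = 1 + n h² ℓ_j / m`, block
   jackknife), LD pruning of significant SNPs to independent leads
   (r² < 0.1 or > 500 kb apart), inverse-variance meta-analysis and
   Benjamini–Hochberg candidate replication.
3. **Gene scores** — SNP p-values in 50-kb gene windows transformed to
   1-df χ² quantiles and summed; the null of the sum is a weighted sum
   of independent χ²₁ with weights the eigenvalues of the SNP LD matrix
   ("eigen-SNPs"). The tail is evaluated by Ruben's positive mixture
   series in 128-bit arithmetic, exact far below p = 1e-100 (reported
   scores are capped at -log10 p = 100 with a flag). Genes < 100 kb
   apart are fused and scored jointly. Gene-set and tissue enrichment
   are rank-based (ranks → uniform → χ²₁ → sum, against χ²_m).
4. **Causal analyses** — bidirectional two-sample Mendelian
   randomization with instrument selection (autosomal, p < 5e-8,
   strand-ambiguous removed, r² < 0.01) and the fixed-effect IVW
   estimator; disease-variant catalogue overlap with r² > 0.8 LD
   proxies; logistic phenotype–disease models; Cohen's d contrasts.

## Worked example

The numbered scripts under `analysis/` run the whole study on a
synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # cohort, genotypes, centerlines
Rscript analysis/02_phenotype.R    # tortuosity measures, QC, aggregation
Rscript analysis/03_gwas.R         # SNP QC, GWAS, LDSC, lead SNPs
Rscript analysis/04_genescore.R    # fusion genes, gene scores, enrichment
Rscript analysis/05_mr_overlap.R   # MR, catalogue overlap, disease models
Rscript analysis/06_replication.R  # replication metacohort, BH, concordance
```

A run at the default seed prints, among other things:

```
combined-vessel DF: mean 1.0294, median 1.0250 (n = 400)
A/V calling vs truth: AUC 0.935, accuracy 0.879
SNP QC: 2000 -> 1915
significant SNPs at p < 2.61e-05: 2; independent leads: 2
leads inside causal LD blocks: 2 / 2
planted tissue tissue01: p = 4.43e-05 (threshold 0.000926); 1 tissue(s) flagged
MR exposure->tortuosity: beta -0.0566 (se 0.0058), p 1.17e-22, 69 instruments
MR tortuosity->exposure: beta -0.0052 (se 0.0062), p 0.407, 62 instruments
candidates replicating at FDR 0.1: 4 / 4
effect-size concordance (discovery p < 0.01): r = 0.935 (p = 4.7e-15), 31/32 same sign
```

Read: the synthetic population's mean distance factor sits at the
empirical 1.03 with a long right tail; the noisy pixel labels give the
artery/vein caller its reference operating point (AUC ≈ 0.93); both
discovered lead SNPs land in planted causal LD blocks; the planted
expression signal clears the 0.05/54 tissue threshold; the simulated
negative exposure effect on tortuosity (-0.05) is recovered with a null
reverse direction; and the planted loci replicate in an independent
metacohort with strongly concordant effect sizes.

The same chain is available programmatically:

```r
library(tortgwas)
res <- run_pipeline(default_config(seed = 1))
cat(res$report, sep = "\n")
```

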