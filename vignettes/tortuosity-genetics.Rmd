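---
title: "From vessel centerlines to genetic association: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From vessel centerlines to genetic association: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tortgwas)
```

# The analysis chain

`tortgwas` implements an end-to-end genetic study of retinal vessel
tortuosity on synthetic data with known ground truth: tortuosity
phenotyping from vessel centerlines, covariate-adjusted per-SNP
association, LD-score-regression heritability, an LD-aware gene test with
very deep tail probabilities, rank-based gene-set and tissue enrichment,
replication meta-analysis, disease-variant overlap, and bidirectional
inverse-variance-weighted (IVW) Mendelian randomization. This vignette
records the models, the tunable parameters, and the design decisions that
were genuinely open.

# Tortuosity phenotyping

**Distance factor.** For a centerline $C$ sampled as ordered points, the
distance factor is $\mathrm{DF} = s(C)/\mathrm{chord}(C)$: total polyline
length over the Euclidean distance between the endpoints. It is 1 exactly
for a straight segment, and invariant under rigid motions, reflection and
uniform scaling. A circular arc of angle $\theta$ has
$\mathrm{DF} = \theta / (2\sin(\theta/2))$, which the tests use as a
closed-form oracle ($\pi/2 \approx 1.5708$ for a semicircle).

**Curvature integrals.** The centerline is interpolated with cubic
splines against cumulative chord length (optionally smoothed via
`smooth.spline`; the smoothing parameter defaults to 0 because the
synthetic centerlines are noise-free — real segmenter output would
warrant a small positive value), resampled on a uniform arc-length grid,
and differentiated by central differences. With curvature
$\kappa = |x'y'' - y'x''|/(x'^2+y'^2)^{3/2}$:

* $\tau_2 = \int |\kappa|\,ds$, $\tau_3 = \int \kappa^2\,ds$;
* $\tau_4 = \tau_2/s$, $\tau_5 = \tau_3/s$ (arc-length normalized);
* $\tau_6 = \tau_2/\mathrm{chord}$, $\tau_7 = \tau_3/\mathrm{chord}$.

The definitions of $\tau_4$–$\tau_7$ as length- and chord-normalized
variants of the two curvature integrals are a design choice: the measures
are only constrained to be "similar to each other" and intermediate
between $\tau_2$, $\tau_3$ and DF, which these normalizations satisfy.
$\tau_3$, $\tau_5$ and $\tau_7$ carry a $1/\text{length}$ unit (halving
under a 2x rescaling); the others are unit-free. On a sampled arc of
radius $r$ and angle $\theta$, $\tau_2 \to \theta$ and
$\tau_3 \to \theta/r$, the convergence oracle used in the tests.

**Vessel type.** Each segment's score is the difference between pixels
labeled arterial and venous; positive calls artery, negative vein, and a
zero score leaves the segment unclassified — excluded from the
vessel-specific phenotypes but kept in the combined one, since the rule
requires a strictly positive or negative score.

**QC and aggregation.** An image passes QC iff its total vasculature
length and vessel count lie within configured bounds (defaults
$[2000, 10^6]$ px and $[10, 500]$ vessels; the reference thresholds are
unpublished, so these are exposed in the configuration and logged).
Aggregation: per image the median of per-segment values; per eye only the
earliest timepoint; across eyes the mean of the (at most two) per-image
medians; subjects with no QC-passing image are dropped for that trait.

# The synthetic cohort

The generators in `sim_config()` define the study conditions:

* **Genotypes** (`gen_genotypes`): two haplotypes per subject from a
  per-block Gaussian copula — within a block adjacent latent normals
  follow an AR(1) with correlation `ld_rho` (or a per-block draw from
  `ld_rho_range`, emulating variable recombination), thresholded at the
  normal quantile of each SNP's allele frequency. Dosages are {0, 1, 2}
  with Hardy–Weinberg structure and r² decaying with distance. MAFs are
  uniform on (0.05, 0.5) with a 1% rare tail below 5e-4 and 15% of SNPs
  carrying a sub-unit imputation info score, so the SNP QC rules have
  something to remove. Whole blocks stay on one chromosome.
* **Trait** (`gen_phenotype_direct`): $y = g + e + $ age/sex effects,
  with the genetic score $g$ built from standardized causal dosages and
  rescaled so $\mathrm{var}(g)$ equals `h2_target` exactly;
  $\mathrm{var}(e) = 1 - h^2$. Causal SNPs are spread one per LD block
  while blocks last. The age effect (0.26 per SD) reproduces a
  standardized old-vs-young contrast near 0.49, the sex effect is 0.049,
  matching the reported demographic contrasts.
* **Vasculature** (`gen_vasculature`): each vessel is a random chord
  plus a perpendicular sinusoid whose relative amplitude is
  $a = a_0\,e^{0.25\,\ell}\,E$, with $\ell$ the subject's latent trait
  (genetic value plus environmental noise) and $E$ gamma-distributed
  multiplicative noise (shape 6, mean 1). Since
  $\mathrm{DF} - 1 \approx \pi^2 k^2 a^2$ for $k$ sinusoid periods, the
  measured DF is a known monotone function of the latent value, keeping
  the geometric measurement inside the causal path. `amp_base = 0.0285`
  puts the population mean DF near 1.030 with a long right tail
  (population skewness about +1.8); veins get a 1.08 amplitude factor
  (vein-artery standardized difference about 0.12). The label-noise
  default 0.425 per point puts the artery/vein score discrimination at
  AUC about 0.93 — the operating point of the reference deep-learning
  classifier. Some subjects have one eye and some eyes extra timepoints,
  so the aggregation rules are exercised.
* **MR summary statistics, annotations, sets, expression, catalogue**:
  see `gen_mr_summary()` and `gen_annotations_and_sets()`. Inter-gene
  gaps straddle the 100-kb fusion boundary; the expression matrix is
  log-normal (sdlog 0.45) with one gene set upregulated 3-fold in one
  tissue, which the rank-based tissue test recovers essentially always
  at the 0.05/54 threshold; the catalogue can be seeded from the
  analysis' own SNP pool so overlap is plantable.

What the generator does **not** emulate: raster images and segmentation
artifacts, vessel branching topology, population structure and
relatedness, genotyping batch effects, linkage between causal density and
LD, and selection effects in cohort assembly. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
additive model, not robustness to those real-data complications.

# Association, diagnostics and heritability

The measured phenotype is rank-transformed
(`inverse_normal_transform`, $\Phi^{-1}((r-0.5)/n)$, average ranks for
ties), and each SNP is tested by OLS of the phenotype on dosage with age,
sex and the phenotype-correlated genotype PCs as joint covariates
(`select_covariate_pcs`, two-sided Pearson screen at $\alpha = 0.05$).
The implementation residualizes phenotype and dosages on the covariates
once (Frisch–Waugh–Lovell), which reproduces the joint fit exactly —
including $n - p - 2$ residual degrees of freedom — and is verified
against per-SNP `lm()` to 1e-8. p-values use the normal approximation
(the convention at GWAS sample sizes; slightly anticonservative for
small synthetic cohorts, which the tests account for by calibrating on
permutations).

$\lambda_{GC}$ is the median $\chi^2$ over `qchisq(0.5, 1)`; LD-score
regression fits $\chi^2_j$ on $\ell_j = \sum_k r^2_{jk}$ (bias-adjusted
$r^2 - (1-r^2)/(n-2)$, 1-Mb window) with $1/\max(\ell_j, 1)$ weights and
one reweighting iteration, slope $= n h^2/m$; standard errors come from a
200-block delete-one jackknife. Two design points matter at desk scale:

* **External LD panel.** Estimating LD scores on the GWAS cohort itself
  correlates the $\ell$ estimation error with the realized tagging of
  causal variants and biases the slope; the package's demonstrations
  therefore draw an independent cohort from the same population for the
  panel, as the original analysis used an external reference panel.
* **Leverage and polygenicity.** With a constant block LD strength all
  LD scores are nearly equal and the regression has no leverage, and
  with very sparse architectures the effective sample is the handful of
  causal blocks, inflating the jackknife SE to ~0.15–0.2 at
  $n = 2000, m = 5000$. The heritability demonstration therefore uses
  dispersed per-block LD (0.3–0.98) and a polygenic architecture
  (200 causal), averaging six replicate cohorts; the sparse 20-causal
  recovery is still verified against its jackknife SE in the tests.

Thresholds: genome-wide $5\times10^{-8}$ (0.05 over an effective million
tests); pruning accepts SNPs in ascending-p order and discards neighbors
within 500 kb at $r^2 \ge 0.1$ (ties broken by chromosome, position, id —
the original rule states only the independence criterion, not the
algorithm). Meta-analysis is fixed-effect inverse-variance with
swap/strand-complement allele alignment; palindromic pairs that match
only via complement-plus-swap are genuinely ambiguous and dropped.
Candidate replication uses the Benjamini–Hochberg step-up rule on the
discovery-significant set only.

# Gene scores and enrichment

SNP p-values in a window from 50 kb before the gene start to 50 kb after
the gene end (strand-agnostic; for equal pads the strand-aware anchoring
coincides) are transformed to 1-df $\chi^2$ quantiles and summed. Under
the null, $T = \sum_i q_i$ is distributed as
$\sum_k \lambda_k W_k$ with $W_k$ iid $\chi^2_1$ and $\lambda_k$ the
eigenvalues of the SNP correlation matrix ("eigen-SNPs"). Genes closer
than 100 kb (body-to-body intervening bases, strictly less; fusion
distance between bodies rather than windows) are fused transitively and
scored as one entity.

The tail probability is evaluated by Ruben's mixture-of-$\chi^2$ series
with shape $\beta = 0.90625\,\lambda_{\min}$, which keeps every mixture
coefficient nonnegative: the series has no cancellation and the
truncation error is bounded by the unaccumulated mixture mass, plus a
geometric bound on the decaying terms for deep tails where the mass
bound saturates at machine resolution. Two backends share the code:
hardware doubles (default for bulk scoring) and 128-bit quadruple
precision (~33 significant digits, exponent range beyond $10^{\pm4900}$),
which resolves the $10^{-100}$ regime with more than 20 significant
digits to spare; the survival chain is carried as mantissa plus log
offset so no intermediate underflows. A single uniform series is used
rather than a separate fast-path algorithm — simpler, and cross-checked
against Monte Carlo, $\chi^2_k$ closed forms, and an independent
multiple-precision evaluation. Numerical edges: eigenvalues in
$[-10^{-8}, 0)$ are clipped to zero, larger negativity is an input
error; a $10^{-6}$ diagonal ridge stabilizes the decomposition and the
spectrum is rescaled so its sum equals the SNP count; reported
$-\log_{10} p$ is capped at 100 with a flag (the uncapped value is kept),
and capped genes may stop the series early once the whole tail is
provably below the cutoff.

Gene-set enrichment is deliberately rank-based: gene scores are reduced
to ranks (most significant = rank 1; ties averaged), made uniform as
$(r - 0.5)/G$, transformed to $\chi^2_1$ quantiles and summed over the
set, against a $\chi^2_m$ null. Tissue enrichment applies the same
transform to expression ranks per tissue (most expressed = rank 1),
with fusion-gene expression pooled by summation over members, and
flags tissues at the Bonferroni threshold $0.05/54 = 9.26\times10^{-4}$.

# Causal analyses

Instruments are autosomal SNPs with exposure $p < 5\times10^{-8}$,
strand-ambiguous (A/T, C/G) variants removed, greedily pruned to pairwise
$r^2 < 0.01$ in ascending-p order. The IVW estimate is fixed-effects with
first-order weights,
$\hat\beta = \sum \beta_X\beta_Y/se_Y^2 \big/ \sum \beta_X^2/se_Y^2$,
reducing to the Wald ratio for one instrument; a multiplicative
random-effects variance inflation is available behind a flag. Because
palindromic SNPs are removed at selection, no frequency-based strand
inference is attempted. The phenotype–disease analysis is a logistic
regression of status on the standardized phenotype with age and sex
adjustment — the disease model is an interpretation (the reported
real-data effect sizes are consistent with log-odds on a standardized
phenotype), and perfect separation is raised as an error rather than
reported. Catalogue overlap reports exact id matches at $r^2 = 1$ and
proxies at $r^2 > 0.8$, with per-trait counts filtered at 5 or more
shared associations.

# Problem sizes and reproducibility

All randomness flows from a single integer seed through fixed substream
offsets, so every generator is bit-reproducible and independent of
execution order. The bundled demonstrations are sized for a desk run:
the analysis scripts use 400–1400 subjects and 2000 SNPs (a few seconds
per stage); the heritability demonstration uses six replicate cohorts of
2000 GWAS + 2000 panel subjects at 5000 SNPs (under a minute each); the
tail-probability oracle uses $10^7$ Monte-Carlo draws. The analysis
drivers plant four strong loci ($h^2 = 0.25$ over 4 causal blocks) so
that discovery, pruning, replication and overlap all have material to
show at these sizes; a biobank-scale architecture spread over hundreds
of loci would leave every single locus undetectable in a 400-subject
cohort, which is exactly what the power analysis predicts.

# Known limitations

* The $\tau_4$–$\tau_7$ definitions and QC bounds are reconstructions
  of unpublished choices (configurable).
* LDSC at desk scale has wide jackknife intervals; its intercept/slope
  trade-off is visible in single runs.
* The IVW implementation ignores exposure-side sampling error (standard
  first-order IVW); with the simulated instrument strengths the induced
  attenuation is far below the reported SEs.
* The weighted-$\chi^2$ series converges slowly for spectra with
  $\lambda_{\max}/\lambda_{\min}$ beyond ~$10^3$; such calls return a
  convergence flag and bound rather than failing silently.
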