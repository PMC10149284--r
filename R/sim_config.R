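#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults emulate
#' the study conditions: a left-skewed, long-tailed distance-factor
#' distribution with mean near 1.03, additive genetic architecture at
#' 25% heritability, genotypes in LD blocks with a realistic MAF spectrum,
#' multi-image/multi-eye subject structure, and artery/vein label noise
#' whose segment-score discrimination is near AUC 0.93.
#'
#' @param n_subjects number of subjects.
#' @param n_snps number of SNPs.
#' @param n_causal number of causal SNPs (each in a distinct LD block when
#'   possible).
#' @param h2_target target narrow-sense heritability in \[0, 1).
#' @param maf_range minor-allele-frequency range for common SNPs, within
#'   (0, 0.5\].
#' @param ld_block_size SNPs per LD block.
#' @param ld_rho latent AR(1) correlation between adjacent SNPs in a block,
#'   in \[0, 1).
#' @param images_per_eye maximum images per eye (extra timepoints beyond
#'   the first arise with probability `extra_image_prob` each).
#' @param points_per_vessel centerline points per vessel.
#' @param vessels_per_image vessels per fundus image.
#' @param av_label_noise per-pixel probability that the artery/vein label
#'   is flipped. The default 0.425 places the signed pixel-difference score
#'   near the discrimination reported for the reference deep-learning
#'   classifier (AUC about 0.93).
#' @param seed integer seed; fully determines all generator output.
#' @param spacing_bp base-pair spacing between adjacent SNPs.
#' @param n_chrom number of simulated chromosomes the SNPs tile.
#' @param rare_fraction fraction of SNPs given a MAF below the 5e-4
#'   association floor (to exercise SNP QC).
#' @param lowinfo_fraction fraction of SNPs given an imputation info score
#'   drawn from \[0.1, 1\) (the rest get 1.0).
#' @param both_eyes_prob probability a subject has images from both eyes.
#' @param extra_image_prob probability of each additional timepoint.
#' @param vessel_len_px nominal vessel length in pixels.
#' @param amp_base baseline relative waviness amplitude (amplitude/length).
#' @param amp_slope increase of log-amplitude per standard deviation of the
#'   latent tortuosity trait — the coupling through which genetics reaches
#'   the measured geometry.
#' @param amp_shape gamma shape of the multiplicative per-vessel amplitude
#'   noise (mean 1; smaller = heavier right tail of DF).
#' @param vein_amp_factor multiplicative amplitude factor for veins
#'   (veins are somewhat more tortuous than arteries).
#' @param age_beta,sex_beta confounder effects on the standardized trait
#'   (per SD of age; additive for female sex).
#' @param ld_rho_range optional length-2 range; when given, each LD block
#'   draws its own AR(1) correlation uniformly from it (variable
#'   recombination), which disperses the LD-score spectrum.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 200, n_snps = 2000, n_causal = 20,
                       h2_target = 0.25, maf_range = c(0.05, 0.5),
                       ld_block_size = 25, ld_rho = 0.8,
                       images_per_eye = 2, points_per_vessel = 50,
                       vessels_per_image = 20, av_label_noise = 0.425,
                       seed = 1, spacing_bp = 5000, n_chrom = 2,
                       rare_fraction = 0.01, lowinfo_fraction = 0.15,
                       both_eyes_prob = 0.9, extra_image_prob = 0.15,
                       vessel_len_px = 220, amp_base = 0.0285,
                       amp_slope = 0.25, amp_shape = 6,
                       vein_amp_factor = 1.08,
                       age_beta = 0.26, sex_beta = 0.049,
                       ld_rho_range = NULL) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, n_snps >= 1, n_causal >= 0,
            n_causal <= n_snps, h2_target >= 0, h2_target < 1,
            length(maf_range) == 2, all(maf_range > 0),
            all(maf_range <= 0.5), maf_range[1] <= maf_range[2],
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            images_per_eye >= 1, points_per_vessel >= 3,
            vessels_per_image >= 1, av_label_noise >= 0,
            av_label_noise <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# derive a deterministic substream seed from the master seed; keeps every
# generator independent of execution order while fully seed-determined
substream_seed <- function(seed, stream) {
  offsets <- c(genotypes = 11L, phenotype = 29L, vasculature = 47L,
               mr = 83L, annotations = 131L, disease = 197L)
  s <- (as.integer(seed) %% 1000000L) * 1000L + offsets[[stream]]
  as.integer(s)
}
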