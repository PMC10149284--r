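#' Generate genotype dosages in LD blocks with a realistic MAF spectrum
#'
#' Haplotypes are simulated from a per-block Gaussian copula: within a
#' block, adjacent latent standard normals follow an AR(1) process with
#' correlation `ld_rho`, so the dosage r-squared decays with SNP distance;
#' blocks are mutually independent. Each latent value is thresholded at
#' the normal quantile of the SNP's allele frequency and the two
#' haplotypes are summed, giving Hardy-Weinberg dosages in {0, 1, 2}.
#'
#' @param cfg a [sim_config()].
#' @return List with `dosage` (n_subjects x n_snps integer matrix, columns
#'   named by SNP id) and `meta` (data.table: `snp`, `chr`, `pos`, `ea`,
#'   `ra`, `freq` (effect-allele frequency, empirical), `info`
#'   (imputation-style quality score), `maf_true`, `block`).
#' @export
gen_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "genotypes"))
  n <- cfg$n_subjects; m <- cfg$n_snps; b <- cfg$ld_block_size
  rho <- cfg$ld_rho

  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  n_rare <- round(cfg$rare_fraction * m)
  if (n_rare > 0) {
    idx <- sample.int(m, n_rare)
    maf[idx] <- stats::runif(n_rare, 1e-4, 5e-4)
  }
  block <- rep(seq_len(ceiling(m / b)), each = b, length.out = m)
  n_blocks <- max(block)
  # per-block LD strength; a range emulates variable recombination and
  # gives the LD-score spectrum the dispersion regression needs
  rho_blk <- if (is.null(cfg$ld_rho_range)) rep(rho, n_blocks)
             else stats::runif(n_blocks, cfg$ld_rho_range[1],
                               cfg$ld_rho_range[2])

  dosage <- matrix(0L, n, m)
  for (hap in 1:2) {
    z <- matrix(0, n, m)
    for (blk in seq_len(n_blocks)) {
      cols <- which(block == blk)
      rb <- rho_blk[blk]
      z[, cols[1]] <- stats::rnorm(n)
      if (length(cols) > 1) {
        for (j in cols[-1]) {
          z[, j] <- rb * z[, j - 1] + sqrt(1 - rb^2) * stats::rnorm(n)
        }
      }
    }
    thr <- stats::qnorm(maf)
    dosage <- dosage + (z < rep(thr, each = n))
  }
  mode(dosage) <- "integer"

  snp <- sprintf("rs%06d", seq_len(m))
  colnames(dosage) <- snp
  pairs <- list(c("A", "G"), c("A", "C"), c("C", "T"), c("G", "T"),
                c("A", "T"), c("C", "G"))
  al <- pairs[sample.int(6, m, replace = TRUE,
                         prob = c(0.3, 0.18, 0.3, 0.18, 0.02, 0.02))]
  swap <- stats::runif(m) < 0.5
  ea <- vapply(seq_len(m), function(j) al[[j]][1 + swap[j]], "")
  ra <- vapply(seq_len(m), function(j) al[[j]][2 - swap[j]], "")
  info <- rep(1, m)
  n_low <- round(cfg$lowinfo_fraction * m)
  if (n_low > 0) {
    idx <- sample.int(m, n_low)
    info[idx] <- stats::runif(n_low, 0.1, 1)
  }
  # whole LD blocks stay on one chromosome
  n_blocks <- max(block)
  blocks_per_chr <- ceiling(n_blocks / cfg$n_chrom)
  chr <- as.integer((block - 1L) %/% blocks_per_chr + 1L)
  pos <- integer(m)
  for (cc in unique(chr)) {
    j <- which(chr == cc)
    pos[j] <- 1e6L + (seq_along(j) - 1L) * as.integer(cfg$spacing_bp)
  }
  meta <- data.table::data.table(
    snp = snp, chr = chr, pos = pos, ea = ea, ra = ra,
    freq = colMeans(dosage) / 2, info = info, maf_true = maf, block = block)
  list(dosage = dosage, meta = meta)
}
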