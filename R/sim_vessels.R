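#' Generate synthetic vessel centerlines coupled to a latent trait
#'
#' Each vessel is a sinusoid-perturbed straight path: a random chord of
#' length about `vessel_len_px` plus a perpendicular sine wave whose
#' relative amplitude is
#' \eqn{a = amp\_base \cdot e^{amp\_slope \cdot \ell} \cdot E}
#' with \eqn{\ell} the subject's latent tortuosity value (genetic value
#' plus environmental noise) and E a gamma(shape, rate = shape)
#' multiplicative noise (mean 1, right-skewed), so the measured distance
#' factor is a known monotone function of the latent value and its
#' population distribution is long-tailed with mean near 1.03. Veins get a
#' slightly larger amplitude than arteries. Some subjects have one eye
#' only, and some eyes carry additional later-timepoint images, exercising
#' the aggregation rules. Per-point artery/vein labels are flipped with
#' probability `av_label_noise`.
#'
#' @param cfg a [sim_config()].
#' @param genetic_value numeric vector, one latent genetic value per
#'   subject (e.g. the `genetic_value` column from
#'   [gen_phenotype_direct()]). Environmental noise of variance
#'   `1 - h2_target` is added internally so that `genetic_value` explains
#'   an `h2_target` share of the latent trait when it has variance
#'   `h2_target`.
#' @param env_sd standard deviation of the added subject-level
#'   environmental noise; default `sqrt(1 - h2_target)`.
#' @param amplitude_override if not `NULL`, a fixed relative amplitude used
#'   for every vessel (bypasses the latent coupling; 0 gives straight
#'   vessels) — useful for geometry calibration.
#' @return A centerline data.table: `subject`, `eye`, `image`, `timepoint`,
#'   `vessel_id`, `true_type`, `n_artery_px`, `n_vein_px` and a `points`
#'   list-column of two-column coordinate matrices (pixels).
#' @export
gen_vasculature <- function(cfg, genetic_value, env_sd = NULL,
                            amplitude_override = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$points_per_vessel < 3) stop("points_per_vessel must be >= 3")
  n <- cfg$n_subjects
  stopifnot(length(genetic_value) == n)
  if (is.null(env_sd)) env_sd <- sqrt(1 - cfg$h2_target)
  set.seed(substream_seed(cfg$seed, "vasculature"))

  latent <- genetic_value + stats::rnorm(n, 0, env_sd)
  subj <- sprintf("S%05d", seq_len(n))
  rows <- vector("list", n)
  npts <- cfg$points_per_vessel
  tgrid <- seq(0, 1, length.out = npts)

  for (i in seq_len(n)) {
    eyes <- if (stats::runif(1) < cfg$both_eyes_prob) c("L", "R")
            else sample(c("L", "R"), 1)
    recs <- list()
    for (eye in eyes) {
      n_imgs <- 1
      while (n_imgs < cfg$images_per_eye &&
             stats::runif(1) < cfg$extra_image_prob) n_imgs <- n_imgs + 1
      for (im in seq_len(n_imgs)) {
        img_id <- sprintf("%s_%s_I%02d", subj[i], eye, im)
        nv <- cfg$vessels_per_image
        true_type <- rep(c("artery", "vein"), length.out = nv)
        L <- cfg$vessel_len_px * stats::runif(nv, 0.8, 1.2)
        amp <- if (!is.null(amplitude_override)) {
          rep(amplitude_override, nv)
        } else {
          cfg$amp_base * exp(cfg$amp_slope * latent[i]) *
            stats::rgamma(nv, shape = cfg$amp_shape, rate = cfg$amp_shape) *
            ifelse(true_type == "vein", cfg$vein_amp_factor, 1)
        }
        freq <- sample(1:3, nv, replace = TRUE)
        phase <- stats::runif(nv, 0, 2 * pi)
        ang <- stats::runif(nv, 0, 2 * pi)
        x0 <- stats::runif(nv, 200, 1300)
        y0 <- stats::runif(nv, 200, 1300)
        flips <- stats::runif(nv * npts) < cfg$av_label_noise
        pts <- vector("list", nv)
        n_a <- integer(nv); n_v <- integer(nv)
        for (v in seq_len(nv)) {
          tt <- tgrid * L[v]
          perp <- amp[v] * L[v] * sin(2 * pi * freq[v] * tgrid + phase[v])
          ca <- cos(ang[v]); sa <- sin(ang[v])
          pts[[v]] <- cbind(x = x0[v] + ca * tt - sa * perp,
                            y = y0[v] + sa * tt + ca * perp)
          lab_artery <- xor(true_type[v] == "artery",
                            flips[((v - 1) * npts + 1):(v * npts)])
          n_a[v] <- sum(lab_artery)
          n_v[v] <- npts - n_a[v]
        }
        recs[[length(recs) + 1]] <- data.table::data.table(
          subject = subj[i], eye = eye, image = img_id,
          timepoint = im - 1L, vessel_id = sprintf("%s_V%03d", img_id,
                                                   seq_len(nv)),
          true_type = true_type, n_artery_px = n_a, n_vein_px = n_v,
          points = pts)
      }
    }
    rows[[i]] <- data.table::rbindlist(recs)
  }
  data.table::rbindlist(rows)
}
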