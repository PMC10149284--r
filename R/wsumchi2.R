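#' Tail probability of a weighted sum of chi-squared(1) variables
#'
#' Computes \eqn{P(\sum_k \lambda_k W_k \ge t)} where the \eqn{W_k} are
#' independent central \eqn{\chi^2_1} variables and the weights
#' \eqn{\lambda_k \ge 0} are typically the eigenvalues of a SNP-SNP
#' correlation matrix ("eigen-SNPs"). The survival function is evaluated by
#' Ruben's mixture-of-chi-squared series with a shape parameter
#' \eqn{\beta = 0.90625\,\lambda_{\min}}, which makes every series
#' coefficient nonnegative, so the truncation error is bounded by the
#' mixture mass not yet accumulated. All arithmetic is 128-bit quadruple
#' precision (about 33 significant digits with exponent range beyond
#' 1e-4900), which resolves tail probabilities far below the 1e-100
#' reporting cutoff used for gene scores with full relative accuracy.
#'
#' @param weights numeric vector of nonnegative weights (eigenvalues).
#'   Values in \[-1e-8, 0) are clipped to zero; more negative values are an
#'   error. At least one weight must be positive.
#' @param t nonnegative quantile at which the upper tail is evaluated.
#' @param precision_digits requested number of significant digits of the
#'   tail probability. Requests up to 15 digits run on the fast hardware
#'   double-precision backend; larger requests switch to the quadruple
#'   precision backend and are honoured up to its 33-digit limit.
#' @param max_terms maximum number of series terms.
#' @param stop_below optional early-stop threshold: if the whole tail is
#'   provably below this probability the series stops and
#'   `stopped_below = TRUE` is returned (used for gene scores that are
#'   reported as "> 100" on the \eqn{-\log_{10}} scale anyway). 0 disables.
#'
#' @return A list with elements `p` (double; underflows to 0 below about
#'   1e-308 — use `neg_log10_p`), `neg_log10_p` (double),
#'   `neg_log10_p_repr` (33-significant-digit character representation of
#'   \eqn{-\log_{10} p}, for cross-checks beyond double resolution),
#'   `terms`, `converged`, `stopped_below`, and `tail_mass_bound` (upper
#'   bound on the truncated mixture mass).
#'
#' @examples
#' # equal weights reduce to an ordinary chi-squared tail
#' weighted_chi2_sf(c(1, 1, 1), qchisq(0.95, df = 3))$p  # 0.05
#' @export
weighted_chi2_sf <- function(weights, t, precision_digits = 30,
                             max_terms = 200000L, stop_below = 0) {
  if (!is.numeric(weights) || length(weights) < 1) {
    stop("'weights' must be a non-empty numeric vector")
  }
  if (any(!is.finite(weights))) stop("'weights' must be finite")
  if (any(weights < -1e-8)) {
    stop("negative weight beyond tolerance (-1e-8): spectrum error")
  }
  weights <- pmax(weights, 0)
  if (all(weights == 0)) stop("all weights are zero")
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("'t' must be a single finite nonnegative number")
  }
  digits <- min(precision_digits, 33)
  out <- ruben_sf_cpp(as.numeric(weights), as.numeric(t),
                      rel_tol = 10^(-digits), max_terms = as.integer(max_terms),
                      use_quad = digits > 15, stop_below = stop_below)
  if (!out$converged) {
    warning(sprintf(
      "series not converged after %d terms; tail mass bound %.3g",
      out$terms, out$tail_mass_bound))
  }
  out
}
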