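#' Distance factor (arc-over-chord) tortuosity of a vessel centerline
#'
#' The distance factor DF of a vessel segment is the total polyline length
#' s(C) divided by the Euclidean distance between the segment endpoints
#' chord(C). A straight segment has DF = 1; any deviation increases it.
#'
#' @param points two-column numeric matrix of ordered centerline
#'   coordinates (pixel units, origin top-left, y increasing downward).
#' @return The distance factor, a scalar >= 1 (up to rounding).
#' @examples
#' distance_factor(cbind(c(0, 0, 0), c(0, 5, 10)))  # 1
#' @export
distance_factor <- function(points) {
  points <- as_centerline(points, min_points = 2)
  d <- sqrt(rowSums(diff(points)^2))
  chord <- sqrt(sum((points[nrow(points), ] - points[1, ])^2))
  if (chord < .Machine$double.eps * max(sum(d), 1)) {
    stop("degenerate segment: coincident endpoints (chord = 0)")
  }
  sum(d) / chord
}

#' Curvature-integral tortuosity measures of a vessel centerline
#'
#' Estimates the curvature \eqn{\kappa} along an arc-length-parameterized
#' resampling of the centerline and integrates it:
#' \eqn{\tau_2 = \int |\kappa| ds}, \eqn{\tau_3 = \int \kappa^2 ds}, and
#' the normalized variants \eqn{\tau_4 = \tau_2/s}, \eqn{\tau_5 = \tau_3/s},
#' \eqn{\tau_6 = \tau_2/chord}, \eqn{\tau_7 = \tau_3/chord}, where s is the
#' arc length. \eqn{\tau_2}, \eqn{\tau_4} and \eqn{\tau_6} are unit-free;
#' \eqn{\tau_3}, \eqn{\tau_5} and \eqn{\tau_7} carry a 1/length scale
#' (halving under a uniform x2 rescaling of the coordinates).
#'
#' The centerline is interpolated with cubic splines against cumulative
#' chord length, optionally smoothed ([stats::smooth.spline] with
#' `spar = smoothing` when `smoothing > 0`), resampled on a uniform grid,
#' and differentiated by central differences;
#' \eqn{\kappa = |x'y'' - y'x''| / (x'^2 + y'^2)^{3/2}} is integrated by
#' the trapezoidal rule.
#'
#' @param points two-column numeric matrix of ordered centerline points.
#' @param smoothing smoothing parameter in \[0, 1\]; 0 (default)
#'   interpolates the points exactly.
#' @param n_grid number of resampling points (default: number of input
#'   points, at least 100, at most 4000).
#' @return Named numeric vector `tau2` ... `tau7`, plus `s` (arc length)
#'   and `chord`. All `NA` (a not-computable marker, excluded from medians
#'   downstream) when fewer than 5 points are supplied.
#' @export
curvature_measures <- function(points, smoothing = 0, n_grid = NULL) {
  na <- c(tau2 = NA_real_, tau3 = NA_real_, tau4 = NA_real_,
          tau5 = NA_real_, tau6 = NA_real_, tau7 = NA_real_,
          s = NA_real_, chord = NA_real_)
  points <- as_centerline(points, min_points = 2)
  if (nrow(points) < 5) return(na)
  sr <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  if (is.null(n_grid)) n_grid <- min(max(nrow(points), 100), 4000)
  if (smoothing > 0 && nrow(points) >= 10) {
    fx <- stats::smooth.spline(sr, points[, 1], spar = smoothing)
    fy <- stats::smooth.spline(sr, points[, 2], spar = smoothing)
    grid <- seq(0, max(sr), length.out = n_grid)
    x <- stats::predict(fx, grid)$y
    y <- stats::predict(fy, grid)$y
  } else {
    grid <- seq(0, max(sr), length.out = n_grid)
    x <- stats::spline(sr, points[, 1], xout = grid)$y
    y <- stats::spline(sr, points[, 2], xout = grid)$y
  }
  h <- grid[2] - grid[1]
  x1 <- fd_gradient(x, h); y1 <- fd_gradient(y, h)
  x2 <- fd_gradient(x1, h); y2 <- fd_gradient(y1, h)
  speed2 <- x1^2 + y1^2
  kappa <- abs(x1 * y2 - y1 * x2) / pmax(speed2^1.5, .Machine$double.eps)
  ds <- sqrt(speed2)           # d(arc)/d(grid), ~1 on an arc-length grid
  s <- trapz(grid, ds)
  chord <- sqrt((x[n_grid] - x[1])^2 + (y[n_grid] - y[1])^2)
  tau2 <- trapz(grid, kappa * ds)
  tau3 <- trapz(grid, kappa^2 * ds)
  if (chord < .Machine$double.eps * max(s, 1)) {
    stop("degenerate segment: coincident endpoints (chord = 0)")
  }
  c(tau2 = tau2, tau3 = tau3, tau4 = tau2 / s, tau5 = tau3 / s,
    tau6 = tau2 / chord, tau7 = tau3 / chord, s = s, chord = chord)
}

#' All seven tortuosity measures of one centerline
#'
#' Convenience wrapper returning the distance factor together with the six
#' curvature-integral measures.
#'
#' @inheritParams curvature_measures
#' @return Named numeric vector `DF`, `tau2` ... `tau7`, `s`, `chord`.
#' @export
tortuosity_measures <- function(points, smoothing = 0, n_grid = NULL) {
  c(DF = distance_factor(points),
    curvature_measures(points, smoothing = smoothing, n_grid = n_grid))
}

#' Call the vessel type of a segment from pixel-wise artery/vein labels
#'
#' The difference between the number of pixels classified as arterial and
#' venous is used as a score that must be positive (artery) or negative
#' (vein); a zero score leaves the segment unclassified, which excludes it
#' from the artery- and vein-specific phenotypes but not from the combined
#' one.
#'
#' @param n_artery_px,n_vein_px nonnegative pixel counts (vectorized).
#' @return Character vector in `c("artery", "vein", "unclassified")`.
#' @examples
#' call_vessel_type(10, 4)  # "artery"
#' call_vessel_type(5, 5)   # "unclassified"
#' @export
call_vessel_type <- function(n_artery_px, n_vein_px) {
  if (any(n_artery_px < 0 | n_vein_px < 0)) stop("pixel counts must be >= 0")
  score <- n_artery_px - n_vein_px
  ifelse(score > 0, "artery", ifelse(score < 0, "vein", "unclassified"))
}

#' Evaluate an artery/vein classifier against true labels
#'
#' AUC is computed by the rank statistic (Mann-Whitney, ties counted 1/2);
#' accuracy is the fraction of correct calls among segments the score
#' actually classifies (nonzero score).
#'
#' @param scores numeric classifier scores (positive calls artery).
#' @param truth character or factor with values "artery"/"vein" (or any
#'   two-level coding where the first sorted level is the negative class).
#' @return List with `auc`, `accuracy`, `n_classified`.
#' @export
evaluate_av_classifier <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  is_artery <- truth == "artery"
  n1 <- sum(is_artery); n0 <- sum(!is_artery)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: truth contains a single class")
  r <- rank(scores)  # average ranks handle ties as 1/2
  auc <- (sum(r[is_artery]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  classified <- scores != 0
  acc <- if (any(classified)) {
    called_artery <- scores[classified] > 0
    mean(called_artery == is_artery[classified])
  } else NA_real_
  list(auc = auc, accuracy = acc, n_classified = sum(classified))
}

# --- internal helpers ------------------------------------------------------

as_centerline <- function(points, min_points = 2) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2) {
    stop("'points' must be a two-column numeric matrix")
  }
  if (nrow(points) < min_points) {
    stop(sprintf("at least %d points are required", min_points))
  }
  dup <- rowSums(abs(diff(points))) == 0
  if (any(dup)) points <- points[c(TRUE, !dup), , drop = FALSE]
  if (nrow(points) < min_points) {
    stop("degenerate segment: consecutive points coincide")
  }
  points
}

fd_gradient <- function(v, h) {
  n <- length(v)
  g <- numeric(n)
  g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  g[1] <- (v[2] - v[1]) / h
  g[n] <- (v[n] - v[n - 1]) / h
  g
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[2:n] - x[1:(n - 1)]) * (y[2:n] + y[1:(n - 1)])) / 2
}
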