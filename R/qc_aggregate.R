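#' Compute tortuosity measures for every segment in a centerline table
#'
#' @param segments a centerline table as produced by [gen_vasculature()] or
#'   [read_centerlines()]: one row per vessel segment with at least the
#'   columns `subject`, `eye`, `image`, `timepoint`, `n_artery_px`,
#'   `n_vein_px` and a `points` list-column of two-column matrices.
#' @param smoothing passed to [curvature_measures()].
#' @return The same table with per-segment columns `DF`, `tau2` ... `tau7`,
#'   `s`, `chord` and the called `vessel_type` appended.
#' @export
measure_segments <- function(segments, smoothing = 0) {
  segments <- data.table::as.data.table(segments)
  vals <- vapply(segments$points, function(p) {
    tortuosity_measures(p, smoothing = smoothing)
  }, numeric(9))
  out <- cbind(segments, data.table::as.data.table(t(vals)))
  out[, vessel_type := call_vessel_type(n_artery_px, n_vein_px)]
  out[]
}

#' Image-level quality control
#'
#' An image passes QC iff its total vasculature length and its vessel count
#' both lie within the configured lower/upper bounds. The thresholds are
#' study-level configuration; defaults are total length in
#' \[2000, 1e6\] pixels and 10 to 500 vessels.
#'
#' @param segments measured segment table ([measure_segments()] output) for
#'   one or more images; QC is applied per (subject, eye, image).
#' @param length_bounds numeric length-2, bounds on the summed segment arc
#'   length per image, in pixels.
#' @param n_bounds numeric length-2, bounds on the number of vessels.
#' @return A data.table with one row per image: `subject`, `eye`, `image`,
#'   `timepoint`, `total_vasculature_length`, `n_vessels`, `pass`,
#'   `reasons` (';'-joined violated bounds, empty when passing).
#' @export
image_qc <- function(segments, length_bounds = c(2000, 1e6),
                     n_bounds = c(10, 500)) {
  stopifnot(length(length_bounds) == 2, diff(length_bounds) >= 0,
            length(n_bounds) == 2, diff(n_bounds) >= 0)
  segments <- data.table::as.data.table(segments)
  qc <- segments[, .(
    total_vasculature_length = sum(s, na.rm = TRUE),
    n_vessels = .N,
    timepoint = timepoint[1]
  ), by = .(subject, eye, image)]
  reason_of <- function(len, n) {
    r <- character(0)
    if (len < length_bounds[1]) r <- c(r, "total length below lower bound")
    if (len > length_bounds[2]) r <- c(r, "total length above upper bound")
    if (n < n_bounds[1]) r <- c(r, "n_vessels below lower bound")
    if (n > n_bounds[2]) r <- c(r, "n_vessels above upper bound")
    paste(r, collapse = ";")
  }
  qc[, reasons := mapply(reason_of, total_vasculature_length, n_vessels)]
  qc[, pass := reasons == ""]
  qc[]
}

#' Aggregate per-segment tortuosity to one value per subject
#'
#' Implements the aggregation rule: within each eye only the earliest
#' timepoint's image is kept; per image the median of the per-segment
#' values is taken; across the available eyes (at most one image each) the
#' per-image medians are averaged. Subjects with no QC-passing image get no
#' value and are dropped from downstream association for that trait.
#'
#' @param segments measured segment table ([measure_segments()]).
#' @param qc image QC table from [image_qc()]; only passing images are
#'   used. `NULL` skips QC filtering.
#' @param measure which measure column to aggregate (e.g. `"DF"`, `"tau3"`).
#' @param vessel_class one of `"combined"`, `"artery"`, `"vein"`.
#'   Artery/vein keep only segments called that type; combined keeps all
#'   segments including unclassified ones.
#' @return data.table with `subject`, `vessel_class`, `measure`, `value`,
#'   `n_images_used` (one row per subject that has at least one usable
#'   image).
#' @export
aggregate_subject <- function(segments, qc = NULL, measure = "DF",
                              vessel_class = c("combined", "artery", "vein")) {
  vessel_class <- match.arg(vessel_class)
  segments <- data.table::as.data.table(segments)
  if (!measure %in% names(segments)) {
    stop(sprintf("measure column '%s' not present; run measure_segments()",
                 measure))
  }
  if (!is.null(qc)) {
    keep_imgs <- qc[pass == TRUE, .(subject, eye, image)]
    segments <- segments[keep_imgs, on = c("subject", "eye", "image")]
  }
  if (vessel_class != "combined") {
    segments <- segments[vessel_type == vessel_class]
  }
  if (nrow(segments) == 0) {
    return(data.table::data.table(subject = character(0),
                                  vessel_class = character(0),
                                  measure = character(0),
                                  value = numeric(0),
                                  n_images_used = integer(0)))
  }
  v <- segments[[measure]]
  segments <- segments[!is.na(v)]
  # earliest timepoint per eye; ties broken by image id for determinism
  per_image <- segments[, .(med = stats::median(.SD[[1]]),
                            timepoint = timepoint[1]),
                        by = .(subject, eye, image),
                        .SDcols = c(measure, "timepoint")]
  data.table::setorder(per_image, subject, eye, timepoint, image)
  chosen <- per_image[, .SD[1], by = .(subject, eye)]
  out <- chosen[, .(value = mean(med), n_images_used = .N), by = subject]
  out[, `:=`(vessel_class = vessel_class, measure = measure)]
  data.table::setcolorder(out, c("subject", "vessel_class", "measure",
                                 "value", "n_images_used"))
  out[]
}

#' Full phenotyping chain: measures, QC, aggregation
#'
#' @param segments centerline table.
#' @param measures character vector of measures to aggregate.
#' @param classes vessel classes to phenotype.
#' @param smoothing passed to [curvature_measures()].
#' @param length_bounds,n_bounds passed to [image_qc()].
#' @return List with `phenotypes` (long data.table), `qc` (image QC table)
#'   and `segments` (measured segment table).
#' @export
compute_phenotypes <- function(segments, measures = "DF",
                               classes = c("combined", "artery", "vein"),
                               smoothing = 0,
                               length_bounds = c(2000, 1e6),
                               n_bounds = c(10, 500)) {
  measured <- measure_segments(segments, smoothing = smoothing)
  qc <- image_qc(measured, length_bounds = length_bounds, n_bounds = n_bounds)
  phen <- data.table::rbindlist(lapply(classes, function(cl) {
    data.table::rbindlist(lapply(measures, function(ms) {
      aggregate_subject(measured, qc, measure = ms, vessel_class = cl)
    }))
  }))
  list(phenotypes = phen, qc = qc, segments = measured)
}
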