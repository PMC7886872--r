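#' Activity scaling constants
#'
#' Bookkeeping constants linking sphere counts to activity: a 3 GBq
#' calibration vial contains 44.48 million spheres, and the average
#' activity per sphere is taken as 50 Bq. Note these two published
#' constants are mutually inconsistent (44.48e6 spheres / 3 GBq implies
#' about 67.4 Bq/sphere); both are carried independently, with 50
#' Bq/sphere the default used for activity accounting, and both are echoed
#' in every report.
#'
#' @param injected_activity_GBq activity of the infusion, GBq.
#' @param activity_per_sphere_Bq average activity per sphere, Bq.
#' @param spheres_per_vial spheres in the calibration vial.
#' @param vial_activity_GBq calibration vial activity, GBq.
#' @return list of class `activity_scaling`.
#' @export
activity_scaling <- function(injected_activity_GBq,
                             activity_per_sphere_Bq = 50,
                             spheres_per_vial = 44.48e6,
                             vial_activity_GBq = 3) {
  check_scalar(injected_activity_GBq, "injected_activity_GBq",
               min = 0, strict_min = TRUE)
  check_scalar(activity_per_sphere_Bq, "activity_per_sphere_Bq",
               min = 0, strict_min = TRUE)
  check_scalar(spheres_per_vial, "spheres_per_vial",
               min = 0, strict_min = TRUE)
  structure(list(injected_activity_GBq = injected_activity_GBq,
                 activity_per_sphere_Bq = activity_per_sphere_Bq,
                 spheres_per_vial = spheres_per_vial,
                 vial_activity_GBq = vial_activity_GBq),
            class = "activity_scaling")
}

#' Number of spheres represented by an infusion
#'
#' `injected_activity / activity_per_sphere`; each simulated particle then
#' stands for `spheres_represented / n_particles` real spheres.
#'
#' @param scaling an [activity_scaling()].
#' @return sphere count (may be fractional).
#' @export
spheres_represented <- function(scaling) {
  scaling$injected_activity_GBq * 1e9 / scaling$activity_per_sphere_Bq
}

#' Per-segment percentages from per-outlet exit counts
#'
#' The activity reaching a segment is the activity leaving the domain
#' through the outlets that irrigate that segment, so the segment
#' percentage is 100 times the summed exit counts of its outlets over the
#' total exited count. Residents are excluded from the numerator and the
#' denominator.
#'
#' @param result a `transport_result`.
#' @param outlet_map data.frame `outlet_id`, `segment` covering every
#'   outlet in `result`.
#' @return named numeric vector of percentages over the segments of
#'   `outlet_map` (zeros included), summing to 100.
#' @export
counts_to_segment_distribution <- function(result, outlet_map) {
  miss <- setdiff(names(result$exits), outlet_map$outlet_id)
  if (length(miss))
    stop_input("outlet(s) missing from the outlet map: ",
               paste(miss, collapse = ", "))
  tot <- sum(result$exits)
  if (tot == 0) stop_input("no exited particles; distribution undefined")
  segs <- sort(unique(outlet_map$segment))
  seg_of <- stats::setNames(outlet_map$segment, outlet_map$outlet_id)
  cnt <- stats::setNames(numeric(length(segs)), segs)
  agg <- tapply(as.numeric(result$exits), seg_of[names(result$exits)], sum)
  cnt[names(agg)] <- agg
  100 * cnt / tot
}

#' Per-segment activity and mean activity concentration
#'
#' Distributes the injected activity over segments according to the
#' percentages and divides by the total segment volume (healthy + tumor
#' parenchyma) to give the mean activity concentration in Bq/ml.
#'
#' @param percent named per-segment percentage vector (sums to 100).
#' @param scaling an [activity_scaling()].
#' @param segments segment table with `segment`, `healthy_volume_ml`,
#'   `tumor_volume_ml`.
#' @return object of class `segment_distribution`: data.frame `segment`,
#'   `percent`, `activity_Bq`, `concentration_Bq_ml`, with the scaling as
#'   an attribute.
#' @export
distribution_to_activity <- function(percent, scaling, segments) {
  if (abs(sum(percent) - 100) > 1e-9 * 100)
    stop_input("percentages must sum to 100")
  vol <- stats::setNames(
    segments$healthy_volume_ml + segments$tumor_volume_ml,
    segments$segment)
  segs <- names(percent)
  if (any(!(segs %in% names(vol))))
    stop_input("segment(s) missing from the volume table: ",
               paste(setdiff(segs, names(vol)), collapse = ", "))
  act <- scaling$injected_activity_GBq * 1e9 * percent / 100
  zv <- act > 0 & vol[segs] <= 0
  if (any(zv))
    stop("activity assigned to zero-volume segment(s): ",
         paste(segs[zv], collapse = ", "), call. = FALSE)
  conc <- ifelse(vol[segs] > 0, act / vol[segs], 0)
  structure(
    data.frame(segment = segs, percent = as.numeric(percent),
               activity_Bq = as.numeric(act),
               concentration_Bq_ml = as.numeric(conc),
               stringsAsFactors = FALSE, row.names = NULL),
    scaling = scaling, class = c("segment_distribution", "data.frame"))
}

#' Combine per-infusion distributions, weighted by infused activity
#'
#' Patients may receive several infusions; the combined per-segment
#' activity is the sum of the per-infusion activities, and combined
#' percentages renormalize that sum.
#'
#' @param dists list of `segment_distribution` objects (same segments).
#' @return a combined `segment_distribution`.
#' @export
combine_distributions <- function(dists) {
  stopifnot(length(dists) >= 1)
  segs <- dists[[1]]$segment
  act <- rep(0, length(segs))
  tot_GBq <- 0
  for (d in dists) {
    if (!identical(d$segment, segs))
      stop_input("distributions cover different segments")
    act <- act + d$activity_Bq
    tot_GBq <- tot_GBq + attr(d, "scaling")$injected_activity_GBq
  }
  # recover segment volumes from any constituent with nonzero concentration
  vols <- rep(NA_real_, length(segs))
  for (d in dists) {
    nz <- d$concentration_Bq_ml > 0
    vols[nz] <- d$activity_Bq[nz] / d$concentration_Bq_ml[nz]
  }
  conc <- ifelse(!is.na(vols) & vols > 0, act / vols, 0)
  structure(
    data.frame(segment = segs, percent = 100 * act / sum(act),
               activity_Bq = act, concentration_Bq_ml = conc,
               stringsAsFactors = FALSE),
    scaling = activity_scaling(tot_GBq),
    class = c("segment_distribution", "data.frame"))
}

#' Write a per-segment distribution CSV
#'
#' Columns: `segment,percent,activity_Bq,concentration_Bq_ml`.
#'
#' @param dist a `segment_distribution`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(dist, path) {
  utils::write.csv(as.data.frame(dist)[, c("segment", "percent",
                                           "activity_Bq",
                                           "concentration_Bq_ml")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "percent")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_input("distribution CSV missing column(s): ",
               paste(miss, collapse = ", "))
  if (nrow(d) == 0) stop_input("empty distribution table")
  d
}
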