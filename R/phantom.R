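#' Synthetic liver perfusion phantom
#'
#' Draws a liver phantom over the eight Couinaud segments (S1-S8): healthy
#' parenchyma volumes, zero or more tumors (each hosted by one or two
#' segments), a tumoral perfusion per tumor and a healthy perfusion per
#' segment. Value envelopes reflect clinically reported ranges: healthy
#' volumes up to 400 ml, tumor volumes up to 70 ml, healthy perfusion
#' 0.02-0.12 ml/min/ml and tumoral perfusion 0.35-1.30 ml/min/ml.
#'
#' @param n_tumors number of tumors (>= 0). A tumor spanning two segments
#'   is bookkept as two co-located tumors, one per host segment, so the
#'   returned `tumors` table may have more rows than `n_tumors` distinct
#'   tumor ids.
#' @param seed integer seed; the phantom is a pure function of
#'   `(n_tumors, seed)`.
#' @return list with
#'   * `segments`: data.frame `segment`, `healthy_volume_ml`,
#'     `tumor_volume_ml`;
#'   * `tumors`: data.frame `tumor_id`, `segment`, `volume_ml`,
#'     `k2_ml_min_ml` (one row per tumor-segment share);
#'   * `perfusion`: data.frame `segment`, `k1_ml_min_ml`.
#' @examples
#' ph <- generate_liver_phantom(n_tumors = 2, seed = 42)
#' ph$segments
#' @export
generate_liver_phantom <- function(n_tumors = 2, seed = NULL) {
  check_scalar(n_tumors, "n_tumors", min = 0, integer = TRUE)
  with_seed(seed, {
    segs <- paste0("S", 1:8)
    healthy <- round(stats::runif(8, 20, 400), 1)
    k1 <- round(stats::runif(8, 0.02, 0.12), 4)
    tumors <- data.frame(tumor_id = character(0), segment = character(0),
                         volume_ml = numeric(0), k2_ml_min_ml = numeric(0),
                         stringsAsFactors = FALSE)
    if (n_tumors > 0) {
      for (i in seq_len(n_tumors)) {
        vol <- round(stats::runif(1, 1, 70), 2)
        k2 <- round(stats::runif(1, 0.35, 1.30), 4)
        n_host <- sample(1:2, 1, prob = c(0.7, 0.3))
        hosts <- sample(segs, n_host)
        share <- if (n_host == 1) 1 else {
          w <- stats::runif(1, 0.3, 0.7); c(w, 1 - w)
        }
        tumors <- rbind(tumors, data.frame(
          tumor_id = paste0("t", i), segment = hosts,
          volume_ml = vol * share, k2_ml_min_ml = k2,
          stringsAsFactors = FALSE))
      }
    }
    tv <- stats::setNames(numeric(8), segs)
    if (nrow(tumors))
      for (s in unique(tumors$segment))
        tv[s] <- sum(tumors$volume_ml[tumors$segment == s])
    list(
      segments = data.frame(segment = segs, healthy_volume_ml = healthy,
                            tumor_volume_ml = as.numeric(tv),
                            stringsAsFactors = FALSE),
      tumors = tumors,
      perfusion = data.frame(segment = segs, k1_ml_min_ml = k1,
                             stringsAsFactors = FALSE))
  })
}

#' Assign tree outlets to liver segments
#'
#' Every liver segment with positive tissue volume receives at least one
#' outlet and every outlet irrigates exactly one segment. Assignment is a
#' seeded random surjection: one outlet is first reserved per positive
#' segment, remaining outlets are distributed uniformly.
#'
#' @param tree an `arterial_tree`.
#' @param segments segment table (`segment`, `healthy_volume_ml`,
#'   `tumor_volume_ml`).
#' @param seed integer seed.
#' @return data.frame `outlet_id`, `segment`.
#' @export
map_outlets_to_segments <- function(tree, segments, seed = NULL) {
  stopifnot(inherits(tree, "arterial_tree"))
  pos <- segments$segment[segments$healthy_volume_ml +
                            segments$tumor_volume_ml > 0]
  outs <- tree$outlet_ids
  if (length(outs) < length(pos))
    stop_input("tree has ", length(outs), " outlets but ", length(pos),
               " segments need irrigation")
  with_seed(seed, {
    sh <- sample(outs)
    seg_of <- character(length(sh))
    seg_of[seq_along(pos)] <- pos
    extra <- length(sh) - length(pos)
    if (extra > 0)
      seg_of[length(pos) + seq_len(extra)] <-
        sample(pos, extra, replace = TRUE)
    out <- data.frame(outlet_id = sh, segment = seg_of,
                      stringsAsFactors = FALSE)
    out[order(out$outlet_id), , drop = FALSE]
  })
}

#' Catheter placement and injection protocol
#'
#' Describes where the microcatheter tip sits inside a vessel and how the
#' spheres are injected. The tip centre is offset from the vessel axis by
#' `radial_offset_fraction * (R_vessel - catheter_inner_radius)` along the
#' azimuth direction, which keeps the catheter lumen inside the vessel
#' lumen for any fraction in [0, 1).
#'
#' @param vessel_id id of the vessel holding the tip.
#' @param axial_fraction tip position along the vessel, 0 = inlet end.
#' @param radial_offset_fraction 0 = centred, towards 1 = at the wall.
#' @param azimuth direction of the radial offset, radians, measured in the
#'   vessel cross-section basis.
#' @param injection_velocity sphere injection speed, m/s.
#' @param injected_activity activity of the infusion, GBq.
#' @param catheter_inner_radius catheter lumen radius, m.
#' @return a `catheter_placement` list.
#' @export
catheter_placement <- function(vessel_id, axial_fraction = 0.5,
                               radial_offset_fraction = 0, azimuth = 0,
                               injection_velocity = 0.5,
                               injected_activity = 0.5,
                               catheter_inner_radius = 1.4e-4) {
  check_scalar(axial_fraction, "axial_fraction", min = 0, max = 1)
  if (radial_offset_fraction < 0 || radial_offset_fraction >= 1)
    stop_input("radial_offset_fraction must be in [0, 1)")
  check_scalar(injection_velocity, "injection_velocity",
               min = 0, strict_min = TRUE)
  check_scalar(injected_activity, "injected_activity",
               min = 0, strict_min = TRUE)
  check_scalar(catheter_inner_radius, "catheter_inner_radius",
               min = 0, strict_min = TRUE)
  structure(list(vessel_id = vessel_id, axial_fraction = axial_fraction,
                 radial_offset_fraction = radial_offset_fraction,
                 azimuth = azimuth, injection_velocity = injection_velocity,
                 injected_activity = injected_activity,
                 catheter_inner_radius = catheter_inner_radius),
            class = "catheter_placement")
}

#' Synthesize a noisy "observed" activity distribution
#'
#' Stand-in for a post-treatment PET-derived per-segment activity
#' distribution: adds independent Gaussian noise (in percentage points) to
#' the true percentages, clamps at zero and renormalizes to sum 100. With
#' `noise_sd = 0` the output equals the input exactly.
#'
#' @param true_percent named numeric vector of per-segment percentages
#'   (must sum to 100).
#' @param noise_sd Gaussian noise standard deviation, percentage points.
#' @param seed integer seed.
#' @return object of class `observed_distribution`: named percentage
#'   vector with attributes `noise_sd` and `seed`.
#' @export
synthesize_observed_distribution <- function(true_percent, noise_sd = 2,
                                             seed = NULL) {
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  if (abs(sum(true_percent) - 100) > 1e-6)
    stop_input("true_percent must sum to 100")
  out <- if (noise_sd == 0) true_percent else with_seed(seed, {
    x <- pmax(true_percent + stats::rnorm(length(true_percent), 0, noise_sd), 0)
    if (sum(x) == 0) x <- true_percent  # pathological: keep the truth
    100 * x / sum(x)
  })
  structure(out, noise_sd = noise_sd, seed = seed,
            class = c("observed_distribution", class(out)))
}
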