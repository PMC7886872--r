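#' Per-segment arterial flow rate from volumes and perfusions
#'
#' The arterial blood flow feeding a liver segment is the healthy
#' parenchyma volume times the healthy perfusion plus, for each tumor
#' hosted by the segment, the tumor volume times that tumor's perfusion:
#' \deqn{q_s = V_{0,s}\,k^*_{1,s} + \sum_i V_{c,i}\,k_{2,i}.}
#'
#' @param healthy_volume healthy tissue volume, ml.
#' @param k1 healthy tissue perfusion, ml/min/ml.
#' @param tumor_volumes tumor tissue volumes in the segment, ml (may be
#'   empty).
#' @param tumor_k2 matching tumoral perfusions, ml/min/ml.
#' @return segment arterial flow rate, ml/min.
#' @examples
#' segment_flow_rate(327.3, 0.031, 2.5, 0.367)  # 11.0638 ml/min
#' @export
segment_flow_rate <- function(healthy_volume, k1,
                              tumor_volumes = numeric(0),
                              tumor_k2 = numeric(0)) {
  if (length(tumor_volumes) != length(tumor_k2))
    stop_input("tumor_volumes and tumor_k2 must have equal length")
  vals <- c(healthy_volume, k1, tumor_volumes, tumor_k2)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_input("volumes and perfusions must be finite and non-negative")
  healthy_volume * k1 + sum(tumor_volumes * tumor_k2)
}

#' Split a segment's healthy volume equally across its outlets
#'
#' All outlets irrigating a segment are assumed to irrigate the same
#' amount of healthy tissue, so each receives the total healthy volume
#' divided by the number of outlets.
#'
#' @param segment_healthy_volume healthy volume, ml.
#' @param outlet_ids character vector of outlet ids (length >= 1).
#' @return named numeric vector of ml per outlet.
#' @export
split_healthy_volume <- function(segment_healthy_volume, outlet_ids) {
  if (length(outlet_ids) < 1L) stop_input("at least one outlet required")
  check_scalar(segment_healthy_volume, "segment_healthy_volume", min = 0)
  stats::setNames(rep(segment_healthy_volume / length(outlet_ids),
                      length(outlet_ids)), outlet_ids)
}

#' Split a tumor's in-segment volume across outlets by proximity weights
#'
#' The tumor-to-outlet assignment is inherently a judgement call (which
#' outlets actually feed the lesion); it is made reproducible here through
#' explicit non-negative weights: outlet o receives
#' `volume * w_o / sum(w)`. Equal weights reproduce the
#' equally-irrigated case; a single positive weight directs the whole
#' tumor volume to one outlet.
#'
#' @param tumor_segment_volume tumor volume hosted in the segment, ml.
#' @param outlet_ids character vector of outlet ids.
#' @param proximity_weights numeric weights, same length, >= 0, not all 0.
#'   Default: equal weights.
#' @return named numeric vector of ml per outlet.
#' @export
split_tumor_volume <- function(tumor_segment_volume, outlet_ids,
                               proximity_weights = rep(1, length(outlet_ids))) {
  check_scalar(tumor_segment_volume, "tumor_segment_volume", min = 0)
  if (length(proximity_weights) != length(outlet_ids))
    stop_input("one weight per outlet required")
  if (any(proximity_weights < 0)) stop_input("weights must be >= 0")
  tot <- sum(proximity_weights)
  if (tot == 0) stop_input("weights must not all be zero")
  stats::setNames(tumor_segment_volume * proximity_weights / tot, outlet_ids)
}

#' Build outlet territories from an outlet-to-segment map and a phantom
#'
#' Combines the equal healthy split and the weighted tumor split into the
#' per-outlet tissue assignment: each outlet carries an equal share of its
#' segment's healthy volume plus proximity-weighted shares of every tumor
#' hosted by that segment.
#'
#' @param outlet_map data.frame `outlet_id`, `segment`.
#' @param segments segment table of the phantom.
#' @param tumors tumor table (`tumor_id`, `segment`, `volume_ml`,
#'   `k2_ml_min_ml`); may be empty.
#' @param tumor_weights optional named list: for tumor-segment key
#'   `"<tumor_id>:<segment>"`, a named weight vector over that segment's
#'   outlets. Defaults to equal weights.
#' @return data.frame `outlet_id`, `segment`, `healthy_ml`, plus a
#'   `tumor_ml` list-column of named per-tumor shares.
#' @export
build_outlet_territories <- function(outlet_map, segments, tumors = NULL,
                                     tumor_weights = NULL) {
  terr <- outlet_map[order(outlet_map$outlet_id), , drop = FALSE]
  terr$healthy_ml <- 0
  terr$tumor_ml <- vector("list", nrow(terr))
  for (i in seq_len(nrow(terr))) terr$tumor_ml[[i]] <- numeric(0)
  for (s in unique(terr$segment)) {
    idx <- which(terr$segment == s)
    hv <- segments$healthy_volume_ml[segments$segment == s]
    if (!length(hv))
      stop_input("segment ", s, " missing from segment table")
    terr$healthy_ml[idx] <- split_healthy_volume(hv, terr$outlet_id[idx])
    if (!is.null(tumors) && nrow(tumors)) {
      trows <- tumors[tumors$segment == s, , drop = FALSE]
      for (j in seq_len(nrow(trows))) {
        key <- paste0(trows$tumor_id[j], ":", s)
        w <- tumor_weights[[key]] %||% rep(1, length(idx))
        sh <- split_tumor_volume(trows$volume_ml[j], terr$outlet_id[idx], w)
        for (k in seq_along(idx)) {
          cur <- terr$tumor_ml[[idx[k]]]
          cur[trows$tumor_id[j]] <- sh[k]
          terr$tumor_ml[[idx[k]]] <- cur
        }
      }
    }
  }
  terr
}

#' Per-outlet flow boundary conditions
#'
#' The blood flow leaving each outlet is the healthy volume assigned to it
#' times the segment's healthy perfusion plus each assigned tumor volume
#' times that tumor's perfusion. Flow fractions are flows normalized by
#' the total (inlet) flow.
#'
#' @param territories output of [build_outlet_territories()].
#' @param perfusion data.frame `segment`, `k1_ml_min_ml`.
#' @param tumors tumor table carrying `tumor_id` and `k2_ml_min_ml`.
#' @return data.frame `outlet_id`, `segment`, `flow_ml_min`,
#'   `flow_fraction`, ordered by `outlet_id`.
#' @export
outlet_flow_rates <- function(territories, perfusion, tumors = NULL) {
  k1 <- stats::setNames(perfusion$k1_ml_min_ml, perfusion$segment)
  k2 <- if (!is.null(tumors) && nrow(tumors))
    stats::setNames(tumors$k2_ml_min_ml,
                    tumors$tumor_id)[!duplicated(tumors$tumor_id)] else
    stats::setNames(numeric(0), character(0))
  miss <- setdiff(unique(territories$segment), names(k1))
  if (length(miss))
    stop_input("no perfusion entry for segment(s): ",
               paste(miss, collapse = ", "))
  q <- vapply(seq_len(nrow(territories)), function(i) {
    tm <- territories$tumor_ml[[i]]
    if (length(tm) && any(!(names(tm) %in% names(k2))))
      stop_input("no k2 for tumor(s): ",
                 paste(setdiff(names(tm), names(k2)), collapse = ", "))
    segment_flow_rate(territories$healthy_ml[i],
                      k1[[territories$segment[i]]],
                      unname(tm), unname(k2[names(tm)]))
  }, numeric(1))
  tot <- sum(q)
  bc <- data.frame(outlet_id = territories$outlet_id,
                   segment = territories$segment,
                   flow_ml_min = q,
                   flow_fraction = if (tot > 0) q / tot else NA_real_,
                   stringsAsFactors = FALSE)
  if (tot == 0)
    warning("all outlet flows are zero; flow fractions undefined",
            call. = FALSE)
  bc[order(bc$outlet_id), , drop = FALSE]
}

#' Inlet flow rate as the sum of the outlet flows
#'
#' @param bcs outlet boundary-condition table from [outlet_flow_rates()].
#' @return inlet arterial flow rate, ml/min.
#' @export
inlet_flow_rate <- function(bcs) {
  if (is.null(bcs) || nrow(bcs) < 1L)
    stop_input("at least one outlet BC required")
  sum(bcs$flow_ml_min)
}
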