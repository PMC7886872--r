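# CSV interfaces mirroring the clinical tables: a per-segment volume table
# (patient, segment, tumoral and healthy volume) and a per-tumor table
# (volume, tumoral and healthy perfusion in ml/min/100ml, host segments,
# injection velocity). Perfusions are converted to ml/min/ml on read;
# everything downstream works in ml/min/ml.

#' Read / write a per-segment volume table
#'
#' Schema: `patient,segment,tumoral_volume_ml,healthy_volume_ml`.
#'
#' @param path CSV path.
#' @param patient optional patient id filter on read.
#' @return data.frame with columns `segment`, `healthy_volume_ml`,
#'   `tumor_volume_ml` (and `patient` when unfiltered).
#' @export
read_segment_table <- function(path, patient = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "segment", "tumoral_volume_ml", "healthy_volume_ml")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_input("segment table missing column(s): ",
               paste(miss, collapse = ", "))
  if (nrow(d) == 0) stop_input("empty segment table")
  if (!is.null(patient)) {
    d <- d[d$patient == patient, , drop = FALSE]
    if (nrow(d) == 0) stop_input("no rows for patient ", patient)
  }
  out <- data.frame(segment = d$segment,
                    healthy_volume_ml = d$healthy_volume_ml,
                    tumor_volume_ml = d$tumoral_volume_ml,
                    stringsAsFactors = FALSE)
  if (is.null(patient)) out$patient <- d$patient
  out
}

#' @rdname read_segment_table
#' @param segments data.frame `segment`, `healthy_volume_ml`,
#'   `tumor_volume_ml`.
#' @param patient_id patient label to stamp on every row.
#' @export
write_segment_table <- function(segments, path, patient_id = "P1") {
  utils::write.csv(
    data.frame(patient = patient_id, segment = segments$segment,
               tumoral_volume_ml = segments$tumor_volume_ml,
               healthy_volume_ml = segments$healthy_volume_ml),
    path, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-tumor table
#'
#' Schema: `tumor,volume_ml,k2_ml_min_100ml,k1_ml_min_100ml,segments,
#' injection_velocity_m_s`; `segments` lists host segments separated by
#' `;`. Perfusions are stored in the file in ml/min/100ml and converted
#' to ml/min/ml on read. A tumor hosted by x segments is expanded into x
#' tumor records with the volume split equally across hosts.
#'
#' @param path CSV path.
#' @return list with `tumors` (data.frame `tumor_id`, `segment`,
#'   `volume_ml`, `k2_ml_min_ml`), `k1` (data.frame `segment`,
#'   `k1_ml_min_ml`, from the rows that state it) and `injections`
#'   (data.frame `tumor_id`, `injection_velocity_m_s`).
#' @export
read_tumor_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tumor", "volume_ml", "k2_ml_min_100ml", "k1_ml_min_100ml",
            "segments", "injection_velocity_m_s")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_input("tumor table missing column(s): ",
               paste(miss, collapse = ", "))
  tum <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    hosts <- trimws(strsplit(d$segments[i], ";", fixed = TRUE)[[1]])
    data.frame(tumor_id = d$tumor[i], segment = hosts,
               volume_ml = d$volume_ml[i] / length(hosts),
               k2_ml_min_ml = d$k2_ml_min_100ml[i] / 100,
               stringsAsFactors = FALSE)
  }))
  k1 <- unique(data.frame(segment = tum$segment,
                          k1_ml_min_ml = rep(d$k1_ml_min_100ml / 100,
                                             times = vapply(
                                               strsplit(d$segments, ";"),
                                               length, integer(1))),
                          stringsAsFactors = FALSE))
  list(tumors = tum, k1 = k1,
       injections = data.frame(tumor_id = d$tumor,
                               injection_velocity_m_s =
                                 d$injection_velocity_m_s,
                               stringsAsFactors = FALSE))
}

#' @rdname read_tumor_table
#' @param tumors data.frame `tumor_id`, `segment`, `volume_ml`,
#'   `k2_ml_min_ml` (per tumor-segment row).
#' @param k1 data.frame `segment`, `k1_ml_min_ml`.
#' @param injection_velocity_m_s velocity stamped on every row.
#' @export
write_tumor_table <- function(tumors, k1, path,
                              injection_velocity_m_s = 0.5) {
  k1v <- stats::setNames(k1$k1_ml_min_ml, k1$segment)
  ids <- unique(tumors$tumor_id)
  rows <- lapply(ids, function(id) {
    tt <- tumors[tumors$tumor_id == id, , drop = FALSE]
    data.frame(tumor = id, volume_ml = sum(tt$volume_ml),
               k2_ml_min_100ml = 100 * tt$k2_ml_min_ml[1],
               k1_ml_min_100ml = 100 * k1v[[tt$segment[1]]],
               segments = paste(tt$segment, collapse = ";"),
               injection_velocity_m_s = injection_velocity_m_s)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an outlet boundary-condition CSV
#'
#' Columns: `outlet_id,segment,flow_ml_min,flow_fraction`.
#'
#' @param bcs BC table from [outlet_flow_rates()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_outlet_bc_csv <- function(bcs, path) {
  utils::write.csv(bcs, path, row.names = FALSE)
  invisible(path)
}
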