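#' Planar bone-scan containers and I/O
#'
#' A `planar_scan` holds one projection of a whole-body bone scintigraphy
#' acquisition: a matrix of non-negative pixel counts (row 1 = image top),
#' a view label (`"ANTERIOR"`, `"POSTERIOR"` or `"UNKNOWN"`) and acquisition
#' metadata. Gamma cameras emit these acquisitions as DICOM; [read_planar_scan()]
#' reads the supported planar dialect and [write_bsi_report()] writes per-scan
#' BSI statistics to CSV.
#'
#' @param pixels numeric matrix of counts, all values `>= 0`.
#' @param view one of `"ANTERIOR"`, `"POSTERIOR"`, `"UNKNOWN"`.
#' @param metadata a list as returned by [scan_metadata()].
#' @return an object of class `planar_scan`.
#' @seealso [read_planar_scan()], [segment_scan()], [compute_bsi()]
#' @export
planar_scan <- function(pixels, view = "UNKNOWN", metadata = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(pixels < 0)) stop("pixel counts must be non-negative")
  view <- match.arg(view, c("ANTERIOR", "POSTERIOR", "UNKNOWN"))
  if (is.null(metadata)) {
    metadata <- scan_metadata(n_rows = nrow(pixels), n_cols = ncol(pixels))
  }
  if (metadata$n_rows != nrow(pixels) || metadata$n_cols != ncol(pixels)) {
    stop("metadata dimensions disagree with the pixel matrix")
  }
  structure(list(pixels = pixels, view = view, metadata = metadata),
            class = "planar_scan")
}

#' Acquisition metadata for a planar scan
#'
#' @param patient_pseudo_id opaque identifier passed through verbatim.
#' @param acquisition_date a `Date` or `NA`.
#' @param n_rows,n_cols matrix dimensions, positive integers.
#' @param energy_descriptor free-text energy window description or `NA`.
#' @param source_path origin file, or `""` for in-memory scans.
#' @return a list of class `scan_metadata`.
#' @export
scan_metadata <- function(patient_pseudo_id = "anonymous",
                          acquisition_date = as.Date(NA),
                          n_rows, n_cols,
                          energy_descriptor = NA_character_,
                          source_path = "") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows <= 0L || n_cols <= 0L) stop("matrix dimensions must be positive")
  structure(list(patient_pseudo_id = as.character(patient_pseudo_id),
                 acquisition_date = as.Date(acquisition_date),
                 n_rows = n_rows, n_cols = n_cols,
                 energy_descriptor = energy_descriptor,
                 source_path = source_path),
            class = "scan_metadata")
}

#' @export
print.planar_scan <- function(x, ...) {
  cat(sprintf("<planar_scan> %s view, %d x %d px, total counts %.0f\n",
              x$view, nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

view_from_label <- function(lab) {
  lab <- toupper(trimws(lab))
  if (grepl("^ANT|ANTERIOR", lab)) "ANTERIOR"
  else if (grepl("^POST|POSTERIOR", lab)) "POSTERIOR"
  else "UNKNOWN"
}

#' Read a planar bone-scan DICOM file
#'
#' Reads a planar nuclear-medicine DICOM file (the explicit-VR little-endian
#' dialect with unsigned 8/16-bit stored pixels, single- or multi-frame) and
#' returns one [planar_scan()] per frame. Rescale slope/intercept are applied
#' when present and the result clamped at zero. View labels come from the
#' per-frame descriptors when present; otherwise frames are labelled
#' `ANTERIOR` then `POSTERIOR` in storage order, and `UNKNOWN` beyond that.
#'
#' @param path path to a DICOM file.
#' @return a list of `planar_scan` objects, one per frame.
#' @export
read_planar_scan <- function(path) {
  attrs <- dicom_read_file(path)
  modality <- attrs[["0008,0060"]] %||% "NM"
  if (toupper(modality) %in% TOMO_MODALITIES) {
    stop(sprintf("unsupported modality '%s': only planar NM acquisitions are read", modality))
  }
  frames <- dicom_decode_frames(attrs)
  if (length(frames) == 0L) stop("DICOM file contains zero frames")
  slope <- as.numeric(attrs[["0028,1053"]] %||% "1")
  intercept <- as.numeric(attrs[["0028,1052"]] %||% "0")
  labels <- attrs[["0020,4000"]]
  labels <- if (is.null(labels) || !nzchar(labels)) character(0) else
    strsplit(labels, "\\", fixed = TRUE)[[1]]
  date_str <- attrs[["0008,0020"]]
  acq_date <- if (is.null(date_str) || !nzchar(date_str)) as.Date(NA) else
    as.Date(date_str, format = "%Y%m%d")
  pid <- attrs[["0010,0020"]] %||% "anonymous"

  lapply(seq_along(frames), function(k) {
    view <- if (k <= length(labels)) view_from_label(labels[k])
            else if (k == 1L) "ANTERIOR"
            else if (k == 2L) "POSTERIOR"
            else "UNKNOWN"
    px <- pmax(frames[[k]] * slope + intercept, 0)
    md <- scan_metadata(patient_pseudo_id = pid, acquisition_date = acq_date,
                        n_rows = nrow(px), n_cols = ncol(px),
                        energy_descriptor = attrs[["0008,0060"]] %||% NA_character_,
                        source_path = path)
    planar_scan(px, view = view, metadata = md)
  })
}

#' Write a CSV report of BSI statistics
#'
#' One data row per quantified scan: pseudo-id, acquisition date, views,
#' per-view ill and body pixel areas and BSI percentages, the combined BSI and
#' the number of manually excluded ROIs. Values round-trip through
#' [utils::read.csv()] at full precision.
#'
#' @param results a non-empty list; each element a list with components
#'   `metadata` ([scan_metadata()]) and `result` ([bsi_result()]).
#' @param path output CSV path.
#' @return the report `data.frame`, invisibly.
#' @export
write_bsi_report <- function(results, path) {
  if (length(results) == 0L) stop("results must be non-empty")
  one_row <- function(x) {
    md <- x$metadata; res <- x$result
    pv <- res$per_view
    get <- function(view, field) {
      if (!is.null(pv[[view]])) pv[[view]][[field]] else NA_real_
    }
    data.frame(
      patient_pseudo_id = md$patient_pseudo_id,
      acquisition_date = format(md$acquisition_date, "%Y-%m-%d"),
      views = paste(names(pv), collapse = "+"),
      ill_pixels_anterior = get("ANTERIOR", "ill_pixels"),
      body_pixels_anterior = get("ANTERIOR", "body_pixels"),
      bsi_anterior = get("ANTERIOR", "bsi_percent"),
      ill_pixels_posterior = get("POSTERIOR", "ill_pixels"),
      body_pixels_posterior = get("POSTERIOR", "body_pixels"),
      bsi_posterior = get("POSTERIOR", "bsi_percent"),
      bsi_combined = res$combined_bsi_percent,
      excluded_roi_count = res$excluded_roi_count,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, lapply(results, one_row))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(df)
}
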