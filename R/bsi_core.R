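#' Estimate the patient body silhouette
#'
#' The BSI denominator is the imaged area of the patient, estimated from the
#' raw counts: threshold `log(1 + counts)` by Otsu's criterion, close with a
#' 3x3 structuring element, keep the largest 8-connected component and fill
#' its enclosed holes. On a whole-body bone scan this recovers the skeleton
#' silhouette against the near-zero background.
#'
#' @param scan a [planar_scan()] with at least one positive pixel.
#' @param method `"silhouette"` (default, as above) or `"frame"` (the whole
#'   image rectangle as denominator).
#' @return a list of class `body_mask` with `mask` (logical matrix),
#'   `body_pixel_count` and `method_tag`.
#' @export
estimate_body_mask <- function(scan, method = c("silhouette", "frame")) {
  stopifnot(inherits(scan, "planar_scan"))
  method <- match.arg(method)
  px <- scan$pixels
  if (method == "frame") {
    mask <- matrix(TRUE, nrow(px), ncol(px))
    return(structure(list(mask = mask, body_pixel_count = length(mask),
                          method_tag = "frame"), class = "body_mask"))
  }
  if (all(px == 0)) stop("cannot estimate a body mask from an all-zero image")
  lg <- log1p(px)
  lgn <- lg / max(lg)
  thr <- EBImage::otsu(EBImage::Image(lgn), range = c(0, 1))
  mask <- lgn > thr
  # 3x3 closing bridges one-pixel gaps in the silhouette boundary
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(3, shape = "box"))
  mask <- matrix(as.numeric(closed) > 0.5, nrow(px), ncol(px))
  lab <- label_components8(mask)
  if (max(lab) == 0L) stop("cannot estimate a body mask from an all-zero image")
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  mask <- matrix(as.numeric(filled) > 0.5, nrow(px), ncol(px))
  structure(list(mask = mask, body_pixel_count = sum(mask),
                 method_tag = "silhouette-otsu"), class = "body_mask")
}

#' Per-view BSI from a segmentation state
#'
#' The BSI numerator is the total pixel count of all non-excluded ROIs; the
#' denominator is the body mask unioned with those ill pixels (so the ratio
#' can never exceed 1 even if the silhouette under-covers a lesion).
#' `bsi_percent = 100 * ill_pixels / body_pixels` exactly.
#'
#' @param state a `segmentation_state` from [segment_scan()].
#' @param body a `body_mask` from [estimate_body_mask()] (same dimensions).
#' @param view view label for the entry.
#' @return a list with `view`, `ill_pixels`, `body_pixels`, `bsi_percent`,
#'   `area_green_total` (sum of non-excluded Green's-theorem areas) and
#'   `excluded_roi_count`.
#' @export
compute_bsi <- function(state, body, view = "UNKNOWN") {
  stopifnot(inherits(state, "segmentation_state"), inherits(body, "body_mask"))
  if (!all(dim(body$mask) == state$source_dims)) {
    stop("segmentation state and body mask dimensions differ")
  }
  kept <- Filter(function(r) !r$excluded, state$rois)
  ill_idx <- unlist(lapply(kept, `[[`, "pixels"), use.names = FALSE)
  denom <- body$mask
  denom[ill_idx] <- TRUE
  ill <- length(ill_idx)
  bp <- sum(denom)
  list(view = view,
       ill_pixels = ill,
       body_pixels = bp,
       bsi_percent = 100 * ill / bp,
       area_green_total = sum(vapply(kept, `[[`, numeric(1), "area_green")),
       excluded_roi_count = sum(vapply(state$rois, `[[`, logical(1), "excluded")))
}

#' Combine anterior/posterior BSI entries
#'
#' @param ant,post per-view entries from [compute_bsi()], either may be `NULL`.
#' @param combine `"mean"` (default) or `"max"` of the available views.
#' @return the combined BSI percentage.
#' @export
combine_views <- function(ant = NULL, post = NULL, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  vals <- c(if (!is.null(ant)) ant$bsi_percent, if (!is.null(post)) post$bsi_percent)
  if (length(vals) == 0L) stop("at least one view is required")
  if (combine == "mean") mean(vals) else max(vals)
}

#' Assemble a BSI result
#'
#' @param entries named list of per-view entries (names are view labels).
#' @param combine view combination rule, see [combine_views()].
#' @return a list of class `bsi_result` with `per_view`,
#'   `combined_bsi_percent` and `excluded_roi_count`.
#' @export
bsi_result <- function(entries, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  if (length(entries) == 0L) stop("at least one view is required")
  vals <- vapply(entries, `[[`, numeric(1), "bsi_percent")
  structure(list(
    per_view = entries,
    combined_bsi_percent = if (combine == "mean") mean(vals) else max(vals),
    excluded_roi_count = sum(vapply(entries, `[[`, numeric(1), "excluded_roi_count"))
  ), class = "bsi_result")
}

#' @export
print.bsi_result <- function(x, ...) {
  for (v in names(x$per_view)) {
    e <- x$per_view[[v]]
    cat(sprintf("  %-9s ill %6d / body %6d px  BSI %6.3f%%\n",
                v, e$ill_pixels, e$body_pixels, e$bsi_percent))
  }
  cat(sprintf("  combined BSI %.3f%%  (%d ROI(s) excluded)\n",
              x$combined_bsi_percent, x$excluded_roi_count))
  invisible(x)
}

#' Quantify a set of planar views end to end
#'
#' The full pipeline for one patient acquisition: for each view, estimate the
#' body silhouette, segment from the given seed, apply exclusions, and
#' compute the per-view and combined BSI.
#'
#' @param scans list of [planar_scan()] objects (typically ANTERIOR and
#'   POSTERIOR of one acquisition).
#' @param seeds either one `c(row, col)` seed reused for every view, or a
#'   list of seeds parallel to `scans`.
#' @param window_factor contrast factor, see [apply_window()].
#' @param exclude_ids integer ROI ids to exclude (applied per view), or a
#'   list parallel to `scans`.
#' @param exclude_mask optional logical matrix (or list of them): ROIs
#'   overlapping it are excluded, see [exclude_rois_overlapping()].
#' @param denominator `"silhouette"` or `"frame"`, see [estimate_body_mask()].
#' @param combine `"mean"` or `"max"`, see [combine_views()].
#' @param min_roi_px minimum ROI size in pixels.
#' @return a `bsi_result`.
#' @export
quantify_views <- function(scans, seeds, window_factor = 1.0,
                           exclude_ids = integer(0), exclude_mask = NULL,
                           denominator = c("silhouette", "frame"),
                           combine = c("mean", "max"), min_roi_px = 1L) {
  denominator <- match.arg(denominator)
  combine <- match.arg(combine)
  if (inherits(scans, "planar_scan")) scans <- list(scans)
  one_seed <- !is.list(seeds)
  one_excl <- !is.list(exclude_ids)
  one_mask <- !is.list(exclude_mask)
  entries <- list()
  for (k in seq_along(scans)) {
    scan <- scans[[k]]
    seed <- if (one_seed) seeds else seeds[[k]]
    state <- segment_scan(scan, seed, window_factor = window_factor,
                          min_roi_px = min_roi_px)
    ids <- if (one_excl) exclude_ids else exclude_ids[[k]]
    for (id in ids) state <- set_roi_excluded(state, id, TRUE)
    if (!is.null(exclude_mask)) {
      m <- if (one_mask) exclude_mask else exclude_mask[[k]]
      if (!is.null(m)) state <- exclude_rois_overlapping(state, m)
    }
    body <- estimate_body_mask(scan, method = denominator)
    entries[[scan$view]] <- compute_bsi(state, body, view = scan$view)
  }
  bsi_result(entries, combine = combine)
}
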