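#' Limited contrast adjustment
#'
#' Multiplies all pixel counts by `window_factor`, the operator-facing
#' contrast control. The factor is restricted to a limited range so that
#' contrast changes can brighten or dim the display but cannot push the
#' selection arbitrarily: thresholding from the *same* seed pixel is
#' invariant under this transform (seed and field rescale together).
#'
#' @param scan a [planar_scan()].
#' @param window_factor multiplicative factor in `[0.5, 2]`.
#' @return a new `planar_scan`; the input is untouched.
#' @export
apply_window <- function(scan, window_factor) {
  stopifnot(inherits(scan, "planar_scan"))
  if (!is.numeric(window_factor) || length(window_factor) != 1L ||
      window_factor < 0.5 || window_factor > 2.0) {
    stop("window_factor must lie in [0.5, 2]")
  }
  out <- scan
  out$pixels <- scan$pixels * window_factor
  out
}

#' Seed-pixel global threshold
#'
#' Marks every pixel whose intensity is greater than or equal to the
#' intensity at the operator-picked seed pixel (inclusive, so the seed is
#' always selected and a uniform image is selected entirely).
#'
#' @param scan a [planar_scan()].
#' @param seed integer vector `c(row, col)`, 1-based, in bounds.
#' @return a logical matrix of the scan's dimensions.
#' @export
threshold_from_seed <- function(scan, seed) {
  stopifnot(inherits(scan, "planar_scan"))
  seed <- as.integer(seed)
  px <- scan$pixels
  if (length(seed) != 2L || seed[1] < 1L || seed[1] > nrow(px) ||
      seed[2] < 1L || seed[2] > ncol(px)) {
    stop("seed out of bounds")
  }
  px >= px[seed[1], seed[2]]
}

# 8-connected component labeling by breadth-first search with a vectorised
# frontier. Returns an integer matrix, 0 = background, components numbered
# in first-encounter (column-major) order; extract_rois re-orders them.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  seeds <- which(mask)
  if (length(seeds) == 0L) return(lab)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% nr) + 1L
      co <- ((frontier - 1L) %/% nr) + 1L
      nb_r <- rep(r, each = 8L) + dr
      nb_c <- rep(co, each = 8L) + dc
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# Crack (border) following around one 8-connected component. `occ(r, c)` is
# pixel membership (1-based, out-of-range FALSE). Starts on the top edge of
# the component's topmost-leftmost pixel heading east, keeps foreground on
# the right, and treats diagonally touching pixels as connected. Vertices
# are pixel-corner coordinates (0-based; pixel (i,j) spans corners
# (i-1,j-1)..(i,j)), so a single pixel traces a unit square.
trace_outer_contour <- function(occ, start_pixel) {
  # directions 1=E, 2=S, 3=W, 4=N; corner deltas (row, col)
  drow <- c(0L, 1L, 0L, -1L)
  dcol <- c(1L, 0L, -1L, 0L)
  r0 <- start_pixel[1] - 1L; c0 <- start_pixel[2] - 1L
  pos <- c(r0, c0); d <- 1L
  verts <- matrix(0L, nrow = 256L, ncol = 2L)
  verts[1L, ] <- pos
  nv <- 1L
  repeat {
    pos <- pos + c(drow[d], dcol[d])
    nv <- nv + 1L
    if (nv > nrow(verts)) verts <- rbind(verts, matrix(0L, nrow(verts), 2L))
    verts[nv, ] <- pos
    r <- pos[1]; co <- pos[2]
    fl_fr <- switch(d,
      c(occ(r, co + 1L), occ(r + 1L, co + 1L)),   # E: north, south of next edge
      c(occ(r + 1L, co + 1L), occ(r + 1L, co)),   # S: east, west
      c(occ(r + 1L, co), occ(r, co)),             # W: south, north
      c(occ(r, co), occ(r, co + 1L)))             # N: west, east
    if (fl_fr[1]) d <- if (d == 1L) 4L else d - 1L        # turn left
    else if (!fl_fr[2]) d <- if (d == 4L) 1L else d + 1L  # turn right
    if (pos[1] == r0 && pos[2] == c0 && d == 1L) break
  }
  verts[seq_len(nv), , drop = FALSE]
}

#' Shoelace (Green's theorem) polygon area
#'
#' Area of a closed polygon via the discrete boundary line integral
#' (shoelace sum), independent of orientation. ROI contours traced on the
#' pixel-corner lattice feed through here, so a hole-free ROI's area equals
#' its pixel count exactly.
#'
#' @param contour numeric matrix with columns `(row, col)`; first and last
#'   vertex must coincide and at least 3 distinct vertices are required.
#' @return the absolute enclosed area (pixel^2 units).
#' @export
polygon_area <- function(contour) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  if (n < 2L || any(contour[1L, ] != contour[n, ])) {
    stop("contour must be closed (first vertex equal to last)")
  }
  if (nrow(unique(contour[-n, , drop = FALSE])) < 3L) {
    stop("degenerate contour: fewer than 3 distinct vertices")
  }
  y <- contour[, 1]; x <- contour[, 2]
  i <- seq_len(n - 1L)
  abs(sum(x[i] * y[i + 1L] - x[i + 1L] * y[i])) / 2
}

#' Extract regions of interest from a threshold mask
#'
#' Clusters the selected pixels into 8-connected components (Suzuki-style
#' border following traces each component's outer boundary on the
#' pixel-corner lattice) and summarises each as an ROI: member pixel count,
#' mean intensity, bounding box, outer contour and its Green's-theorem area.
#' Enclosed holes are excluded from `pixel_count` but lie inside the outer
#' contour, so `area_green` may exceed `pixel_count` for ROIs with holes.
#' ROIs are numbered 1..k ordered by bounding box `(min_row, min_col)`.
#'
#' @param mask logical matrix of selected pixels.
#' @param intensity a [planar_scan()] (or matrix) with the same dimensions.
#' @param min_roi_px drop components smaller than this many pixels (default 1,
#'   i.e. keep everything).
#' @return a list of `roi` objects.
#' @export
extract_rois <- function(mask, intensity, min_roi_px = 1L) {
  px <- if (inherits(intensity, "planar_scan")) intensity$pixels else as.matrix(intensity)
  if (!all(dim(mask) == dim(px))) stop("mask and intensity dimensions differ")
  lab <- label_components8(mask)
  k <- max(lab)
  if (k == 0L) return(list())
  nr <- nrow(mask)
  rois <- vector("list", k)
  for (id in seq_len(k)) {
    idx <- which(lab == id)
    r <- ((idx - 1L) %% nr) + 1L
    co <- ((idx - 1L) %/% nr) + 1L
    bbox <- c(min_row = min(r), min_col = min(co), max_row = max(r), max_col = max(co))
    start <- idx[r == min(r)]
    start <- start[which.min(((start - 1L) %/% nr) + 1L)]
    occ <- function(i, j) {
      i >= 1L && i <= nr && j >= 1L && j <= ncol(mask) && lab[i, j] == id
    }
    contour <- trace_outer_contour(occ, c(((start - 1L) %% nr) + 1L,
                                          ((start - 1L) %/% nr) + 1L))
    rois[[id]] <- structure(list(
      roi_id = NA_integer_,
      contour = contour,
      pixel_count = length(idx),
      area_green = polygon_area(contour),
      perimeter = nrow(contour) - 1L,
      mean_intensity = mean(px[idx]),
      bbox = bbox,
      pixels = idx,
      excluded = FALSE
    ), class = "roi")
  }
  keep <- vapply(rois, function(x) x$pixel_count >= min_roi_px, logical(1))
  rois <- rois[keep]
  ord <- order(vapply(rois, function(x) x$bbox[["min_row"]], numeric(1)),
               vapply(rois, function(x) x$bbox[["min_col"]], numeric(1)))
  rois <- rois[ord]
  for (i in seq_along(rois)) rois[[i]]$roi_id <- i
  rois
}

#' Run the full selection on a scan
#'
#' Applies the contrast window, thresholds at the seed pixel's intensity and
#' extracts ROIs, returning a `segmentation_state` that downstream operations
#' (ROI exclusion, BSI computation) act on.
#'
#' @inheritParams threshold_from_seed
#' @inheritParams apply_window
#' @inheritParams extract_rois
#' @return an object of class `segmentation_state`.
#' @export
segment_scan <- function(scan, seed, window_factor = 1.0, min_roi_px = 1L) {
  scan_w <- apply_window(scan, window_factor)
  mask <- threshold_from_seed(scan_w, seed)
  rois <- extract_rois(mask, scan_w, min_roi_px = min_roi_px)
  structure(list(
    seed = as.integer(seed),
    seed_intensity = scan_w$pixels[seed[1], seed[2]],
    window_factor = window_factor,
    rois = rois,
    source_dims = dim(scan$pixels)
  ), class = "segmentation_state")
}

#' @export
print.segmentation_state <- function(x, ...) {
  cat(sprintf("<segmentation_state> seed (%d,%d) @ %.1f, %d ROI(s), %d excluded\n",
              x$seed[1], x$seed[2], x$seed_intensity, length(x$rois),
              sum(vapply(x$rois, `[[`, logical(1), "excluded"))))
  invisible(x)
}

#' Manually include or exclude an ROI
#'
#' Marks an ROI as excluded from the BSI numerator — the operator's tool for
#' removing uptake unrelated to metastatic disease (bladder activity,
#' fracture sites, degenerative joints). Idempotent; all other ROIs are
#' untouched.
#'
#' @param state a `segmentation_state` from [segment_scan()].
#' @param roi_id an existing ROI id.
#' @param excluded logical flag.
#' @return the updated `segmentation_state`.
#' @export
set_roi_excluded <- function(state, roi_id, excluded = TRUE) {
  stopifnot(inherits(state, "segmentation_state"))
  ids <- vapply(state$rois, `[[`, integer(1), "roi_id")
  pos <- match(as.integer(roi_id), ids)
  if (is.na(pos)) stop(sprintf("no ROI with id %d", as.integer(roi_id)))
  state$rois[[pos]]$excluded <- isTRUE(excluded)
  state
}

#' Exclude every ROI overlapping a mask
#'
#' Convenience wrapper over [set_roi_excluded()]: flags all ROIs whose pixel
#' set intersects `mask` (e.g. a known bladder region, or a sidecar-supplied
#' exclusion map).
#'
#' @param state a `segmentation_state`.
#' @param mask logical matrix of the scan's dimensions.
#' @return the updated state.
#' @export
exclude_rois_overlapping <- function(state, mask) {
  stopifnot(inherits(state, "segmentation_state"))
  if (!all(dim(mask) == state$source_dims)) stop("mask dimensions differ from scan")
  hit <- which(mask)
  for (roi in state$rois) {
    if (any(roi$pixels %in% hit)) state <- set_roi_excluded(state, roi$roi_id, TRUE)
  }
  state
}

#' Read an ROI exclusion sidecar
#'
#' Plain-text sidecar listing ROI ids to exclude, one per line (or a CSV
#' whose first column holds the ids; a header line is tolerated).
#'
#' @param path file path.
#' @return integer vector of ROI ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(vapply(strsplit(lines, ","), `[`, character(1), 1L))
  ids <- suppressWarnings(as.integer(lines))
  ids[!is.na(ids)]
}
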