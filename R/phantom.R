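# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fill_ellipse <- function(mask, cr, cc, rr, rc) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- matrix(seq_len(nr), nr, nc)
  co <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask | (((r - cr) / rr)^2 + ((co - cc) / rc)^2 <= 1)
}

fill_rect <- function(mask, r1, r2, c1, c2) {
  r1 <- max(1L, round(r1)); r2 <- min(nrow(mask), round(r2))
  c1 <- max(1L, round(c1)); c2 <- min(ncol(mask), round(c2))
  mask[r1:r2, c1:c2] <- TRUE
  mask
}

# procedural humanoid skeleton silhouette in fractional coordinates, so any
# matrix size yields a connected head / spine / rib cage / arms / pelvis /
# legs figure
skeleton_silhouette <- function(nr, nc) {
  m <- matrix(FALSE, nr, nc)
  m <- fill_ellipse(m, 0.07 * nr, 0.50 * nc, 0.050 * nr, 0.13 * nc)   # head
  m <- fill_rect(m, 0.11 * nr, 0.62 * nr, 0.45 * nc, 0.55 * nc)       # spine
  m <- fill_rect(m, 0.17 * nr, 0.21 * nr, 0.10 * nc, 0.90 * nc)       # shoulder girdle
  m <- fill_rect(m, 0.17 * nr, 0.48 * nr, 0.07 * nc, 0.15 * nc)       # left arm
  m <- fill_rect(m, 0.17 * nr, 0.48 * nr, 0.85 * nc, 0.93 * nc)       # right arm
  m <- fill_ellipse(m, 0.27 * nr, 0.50 * nc, 0.105 * nr, 0.30 * nc)   # rib cage
  m <- fill_ellipse(m, 0.60 * nr, 0.50 * nc, 0.060 * nr, 0.23 * nc)   # pelvis
  m <- fill_rect(m, 0.63 * nr, 0.97 * nr, 0.31 * nc, 0.42 * nc)       # left leg
  m <- fill_rect(m, 0.63 * nr, 0.97 * nr, 0.58 * nc, 0.69 * nc)       # right leg
  m
}

bladder_region <- function(nr, nc) {
  fill_ellipse(matrix(FALSE, nr, nc), 0.585 * nr, 0.50 * nc,
               max(2, 0.022 * nr), max(2, 0.05 * nc))
}

#' Phantom configuration
#'
#' Defaults emulate a whole-body acquisition downsampled to a 256 x 96
#' matrix: a quiet background of ~1 count, a skeleton baseline of ~40 counts
#' (typical of a 2-h post-injection sweep at this pixel size), focal lesions
#' at several times the baseline uptake, and a bright bladder hotspot.
#'
#' @param dims `c(n_rows, n_cols)`.
#' @param body_baseline_counts mean counts per skeleton pixel.
#' @param background_counts mean counts outside the body.
#' @param n_lesions number of lesion discs when `lesion_fraction` is `NULL`.
#' @param lesion_fraction target fraction of skeleton pixels that are lesion,
#'   in `[0, 0.5]`; overrides `n_lesions`.
#' @param lesion_amplitude lesion mean as a multiple of baseline (`> 1`).
#' @param bladder_hotspot draw a non-metastatic bladder hotspot?
#' @param rng_seed integer seed; generation is deterministic given it.
#' @return a list of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(256L, 96L), body_baseline_counts = 40,
                           background_counts = 1, n_lesions = 8L,
                           lesion_fraction = NULL, lesion_amplitude = 6,
                           bladder_hotspot = TRUE, rng_seed = 1L) {
  stopifnot(length(dims) == 2L, all(dims >= 16L),
            body_baseline_counts > 0, background_counts >= 0,
            n_lesions >= 0L, lesion_amplitude > 1)
  if (!is.null(lesion_fraction) &&
      (lesion_fraction < 0 || lesion_fraction > 0.5)) {
    stop("lesion_fraction must lie in [0, 0.5]")
  }
  structure(list(dims = as.integer(dims),
                 body_baseline_counts = body_baseline_counts,
                 background_counts = background_counts,
                 n_lesions = as.integer(n_lesions),
                 lesion_fraction = lesion_fraction,
                 lesion_amplitude = lesion_amplitude,
                 bladder_hotspot = isTRUE(bladder_hotspot),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

#' Generate a synthetic planar bone-scan pair with ground truth
#'
#' Draws anterior and posterior projections of a procedural skeleton
#' silhouette with focal hot lesions, an optional bladder hotspot and Poisson
#' counting noise. The posterior view is the mirrored silhouette with
#' independently drawn noise. Ground truth (body mask, lesion mask, true BSI)
#' is returned alongside, making seed thresholding, ROI exclusion and BSI
#' recovery testable end to end.
#'
#' @param config a [phantom_config()].
#' @return a list with `ant`, `post` ([planar_scan()]s) and `truth`
#'   (class `phantom_truth`: `body_mask`, `lesion_mask`, `bladder_mask`,
#'   posterior mirrors, and `true_bsi_percent`).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  nr <- config$dims[1]; nc <- config$dims[2]
  with_seed(config$rng_seed, {
    body <- skeleton_silhouette(nr, nc)
    bladder <- bladder_region(nr, nc) & body
    if (!config$bladder_hotspot) bladder[] <- FALSE
    # keep lesions clear of the bladder so exclusion tests are unambiguous
    forbidden <- if (any(bladder)) {
      EBImage::dilate(EBImage::Image(bladder * 1), EBImage::makeBrush(5, "box")) > 0.5
    } else bladder
    forbidden <- matrix(as.logical(forbidden), nr, nc)

    lesions <- matrix(FALSE, nr, nc)
    allowed <- body & !forbidden
    allowed_idx <- which(allowed)
    rad_max <- max(2, round(nr / 64))
    target_px <- if (!is.null(config$lesion_fraction)) {
      round(config$lesion_fraction * sum(body))
    } else NA_integer_
    if (!is.na(target_px) && target_px > length(allowed_idx)) {
      stop("lesion_fraction infeasible for this silhouette size")
    }
    place_disc <- function(les) {
      ctr <- allowed_idx[sample.int(length(allowed_idx), 1L)]
      cr <- ((ctr - 1L) %% nr) + 1L
      cc <- ((ctr - 1L) %/% nr) + 1L
      rad <- sample(2:rad_max, 1L)
      disc <- fill_ellipse(matrix(FALSE, nr, nc), cr, cc, rad, rad)
      les | (disc & allowed)
    }
    if (!is.na(target_px)) {
      tries <- 0L
      while (sum(lesions) < target_px) {
        lesions <- place_disc(lesions)
        tries <- tries + 1L
        if (tries > 20000L) stop("lesion_fraction infeasible for this silhouette size")
      }
    } else if (config$n_lesions > 0L) {
      for (i in seq_len(config$n_lesions)) lesions <- place_disc(lesions)
    }

    mean_map <- matrix(config$background_counts, nr, nc)
    mean_map[body] <- config$body_baseline_counts
    mean_map[lesions] <- config$body_baseline_counts * config$lesion_amplitude
    mean_map[bladder] <- config$body_baseline_counts * 12

    mirror <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    draw <- function(mm) matrix(stats::rpois(length(mm), mm), nrow(mm), ncol(mm))
    ant_px <- draw(mean_map)
    post_px <- draw(mirror(mean_map))

    md <- function(view) scan_metadata(
      patient_pseudo_id = sprintf("PHANTOM-%d", config$rng_seed),
      acquisition_date = as.Date("2022-01-01"),
      n_rows = nr, n_cols = nc, energy_descriptor = "140 keV +/- 10%")
    truth <- structure(list(
      body_mask = body, lesion_mask = lesions, bladder_mask = bladder,
      body_mask_post = mirror(body), lesion_mask_post = mirror(lesions),
      bladder_mask_post = mirror(bladder),
      true_bsi_percent = 100 * sum(lesions) / sum(body)
    ), class = "phantom_truth")
    list(ant = planar_scan(ant_px, "ANTERIOR", md("ANTERIOR")),
         post = planar_scan(post_px, "POSTERIOR", md("POSTERIOR")),
         truth = truth)
  })
}

#' Seed pixel for automated quantification of a phantom
#'
#' Picks the operator's seed for a generated view: the lesion pixel whose
#' intensity is the lower 10th-percentile of intensities over the lesion
#' mask (type-1 quantile on integer counts). The inclusive threshold then
#' captures at least 90 % of the lesion area while essentially no baseline
#' skeleton reaches it at the default amplitude.
#'
#' @param scan a phantom view.
#' @param lesion_mask the matching truth lesion mask for that view.
#' @param prob quantile level (default 0.10).
#' @return `c(row, col)` seed, or `NULL` if the lesion mask is empty.
#' @export
seed_from_truth <- function(scan, lesion_mask, prob = 0.10) {
  idx <- which(lesion_mask)
  if (length(idx) == 0L) return(NULL)
  vals <- scan$pixels[idx]
  q <- stats::quantile(vals, probs = prob, type = 1, names = FALSE)
  pick <- idx[vals == q][1L]
  nr <- nrow(scan$pixels)
  c(((pick - 1L) %% nr) + 1L, ((pick - 1L) %/% nr) + 1L)
}

#' Write a phantom to the supported DICOM dialect
#'
#' @param scans a single [planar_scan()] or list of them (frames share
#'   dimensions); counts are rounded to integers and must fit 16 bits.
#' @param path output path.
#' @param patient_id,study_date metadata to embed (`study_date` as
#'   `"YYYYMMDD"`).
#' @return `path`, invisibly.
#' @export
write_phantom_dicom <- function(scans, path, patient_id = NULL,
                                study_date = "20220101") {
  if (inherits(scans, "planar_scan")) scans <- list(scans)
  stopifnot(length(scans) >= 1L)
  frames <- lapply(scans, function(s) round(s$pixels))
  if (any(vapply(frames, max, numeric(1)) > 65535)) {
    stop("pixel counts exceed the 16-bit stored range")
  }
  labels <- vapply(scans, function(s) switch(s$view, ANTERIOR = "ANT",
                                             POSTERIOR = "POST", "UNK"),
                   character(1))
  pid <- patient_id %||% scans[[1]]$metadata$patient_pseudo_id
  b <- dicom_write_raw(frames, patient_id = pid, study_date = study_date,
                       view_labels = labels, bits = 16L)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop(sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  writeBin(b, con)
  invisible(path)
}
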