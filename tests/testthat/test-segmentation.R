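test_that("the contrast window scales counts multiplicatively within its range", {
  s <- make_scan(matrix(c(1, 3, 2, 4), 2, 2))
  expect_identical(apply_window(s, 1.0)$pixels, s$pixels)
  expect_equal(apply_window(s, 2.0)$pixels, s$pixels * 2)
  expect_error(apply_window(s, 0.3), "\\[0.5, 2\\]")
  expect_error(apply_window(s, 2.5), "\\[0.5, 2\\]")
  # original untouched
  s2 <- apply_window(s, 1.5)
  expect_equal(s$pixels[1, 1], 1)
})

test_that("seed thresholding is inclusive and matches exhaustive comparison", {
  uni <- make_scan(matrix(7, 4, 5))
  expect_true(all(threshold_from_seed(uni, c(2, 3))))

  m <- matrix(1:9, 3, 3, byrow = TRUE)
  s <- make_scan(m)
  expect_equal(sum(threshold_from_seed(s, c(2, 2))), 5L)  # pixels 5..9

  peak <- matrix(1, 6, 6); peak[4, 2] <- 99
  mask <- threshold_from_seed(make_scan(peak), c(4, 2))
  expect_equal(which(mask), which(peak == 99))

  set.seed(41)
  for (rep in 1:20) {
    img <- matrix(rpois(30, 8), 5, 6)
    seed <- c(sample(5, 1), sample(6, 1))
    got <- threshold_from_seed(make_scan(img), seed)
    want <- matrix(FALSE, 5, 6)
    for (i in 1:5) for (j in 1:6) want[i, j] <- img[i, j] >= img[seed[1], seed[2]]
    expect_identical(got, want)
    expect_true(got[seed[1], seed[2]])
  }
  expect_error(threshold_from_seed(s, c(0, 1)), "bounds")
  expect_error(threshold_from_seed(s, c(1, 9)), "bounds")
})

test_that("threshold masks are nested as the seed intensity grows", {
  set.seed(42)
  img <- make_scan(matrix(rpois(400, 20), 20, 20))
  vals <- img$pixels
  seeds <- list(which(vals == quantile(vals, .2, type = 1))[1],
                which(vals == quantile(vals, .5, type = 1))[1],
                which(vals == quantile(vals, .8, type = 1))[1])
  to_rc <- function(k) c((k - 1) %% 20 + 1, (k - 1) %/% 20 + 1)
  masks <- lapply(seeds, function(k) threshold_from_seed(img, to_rc(k)))
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
})

test_that("ROI extraction matches a scalar flood-fill oracle on random masks", {
  m0 <- matrix(FALSE, 6, 6)
  expect_identical(extract_rois(m0, matrix(0, 6, 6)), list())

  full <- matrix(TRUE, 10, 10)
  rois <- extract_rois(full, matrix(1, 10, 10))
  expect_length(rois, 1L)
  expect_equal(rois[[1]]$pixel_count, 100L)
  expect_equal(rois[[1]]$area_green, 100)

  diagm <- matrix(FALSE, 4, 4); diagm[2, 2] <- TRUE; diagm[3, 3] <- TRUE
  rois <- extract_rois(diagm, matrix(1, 4, 4))
  expect_length(rois, 1L)   # 8-connectivity joins the diagonal pair
  expect_equal(rois[[1]]$pixel_count, 2L)
  expect_equal(rois[[1]]$area_green, 2)

  set.seed(7)
  for (rep in 1:100) {
    nr <- sample(5:14, 1); nc <- sample(5:14, 1)
    mask <- matrix(runif(nr * nc) < 0.35, nr, nc)
    rois <- extract_rois(mask, matrix(1, nr, nc))
    got <- lapply(rois, function(r) sort(r$pixels))
    got <- got[order(vapply(got, function(p) if (length(p)) min(p) else Inf, numeric(1)))]
    expect_identical(got, flood_fill_components8(mask))
  }
  expect_error(extract_rois(matrix(TRUE, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("ROI pixel sets are disjoint, cover the mask, and ids are deterministic", {
  set.seed(11)
  for (rep in 1:20) {
    mask <- matrix(runif(12 * 12) < 0.3, 12, 12)
    rois <- extract_rois(mask, matrix(1, 12, 12))
    all_px <- unlist(lapply(rois, `[[`, "pixels"))
    expect_equal(sort(all_px), which(mask))       # coverage
    expect_equal(anyDuplicated(all_px), 0L)       # disjoint
    ids <- vapply(rois, `[[`, integer(1), "roi_id")
    expect_equal(ids, seq_along(rois))            # consecutive from 1
    bb <- t(vapply(rois, function(r) r$bbox[c("min_row", "min_col")], numeric(2)))
    if (nrow(bb) > 1L) {
      expect_false(is.unsorted(order(bb[, 1], bb[, 2])))  # bbox ordering
    }
  }
})

test_that("Green's-theorem area stays within a perimeter bound of the pixel count", {
  set.seed(13)
  for (rep in 1:30) {
    mask <- matrix(runif(15 * 15) < 0.4, 15, 15)
    for (roi in extract_rois(mask, matrix(1, 15, 15))) {
      expect_lte(abs(roi$area_green - roi$pixel_count), roi$perimeter)
      expect_identical(roi$contour[1, ], roi$contour[nrow(roi$contour), ])
    }
  }
})

test_that("polygon_area equals the independent shoelace oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(polygon_area(sq), 1.0)
  tri <- rbind(c(0, 0), c(0, 4), c(3, 0), c(0, 0))
  expect_equal(polygon_area(tri), 6.0)

  skip_if_not_installed("pracma")
  set.seed(19)
  for (rep in 1:25) {
    poly <- random_histogram_polygon(sample(3:8, 1))
    expect_equal(polygon_area(poly), shoelace_oracle(poly), tolerance = 1e-9)
  }
  for (rep in 1:25) {
    poly <- random_convex_polygon(sample(5:12, 1))
    expect_equal(polygon_area(poly), shoelace_oracle(poly), tolerance = 1e-9)
  }
})

test_that("degenerate contours raise geometry errors", {
  expect_error(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1))), "closed")
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1), c(0, 0))), "degenerate")
})

test_that("ROI exclusion is idempotent, local and checked", {
  img <- matrix(0, 9, 9)
  img[2:3, 2:3] <- 10; img[2, 7:8] <- 12; img[7:8, 4:6] <- 11
  s <- make_scan(img)
  st <- segment_scan(s, c(2, 2))
  expect_length(st$rois, 3L)
  st2 <- set_roi_excluded(st, 2, TRUE)
  st3 <- set_roi_excluded(st2, 2, TRUE)
  expect_identical(st2, st3)                       # idempotent
  flags <- vapply(st2$rois, `[[`, logical(1), "excluded")
  expect_equal(flags, c(FALSE, TRUE, FALSE))       # locality
  expect_error(set_roi_excluded(st, 99), "no ROI")
})

test_that("same-seed selection is invariant to the contrast window", {
  set.seed(23)
  img <- make_scan(matrix(rpois(200, 15), 20, 10))
  seed <- c(7, 4)
  base <- threshold_from_seed(img, seed)
  for (f in c(0.5, 0.77, 1.3, 2.0)) {
    expect_identical(threshold_from_seed(apply_window(img, f), seed), base)
  }
})
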