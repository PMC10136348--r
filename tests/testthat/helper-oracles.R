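# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: scalar flood fill instead of the vectorised BFS
# labeler, pracma's shoelace instead of polygon_area, a hand-written
# product-limit and partial likelihood instead of the survival backend, and
# a raw-byte DICOM pixel decode instead of the package reader.

# 8-connected component membership by depth-first scalar flood fill;
# returns a canonical representation: list of sorted pixel-index vectors,
# ordered by their smallest member.
flood_fill_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || seen[i, j]) next
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      members <- c(members, (p[2] - 1L) * nr + p[1])
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1L && a <= nr && b >= 1L && b <= nc &&
            mask[a, b] && !seen[a, b]) {
          seen[a, b] <- TRUE
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# shoelace oracle on a closed (row, col) contour
shoelace_oracle <- function(contour) {
  n <- nrow(contour)
  abs(pracma::polyarea(contour[-n, 2], contour[-n, 1]))
}

# random simple "histogram" rectilinear polygon: flat bottom, staircase top
random_histogram_polygon <- function(k = 6L) {
  xs <- cumsum(sample(1:4, k, replace = TRUE))
  xs <- c(0, xs)
  hs <- sample(1:9, k, replace = TRUE)
  verts <- matrix(c(0, 0), ncol = 2)
  for (i in seq_len(k)) {
    verts <- rbind(verts, c(-hs[i], xs[i]), c(-hs[i], xs[i + 1]))
  }
  verts <- rbind(verts, c(0, xs[k + 1]), c(0, 0))
  verts  # (row, col) with top heights as negative rows; closed
}

random_convex_polygon <- function(k = 8L) {
  pts <- matrix(stats::rnorm(2 * k, sd = 5), ncol = 2)
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 1] - ctr[1], pts[, 2] - ctr[2])
  pts <- pts[order(ang), , drop = FALSE]
  rbind(pts, pts[1, , drop = FALSE])
}

# hand-computed Kaplan-Meier product limit: deaths processed before
# censorings at tied times; returns survival at each distinct event time
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (k in seq_along(ts)) {
    t <- ts[k]
    at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}

# Cox partial log-likelihood for a single covariate, Breslow form, no ties
# expected (times should be continuous)
partial_loglik_oracle <- function(time, event, x, beta) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  n <- length(time)
  eta <- x * beta
  ll <- 0
  for (i in seq_len(n)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  ll
}

# independent decode of the pixel payload of a package-written DICOM file:
# locate the (7FE0,0010) OW element byte pattern and read uint16 LE values
raw_pixel_decode <- function(path, n_rows, n_cols, frame = 1L) {
  b <- readBin(path, "raw", n = file.size(path))
  pat <- as.raw(c(0xE0, 0x7F, 0x10, 0x00, 0x4F, 0x57))
  hits <- which(b == pat[1])
  start <- NA_integer_
  for (h in hits) {
    if (h + 5L <= length(b) && identical(b[h:(h + 5L)], pat)) { start <- h; break }
  }
  stopifnot(!is.na(start))
  off <- start + 12L  # tag(4) + VR(2) + reserved(2) + length(4)
  npx <- n_rows * n_cols
  skip <- (frame - 1L) * npx * 2L
  idx <- off + skip + seq(0L, by = 2L, length.out = npx)
  vals <- as.integer(b[idx]) + 256L * as.integer(b[idx + 1L])
  matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
}

# flat test scan helper
make_scan <- function(m, view = "ANTERIOR") planar_scan(m, view = view)
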