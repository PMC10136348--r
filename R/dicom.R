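# Minimal DICOM codec for planar nuclear-medicine images.
#
# Scope is deliberately narrow: explicit-VR little-endian transfer syntax,
# single- or multi-frame MONOCHROME2 images with unsigned 8- or 16-bit
# stored pixels, optional rescale slope/intercept. Sequences and overlays
# are skipped, colour LUTs ignored. This covers whole-body bone-scan
# acquisitions; anything else is rejected with an informative error.

DICOM_MAGIC <- charToRaw("DICM")
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_NM_STORAGE <- "1.2.840.10008.5.1.4.1.1.20"
UID_IMPL_CLASS <- "1.2.826.0.1.3680043.9.9999.1"

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
# modalities that imply tomographic or otherwise unsupported acquisitions
TOMO_MODALITIES <- c("CT", "MR", "PT", "ST", "US", "XA", "RF", "CR", "DX")

uint16_raw <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

uint32_raw <- function(x) {
  b <- integer(4)
  for (i in 1:4) {
    b[i] <- x %% 256
    x <- x %/% 256
  }
  as.raw(b)
}

# pack a vector of non-negative integers < 2^16 as little-endian uint16 raws
uint16_vec_raw <- function(v) {
  v <- as.integer(round(v))
  out <- raw(2L * length(v))
  out[seq(1L, length(out), by = 2L)] <- as.raw(v %% 256L)
  out[seq(2L, length(out), by = 2L)] <- as.raw(v %/% 256L)
  out
}

dcm_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (len %% 2L != 0L) stop("internal: odd element length")
  if (vr %in% LONG_VRS) {
    c(uint16_raw(group), uint16_raw(elem), charToRaw(vr), as.raw(c(0, 0)),
      uint32_raw(len), value_raw)
  } else {
    c(uint16_raw(group), uint16_raw(elem), charToRaw(vr),
      uint16_raw(len), value_raw)
  }
}

# UI values are NUL-padded to even length, text values space-padded
dcm_string <- function(group, elem, vr, s, pad = c("space", "null")) {
  pad <- match.arg(pad)
  v <- charToRaw(enc2utf8(as.character(s)))
  if (length(v) %% 2L != 0L) v <- c(v, if (pad == "null") as.raw(0) else charToRaw(" "))
  dcm_element(group, elem, vr, v)
}

dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", uint16_raw(x))

#' @noRd
#' @param frames list of integer matrices (row-major image rows x cols)
dicom_write_raw <- function(frames, patient_id, study_date, view_labels,
                            bits = 16L, rescale_slope = 1, rescale_intercept = 0) {
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  maxval <- if (bits == 16L) 65535 else 255
  for (f in frames) {
    if (!all(dim(f) == c(nr, nc))) stop("all frames must share dimensions")
    if (any(f < 0) || any(f > maxval)) {
      stop(sprintf("stored pixel values must lie in [0, %d] for %d-bit output", maxval, bits))
    }
  }
  # pixel data, frames concatenated, each row-major
  px <- unlist(lapply(frames, function(f) as.integer(t(f))), use.names = FALSE)
  px_raw <- if (bits == 16L) uint16_vec_raw(px) else {
    v <- as.raw(as.integer(round(px)))
    if (length(v) %% 2L != 0L) v <- c(v, as.raw(0))
    v
  }

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_string(0x0002, 0x0002, "UI", UID_NM_STORAGE, pad = "null"),
    dcm_string(0x0002, 0x0003, "UI", paste0(UID_IMPL_CLASS, ".", format(Sys.time(), "%Y%m%d%H%M%S")), pad = "null"),
    dcm_string(0x0002, 0x0010, "UI", UID_EXPLICIT_LE, pad = "null"),
    dcm_string(0x0002, 0x0012, "UI", UID_IMPL_CLASS, pad = "null")
  )
  ds <- c(
    dcm_string(0x0008, 0x0016, "UI", UID_NM_STORAGE, pad = "null"),
    dcm_string(0x0008, 0x0018, "UI", paste0(UID_IMPL_CLASS, ".1"), pad = "null"),
    dcm_string(0x0008, 0x0020, "DA", study_date),
    dcm_string(0x0008, 0x0060, "CS", "NM"),
    dcm_string(0x0010, 0x0010, "PN", patient_id),
    dcm_string(0x0010, 0x0020, "LO", patient_id),
    dcm_string(0x0020, 0x4000, "LT", paste(view_labels, collapse = "\\")),
    dcm_us(0x0028, 0x0002, 1L),
    dcm_string(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_string(0x0028, 0x0008, "IS", as.character(length(frames))),
    dcm_us(0x0028, 0x0010, nr),
    dcm_us(0x0028, 0x0011, nc),
    dcm_us(0x0028, 0x0100, bits),
    dcm_us(0x0028, 0x0101, bits),
    dcm_us(0x0028, 0x0102, bits - 1L),
    dcm_us(0x0028, 0x0103, 0L),
    dcm_string(0x0028, 0x1052, "DS", format(rescale_intercept, scientific = FALSE)),
    dcm_string(0x0028, 0x1053, "DS", format(rescale_slope, scientific = FALSE)),
    dcm_element(0x7FE0, 0x0010, "OW", px_raw)
  )
  c(raw(128), DICOM_MAGIC,
    dcm_element(0x0002, 0x0000, "UL", uint32_raw(length(meta))),
    meta, ds)
}

read_u16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1L])
read_u32 <- function(b, i) {
  as.integer(b[i]) + 256 * as.integer(b[i + 1L]) +
    65536 * as.integer(b[i + 2L]) + 16777216 * as.integer(b[i + 3L])
}

# skip a sequence / item of undefined length, returning the offset just past
# its delimiter. `b` raw vector, `i` offset of first item tag.
skip_undefined <- function(b, i, end_group, end_elem) {
  repeat {
    if (i + 7L > length(b)) stop("truncated DICOM stream inside sequence")
    g <- read_u16(b, i); e <- read_u16(b, i + 2L); len <- read_u32(b, i + 4L)
    i <- i + 8L
    if (g == 0xFFFE && e == end_elem && e == 0xE0DD) return(i)
    if (g == 0xFFFE && e == end_elem) return(i)
    if (g == 0xFFFE && e == 0xE000) {
      i <- if (len == 0xFFFFFFFF) skip_undefined(b, i, 0xFFFE, 0xE00D) else i + len
    } else {
      i <- i + len
    }
  }
}

#' @noRd
#' Parse the supported explicit-VR little-endian dialect; returns a list of
#' attribute values keyed "gggg,eeee" plus the raw pixel payload.
dicom_parse <- function(b) {
  if (length(b) < 140L || !identical(b[129:132], DICOM_MAGIC)) {
    stop("not a DICOM file (missing DICM magic)")
  }
  i <- 133L
  attrs <- list()
  transfer <- NULL
  n <- length(b)
  while (i + 7L <= n) {
    g <- read_u16(b, i); e <- read_u16(b, i + 2L)
    vr <- rawToChar(b[(i + 4L):(i + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(b, i + 8L)
      i <- i + 12L
    } else {
      len <- read_u16(b, i + 6L)
      i <- i + 8L
    }
    key <- sprintf("%04x,%04x", g, e)
    if (vr == "SQ" || len == 0xFFFFFFFF) {
      i <- if (len == 0xFFFFFFFF) skip_undefined(b, i, 0xFFFE, 0xE0DD) else i + len
      next
    }
    val_raw <- if (len > 0L) b[i:(i + len - 1L)] else raw(0)
    i <- i + len
    attrs[[key]] <- switch(vr,
      US = read_u16(val_raw, 1L),
      UL = read_u32(val_raw, 1L),
      OW = val_raw, OB = val_raw,
      sub("[ ]+$", "", rawToChar(val_raw[val_raw != as.raw(0)]))
    )
    if (key == "0002,0010") transfer <- attrs[[key]]
    if (!is.null(transfer) && transfer != UID_EXPLICIT_LE) {
      stop(sprintf("unsupported transfer syntax '%s' (only explicit-VR little endian is read)", transfer))
    }
  }
  attrs
}

dicom_read_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  b <- readBin(path, "raw", n = file.size(path))
  dicom_parse(b)
}

# decode the pixel payload into a list of matrices, stored values only
dicom_decode_frames <- function(attrs) {
  nr <- attrs[["0028,0010"]]; nc <- attrs[["0028,0011"]]
  if (is.null(nr) || is.null(nc)) stop("DICOM file lacks Rows/Columns")
  bits <- attrs[["0028,0100"]] %||% 16L
  if (!bits %in% c(8L, 16L)) stop(sprintf("unsupported BitsAllocated: %d", bits))
  if ((attrs[["0028,0103"]] %||% 0L) != 0L) stop("signed stored pixels are not supported")
  nframes <- as.integer(attrs[["0028,0008"]] %||% "1")
  payload <- attrs[["7fe0,0010"]]
  if (is.null(payload)) stop("DICOM file contains zero frames (no pixel data)")
  vals <- if (bits == 16L) {
    idx <- seq(1L, length(payload), by = 2L)
    as.integer(payload[idx]) + 256L * as.integer(payload[idx + 1L])
  } else {
    as.integer(payload)
  }
  need <- nr * nc * nframes
  if (length(vals) < need) stop("pixel payload shorter than Rows x Columns x Frames")
  lapply(seq_len(nframes), function(k) {
    chunk <- vals[((k - 1L) * nr * nc + 1L):(k * nr * nc)]
    matrix(chunk, nrow = nr, ncol = nc, byrow = TRUE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
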