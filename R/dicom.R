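# Minimal single-frame DICOM support.
#
# Scope: uncompressed, little-endian files (implicit VR "1.2.840.10008.1.2"
# and explicit VR "1.2.840.10008.1.2.1"), 8- or 16-bit grayscale, one frame.
# Sequences, pixel-data encapsulation and big-endian syntaxes are rejected.
# This is deliberately not a general DICOM implementation: it covers the
# tags the segmentation pipeline needs (Rows, Columns, BitsAllocated,
# PixelRepresentation, RescaleSlope/Intercept, NumberOfFrames, PixelData).

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

.u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE,
          endian = "little")
}
.u32 <- function(raw, off) {
  lo <- .u16(raw, off); hi <- .u16(raw, off + 2)
  lo + hi * 65536
}

# VRs carrying a 2-byte reserved field + 4-byte length in explicit VR
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# ASCII tag value: drop padding NULs (rawToChar rejects embedded NUL bytes)
raw_to_string <- function(r) {
  sub("\\s+$", "", rawToChar(r[r != as.raw(0)]))
}

#' Read a single-frame DICOM file
#'
#' Parses the file meta group, dispatches on the transfer syntax (implicit or
#' explicit VR little endian), decodes the stored pixel values and applies the
#' rescale slope/intercept when present. Multi-frame files are rejected with
#' an instruction to extract a single frame first.
#'
#' @param path DICOM file path.
#' @return A list with `pixels` (numeric matrix, rows x columns, rescaled
#'   stored values -- not normalized) and `meta` (named list of parsed tags).
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    stop(sprintf("not a DICOM part-10 file (missing DICM magic): %s", path),
         call. = FALSE)
  }
  off <- 132L
  ts <- NULL
  # file meta group (0002,....) is always explicit VR little endian
  while (off + 8 <= length(raw) && .u16(raw, off) == 0x0002) {
    elem <- .u16(raw, off + 2)
    vr <- rawToChar(raw[(off + 5):(off + 6)])
    if (vr %in% .LONG_VRS) {
      len <- .u32(raw, off + 8); voff <- off + 12L
    } else {
      len <- .u16(raw, off + 6); voff <- off + 8L
    }
    if (elem == 0x0010) {
      ts <- raw_to_string(raw[(voff + 1):(voff + len)])
    }
    off <- voff + len
  }
  if (is.null(ts)) stop(sprintf("missing transfer syntax UID in %s", path),
                        call. = FALSE)
  if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE)) {
    stop(sprintf("unsupported transfer syntax %s in %s (only uncompressed little endian is supported)",
                 ts, path), call. = FALSE)
  }
  explicit <- ts == TS_EXPLICIT_LE

  meta <- list(rescale_slope = 1, rescale_intercept = 0,
               pixel_representation = 0L)
  pixel_raw <- NULL
  while (off + 8 <= length(raw)) {
    group <- .u16(raw, off); elem <- .u16(raw, off + 2)
    if (explicit) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% .LONG_VRS) {
        len <- .u32(raw, off + 8); voff <- off + 12L
      } else {
        len <- .u16(raw, off + 6); voff <- off + 8L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, off + 4); voff <- off + 8L
    }
    if (len == 4294967295 || identical(vr, "SQ")) {
      stop(sprintf("unsupported DICOM structure (sequence or undefined length) at tag (%04x,%04x) in %s",
                   group, elem, path), call. = FALSE)
    }
    val_raw <- if (len > 0) raw[(voff + 1):(voff + len)] else raw(0)
    tag <- sprintf("%04x%04x", group, elem)
    ascii <- function() raw_to_string(val_raw)
    if (tag == "00280010") meta$rows <- .u16(val_raw, 0)
    if (tag == "00280011") meta$columns <- .u16(val_raw, 0)
    if (tag == "00280100") meta$bits_allocated <- .u16(val_raw, 0)
    if (tag == "00280103") meta$pixel_representation <- .u16(val_raw, 0)
    if (tag == "00280008") meta$number_of_frames <- as.integer(ascii())
    if (tag == "00281052") meta$rescale_intercept <- as.numeric(ascii())
    if (tag == "00281053") meta$rescale_slope <- as.numeric(ascii())
    if (tag == "7fe00010") { pixel_raw <- val_raw; break }
    off <- voff + len
  }
  if (!is.null(meta$number_of_frames) && meta$number_of_frames > 1) {
    stop(sprintf("multi-frame DICOM (%d frames) in %s: extract a single frame before reading",
                 meta$number_of_frames, path), call. = FALSE)
  }
  if (is.null(pixel_raw) || is.null(meta$rows) || is.null(meta$columns) ||
      is.null(meta$bits_allocated)) {
    stop(sprintf("DICOM file %s lacks pixel data or image geometry tags", path),
         call. = FALSE)
  }
  n_px <- meta$rows * meta$columns
  stored <- if (meta$bits_allocated == 8) {
    as.integer(pixel_raw[seq_len(n_px)])
  } else if (meta$bits_allocated == 16) {
    readBin(pixel_raw, "integer", n = n_px, size = 2,
            signed = meta$pixel_representation == 1L, endian = "little")
  } else {
    stop(sprintf("unsupported BitsAllocated=%d in %s", meta$bits_allocated, path),
         call. = FALSE)
  }
  if (length(stored) < n_px) {
    stop(sprintf("truncated pixel data in %s", path), call. = FALSE)
  }
  # pixel data is stored row by row (top-left origin)
  px <- t(matrix(stored, nrow = meta$columns, ncol = meta$rows))
  px <- px * meta$rescale_slope + meta$rescale_intercept
  list(pixels = px, meta = meta)
}

# Minimal explicit-VR little-endian writer, used for fixtures and round-trip
# tests (not exported as a general-purpose DICOM producer).
write_dicom <- function(pixels, path, bits_allocated = 16,
                        rescale_slope = NULL, rescale_intercept = NULL,
                        signed = FALSE, number_of_frames = NULL) {
  stopifnot(is.matrix(pixels), bits_allocated %in% c(8, 16))
  rows <- nrow(pixels); cols <- ncol(pixels)
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  pad_even <- function(s, pad = " ", nul = FALSE) {
    r <- charToRaw(s)
    if (length(r) %% 2 == 1) r <- c(r, if (nul) as.raw(0) else charToRaw(pad))
    r
  }
  short_el <- function(group, elem, vr, value_raw) {
    c(u16(group), u16(elem), charToRaw(vr), u16(length(value_raw)), value_raw)
  }
  long_el <- function(group, elem, vr, value_raw) {
    len <- length(value_raw)
    c(u16(group), u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(len), raw(), size = 4, endian = "little"), value_raw)
  }
  ts_raw <- pad_even(TS_EXPLICIT_LE, nul = TRUE)
  meta_body <- short_el(0x0002, 0x0010, "UI", ts_raw)
  meta <- c(
    short_el(0x0002, 0x0000, "UL",
             writeBin(as.integer(length(meta_body)), raw(), size = 4,
                      endian = "little")),
    meta_body)
  v <- as.integer(round(t(pixels)))  # row-major storage order
  px_raw <- if (bits_allocated == 8) {
    as.raw(v)
  } else {
    if (signed) writeBin(v, raw(), size = 2, endian = "little")
    else {
      v2 <- ifelse(v > 32767L, v - 65536L, v)  # reinterpret as uint16 bytes
      writeBin(as.integer(v2), raw(), size = 2, endian = "little")
    }
  }
  if (length(px_raw) %% 2 == 1) px_raw <- c(px_raw, as.raw(0))
  ds <- raw(0)
  if (!is.null(number_of_frames)) {
    ds <- c(ds, short_el(0x0028, 0x0008, "IS",
                         pad_even(format(as.integer(number_of_frames)), " ")))
  }
  ds <- c(ds,
    short_el(0x0028, 0x0010, "US", u16(rows)),
    short_el(0x0028, 0x0011, "US", u16(cols)),
    short_el(0x0028, 0x0100, "US", u16(bits_allocated)),
    short_el(0x0028, 0x0101, "US", u16(bits_allocated)),
    short_el(0x0028, 0x0102, "US", u16(bits_allocated - 1)),
    short_el(0x0028, 0x0103, "US", u16(if (signed) 1 else 0))
  )
  if (!is.null(rescale_intercept)) {
    ds <- c(ds, short_el(0x0028, 0x1052, "DS",
                         pad_even(format(rescale_intercept), " ")))
  }
  if (!is.null(rescale_slope)) {
    ds <- c(ds, short_el(0x0028, 0x1053, "DS",
                         pad_even(format(rescale_slope), " ")))
  }
  ds <- c(ds, long_el(0x7fe0, 0x0010, "OW", px_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}
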