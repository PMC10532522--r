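#' Read an image and canonicalize it to 224x224x3 in [0, 1]
#'
#' PNG and JPEG sources are read on their native \[0, 1\] scale (8-bit 255
#' maps to 1.0). Single-frame DICOM sources are decoded from raw stored
#' values, the rescale slope/intercept applied when present, then min-max
#' scaled to \[0, 1\] over the frame (a constant frame maps to all zeros; no
#' Hounsfield windowing is applied). All sources are then resized to 224x224
#' (bilinear by default) and grayscale images are replicated across three
#' channels.
#'
#' @param path file path.
#' @param modality one of `"auto"`, `"png"`, `"jpeg"`, `"dicom"`; `"auto"`
#'   dispatches on the file extension.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return An [image224].
#' @export
read_image <- function(path, modality = c("auto", "png", "jpeg", "dicom"),
                       interpolation = c("bilinear", "nearest")) {
  modality <- match.arg(modality)
  interpolation <- match.arg(interpolation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (modality == "auto") {
    ext <- tolower(tools::file_ext(path))
    modality <- switch(ext,
      png = "png", jpg = "jpeg", jpeg = "jpeg", dcm = "dicom", dicom = "dicom",
      stop(sprintf("cannot infer image format from extension of %s", path),
           call. = FALSE))
  }
  arr <- if (modality == "dicom") {
    dcm <- read_dicom(path)
    g <- dcm$pixels
    rng <- range(g)
    g <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else g * 0
    array(g, dim = c(dim(g), 1L))
  } else {
    eb <- tryCatch(EBImage::readImage(path),
                   error = function(e) stop(sprintf(
                     "failed to read %s file %s: %s", modality, path,
                     conditionMessage(e)), call. = FALSE))
    ebimage_to_array(eb)
  }
  arr <- resize_array(arr, 224L, 224L, interpolation)
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  if (dim(arr)[3] == 1L) arr <- array(arr, dim = c(224L, 224L, 3L))
  image224(arr[, , 1:3, drop = FALSE],
           source_id = tools::file_path_sans_ext(basename(path)))
}

# EBImage stores x (column) as the first dimension; convert to [row, col, ch].
ebimage_to_array <- function(eb) {
  d <- EBImage::imageData(eb)
  if (length(dim(d)) == 2L) {
    array(t(d), dim = c(dim(d)[2], dim(d)[1], 1L))
  } else {
    nch <- dim(d)[3]
    if (nch > 3L) d <- d[, , 1:3, drop = FALSE]  # drop alpha
    aperm(d, c(2L, 1L, 3L))
  }
}

array_to_ebimage <- function(arr) {
  if (length(dim(arr)) == 2L) {
    EBImage::Image(t(arr))
  } else {
    EBImage::Image(aperm(arr, c(2L, 1L, 3L)), colormode = "Color")
  }
}

resize_array <- function(arr, h, w, interpolation = "bilinear") {
  if (nrow(arr) == h && ncol(arr) == w) return(arr)
  filt <- if (interpolation == "nearest") "none" else "bilinear"
  out <- EBImage::resize(array_to_ebimage(arr), w = w, h = h, filter = filt)
  ebimage_to_array(out)
}

#' Decode a grayscale mask image into class labels
#'
#' Mask images use the gray-value dialect 0 = background, 128 = heart tissue,
#' 255 = enlarged region (three-class) or 0/255 (two-class), with a tolerance
#' band of +/-32 gray levels around each canonical value.
#'
#' @param gray_image integer-valued matrix with entries in \[0, 255\].
#' @param n_classes 2 or 3.
#' @return A [label_mask].
#' @export
decode_mask <- function(gray_image, n_classes = 3) {
  n_classes <- as.integer(n_classes)
  if (!is.matrix(gray_image)) stop("gray_image must be a matrix", call. = FALSE)
  g <- round(gray_image)
  canon <- if (n_classes == 3L) c(0, 128, 255) else c(0, 255)
  dist <- vapply(canon, function(v) abs(as.vector(g) - v), numeric(length(g)))
  dist <- matrix(dist, ncol = length(canon))
  nearest <- max.col(-dist, ties.method = "first")
  bad <- dist[cbind(seq_len(nrow(dist)), nearest)] > 32
  if (any(bad)) {
    i <- which(bad)[1]
    r <- ((i - 1) %% nrow(g)) + 1
    cc <- ((i - 1) %/% nrow(g)) + 1
    stop(sprintf(
      "mask value %d at (row %d, col %d) is outside every tolerance band (%s +/-32)",
      as.integer(g[r, cc]), r, cc, paste(canon, collapse = "/")), call. = FALSE)
  }
  label_mask(matrix(nearest - 1L, nrow(g), ncol(g)), n_classes = n_classes)
}

#' Encode class labels as canonical gray values
#'
#' Inverse of [decode_mask] on the canonical values: class 0 -> 0,
#' class 1 -> 128 (three-class only), top class -> 255.
#'
#' @param mask a [label_mask].
#' @return Integer matrix of gray values.
#' @export
encode_mask <- function(mask) {
  nc <- mask_n_classes(mask)
  canon <- if (nc == 3L) c(0L, 128L, 255L) else c(0L, 255L)
  m <- mask_classes(mask)
  matrix(canon[m + 1L], nrow(m), ncol(m))
}

#' Overlay the enlarged region in red
#'
#' Pixels where the binary mask is 1 are replaced by pure red (1, 0, 0);
#' every other pixel is left untouched (opaque replacement, no blending).
#'
#' @param image an [image224].
#' @param binary_mask a two-class [label_mask] of the same spatial shape.
#' @return An [image224] with the overlay applied.
#' @export
red_overlay <- function(image, binary_mask) {
  px <- image_pixels(image)
  stop_if_shape_mismatch(dim(px)[1:2], dim(binary_mask), "image and mask")
  if (mask_n_classes(binary_mask) != 2L) {
    stop("overlay requires a two-class mask", call. = FALSE)
  }
  hit <- mask_classes(binary_mask) == 1L
  out <- px
  out[, , 1][hit] <- 1
  out[, , 2][hit] <- 0
  out[, , 3][hit] <- 0
  image224(out, source_id = image_source_id(image))
}

#' Write an image as PNG
#' @param image an [image224] (or plain numeric array in \[0,1\]).
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  arr <- if (inherits(image, "image224")) image_pixels(image) else image
  EBImage::writeImage(array_to_ebimage(arr), path, type = "png")
  invisible(path)
}

#' Write a label mask as a grayscale PNG using the canonical gray dialect
#' @param mask a [label_mask].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  g <- encode_mask(mask) / 255
  EBImage::writeImage(array_to_ebimage(g), path, type = "png")
  invisible(path)
}

#' Read a grayscale PNG written with [write_mask_png] back into a label mask
#' @param path PNG path.
#' @param n_classes 2 or 3.
#' @return A [label_mask].
#' @export
read_mask_png <- function(path, n_classes = 3) {
  arr <- ebimage_to_array(EBImage::readImage(path))
  decode_mask(round(arr[, , 1] * 255), n_classes = n_classes)
}
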