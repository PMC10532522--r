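#' Canonical 224x224 RGB image
#'
#' The pipeline's canonical input: a 224 x 224 x 3 numeric array with all
#' intensities in \[0, 1\]. Grayscale sources are replicated across the three
#' channels, so for them all channels are identical. The coordinate convention
#' is row-major with the origin at the top-left: `pixels[r, c, ch]`.
#'
#' @param pixels numeric array of dimension 224 x 224 x 3 with values in
#'   \[0, 1\].
#' @param source_id character scalar identifying the subject or source file.
#' @return An object of class `image224`: the pixel array carrying a
#'   `source_id` attribute.
#' @export
image224 <- function(pixels, source_id = "unknown") {
  pixels <- validate_image224(pixels)
  attr(pixels, "source_id") <- as.character(source_id)[1]
  class(pixels) <- c("image224", class(pixels))
  pixels
}

validate_image224 <- function(pixels) {
  if (!is.numeric(pixels) || length(dim(pixels)) != 3L) {
    stop("image must be a numeric 3-d array", call. = FALSE)
  }
  d <- dim(pixels)
  if (!all(d == c(224L, 224L, 3L))) {
    stop(sprintf("image must be 224x224x3, got %s", paste(d, collapse = "x")),
         call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("image intensities must lie in [0, 1] with no missing values",
         call. = FALSE)
  }
  unclass(pixels)
}

#' @export
print.image224 <- function(x, ...) {
  cat(sprintf("<image224> source_id=%s range=[%.3f, %.3f]\n",
              attr(x, "source_id"), min(x), max(x)))
  invisible(x)
}

#' Pixel label mask
#'
#' A 224 x 224 (or generally H x W) integer class mask. Three-class masks use
#' the fixed semantics 0 = background (black), 1 = heart tissue (grey),
#' 2 = enlarged region (white); two-class masks use 0 = negative,
#' 1 = enlarged.
#'
#' @param classes integer matrix of class labels.
#' @param n_classes 2 or 3.
#' @return An object of class `label_mask`: an integer matrix with an
#'   `n_classes` attribute.
#' @export
label_mask <- function(classes, n_classes) {
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(2L, 3L)) stop("n_classes must be 2 or 3", call. = FALSE)
  if (!is.matrix(classes)) stop("mask classes must be a matrix", call. = FALSE)
  m <- matrix(as.integer(classes), nrow = nrow(classes), ncol = ncol(classes))
  if (anyNA(m) || any(m < 0L) || any(m >= n_classes)) {
    stop(sprintf("mask values must lie in {0,...,%d}", n_classes - 1L),
         call. = FALSE)
  }
  attr(m, "n_classes") <- n_classes
  class(m) <- c("label_mask", class(m))
  m
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %dx%d n_classes=%d counts: %s\n",
              nrow(x), ncol(x), attr(x, "n_classes"),
              paste(sprintf("%d=%d", as.integer(names(table(unclass(x)))),
                            as.integer(table(unclass(x)))), collapse = " ")))
  invisible(x)
}

mask_classes <- function(mask) {
  m <- unclass(mask)
  attr(m, "n_classes") <- NULL
  m
}

mask_n_classes <- function(mask) attr(mask, "n_classes")

image_pixels <- function(image) {
  p <- unclass(image)
  attr(p, "source_id") <- NULL
  p
}

image_source_id <- function(image) {
  sid <- attr(image, "source_id")
  if (is.null(sid)) "unknown" else sid
}

stop_if_shape_mismatch <- function(a_dim, b_dim, what = "inputs") {
  if (!identical(as.integer(a_dim), as.integer(b_dim))) {
    stop(sprintf("%s have mismatched shapes: %s vs %s", what,
                 paste(a_dim, collapse = "x"), paste(b_dim, collapse = "x")),
         call. = FALSE)
  }
}
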