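# Frozen convolutional feature extraction.
#
# A fixed bank of 64 kernels of shape 3x3x3 (height x width x input channel)
# maps each 224x224x3 image to a 224x224x64 feature map (stride 1, zero
# "same" padding, rectified). The map is then reindexed losslessly into a
# per-pixel feature table (one row per pixel, 64 columns) or tiled into
# non-overlapping 8x8 frames. Convolution follows the deep-learning
# convention (cross-correlation, no kernel flip).

#' 2-D convolution (cross-correlation) of a single channel
#'
#' Correlates a single-channel image with a square odd-sized kernel. With
#' `padding = "same"` the input is zero-padded so that at stride 1 the output
#' has the input's shape; with `"valid"` only fully-overlapping positions are
#' produced. No kernel flip is applied (deep-learning convention).
#'
#' @param x numeric matrix (H x W).
#' @param kernel numeric k x k matrix, k odd.
#' @param stride positive integer step between output positions.
#' @param padding `"same"` or `"valid"`.
#' @return Numeric matrix of correlation sums.
#' @export
convolve2d <- function(x, kernel, stride = 1L, padding = c("same", "valid")) {
  padding <- match.arg(padding)
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel)) {
    stop("kernel must be a square matrix", call. = FALSE)
  }
  k <- nrow(kernel)
  if (k %% 2 == 0) stop("kernel size must be odd", call. = FALSE)
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  if (nrow(x) < k || ncol(x) < k) stop("input smaller than kernel", call. = FALSE)
  p <- if (padding == "same") (k - 1L) %/% 2L else 0L
  hp <- nrow(x) + 2L * p
  wp <- ncol(x) + 2L * p
  xp <- matrix(0, hp, wp)
  xp[(p + 1):(p + nrow(x)), (p + 1):(p + ncol(x))] <- x
  out_h <- (hp - k) %/% stride + 1L
  out_w <- (wp - k) %/% stride + 1L
  rows0 <- (seq_len(out_h) - 1L) * stride
  cols0 <- (seq_len(out_w) - 1L) * stride
  out <- matrix(0, out_h, out_w)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      out <- out + kernel[a, b] * xp[rows0 + a, cols0 + b, drop = FALSE]
    }
  }
  out
}

#' Construct a filter bank
#'
#' Low-level constructor: `kernels` is a 4-d array (k x k x in_channels x
#' n_filters), `bias` one value per filter. [make_filter_bank] builds the
#' canonical 64-filter, 3-channel bank.
#'
#' @param kernels numeric array, k x k x C_in x N.
#' @param bias numeric vector of length N.
#' @param provenance character tag recording where the kernels came from.
#' @param seed integer seed (for seeded banks), or NA.
#' @return An object of class `filter_bank`.
#' @export
filter_bank <- function(kernels, bias, provenance = "custom", seed = NA_integer_) {
  d <- dim(kernels)
  if (length(d) != 4L || d[1] != d[2] || d[1] %% 2 == 0) {
    stop("kernels must be a k x k x C_in x N array with odd k", call. = FALSE)
  }
  if (length(bias) != d[4]) stop("bias length must equal the filter count", call. = FALSE)
  structure(list(kernels = kernels, bias = as.numeric(bias),
                 provenance = provenance, seed = as.integer(seed)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  d <- dim(x$kernels)
  cat(sprintf("<filter_bank> %d filters of %dx%dx%d, provenance=%s seed=%s\n",
              d[4], d[1], d[2], d[3], x$provenance,
              ifelse(is.na(x$seed), "-", x$seed)))
  invisible(x)
}

#' Build the canonical 64-filter bank
#'
#' Two provenances are supported. `"seeded_random"` draws kernel entries from
#' a zero-mean Gaussian scaled by 1/sqrt(fan-in) (fan-in = 3*3*3 = 27) with
#' zero biases; the bank is reproducible from its seed. In that regime the
#' bank acts as a fixed random projection of each pixel's 3x3 neighborhood,
#' which is all the downstream per-pixel classifiers need.
#' `"pretrained_vgg_block1"` loads the first convolutional layer of a
#' VGG-style network from a local plain-text weights file (no network
#' access): a headerless whitespace-separated numeric file holding the
#' 3*3*3*64 = 1728 kernel values in index order (kernel row fastest, then
#' kernel column, then input channel, then filter) followed by the 64 biases.
#'
#' @param provenance `"seeded_random"` or `"pretrained_vgg_block1"`.
#' @param seed integer seed for the seeded bank (default 42).
#' @param weights_file path to the weights file for the pretrained bank.
#' @return A `filter_bank` with 64 kernels of shape 3x3x3.
#' @export
make_filter_bank <- function(provenance = c("seeded_random", "pretrained_vgg_block1"),
                             seed = 42, weights_file = NULL) {
  provenance <- match.arg(provenance)
  n_filters <- 64L; k <- 3L; cin <- 3L
  n_kernel_vals <- k * k * cin * n_filters
  if (provenance == "seeded_random") {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
    vals <- stats::rnorm(n_kernel_vals, sd = 1 / sqrt(k * k * cin))
    kernels <- array(vals, dim = c(k, k, cin, n_filters))
    filter_bank(kernels, rep(0, n_filters), provenance, as.integer(seed))
  } else {
    if (is.null(weights_file) || !file.exists(weights_file)) {
      stop("pretrained_vgg_block1 requires a local weights file holding a 3x3x3x64 kernel tensor plus 64 biases",
           call. = FALSE)
    }
    vals <- scan(weights_file, what = numeric(), quiet = TRUE)
    if (length(vals) != n_kernel_vals + n_filters) {
      stop(sprintf(
        "weights file %s holds %d values; expected %d (3x3x3x64 kernels) + %d biases",
        weights_file, length(vals), n_kernel_vals, n_filters), call. = FALSE)
    }
    kernels <- array(vals[seq_len(n_kernel_vals)], dim = c(k, k, cin, n_filters))
    filter_bank(kernels, vals[n_kernel_vals + seq_len(n_filters)],
                provenance, NA_integer_)
  }
}

# Write a bank in the plain-text layout make_filter_bank() reads.
write_filter_bank <- function(bank, path) {
  vals <- c(as.numeric(bank$kernels), bank$bias)
  writeLines(format(vals, digits = 17), path)
  invisible(path)
}

#' Extract the per-pixel feature map from an image
#'
#' Applies every kernel of the bank at stride 1 with zero same-padding: for
#' each filter the per-channel correlations are summed, the bias added, and
#' negative responses rectified to 0. For the canonical bank the result is a
#' 224x224x64 map aligned pixel-for-pixel with the input.
#'
#' Implemented as one im2col matrix product (each pixel's 3x3x3 neighborhood
#' against the 27 x N kernel matrix), which is algebraically identical to
#' summing [convolve2d] per channel; a test asserts that identity.
#'
#' @param image an [image224] (or H x W x C numeric array).
#' @param bank a `filter_bank` whose kernels have C input channels.
#' @return Numeric H x W x N array, all values >= 0.
#' @export
extract_features <- function(image, bank) {
  px <- if (inherits(image, "image224")) image_pixels(image) else image
  d <- dim(px)
  kd <- dim(bank$kernels)
  if (d[3] != kd[3]) {
    stop(sprintf("image has %d channels but bank kernels expect %d", d[3], kd[3]),
         call. = FALSE)
  }
  h <- d[1]; w <- d[2]; k <- kd[1]; cin <- kd[3]; nf <- kd[4]
  p <- (k - 1L) %/% 2L
  # im2col in row-major pixel order: column (a,b,ch) holds the padded pixel
  # at offset (a,b) in channel ch for every output pixel
  X <- matrix(0, h * w, k * k * cin)
  K <- matrix(0, k * k * cin, nf)
  tap <- 0L
  for (ch in seq_len(cin)) {
    xp <- matrix(0, h + 2L * p, w + 2L * p)
    xp[(p + 1):(p + h), (p + 1):(p + w)] <- px[, , ch]
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        tap <- tap + 1L
        X[, tap] <- as.vector(t(xp[(a - 1L) + seq_len(h), (b - 1L) + seq_len(w)]))
        K[tap, ] <- bank$kernels[a, b, ch, ]
      }
    }
  }
  out <- X %*% K
  out <- sweep(out, 2L, bank$bias, "+")
  out[out < 0] <- 0
  # undo the row-major flattening: column f fills width-fastest
  aperm(array(out, dim = c(w, h, nf)), c(2L, 1L, 3L))
}

#' Flatten a feature map into the per-pixel feature table
#'
#' Row-major pixel order: the row for pixel (r, c) of an H x W map is
#' `(r-1)*W + c`. When a mask is supplied its class values become the
#' `label` column.
#'
#' @param map H x W x C numeric feature array.
#' @param mask optional [label_mask] of matching spatial shape.
#' @return An object of class `feature_frame`: list with `x` (N_pixels x C
#'   matrix, columns `f1...fC`), `label` (integer vector or NULL), and
#'   `height`/`width` of the source map.
#' @export
flatten_to_frame <- function(map, mask = NULL) {
  d <- dim(map)
  if (length(d) != 3L) stop("feature map must be a 3-d array", call. = FALSE)
  x <- matrix(aperm(map, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  colnames(x) <- paste0("f", seq_len(d[3]))
  lab <- NULL
  if (!is.null(mask)) {
    stop_if_shape_mismatch(d[1:2], dim(mask), "feature map and mask")
    lab <- as.integer(t(mask_classes(mask)))
  }
  structure(list(x = x, label = lab, height = d[1], width = d[2]),
            class = "feature_frame")
}

#' @export
print.feature_frame <- function(x, ...) {
  cat(sprintf("<feature_frame> %d pixels x %d features%s\n", nrow(x$x),
              ncol(x$x), if (is.null(x$label)) "" else " (labeled)"))
  invisible(x)
}

#' Rebuild a feature map from a flattened frame (inverse of flatten)
#' @param frame a `feature_frame`.
#' @return H x W x C numeric array.
#' @export
frame_to_map <- function(frame) {
  h <- frame$height; w <- frame$width
  aperm(array(frame$x, dim = c(w, h, ncol(frame$x))), c(2L, 1L, 3L))
}

#' Concatenate feature frames vertically (in input order)
#' @param frames list of `feature_frame`s with equal column counts.
#' @return A `feature_frame` (height/width of the first frame are kept only
#'   for provenance; the combined frame no longer maps to one image).
#' @export
bind_frames <- function(frames) {
  x <- do.call(rbind, lapply(frames, function(f) f$x))
  labs <- lapply(frames, function(f) f$label)
  lab <- if (any(vapply(labs, is.null, logical(1)))) NULL else unlist(labs)
  structure(list(x = x, label = lab, height = frames[[1]]$height,
                 width = frames[[1]]$width),
            class = "feature_frame")
}

#' Tile a feature map into non-overlapping square frames
#'
#' Splits an H x W x C map into (H/s) x (W/s) frames of s x s pixels, in
#' row-major frame order. The tiling is a lossless reindexing: every pixel
#' appears in exactly one frame.
#'
#' @param map H x W x C numeric array.
#' @param frame_size side length s; must divide both H and W (default 8).
#' @return List of frames, each a list with `frame_row`, `frame_col`, and
#'   `block` (s x s x C array).
#' @export
tile_frames <- function(map, frame_size = 8L) {
  d <- dim(map)
  s <- as.integer(frame_size)
  if (d[1] %% s != 0 || d[2] %% s != 0) {
    stop(sprintf("frame_size %d does not divide map dimensions %dx%d",
                 s, d[1], d[2]), call. = FALSE)
  }
  nfr <- d[1] %/% s; nfc <- d[2] %/% s
  out <- vector("list", nfr * nfc)
  idx <- 1L
  for (fr in seq_len(nfr)) {
    for (fc in seq_len(nfc)) {
      out[[idx]] <- list(
        frame_row = fr, frame_col = fc,
        block = map[(fr - 1L) * s + seq_len(s), (fc - 1L) * s + seq_len(s), ,
                    drop = FALSE])
      idx <- idx + 1L
    }
  }
  out
}

# Permutation mapping row-major pixel order to frame-major order (all pixels
# of frame 1 in row-major order, then frame 2, ...). Training assembles the
# labeled table in this order, mirroring the frame-by-frame extraction step.
frame_order_index <- function(height, width, frame_size = 8L) {
  s <- as.integer(frame_size)
  r <- rep(seq_len(height), each = width)
  cc <- rep(seq_len(width), times = height)
  fr <- (r - 1L) %/% s
  fc <- (cc - 1L) %/% s
  within_r <- (r - 1L) %% s
  within_c <- (cc - 1L) %% s
  key <- ((fr * (width %/% s) + fc) * s + within_r) * s + within_c
  order(key)
}

#' Export a feature frame to CSV
#' @param frame a `feature_frame`.
#' @param path output CSV path (header `f1...fC[,label]`).
#' @return `path`, invisibly.
#' @export
export_frame_csv <- function(frame, path) {
  df <- as.data.frame(frame$x)
  if (!is.null(frame$label)) df$label <- frame$label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
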