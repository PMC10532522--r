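# Synthetic thorax/heart phantoms.
#
# Each phantom is a 224x224 CT-like grayscale scene: a mid-gray thorax
# ellipse on a dark background with a bright interior heart ellipse. The
# diagnostic parameter is the cardiothoracic ratio (CTR): the heart's
# horizontal extent divided by the thorax's horizontal extent. Subjects with
# CTR >= 0.5 carry an "enlarged" core inside the heart, drawn brighter and
# labeled class 2; healthy subjects have no class-2 pixels at all. Intensity
# levels before noise: background 0.10, thorax 0.45, heart tissue 0.80,
# enlarged core 0.95 -- chosen so the three mask classes are separable from
# local intensity, which is what makes the downstream per-pixel classifier
# testable without real CT data.

PHANTOM_LEVELS <- c(background = 0.10, thorax = 0.45, heart = 0.80,
                    core = 0.95)
CORE_SCALE <- 0.7  # enlarged core axes as a fraction of the heart axes

inside_ellipse <- function(rows, cols, cy, cx, a, b) {
  # a = horizontal (column) semi-axis, b = vertical (row) semi-axis
  outer(rows - cy, rep(1, length(cols)))^2 / b^2 +
    outer(rep(1, length(rows)), cols - cx)^2 / a^2 <= 1
}

#' Generate one thorax/heart phantom with its ground-truth mask
#'
#' Deterministic in `seed`: the same (seed, ctr, noise_sd) always yields a
#' bit-identical image and mask. The heart's horizontal extent is
#' `ctr` times the thorax's horizontal extent; when `ctr >= 0.5` a concentric
#' inner core of the heart is rendered brighter and labeled class 2
#' (enlarged), otherwise the whole heart is class 1 (tissue).
#'
#' @param seed integer RNG seed for geometry jitter and noise.
#' @param ctr cardiothoracic ratio in (0.05, 0.95).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (clipped back to \[0, 1\]).
#' @return A list with `image` ([image224]), `mask` (three-class
#'   [label_mask]), and `ctr`.
#' @export
generate_phantom <- function(seed, ctr, noise_sd = 0.02) {
  if (ctr <= 0.05 || ctr >= 0.95) stop("ctr must lie in (0.05, 0.95)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  n <- 224L
  rows <- seq_len(n); cols <- seq_len(n)
  cy <- 112 + sample(-4:4, 1)
  cx <- 112 + sample(-4:4, 1)
  a_t <- 100
  b_t <- 72 + sample(-4:4, 1)
  thorax <- inside_ellipse(rows, cols, cy, cx, a_t, b_t)

  a_h <- ctr * a_t
  b_h <- min(0.78 * a_h, b_t - 6)
  cx_h <- cx - 8
  heart <- inside_ellipse(rows, cols, cy, cx_h, a_h, b_h)
  core <- inside_ellipse(rows, cols, cy, cx_h, CORE_SCALE * a_h, CORE_SCALE * b_h)

  gray <- matrix(PHANTOM_LEVELS[["background"]], n, n)
  gray[thorax] <- PHANTOM_LEVELS[["thorax"]]
  gray[heart] <- PHANTOM_LEVELS[["heart"]]
  cls <- matrix(0L, n, n)
  cls[heart] <- 1L
  if (ctr >= 0.5) {
    gray[core] <- PHANTOM_LEVELS[["core"]]
    cls[core] <- 2L
  }
  if (noise_sd > 0) {
    gray <- gray + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    gray[gray < 0] <- 0
    gray[gray > 1] <- 1
  }
  img <- image224(array(gray, dim = c(n, n, 3L)),
                  source_id = sprintf("phantom_seed%d", as.integer(seed)))
  list(image = img, mask = label_mask(cls, 3L), ctr = ctr)
}

#' Generate a phantom dataset emulating a small clinical cohort
#'
#' Defaults match a 20-subject cohort with 11 enlarged and 9 healthy hearts.
#' Per-subject seeds, the assignment of the enlarged diagnosis to subjects,
#' and the CTR draws are all derived deterministically from `master_seed`.
#' The two-class mask of each subject is the indicator of class 2 in its
#' three-class mask.
#'
#' @param n_subjects total number of subjects (>= 2).
#' @param n_enlarged number of enlarged-heart subjects (<= n_subjects).
#' @param master_seed integer seed controlling the whole dataset.
#' @param ctr_healthy_range CTR interval for healthy subjects (below 0.5).
#' @param ctr_enlarged_range CTR interval for enlarged subjects (at/above 0.5).
#' @param noise_sd additive intensity noise standard deviation.
#' @return A list of subjects, each a list with `subject_id`, `image`,
#'   `mask3`, `mask2`, `enlarged` (logical), `ctr`, and `seed`.
#' @export
generate_dataset <- function(n_subjects = 20, n_enlarged = 11,
                             master_seed = 42,
                             ctr_healthy_range = c(0.32, 0.45),
                             ctr_enlarged_range = c(0.55, 0.70),
                             noise_sd = 0.02) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  if (n_enlarged > n_subjects) stop("n_enlarged must be <= n_subjects", call. = FALSE)
  if (max(ctr_healthy_range) >= 0.5) stop("ctr_healthy_range must lie below 0.5", call. = FALSE)
  if (min(ctr_enlarged_range) < 0.5) stop("ctr_enlarged_range must lie at/above 0.5", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  enlarged <- rep(FALSE, n_subjects)
  enlarged[sample.int(n_subjects, n_enlarged)] <- TRUE
  ctrs <- ifelse(enlarged,
                 stats::runif(n_subjects, ctr_enlarged_range[1], ctr_enlarged_range[2]),
                 stats::runif(n_subjects, ctr_healthy_range[1], ctr_healthy_range[2]))
  lapply(seq_len(n_subjects), function(i) {
    ph <- generate_phantom(seeds[i], ctrs[i], noise_sd)
    m3 <- ph$mask
    m2 <- label_mask(matrix(as.integer(mask_classes(m3) == 2L), 224, 224), 2L)
    list(subject_id = sprintf("S%02d", i),
         image = image224(image_pixels(ph$image), source_id = sprintf("S%02d", i)),
         mask3 = m3, mask2 = m2,
         enlarged = enlarged[i], ctr = ctrs[i], seed = seeds[i])
  })
}

#' Flip augmentation
#'
#' Returns the original pair plus its horizontal and vertical reflections,
#' with image and mask flipped identically so alignment is preserved.
#'
#' @param image an [image224].
#' @param mask a [label_mask] with the same spatial shape.
#' @return A list of three `list(image=, mask=)` pairs:
#'   original, horizontal flip (columns reversed), vertical flip (rows
#'   reversed).
#' @export
augment_flips <- function(image, mask) {
  px <- image_pixels(image)
  stop_if_shape_mismatch(dim(px)[1:2], dim(mask), "image and mask")
  sid <- image_source_id(image)
  nc <- mask_n_classes(mask)
  cls <- mask_classes(mask)
  flip_img <- function(p, idx_row, idx_col) p[idx_row, idx_col, , drop = FALSE]
  h_rows <- seq_len(nrow(cls)); h_cols <- rev(seq_len(ncol(cls)))
  v_rows <- rev(seq_len(nrow(cls))); v_cols <- seq_len(ncol(cls))
  list(
    list(image = image224(px, sid), mask = label_mask(cls, nc)),
    list(image = image224(flip_img(px, h_rows, h_cols), paste0(sid, "_hflip")),
         mask = label_mask(cls[h_rows, h_cols], nc)),
    list(image = image224(flip_img(px, v_rows, v_cols), paste0(sid, "_vflip")),
         mask = label_mask(cls[v_rows, v_cols], nc))
  )
}

# Save/restore the global RNG state so generators are pure in their seeds.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
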