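# Independent brute-force oracles and small fixture builders shared by the
# tests. Oracles deliberately avoid the code paths they check.

# Quadruple-loop cross-correlation: explicit sums over output position and
# kernel index.
conv_oracle <- function(x, kernel, stride = 1, padding = "same") {
  k <- nrow(kernel)
  p <- if (padding == "same") (k - 1) %/% 2 else 0
  xp <- matrix(0, nrow(x) + 2 * p, ncol(x) + 2 * p)
  xp[(p + 1):(p + nrow(x)), (p + 1):(p + ncol(x))] <- x
  out_h <- (nrow(xp) - k) %/% stride + 1
  out_w <- (ncol(xp) - k) %/% stride + 1
  out <- matrix(0, out_h, out_w)
  for (i in seq_len(out_h)) {
    for (j in seq_len(out_w)) {
      acc <- 0
      for (a in seq_len(k)) {
        for (b in seq_len(k)) {
          acc <- acc + xp[(i - 1) * stride + a, (j - 1) * stride + b] * kernel[a, b]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Direct (non-log) naive Bayes posterior: prior times the product of
# per-feature Gaussian densities, normalized.
nb_oracle <- function(model, row) {
  k <- length(model$class_set)
  joint <- vapply(seq_len(k), function(i) {
    model$priors[i] * prod(nb_pdf(row, model$means[i, ], model$sds[i, ]))
  }, numeric(1))
  joint / sum(joint)
}

# Count-and-argmax voting oracle with lowest-index tie-break.
vote_oracle <- function(predictions, weights, class_set) {
  score <- sapply(class_set, function(cl) sum(weights[predictions == cl]))
  class_set[which.max(score)]
}

# Mann-Whitney pairwise AUC: P(score_pos > score_neg), ties counted 1/2.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# pixel array without the source_id attribute, for content comparisons
px <- function(img) {
  a <- unclass(img)
  attr(a, "source_id") <- NULL
  a
}

random_mask <- function(n_classes = 3, h = 20, w = 20) {
  label_mask(matrix(sample(0:(n_classes - 1), h * w, replace = TRUE), h, w),
             n_classes)
}

# Small random bank for feature tests (n_filters free, unlike the canonical
# 64-filter bank).
tiny_bank <- function(n_filters = 4, cin = 3, seed = 1) {
  set.seed(seed)
  filter_bank(array(rnorm(3 * 3 * cin * n_filters, sd = 0.2),
                    dim = c(3, 3, cin, n_filters)),
              bias = rep(0, n_filters), provenance = "custom")
}

# Linearly separable 3-class Gaussian blobs (class-mean separation >= 6 sd).
blob_frame <- function(n_per_class = 70, d = 4, seed = 3) {
  set.seed(seed)
  centers <- rbind(rep(0, d), rep(6, d), rep(12, d))
  x <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rnorm(n_per_class * d, mean = centers[i, 1], sd = 1),
           n_per_class, d)
  }))
  list(x = x, y = rep(0:2, each = n_per_class))
}

light_pipeline_config <- function(seed = 7) {
  pipeline_config(
    ensemble = ensemble_config(n_trees = 10, n_rounds = 8, seed = seed),
    max_train_pixels = 30000, seed = seed)
}
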