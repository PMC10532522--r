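test_that("nb_pdf is the Gaussian density", {
  expect_equal(nb_pdf(0, 0, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(nb_pdf(1.3, 0.3, 0.7), nb_pdf(-0.7, 0.3, 0.7), tolerance = 1e-12)
  # integrates to 1 (numerical quadrature oracle)
  q <- stats::integrate(function(x) nb_pdf(x, 2, 0.5), -Inf, Inf)
  expect_lt(abs(q$value - 1), 1e-6)
  expect_error(nb_pdf(0, 0, 0), "sd")
})

test_that("Gaussian NB fits population moments and clamps constants", {
  x <- matrix(c(0, 2, 5, 7, 9), ncol = 1)
  y <- c(0L, 0L, 1L, 1L, 1L)
  fit <- fit_gaussian_nb(list(x = x, y = y))
  expect_equal(fit$means[1, 1], 1.0)
  expect_equal(fit$sds[1, 1], 1.0)  # population sd: sqrt(((0-1)^2+(2-1)^2)/2)
  expect_equal(fit$priors, c(0.4, 0.6))

  # 60/40 priors
  fit2 <- fit_gaussian_nb(list(x = matrix(rnorm(10), ncol = 1),
                               y = c(rep(0L, 6), rep(1L, 4))))
  expect_equal(fit2$priors, c(0.6, 0.4))

  # constant feature -> sd_floor, no error
  xc <- cbind(c(0, 2, 5, 7), c(1, 1, 1, 1))
  fitc <- fit_gaussian_nb(list(x = xc, y = c(0L, 0L, 1L, 1L)), sd_floor = 1e-6)
  expect_equal(fitc$sds[, 2], c(1e-6, 1e-6))

  expect_error(fit_gaussian_nb(list(x = x, y = rep(0L, 5))), "2 classes")
})

test_that("nb_posterior: separation, symmetry, and the direct product oracle", {
  sep <- fit_gaussian_nb(list(x = matrix(c(rnorm(20), rnorm(20, 10)), ncol = 1),
                              y = rep(0:1, each = 20)))
  p <- nb_posterior(sep, matrix(0))
  expect_gt(p[1, 1], 0.999)

  # symmetric classes, midway row -> (0.5, 0.5)
  sym <- fit_gaussian_nb(list(x = matrix(c(-2, -2.5, -1.5, 2, 2.5, 1.5), ncol = 1),
                              y = rep(0:1, each = 3)))
  pm <- nb_posterior(sym, matrix(0))
  expect_equal(as.numeric(pm), c(0.5, 0.5), tolerance = 1e-12)

  # random small models: log-space path vs direct non-log product
  set.seed(31)
  for (i in 1:100) {
    k <- sample(2:3, 1); d <- sample(1:4, 1); n <- 10 * k
    x <- matrix(rnorm(n * d, sd = 2), n, d)
    y <- rep(seq_len(k) - 1L, length.out = n)
    m <- fit_gaussian_nb(list(x = x, y = y))
    row <- rnorm(d, sd = 2)
    expect_equal(as.numeric(nb_posterior(m, row)), nb_oracle(m, row),
                 tolerance = 1e-9)
  }

  expect_error(nb_posterior(sep, matrix(0, 1, 3)), "features")
})

test_that("forest member: split rule, determinism, tree averaging", {
  set.seed(12)
  x64 <- matrix(rnorm(300 * 64), 300, 64)
  y <- sample(0:1, 300, replace = TRUE)
  fit <- fit_forest(list(x = x64, y = y), n_trees = 5, seed = 3)
  expect_equal(fit$features_per_split, 7)  # floor(log2 64) + 1

  # single tree nails a linearly separable single-feature toy
  xs <- matrix(c(rnorm(50), rnorm(50, 10)), ncol = 1)
  ys <- rep(0:1, each = 50)
  f1 <- fit_forest(list(x = xs, y = ys), n_trees = 1, seed = 2)
  p1 <- forest_predict(f1, xs)
  expect_equal(as.integer(colnames(p1)[max.col(p1)]), ys)

  # same seed twice -> identical held-out predictions
  xh <- matrix(rnorm(40 * 64), 40, 64)
  fa <- fit_forest(list(x = x64, y = y), n_trees = 10, seed = 9)
  fb <- fit_forest(list(x = x64, y = y), n_trees = 10, seed = 9)
  expect_identical(forest_predict(fa, xh), forest_predict(fb, xh))

  # aggregate prediction is the mean of the per-tree responses
  f3 <- fit_forest(list(x = xs, y = ys), n_trees = 3, seed = 5)
  df <- as.data.frame(xh[, 1, drop = FALSE]); colnames(df) <- "f1"
  per_tree <- predict(f3$fit, data = df, num.threads = 1,
                      predict.all = TRUE)$predictions
  expect_equal(unname(forest_predict(f3, xh[, 1, drop = FALSE])),
               unname(apply(per_tree, c(1, 2), mean)), tolerance = 1e-12)

  expect_error(fit_forest(list(x = x64[0, ], y = integer(0)), 5, 1), "empty|label")
})

test_that("boosted member honors the regularized second-order objective", {
  # Leaf-weight closed form. A one-split tree on a binary feature puts n
  # pure-class rows in each leaf; with base score 0.5 the logistic
  # derivatives give each leaf G = -(+/-) n/2 and H = n/4, so the leaf
  # weight must be -G/(H + lambda) and the round-1 predictions
  # plogis(+/- (n/2)/(n/4 + lambda)).
  n <- 40; lambda <- 3
  xsep <- matrix(c(rep(0, n), rep(1, n)), ncol = 1)
  ysep <- c(rep(0L, n), rep(1L, n))
  fitsep <- fit_boosted(list(x = xsep, y = ysep), n_rounds = 1,
                        learning_rate = 1, lambda_reg = lambda,
                        gamma_penalty = 0, seed = 1)
  p <- boosted_predict(fitsep, matrix(c(0, 1), ncol = 1))
  # each leaf holds n one-class rows: G = -(+/-)n/2, H = n/4
  w <- (n / 2) / (n / 4 + lambda)
  expect_equal(unname(p[, "1"]), c(plogis(-w), plogis(w)), tolerance = 1e-6)

  # training logistic loss is non-increasing over rounds
  set.seed(17)
  xr <- matrix(rnorm(200 * 5), 200, 5)
  yr <- as.integer(xr[, 1] + 0.5 * rnorm(200) > 0)
  fitr <- fit_boosted(list(x = xr, y = yr), n_rounds = 12, seed = 4)
  expect_true(all(diff(fitr$train_loss) <= 1e-10))

  # lambda -> infinity drives predictions to the base score
  fit_inf <- fit_boosted(list(x = xr, y = yr), n_rounds = 5,
                         lambda_reg = 1e12, seed = 4)
  expect_equal(unname(boosted_predict(fit_inf, xr[1:5, ])[, 2]), rep(0.5, 5),
               tolerance = 1e-4)

  # three-class frame yields a 3-column probability simplex
  y3 <- rep(0:2, length.out = 200)
  fit3 <- fit_boosted(list(x = xr, y = y3), n_rounds = 3, seed = 1)
  p3 <- boosted_predict(fit3, xr[1:7, ])
  expect_equal(dim(p3), c(7L, 3L))
  expect_equal(rowSums(p3), rep(1, 7), tolerance = 1e-6)
  expect_true(all(diff(fit3$train_loss) <= 1e-10))

  expect_error(fit_boosted(list(x = xr, y = yr), n_rounds = 2, lambda_reg = -1),
               "lambda")
  expect_error(fit_boosted(list(x = xr, y = yr), n_rounds = 2,
                           gamma_penalty = -1), "gamma")
})

test_that("voting rules match counting oracles and spec examples", {
  cls <- c(0L, 1L, 2L)
  # mode rule and tie-break
  expect_equal(vote_hard(c(0L, 0L, 1L), cls), 0L)        # {A,A,B} -> A
  expect_equal(vote_hard(c(0L, 1L), c(0L, 1L)), 0L)      # tie -> lowest index
  # weighted example: (A,B,B) with weights (0.6,0.2,0.2) -> A
  expect_equal(vote_weighted(c(0L, 1L, 1L), c(0.6, 0.2, 0.2), cls), 0L)

  # exhaustive 27 member-prediction triples: hard == uniform weighted == oracle
  grid <- expand.grid(a = cls, b = cls, c = cls)
  for (i in seq_len(nrow(grid))) {
    preds <- as.integer(grid[i, ])
    expect_equal(vote_hard(preds, cls), vote_oracle(preds, c(1, 1, 1), cls))
    expect_equal(vote_weighted(preds, c(1, 1, 1), cls), vote_hard(preds, cls))
  }

  # 1000 random weighted cases vs the counting oracle
  set.seed(23)
  for (i in 1:1000) {
    m <- sample(2:5, 1)
    preds <- sample(cls, m, replace = TRUE)
    w <- round(runif(m, 0.05, 1), 3)  # distinct-ish, no accidental ties
    expect_equal(vote_weighted(preds, w, cls), vote_oracle(preds, w, cls))
  }

  # zero-weight member never changes the outcome
  for (i in 1:50) {
    preds <- sample(cls, 4, replace = TRUE)
    w <- c(runif(3, 0.1, 1), 0)
    expect_equal(vote_weighted(preds, w, cls),
                 vote_weighted(preds[1:3], w[1:3], cls))
  }

  expect_error(vote_weighted(c(0L, 1L), c(1, 1, 1), cls), "length")
  expect_error(vote_weighted(c(0L, 1L), c(0, 0), cls), "weights")
})

test_that("soft voting averages member probabilities", {
  probs <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.4, 0.6))
  out <- vote_soft(probs, class_set = c(0L, 1L))
  expect_equal(unname(out$probabilities), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(out$class, 0L)  # tie -> lowest class index

  one <- vote_soft(matrix(c(0.2, 0.3, 0.5), 1), weights = 7,
                   class_set = c(0L, 1L, 2L))
  expect_equal(one$class, 2L)

  set.seed(9)
  for (i in 1:30) {
    m <- sample(2:4, 1); k <- sample(2:3, 1)
    p <- matrix(runif(m * k), m, k); p <- p / rowSums(p)
    w <- runif(m, 0.1, 2)
    out <- vote_soft(p, w, seq_len(k) - 1L)
    expect_equal(sum(out$probabilities), 1, tolerance = 1e-12)
    scaled <- vote_soft(p, 3.7 * w, seq_len(k) - 1L)
    expect_equal(out$probabilities, scaled$probabilities, tolerance = 1e-12)
  }

  expect_error(vote_soft(rbind(c(0.5, 0.6)), 1, c(0L, 1L)), "sum to 1")
})

test_that("the fitted ensemble recovers separable blobs and is composable", {
  fr <- blob_frame()
  cfg <- ensemble_config(n_trees = 15, n_rounds = 10, seed = 6)
  ens <- fit_ensemble(fr, cfg)
  pred <- ensemble_predict(ens, fr$x)
  acc_ens <- mean(pred$class == fr$y)
  expect_gte(acc_ens, 0.95)

  # ensemble at least matches its worst member on training data
  accs <- c(
    nb = mean(as.integer(colnames(nb_posterior(ens$nb, fr$x))[
      max.col(nb_posterior(ens$nb, fr$x))]) == fr$y),
    forest = mean(as.integer(colnames(forest_predict(ens$forest, fr$x))[
      max.col(forest_predict(ens$forest, fr$x))]) == fr$y),
    boosted = mean(as.integer(colnames(boosted_predict(ens$boosted, fr$x))[
      max.col(boosted_predict(ens$boosted, fr$x))]) == fr$y))
  expect_gte(acc_ens, min(accs))

  # probabilities cover all training classes and rows map 1:1
  expect_equal(colnames(pred$prob), c("0", "1", "2"))
  expect_equal(nrow(pred$prob), nrow(fr$x))

  # soft-vote outcome equals vote_soft applied to the member outputs
  row <- fr$x[101, , drop = FALSE]
  members <- rbind(nb_posterior(ens$nb, row),
                   forest_predict(ens$forest, row),
                   boosted_predict(ens$boosted, row))
  ref <- vote_soft(members, cfg$weights, ens$class_set)
  expect_equal(pred$class[101], ref$class)
  expect_equal(unname(pred$prob[101, ]), unname(ref$probabilities),
               tolerance = 1e-12)

  # deterministic given seeds
  ens2 <- fit_ensemble(fr, cfg)
  expect_identical(ensemble_predict(ens2, fr$x)$class, pred$class)

  # hard and weighted modes agree with the row-wise voting rules
  hard <- fit_ensemble(fr, ensemble_config(voting = "hard", n_trees = 15,
                                           n_rounds = 10, seed = 6))
  ph <- ensemble_predict(hard, fr$x[1:20, ])
  member_cls <- cbind(
    as.integer(colnames(members)[max.col(nb_posterior(hard$nb, fr$x[1:20, ]))]),
    as.integer(colnames(members)[max.col(forest_predict(hard$forest, fr$x[1:20, ]))]),
    as.integer(colnames(members)[max.col(boosted_predict(hard$boosted, fr$x[1:20, ]))]))
  expect_equal(ph$class,
               apply(member_cls, 1, vote_hard, class_set = hard$class_set))

  expect_error(ensemble_predict(ens, fr$x[, 1:2]), "features")
})

test_that("ensemble archives round-trip exactly", {
  fr <- blob_frame(n_per_class = 40)
  ens <- fit_ensemble(fr, ensemble_config(n_trees = 8, n_rounds = 5, seed = 2))
  path <- tempfile(fileext = ".rds")
  save_ensemble(ens, path)
  back <- load_ensemble(path)
  a <- ensemble_predict(ens, fr$x)
  b <- ensemble_predict(back, fr$x)
  expect_identical(a$class, b$class)
  expect_equal(a$prob, b$prob, tolerance = 1e-12)
  expect_error(load_ensemble(system.file("DESCRIPTION", package = "cardioseg")),
               "archive|readRDS|unknown", ignore.case = TRUE)
  unlink(path)
})
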