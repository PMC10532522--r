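# Three-member voting ensemble over per-pixel feature rows.
#
# Members: hand-written Gaussian naive Bayes (population-variance estimates,
# log-space posteriors), a random forest (ranger; probability forest whose
# prediction is the average of the per-tree class responses, with
# floor(log2 M) + 1 candidate features per split), and regularized
# gradient-boosted trees (xgboost; second-order logistic objective with L2
# leaf penalty lambda and pruning penalty gamma, so a leaf with gradient sum
# G and hessian sum H gets weight -G/(H + lambda)). The combiner supports
# hard (mode), weighted (weighted indicator argmax), and soft (weighted
# average of member class probabilities) voting; ties always break to the
# lowest class index in the ensemble's class order.

#' Gaussian probability density
#'
#' `(1 / (sqrt(2*pi) * sd)) * exp(-(x - mean)^2 / (2 * sd^2))`, the density
#' naive Bayes evaluates per feature.
#'
#' @param x,mean,sd numeric (vectorized); `sd` must be positive.
#' @return Density values.
#' @export
nb_pdf <- function(x, mean, sd) {
  if (any(sd <= 0)) stop("sd must be > 0", call. = FALSE)
  (1 / (sqrt(2 * pi) * sd)) * exp(-(x - mean)^2 / (2 * sd^2))
}

frame_xy <- function(frame) {
  d <- if (inherits(frame, "feature_frame")) {
    if (is.null(frame$label)) stop("frame has no label column", call. = FALSE)
    list(x = frame$x, y = as.integer(frame$label))
  } else if (is.list(frame) && !is.null(frame$x) && !is.null(frame$y)) {
    list(x = as.matrix(frame$x), y = as.integer(frame$y))
  } else {
    stop("expected a labeled feature_frame or list(x=, y=)", call. = FALSE)
  }
  colnames(d$x) <- paste0("f", seq_len(ncol(d$x)))
  if (length(d$y) != nrow(d$x)) stop("label length must match row count", call. = FALSE)
  d
}

#' Fit a Gaussian naive Bayes model
#'
#' Per class and feature, stores the mean and the population standard
#' deviation (divisor n, not n-1); standard deviations are clamped from below
#' at `sd_floor` so constant features do not produce degenerate densities.
#' Class priors are the training class frequencies.
#'
#' @param frame labeled `feature_frame` (or `list(x=, y=)`).
#' @param sd_floor minimum stored standard deviation (default 1e-6).
#' @return An object of class `gaussian_nb`.
#' @export
fit_gaussian_nb <- function(frame, sd_floor = 1e-6) {
  d <- frame_xy(frame)
  classes <- sort(unique(d$y))
  if (length(classes) < 2) stop("need at least 2 classes to fit", call. = FALSE)
  tab <- table(factor(d$y, levels = classes))
  if (any(tab < 2)) stop("need at least 2 rows per class", call. = FALSE)
  means <- matrix(0, length(classes), ncol(d$x))
  sds <- matrix(0, length(classes), ncol(d$x))
  for (i in seq_along(classes)) {
    xi <- d$x[d$y == classes[i], , drop = FALSE]
    mu <- colMeans(xi)
    sd_pop <- sqrt(colMeans(sweep(xi, 2L, mu)^2))
    means[i, ] <- mu
    sds[i, ] <- pmax(sd_pop, sd_floor)
  }
  structure(list(class_set = classes,
                 priors = as.numeric(tab) / length(d$y),
                 means = means, sds = sds, sd_floor = sd_floor),
            class = "gaussian_nb")
}

#' Naive Bayes class posteriors
#'
#' For each row: prior times the product over features of the Gaussian
#' density, evaluated in log space and normalized to sum to 1.
#'
#' @param model a `gaussian_nb`.
#' @param rows numeric matrix (or single vector) of feature rows.
#' @return N x K matrix of posterior probabilities, columns in `class_set`
#'   order.
#' @export
nb_posterior <- function(model, rows) {
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1)
  if (ncol(rows) != ncol(model$means)) {
    stop(sprintf("row has %d features but model expects %d",
                 ncol(rows), ncol(model$means)), call. = FALSE)
  }
  k <- length(model$class_set)
  ll <- matrix(0, nrow(rows), k)
  for (i in seq_len(k)) {
    mu <- model$means[i, ]; sd <- model$sds[i, ]
    z <- sweep(sweep(rows, 2L, mu), 2L, sd, "/")
    ll[, i] <- log(model$priors[i]) - sum(log(sd)) -
      0.5 * ncol(rows) * log(2 * pi) - 0.5 * rowSums(z^2)
  }
  m <- ll - apply(ll, 1L, max)
  p <- exp(m)
  p <- p / rowSums(p)
  colnames(p) <- as.character(model$class_set)
  p
}

#' Fit the random-forest member
#'
#' Bootstrap-resampled probability trees with `floor(log2(M)) + 1` candidate
#' features per split (M = feature count). Single-threaded and seeded, so the
#' fitted model and its predictions are reproducible.
#'
#' @param frame labeled `feature_frame` (or `list(x=, y=)`).
#' @param n_trees number of trees K.
#' @param seed integer seed.
#' @return An object of class `forest_model`.
#' @export
fit_forest <- function(frame, n_trees = 50, seed = 1) {
  d <- frame_xy(frame)
  if (nrow(d$x) == 0) stop("empty training frame", call. = FALSE)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  classes <- sort(unique(d$y))
  mtry <- min(ncol(d$x), floor(log2(ncol(d$x))) + 1)
  fit <- ranger::ranger(
    x = as.data.frame(d$x),
    y = factor(d$y, levels = classes),
    num.trees = as.integer(n_trees), mtry = mtry, probability = TRUE,
    seed = as.integer(seed), num.threads = 1L, verbose = FALSE)
  structure(list(fit = fit, class_set = classes, n_trees = as.integer(n_trees),
                 features_per_split = mtry, seed = as.integer(seed),
                 n_features = ncol(d$x)),
            class = "forest_model")
}

#' Random-forest class probabilities
#'
#' The forest prediction is the average over the K trees of each tree's
#' class-probability response.
#'
#' @param model a `forest_model`.
#' @param rows numeric feature matrix.
#' @return N x K probability matrix, columns in `class_set` order.
#' @export
forest_predict <- function(model, rows) {
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1)
  df <- as.data.frame(rows)
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  p <- stats::predict(model$fit, data = df, num.threads = 1L,
                      verbose = FALSE)$predictions
  colnames(p) <- as.character(model$class_set)
  p
}

#' Fit the gradient-boosted member
#'
#' Additive trees minimizing a regularized logistic objective by its
#' second-order expansion: per boosting round each leaf's weight is the
#' closed-form minimizer -G/(H + lambda) of the quadratic, with gamma as the
#' per-leaf pruning penalty. More than two classes use a one-vs-rest softmax
#' objective. The per-round training logistic loss is recorded so its
#' monotone decrease can be checked.
#'
#' @param frame labeled `feature_frame` (or `list(x=, y=)`).
#' @param n_rounds boosting rounds.
#' @param learning_rate shrinkage eta.
#' @param lambda_reg L2 leaf-weight penalty lambda (>= 0).
#' @param gamma_penalty per-leaf pruning penalty gamma (>= 0).
#' @param max_depth tree depth.
#' @param seed integer seed.
#' @return An object of class `boosted_model`.
#' @export
fit_boosted <- function(frame, n_rounds = 25, learning_rate = 0.3,
                        lambda_reg = 1, gamma_penalty = 0, max_depth = 6,
                        seed = 1) {
  if (n_rounds < 1) stop("n_rounds must be >= 1", call. = FALSE)
  if (lambda_reg < 0) stop("lambda_reg must be >= 0", call. = FALSE)
  if (gamma_penalty < 0) stop("gamma_penalty must be >= 0", call. = FALSE)
  d <- frame_xy(frame)
  classes <- sort(unique(d$y))
  k <- length(classes)
  ymap <- match(d$y, classes) - 1L
  dtrain <- xgboost::xgb.DMatrix(d$x, label = ymap)
  params <- list(eta = learning_rate, lambda = lambda_reg,
                 gamma = gamma_penalty, max_depth = as.integer(max_depth),
                 nthread = 1L, seed = as.integer(seed))
  if (k == 2) {
    params$objective <- "binary:logistic"
    params$base_score <- 0.5
  } else {
    params$objective <- "multi:softprob"
    params$num_class <- k
  }
  fit <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = as.integer(n_rounds), verbose = 0)
  # training logistic loss after each round, from the model's own predictions
  loss <- vapply(seq_len(n_rounds), function(r) {
    p <- boosted_prob(fit, dtrain, k, iterationrange = c(1, r))
    eps <- 1e-15
    -mean(log(pmax(p[cbind(seq_along(ymap), ymap + 1L)], eps)))
  }, numeric(1))
  structure(list(fit = fit, class_set = classes, n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate, lambda_reg = lambda_reg,
                 gamma_penalty = gamma_penalty, seed = as.integer(seed),
                 train_loss = loss, n_features = ncol(d$x)),
            class = "boosted_model")
}

boosted_prob <- function(fit, dmat, k, iterationrange = NULL) {
  p <- stats::predict(fit, dmat, iterationrange = iterationrange)
  if (k == 2) {
    p <- as.numeric(p)
    cbind(1 - p, p)
  } else {
    matrix(as.numeric(p), ncol = k, byrow = !is.matrix(p))
  }
}

#' Boosted-tree class probabilities
#' @param model a `boosted_model`.
#' @param rows numeric feature matrix.
#' @return N x K probability matrix, columns in `class_set` order.
#' @export
boosted_predict <- function(model, rows) {
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1)
  k <- length(model$class_set)
  p <- boosted_prob(model$fit, xgboost::xgb.DMatrix(rows), k)
  colnames(p) <- as.character(model$class_set)
  p
}

#' Hard (popularity) vote
#'
#' The mode of the member predictions; ties break to the class occurring
#' earliest in `class_set`.
#'
#' @param predictions vector of member class labels.
#' @param class_set ordered vector of possible classes.
#' @return The winning class.
#' @export
vote_hard <- function(predictions, class_set) {
  vote_weighted(predictions, rep(1, length(predictions)), class_set)
}

#' Weighted majority vote
#'
#' `argmax_i sum_j w_j * 1(C_j(x) = i)` over the classes in `class_set`
#' order; ties break to the lowest class index.
#'
#' @param predictions vector of member class labels.
#' @param weights non-negative member weights (not all zero).
#' @param class_set ordered vector of possible classes.
#' @return The winning class.
#' @export
vote_weighted <- function(predictions, weights, class_set) {
  if (length(predictions) < 1) stop("need at least one member", call. = FALSE)
  if (length(predictions) != length(weights)) {
    stop("predictions and weights must have equal length", call. = FALSE)
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  idx <- match(predictions, class_set)
  if (anyNA(idx)) stop("prediction outside class_set", call. = FALSE)
  score <- vapply(seq_along(class_set),
                  function(i) sum(weights[idx == i]), numeric(1))
  class_set[which.max(score)]
}

#' Soft (probability-averaging) vote
#'
#' Combined probability for class i is `sum_j w_j * p_ij / sum_j w_j`; the
#' winner is its argmax with ties to the lowest class index.
#'
#' @param prob_rows members x classes matrix of member class probabilities
#'   (each row sums to 1).
#' @param weights non-negative member weights (not all zero).
#' @param class_set ordered vector of classes matching the columns.
#' @return List with `class` and `probabilities` (named, sums to 1).
#' @export
vote_soft <- function(prob_rows, weights = rep(1, nrow(prob_rows)),
                      class_set = seq_len(ncol(prob_rows)) - 1L) {
  prob_rows <- as.matrix(prob_rows)
  if (length(weights) != nrow(prob_rows)) {
    stop("one weight per member required", call. = FALSE)
  }
  if (any(weights < 0) || all(weights == 0)) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  if (any(abs(rowSums(prob_rows) - 1) > 1e-6) || any(prob_rows < 0)) {
    stop("each member's probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  combined <- as.numeric(crossprod(prob_rows, weights)) / sum(weights)
  names(combined) <- as.character(class_set)
  list(class = class_set[which.max(combined)], probabilities = combined)
}

#' Ensemble configuration
#'
#' @param voting `"soft"` (default), `"hard"`, or `"weighted"`.
#' @param weights per-member weights in member order (NB, forest, boosted);
#'   uniform by default.
#' @param n_trees forest size.
#' @param n_rounds boosting rounds.
#' @param learning_rate boosting shrinkage.
#' @param lambda_reg boosting L2 leaf penalty.
#' @param gamma_penalty boosting pruning penalty.
#' @param max_depth boosting tree depth.
#' @param sd_floor naive-Bayes standard-deviation floor.
#' @param seed integer seed shared by the tree members.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(voting = c("soft", "hard", "weighted"),
                            weights = c(1, 1, 1), n_trees = 50, n_rounds = 25,
                            learning_rate = 0.3, lambda_reg = 1,
                            gamma_penalty = 0, max_depth = 6,
                            sd_floor = 1e-6, seed = 1) {
  voting <- match.arg(voting)
  if (length(weights) != 3) stop("three member weights required", call. = FALSE)
  structure(list(voting = voting, weights = as.numeric(weights),
                 n_trees = n_trees, n_rounds = n_rounds,
                 learning_rate = learning_rate, lambda_reg = lambda_reg,
                 gamma_penalty = gamma_penalty, max_depth = max_depth,
                 sd_floor = sd_floor, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Fit the three-member voting ensemble
#'
#' Fits the Gaussian naive Bayes, random-forest, and boosted-tree members on
#' the same labeled frame and stores the voting configuration.
#'
#' @param frame labeled `feature_frame` (or `list(x=, y=)`).
#' @param config an [ensemble_config].
#' @return An object of class `trained_ensemble`.
#' @export
fit_ensemble <- function(frame, config = ensemble_config()) {
  d <- frame_xy(frame)
  classes <- sort(unique(d$y))
  if (length(classes) < 2) stop("need at least 2 classes to fit", call. = FALSE)
  structure(list(
    nb = fit_gaussian_nb(d, sd_floor = config$sd_floor),
    forest = fit_forest(d, n_trees = config$n_trees, seed = config$seed),
    boosted = fit_boosted(d, n_rounds = config$n_rounds,
                          learning_rate = config$learning_rate,
                          lambda_reg = config$lambda_reg,
                          gamma_penalty = config$gamma_penalty,
                          max_depth = config$max_depth, seed = config$seed),
    config = config, class_set = classes),
    class = "trained_ensemble")
}

member_probs <- function(model, rows) {
  list(nb = nb_posterior(model$nb, rows),
       forest = forest_predict(model$forest, rows),
       boosted = boosted_predict(model$boosted, rows))
}

#' Predict classes (and combined probabilities) with the ensemble
#'
#' Soft voting averages the members' probability rows with the configured
#' weights; hard/weighted voting first takes each member's argmax and then
#' applies the mode / weighted-indicator rule. Ties always break to the
#' lowest class index in `class_set` order. The reported probabilities are
#' the weighted member average in every mode.
#'
#' @param model a `trained_ensemble`.
#' @param rows numeric feature matrix (or `feature_frame`).
#' @return List with `class` (vector, one per row) and `prob` (N x K matrix
#'   in `class_set` column order).
#' @export
ensemble_predict <- function(model, rows) {
  if (inherits(rows, "feature_frame")) rows <- rows$x
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1)
  if (ncol(rows) != model$forest$n_features) {
    stop(sprintf("rows have %d features but the ensemble was trained on %d",
                 ncol(rows), model$forest$n_features), call. = FALSE)
  }
  probs <- member_probs(model, rows)
  w <- model$config$weights
  combined <- (w[1] * probs$nb + w[2] * probs$forest + w[3] * probs$boosted) /
    sum(w)
  cls_set <- model$class_set
  if (model$config$voting == "soft") {
    cls <- cls_set[max.col(combined, ties.method = "first")]
  } else {
    vote_w <- if (model$config$voting == "hard") rep(1, 3) else w
    member_cls <- vapply(probs, function(p)
      cls_set[max.col(p, ties.method = "first")], numeric(nrow(rows)))
    member_cls <- matrix(member_cls, nrow = nrow(rows))
    cls <- apply(member_cls, 1L, vote_weighted, weights = vote_w,
                 class_set = cls_set)
  }
  colnames(combined) <- as.character(cls_set)
  list(class = as.integer(cls), prob = combined)
}

#' Save a trained ensemble to a single versioned archive
#'
#' The boosted member is serialized through its raw byte representation so
#' the archive is portable across sessions; loading restores a model whose
#' predictions are identical to the original's.
#'
#' @param model a `trained_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_ensemble <- function(model, path) {
  obj <- list(format = "cardioseg_ensemble", version = 1L,
              nb = model$nb,
              forest = model$forest,
              boosted_raw = xgboost::xgb.save.raw(model$boosted$fit),
              boosted_meta = model$boosted[setdiff(names(model$boosted), "fit")],
              config = model$config, class_set = model$class_set)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a trained ensemble saved with [save_ensemble]
#' @param path archive path.
#' @return A `trained_ensemble`.
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cardioseg_ensemble")) {
    stop(sprintf("%s is not an ensemble archive", path), call. = FALSE)
  }
  boosted <- obj$boosted_meta
  boosted$fit <- xgboost::xgb.load.raw(obj$boosted_raw)
  class(boosted) <- "boosted_model"
  structure(list(nb = obj$nb, forest = obj$forest, boosted = boosted,
                 config = obj$config, class_set = obj$class_set),
            class = "trained_ensemble")
}
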