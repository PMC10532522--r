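# End-to-end pipeline: freeze a filter bank, extract per-pixel features from
# labeled training images (optionally flip-augmented), assemble the labeled
# pixel table frame by frame, fit the voting ensemble, and for new images
# predict the three-class filter, map it to the binary enlarged-region mask
# (small components removed), diagnose the subject, and score.

#' Pipeline configuration
#'
#' @param bank_provenance filter-bank source (see [make_filter_bank]).
#' @param bank_seed seed for the seeded random bank.
#' @param weights_file weights file for the pretrained bank.
#' @param frame_size side of the square training frames; must divide 224.
#' @param ensemble an [ensemble_config] for the three members and the vote.
#' @param augment apply flip augmentation to training subjects (default TRUE).
#' @param max_train_pixels cap on labeled pixels used to fit the ensemble,
#'   drawn balanced across classes (default 90000, i.e. up to 30000 per
#'   class); the cap keeps training tractable on a single CPU while leaving
#'   each class abundantly represented.
#' @param min_region_px connected components of the predicted enlarged region
#'   smaller than this (4-connectivity) are discarded (default 25).
#' @param seed master seed for pixel subsampling.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(bank_provenance = "seeded_random", bank_seed = 42,
                            weights_file = NULL, frame_size = 8,
                            ensemble = ensemble_config(), augment = TRUE,
                            max_train_pixels = 90000, min_region_px = 25,
                            seed = 1) {
  if (224 %% frame_size != 0) stop("frame_size must divide 224", call. = FALSE)
  if (min_region_px < 0) stop("min_region_px must be >= 0", call. = FALSE)
  structure(list(bank_provenance = bank_provenance,
                 bank_seed = as.integer(bank_seed),
                 weights_file = weights_file,
                 frame_size = as.integer(frame_size), ensemble = ensemble,
                 augment = isTRUE(augment),
                 max_train_pixels = as.integer(max_train_pixels),
                 min_region_px = as.integer(min_region_px),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# labeled pixel table for one image, rows in frame-major order
image_frame <- function(image, mask3, bank, frame_size) {
  fmap <- extract_features(image, bank)
  fr <- flatten_to_frame(fmap, mask3)
  ord <- frame_order_index(fr$height, fr$width, frame_size)
  fr$x <- fr$x[ord, , drop = FALSE]
  fr$label <- fr$label[ord]
  fr
}

#' Train the segmentation pipeline
#'
#' Freezes the configured filter bank, extracts the feature map of every
#' training image, assembles the labeled per-pixel table frame by frame
#' (optionally including horizontal/vertical flips of each training pair),
#' subsamples it balanced across classes up to `max_train_pixels`, and fits
#' the three-member voting ensemble. Deterministic given the config seeds.
#'
#' @param dataset list of subjects, each with `image` ([image224]) and
#'   `mask3` (three-class [label_mask]) entries (as produced by
#'   [generate_dataset]).
#' @param config a [pipeline_config].
#' @param quiet suppress progress messages.
#' @return An object of class `cardioseg_model` holding the trained ensemble,
#'   the frozen bank, and the config.
#' @export
train_pipeline <- function(dataset, config = pipeline_config(), quiet = FALSE) {
  if (length(dataset) < 2) stop("need at least 2 training subjects", call. = FALSE)
  for (s in dataset) {
    stop_if_shape_mismatch(dim(image_pixels(s$image))[1:2], dim(s$mask3),
                           "image and mask")
  }
  bank <- make_filter_bank(config$bank_provenance, seed = config$bank_seed,
                           weights_file = config$weights_file)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  frames <- list()
  for (s in dataset) {
    pairs <- if (config$augment) augment_flips(s$image, s$mask3) else
      list(list(image = s$image, mask = s$mask3))
    for (pr in pairs) {
      frames[[length(frames) + 1L]] <-
        image_frame(pr$image, pr$mask, bank, config$frame_size)
    }
  }
  frame <- bind_frames(frames)
  say("feature extraction: %d images -> %d labeled pixels (%.1fs)",
      length(frames), nrow(frame$x), as.numeric(Sys.time() - t0, units = "secs"))
  if (length(unique(frame$label)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  # balanced subsample across classes
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  classes <- sort(unique(frame$label))
  per_class <- config$max_train_pixels %/% length(classes)
  keep <- unlist(lapply(classes, function(cl) {
    idx <- which(frame$label == cl)
    if (length(idx) > per_class) sort(sample(idx, per_class)) else idx
  }))
  sub <- list(x = frame$x[keep, , drop = FALSE], y = frame$label[keep])
  t1 <- Sys.time()
  ensemble <- fit_ensemble(sub, config$ensemble)
  say("ensemble fit on %d pixels x %d features (%.1fs)", nrow(sub$x),
      ncol(sub$x), as.numeric(Sys.time() - t1, units = "secs"))
  structure(list(ensemble = ensemble, bank = bank, config = config,
                 class_set = ensemble$class_set),
            class = "cardioseg_model")
}

#' @export
print.cardioseg_model <- function(x, ...) {
  cat(sprintf("<cardioseg_model> classes={%s} voting=%s bank=%s/seed %s\n",
              paste(x$class_set, collapse = ","), x$ensemble$config$voting,
              x$bank$provenance, ifelse(is.na(x$bank$seed), "-", x$bank$seed)))
  invisible(x)
}

check_bank_match <- function(model, bank) {
  if (is.null(bank)) return(model$bank)
  if (!identical(bank$provenance, model$bank$provenance) ||
      !identical(bank$seed, model$bank$seed) ||
      !isTRUE(all.equal(bank$kernels, model$bank$kernels))) {
    stop("supplied filter bank differs from the bank the model was trained with",
         call. = FALSE)
  }
  bank
}

pipeline_predict <- function(model, image, bank = NULL) {
  bank <- check_bank_match(model, bank)
  fmap <- extract_features(image, bank)
  fr <- flatten_to_frame(fmap)
  pred <- ensemble_predict(model$ensemble, fr$x)
  cls <- matrix(pred$class, nrow = fr$height, ncol = fr$width, byrow = TRUE)
  list(mask3 = label_mask(cls, 3L), prob = pred$prob,
       height = fr$height, width = fr$width)
}

#' Predict the three-class mask of an image
#'
#' Classifies every pixel's 64-feature row with the trained ensemble and
#' reshapes the result back to the image grid.
#'
#' @param model a `cardioseg_model` from [train_pipeline].
#' @param image an [image224].
#' @param bank optional filter bank; when given it must be identical to the
#'   bank the model was trained with (provenance, seed, kernels), otherwise
#'   an error is raised.
#' @return A three-class [label_mask].
#' @export
predict_mask <- function(model, image, bank = NULL) {
  pipeline_predict(model, image, bank)$mask3
}

#' Map a three-class mask to the binary enlarged-region mask
#'
#' The binary mask is the indicator of class 2, post-processed by removing
#' 4-connected components smaller than `min_region_px` pixels.
#'
#' @param mask3 a three-class [label_mask].
#' @param min_region_px minimum surviving component size (0 disables the
#'   filter).
#' @return A two-class [label_mask].
#' @export
to_binary <- function(mask3, min_region_px = 25) {
  bin <- mask_classes(mask3) == 2L
  if (min_region_px > 0 && any(bin)) {
    lab <- EBImage::bwlabel(bin * 1)  # 4-connectivity component labeling
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_region_px)
    bin[lab %in% small] <- FALSE
  }
  label_mask(matrix(as.integer(bin), nrow(mask3), ncol(mask3)), 2L)
}

#' Subject-level diagnosis from the binary mask
#'
#' A subject is called enlarged iff any pixel of the (component-filtered)
#' binary mask is 1.
#'
#' @param binary_mask a two-class [label_mask].
#' @return Logical flag.
#' @export
diagnose_subject <- function(binary_mask) {
  any(mask_classes(binary_mask) == 1L)
}

#' Evaluate the pipeline on a labeled dataset
#'
#' Per subject: predicts the three-class mask, maps it to the binary mask,
#' diagnoses, and scores. Pixel-level sensitivity/specificity (and the
#' Eq.-style accuracy) use class 2 as the positive class; `accuracy_multiclass`
#' is the plain fraction of pixels whose three-class label is correct.
#' Sensitivity is undefined (NA) for subjects with no true class-2 pixels,
#' and the summary averages over the subjects where it is defined.
#'
#' @param model a `cardioseg_model`.
#' @param dataset list of subjects with `subject_id`, `image`, `mask3`,
#'   `mask2`, and `enlarged` entries.
#' @param quiet suppress progress messages.
#' @return List with `per_subject` (data.frame, one row per subject),
#'   `summary` (named list of unweighted means plus the subject-level
#'   confusion), `results` (per-subject list with predicted masks and
#'   class-2 pixel probabilities).
#' @export
evaluate_pipeline <- function(model, dataset, quiet = FALSE) {
  if (length(dataset) == 0) stop("empty evaluation dataset", call. = FALSE)
  min_px <- model$config$min_region_px
  results <- vector("list", length(dataset))
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    t0 <- Sys.time()
    pred <- pipeline_predict(model, s$image)
    bin <- to_binary(pred$mask3, min_px)
    conf2 <- confusion(pred$mask3, s$mask3, positive_class = 2L)
    sens <- if (conf2$tp + conf2$fn > 0) sensitivity(conf2) else NA_real_
    spec <- if (conf2$tn + conf2$fp > 0) specificity(conf2) else NA_real_
    diag <- diagnose_subject(bin)
    rows[[i]] <- data.frame(
      subject_id = s$subject_id,
      accuracy = accuracy(conf2),
      accuracy_multiclass = mean(mask_classes(pred$mask3) == mask_classes(s$mask3)),
      sensitivity = sens,
      specificity = spec,
      dice_binary = dice(bin, s$mask2, mode = "binary"),
      dice_macro = dice(pred$mask3, s$mask3, mode = "macro"),
      diagnosis = diag,
      truth = s$enlarged,
      stringsAsFactors = FALSE)
    # per-pixel probability of the enlarged class, for ROC analysis
    p2 <- pred$prob[, match("2", colnames(pred$prob))]
    results[[i]] <- list(subject_id = s$subject_id, mask3 = pred$mask3,
                         binary = bin, prob_enlarged = p2)
    if (!quiet) {
      message(sprintf("evaluated %s: acc=%.3f dice=%.3f (%.1fs)", s$subject_id,
                      rows[[i]]$accuracy, rows[[i]]$dice_binary,
                      as.numeric(Sys.time() - t0, units = "secs")))
    }
  }
  per_subject <- do.call(rbind, rows)
  subj_conf <- structure(list(
    tp = sum(per_subject$diagnosis & per_subject$truth),
    tn = sum(!per_subject$diagnosis & !per_subject$truth),
    fp = sum(per_subject$diagnosis & !per_subject$truth),
    fn = sum(!per_subject$diagnosis & per_subject$truth)),
    class = "confusion_counts")
  summary <- list(
    mean_accuracy = mean(per_subject$accuracy),
    mean_accuracy_multiclass = mean(per_subject$accuracy_multiclass),
    mean_sensitivity = mean(per_subject$sensitivity, na.rm = TRUE),
    mean_specificity = mean(per_subject$specificity, na.rm = TRUE),
    mean_dice_binary = mean(per_subject$dice_binary),
    mean_dice_macro = mean(per_subject$dice_macro),
    subject_confusion = subj_conf,
    subject_accuracy = accuracy(subj_conf))
  list(per_subject = per_subject, summary = summary, results = results)
}

#' Save a trained pipeline model to a single versioned archive
#' @param model a `cardioseg_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  tmp <- tempfile(fileext = ".rds")
  save_ensemble(model$ensemble, tmp)
  obj <- list(format = "cardioseg_model", version = 1L,
              ensemble_archive = readRDS(tmp),
              bank = model$bank, config = model$config,
              class_set = model$class_set)
  unlink(tmp)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a pipeline model saved with [save_model]
#' @param path archive path.
#' @return A `cardioseg_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cardioseg_model")) {
    stop(sprintf("%s is not a cardioseg model archive", path), call. = FALSE)
  }
  tmp <- tempfile(fileext = ".rds")
  saveRDS(obj$ensemble_archive, tmp)
  ens <- load_ensemble(tmp)
  unlink(tmp)
  structure(list(ensemble = ens, bank = obj$bank, config = obj$config,
                 class_set = obj$class_set),
            class = "cardioseg_model")
}
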