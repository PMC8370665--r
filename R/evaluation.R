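#' Training configuration
#'
#' Defaults follow the study protocol: 224 px inputs, RMSprop for the
#' proposed CNN (Adam is the default for transfer models), mini-batch 32,
#' 10-fold cross-validation, initial learning rate 3e-4, binary
#' cross-entropy, 50 epochs, 80/20 stratified split.
#'
#' @param image_side input side in pixels.
#' @param optimizer `"rmsprop"` or `"adam"`.
#' @param batch_size mini-batch size.
#' @param cv_folds folds for cross-validation (>= 2).
#' @param learning_rate initial learning rate.
#' @param loss loss tag (binary cross-entropy for the sigmoid head).
#' @param epochs training epochs.
#' @param split_fraction training fraction of the train/test split, in (0,1).
#' @param seed integer seed.
#' @return object of class `train_config`.
#' @export
train_config <- function(image_side = 224L, optimizer = c("rmsprop", "adam"),
                         batch_size = 32L, cv_folds = 10L,
                         learning_rate = 3e-4, loss = "bce", epochs = 50L,
                         split_fraction = 0.8, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(image_side = as.integer(image_side), optimizer = optimizer,
                 batch_size = as.integer(batch_size),
                 cv_folds = as.integer(cv_folds),
                 learning_rate = learning_rate, loss = loss,
                 epochs = as.integer(epochs), split_fraction = split_fraction,
                 seed = as.integer(seed)), class = "train_config")
}

#' Stratified train/test split
#'
#' @param labels vector of class labels (one per item).
#' @param fraction training fraction; per-class training sizes are
#'   `round(fraction * n_class)` (within 1 of the exact fraction).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_data <- function(labels, fraction = 0.8, seed = 1L) {
  tab <- table(labels)
  if (any(tab < 2)) stop("every class needs at least 2 items")
  with_seed(derive_seed(seed, "split"), {
    train <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      n_tr <- max(1L, min(length(idx) - 1L, round(fraction * length(idx))))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Stratified k-fold assignment
#'
#' Folds are pairwise disjoint, tile the data exactly once, differ in size
#' by at most one, and are stratified by label.
#'
#' @param labels vector of class labels.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`, one per item.
#' @export
kfold <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (n < k) stop("n < k: cannot build ", k, " folds from ", n, " items")
  with_seed(derive_seed(seed, "kfold"), {
    fold <- integer(n)
    cursor <- 0L  # global rotation keeps overall fold sizes within 1
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
      cursor <- (cursor + length(idx)) %% k
    }
    fold
  })
}

#' Class-balancing undersampling
#'
#' @param labels vector of class labels.
#' @param n_per_class items kept per class; every class must have at least
#'   this many.
#' @param seed integer seed.
#' @return sorted integer vector of kept indices.
#' @export
undersample <- function(labels, n_per_class, seed = 1L) {
  tab <- table(labels)
  if (any(tab < n_per_class))
    stop("insufficient class size: smallest class has ", min(tab), " items")
  with_seed(derive_seed(seed, "undersample"), {
    keep <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      keep <- c(keep, if (length(idx) == n_per_class) idx
                else sample(idx, n_per_class))
    }
    sort(keep)
  })
}

#' Binary confusion matrix
#'
#' @param truth,predicted equal-length label vectors (logical, 0/1, or
#'   factors/characters with `positive` naming the positive class).
#' @param positive positive-class label when inputs are not logical/0-1.
#' @return object of class `confusion_matrix` with fields TP, FN, FP, TN.
#' @export
confusion <- function(truth, predicted, positive = NULL) {
  if (length(truth) != length(predicted))
    stop("label sequences differ in length")
  to01 <- function(v) {
    if (is.logical(v)) return(as.integer(v))
    if (is.numeric(v)) return(as.integer(v != 0))
    if (is.null(positive)) stop("positive class must be named for label vectors")
    as.integer(v == positive)
  }
  t01 <- to01(truth); p01 <- to01(predicted)
  structure(list(TP = sum(t01 == 1 & p01 == 1), FN = sum(t01 == 1 & p01 == 0),
                 FP = sum(t01 == 0 & p01 == 1), TN = sum(t01 == 0 & p01 == 0)),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' accuracy = (TP + TN) / (TP + FN + TN + FP); sensitivity (recall) =
#' TP / (TP + FN); specificity = TN / (TN + FP); precision = TP / (TP + FP).
#' A metric with a zero denominator is returned as `NA` and listed in the
#' `undefined` attribute rather than silently coerced to 0.
#'
#' @param cm a [confusion()] result.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `precision`
#'   (proportions in `[0, 1]`) and attribute `undefined`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    accuracy = safe(cm$TP + cm$TN, cm$TP + cm$FN + cm$TN + cm$FP),
    sensitivity = safe(cm$TP, cm$TP + cm$FN),
    specificity = safe(cm$TN, cm$TN + cm$FP),
    precision = safe(cm$TP, cm$TP + cm$FP))
  attr(out, "undefined") <- names(out)[vapply(out, is.na, TRUE)]
  out
}

#' Stack a list of images into a batch array
#'
#' @param images list of `H x W (x C)` arrays with common dimensions, or an
#'   already-stacked `H x W x C x N` array (returned unchanged).
#' @return array `H x W x C x N`.
#' @export
as_batch_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 4) return(images)
  d <- dim(images[[1]])
  if (length(d) == 2) d <- c(d, 1L)
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

#' Train a CNN model
#'
#' Mini-batch gradient descent with the configured optimizer and binary (or
#' categorical) cross-entropy. Augmentation, when given, re-draws one
#' geometric transform per training image per epoch, so the stored dataset
#' is never enlarged. Seeded runs are reproducible.
#'
#' @param spec a trainable `cnn_spec` (see [build_proposed_cnn()]).
#' @param images list of `H x W x C` arrays or an `H x W x C x N` array,
#'   0-255 scale.
#' @param y numeric 0/1 labels (sigmoid head) or integer classes 1..K
#'   (softmax head).
#' @param cfg a [train_config()].
#' @param augment optional [augment_config()].
#' @return list with `model` (a `cnn_model`) and `history` (data.frame with
#'   one row per epoch: epoch, loss, accuracy).
#' @export
train_model <- function(spec, images, y, cfg = train_config(),
                        augment = NULL) {
  x0 <- as_batch_array(images)
  n <- dim(x0)[4]
  if (n == 0 || length(y) != n) stop("shape mismatch between data and labels")
  model <- init_cnn_model(spec, seed = cfg$seed)
  if (cfg$epochs == 0)
    return(list(model = model,
                history = data.frame(epoch = integer(), loss = numeric(),
                                     accuracy = numeric())))
  out_units <- spec$layers[[length(spec$layers)]]$units
  opt <- make_optimizer(cfg$optimizer, cfg$learning_rate)
  history <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    x <- x0
    if (!is.null(augment)) {
      ds <- draw_transforms(augment, n, ep)
      for (i in seq_len(n)) x[, , , i] <- apply_transform(x0[, , , i], ds[[i]])
    }
    ep_seed <- derive_seed(cfg$seed, "epoch", ep)
    res <- with_seed(ep_seed, {
      ord <- sample(n)
      tot_loss <- 0; tot_correct <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        bi <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        xb <- x[, , , bi, drop = FALSE] / 255
        fw <- cnn_forward(model, xb, training = TRUE)
        hl <- head_loss(fw$out, y[bi], out_units)
        grads <- cnn_backward(model, fw, hl$dz)
        model$params <- opt(model$params, grads)
        tot_loss <- tot_loss + hl$loss * length(bi)
        pred <- if (out_units == 1) as.integer(fw$out[1, ] > 0.5)
                else apply(fw$out, 2, which.max)
        tot_correct <- tot_correct + sum(pred == y[bi])
      }
      list(loss = tot_loss / n, acc = tot_correct / n, model = model)
    })
    model <- res$model
    history$loss[ep] <- res$loss
    history$accuracy[ep] <- res$acc
  }
  list(model = model, history = history)
}

#' Preprocess a fundus image into a lesion-emphasizing training input
#'
#' Builds a three-channel representation from the segmentation pipeline:
#' (1) the CLAHE-enhanced, illumination-corrected green channel, (2) the
#' green channel with the optic disc and vessels removed, and (3) the
#' exudate-candidate mask scaled to 0/255. Optic-disc detection failures
#' fall back to an empty disc mask so the pipeline never aborts mid-dataset.
#'
#' @param img RGB fundus array.
#' @param vessel_cfg a [vessel_config()].
#' @return `H x W x 3` array on the 0-255 scale.
#' @export
preprocess_for_training <- function(img, vessel_cfg = vessel_config()) {
  g <- extract_green(img)
  enh <- enhance_fundus(img, vessel_cfg$clahe,
                        illum_window = vessel_cfg$illum_window)
  vess <- segment_vessels(img, vessel_cfg)
  disc <- tryCatch(detect_optic_disc(img)$mask,
                   error = function(e) matrix(FALSE, nrow(g), ncol(g)))
  cleaned <- remove_region(remove_region(g, disc, "background-mean"),
                           vess, "neighborhood-mean")
  ex <- detect_exudates(img, disc, vess)
  out <- array(0, c(nrow(g), ncol(g), 3))
  out[, , 1] <- enh
  out[, , 2] <- cleaned
  out[, , 3] <- ex * 255
  out
}

#' Desk-scale screening experiment: raw versus preprocessed inputs
#'
#' Generates a balanced synthetic normal-vs-lesion dataset, holds out a
#' stratified 20% test split, and trains a reduced variant of the proposed
#' CNN twice under identical seeds and budgets: once on the raw RGB images
#' and once on the lesion-emphasizing [preprocess_for_training()]
#' representation. Both inputs are resized to `image_side`.
#'
#' @param n_per_class images per class.
#' @param classes two class tags; the second is the positive class.
#' @param gen_side synthetic image side in pixels.
#' @param image_side network input side (reduced proposed-CNN variant).
#' @param filters_scale filter-bank multiplier of the reduced variant.
#' @param epochs training epochs.
#' @param seed integer seed driving generation, split and both trainings.
#' @param run_raw,run_preprocessed toggles for the two arms.
#' @return list with `raw` and `preprocessed` sub-lists (each with
#'   `accuracy`, `metrics`, `confusion`, `history`) and `n_test`.
#' @export
screening_experiment <- function(n_per_class = 100L,
                                 classes = c("normal", "mild_dme"),
                                 gen_side = 128L, image_side = 64L,
                                 filters_scale = 1 / 16, epochs = 10L,
                                 seed = 1L, run_raw = TRUE,
                                 run_preprocessed = TRUE) {
  sc <- synth_config(image_side = gen_side, seed = derive_seed(seed, "e2e"))
  ds <- generate_dataset(sc, n_per_class, classes)
  labels <- attr(ds, "labels")
  y <- as.integer(labels == classes[2])
  sp <- split_data(labels, 0.8, seed)
  spec <- build_proposed_cnn(image_side, 2L, filters_scale = filters_scale)
  tc <- train_config(image_side = image_side, optimizer = "rmsprop",
                     epochs = epochs, seed = seed)
  arm <- function(imgs) {
    imgs <- lapply(imgs, function(im) resize_bilinear(im, image_side, image_side))
    fit <- train_model(spec, imgs[sp$train], y[sp$train], tc)
    p <- predict_cnn(fit$model, as_batch_array(imgs[sp$test]))
    cm <- confusion(y[sp$test], as.integer(p > 0.5))
    m <- classification_metrics(cm)
    list(accuracy = m$accuracy, metrics = m, confusion = cm,
         history = fit$history)
  }
  out <- list(n_test = length(sp$test))
  if (run_raw) out$raw <- arm(lapply(ds, `[[`, "image"))
  if (run_preprocessed)
    out$preprocessed <- arm(lapply(ds, function(d)
      preprocess_for_training(d$image)))
  out
}

#' ROC curve by threshold sweep
#'
#' @param scores numeric scores (higher = more positive).
#' @param truth 0/1 labels.
#' @return data.frame with columns `threshold`, `tpr`, `fpr`, sorted by
#'   descending threshold, plus an `auc` attribute (trapezoidal).
#' @export
roc_curve <- function(scores, truth) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  P <- sum(truth == 1); N <- sum(truth == 0)
  tpr <- vapply(th, function(t) if (P) sum(scores >= t & truth == 1) / P else NA_real_, 0)
  fpr <- vapply(th, function(t) if (N) sum(scores >= t & truth == 0) / N else NA_real_, 0)
  out <- data.frame(threshold = th, tpr = tpr, fpr = fpr)
  attr(out, "auc") <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out
}
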