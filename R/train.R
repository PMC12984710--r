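# Supervised training protocol: weighted categorical cross-entropy, Adam,
# reduce-learning-rate-on-plateau, early stopping, best-epoch checkpointing.

#' Training configuration
#'
#' The supervised training protocol applied to any registered backbone:
#' minibatch Adam on weighted categorical cross-entropy, with the learning
#' rate reduced by `lr_reduce_factor` after `lr_reduce_patience` epochs
#' without validation-loss improvement, training stopped after
#' `early_stop_patience` such epochs, and the best-validation-loss epoch's
#' parameters restored at the end (checkpointing). An improvement means a
#' validation-loss decrease of at least `min_delta`.
#'
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_reduce_factor Multiplicative learning-rate reduction factor.
#' @param lr_reduce_patience Epochs without improvement before reduction;
#'   must be smaller than `early_stop_patience` so a reduction can fire
#'   before training stops.
#' @param early_stop_patience Epochs without improvement before stopping.
#' @param min_delta Minimum validation-loss decrease that counts as
#'   improvement for the patience counters.
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation draws; fitting is a pure function of (data, config).
#' @param backbone Name of a registered backbone (see [register_backbone()]).
#' @param backbone_args List of arguments for the backbone constructor.
#' @param augment `NULL` (no augmentation) or an [augment_config()]; when
#'   enabled, each training image contributes `augment_copies` stochastically
#'   augmented copies in addition to the original. Augmentation is applied to
#'   training inputs only, never to validation data.
#' @param augment_copies Augmented copies per training image.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L,
                         max_epochs = 100L,
                         learning_rate = 0.001,
                         lr_reduce_factor = 0.1,
                         lr_reduce_patience = 10L,
                         early_stop_patience = 15L,
                         min_delta = 1e-4,
                         seed = 1L,
                         backbone = "small_mlp",
                         backbone_args = list(),
                         augment = NULL,
                         augment_copies = 1L) {
  stopifnot_scalar_number(batch_size, "batch_size", lower = 1)
  stopifnot_scalar_number(max_epochs, "max_epochs", lower = 1)
  stopifnot_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  stopifnot_scalar_number(lr_reduce_factor, "lr_reduce_factor", 1e-12, 1)
  stopifnot_scalar_number(lr_reduce_patience, "lr_reduce_patience", lower = 1)
  stopifnot_scalar_number(early_stop_patience, "early_stop_patience", lower = 1)
  if (lr_reduce_patience >= early_stop_patience) {
    stop("lr_reduce_patience must be < early_stop_patience so a reduction can fire",
         call. = FALSE)
  }
  if (!is.null(augment) && !inherits(augment, "augment_config")) {
    stop("augment must be NULL or an augment_config", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta,
                 seed = as.integer(seed),
                 backbone = backbone,
                 backbone_args = backbone_args,
                 augment = augment,
                 augment_copies = as.integer(augment_copies)),
            class = "train_config")
}

#' @export
fit.small_mlp <- function(object, images, labels, sample_weights = NULL,
                          config = train_config(), val_images, val_labels, ...) {
  labels <- as_oct_factor(labels)
  val_labels <- as_oct_factor(val_labels)
  if (length(images) == 0L) stop("empty training set", call. = FALSE)
  if (length(val_images) == 0L) stop("empty validation set", call. = FALSE)
  if (is.null(sample_weights)) sample_weights <- rep(1, length(images))
  stopifnot(length(sample_weights) == length(images), length(labels) == length(images))

  with_seed(config$seed, {
    augmented_ids <- character(0)
    if (!is.null(config$augment) && config$augment$enabled && config$augment_copies > 0) {
      ids <- names(images)
      aug_images <- list(); aug_labels <- character(0); aug_w <- numeric(0)
      for (k in seq_len(config$augment_copies)) {
        for (i in seq_along(images)) {
          nm <- sprintf("%s#aug%d", ids[i], k)
          aug_images[[nm]] <- augment_image(images[[i]], config$augment)
          aug_labels <- c(aug_labels, as.character(labels[i]))
          aug_w <- c(aug_w, sample_weights[i])
        }
      }
      augmented_ids <- ids
      images <- c(images, aug_images)
      labels <- as_oct_factor(c(as.character(labels), aug_labels))
      sample_weights <- c(sample_weights, aug_w)
    }

    X <- featurize_images(images, object$input_size)
    y <- as.integer(labels)
    Xval <- featurize_images(val_images, object$input_size)
    yval <- as.integer(val_labels)
    n <- nrow(X)

    params <- mlp_init(object)
    opt <- adam_init(params)
    lr <- config$learning_rate
    best_ckpt <- Inf; best_params <- params; best_epoch <- 0L
    best_seen <- Inf; wait_lr <- 0L; wait_es <- 0L
    stopped_early <- FALSE
    hist <- vector("list", config$max_epochs)

    for (epoch in seq_len(config$max_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      tl <- 0
      for (s0 in starts) {
        bi <- idx[s0:min(s0 + config$batch_size - 1L, n)]
        gr <- mlp_grad(object, params, X[bi, , drop = FALSE], y[bi], sample_weights[bi])
        st <- adam_step(params, gr$grad, opt, lr)
        params <- st$params; opt <- st$state
        tl <- tl + gr$loss * length(bi)
      }
      train_loss <- tl / n

      Pv <- mlp_forward(params, Xval)$proba
      val_loss <- -mean(log(pmax(Pv[cbind(seq_along(yval), yval)], 1e-12)))
      val_acc <- mean(max.col(Pv, ties.method = "first") == yval)
      hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                      val_loss = val_loss, val_acc = val_acc, lr = lr)

      if (val_loss < best_ckpt) {
        best_ckpt <- val_loss; best_params <- params; best_epoch <- epoch
      }
      if (val_loss < best_seen - config$min_delta) {
        best_seen <- val_loss; wait_lr <- 0L; wait_es <- 0L
      } else {
        wait_lr <- wait_lr + 1L; wait_es <- wait_es + 1L
        if (wait_es >= config$early_stop_patience) { stopped_early <- TRUE; break }
        if (wait_lr >= config$lr_reduce_patience) {
          lr <- lr * config$lr_reduce_factor; wait_lr <- 0L
        }
      }
    }

    object$params <- best_params
    object$history <- structure(list(
      epochs = dplyr::bind_rows(hist),
      best_epoch = best_epoch,
      stopped_early = stopped_early,
      augmented_ids = augmented_ids
    ), class = "train_history")
    object
  })
}

#' @export
print.train_history <- function(x, ...) {
  cat("<train_history> ", nrow(x$epochs), " epochs, best epoch ", x$best_epoch,
      if (x$stopped_early) " (early stop)" else "", "\n", sep = "")
  invisible(x)
}

#' Train a classifier on labeled records
#'
#' Runs the full supervised protocol of [train_config()] for the configured
#' backbone: class-weighted categorical cross-entropy, learning-rate reduction
#' on plateau, early stopping, and restoration of the best-validation-loss
#' checkpoint. The labeled set must contain at least two distinct classes.
#'
#' @param images Named list of training images (names are image ids).
#' @param labels Training labels, one of `normal`, `drusen`, `cnv`.
#' @param val_images,val_labels Validation set (never augmented).
#' @param weights `NULL` (computed from `labels` via [class_weights()]) or a
#'   class-weights vector.
#' @param config A [train_config()].
#' @param sample_weight_multiplier Optional per-image multiplier on top of the
#'   class weights (e.g. to down-weight pseudo-labeled images).
#' @return A list with `model` (the trained classifier) and `history`
#'   (a `train_history`).
#' @export
train_supervised <- function(images, labels, val_images, val_labels,
                             weights = NULL, config = train_config(),
                             sample_weight_multiplier = NULL) {
  labels <- as_oct_factor(labels)
  present <- levels(labels)[tabulate(labels, 3L) > 0]
  if (length(present) < 2L) {
    stop("labeled set must contain at least 2 classes; missing: ",
         paste(setdiff(OCT_CLASSES, present), collapse = ", "), call. = FALSE)
  }
  if (is.null(weights)) weights <- class_weights(labels)
  sw <- as.numeric(weights[as.character(labels)])
  if (!is.null(sample_weight_multiplier)) {
    stopifnot(length(sample_weight_multiplier) == length(images))
    sw <- sw * sample_weight_multiplier
  }
  model <- do.call(new_backbone, c(list(config$backbone), config$backbone_args))
  model <- fit(model, images, labels, sample_weights = sw, config = config,
               val_images = val_images, val_labels = val_labels)
  list(model = model, history = model$history)
}

#' Hard class predictions
#'
#' Argmax of [predict_proba()], with probability ties broken in canonical
#' class order (`normal` before `drusen` before `cnv`).
#'
#' @param model A trained classifier.
#' @param images Named list of images.
#' @return Factor of predicted classes.
#' @export
predict_class <- function(model, images) {
  P <- predict_proba(model, images)
  factor(OCT_CLASSES[max.col(P, ties.method = "first")], levels = OCT_CLASSES)
}
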