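# Pluggable probabilistic 3-class classifier contract and the reference
# backbone: a small single-hidden-layer softmax network over downsampled,
# per-image standardized pixels, trained by minibatch Adam.
#
# The contract any backbone must satisfy:
#   fit(object, images, labels, sample_weights, config, val_images, val_labels)
#     -> trained classifier with a $history train record attached
#   predict_proba(object, images) -> n x 3 matrix, rows summing to 1
#   clone_untrained(object) -> same architecture, no learned state

.backbone_registry <- new.env(parent = emptyenv())

#' Register or construct a classifier backbone
#'
#' Backbones are registered under a name and built on demand from a training
#' configuration, so experiments select the architecture by name. The package
#' registers `"small_mlp"` (the reference backbone: one hidden layer of ReLU
#' units over downsampled pixels) and `"softmax_linear"` (no hidden layer,
#' i.e. multinomial logistic regression on pixels).
#'
#' @param name Backbone name.
#' @param constructor A function `function(...)` returning an untrained
#'   classifier object.
#' @param ... Arguments passed to the registered constructor.
#' @return `new_backbone()` returns an untrained classifier;
#'   `registered_backbones()` the registered names.
#' @export
register_backbone <- function(name, constructor) {
  stopifnot(is.character(name), length(name) == 1L, is.function(constructor))
  assign(name, constructor, envir = .backbone_registry)
  invisible(name)
}

#' @rdname register_backbone
#' @export
new_backbone <- function(name, ...) {
  if (!exists(name, envir = .backbone_registry, inherits = FALSE)) {
    stop("unknown backbone '", name, "'; registered: ",
         paste(registered_backbones(), collapse = ", "), call. = FALSE)
  }
  get(name, envir = .backbone_registry)(...)
}

#' @rdname register_backbone
#' @export
registered_backbones <- function() ls(.backbone_registry)

#' Classifier generics
#'
#' `fit()` trains a classifier under a [train_config()] protocol;
#' `predict_proba()` returns class probabilities with columns in canonical
#' order (`normal`, `drusen`, `cnv`); `clone_untrained()` returns a fresh
#' classifier with the same architecture and no learned state;
#' `is_trained()` reports whether learned state is present.
#'
#' @param object A classifier.
#' @param ... Method arguments.
#' @export
fit <- function(object, ...) UseMethod("fit")

#' @rdname fit
#' @export
predict_proba <- function(object, ...) UseMethod("predict_proba")

#' @rdname fit
#' @export
clone_untrained <- function(object) UseMethod("clone_untrained")

#' @rdname fit
#' @export
is_trained <- function(object) UseMethod("is_trained")

#' Reference backbone: small multilayer perceptron
#'
#' The reference classifier: input images are bilinearly downsampled to
#' `input_size x input_size`, standardized per image and flattened; a single
#' hidden layer of `hidden` ReLU units (none when `hidden = 0`, giving
#' multinomial logistic regression) feeds a 3-way softmax. Small enough
#' (~37k parameters at the defaults) to train in seconds on one CPU, yet
#' expressive enough to learn the phantom classes from modest labeled sets.
#'
#' @param input_size Side length of the downsampled input, in pixels.
#' @param hidden Number of hidden units; 0 for a linear softmax model.
#' @param l2 L2 penalty on the weight matrices (not biases).
#' @return An untrained classifier of class `small_mlp`.
#' @export
small_mlp <- function(input_size = 24L, hidden = 64L, l2 = 1e-4) {
  stopifnot_scalar_number(input_size, "input_size", lower = 4)
  stopifnot_scalar_number(hidden, "hidden", lower = 0)
  stopifnot_scalar_number(l2, "l2", lower = 0)
  structure(list(input_size = as.integer(input_size), hidden = as.integer(hidden),
                 l2 = l2, params = NULL, history = NULL),
            class = c("small_mlp", "oct_classifier"))
}

#' @export
is_trained.small_mlp <- function(object) !is.null(object$params)

#' @export
clone_untrained.small_mlp <- function(object) {
  small_mlp(object$input_size, object$hidden, object$l2)
}

#' @export
print.small_mlp <- function(x, ...) {
  d <- x$input_size^2
  npar <- if (x$hidden > 0) d * x$hidden + x$hidden + x$hidden * 3 + 3 else d * 3 + 3
  cat("<small_mlp> input ", x$input_size, "x", x$input_size,
      ", hidden ", x$hidden, ", ", npar, " parameters, ",
      if (is_trained(x)) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

# Downsample + standardize + flatten a list of images into an n x d matrix.
featurize_images <- function(images, input_size) {
  s <- as.integer(input_size)
  t(vapply(images, function(im) {
    if (nrow(im) != s || ncol(im) != s) im <- resize_image(im, c(s, s))
    v <- as.vector(im)
    sd_v <- stats::sd(v)
    if (!is.finite(sd_v) || sd_v < 1e-12) rep(0, s * s) else (v - mean(v)) / sd_v
  }, numeric(s * s)))
}

mlp_init <- function(object) {
  d <- object$input_size^2
  h <- object$hidden
  if (h > 0) {
    list(W1 = matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h),
         b1 = rep(0, h),
         W2 = matrix(stats::rnorm(h * 3, 0, sqrt(2 / h)), h, 3),
         b2 = rep(0, 3))
  } else {
    list(W2 = matrix(stats::rnorm(d * 3, 0, sqrt(1 / d)), d, 3), b2 = rep(0, 3))
  }
}

mlp_forward <- function(params, X) {
  if (!is.null(params$W1)) {
    Hid <- pmax(sweep(X %*% params$W1, 2, params$b1, "+"), 0)
  } else Hid <- X
  logits <- sweep(Hid %*% params$W2, 2, params$b2, "+")
  logits <- logits - apply(logits, 1, max)
  E <- exp(logits)
  list(hidden = Hid, proba = E / rowSums(E))
}

# Weighted categorical cross-entropy (+ L2) and parameter gradients for one
# minibatch. y: integer class index 1..3; w: per-sample weights.
mlp_grad <- function(object, params, X, y, w) {
  n <- nrow(X)
  fw <- mlp_forward(params, X)
  P <- fw$proba
  Y <- matrix(0, n, 3); Y[cbind(seq_len(n), y)] <- 1
  wsum <- sum(w)
  loss <- -sum(w * log(pmax(P[cbind(seq_len(n), y)], 1e-12))) / wsum
  dlogits <- (P - Y) * (w / wsum)
  g <- list()
  if (!is.null(params$W1)) {
    g$W2 <- crossprod(fw$hidden, dlogits) + 2 * object$l2 * params$W2
    g$b2 <- colSums(dlogits)
    dH <- dlogits %*% t(params$W2)
    dH[fw$hidden <= 0] <- 0
    g$W1 <- crossprod(X, dH) + 2 * object$l2 * params$W1
    g$b1 <- colSums(dH)
    loss <- loss + object$l2 * (sum(params$W1^2) + sum(params$W2^2))
  } else {
    g$W2 <- crossprod(X, dlogits) + 2 * object$l2 * params$W2
    g$b2 <- colSums(dlogits)
    loss <- loss + object$l2 * sum(params$W2^2)
  }
  list(loss = loss, grad = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grad[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grad[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' @export
predict_proba.small_mlp <- function(object, images, ...) {
  if (!is_trained(object)) stop("classifier is untrained; call fit() first", call. = FALSE)
  X <- featurize_images(images, object$input_size)
  P <- mlp_forward(object$params, X)$proba
  colnames(P) <- OCT_CLASSES
  rownames(P) <- names(images)
  P
}
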