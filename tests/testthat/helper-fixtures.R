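# Shared fixtures: small phantom cohorts, fast training configurations, a
# deterministic mock classifier, and a linearly separable toy image task.

tiny_cohort <- function(n_patients = 12, seed = 1, bscans = c(2L, 4L), ...) {
  generate_cohort(phantom_spec(n_patients = n_patients, bscans_per_volume = bscans,
                               seed = seed, ...))
}

fast_train_config <- function(seed = 1, max_epochs = 12L, ...) {
  train_config(max_epochs = max_epochs, early_stop_patience = 5L,
               lr_reduce_patience = 2L, seed = seed, ...)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

# A classifier returning a fixed probability matrix, for exercising the
# pseudo-labeling contract without any training.
mock_classifier <- function(proba) {
  colnames(proba) <- oct_classes()
  structure(list(proba = proba), class = c("mock_clf", "oct_classifier"))
}
predict_proba_mock <- function(object, images, ...) {
  object$proba[seq_along(images), , drop = FALSE]
}
is_trained_mock <- function(object) TRUE
registerS3method("predict_proba", "mock_clf", predict_proba_mock,
                 envir = asNamespace("octits"))
registerS3method("is_trained", "mock_clf", is_trained_mock,
                 envir = asNamespace("octits"))

# Linearly separable toy task as tiny images: each class lights up a
# different horizontal third of the image.
toy_images <- function(n_per_class, seed = 1, size = 32L) {
  set.seed(seed)
  classes <- oct_classes()
  images <- list(); labels <- character(0)
  third <- size %/% 3
  for (k in 1:3) {
    for (i in seq_len(n_per_class)) {
      img <- matrix(stats::rnorm(size * size, 0.1, 0.05), size, size)
      rows <- ((k - 1) * third + 1):(k * third)
      img[rows, ] <- img[rows, ] + 0.8
      nm <- sprintf("toy%d_%s_%03d", seed, classes[k], i)
      images[[nm]] <- pmin(pmax(img, 0), 1)
      labels <- c(labels, classes[k])
    }
  }
  list(images = images, labels = factor(labels, levels = classes))
}
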