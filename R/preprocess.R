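# Deterministic preprocessing (resize, per-image standardization) and
# stochastic training-time augmentation (crop, flip, rotation, affine).

#' Bilinear image resize
#'
#' Resizes a grayscale matrix to `target` by separable bilinear interpolation
#' (half-pixel-center sampling). Resizing to the input size is an exact
#' identity, and output values are convex combinations of input values, so the
#' output range never exceeds the input range.
#'
#' @param image Non-empty numeric matrix.
#' @param target Integer pair `c(height, width)`, both at least 1.
#' @return A `target[1] x target[2]` matrix.
#' @export
resize_image <- function(image, target) {
  if (!is.matrix(image) || length(image) == 0L) stop("image must be a non-empty matrix", call. = FALSE)
  if (length(target) != 2L || any(target < 1)) {
    stop("target dimensions must be at least 1", call. = FALSE)
  }
  h <- as.integer(target[1]); w <- as.integer(target[2])
  interp_matrix(h, nrow(image)) %*% image %*% t(interp_matrix(w, ncol(image)))
}

# s x n matrix L with L %*% v the bilinear resample of v from n to s points.
interp_matrix <- function(s, n) {
  pos <- (seq_len(s) - 0.5) * n / s + 0.5
  lo <- pmin(pmax(floor(pos), 1), max(n - 1L, 1L))
  wgt <- pmin(pmax(pos - lo, 0), 1)
  if (n == 1L) wgt <- rep(0, s)
  L <- matrix(0, s, n)
  L[cbind(seq_len(s), lo)] <- 1 - wgt
  L[cbind(seq_len(s), pmin(lo + 1L, n))] <- L[cbind(seq_len(s), pmin(lo + 1L, n))] + wgt
  L
}

#' Per-image standardization
#'
#' Subtracts the image mean and divides by the image standard deviation
#' (population convention, denominator `n`), so every non-constant image has
#' mean 0 and unit standard deviation; an image holding two equally frequent
#' values maps exactly to -1 and +1. A constant image (zero variance) is
#' returned as all zeros, with a warning.
#'
#' @param image Numeric matrix.
#' @return A matrix of the same shape, standardized.
#' @export
normalize_image <- function(image) {
  v <- as.vector(image)
  s <- sqrt(mean((v - mean(v))^2))
  if (!is.finite(s) || s < 1e-12) {
    warning("constant image: standardized to all zeros", call. = FALSE)
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - mean(v)) / s
}

#' Augmentation configuration
#'
#' Settings for stochastic training-time augmentation, applied in the fixed
#' order crop, horizontal flip, rotation, affine (translation + shear). All
#' magnitudes default to small values that perturb field of view and pose
#' without destroying the band/lesion structure that defines the classes.
#'
#' @param crop_scale_range Fraction interval within `(0, 1]`; a random crop of
#'   this linear scale is taken and resized back.
#' @param hflip_probability Probability of mirroring columns.
#' @param rotation_range_deg Rotation is drawn uniformly from
#'   `[-rotation_range_deg, rotation_range_deg]` degrees.
#' @param translate_fraction Translation drawn from this fraction of each
#'   image dimension, per axis.
#' @param shear_deg Horizontal shear angle drawn from `[-shear_deg, shear_deg]`.
#' @param enabled If `FALSE`, [augment_image()] is the identity.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(crop_scale_range = c(0.85, 1.0),
                           hflip_probability = 0.5,
                           rotation_range_deg = 15,
                           translate_fraction = 0.1,
                           shear_deg = 10,
                           enabled = TRUE) {
  if (length(crop_scale_range) != 2L || crop_scale_range[1] > crop_scale_range[2] ||
      crop_scale_range[1] <= 0 || crop_scale_range[2] > 1) {
    stop("crop_scale_range must be an ordered interval within (0, 1]", call. = FALSE)
  }
  stopifnot_scalar_number(hflip_probability, "hflip_probability", 0, 1)
  stopifnot_scalar_number(rotation_range_deg, "rotation_range_deg", 0)
  stopifnot_scalar_number(translate_fraction, "translate_fraction", 0, 1)
  stopifnot_scalar_number(shear_deg, "shear_deg", 0, 89)
  structure(list(crop_scale_range = as.numeric(crop_scale_range),
                 hflip_probability = hflip_probability,
                 rotation_range_deg = rotation_range_deg,
                 translate_fraction = translate_fraction,
                 shear_deg = shear_deg,
                 enabled = isTRUE(enabled)),
            class = "augment_config")
}

pad_reflect <- function(image, p) {
  H <- nrow(image); W <- ncol(image)
  p <- min(p, H - 1L, W - 1L)
  ri <- c(rev(seq_len(p)) + 1L, seq_len(H), H - seq_len(p))
  ci <- c(rev(seq_len(p)) + 1L, seq_len(W), W - seq_len(p))
  list(img = image[ri, ci, drop = FALSE], p = p)
}

#' Stochastic augmentation of one image
#'
#' Applies, in order, a random crop (resized back to the input shape), a
#' horizontal flip, a rotation and an affine translation + shear, with
#' magnitudes drawn from the current R random stream according to `config`.
#' Rotation and affine resampling use bilinear interpolation on a
#' reflection-padded canvas, so no dark corner artifacts are introduced. With
#' `enabled = FALSE`, or with all ranges degenerate at the identity, the input
#' is returned unchanged.
#'
#' @param image Numeric matrix.
#' @param config An [augment_config()].
#' @return A matrix of the same shape as `image`.
#' @export
augment_image <- function(image, config) {
  if (!inherits(config, "augment_config")) stop("config must be an augment_config", call. = FALSE)
  if (!config$enabled) return(image)
  H <- nrow(image); W <- ncol(image)

  sc <- stats::runif(1, config$crop_scale_range[1], config$crop_scale_range[2])
  ch <- max(2L, round(sc * H)); cw <- max(2L, round(sc * W))
  if (ch < H || cw < W) {
    top <- sample.int(H - ch + 1L, 1L) - 1L
    left <- sample.int(W - cw + 1L, 1L) - 1L
    image <- resize_image(image[(top + 1L):(top + ch), (left + 1L):(left + cw), drop = FALSE],
                          c(H, W))
  }

  if (stats::runif(1) < config$hflip_probability) image <- image[, W:1, drop = FALSE]

  angle <- stats::runif(1, -config$rotation_range_deg, config$rotation_range_deg)
  tx <- stats::runif(1, -config$translate_fraction, config$translate_fraction) * W
  ty <- stats::runif(1, -config$translate_fraction, config$translate_fraction) * H
  shear <- stats::runif(1, -config$shear_deg, config$shear_deg)

  if (abs(angle) > 1e-12 || abs(tx) > 1e-12 || abs(ty) > 1e-12 || abs(shear) > 1e-12) {
    pad <- pad_reflect(image, ceiling(0.25 * max(H, W)))
    pd <- dim(pad$img)
    th <- angle * pi / 180
    sh <- tan(shear * pi / 180)
    A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) %*%
      matrix(c(1, sh, 0, 1), 2, 2)
    ctr <- (pd + 1) / 2
    off <- ctr + c(ty, tx) - ctr %*% A
    m <- rbind(A, off)
    out <- EBImage::affine(pad$img, m, filter = "bilinear", bg.col = 0)
    out <- EBImage::imageData(out)[seq_len(pd[1]), seq_len(pd[2])]
    image <- out[(pad$p + 1L):(pad$p + H), (pad$p + 1L):(pad$p + W), drop = FALSE]
  }
  image
}
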