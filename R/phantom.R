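# Synthetic OCT phantom cohorts.
#
# A phantom B-scan is a stack of smooth bright horizontal bands (stylized
# retinal layers) on a dark background. Pathology is injected into the lowest
# band (the RPE analogue): drusen as small upward domes deforming the band,
# CNV as one large bright blob beneath a locally disrupted band. Per-image
# nuisance variation (band positions, widths, brightness) is constant across
# columns, so a noise-free normal scan has identical column profiles.

#' Specification of a synthetic OCT phantom cohort
#'
#' Defines the cohort geometry (patients, volumes, B-scans per volume), the
#' class mix at the volume level, the image size and the additive noise level.
#' Defaults emulate the structure of a clinical OCT archive: three imbalanced
#' classes with per-volume labels inherited by all B-scans of the volume,
#' roughly 30 B-scans per volume, and a fraction of patients contributing a
#' second (independently labelled) volume, as when both eyes are scanned.
#'
#' @param n_patients Number of patients (positive integer).
#' @param volumes_per_patient Integer range `c(low, high)` of volumes per
#'   patient. With the default `c(1, 2)`, a patient receives a second volume
#'   with probability `two_volume_fraction`.
#' @param two_volume_fraction Fraction of patients with two volumes (both eyes
#'   scanned); used when `volumes_per_patient` is `c(1, 2)`, otherwise volume
#'   counts are drawn uniformly from the range.
#' @param bscans_per_volume Integer range of B-scans per volume, centred near
#'   30 by default.
#' @param class_proportions Named or ordered triple of volume-level class
#'   probabilities over (normal, drusen, cnv); must sum to 1. The default
#'   (0.51, 0.30, 0.19) matches the volume-level class mix of a typical
#'   clinical AMD archive, with normal scans the majority class.
#' @param image_height,image_width Image size in pixels (at least 32).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (intensities live in `[0, 1]`).
#' @param seed Integer seed; the cohort is a pure function of the spec.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 150,
                         volumes_per_patient = c(1L, 2L),
                         two_volume_fraction = 0.25,
                         bscans_per_volume = c(28L, 32L),
                         class_proportions = c(normal = 0.51, drusen = 0.30, cnv = 0.19),
                         image_height = 32L,
                         image_width = 32L,
                         noise_sd = 0.05,
                         seed = 1L) {
  stopifnot_scalar_number(n_patients, "n_patients", lower = 1)
  if (length(volumes_per_patient) != 2L || volumes_per_patient[1] > volumes_per_patient[2] ||
      volumes_per_patient[1] < 1) {
    stop("volumes_per_patient must be an ordered range c(low, high) with low >= 1",
         call. = FALSE)
  }
  if (length(bscans_per_volume) != 2L || bscans_per_volume[1] > bscans_per_volume[2] ||
      bscans_per_volume[1] < 1) {
    stop("bscans_per_volume must be an ordered range c(low, high) with low >= 1",
         call. = FALSE)
  }
  stopifnot_scalar_number(two_volume_fraction, "two_volume_fraction", 0, 1)
  if (length(class_proportions) != 3L || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must be 3 non-negative fractions summing to 1",
         call. = FALSE)
  }
  stopifnot_scalar_number(image_height, "image_height", lower = 32)
  stopifnot_scalar_number(image_width, "image_width", lower = 32)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(list(
    n_patients = as.integer(n_patients),
    volumes_per_patient = as.integer(volumes_per_patient),
    two_volume_fraction = two_volume_fraction,
    bscans_per_volume = as.integer(bscans_per_volume),
    class_proportions = stats::setNames(as.numeric(class_proportions), OCT_CLASSES),
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Non-diagnostic bright spots above the band stack (vitreous-opacity-like
# distractors, present in every class): they force the classifier to localize
# lesions relative to the bands instead of reacting to overall brightness,
# and are redrawn fresh for every B-scan.
sample_spots <- function() {
  n_spot <- stats::rpois(1, 1.2)
  if (n_spot == 0) return(NULL)
  list(cx = stats::runif(n_spot, 0.05, 0.95),
       cy = stats::runif(n_spot, 0.03, 0.20),
       sx = stats::runif(n_spot, 0.04, 0.10),
       sy = stats::runif(n_spot, 0.03, 0.06),
       amp = stats::runif(n_spot, 0.20, 0.45))
}

# Latent scan parameters, all in units relative to image height/width, so a
# volume's geometry renders consistently at any pixel size. B-scans of one
# volume share a latent draw with small per-scan jitter, mirroring the strong
# within-volume correlation of adjacent slices of a real OCT volume.
sample_scan_latent <- function(label) {
  lat <- list(
    label = label,
    shift = stats::runif(1, -0.09, 0.09),
    amps = c(0.50, 0.35, 0.75) * (1 + stats::runif(3, -0.2, 0.2)),
    sds = c(0.030, 0.040, 0.026) * (1 + stats::runif(3, -0.25, 0.25)),
    spots = NULL, bumps = NULL, blob = NULL
  )
  lat$spots <- sample_spots()
  if (label == "drusen") {
    k <- sample(1:5, 1)
    lat$bumps <- list(cx = stats::runif(k, 0.10, 0.90),
                      sx = stats::runif(k, 0.035, 0.08),
                      h = stats::runif(k, 0.04, 0.10))
  } else if (label == "cnv") {
    lat$blob <- list(cx = stats::runif(1, 0.25, 0.75),
                     sx = stats::runif(1, 0.10, 0.16),
                     sy = stats::runif(1, 0.06, 0.10),
                     dy = stats::runif(1, 0.10, 0.18),
                     amp = stats::runif(1, 0.25, 0.42))
  }
  lat
}

# Per-scan perturbation of a volume's latent geometry: band pose and lesion
# shape wobble between adjacent slices, and the nuisance spots are redrawn
# entirely (they are not part of the eye's anatomy).
jitter_latent <- function(lat, sd = 0.25) {
  lat$shift <- lat$shift + stats::rnorm(1, 0, 0.02)
  lat$amps <- lat$amps * (1 + stats::rnorm(3, 0, sd / 3))
  lat$spots <- sample_spots()
  if (!is.null(lat$bumps)) {
    lat$bumps$cx <- lat$bumps$cx + stats::rnorm(length(lat$bumps$cx), 0, 0.02)
    lat$bumps$h <- pmax(lat$bumps$h * (1 + stats::rnorm(length(lat$bumps$h), 0, sd)), 0.02)
  }
  if (!is.null(lat$blob)) {
    lat$blob$cx <- lat$blob$cx + stats::rnorm(1, 0, 0.025)
    lat$blob$amp <- max(lat$blob$amp * (1 + stats::rnorm(1, 0, sd)), 0.15)
  }
  lat
}

render_from_latent <- function(lat, H, W, noise_sd) {
  rows <- seq_len(H); cols <- seq_len(W)
  centers <- (c(0.28, 0.45, 0.64) + lat$shift) * H
  sds <- lat$sds * H
  c3 <- rep(centers[3], W)
  a3 <- rep(lat$amps[3], W)
  blob <- NULL
  if (!is.null(lat$bumps)) {
    disp <- numeric(W)
    for (j in seq_along(lat$bumps$cx)) {
      disp <- disp + lat$bumps$h[j] * H *
        exp(-((cols - lat$bumps$cx[j] * W)^2) / (2 * (lat$bumps$sx[j] * W)^2))
    }
    c3 <- c3 - pmin(disp, 0.17 * H)
  }
  if (!is.null(lat$blob)) {
    prof <- exp(-((cols - lat$blob$cx * W)^2) / (2 * (lat$blob$sx * W)^2))
    cy <- centers[3] + lat$blob$dy * H
    blob <- lat$blob$amp * outer(exp(-((rows - cy)^2) / (2 * (lat$blob$sy * H)^2)), prof)
    a3 <- a3 * (1 - 0.6 * prof)     # local disruption of the band
    c3 <- c3 + 0.04 * H * prof      # slight sag over the lesion
  }
  img <- outer(0.05 + 0.03 * rows / H, rep(1, W))
  if (!is.null(lat$spots)) {
    for (j in seq_along(lat$spots$cx)) {
      img <- img + lat$spots$amp[j] *
        outer(exp(-((rows - lat$spots$cy[j] * H)^2) / (2 * (lat$spots$sy[j] * H)^2)),
              exp(-((cols - lat$spots$cx[j] * W)^2) / (2 * (lat$spots$sx[j] * W)^2)))
    }
  }
  for (b in 1:2) {
    img <- img + lat$amps[b] * outer(exp(-((rows - centers[b])^2) / (2 * sds[b]^2)), rep(1, W))
  }
  img <- img + sweep(exp(-(outer(rows, c3, "-")^2) / (2 * sds[3]^2)), 2, a3, "*")
  if (!is.null(blob)) img <- img + blob
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  pmin(pmax(img, 0), 1)
}

#' Render one synthetic B-scan
#'
#' Draws a single phantom B-scan for a given class, consuming the current R
#' random stream (seed with [set.seed()] for reproducibility). All per-image
#' nuisance variation (band position, width, brightness, distractor spots
#' above the band stack) is shared across columns, so a `normal` image at
#' `noise_sd = 0` has identical column profiles wherever no spot is present;
#' with no spots it is exactly column-constant. `drusen` adds 1-5 small
#' upward domes to the lowest band; `cnv` adds one large bright blob beneath
#' a locally attenuated, sagging band.
#'
#' @param label One of `"normal"`, `"drusen"`, `"cnv"`.
#' @param height,width Image size in pixels (at least 32).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param latent Optional latent parameter list (an internal draw shared
#'   across the B-scans of one volume); drawn fresh when `NULL`.
#'
#' @return A `height x width` matrix with values in `[0, 1]`.
#' @export
render_bscan <- function(label, height, width, noise_sd = 0.05, latent = NULL) {
  if (!is.character(label) || length(label) != 1L || !(label %in% OCT_CLASSES)) {
    stop("unknown label '", paste(label, collapse = ","),
         "'; expected one of ", paste(OCT_CLASSES, collapse = ", "), call. = FALSE)
  }
  stopifnot_scalar_number(height, "height", lower = 32)
  stopifnot_scalar_number(width, "width", lower = 32)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(latent)) latent <- sample_scan_latent(label)
  render_from_latent(latent, as.integer(height), as.integer(width), noise_sd)
}

#' Summary statistics that separate the phantom classes
#'
#' Computes two simple hand-written features from a phantom B-scan: the
#' column-to-column deviation energy of the detected lowest-band ridge (large
#' when domes or lesions deform the band) and the mean intensity in a window
#' beneath the band (large when a CNV-like blob is present). These features
#' document that the phantom classes are recoverable without any learning and
#' give tests an independent check on class structure.
#'
#' @param image A grayscale matrix in `[0, 1]`.
#' @return Named numeric vector `c(dev_energy, sub_band_mass)`.
#' @export
bscan_statistics <- function(image) {
  H <- nrow(image); W <- ncol(image)
  lo <- floor(0.50 * H); hi <- ceiling(0.88 * H)
  band <- apply(image[lo:hi, , drop = FALSE], 2, which.max) + lo - 1L
  med <- stats::median(band)
  w0 <- min(H, round(med + 0.10 * H)); w1 <- min(H, round(med + 0.28 * H))
  sub_mass <- mean(image[w0:w1, , drop = FALSE])
  c(dev_energy = stats::sd(band) / H, sub_band_mass = sub_mass)
}

#' Rule-based phantom classifier
#'
#' Classifies a phantom B-scan from [bscan_statistics()] alone: high sub-band
#' mass indicates a CNV blob; otherwise high ridge-deviation energy indicates
#' drusen; otherwise normal. Used as a learning-free reference for the
#' phantom's class separability, not in the pipeline itself.
#'
#' @param image A grayscale matrix in `[0, 1]`.
#' @param blob_threshold Sub-band mean-intensity cut for calling CNV.
#' @param dev_threshold Ridge deviation (as a fraction of image height) cut
#'   for calling drusen.
#' @return One of `"normal"`, `"drusen"`, `"cnv"`.
#' @export
classify_by_statistics <- function(image, blob_threshold = 0.11, dev_threshold = 0.016) {
  s <- bscan_statistics(image)
  if (s[["sub_band_mass"]] > blob_threshold) return("cnv")
  if (s[["dev_energy"]] > dev_threshold) return("drusen")
  "normal"
}

#' Generate a synthetic phantom cohort
#'
#' Samples the patient / volume / B-scan hierarchy defined by a
#' [phantom_spec()]: volume counts per patient, one class label per volume
#' drawn from `class_proportions` (so the two volumes of one patient may carry
#' different labels), B-scan counts per volume, and the rendered images. The
#' result is a pure function of the spec, including its seed.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `oct_cohort`: a list with `images` (named list
#'   of matrices), `manifest` (tibble with `image_id`, `patient_id`,
#'   `volume_id`, `label`) and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec", call. = FALSE)
  with_seed(spec$seed, {
    images <- list()
    rows <- vector("list", 0L)
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("P%04d", p)
      rng <- spec$volumes_per_patient
      nv <- if (identical(rng, c(1L, 2L))) {
        1L + stats::rbinom(1, 1, spec$two_volume_fraction)
      } else if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
      for (v in seq_len(nv)) {
        vid <- sprintf("%s_V%d", pid, v)
        lab <- sample(OCT_CLASSES, 1, prob = spec$class_proportions)
        nb <- if (spec$bscans_per_volume[1] == spec$bscans_per_volume[2]) {
          spec$bscans_per_volume[1]
        } else sample(spec$bscans_per_volume[1]:spec$bscans_per_volume[2], 1)
        vlat <- sample_scan_latent(lab)   # volume geometry shared by its B-scans
        for (b in seq_len(nb)) {
          iid <- sprintf("%s_B%02d", vid, b)
          images[[iid]] <- render_from_latent(jitter_latent(vlat),
                                              spec$image_height, spec$image_width,
                                              spec$noise_sd)
          rows[[length(rows) + 1L]] <- list(image_id = iid, patient_id = pid,
                                            volume_id = vid, label = lab)
        }
      }
    }
    manifest <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
    new_cohort(images, manifest, spec)
  })
}

new_cohort <- function(images, manifest, spec = NULL) {
  stopifnot(all(c("image_id", "patient_id", "volume_id", "label") %in% names(manifest)))
  if (anyDuplicated(manifest$image_id)) stop("image_ids must be unique", call. = FALSE)
  v2p <- unique(manifest[, c("volume_id", "patient_id")])
  if (anyDuplicated(v2p$volume_id)) {
    stop("hierarchy violation: a volume_id maps to more than one patient_id",
         call. = FALSE)
  }
  vlab <- unique(manifest[, c("volume_id", "label")])
  if (anyDuplicated(vlab$volume_id)) {
    stop("labels must be constant within a volume", call. = FALSE)
  }
  structure(list(images = images, manifest = tibble::as_tibble(manifest), spec = spec),
            class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  m <- x$manifest
  cat("<oct_cohort> ", nrow(m), " B-scans, ",
      length(unique(m$patient_id)), " patients, ",
      length(unique(m$volume_id)), " volumes\n", sep = "")
  print(table(m$label)[OCT_CLASSES])
  invisible(x)
}

#' Extract images or labels for a set of image ids
#'
#' @param cohort An `oct_cohort`.
#' @param ids Character vector of image ids (default: all, in manifest order).
#' @return `cohort_images()`: a named list of matrices; `cohort_labels()`: a
#'   factor with levels `normal, drusen, cnv`.
#' @export
cohort_images <- function(cohort, ids = cohort$manifest$image_id) {
  missing <- setdiff(ids, names(cohort$images))
  if (length(missing) > 0L) {
    stop("unknown image_id(s): ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  cohort$images[ids]
}

#' @rdname cohort_images
#' @export
cohort_labels <- function(cohort, ids = cohort$manifest$image_id) {
  lab <- cohort$manifest$label[match(ids, cohort$manifest$image_id)]
  if (anyNA(lab)) stop("unknown image_id(s) in ids", call. = FALSE)
  as_oct_factor(lab)
}
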