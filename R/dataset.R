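# Experimental-design layer: patient-wise grouped splitting, nested
# label-fraction subsetting on whole volumes, inverse-frequency class weights.

#' Patient-wise train/validation/test split
#'
#' Assigns whole patients (never individual images or volumes) to the three
#' splits, so no patient's images can leak across the train/test boundary.
#' Patients are ordered by a seeded shuffle, largest image count first, and
#' assigned greedily to the split whose image-count deficit against its target
#' fraction is largest; realized image fractions therefore approach the
#' targets without solving a partition problem. The assignment is a pure
#' function of (cohort, fractions, seed), so the test set can be held fixed
#' across experiments.
#'
#' @param cohort An `oct_cohort` with at least 3 patients.
#' @param fractions Numeric triple `(train, val, test)`, each positive,
#'   summing to 1.
#' @param seed Integer seed for the patient shuffle.
#' @return An object of class `cohort_split` with `train_ids`, `val_ids`,
#'   `test_ids` (image ids), the train partition `labeled_ids` /
#'   `unlabeled_ids` (initially all labeled), and provenance notes.
#' @export
patient_wise_split <- function(cohort, fractions = c(0.64, 0.17, 0.19), seed = 1L) {
  stopifnot(inherits(cohort, "oct_cohort"))
  if (length(fractions) != 3L || any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must be 3 positive values summing to 1", call. = FALSE)
  }
  m <- cohort$manifest
  patients <- unique(m$patient_id)
  if (length(patients) < 3L) {
    stop("cohort must have at least 3 patients (one per split)", call. = FALSE)
  }
  counts <- table(m$patient_id)[patients]
  ord <- with_seed(seed, {
    shuffled <- sample(patients)
    shuffled[order(-as.integer(counts[shuffled]))]
  })
  total <- nrow(m)
  target <- fractions * total
  assigned <- stats::setNames(integer(3), c("train", "val", "test"))
  membership <- stats::setNames(character(length(ord)), ord)
  for (i in seq_along(ord)) {
    p <- ord[i]
    deficit <- target - assigned
    empty <- names(assigned)[assigned == 0]
    remaining <- length(ord) - i + 1L
    pick <- if (length(empty) >= remaining) {
      empty[which.max(deficit[empty])]   # guarantee no split ends empty
    } else names(assigned)[which.max(deficit)]
    membership[p] <- pick
    assigned[pick] <- assigned[pick] + as.integer(counts[p])
  }
  sp <- split(m$image_id, membership[m$patient_id])
  structure(list(
    train_ids = sp[["train"]], val_ids = sp[["val"]], test_ids = sp[["test"]],
    labeled_ids = sp[["train"]], unlabeled_ids = character(0),
    seed = as.integer(seed), fractions = as.numeric(fractions),
    labeled_fraction = 1.0, provenance = character(0)
  ), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("<cohort_split> train ", length(x$train_ids),
      " (labeled ", length(x$labeled_ids), " / unlabeled ", length(x$unlabeled_ids),
      "), val ", length(x$val_ids), ", test ", length(x$test_ids), "\n", sep = "")
  if (length(x$provenance) > 0) cat("notes:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Mark a fraction of the training images as labeled
#'
#' Partitions the training split into a labeled and an unlabeled pool by
#' selecting whole volumes (a clinician labels a scan volume in its entirety)
#' until approximately `labeled_fraction` of the training images are covered.
#' Volumes are ranked by a single seeded per-class shuffle interleaved across
#' classes, so the labeled class mix tracks the full training set and, for a
#' fixed seed, the labeled sets are nested across fractions
#' (5% within 20% within 50% within 70%). Validation and test sets are
#' untouched and remain fully labeled.
#'
#' @param split A [patient_wise_split()] result.
#' @param cohort The `oct_cohort` the split was made from.
#' @param labeled_fraction Fraction of training images to label, in `(0, 1]`.
#' @param seed Integer seed for the volume shuffle; use one seed across the
#'   whole fraction sweep to obtain nested subsets.
#' @return A `cohort_split` with updated `labeled_ids` / `unlabeled_ids`. If
#'   some class ends with zero labeled volumes a note is recorded in the
#'   split's provenance (not an error).
#' @export
subset_labels <- function(split, cohort, labeled_fraction, seed = split$seed) {
  stopifnot(inherits(split, "cohort_split"), inherits(cohort, "oct_cohort"))
  if (!is.numeric(labeled_fraction) || length(labeled_fraction) != 1L ||
      labeled_fraction <= 0 || labeled_fraction > 1) {
    stop("labeled_fraction must be in (0, 1]", call. = FALSE)
  }
  m <- cohort$manifest
  tr <- m[m$image_id %in% split$train_ids, ]
  vols <- dplyr::summarise(dplyr::group_by(tr, .data$volume_id, .data$label),
                           n = dplyr::n(), .groups = "drop")
  # One seeded permutation per class, interleaved by within-class quantile so
  # every prefix of the priority order has a representative class mix.
  prio <- with_seed(derive_seed(seed, "subset"), {
    parts <- lapply(OCT_CLASSES, function(cl) {
      v <- vols$volume_id[vols$label == cl]
      if (length(v) == 0L) return(NULL)
      v <- sample(v)
      tibble::tibble(volume_id = v, key = (seq_along(v) - 0.5) / length(v),
                     class_rank = match(cl, OCT_CLASSES))
    })
    dplyr::bind_rows(parts)
  })
  prio <- prio[order(prio$key, prio$class_rank, prio$volume_id), ]
  sizes <- vols$n[match(prio$volume_id, vols$volume_id)]
  target <- labeled_fraction * nrow(tr)
  cum_before <- cumsum(sizes) - sizes
  take <- prio$volume_id[cum_before < target]  # overshoot by less than one volume
  labeled <- tr$image_id[tr$volume_id %in% take]
  unlabeled <- setdiff(split$train_ids, labeled)
  lab_classes <- unique(tr$label[tr$volume_id %in% take])
  missing <- setdiff(unique(tr$label), lab_classes)
  if (length(missing) > 0L) {
    note <- paste0("labeled_fraction ", labeled_fraction,
                   " leaves class(es) without labeled volumes: ",
                   paste(missing, collapse = ", "))
    warning(note, call. = FALSE)
    split$provenance <- c(split$provenance, note)
  }
  split$labeled_ids <- labeled
  split$unlabeled_ids <- unlabeled
  split$labeled_fraction <- labeled_fraction
  split
}

#' Inverse-frequency class weights
#'
#' Computes the class-balancing weights used in the weighted cross-entropy
#' loss: `w_c = N_total / (K * N_c)` over the `K = 3` classes, so weights are
#' uniform at 1 when the classes are balanced. A class with zero labeled
#' examples gets weight 0, with a warning.
#'
#' @param x Either a vector of labels, or a numeric length-3 vector of class
#'   counts in canonical order `(normal, drusen, cnv)`.
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(x) {
  counts <- if (is.numeric(x)) {
    if (length(x) != 3L || any(x < 0)) stop("counts must be 3 non-negative numbers", call. = FALSE)
    stats::setNames(as.numeric(x), OCT_CLASSES)
  } else {
    tab <- table(as_oct_factor(x))
    stats::setNames(as.numeric(tab[OCT_CLASSES]), OCT_CLASSES)
  }
  if (sum(counts) == 0) stop("no labeled records", call. = FALSE)
  w <- ifelse(counts > 0, sum(counts) / (3 * counts), 0)
  if (any(counts == 0)) {
    warning("class(es) with zero examples get weight 0: ",
            paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(w), OCT_CLASSES)
}

#' Serialize a split as a flat table
#'
#' Long-format view of a `cohort_split` suitable for writing alongside a
#' cohort manifest: one row per image with its split assignment and labeled
#' status (validation and test images are always labeled).
#'
#' @param split A `cohort_split`.
#' @return A tibble with columns `image_id`, `split`, `is_labeled`.
#' @export
split_table <- function(split) {
  stopifnot(inherits(split, "cohort_split"))
  ids <- c(split$train_ids, split$val_ids, split$test_ids)
  assignment <- rep(c("train", "val", "test"),
                    c(length(split$train_ids), length(split$val_ids),
                      length(split$test_ids)))
  labeled <- c(split$train_ids %in% split$labeled_ids,
               rep(TRUE, length(split$val_ids) + length(split$test_ids)))
  tibble::tibble(image_id = ids, split = assignment, is_labeled = labeled)
}
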