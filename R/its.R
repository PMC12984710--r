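# Confidence-filtered self-training: pseudo-label assignment, reliability
# filtering, student train-set construction, and the iterative
# teacher -> student promotion loop.

#' Iterative teacher-student configuration
#'
#' @param confidence_threshold Minimum predicted-probability mass (maximum
#'   softmax probability) for a pseudo-label to be accepted, in `[0, 1]`.
#'   Acceptance uses `>=`, so a threshold of 0 accepts every pseudo-label.
#'   The study grid is 0, 0.90, 0.95, 0.99.
#' @param max_iterations Number of teacher -> student promotions.
#' @param stop_on_val_decline Stop iterating when validation accuracy drops
#'   below the previous iteration's (the previous iteration is then best).
#' @param pseudo_weight Sample-weight multiplier for pseudo-labeled images
#'   (1 = full weight, matching the base scheme).
#' @param seed Seed recorded for provenance; the training streams come from
#'   the [train_config()].
#' @return An object of class `its_config`.
#' @export
its_config <- function(confidence_threshold = 0.95,
                       max_iterations = 4L,
                       stop_on_val_decline = TRUE,
                       pseudo_weight = 1,
                       seed = 1L) {
  stopifnot_scalar_number(confidence_threshold, "confidence_threshold", 0, 1)
  stopifnot_scalar_number(max_iterations, "max_iterations", lower = 1)
  stopifnot_scalar_number(pseudo_weight, "pseudo_weight", lower = 0)
  structure(list(confidence_threshold = confidence_threshold,
                 max_iterations = as.integer(max_iterations),
                 stop_on_val_decline = isTRUE(stop_on_val_decline),
                 pseudo_weight = pseudo_weight,
                 seed = as.integer(seed)),
            class = "its_config")
}

#' Assign pseudo-labels to unlabeled records
#'
#' Runs the teacher on every unlabeled record and converts each probability
#' row into a hard pseudo-label: the predicted class is the row argmax (ties
#' broken in canonical class order) and the confidence is the row maximum.
#'
#' @param teacher A trained classifier.
#' @param images Named list of unlabeled images.
#' @param iteration Iteration index recorded with each pseudo-label.
#' @return A tibble with one row per record: `image_id`, `predicted_class`,
#'   `confidence`, `iteration`, `accepted` (initialized `NA`, set by
#'   [reliability_filter()]). An empty pool returns an empty tibble with a
#'   warning rather than an error.
#' @export
assign_pseudo_labels <- function(teacher, images, iteration = 1L) {
  if (length(images) == 0L) {
    warning("empty unlabeled pool: no pseudo-labels assigned", call. = FALSE)
    return(tibble::tibble(image_id = character(0), predicted_class = character(0),
                          confidence = numeric(0), iteration = integer(0),
                          accepted = logical(0)))
  }
  P <- predict_proba(teacher, images)
  k <- max.col(P, ties.method = "first")
  tibble::tibble(
    image_id = names(images),
    predicted_class = OCT_CLASSES[k],
    confidence = P[cbind(seq_along(k), k)],
    iteration = as.integer(iteration),
    accepted = NA
  )
}

#' Reliability check on pseudo-labels
#'
#' Partitions pseudo-labels into accepted (`confidence >= threshold`) and
#' rejected sets, both preserving input order. With threshold 0 every
#' pseudo-label is accepted, so the whole unlabeled pool enters training.
#'
#' @param pseudo A pseudo-label tibble from [assign_pseudo_labels()].
#' @param threshold Confidence threshold in `[0, 1]`.
#' @return List with `accepted` and `rejected` tibbles (with the `accepted`
#'   flag filled in); together they partition the input.
#' @export
reliability_filter <- function(pseudo, threshold) {
  stopifnot_scalar_number(threshold, "threshold", 0, 1)
  keep <- pseudo$confidence >= threshold
  pseudo$accepted <- keep
  list(accepted = pseudo[keep, , drop = FALSE],
       rejected = pseudo[!keep, , drop = FALSE])
}

#' Build the student training set
#'
#' Combines the original labeled records (true labels) with the accepted
#' pseudo-labeled records (hard predicted labels). Class weights are
#' recomputed on the union, and pseudo-labeled records can carry a
#' sample-weight multiplier. Every accepted pseudo-label must reference a
#' record in the unlabeled pool, so no image can appear twice.
#'
#' @param labeled_ids,labeled_labels The labeled pool and its true labels.
#' @param accepted Accepted pseudo-label tibble.
#' @param unlabeled_ids The unlabeled pool the pseudo-labels refer to.
#' @param pseudo_weight Sample-weight multiplier for pseudo-labeled records.
#' @return List with `ids`, `labels` (factor), `is_pseudo` (logical),
#'   `weights` (class weights on the union) and `multiplier` (per-record
#'   sample-weight multipliers).
#' @export
build_student_trainset <- function(labeled_ids, labeled_labels, accepted,
                                   unlabeled_ids, pseudo_weight = 1) {
  labeled_labels <- as_oct_factor(labeled_labels)
  stopifnot(length(labeled_ids) == length(labeled_labels))
  unknown <- setdiff(accepted$image_id, unlabeled_ids)
  if (length(unknown) > 0L) {
    stop("pseudo-label(s) reference images outside the unlabeled pool: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  ids <- c(labeled_ids, accepted$image_id)
  stopifnot(!anyDuplicated(ids))
  labels <- as_oct_factor(c(as.character(labeled_labels), accepted$predicted_class))
  is_pseudo <- c(rep(FALSE, length(labeled_ids)), rep(TRUE, nrow(accepted)))
  list(ids = ids, labels = labels, is_pseudo = is_pseudo,
       weights = class_weights(labels),
       multiplier = ifelse(is_pseudo, pseudo_weight, 1))
}

#' Run the iterative teacher-student loop
#'
#' Implements confidence-filtered self-training: a teacher is trained on the
#' labeled pool; at each iteration the current teacher re-predicts the entire
#' unlabeled pool, pseudo-labels are filtered by the confidence threshold, a
#' fresh student is trained on the labeled records plus the accepted
#' pseudo-labels, and the student becomes the next teacher. Pseudo-labels are
#' never sticky: every iteration rebuilds the accepted set from the new
#' teacher's predictions. Iterating stops at `max_iterations` or, when
#' `stop_on_val_decline` is set, as soon as validation accuracy drops below
#' the previous iteration's; the best iteration is chosen by validation
#' (never test) accuracy.
#'
#' When the cohort carries ground-truth labels for the unlabeled pool (the
#' phantom setting), each iteration also records pseudo-label purity: the
#' fraction of accepted pseudo-labels whose predicted class matches the
#' hidden truth.
#'
#' @param cohort An `oct_cohort`.
#' @param split A `cohort_split` with non-empty labeled and unlabeled pools
#'   (an empty unlabeled pool degrades to one supervised run, with a warning).
#' @param train_cfg A [train_config()].
#' @param its_cfg An [its_config()].
#' @param teacher Optionally, an already-trained initial teacher (must match
#'   what [train_supervised()] would produce for the labeled pool); used to
#'   avoid retraining when a matching supervised baseline exists.
#' @return An object of class `its_result`: `iterations` (one row per
#'   completed iteration with per-class accepted counts, rejected count,
#'   purity, validation and test metrics), `best_iteration`, `model` (the
#'   best iteration's student), and `baseline` (the supervised teacher's
#'   validation/test metrics).
#' @export
run_its <- function(cohort, split, train_cfg = train_config(),
                    its_cfg = its_config(), teacher = NULL) {
  stopifnot(inherits(cohort, "oct_cohort"), inherits(split, "cohort_split"))
  if (length(split$labeled_ids) == 0L) stop("labeled pool is empty", call. = FALSE)

  lab_imgs <- cohort_images(cohort, split$labeled_ids)
  lab_y <- cohort_labels(cohort, split$labeled_ids)
  val_imgs <- cohort_images(cohort, split$val_ids)
  val_y <- cohort_labels(cohort, split$val_ids)
  test_imgs <- cohort_images(cohort, split$test_ids)
  test_y <- cohort_labels(cohort, split$test_ids)

  if (is.null(teacher)) {
    teacher <- train_supervised(lab_imgs, lab_y, val_imgs, val_y,
                                config = train_cfg)$model
  }
  base_val <- evaluate_model(teacher, val_imgs, val_y)
  base_test <- evaluate_model(teacher, test_imgs, test_y)
  baseline <- list(val_accuracy = base_val$accuracy, test_accuracy = base_test$accuracy,
                   test_metrics = base_test$metrics, model = teacher)

  if (length(split$unlabeled_ids) == 0L) {
    warning("empty unlabeled pool: degenerating to a single supervised run",
            call. = FALSE)
    return(structure(list(iterations = tibble::tibble(), best_iteration = 0L,
                          model = teacher, baseline = baseline,
                          config = its_cfg), class = "its_result"))
  }

  unl_imgs <- cohort_images(cohort, split$unlabeled_ids)
  unl_truth <- cohort$manifest$label[match(split$unlabeled_ids, cohort$manifest$image_id)]
  have_truth <- all(unl_truth %in% OCT_CLASSES)

  rows <- list(); models <- list()
  for (t in seq_len(its_cfg$max_iterations)) {
    pseudo <- assign_pseudo_labels(teacher, unl_imgs, iteration = t)
    flt <- reliability_filter(pseudo, its_cfg$confidence_threshold)
    stopifnot(nrow(flt$accepted) + nrow(flt$rejected) == length(unl_imgs))

    purity <- if (have_truth && nrow(flt$accepted) > 0L) {
      truth_acc <- unl_truth[match(flt$accepted$image_id, split$unlabeled_ids)]
      mean(flt$accepted$predicted_class == truth_acc)
    } else NA_real_

    ts <- build_student_trainset(split$labeled_ids, lab_y, flt$accepted,
                                 split$unlabeled_ids, its_cfg$pseudo_weight)
    stopifnot(length(intersect(ts$ids, c(split$val_ids, split$test_ids))) == 0L)
    student <- train_supervised(cohort_images(cohort, ts$ids), ts$labels,
                                val_imgs, val_y, weights = ts$weights,
                                config = train_cfg,
                                sample_weight_multiplier = ts$multiplier)$model
    ev_val <- evaluate_model(student, val_imgs, val_y)
    ev_test <- evaluate_model(student, test_imgs, test_y)

    acc_by_class <- table(factor(flt$accepted$predicted_class, levels = OCT_CLASSES))
    rows[[t]] <- tibble::tibble(
      iteration = t,
      n_accepted = nrow(flt$accepted),
      n_accepted_normal = as.integer(acc_by_class[["normal"]]),
      n_accepted_drusen = as.integer(acc_by_class[["drusen"]]),
      n_accepted_cnv = as.integer(acc_by_class[["cnv"]]),
      n_rejected = nrow(flt$rejected),
      purity = purity,
      val_accuracy = ev_val$accuracy,
      test_accuracy = ev_test$accuracy,
      test_macro_precision = ev_test$metrics$macro[["precision"]],
      test_macro_recall = ev_test$metrics$macro[["recall"]],
      test_macro_f1 = ev_test$metrics$macro[["f1"]],
      test_auc_micro = roc_auc(ev_test$roc, "micro"),
      test_auc_macro = roc_auc(ev_test$roc, "macro")
    )
    models[[t]] <- student

    if (its_cfg$stop_on_val_decline && t >= 2L &&
        rows[[t]]$val_accuracy < rows[[t - 1L]]$val_accuracy) {
      break
    }
    teacher <- student
  }

  iterations <- dplyr::bind_rows(rows)
  best_iteration <- which.max(iterations$val_accuracy)[1]
  structure(list(iterations = iterations,
                 best_iteration = as.integer(best_iteration),
                 model = models[[best_iteration]],
                 baseline = baseline,
                 config = its_cfg),
            class = "its_result")
}

#' @export
print.its_result <- function(x, ...) {
  cat("<its_result> ", nrow(x$iterations), " iteration(s), best ",
      x$best_iteration, "\n", sep = "")
  if (nrow(x$iterations) > 0) {
    print(x$iterations[, c("iteration", "n_accepted", "n_rejected", "purity",
                           "val_accuracy", "test_accuracy")])
  }
  cat(sprintf("supervised baseline: val %.4f test %.4f\n",
              x$baseline$val_accuracy, x$baseline$test_accuracy))
  invisible(x)
}
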