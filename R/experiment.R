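# Study orchestration: supervised baselines across label fractions, TS (one
# iteration) and ITS sweeps across confidence thresholds, with seed
# replication and a long-format report.

#' Experiment plan
#'
#' Describes a full sweep: which label fractions, which confidence
#' thresholds, which modes (`SL` supervised-only, `TS` one teacher-student
#' pass, `ITS` the iterative loop), how many seed replicates, and the phantom
#' cohort and training configurations to use. Within one seed, the cohort,
#' the patient-wise split (hence the test set) and the training stream are
#' fixed across all fractions, thresholds and modes; labeled subsets are
#' nested across fractions.
#'
#' @param phantom A [phantom_spec()]; its seed field is replaced per replicate.
#' @param label_fractions Fractions of training images labeled.
#' @param thresholds Confidence thresholds for the TS/ITS sweeps.
#' @param modes Subset of `c("SL", "TS", "ITS")`.
#' @param n_seeds Number of seed replicates.
#' @param base_seed Root seed; replicate `i` uses root `base_seed + i - 1`.
#' @param split_fractions Patient-wise `(train, val, test)` image fractions.
#' @param train A [train_config()] (its seed field is replaced per replicate).
#' @param its An [its_config()]; `TS` mode runs the same loop with
#'   `max_iterations = 1`.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(phantom = phantom_spec(),
                            label_fractions = c(1, 0.7, 0.5, 0.2, 0.05),
                            thresholds = c(0, 0.90, 0.95, 0.99),
                            modes = c("SL", "TS", "ITS"),
                            n_seeds = 5L,
                            base_seed = 1L,
                            split_fractions = c(0.64, 0.17, 0.19),
                            train = train_config(),
                            its = its_config()) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(train, "train_config"),
            inherits(its, "its_config"))
  if (any(label_fractions <= 0) || any(label_fractions > 1)) {
    stop("label_fractions must lie in (0, 1]", call. = FALSE)
  }
  modes <- match.arg(modes, c("SL", "TS", "ITS"), several.ok = TRUE)
  stopifnot_scalar_number(n_seeds, "n_seeds", lower = 1)
  structure(list(phantom = phantom, label_fractions = label_fractions,
                 thresholds = thresholds, modes = modes,
                 n_seeds = as.integer(n_seeds), base_seed = as.integer(base_seed),
                 split_fractions = split_fractions, train = train, its = its),
            class = "experiment_plan")
}

#' Run an experiment plan
#'
#' Executes every cell of the plan. For each seed replicate a fresh phantom
#' cohort is generated and split patient-wise once, so the test set is
#' identical across every cell of that replicate (asserted internally).
#' `SL` trains on the labeled subset only; `TS` runs the teacher-student loop
#' for one iteration; `ITS` runs it with the plan's configuration. The
#' supervised model is reused as the initial teacher for `TS`/`ITS` at the
#' same fraction (it is identical by determinism). Failures of individual
#' cells are recorded as warnings, not fatal.
#'
#' @param plan An [experiment_plan()].
#' @param cohorts Optional pre-generated list of cohorts, one per seed
#'   (mainly for tests); by default cohorts are generated from the plan's
#'   phantom spec.
#' @return A `sweep_report`: a tibble with one row per evaluation (mode,
#'   label_fraction, threshold, iteration, seed, test metrics, pseudo-label
#'   counts and purity), with the per-seed test-id sets attached as the
#'   `test_ids` attribute.
#' @export
run_plan <- function(plan, cohorts = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  rows <- list()
  test_ids_by_seed <- list()
  for (i in seq_len(plan$n_seeds)) {
    root <- plan$base_seed + i - 1L
    cohort <- if (!is.null(cohorts)) cohorts[[i]] else {
      spec <- plan$phantom; spec$seed <- derive_seed(root, "cohort")
      generate_cohort(spec)
    }
    split0 <- patient_wise_split(cohort, plan$split_fractions,
                                 seed = derive_seed(root, "split"))
    test_ids_by_seed[[as.character(root)]] <- split0$test_ids
    tcfg <- plan$train; tcfg$seed <- derive_seed(root, "train")
    subset_seed <- derive_seed(root, "subset")

    val_imgs <- cohort_images(cohort, split0$val_ids)
    val_y <- cohort_labels(cohort, split0$val_ids)
    test_imgs <- cohort_images(cohort, split0$test_ids)
    test_y <- cohort_labels(cohort, split0$test_ids)

    for (f in plan$label_fractions) {
      sub <- if (f < 1) subset_labels(split0, cohort, f, seed = subset_seed) else split0
      stopifnot(identical(sub$test_ids, split0$test_ids))
      sl_model <- NULL
      cell <- function(expr) tryCatch(expr, error = function(e) {
        warning("experiment cell failed (seed ", root, ", fraction ", f, "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })

      if ("SL" %in% plan$modes || length(sub$unlabeled_ids) > 0L) {
        sl_model <- cell(train_supervised(
          cohort_images(cohort, sub$labeled_ids), cohort_labels(cohort, sub$labeled_ids),
          val_imgs, val_y, config = tcfg)$model)
      }
      if ("SL" %in% plan$modes && !is.null(sl_model)) {
        ev <- evaluate_model(sl_model, test_imgs, test_y)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mode = "SL", label_fraction = f, threshold = NA_real_,
          iteration = NA_integer_, seed = root,
          is_best = TRUE, val_accuracy = NA_real_,
          accuracy = ev$accuracy,
          macro_precision = ev$metrics$macro[["precision"]],
          macro_recall = ev$metrics$macro[["recall"]],
          macro_f1 = ev$metrics$macro[["f1"]],
          auc_micro = roc_auc(ev$roc, "micro"), auc_macro = roc_auc(ev$roc, "macro"),
          n_pseudo_accepted = NA_integer_, purity = NA_real_)
      }
      ssl_modes <- intersect(plan$modes, c("TS", "ITS"))
      if (length(ssl_modes) > 0L && length(sub$unlabeled_ids) == 0L) next
      for (mode in ssl_modes) {
        for (th in plan$thresholds) {
          icfg <- plan$its
          icfg$confidence_threshold <- th
          if (mode == "TS") icfg$max_iterations <- 1L
          res <- cell(run_its(cohort, sub, tcfg, icfg, teacher = sl_model))
          if (is.null(res) || nrow(res$iterations) == 0L) next
          it <- res$iterations
          rows[[length(rows) + 1L]] <- tibble::tibble(
            mode = mode, label_fraction = f, threshold = th,
            iteration = it$iteration, seed = root,
            is_best = it$iteration == res$best_iteration,
            val_accuracy = it$val_accuracy,
            accuracy = it$test_accuracy,
            macro_precision = it$test_macro_precision,
            macro_recall = it$test_macro_recall,
            macro_f1 = it$test_macro_f1,
            auc_micro = it$test_auc_micro, auc_macro = it$test_auc_macro,
            n_pseudo_accepted = it$n_accepted, purity = it$purity)
        }
      }
    }
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "test_ids") <- test_ids_by_seed
  class(report) <- c("sweep_report", class(report))
  report
}

#' Aggregate a sweep report over seeds
#'
#' Mean and standard deviation of every metric per
#' (mode, label_fraction, threshold, iteration) cell, with the number of seed
#' replicates contributing to each cell.
#'
#' @param report A `sweep_report` from [run_plan()].
#' @return A tibble of per-cell summaries.
#' @export
summarize_sweep <- function(report) {
  stopifnot(nrow(report) > 0)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(report), .data$mode, .data$label_fraction,
                    .data$threshold, .data$iteration),
    n_seeds = dplyr::n(),
    dplyr::across(c("accuracy", "macro_precision", "macro_recall", "macro_f1",
                    "auc_micro", "auc_macro"),
                  list(mean = mean, sd = function(v) if (length(v) > 1) stats::sd(v) else 0)),
    .groups = "drop")
}
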