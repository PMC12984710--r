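test_that("pseudo-labels are the argmax and max of each probability row", {
  proba <- rbind(c(0.97, 0.02, 0.01),
                 c(0.50, 0.50, 0.00),
                 c(0.10, 0.30, 0.60))
  clf <- mock_classifier(proba)
  imgs <- stats::setNames(replicate(3, matrix(0, 4, 4), simplify = FALSE),
                          c("a", "b", "c"))
  ps <- assign_pseudo_labels(clf, imgs, iteration = 2L)
  expect_equal(ps$predicted_class, c("normal", "normal", "cnv"))  # tie -> normal
  expect_equal(ps$confidence, c(0.97, 0.50, 0.60))
  expect_true(all(ps$iteration == 2L))
  expect_warning(empty <- assign_pseudo_labels(clf, list()), "empty unlabeled pool")
  expect_equal(nrow(empty), 0)
})

test_that("pseudo-label confidences equal independently recomputed row maxima", {
  co <- tiny_cohort(n_patients = 15, seed = 14)
  sp <- patient_wise_split(co, seed = 1)
  sub <- subset_labels(sp, co, 0.5, seed = 1)
  model <- train_supervised(cohort_images(co, sub$labeled_ids),
                            cohort_labels(co, sub$labeled_ids),
                            cohort_images(co, sp$val_ids), cohort_labels(co, sp$val_ids),
                            config = fast_train_config(max_epochs = 4L))$model
  unl <- cohort_images(co, sub$unlabeled_ids)
  ps <- assign_pseudo_labels(model, unl)
  P <- predict_proba(model, unl)
  expect_equal(nrow(ps), length(unl))
  expect_equal(ps$confidence, unname(apply(P, 1, max)))
  expect_equal(ps$predicted_class, unname(oct_classes()[apply(P, 1, which.max)]))
})

test_that("the reliability filter is exact, order-preserving and monotone", {
  set.seed(81)
  conf <- runif(1000)
  ps <- tibble::tibble(image_id = sprintf("i%04d", 1:1000),
                       predicted_class = sample(oct_classes(), 1000, TRUE),
                       confidence = conf, iteration = 1L, accepted = NA)
  out0 <- reliability_filter(ps, 0)
  expect_equal(nrow(out0$accepted), 1000)
  prev <- Inf
  for (th in c(0, 0.90, 0.95, 0.99)) {
    out <- reliability_filter(ps, th)
    expect_equal(nrow(out$accepted), sum(conf >= th))
    expect_equal(nrow(out$accepted) + nrow(out$rejected), 1000)
    expect_identical(out$accepted$image_id, ps$image_id[conf >= th])
    expect_lte(nrow(out$accepted), prev)
    prev <- nrow(out$accepted)
  }
  boundary <- tibble::tibble(image_id = "x", predicted_class = "cnv",
                             confidence = 0.95, iteration = 1L, accepted = NA)
  expect_equal(nrow(reliability_filter(boundary, 0.95)$accepted), 1)
})

test_that("the student train set is the disjoint union with recomputed weights", {
  lab_ids <- sprintf("L%02d", 1:10)
  lab_y <- rep(c("normal", "drusen", "cnv"), c(4, 3, 3))
  unl_ids <- sprintf("U%02d", 1:8)
  acc <- tibble::tibble(image_id = unl_ids[1:4],
                        predicted_class = c("normal", "normal", "normal", "drusen"),
                        confidence = 0.99, iteration = 1L, accepted = TRUE)
  empty <- acc[0, ]
  ts0 <- build_student_trainset(lab_ids, lab_y, empty, unl_ids)
  expect_identical(ts0$ids, lab_ids)
  expect_identical(as.character(ts0$labels), lab_y)

  ts <- build_student_trainset(lab_ids, lab_y, acc, unl_ids, pseudo_weight = 0.5)
  expect_length(ts$ids, 14)
  expect_false(anyDuplicated(ts$ids) > 0)
  expect_equal(sum(ts$is_pseudo), 4)
  expect_equal(unname(ts$multiplier), rep(c(1, 0.5), c(10, 4)))
  w_union <- class_weights(c(as.character(lab_y), acc$predicted_class))
  expect_equal(ts$weights, w_union)
  expect_false(isTRUE(all.equal(ts$weights, class_weights(lab_y))))

  bad <- acc; bad$image_id[1] <- "nope"
  expect_error(build_student_trainset(lab_ids, lab_y, bad, unl_ids), "nope")
})

test_that("run_its records per-iteration structure and never leaks into val/test", {
  co <- tiny_cohort(n_patients = 25, seed = 16, bscans = c(3L, 5L))
  sp <- patient_wise_split(co, seed = 2)
  sub <- subset_labels(sp, co, 0.4, seed = 3)
  res <- suppressWarnings(
    run_its(co, sub, fast_train_config(max_epochs = 5L, seed = 7),
            its_config(confidence_threshold = 0.95, max_iterations = 2L)))
  it <- res$iterations
  expect_lte(nrow(it), 2)
  expect_true(all(it$n_accepted + it$n_rejected == length(sub$unlabeled_ids)))
  expect_true(all(it$n_accepted_normal + it$n_accepted_drusen + it$n_accepted_cnv ==
                    it$n_accepted))
  expect_true(all(is.na(it$purity) | (it$purity >= 0 & it$purity <= 1)))
  expect_gte(res$best_iteration, 1)
  expect_true(is_trained(res$model))
})

test_that("an always-rejecting threshold reduces ITS to the supervised baseline", {
  co <- tiny_cohort(n_patients = 30, seed = 17, bscans = c(3L, 5L))
  sp <- patient_wise_split(co, seed = 4)
  sub <- subset_labels(sp, co, 0.4, seed = 5)
  cfg <- fast_train_config(max_epochs = 5L, seed = 8)
  sl <- train_supervised(cohort_images(co, sub$labeled_ids),
                         cohort_labels(co, sub$labeled_ids),
                         cohort_images(co, sp$val_ids), cohort_labels(co, sp$val_ids),
                         config = cfg)
  res <- suppressWarnings(
    run_its(co, sub, cfg, its_config(confidence_threshold = 1.0, max_iterations = 2L,
                                     stop_on_val_decline = FALSE)))
  # no pseudo-label reaches confidence 1, so each student sees only labeled data
  expect_true(all(res$iterations$n_accepted == 0))
  ev_sl <- evaluate_model(sl$model, cohort_images(co, sp$test_ids),
                          cohort_labels(co, sp$test_ids))
  expect_equal(res$iterations$test_accuracy, rep(ev_sl$accuracy, 2), tolerance = 1e-12)
})

test_that("its_config validates the threshold and iteration count", {
  expect_error(its_config(confidence_threshold = 1.5), "confidence_threshold")
  expect_error(its_config(max_iterations = 0), "max_iterations")
})
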