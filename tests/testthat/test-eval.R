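hand_metrics <- function(cm) {
  # independent oracle: metrics straight from their definitions
  prec <- rec <- f1 <- numeric(3)
  for (k in 1:3) {
    prec[k] <- if (sum(cm[, k]) > 0) cm[k, k] / sum(cm[, k]) else 0
    rec[k] <- if (sum(cm[k, ]) > 0) cm[k, k] / sum(cm[k, ]) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(acc = sum(diag(cm)) / sum(cm), prec = prec, rec = rec, f1 = f1)
}

mw_auc <- function(pos_scores, neg_scores) {
  # pairwise Mann-Whitney oracle, ties counted 1/2
  s <- 0
  for (p in pos_scores) for (n in neg_scores) {
    s <- s + (p > n) + 0.5 * (p == n)
  }
  s / (length(pos_scores) * length(neg_scores))
}

test_that("confusion matrices tally truth against prediction", {
  truth <- rep(oct_classes(), c(5, 3, 2))
  expect_equal(unname(confusion_matrix3(truth, truth)), diag(c(5L, 3L, 2L)))
  all_normal <- confusion_matrix3(truth, rep("normal", 10))
  expect_equal(unname(all_normal[, 1]), c(5L, 3L, 2L))
  expect_equal(sum(all_normal[, 2:3]), 0L)
  expect_error(confusion_matrix3(c("normal", "dme"), c("normal", "cnv")), "dme")

  set.seed(21)
  t200 <- sample(oct_classes(), 200, replace = TRUE)
  p200 <- sample(oct_classes(), 200, replace = TRUE)
  cm <- confusion_matrix3(t200, p200)
  expect_equal(sum(cm), 200L)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm[i, j],
                 sum(t200 == oct_classes()[i] & p200 == oct_classes()[j]))
  }
})

test_that("classification metrics match hand-computed values", {
  perfect <- classification_metrics(diag(c(10, 10, 10)))
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(unname(perfect$macro), c(1, 1, 1))

  cm <- rbind(c(8, 1, 1), c(2, 6, 2), c(0, 2, 8))
  rep <- classification_metrics(cm)
  o <- hand_metrics(cm)
  expect_equal(rep$accuracy, 22 / 30)
  expect_equal(rep$per_class$precision, o$prec)
  expect_equal(rep$per_class$recall, o$rec)
  expect_equal(rep$per_class$f1, o$f1)
  expect_equal(unname(rep$macro["f1"]), mean(o$f1))

  degenerate <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 0))
  expect_warning(repd <- classification_metrics(degenerate), "zero")
  expect_equal(repd$per_class$recall[3], 0)
  expect_equal(unname(repd$macro["recall"]), mean(c(1, 1, 0)))
  expect_error(classification_metrics(matrix(0, 3, 3)), "empty")
})

test_that("metrics agree with the brute-force oracle on random confusion matrices", {
  set.seed(31)
  for (i in 1:100) {
    cm <- matrix(rpois(9, 10), 3, 3)
    if (sum(cm) == 0) next
    rep <- suppressWarnings(classification_metrics(cm))
    o <- hand_metrics(cm)
    expect_lt(abs(rep$accuracy - o$acc), 1e-9)
    expect_lt(max(abs(rep$per_class$precision - o$prec)), 1e-9)
    expect_lt(max(abs(rep$per_class$recall - o$rec)), 1e-9)
    expect_lt(max(abs(rep$per_class$f1 - o$f1)), 1e-9)
  }
})

test_that("ROC analysis hits the degenerate anchors exactly", {
  truth <- rep(oct_classes(), each = 4)
  sep <- matrix(0.05, 12, 3)
  sep[cbind(1:12, rep(1:3, each = 4))] <- 0.9
  r <- roc_analysis(truth, sep)
  for (cl in oct_classes()) expect_equal(r$per_class[[cl]]$auc, 1.0)
  expect_equal(r$micro$auc, 1.0)
  expect_equal(r$macro$auc, 1.0)

  flat <- matrix(1 / 3, 12, 3)
  rf <- roc_analysis(truth, flat)
  for (cl in oct_classes()) expect_equal(rf$per_class[[cl]]$auc, 0.5)
  expect_equal(rf$micro$auc, 0.5)
  expect_equal(rf$macro$auc, 0.5)
})

test_that("per-class AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(41)
  for (rep_i in 1:4) {
    n <- 50
    truth <- sample(oct_classes(), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    raw <- matrix(runif(n * 3), n, 3)
    raw <- round(raw, 1) + 0.05     # force score ties; keep rows normalizable
    proba <- raw / rowSums(raw)
    r <- roc_analysis(truth, proba)
    for (k in 1:3) {
      cl <- oct_classes()[k]
      pos <- truth == cl
      if (sum(pos) == 0 || sum(!pos) == 0) next
      expect_lt(abs(r$per_class[[cl]]$auc - mw_auc(proba[pos, k], proba[!pos, k])),
                1e-12)
    }
  }
})

test_that("AUCs match an established ROC implementation", {
  set.seed(51)
  n <- 80
  truth <- sample(oct_classes(), n, replace = TRUE)
  raw <- matrix(runif(n * 3), n, 3)
  proba <- raw / rowSums(raw)
  r <- roc_analysis(truth, proba)
  for (k in 1:3) {
    cl <- oct_classes()[k]
    ref <- pROC::roc(response = truth == cl, predictor = proba[, k],
                     quiet = TRUE, direction = "<")
    expect_lt(abs(r$per_class[[cl]]$auc - as.numeric(ref$auc)), 1e-9)
  }
})

test_that("ROC curves are monotone from (0,0) to (1,1) and permutation-invariant", {
  set.seed(61)
  n <- 60
  truth <- sample(oct_classes(), n, replace = TRUE)
  raw <- matrix(runif(n * 3), n, 3)
  proba <- raw / rowSums(raw)
  r <- roc_analysis(truth, proba)
  for (curve in c(r$per_class, list(r$micro, r$macro))) {
    expect_equal(curve$fpr[1], 0)
    expect_equal(curve$tpr[1], 0)
    expect_equal(utils::tail(curve$fpr, 1), 1)
    expect_equal(utils::tail(curve$tpr, 1), 1)
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= -1e-12))
  }
  # relabel classes by a permutation: micro and macro AUC must be unchanged
  sigma <- c(normal = "cnv", drusen = "normal", cnv = "drusen")
  truth_p <- unname(sigma[truth])
  proba_p <- proba
  for (o in oct_classes()) proba_p[, match(sigma[[o]], oct_classes())] <- proba[, match(o, oct_classes())]
  rp <- roc_analysis(truth_p, proba_p)
  expect_equal(rp$micro$auc, r$micro$auc, tolerance = 1e-12)
  expect_equal(rp$macro$auc, r$macro$auc, tolerance = 1e-12)
})

test_that("accuracy via the confusion matrix equals direct accuracy", {
  set.seed(71)
  truth <- sample(oct_classes(), 150, replace = TRUE)
  pred <- sample(oct_classes(), 150, replace = TRUE)
  cm <- suppressWarnings(classification_metrics(confusion_matrix3(truth, pred)))
  expect_equal(cm$accuracy, mean(truth == pred))
})
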