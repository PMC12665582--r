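test_that("confusion counts follow the 0.5 cutoff with positive ties", {
  y <- c(1, 1, 0, 0)
  expect_equal(unclass(confusion(y, c(1, 1, 0, 0)))[c("FP", "FN")],
               list(FP = 0L, FN = 0L), ignore_attr = TRUE)
  cm0 <- confusion(c(1, 1, 0), c(0, 0, 0))
  expect_equal(c(cm0$TP, cm0$FP, cm0$FN, cm0$TN), c(0, 0, 2, 1))
  # probability exactly 0.5 classifies positive
  cmt <- confusion(0, 0.5)
  expect_equal(cmt$FP, 1)
  expect_error(confusion(c(1, 0), 0.4), "length mismatch")
  expect_error(confusion(1, 1.2), "probabilities")
})

test_that("metrics evaluate their defining formulas exactly", {
  perfect <- structure(list(TP = 50, TN = 50, FP = 0, FN = 0),
                       class = "confusion_matrix")
  expect_equal(as.numeric(classification_metrics(perfect)), rep(1, 4))

  cm <- structure(list(TP = 40, FP = 10, FN = 20, TN = 30),
                  class = "confusion_matrix")
  m <- classification_metrics(cm)
  expect_equal(unname(m["accuracy"]), 0.70)
  expect_equal(unname(m["precision"]), 0.80)
  expect_equal(unname(m["recall"]), 0.6667, tolerance = 1e-4)
  expect_equal(unname(m["F1"]), 0.7273, tolerance = 1e-4)

  nopos <- structure(list(TP = 0, FP = 0, FN = 5, TN = 5),
                     class = "confusion_matrix")
  mn <- classification_metrics(nopos)
  expect_equal(unname(mn[c("precision", "recall", "F1")]), c(0, 0, 0))
  expect_true(attr(mn, "flag"))
})

test_that("AUC equals the pairwise-ordering oracle", {
  # oracle: fraction of (positive, negative) pairs ranked correctly (+ half ties)
  auc_oracle <- function(y, p) {
    pos <- p[y == 1]
    neg <- p[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))$auc, 0)
  set.seed(91)
  for (i in 1:300) {
    n <- sample(5:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties
    expect_equal(roc_auc(y, p)$auc, auc_oracle(y, p), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("Friedman statistic and exact p match the permutation oracle", {
  # 5 folds x 3 models with a perfect, repeated ordering
  M <- matrix(rep(c(3, 2, 1), each = 5), 5, 3)
  fr <- friedman_eval(M)
  expect_equal(fr$statistic, 10)

  ex <- friedman_eval(M, exact = TRUE)
  # brute-force oracle over all 6^5 orderings
  perms <- sleepdepEEG:::permutations_(3)
  stats_all <- sleepdepEEG:::exact_friedman_dist(M, perms)
  expect_length(stats_all, 6^5)
  p_oracle <- mean(stats_all >= 10 - 1e-12)
  expect_equal(ex$p_value, p_oracle, tolerance = 1e-9)
  # the maximum is reached only when every fold repeats one common ordering
  expect_equal(p_oracle, 6 / 6^5)
})

test_that("Friedman handles ties, constants and monotone invariance", {
  M0 <- matrix(0.7, 6, 3)
  fr0 <- friedman_eval(M0)
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p_value, 1)

  set.seed(92)
  M <- matrix(runif(15), 5, 3)
  f1 <- friedman_eval(M)
  f2 <- friedman_eval(exp(3 * M)) # strictly monotone transform
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)

  # agreement with the base-R implementation on tie-free data
  fb <- stats::friedman.test(M)
  expect_equal(f1$statistic, unname(fb$statistic), tolerance = 1e-12)
  expect_equal(f1$p_value, unname(fb$p.value), tolerance = 1e-12)
})

test_that("Dunn post hoc is antisymmetric, bounded and Holm-adjusted", {
  set.seed(93)
  M <- matrix(runif(35), 5, 7)
  colnames(M) <- paste0("m", 1:7)
  d <- dunn_posthoc(M)
  # antisymmetry via recompute with swapped column order
  Mr <- M[, 7:1]
  dr <- dunn_posthoc(Mr)
  ab <- d[d$model_a == "m1" & d$model_b == "m2", "rank_sum_diff"]
  ba <- dr[dr$model_a == "m2" & dr$model_b == "m1", "rank_sum_diff"]
  expect_equal(ab, -ba)
  expect_true(all(d$p_adj >= d$p_raw - 1e-15))

  # one model always first, one always last -> |diff| = n(k-1) = 30
  M2 <- matrix(runif(35, 0.4, 0.6), 5, 7)
  M2[, 1] <- 1
  M2[, 7] <- 0
  colnames(M2) <- paste0("m", 1:7)
  d2 <- dunn_posthoc(M2)
  expect_equal(d2[d2$model_a == "m1" & d2$model_b == "m7", "rank_sum_diff"], 30)
  expect_equal(max(abs(d2$rank_sum_diff)), 30)
})

test_that("metric aggregation reports mean and n-1 SD per model", {
  res <- list(
    A = lapply(1:5, function(i) structure(list(
      fold_index = i, metrics = c(accuracy = 0.9 + i / 100, precision = 0.9,
                                  recall = 0.9, F1 = 0.9, AUC = 0.95)),
      class = "fold_result")),
    B = lapply(1:5, function(i) structure(list(
      fold_index = i, metrics = c(accuracy = 0.8, precision = 0.8,
                                  recall = 0.8, F1 = 0.8, AUC = 0.85)),
      class = "fold_result"))
  )
  mt <- metric_table(res)
  accA <- mt$summary[mt$summary$model == "A" & mt$summary$metric == "accuracy", ]
  expect_equal(accA$mean, mean(0.9 + (1:5) / 100))
  expect_equal(accA$sd, sd(0.9 + (1:5) / 100))
  cmp <- compare_models(mt$per_fold)
  expect_named(cmp, c("accuracy", "F1", "AUC"))
  expect_lt(cmp$accuracy$friedman$p_value, 0.05)
})
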