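test_that("epoch-level folds are stratified shuffled partitions", {
  y <- rep(c(0L, 1L), each = 50)
  plan <- make_epoch_folds(y, k = 5, seed = 4)
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(all_test, seq_along(y)) # every row in exactly one test fold
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    tab <- table(factor(y[f$test], levels = c(0, 1)))
    expect_true(all(abs(tab - 10) <= 1))
  }
  expect_identical(make_epoch_folds(y, 5, seed = 4)$folds, plan$folds)
  expect_false(identical(make_epoch_folds(y, 5, seed = 5)$folds, plan$folds))
  expect_error(make_epoch_folds(rep(0L, 10), 5), "both classes")
})

test_that("subject-level folds never split a subject and balance classes", {
  set.seed(7)
  subj <- rep(sprintf("S%02d", 1:10), each = 12)
  y <- rep(rep(c(0L, 1L), each = 6), 10)
  plan <- make_subject_folds(y, subj, k = 5)
  for (f in plan$folds) {
    expect_length(intersect(unique(subj[f$train]), unique(subj[f$test])), 0)
    expect_gt(length(f$test), 0)
    # paired design -> equal label counts inside each fold
    expect_equal(sum(y[f$test] == 0), sum(y[f$test] == 1))
    p <- mean(y[f$test])
    expect_lt(abs(p - 0.5), 0.05)
  }
  expect_error(make_subject_folds(y, subj, k = 11), "exceeds")

  # unequal epochs per subject still fill every fold
  keep <- seq_along(y)[-(1:10)]
  plan2 <- make_subject_folds(y[keep], subj[keep], k = 5)
  expect_true(all(vapply(plan2$folds, function(f) length(f$test), integer(1)) > 0))
})

test_that("randomized search draws the pinned number of distinct candidates", {
  sp <- default_search_space("rf", n_candidates = 25, seed = 2)
  cfgs <- sample_configs(sp)
  expect_length(cfgs, 25)
  keys <- vapply(cfgs, function(c) paste(unlist(c), collapse = "|"), character(1))
  expect_false(any(duplicated(keys))) # without replacement
  expect_identical(sample_configs(sp), cfgs) # seeded
  expect_named(cfgs[[1]], c("n_estimators", "max_depth", "criterion",
                            "max_features", "bootstrap"))
  # capped at grid size
  small <- search_space("svc", list(C = c(1, 10), kernel = "linear"),
                        n_candidates = 25, seed = 1)
  expect_length(sample_configs(small), 2)
  expect_named(sample_configs(default_search_space("xgboost"))[[1]],
               c("n_estimators", "learning_rate", "max_depth", "subsample",
                 "colsample_bytree"))
  expect_named(sample_configs(default_search_space("svc"))[[1]],
               c("C", "kernel", "gamma"))
})

test_that("inner search evaluates all candidates and finds a planted winner", {
  sp <- search_space("rf", list(n_estimators = c(1, 200)), n_candidates = 25,
                     seed = 1)
  cfgs <- sample_configs(sp)
  expect_length(cfgs, 2) # capped at the 2-point grid
  wins <- vapply(1:10, function(s) {
    fm <- toy_feature_matrix(seed = s, n = 60, p = 10, shift = 1.2)
    sr <- inner_search(fm$X, fm$meta$label, sp, seed = s)
    sr$best$n_estimators == 200
  }, logical(1))
  expect_gte(sum(wins), 9)
  # same seed -> same candidate sequence and same winner
  fm <- toy_feature_matrix(seed = 3, n = 60, p = 10)
  s1 <- inner_search(fm$X, fm$meta$label, sp, seed = 7)
  s2 <- inner_search(fm$X, fm$meta$label, sp, seed = 7)
  expect_identical(s1$best, s2$best)
  expect_identical(s1$scores, s2$scores)
})

test_that("all three learners run through the identical harness", {
  fm <- toy_feature_matrix(seed = 11, n = 60, p = 12, shift = 2)
  for (model in c("rf", "xgboost", "svc")) {
    sp <- default_search_space(model, n_candidates = 2, seed = 1)
    m <- fit_model(model, fm$X, fm$meta$label, sample_configs(sp)[[1]], seed = 1)
    p <- predict_prob(m, fm$X)
    expect_length(p, nrow(fm$X))
    expect_true(all(p >= 0 & p <= 1))
    expect_gt(suppressWarnings(cor(p, fm$meta$label)), 0.5)
  }
})

test_that("nested CV is leakage-safe and learns separable simulated cohorts", {
  fx <- fixture_strong()
  fm <- fx$fm
  sp <- search_space("rf", list(n_estimators = c(100, 200)), n_candidates = 2,
                     seed = 1)
  plan <- make_epoch_folds(fm$meta$label, k = 5, seed = 1)
  res <- run_nested_cv(fm, plan, sp, seed = 1)
  expect_length(res, 5)
  acc <- vapply(res, function(r) r$metrics[["accuracy"]], numeric(1))
  # strong effects, no fingerprints -> high epoch-level accuracy
  expect_gt(mean(acc), 0.9)
  for (r in res) {
    expect_true(all(r$prob >= 0 & r$prob <= 1))
    expect_length(r$prob, length(r$test))
    expect_length(r$selection$combined, 100)
  }

  # perturbing outer-test rows changes neither selection nor parameters
  fm2 <- fm
  f1_test <- plan$folds[[1]]$test
  fm2$X[f1_test, ] <- fm2$X[f1_test, ] * 5 + 100
  res2 <- run_nested_cv(fm2, structure(list(level = "epoch", k = 1, seed = 1L,
                                            folds = plan$folds[1]),
                                       class = "fold_plan"), sp, seed = 1)
  expect_identical(res2[[1]]$selection$combined, res[[1]]$selection$combined)
  expect_identical(res2[[1]]$params, res[[1]]$params)
})
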