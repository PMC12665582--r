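#' Stratified shuffled k-fold plan at the epoch level
#'
#' Rows of each class are shuffled (seeded) and dealt round-robin to `k`
#' test folds, so per-fold class proportions stay within rounding of the
#' global proportions. Train/test pairs partition all rows.
#'
#' @param labels Binary labels (0/1), one per row.
#' @param k Number of outer folds (default 5).
#' @param seed Shuffle seed.
#' @return Object of class `fold_plan`: list with `level = "epoch"`, `k`,
#'   `seed`, and `folds` (list of `list(train, test)` row indices).
#' @export
make_epoch_folds <- function(labels, k = 5, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (min(table(labels)) < k) stop("need at least k rows per class")
  assign_fold <- integer(length(labels))
  set.seed(as.integer(seed))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign_fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds <- lapply(seq_len(k), function(f) {
    test <- which(assign_fold == f)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
  structure(list(level = "epoch", k = k, seed = as.integer(seed), folds = folds),
            class = "fold_plan")
}

#' Stratified group k-fold plan at the subject level
#'
#' Whole subjects are assigned to test folds greedily (by descending epoch
#' count) to the fold that minimises the squared deviation of class
#' proportions from the global proportions (with a mild size-balance term),
#' so no subject ever appears in both train and test of any fold.
#' Deterministic given its inputs.
#'
#' @param labels Binary labels per row.
#' @param subject_ids Subject identifier per row.
#' @param k Number of folds (default 5; must not exceed the subject count).
#' @return A `fold_plan` with `level = "subject"` and per-fold subject sets.
#' @export
make_subject_folds <- function(labels, subject_ids, k = 5) {
  labels <- as.integer(labels)
  subjects <- unique(subject_ids)
  if (k > length(subjects)) stop("k exceeds number of subjects")
  counts <- t(vapply(subjects, function(s) {
    rows <- subject_ids == s
    c(n0 = sum(labels[rows] == 0), n1 = sum(labels[rows] == 1))
  }, numeric(2)))
  total <- colSums(counts)
  ideal <- total / k # ideal per-fold class counts
  ord <- order(-rowSums(counts), subjects)
  fold_counts <- matrix(0, k, 2)
  fold_of <- stats::setNames(integer(length(subjects)), subjects)
  for (si in ord) {
    best <- 1L; best_cost <- Inf
    for (f in seq_len(k)) {
      cand <- fold_counts
      cand[f, ] <- cand[f, ] + counts[si, ]
      cost <- sum((sweep(cand, 2, ideal))^2)
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- f }
    }
    fold_counts[best, ] <- fold_counts[best, ] + counts[si, ]
    fold_of[subjects[si]] <- best
  }
  folds <- lapply(seq_len(k), function(f) {
    test_subjects <- subjects[fold_of == f]
    test <- which(subject_ids %in% test_subjects)
    list(train = setdiff(seq_along(labels), test), test = test,
         test_subjects = test_subjects)
  })
  structure(list(level = "subject", k = k, seed = NA_integer_, folds = folds),
            class = "fold_plan")
}

#' Default hyperparameter grids (randomised-search candidate values)
#'
#' Grid dimension names follow the standard tuning surfaces of each
#' learner; the candidate values are package defaults and fully
#' overridable. Models: `"rf"` (random forest via ranger: n_estimators,
#' max_depth, criterion, max_features, bootstrap), `"xgboost"`
#' (n_estimators, learning_rate, max_depth, subsample, colsample_bytree),
#' `"svc"` (C, kernel, gamma).
#'
#' @param model One of `"rf"`, `"xgboost"`, `"svc"`.
#' @param n_candidates Number of randomised-search draws (default 25).
#' @param seed Seed for the candidate draws.
#' @return Object of class `search_space`.
#' @export
default_search_space <- function(model = c("rf", "xgboost", "svc"),
                                 n_candidates = 25, seed = 1L) {
  model <- match.arg(model)
  grid <- switch(model,
    rf = list(n_estimators = c(100, 200, 400),
              max_depth = c(3, 6, 10, 0), # 0 = unlimited
              criterion = c("gini", "hellinger"),
              max_features = c("sqrt", 0.2, 0.5),
              bootstrap = c(TRUE, FALSE)),
    xgboost = list(n_estimators = c(100, 200, 400),
                   learning_rate = c(0.01, 0.05, 0.1),
                   max_depth = c(3, 6, 10),
                   subsample = c(0.7, 1),
                   colsample_bytree = c(0.7, 1)),
    svc = list(C = c(0.1, 1, 10, 100),
               kernel = c("rbf", "linear"),
               gamma = c("scale", 0.01, 0.001))
  )
  search_space(model, grid, n_candidates = n_candidates, seed = seed)
}

#' Construct a search space from an explicit grid
#' @param model Model name.
#' @param grid Named list of candidate value vectors.
#' @param n_candidates Number of candidates to draw (capped at grid size).
#' @param seed Draw seed.
#' @return Object of class `search_space`.
#' @export
search_space <- function(model, grid, n_candidates = 25, seed = 1L) {
  structure(list(model = model, grid = grid,
                 n_candidates = n_candidates, seed = as.integer(seed)),
            class = "search_space")
}

#' Draw the randomised-search candidate configurations
#'
#' Uniform draws without replacement from the grid's Cartesian product
#' (capped at the grid size), reproducible from the space's seed.
#'
#' @param space A `search_space`.
#' @return List of named parameter lists, in draw order.
#' @export
sample_configs <- function(space) {
  stopifnot(inherits(space, "search_space"))
  sizes <- vapply(space$grid, length, integer(1))
  total <- prod(sizes)
  n <- min(space$n_candidates, total)
  set.seed(space$seed)
  picks <- sample.int(total, n)
  lapply(picks, function(ix) {
    ix <- ix - 1L
    cfg <- vector("list", length(sizes))
    names(cfg) <- names(space$grid)
    for (d in seq_along(sizes)) {
      cfg[[d]] <- space$grid[[d]][ix %% sizes[d] + 1L]
      ix <- ix %/% sizes[d]
    }
    cfg
  })
}

# ---- model registry ----

fit_model <- function(model, X, y, params, seed = 1L) {
  y <- as.integer(y)
  if (model == "rf") {
    mf <- params$max_features
    mtry <- if (identical(mf, "sqrt") || is.null(mf)) {
      max(1, floor(sqrt(ncol(X))))
    } else {
      max(1, floor(as.numeric(mf) * ncol(X)))
    }
    fit <- ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
      num.trees = params$n_estimators %||% 200,
      max.depth = params$max_depth %||% 0,
      splitrule = params$criterion %||% "gini",
      mtry = mtry,
      replace = isTRUE(params$bootstrap %||% TRUE),
      sample.fraction = if (isTRUE(params$bootstrap %||% TRUE)) 1 else 0.632,
      probability = TRUE, num.threads = 1, seed = seed)
    structure(list(model = "rf", fit = fit, features = colnames(X)),
              class = "sdeeg_model")
  } else if (model == "xgboost") {
    fit <- xgboost::xgb.train(
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = params$n_estimators %||% 200,
      params = list(objective = "binary:logistic",
                    eta = params$learning_rate %||% 0.1,
                    max_depth = params$max_depth %||% 6,
                    subsample = params$subsample %||% 1,
                    colsample_bytree = params$colsample_bytree %||% 1,
                    nthread = 1, seed = seed),
      verbose = 0)
    structure(list(model = "xgboost", fit = fit, features = colnames(X)),
              class = "sdeeg_model")
  } else if (model == "svc") {
    gamma <- params$gamma %||% "scale"
    if (identical(gamma, "scale")) {
      v <- mean(apply(X, 2, stats::var))
      gamma <- if (v > 0) 1 / (ncol(X) * v) else 1 / ncol(X)
    } else {
      gamma <- as.numeric(gamma)
    }
    kernel <- switch(params$kernel %||% "rbf", rbf = "radial",
                     linear = "linear", params$kernel)
    fit <- local({
      set.seed(seed) # probability calibration is internally cross-validated
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                 cost = params$C %||% 1, kernel = kernel, gamma = gamma,
                 probability = TRUE, scale = FALSE)
    })
    structure(list(model = "svc", fit = fit, features = colnames(X)),
              class = "sdeeg_model")
  } else {
    stop("unknown model: ", model)
  }
}

predict_prob <- function(object, X) {
  X <- X[, object$features, drop = FALSE]
  if (object$model == "rf") {
    p <- stats::predict(object$fit, data = as.data.frame(X),
                        num.threads = 1)$predictions
    unname(p[, "1"])
  } else if (object$model == "xgboost") {
    unname(stats::predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1)))
  } else {
    p <- attr(stats::predict(object$fit, X, probability = TRUE),
              "probabilities")
    unname(p[, "1"])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Randomised inner search over hyperparameter candidates
#'
#' Evaluates each drawn candidate with stratified `k_inner`-fold
#' cross-validation on the (already scaled and feature-selected) training
#' rows, scoring by mean validation accuracy; ties keep the first-drawn
#' candidate. Degenerate inner folds (a single class in training) are
#' skipped with a flag.
#'
#' @param X Training matrix (scaled, selected features).
#' @param y Binary labels.
#' @param space A `search_space`.
#' @param k_inner Number of inner folds (default 3).
#' @param seed Seed for the inner fold split and model fits.
#' @return List with `best` (parameter list), `scores` (mean accuracy per
#'   candidate), `configs`.
#' @export
inner_search <- function(X, y, space, k_inner = 3, seed = 1L) {
  configs <- sample_configs(space)
  inner <- make_epoch_folds(y, k = k_inner, seed = seed + 1L)
  scores <- vapply(configs, function(cfg) {
    accs <- vapply(inner$folds, function(f) {
      ytr <- y[f$train]
      if (length(unique(ytr)) < 2) return(NA_real_)
      m <- fit_model(space$model, X[f$train, , drop = FALSE], ytr, cfg,
                     seed = seed)
      p <- predict_prob(m, X[f$test, , drop = FALSE])
      mean((p >= 0.5) == (y[f$test] == 1))
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores) # ties -> first drawn
  list(best = configs[[best]], scores = scores, configs = configs)
}

#' Run the nested cross-validation pipeline
#'
#' Per outer fold: fit the 0-1 scaler and the chi-squared + NCA selection on
#' the outer-training rows only; run the randomised inner search
#' (stratified `k_inner`-fold) on the selected features; retrain the winner
#' on the full outer-training partition; predict held-out probabilities and
#' labels at the 0.5 cutoff.
#'
#' @param fm A `feature_matrix` (see [extract_feature_matrix()]).
#' @param plan A `fold_plan` from [make_epoch_folds()] or
#'   [make_subject_folds()].
#' @param space A `search_space`.
#' @param k_inner Inner folds (default 3).
#' @param select Run the chi2+NCA selection (default TRUE; FALSE uses all
#'   features, for diagnostics only).
#' @param seed Base seed for inner splits and model fits.
#' @return List of per-fold results (class `fold_result`): fold index,
#'   model, chosen parameters, `selection`, `test` indices, `prob`, `pred`,
#'   and `metrics` (accuracy, precision, recall, F1, AUC).
#' @export
run_nested_cv <- function(fm, plan, space, k_inner = 3, select = TRUE,
                          seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(plan, "fold_plan"))
  y <- fm$meta$label
  lapply(seq_along(plan$folds), function(fi) {
    f <- plan$folds[[fi]]
    Xtr <- fm$X[f$train, , drop = FALSE]
    ytr <- y[f$train]
    scaler <- fit_scaler(Xtr)
    Xtr01 <- apply_scaler(scaler, Xtr)
    if (select) {
      sel <- select_features(Xtr01, ytr, nca_seed = seed + fi)
      feats <- sel$combined
    } else {
      sel <- NULL
      feats <- colnames(fm$X)
    }
    sr <- inner_search(Xtr01[, feats, drop = FALSE], ytr, space,
                       k_inner = k_inner, seed = seed + 100 * fi)
    model <- fit_model(space$model, Xtr01[, feats, drop = FALSE], ytr,
                       sr$best, seed = seed + 100 * fi)
    Xte01 <- apply_scaler(scaler, fm$X[f$test, , drop = FALSE])
    prob <- predict_prob(model, Xte01[, feats, drop = FALSE])
    pred <- as.integer(prob >= 0.5)
    yte <- y[f$test]
    cm <- confusion(yte, prob)
    mets <- c(classification_metrics(cm), AUC = roc_auc(yte, prob)$auc)
    structure(list(fold_index = fi, model = space$model, params = sr$best,
                   selection = sel, scaler = scaler, features = feats,
                   fitted = model, test = f$test, prob = prob, pred = pred,
                   metrics = mets),
              class = "fold_result")
  })
}

#' Aggregate fold metrics into a per-model summary table
#'
#' @param results Named list: one entry per model, each a list of
#'   `fold_result`s from [run_nested_cv()].
#' @return List with `per_fold` (folds x metrics per model) and `summary`
#'   (mean and SD over folds; SD uses the n-1 denominator).
#' @export
metric_table <- function(results) {
  stopifnot(length(results) > 0, !is.null(names(results)))
  per_fold <- lapply(results, function(res) {
    t(vapply(res, function(fr) fr$metrics, numeric(5)))
  })
  summary <- do.call(rbind, lapply(names(per_fold), function(m) {
    M <- per_fold[[m]]
    data.frame(model = m, metric = colnames(M),
               mean = colMeans(M), sd = apply(M, 2, stats::sd),
               row.names = NULL)
  }))
  list(per_fold = per_fold, summary = summary)
}
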