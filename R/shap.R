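sigmoid_ <- function(x) 1 / (1 + exp(-x))

#' Per-sample SHAP values for one cross-validation fold
#'
#' Attributions are computed on the fold's held-out test rows only, on the
#' probability scale for every model family so magnitudes are comparable.
#' Tree path (XGBoost): exact tree SHAP on the margin, rescaled linearly to
#' the probability scale (the rescaling preserves exact additivity:
#' per-row SHAP sum + base equals the predicted probability). Other models:
#' permutation-sampling model-agnostic SHAP against a seeded background
#' subsample (at most `background_max` training rows); the telescoping sum
#' over each permutation makes the estimate exactly locally accurate with
#' base value `mean(f(background))`.
#'
#' @param fr A `fold_result` from [run_nested_cv()].
#' @param fm The `feature_matrix` the folds were computed on.
#' @param background_max Background row cap (default 200, truncated with a
#'   seeded subsample and a message when exceeded).
#' @param budget Model-call budget per test row for the model-agnostic path
#'   (default `2 * nfeatures + 2048`).
#' @param seed Seed for background subsampling and permutations.
#' @return List with `shap` (test rows x selected features), `base`
#'   (per-row base value), `prob` (predicted probabilities), `features`,
#'   `test` (row indices), and `values01` (0-1 scaled feature values of the
#'   test rows, for beeswarm-style displays).
#' @export
fold_shap <- function(fr, fm, background_max = 200, budget = NULL,
                      seed = 1L) {
  stopifnot(inherits(fr, "fold_result"), inherits(fm, "feature_matrix"))
  feats <- fr$features
  Xte <- apply_scaler(fr$scaler, fm$X[fr$test, , drop = FALSE])[, feats, drop = FALSE]
  if (fr$model == "xgboost") {
    contrib <- stats::predict(fr$fitted$fit,
                              xgboost::xgb.DMatrix(Xte, nthread = 1),
                              predcontrib = TRUE)
    j <- seq_len(ncol(Xte))
    base_m <- contrib[, ncol(contrib)]
    margin <- rowSums(contrib)
    p <- sigmoid_(margin)
    p0 <- sigmoid_(base_m)
    dm <- margin - base_m
    factor <- ifelse(abs(dm) > 1e-12, (p - p0) / dm, p0 * (1 - p0))
    shap <- contrib[, j, drop = FALSE] * factor
    colnames(shap) <- feats
    out <- list(shap = shap, base = p0, prob = p)
  } else {
    train_rows <- setdiff(seq_len(nrow(fm$X)), fr$test)
    Xbg_all <- apply_scaler(fr$scaler,
                            fm$X[train_rows, , drop = FALSE])[, feats, drop = FALSE]
    set.seed(as.integer(seed))
    if (nrow(Xbg_all) > background_max) {
      message("background truncated to ", background_max, " seeded rows")
      Xbg_all <- Xbg_all[sample.int(nrow(Xbg_all), background_max), , drop = FALSE]
    }
    out <- sampling_shap(fr$fitted, Xte, Xbg_all, budget = budget, seed = seed)
  }
  out$features <- feats
  out$test <- fr$test
  out$values01 <- Xte
  out
}

# Permutation-sampling Shapley attribution on the probability scale.
# For each test row, feature-permutation walks from a background row to the
# test row telescope to f(x) - mean(f(background)), so additivity is exact.
sampling_shap <- function(model, Xte, Xbg, budget = NULL, seed = 1L) {
  p <- ncol(Xte)
  if (is.null(budget)) budget <- 2 * p + 2048
  pairs <- max(1, budget %/% (p + 1))
  n_bg <- min(nrow(Xbg), max(1, pairs %/% 2))
  n_perm <- max(1, pairs %/% n_bg)
  set.seed(as.integer(seed))
  bg_idx <- sample.int(nrow(Xbg), n_bg)
  perms <- lapply(seq_len(n_perm), function(i) sample.int(p))
  base_pred <- predict_prob(model, Xbg)
  shap <- matrix(0, nrow(Xte), p, dimnames = list(NULL, colnames(Xte)))
  for (r in seq_len(nrow(Xte))) {
    x <- Xte[r, ]
    total <- matrix(0, n_perm * n_bg, p + 1)
    # build all hybrid rows: for each (perm, bg) a walk of p+1 points
    H <- matrix(0, n_perm * n_bg * (p + 1), p,
                dimnames = list(NULL, colnames(Xte)))
    row <- 0L
    for (pe in seq_len(n_perm)) {
      pi <- perms[[pe]]
      for (b in seq_len(n_bg)) {
        z <- Xbg[bg_idx[b], ]
        H[row + 1L, ] <- z
        for (t in seq_len(p)) {
          z[pi[t]] <- x[pi[t]]
          H[row + t + 1L, ] <- z
        }
        row <- row + p + 1L
      }
    }
    preds <- predict_prob(model, H)
    preds <- matrix(preds, ncol = p + 1, byrow = TRUE)
    acc <- numeric(p)
    i <- 0L
    for (pe in seq_len(n_perm)) {
      pi <- perms[[pe]]
      for (b in seq_len(n_bg)) {
        i <- i + 1L
        acc[pi] <- acc[pi] + diff(preds[i, ])
      }
    }
    shap[r, ] <- acc / (n_perm * n_bg)
    total <- NULL
  }
  base <- mean(base_pred[bg_idx])
  prob <- base + rowSums(shap)
  list(shap = shap, base = rep(base, nrow(Xte)), prob = prob)
}

#' Global SHAP importance aligned across folds
#'
#' Restricts to the intersection of the per-fold selected feature sets and
#' pools the per-sample |SHAP| over all test rows of all folds; features
#' are ranked by descending mean |SHAP| (ties break by name order).
#'
#' @param fold_shaps List of [fold_shap()] results (>= 1).
#' @return Object of class `shap_summary`: list with `ranking` (data.frame
#'   `feature`, `mean_abs_shap`), `aligned_features`, `shap` (pooled rows x
#'   aligned features), `values01` (matching 0-1 feature values), `rows`
#'   (original row indices).
#' @export
global_importance <- function(fold_shaps) {
  stopifnot(length(fold_shaps) >= 1)
  sets <- lapply(fold_shaps, `[[`, "features")
  aligned <- Reduce(intersect, sets)
  if (length(aligned) == 0) {
    stop("empty intersection of fold feature sets; per-fold sizes: ",
         paste(vapply(sets, length, integer(1)), collapse = ", "))
  }
  shap <- do.call(rbind, lapply(fold_shaps, function(f)
    f$shap[, aligned, drop = FALSE]))
  vals <- do.call(rbind, lapply(fold_shaps, function(f)
    f$values01[, aligned, drop = FALSE]))
  rows <- unlist(lapply(fold_shaps, `[[`, "test"))
  imp <- colMeans(abs(shap))
  ord <- order(-imp, names(imp))
  structure(list(
    ranking = data.frame(feature = names(imp)[ord],
                         mean_abs_shap = unname(imp[ord]),
                         stringsAsFactors = FALSE),
    aligned_features = aligned,
    shap = shap, values01 = vals, rows = rows
  ), class = "shap_summary")
}

#' Spearman correlation of the top-10 SHAP-ranked features
#'
#' Rank correlation on the raw (unscaled) feature values over all epochs;
#' symmetric with unit diagonal. Constant features yield 0 correlations and
#' set the `flag` attribute.
#'
#' @param fm The `feature_matrix`.
#' @param summary A `shap_summary` with at least 10 aligned features.
#' @param n_top Number of top features (default 10).
#' @return Correlation matrix (n_top x n_top) with `flag` attribute.
#' @export
spearman_top10 <- function(fm, summary, n_top = 10) {
  stopifnot(inherits(summary, "shap_summary"))
  if (nrow(summary$ranking) < n_top) {
    stop("need at least ", n_top, " aligned features")
  }
  top <- summary$ranking$feature[seq_len(n_top)]
  X <- fm$X[, top, drop = FALSE]
  const <- apply(X, 2, function(v) max(v) == min(v))
  C <- suppressWarnings(stats::cor(X, method = "spearman"))
  C[const, ] <- 0
  C[, const] <- 0
  diag(C) <- 1
  attr(C, "flag") <- any(const)
  C
}
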