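#' Confusion matrix at a probability cutoff
#'
#' Class 1 (sleep-deprived) is the positive class; a row is predicted
#' positive iff its probability is at or above the cutoff (ties at exactly
#' 0.5 classify positive).
#'
#' @param y_true Binary labels (0/1).
#' @param y_prob Predicted probabilities of class 1, in `[0, 1]`.
#' @param threshold Cutoff (default 0.5).
#' @return Object of class `confusion_matrix`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) stop("length mismatch")
  if (any(y_prob < 0 | y_prob > 1)) stop("probabilities outside [0, 1]")
  y_true <- as.integer(y_true)
  pred <- as.integer(y_prob >= threshold)
  structure(list(TP = sum(pred == 1 & y_true == 1),
                 TN = sum(pred == 0 & y_true == 0),
                 FP = sum(pred == 1 & y_true == 0),
                 FN = sum(pred == 0 & y_true == 1)),
            class = "confusion_matrix")
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`; a zero denominator
#' yields 0 for the affected metric (flagged via attribute).
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector (`accuracy`, `precision`, `recall`, `F1`).
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  if (n == 0) stop("empty confusion matrix")
  flag <- FALSE
  div <- function(num, den) {
    if (den == 0) { flag <<- TRUE; 0 } else num / den
  }
  prec <- div(cm$TP, cm$TP + cm$FP)
  rec <- div(cm$TP, cm$TP + cm$FN)
  f1 <- div(2 * prec * rec, prec + rec)
  out <- c(accuracy = (cm$TP + cm$TN) / n, precision = prec,
           recall = rec, F1 = f1)
  attr(out, "flag") <- flag
  out
}

#' ROC curve and area under it
#'
#' Threshold sweep over the unique scores (ties cross simultaneously),
#' trapezoidal area over the (FPR, TPR) points.
#'
#' @param y_true Binary labels (both classes must be present).
#' @param y_prob Scores (higher = more positive).
#' @return List with `auc`, and `fpr`/`tpr`/`thresholds` vectors.
#' @export
roc_auc <- function(y_true, y_prob) {
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2) stop("both classes required for ROC")
  ord <- order(-y_prob)
  ys <- y_true[ord]
  ps <- y_prob[ord]
  npos <- sum(ys == 1)
  nneg <- sum(ys == 0)
  tp <- cumsum(ys == 1)
  fp <- cumsum(ys == 0)
  last <- !duplicated(ps, fromLast = TRUE) # last index of each tied score
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, fpr = fpr, tpr = tpr, thresholds = c(Inf, ps[last]))
}

# within-row ranks with average tie handling, rows = blocks (folds)
row_ranks <- function(M) t(apply(M, 1, rank))

#' Friedman test across models over cross-validation folds
#'
#' Nonparametric repeated-measures omnibus test: metric values are ranked
#' within each fold (average ranks for ties) and the tie-corrected Friedman
#' chi-squared statistic is referred to the chi-squared distribution with
#' `k - 1` degrees of freedom. For small problems an exact p-value is
#' available by enumerating all within-fold rank orderings.
#'
#' @param M Numeric matrix, folds x models.
#' @param exact Use the exact permutation null (enumerates `k!^n` orderings;
#'   only sensible for small `k`, `n`).
#' @return List with `statistic`, `p_value`, `ranks` (rank sums per model),
#'   `method`.
#' @export
friedman_eval <- function(M, exact = FALSE) {
  stopifnot(is.matrix(M), nrow(M) >= 2, ncol(M) >= 2)
  n <- nrow(M)
  k <- ncol(M)
  R <- row_ranks(M)
  Rj <- colSums(R)
  stat_from_ranks <- function(R) {
    Rj <- colSums(R)
    num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
    # tie correction: sum over blocks of (sum r^2) compared with untied value
    den <- sum(R^2) - n * k * (k + 1)^2 / 4
    if (den <= 0) return(0)
    num / den
  }
  stat <- stat_from_ranks(R)
  if (exact) {
    perms <- permutations_(k)
    stats_all <- exact_friedman_dist(M, perms)
    p <- mean(stats_all >= stat - 1e-12)
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "chi-squared approximation"
  }
  list(statistic = stat, p_value = p, ranks = Rj, method = method)
}

permutations_ <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- permutations_(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# all k!^n assignments of within-fold orderings, applied to the observed
# tie pattern of each fold
exact_friedman_dist <- function(M, perms) {
  n <- nrow(M)
  k <- ncol(M)
  R_obs <- row_ranks(M)
  # rank rows per fold: the observed (possibly tied) ranks under every
  # permutation of the columns, each equally likely under the null
  per_fold <- lapply(seq_len(n), function(i) {
    t(apply(perms, 1, function(p) R_obs[i, p]))
  })
  counts <- vapply(per_fold, nrow, integer(1))
  idx <- rep(1L, n)
  total <- prod(counts)
  out <- numeric(total)
  R <- matrix(0, n, k)
  for (t in seq_len(total)) {
    for (i in seq_len(n)) R[i, ] <- per_fold[[i]][idx[i], ]
    Rj <- colSums(R)
    num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
    den <- sum(R^2) - n * k * (k + 1)^2 / 4
    out[t] <- if (den <= 0) 0 else num / den
    # increment mixed-radix counter
    for (i in seq_len(n)) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= counts[i]) break
      idx[i] <- 1L
    }
  }
  out
}

#' Dunn-style post hoc pairwise comparisons after Friedman
#'
#' For each model pair the difference of within-fold rank sums is referred
#' to the normal approximation with standard error
#' `sqrt(n * k * (k + 1) / 6)` (tie-corrected); p-values are adjusted by
#' Holm's step-down procedure (Bonferroni available).
#'
#' @param M Numeric matrix, folds x models (named columns recommended).
#' @param adjust `"holm"` (default) or `"bonferroni"`.
#' @return data.frame with one row per ordered pair (i < j): `model_a`,
#'   `model_b`, `rank_sum_diff` (a minus b; positive = a ranks higher),
#'   `z`, `p_raw`, `p_adj`.
#' @export
dunn_posthoc <- function(M, adjust = c("holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  n <- nrow(M)
  k <- ncol(M)
  R <- row_ranks(M)
  Rj <- colSums(R)
  # tie-corrected variance of a rank-sum difference
  tie_term <- sum(R^2) - n * k * (k + 1)^2 / 4
  se <- sqrt(2 * tie_term / (n * (k - 1)) * n)
  models <- colnames(M)
  if (is.null(models)) models <- paste0("model", seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    model_a = models[pairs[1, ]],
    model_b = models[pairs[2, ]],
    rank_sum_diff = Rj[pairs[1, ]] - Rj[pairs[2, ]],
    stringsAsFactors = FALSE
  )
  out$z <- out$rank_sum_diff / se
  out$p_raw <- 2 * stats::pnorm(-abs(out$z))
  out$p_adj <- stats::p.adjust(out$p_raw, method = adjust)
  rownames(out) <- NULL
  out
}

#' Friedman + Dunn report over a set of models and metrics
#'
#' @param per_fold Named list of folds x metrics matrices (one per model),
#'   as returned in `metric_table()$per_fold`.
#' @param metrics Which metric columns to analyse (default accuracy, F1,
#'   AUC).
#' @return Named list per metric: `friedman` result and `dunn` table.
#' @export
compare_models <- function(per_fold, metrics = c("accuracy", "F1", "AUC")) {
  stopifnot(length(per_fold) >= 2)
  out <- list()
  for (met in metrics) {
    M <- vapply(per_fold, function(x) x[, met], numeric(nrow(per_fold[[1]])))
    out[[met]] <- list(friedman = friedman_eval(M),
                       dunn = dunn_posthoc(M))
  }
  out
}
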