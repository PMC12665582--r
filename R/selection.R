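#' Fit a 0-1 range scaler on training rows only
#'
#' Stores per-feature training minima and maxima. Scaling test rows with the
#' trained state may produce values outside `[0, 1]`; no clipping is applied
#' (the chi-squared filter only ever sees training rows, which are in range
#' by construction).
#'
#' @param X Training feature matrix (rows x features, named columns).
#' @return Object of class `scaler_state` with `min`, `range`, and
#'   `constant` (logical per feature: zero training range, mapped to 0).
#' @export
fit_scaler <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2)
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  rg <- mx - mn
  structure(list(min = mn, range = rg, constant = rg == 0),
            class = "scaler_state")
}

#' Apply a fitted 0-1 scaler
#' @param state A `scaler_state` from [fit_scaler()].
#' @param X Matrix of rows to scale (same columns as the training matrix).
#' @return Scaled matrix; constant training features map to 0.
#' @export
apply_scaler <- function(state, X) {
  stopifnot(inherits(state, "scaler_state"))
  rg <- ifelse(state$constant, 1, state$range)
  out <- sweep(sweep(X, 2, state$min), 2, rg, "/")
  out[, state$constant] <- 0
  out
}

#' Univariate chi-squared feature filter
#'
#' For nonnegative (0-1 scaled) training features, each feature's observed
#' class-wise sums are compared with the expectation under the class priors:
#' `score_j = sum_c (O_jc - E_jc)^2 / E_jc` with `E_jc = prior_c * sum_i
#' x_ij`. The top `k` features by score are retained; ties break by
#' canonical column order.
#'
#' @param X01 Scaled training matrix (values >= 0).
#' @param y Binary labels (0/1), one per row.
#' @param k Number of features to retain (default 50).
#' @return List with `names` (top-k, score order), `scores` (all features).
#' @export
chi2_select <- function(X01, y, k = 50) {
  if (any(X01 < 0)) stop("chi-squared filter requires nonnegative input")
  stopifnot(nrow(X01) == length(y), k <= ncol(X01))
  y <- as.integer(y)
  priors <- c(mean(y == 0), mean(y == 1))
  O0 <- colSums(X01[y == 0, , drop = FALSE])
  O1 <- colSums(X01[y == 1, , drop = FALSE])
  tot <- O0 + O1
  E0 <- priors[1] * tot
  E1 <- priors[2] * tot
  sc <- numeric(ncol(X01))
  nz <- tot > 0
  sc[nz] <- (O0[nz] - E0[nz])^2 / E0[nz] + (O1[nz] - E1[nz])^2 / E1[nz]
  names(sc) <- colnames(X01)
  ord <- order(-sc, seq_along(sc)) # ties -> canonical column order
  list(names = colnames(X01)[ord[seq_len(k)]], scores = sc)
}

#' Neighbourhood-component-analysis feature weights
#'
#' Diagonal (per-feature) NCA for feature selection: weights `w` maximize
#' the expected leave-one-out soft-nearest-neighbour classification
#' objective with weighted distance `d(i,k) = sum_j w_j^2 |x_ij - x_kj|`,
#' minus an L2 penalty `lambda * sum_j w_j^2`. Optimised by adaptive
#' gradient ascent from `w = 1` (at most `max_iter` steps, early stop on
#' relative objective change below `tol`). For large training sets the LOO
#' objective is evaluated on a seeded stratified subsample of at most
#' `max_rows` rows. Features are ranked by `|w|`.
#'
#' @param X Scaled training matrix restricted to candidate features.
#' @param y Binary labels (0/1).
#' @param lambda L2 regularisation (default `1 / nrow(X)`).
#' @param max_iter Optimiser step budget (default 200).
#' @param tol Early-stopping tolerance on relative objective change.
#' @param max_rows Row cap for the LOO objective (default 128; the
#'   objective cost is quadratic in rows and linear in features).
#' @param seed Seed for the row subsample.
#' @return List with `weights` (named, `|w|`), `objective`, `iterations`,
#'   `converged`.
#' @export
nca_weights <- function(X, y, lambda = 1 / nrow(X), max_iter = 200,
                        tol = 1e-4, max_rows = 128, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("need both classes present")
  if (nrow(X) > max_rows) {
    idx <- local({
      set.seed(as.integer(seed))
      i0 <- which(y == 0)
      i1 <- which(y == 1)
      n0 <- round(max_rows * length(i0) / length(y))
      n1 <- max_rows - n0
      sort(c(sample(i0, min(n0, length(i0))), sample(i1, min(n1, length(i1)))))
    })
    X <- X[idx, , drop = FALSE]
    y <- y[idx]
  }
  fit <- cpp_nca_weights(X, y, lambda, as.integer(max_iter), tol)
  if (!fit$converged) {
    warning("NCA did not converge within ", max_iter, " iterations; ",
            "returning best iterate")
  }
  list(weights = stats::setNames(abs(as.numeric(fit$weights)), colnames(X)),
       objective = fit$objective,
       iterations = fit$iterations,
       converged = fit$converged)
}

#' Two-stage chi-squared + NCA feature selection
#'
#' Stage 1 retains the top `k_chi2` features by the univariate chi-squared
#' filter; stage 2 fits NCA on the complement and retains the `k_nca`
#' features with the largest `|w|`, so the combined set of
#' `k_chi2 + k_nca = 100` features is disjoint by construction.
#'
#' @param X01 Scaled (0-1) training matrix with named columns.
#' @param y Binary labels.
#' @param k_chi2,k_nca Stage sizes (defaults 50 + 50).
#' @param nca_seed Seed for the NCA row subsample.
#' @param ... Passed to [nca_weights()].
#' @return Object of class `selection_result`: list with `chi2_names`,
#'   `nca_names`, `combined`, `chi2_scores`, `nca_weights`.
#' @export
select_features <- function(X01, y, k_chi2 = 50, k_nca = 50,
                            nca_seed = 1L, ...) {
  if (ncol(X01) < k_chi2 + k_nca) {
    stop("need at least ", k_chi2 + k_nca, " features, got ", ncol(X01))
  }
  ch <- chi2_select(X01, y, k = k_chi2)
  rest <- setdiff(colnames(X01), ch$names)
  nw <- nca_weights(X01[, rest, drop = FALSE], y, seed = nca_seed, ...)
  ord <- order(-nw$weights, seq_along(nw$weights))
  nca_names <- rest[ord[seq_len(k_nca)]]
  structure(list(chi2_names = ch$names,
                 nca_names = nca_names,
                 combined = c(ch$names, nca_names),
                 chi2_scores = ch$scores,
                 nca_weights = nw$weights),
            class = "selection_result")
}
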