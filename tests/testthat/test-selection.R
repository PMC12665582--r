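test_that("0-1 scaling is train-fitted, exact at extremes and leakage-safe", {
  set.seed(81)
  X <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  X[, 3] <- 7 # constant feature
  sc <- fit_scaler(X)
  S <- apply_scaler(sc, X)
  expect_equal(unname(apply(S[, -3], 2, min)), rep(0, 7))
  expect_equal(unname(apply(S[, -3], 2, max)), rep(1, 7))
  expect_true(all(S[, 3] == 0))
  expect_true(sc$constant[3])

  # appending an extreme TEST row changes nothing about the fitted state
  test_rows <- matrix(1e6, 2, 8, dimnames = list(NULL, colnames(X)))
  S2 <- apply_scaler(sc, X)
  expect_identical(S, S2)
  scaled_test <- apply_scaler(sc, test_rows)
  expect_true(any(scaled_test > 1)) # out-of-range is allowed, unclipped
})

test_that("chi-squared scores match the hand formula and rank indicators first", {
  # 4-sample toy: O0 = 0, O1 = 2, E = (1, 1) -> score 2
  X <- cbind(a = c(0, 0, 1, 1), b = c(0.5, 0.5, 0.5, 0.5))
  y <- c(0, 0, 1, 1)
  cs <- chi2_select(X, y, k = 1)
  expect_equal(unname(cs$scores["a"]), 2)
  expect_equal(unname(cs$scores["b"]), 0, tolerance = 1e-12)
  expect_equal(cs$names, "a")

  # class indicator achieves the maximal score in a random matrix
  set.seed(82)
  n <- 40
  Xr <- matrix(runif(n * 30), n, 30,
               dimnames = list(NULL, sprintf("r%02d", 1:30)))
  yr <- rep(c(0, 1), each = n / 2)
  Xr[, 17] <- yr
  csr <- chi2_select(Xr, yr, k = 5)
  expect_equal(csr$names[1], "r17")
  expect_equal(unname(which.max(csr$scores)), 17)

  expect_error(chi2_select(Xr - 5, yr), "nonnegative")
})

test_that("NCA gives large weight to the discriminative feature and none under permuted labels", {
  hits <- 0
  null_ok <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 60
    X <- matrix(runif(n * 21), n, 21,
                dimnames = list(NULL, sprintf("g%02d", 1:21)))
    y <- rep(c(0L, 1L), each = n / 2)
    X[, 1] <- (y + rnorm(n, 0, 0.15) + 1) / 3
    nw <- nca_weights(X, y, seed = s)
    w <- nw$weights
    if (which.max(w) == 1 && w[1] > 3 * median(w[-1])) hits <- hits + 1
    # permuted labels: every weight shrinks far below both the w = 1
    # initialisation and the informative-feature scale
    yperm <- sample(y)
    wp <- nca_weights(X, yperm, seed = s)$weights
    if (max(wp) < 0.5 && max(wp) < w[1] / 3) null_ok <- null_ok + 1
  }
  expect_gte(hits, 9)
  expect_gte(null_ok, 9)
})

test_that("stronger regularisation shrinks the dominant weight", {
  shrunk <- vapply(1:8, function(s) {
    set.seed(s)
    n <- 50
    X <- matrix(runif(n * 11), n, 11)
    colnames(X) <- sprintf("h%02d", 1:11)
    y <- rep(c(0L, 1L), each = n / 2)
    X[, 1] <- (y + rnorm(n, 0, 0.2) + 1) / 3
    w_lo <- nca_weights(X, y, lambda = 1 / n, seed = s)$weights
    w_hi <- nca_weights(X, y, lambda = 1000 / n, seed = s)$weights
    max(w_hi) < max(w_lo)
  }, logical(1))
  expect_gte(sum(shrunk), 7)
})

test_that("two-stage selection returns 100 disjoint features deterministically", {
  fm <- toy_feature_matrix(seed = 5, n = 60, p = 150)
  sc <- fit_scaler(fm$X)
  X01 <- apply_scaler(sc, fm$X)
  sel <- select_features(X01, fm$meta$label, nca_seed = 3)
  expect_length(sel$combined, 100)
  expect_length(intersect(sel$chi2_names, sel$nca_names), 0)
  expect_true(all(sel$combined %in% colnames(fm$X)))
  # chi2 stage fully deterministic across repeated calls
  for (i in 1:3) {
    expect_identical(chi2_select(X01, fm$meta$label)$names, sel$chi2_names)
  }
  sel2 <- select_features(X01, fm$meta$label, nca_seed = 3)
  expect_identical(sel2$combined, sel$combined)

  expect_error(select_features(X01[, 1:50], fm$meta$label), "at least 100")
})

test_that("selection is invariant to arbitrary test-partition modification", {
  fm <- toy_feature_matrix(seed = 6, n = 80, p = 120)
  train <- 1:60
  test <- 61:80
  run_sel <- function(Xall) {
    sc <- fit_scaler(Xall[train, ])
    select_features(apply_scaler(sc, Xall[train, ]), fm$meta$label[train],
                    nca_seed = 9)
  }
  s1 <- run_sel(fm$X)
  Xmod <- fm$X
  Xmod[test, ] <- Xmod[test, ] * 1e3 + 77
  s2 <- run_sel(Xmod)
  expect_identical(s1$combined, s2$combined)
  expect_identical(s1$chi2_scores, s2$chi2_scores)
})

test_that("planted physiological markers survive selection on simulated cohorts", {
  fx <- fixture_strong()
  fm <- fx$fm
  markers <- c("Fp1_theta_meanAM", "Fpz_theta_meanAM", "Fp2_theta_meanAM",
               "AF3_theta_meanAM", "AF4_theta_meanAM", "coh_beta")
  hits <- vapply(1:5, function(s) {
    rows <- sample(nrow(fm$X), 0.8 * nrow(fm$X))
    sc <- fit_scaler(fm$X[rows, ])
    sel <- select_features(apply_scaler(sc, fm$X[rows, ]),
                           fm$meta$label[rows], nca_seed = s)
    any(markers %in% sel$combined)
  }, logical(1))
  expect_gte(sum(hits), 5)
})
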