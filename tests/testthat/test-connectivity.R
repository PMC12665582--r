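test_that("PLV hits its closed-form anchors", {
  e <- noise_epoch(seed = 41)
  # identical channels -> PLV 1
  e$data[2, ] <- e$data[1, ]
  cm <- plv_matrix(e, "alpha")
  expect_lt(abs(cm$weights[1, 2] - 1), 1e-9)
  expect_s3_class(cm, "connectivity_matrix")
  W <- cm$weights
  expect_lt(max(abs(W - t(W))), 1e-12)
  expect_true(all(W >= 0 & W <= 1))
  expect_true(all(diag(W) == 0))

  # constant phase shift of a narrowband signal -> PLV ~ 1
  x <- tone(10, dur_s = 20)
  e2 <- noise_epoch(seed = 42)
  e2$data[1, ] <- 20 * x
  e2$data[2, ] <- 20 * tone(10, dur_s = 20, phase = pi / 2)
  cm2 <- plv_matrix(e2, "alpha")
  expect_gt(cm2$weights[1, 2], 0.99)

  # amplitude rescaling leaves PLV unchanged
  e3 <- e
  e3$data <- e$data * 10
  cm3 <- plv_matrix(e3, "alpha")
  expect_lt(max(abs(cm3$weights - cm$weights)), 1e-6)
})

test_that("independent channels give near-zero PLV and bounded coherence", {
  null_plv <- vapply(1:5, function(s) {
    mean_plv(plv_matrix(noise_epoch(seed = 100 + s), "alpha"))
  }, numeric(1))
  expect_lt(mean(null_plv), 0.25)

  e <- noise_epoch(seed = 50)
  expect_lt(mean_coherence(e, "beta"), 0.4)
  # all channels identical -> coherence 1
  same <- e
  for (i in 2:61) same$data[i, ] <- same$data[1, ]
  expect_lt(abs(mean_coherence(same, "beta") - 1), 1e-6)
  for (b in c("delta", "theta", "alpha", "beta")) {
    v <- mean_coherence(e, b)
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("graph metrics match closed forms on the complete n=4 graph", {
  W <- matrix(0.5, 4, 4)
  diag(W) <- 0
  gm <- graph_metrics(W)
  expect_equal(gm$meanNodeStrength, 1.5)
  expect_equal(gm$charPathLength, 2.0)
  expect_equal(gm$globalEfficiency, 0.5)
  expect_equal(gm$weightedClustering, 0.5)
  expect_lt(abs(gm$modularity - 0), 1e-9)
  expect_false(gm$flag)
})

test_that("two disconnected triangles give modularity 1/2 and a flag", {
  W <- matrix(0, 6, 6)
  tri <- function(i) { W[i, i[c(2, 3, 1)]] <<- 1; W[i[c(2, 3, 1)], i] <<- 1 }
  tri(1:3); tri(4:6)
  # hand-computed Q of the 2-community partition: 2 * (1/2 - 1/4) = 1/2
  gm <- graph_metrics(W)
  expect_equal(gm$modularity, 0.5, tolerance = 1e-9)
  expect_true(gm$flag) # cross-triangle pairs unreachable
  # 12 of 30 ordered pairs reachable at distance 1
  expect_equal(gm$globalEfficiency, 12 / 30)
  expect_equal(gm$charPathLength, 1)
})

test_that("Louvain Q agrees with exhaustive partition search at n = 6", {
  # brute-force oracle: maximize Q over all partitions of 6 nodes
  set_partitions <- function(n) {
    parts <- list(list(1L))
    for (el in 2:n) {
      out <- list()
      for (p in parts) {
        for (b in seq_along(p)) {
          q <- p
          q[[b]] <- c(q[[b]], el)
          out[[length(out) + 1]] <- q
        }
        out[[length(out) + 1]] <- c(p, list(el))
      }
      parts <- out
    }
    parts
  }
  modularity_Q <- function(W, membership) {
    m2 <- sum(W)
    if (m2 == 0) return(0)
    k <- rowSums(W)
    Q <- 0
    for (c in unique(membership)) {
      idx <- membership == c
      Q <- Q + sum(W[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
    }
    Q
  }
  check_graph <- function(W) {
    parts <- set_partitions(nrow(W))
    qs <- vapply(parts, function(p) {
      mem <- integer(nrow(W))
      for (b in seq_along(p)) mem[p[[b]]] <- b
      modularity_Q(W, mem)
    }, numeric(1))
    best <- max(qs)
    gm <- graph_metrics(W)
    list(best = best, louvain = gm$modularity)
  }
  # complete uniform graph: best partition is the trivial one, Q = 0
  W1 <- matrix(0.7, 6, 6); diag(W1) <- 0
  r1 <- check_graph(W1)
  expect_lt(abs(r1$best - 0), 1e-9)
  expect_lt(abs(r1$louvain - r1$best), 1e-9)
  # two triangles: exhaustive optimum matches Louvain
  W2 <- matrix(0, 6, 6)
  W2[1:3, 1:3] <- 1; W2[4:6, 4:6] <- 1; diag(W2) <- 0
  r2 <- check_graph(W2)
  expect_lt(abs(r2$louvain - r2$best), 1e-9)
  expect_equal(r2$best, 0.5, tolerance = 1e-9)
})

test_that("graph metrics respect type invariants on random PLV-like matrices", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    W <- matrix(runif(n * n), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    gm <- graph_metrics(W)
    expect_true(gm$meanNodeStrength >= 0 && gm$meanNodeStrength <= n - 1)
    expect_true(gm$globalEfficiency >= 0 && gm$globalEfficiency <= 1)
    expect_true(gm$modularity >= -0.5 && gm$modularity <= 1)
    expect_true(gm$weightedClustering >= 0 && gm$weightedClustering <= 1)
  }
  # Louvain is run-to-run deterministic under the pinned seed
  W <- matrix(runif(100), 10, 10); W <- (W + t(W)) / 2; diag(W) <- 0
  expect_identical(graph_metrics(W)$modularity, graph_metrics(W)$modularity)
})

test_that("shortest-path backend agrees with igraph distances", {
  set.seed(62)
  W <- matrix(runif(64), 8, 8)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W[W < 0.3] <- 0 # some missing edges
  D <- sleepdepEEG:::cpp_shortest_dists(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D2 <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  expect_equal(unname(D), unname(D2), tolerance = 1e-12)
})

test_that("raising the simulator's beta coupling raises beta PLV and coherence", {
  level_stats <- function(effect, seed) {
    cfg <- sim_config(n_subjects = 2, duration_s = 20,
                      beta_coh_effect = effect, fingerprint_sd = 0,
                      noise_sd = 5, seed = seed)
    r <- synthesize_recording(make_fingerprint(cfg, "S01"), 1, cfg)
    e <- preprocess_recording(r)$epochs[[1]]
    c(plv = mean_plv(plv_matrix(e, "beta")),
      coh = mean_coherence(e, "beta"))
  }
  seeds <- 1:8
  s0 <- vapply(seeds, function(s) level_stats(0, s), numeric(2))
  s1 <- vapply(seeds, function(s) level_stats(0.6, s), numeric(2))
  s2 <- vapply(seeds, function(s) level_stats(1.5, s), numeric(2))
  # monotone in the effect for nearly every seed, both measures
  expect_gte(sum(s1["plv", ] > s0["plv", ] & s2["plv", ] > s1["plv", ]), 7)
  expect_gte(sum(s1["coh", ] > s0["coh", ] & s2["coh", ] > s1["coh", ]), 7)
  # coherence invariant to per-channel amplitude rescaling
  cfg <- sim_config(n_subjects = 2, duration_s = 20, seed = 3)
  e <- preprocess_recording(synthesize_cohort(cfg)[[1]])$epochs[[1]]
  e2 <- e; e2$data <- e2$data * 2
  expect_lt(abs(mean_coherence(e, "beta") - mean_coherence(e2, "beta")), 1e-6)
})
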