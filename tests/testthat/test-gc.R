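test_that("VAR fitting is consistent on white noise and known systems", {
  gt0 <- var_ground_truth(array(0, c(2, 2, 1)))
  x0 <- simulate_var(gt0, 20000, 5, seed = 1) # T*N = 1e5
  f0 <- fit_var(x0, order = 3)
  expect_lt(max(abs(f0$A)), 0.05)
  # order 15 at 500 Hz spans 30 ms of history
  expect_equal(15 * 2, 30)
  # ground-truth refit recovery
  gt <- make_var_ground_truth(2)
  xs <- simulate_var(gt, 10000, 5, seed = 2)
  fit <- fit_var(xs, order = 4)
  expect_lt(max(abs(fit$A[, , 1:2] - gt$A)), 0.05)
  expect_error(fit_var(xs[, 1:20, 1], order = 15), "too short")
})

test_that("pairwise conditional GC matches the closed-form bivariate value", {
  A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.8
  gt <- var_ground_truth(A, diag(c(1, 0.36)))
  xs <- simulate_var(gt, 20000, 5, seed = 3) # T*N = 1e5
  g <- pairwise_conditional_gc(xs, order = 15)
  # restricted variance for Y alone is 0.64 + 0.36 = 1: GC = ln(1/0.36)
  expect_lt(abs(g$values[2, 1] - log(1 / 0.36)), 0.05)
  # absent direction stays below the shift-surrogate threshold
  thr <- gc_surrogate_threshold(xs[, 1:4000, 1:2], order = 15,
                                n_surrogate = 10, seed = 4)
  g_small <- pairwise_conditional_gc(xs[, 1:4000, 1:2], order = 15)
  expect_lt(g_small$values[1, 2], thr)
})

test_that("independent channels stay below the surrogate threshold", {
  gt0 <- var_ground_truth(array(0, c(2, 2, 1)))
  x0 <- simulate_var(gt0, 4000, 2, seed = 5)
  g <- pairwise_conditional_gc(x0, order = 15)
  thr <- gc_surrogate_threshold(x0, order = 15, n_surrogate = 10, seed = 6)
  expect_lt(g$values[1, 2], thr)
  expect_lt(g$values[2, 1], thr)
})

test_that("GC is equivariant under channel relabeling", {
  gt <- make_var_ground_truth(2, n_l23 = 2, n_l4c = 1)
  xs <- simulate_var(gt, 3000, 2, seed = 7)
  g <- pairwise_conditional_gc(xs, order = 6)
  perm <- c(3, 1, 2)
  gp <- pairwise_conditional_gc(xs[perm, , ], order = 6)
  expect_equal(unname(gp$values), unname(g$values[perm, perm]),
               tolerance = 1e-8)
})

test_that("GC is invariant to per-channel rescaling (to tolerance)", {
  gt <- make_var_ground_truth(1, n_l23 = 2, n_l4c = 2)
  xs <- simulate_var(gt, 6000, 2, seed = 8)
  g1 <- pairwise_conditional_gc(xs, order = 6)
  scaled <- xs * rep(c(3, 0.5, 10, 1), times = prod(dim(xs)[2:3]) / 1)
  scaled <- array(scaled, dim(xs))
  g2 <- pairwise_conditional_gc(scaled, order = 6)
  expect_equal(unname(g2$values), unname(g1$values), tolerance = 1e-6)
})

test_that("layer aggregation and normalized GC follow their definitions", {
  v <- matrix(0, 4, 4); diag(v) <- NA
  lm <- c("L2", "L2", "L4Cb", "L4Cb")
  # recurrent > 0, feedforward 0: normalized GC = 1
  v[1, 2] <- v[2, 1] <- 0.3
  expect_equal(aggregate_connections(v, lm)$normalized_gc, 1)
  # recurrent = feedforward: 0.5
  v[1, 3] <- v[1, 4] <- v[2, 3] <- v[2, 4] <- 0.3
  expect_equal(aggregate_connections(v, lm)$normalized_gc, 0.5)
  # recurrent 0: 0
  v[1, 2] <- v[2, 1] <- 0
  expect_equal(aggregate_connections(v, lm)$normalized_gc, 0)
  expect_error(aggregate_connections(v, c("L5", "L5", "L5", "L5")),
               "qualifying")
  expect_error(aggregate_connections(v, lm[1:3]), "cover")
})

test_that("normalized GC separates recurrent- from feedforward-dominated columns", {
  sep <- vapply(1:12, function(s) {
    n1 <- aggregate_connections(
      pairwise_conditional_gc(simulate_var(make_var_ground_truth(1), 1500, 3,
                                           seed = s), order = 15),
      make_var_ground_truth(1)$layer_map)$normalized_gc
    n2 <- aggregate_connections(
      pairwise_conditional_gc(simulate_var(make_var_ground_truth(2), 1500, 3,
                                           seed = s), order = 15),
      make_var_ground_truth(2)$layer_map)$normalized_gc
    n2 > n1
  }, logical(1))
  expect_gte(mean(sep), 0.95)
})
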