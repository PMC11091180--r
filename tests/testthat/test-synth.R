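test_that("stimulus sequences satisfy the protocol invariants", {
  seq1 <- make_stimulus_sequence(150, sf = 2.5, seed = 1)
  expect_equal(nrow(seq1), 150)
  # contiguous, non-overlapping 20-ms frames: one 3-s trial segment
  expect_equal(diff(seq1$onset_ms), rep(20, 149))
  expect_equal(max(seq1$onset_ms) + 20, 3000)
  expect_true(all(seq1$sf_cpd == 2.5))
  expect_true(all(is.na(seq1$orientation_idx[seq1$blank])))
  expect_true(all(seq1$orientation_idx[!seq1$blank] %in% 0:8))
  expect_true(all(seq1$phase_idx[!seq1$blank] %in% 0:7))

  # blank fraction within 3 binomial SDs of 0.10 at n = 10000
  big <- make_stimulus_sequence(10000, sf = 1, seed = 7)
  p_hat <- mean(big$blank)
  expect_lt(abs(p_hat - 0.10), 3 * sqrt(0.1 * 0.9 / 10000))

  # (orientation, phase) pairs approximately uniform
  tab <- table(big$orientation_idx, big$phase_idx)
  expect_gt(min(tab) / max(tab), 0.5)

  # determinism
  expect_identical(make_stimulus_sequence(500, sf = 5, seed = 42),
                   make_stimulus_sequence(500, sf = 5, seed = 42))
  expect_error(make_stimulus_sequence(0, sf = 1, seed = 1), "positive")
})

test_that("stimulus sequences round-trip through TSV", {
  s <- make_stimulus_sequence(100, sf = 7.5, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_stimulus_sequence(s, path)
  r <- read_stimulus_sequence(path)
  expect_equal(r$onset_ms, s$onset_ms)
  expect_equal(r$blank, s$blank)
  expect_equal(r$sf_cpd, s$sf_cpd)
})

test_that("input drives have the stated SF and temporal structure", {
  d <- make_input_drives()
  expect_equal(dim(d$m), c(7, 76))
  # pooled (unit-scaled) input drive peaks near 52 ms
  pooled <- colMeans(d$m / max(d$m) + d$p / max(d$p))
  expect_lt(abs(d$time[which.max(pooled)] - 52), 6)
  # M gain decreasing beyond its preferred SF; lowest > highest
  gm <- apply(d$m, 1, max)
  expect_gt(gm[1], gm[7])
  expect_true(all(diff(gm[3:7]) < 0))
  # P peaks at a higher SF than M
  expect_gt(d$sf[which.max(apply(d$p, 1, max))],
            d$sf[which.max(gm)])
  # drives are causal
  expect_true(all(d$m[, d$time <= 0] == 0))
  # all-zero gains give identically zero drives
  z <- make_input_drives(m_gain_params = list(amp = 0, peak_sf = 1,
                                              sigma_oct = 1),
                         p_gain_params = list(amp = 0, peak_sf = 6,
                                              sigma_oct = 1))
  expect_true(all(z$m == 0) && all(z$p == 0))
  expect_error(make_input_drives(numeric(0)), "non-empty")
})

test_that("simulated placements realise the forward model exactly", {
  pl <- simulate_placement(2, noise_sd = 0, jitter_sd = 0, seed = 1)
  fit_cols <- pl$time >= 0
  for (s in which(!pl$sites$layer %in% c("L4Ca", "L4Cb"))[c(1, 5, 9)]) {
    expect_equal(unname(pl$clean[[s]][, fit_cols]),
                 unname(predict_ffrec(pl$params[[s]], pl$drives)))
  }
  # forward-model conservation: w_rec = 0 everywhere reduces to the FF model
  pl1 <- simulate_placement(1, noise_sd = 0, jitter_sd = 0, seed = 1)
  s <- which(pl1$sites$layer == "L2")[1]
  expect_identical(unname(pl1$clean[[s]][, fit_cols]),
                   unname(predict_ff(pl1$params[[s]], pl1$drives)))
  # L4Ca sites lie above L4Cb sites
  expect_lt(max(pl$sites$depth[pl$sites$layer == "L4Ca"]),
            min(pl$sites$depth[pl$sites$layer == "L4Cb"]))
  expect_error(simulate_placement(3), "group")
})

test_that("noiseless activation separates the groups as constructed", {
  a1 <- placement_activation(simulate_placement(1, noise_sd = 0,
                                                jitter_sd = 0), clean = TRUE)
  a2 <- placement_activation(simulate_placement(2, noise_sd = 0,
                                                jitter_sd = 0), clean = TRUE)
  expect_true(all(a1$activation < 1))
  expect_gt(a2$activation[which.max(a2$sf)], 1)
  expect_lt(a2$activation[which.min(a2$sf)], 1)
})

test_that("group separation holds across seeded noisy placements", {
  highs <- function(group) {
    vapply(1:20, function(s) {
      a <- placement_activation(simulate_placement(group, seed = s))
      a$activation[a$sf == 15]
    }, numeric(1))
  }
  expect_gte(mean(highs(2) > 1), 0.95)
  expect_gte(mean(highs(1) < 1), 0.95)
})

test_that("spike trains are Poisson with the integrated rate", {
  pl <- simulate_placement(1, noise_sd = 0, jitter_sd = 0, seed = 1)
  seqs <- make_stimulus_sequence(5000, sf = 0.625, seed = 2) # 100 s
  st <- simulate_spike_trains(pl, seqs, seed = 3, baseline_rate = 10,
                              kernel_scale = 0, sites = 1)
  dur_s <- attr(st, "duration_ms") / 1000
  expect_lt(abs(length(st[[1]]) - 10 * dur_s), 3 * sqrt(10 * dur_s))
  # doubling the rate doubles expected counts
  st2 <- simulate_spike_trains(pl, seqs, seed = 4, baseline_rate = 20,
                               kernel_scale = 0, sites = 1)
  expect_lt(abs(length(st2[[1]]) / length(st[[1]]) - 2), 0.2)
  # determinism
  st3 <- simulate_spike_trains(pl, seqs, seed = 3, baseline_rate = 10,
                               kernel_scale = 0, sites = 1)
  expect_identical(as.numeric(st[[1]]), as.numeric(st3[[1]]))
  expect_error(simulate_spike_trains(pl, seqs, baseline_rate = -1),
               "negative")
})

test_that("VAR simulator matches its ground truth statistically", {
  # all A_k = 0: independent white noise
  gt0 <- var_ground_truth(array(0, c(2, 2, 1)))
  x0 <- simulate_var(gt0, 5000, 1, seed = 1)
  expect_lt(abs(cor(x0[1, , 1], x0[2, , 1])), 0.05)
  expect_lt(abs(cor(x0[1, -1, 1], x0[1, -5000, 1])), 0.05)

  # bivariate Y_t = 0.8 X_{t-1} + eps, var(eps) = 0.36: refit recovers 0.8
  A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.8
  gt <- var_ground_truth(A, diag(c(1, 0.36)))
  xs <- simulate_var(gt, 20000, 5, seed = 2)
  fit <- fit_var(xs, order = 1)
  expect_lt(abs(fit$A[2, 1, 1] - 0.8), 0.05)

  expect_identical(simulate_var(gt, 100, 2, seed = 9),
                   simulate_var(gt, 100, 2, seed = 9))
  # unstable coefficients rejected
  Abad <- array(0, c(2, 2, 1)); diag(Abad[, , 1]) <- 1.05
  expect_error(var_ground_truth(Abad), "unstable")
})
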