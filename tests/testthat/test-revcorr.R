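test_that("reverse correlation localises a delta response", {
  # isolated frames (400 ms apart, so delay windows never overlap) and
  # spikes exactly 40 ms after every 0-degree frame
  n <- 400
  onsets <- (seq_len(n) - 1) * 400
  ori <- rep(0:8, length.out = n)
  blank <- rep(FALSE, n); blank[seq(10, n, by = 10)] <- TRUE
  ori[blank] <- NA
  seqs <- tibble::tibble(onset_ms = onsets, orientation_idx = ori,
                         phase_idx = ifelse(blank, NA, 0L), blank = blank,
                         sf_cpd = 2.5)
  attr(seqs, "frame_duration_ms") <- 20
  spikes <- onsets[!blank & ori %in% 0] + 40.5
  dr <- reverse_correlate(spikes, seqs)
  tb <- attr(dr, "time")
  nz <- which(unclass(dr) != 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] == 1))           # only orientation 0
  expect_true(all(tb[nz[, 2]] == 40))      # only the 40-ms delay bin
  expect_error(reverse_correlate(spikes, dplyr::mutate(seqs, blank = FALSE)),
               "blank")
})

test_that("reverse correlation recovers a known generating kernel", {
  pl <- simulate_placement(2, noise_sd = 0, jitter_sd = 0, seed = 1)
  site <- which(pl$sites$layer == "L3")[1]
  seqs <- make_stimulus_sequence(7500, sf = 7.5, seed = 11) # 150 s, ~150 reps
  st <- simulate_spike_trains(pl, seqs, seed = 12, baseline_rate = 10,
                              sites = site)
  dr <- smooth_response(reverse_correlate(st[[1]], seqs))
  tb <- attr(dr, "time")
  kern <- pl$clean[[site]][pl$sf == 7.5, pl$time >= 0] # rate kernel, t >= 0
  pref <- attr(st[[1]], "pref_idx")
  r <- cor(dr[pref + 1, tb >= 0], smooth_response(kern))
  expect_gt(r, 0.9)
  # stimulus-independent rate gives ~zero response
  st0 <- simulate_spike_trains(pl, seqs, seed = 13, kernel_scale = 0,
                               sites = site)
  dr0 <- smooth_response(reverse_correlate(st0[[1]], seqs))
  expect_lt(max(abs(dr0)), 5) # spikes/s, pure sampling noise around 0
  expect_lt(abs(mean(dr0)), 1)
})

test_that("reverse correlation is linear in the spike train", {
  n <- 300
  seqs <- make_stimulus_sequence(n, sf = 2.5, seed = 21)
  set.seed(22)
  t1 <- sort(runif(300, 0, n * 20))
  t2 <- sort(runif(500, 0, n * 20))
  r1 <- reverse_correlate(t1, seqs)
  r2 <- reverse_correlate(t2, seqs)
  r12 <- reverse_correlate(c(t1, t2), seqs)
  expect_equal(unclass(r12), unclass(r1) + unclass(r2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("rectangular smoothing behaves as a 10-point moving average", {
  x <- matrix(rnorm(86), 1)
  expect_equal(smooth_response(matrix(5, 1, 86))[1, ], rep(5, 86))
  # interior unit impulse becomes a boxcar of height 1/10 over 10 bins
  imp <- matrix(0, 1, 86); imp[1, 43] <- 1
  sm <- smooth_response(imp)
  expect_equal(sum(sm[1, ] > 0), 10)
  expect_equal(max(sm[1, ]), 1 / 10)
  # 20 ms at 2-ms bins = 10 samples
  expect_equal(20 / 2, 10)
  # interior mean preserved
  expect_equal(mean(smooth_response(x)[1, 20:60]), mean(x[1, 20:60]),
               tolerance = 0.2)
  expect_error(smooth_response(x, width_ms = 1), "even multiple")
  expect_error(smooth_response(x, width_ms = 6, bin_ms = 4), "even multiple")
})

test_that("SER statistics follow their definition", {
  tb <- response_timebase()
  const <- matrix(2, 9, length(tb))
  attr(const, "time") <- tb; attr(const, "sf_cpd") <- 1
  q <- compute_ser(list("1" = const))
  expect_equal(q$final_ser, 1)
  # SER is invariant to positive rescaling
  scaled <- const * 7.3
  attr(scaled, "time") <- tb; attr(scaled, "sf_cpd") <- 1
  expect_equal(compute_ser(list("1" = scaled))$final_ser, 1)
  # zero baseline energy is an error
  zed <- const; zed[, tb < 0] <- 0
  attr(zed, "time") <- tb; attr(zed, "sf_cpd") <- 1
  expect_error(compute_ser(list("1" = zed)), "baseline")
  # final SER is the max across SF conditions
  strong <- const; strong[, tb > 40 & tb < 60] <- 10
  attr(strong, "time") <- tb; attr(strong, "sf_cpd") <- 2
  q2 <- compute_ser(list("1" = const, "2" = strong))
  expect_equal(q2$final_ser, max(q2$per_sf$ser))
  expect_gt(q2$final_ser, 1)
})

test_that("pure-noise sites rarely reach the SER threshold", {
  # Monte-Carlo calibration of the SER > 3 criterion: rate noise around the
  # default 10 spikes/s baseline with the default response-noise SD
  tb <- response_timebase()
  ser <- vapply(1:300, function(i) {
    set.seed(i)
    resp <- matrix(rnorm(9 * length(tb), 0, 2), 9)
    sm <- smooth_response(resp)
    attr(sm, "time") <- tb
    attr(sm, "baseline_rate") <- 10
    compute_ser(list("1" = sm))$final_ser
  }, numeric(1))
  expect_lt(quantile(ser, 0.95), 3)
  expect_gte(mean(ser <= 3), 0.95) # >= 95% of noise sites excluded
  # while a visually driven site comfortably exceeds it
  pl <- simulate_placement(2, noise_sd = 0, jitter_sd = 0, seed = 1)
  driven <- pl$clean[[which(pl$sites$layer == "L3")[1]]]
  ori <- lapply(1:9, function(o) driven[5, ] * orientation_gain(o - 1, 4))
  driven_m <- do.call(rbind, ori)
  attr(driven_m, "time") <- pl$time
  attr(driven_m, "baseline_rate") <- 10
  expect_gt(compute_ser(list("7.5" = driven_m))$final_ser, 3)
})

test_that("dynamic SNR has the stated invariances", {
  tb <- response_timebase()
  set.seed(5)
  resp <- matrix(rnorm(9 * length(tb)), 9)
  resp[4, tb > 38 & tb < 62] <- resp[4, tb > 38 & tb < 62] + 10
  attr(resp, "time") <- tb
  snr <- compute_dynamic_snr(resp)
  expect_true(tb[which.max(snr)] > 38 && tb[which.max(snr)] < 62)
  # scale invariance
  resp2 <- resp * 3
  attr(resp2, "time") <- tb
  expect_equal(unname(compute_dynamic_snr(resp2)), unname(snr))
  # exchangeable noise gives SNR ~ 1 on average
  noise <- matrix(rnorm(9 * length(tb)), 9)
  attr(noise, "time") <- tb
  expect_lt(abs(mean(compute_dynamic_snr(noise)) - 1), 0.5)
  expect_error(compute_dynamic_snr(resp[1, , drop = FALSE]), "orientations")
})

test_that("site selection is strict at the SER threshold", {
  expect_equal(select_sites(c(3.0, 3.01, 2.99, 10)),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_error(select_sites(c(1, Inf)), "finite")
})
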