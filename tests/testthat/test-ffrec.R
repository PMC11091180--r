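test_that("log-normal kernels match the formula pointwise", {
  tb <- fit_timebase()
  set.seed(31)
  for (i in 1:10) {
    dt1 <- runif(1, log(10), log(140)); s1 <- runif(1, 0.1, 1.2)
    dt2 <- runif(1, log(10), log(140)); s2 <- runif(1, 0.1, 1.2)
    g <- runif(1)
    k <- lognormal_kernel(dt1, s1, dt2, s2, g, timebase = tb)
    manual <- ifelse(tb > 0,
                     exp(-(log(pmax(tb, 1e-12)) - dt1)^2 / (2 * s1^2)) -
                       g * exp(-(log(pmax(tb, 1e-12)) - dt2)^2 / (2 * s2^2)),
                     0)
    expect_equal(k, manual)
  }
  # single lobe peaks at exp(dt1): 52 ms
  k52 <- lognormal_kernel(log(52), 0.4)
  expect_equal(tb[which.max(k52)], 52)
  # g = 1 with identical lobes cancels exactly
  expect_true(all(lognormal_kernel(log(40), 0.5, log(40), 0.5, 1) == 0))
  expect_error(lognormal_kernel(log(40), -1), "positive")
  # zero for t <= 0 on the full grid
  full <- response_timebase()
  expect_true(all(lognormal_kernel(log(40), 0.5, timebase = full)[full <= 0]
                  == 0))
})

test_that("recurrent course is unit-peak and symmetric in log time", {
  tb <- seq(0, 1000, 0.5)
  r <- recurrent_course(log(65), 0.3, timebase = tb)
  expect_equal(max(r), 1)
  expect_equal(tb[which.max(r)], 65)
  # symmetry about dt_rec in log time
  lt <- c(log(65) - 0.25, log(65) + 0.25)
  vals <- recurrent_course(log(65), 0.3, timebase = exp(lt))
  expect_equal(vals[1], vals[2], tolerance = 1e-12)
})

test_that("FF prediction is a causal weighted convolution", {
  sf <- c(1, 4)
  tb <- fit_timebase()
  imp <- matrix(0, 2, length(tb)); imp[, tb == 30] <- 1
  drives <- list(sf = sf, time = tb, m = imp, p = 0 * imp)
  p <- ffrec_params(w_m = 2, w_p = 0, dt_m1 = log(15), sigma_m1 = 0.4)
  out <- predict_ff(p, drives)
  k <- lognormal_kernel(log(15), 0.4, timebase = tb, normalize = "area")
  shift <- c(rep(0, sum(tb < 30)), k[seq_len(sum(tb >= 30))])
  expect_equal(unname(out[1, ]), 2 * shift)
  # zero weights: identically zero
  p0 <- ffrec_params(w_m = 0, w_p = 0, dt_m1 = log(15), sigma_m1 = 0.4)
  expect_true(all(predict_ff(p0, drives) == 0))
  # linearity in the drives
  d2 <- drives; d2$m <- matrix(rnorm(length(imp)), 2)
  d3 <- drives; d3$m <- imp + d2$m
  expect_equal(predict_ff(p, d3), predict_ff(p, drives) + predict_ff(p, d2))
})

test_that("FF & Rec prediction adds the SF-dependent recurrent component", {
  drives <- make_input_drives(c(1.25, 5))
  p <- ffrec_params(w_m = 0.3, w_p = 0.4, dt_m1 = log(15), sigma_m1 = 0.4,
                    w_rec = c("1.25" = 0, "5" = 0))
  expect_identical(predict_ffrec(p, drives), predict_ff(p, drives))
  # zero drives, w_rec = 2: prediction is exactly 2 * R_rec
  z <- drives; z$m[] <- 0; z$p[] <- 0
  p2 <- ffrec_params(w_m = 1, w_p = 1, dt_m1 = log(15), sigma_m1 = 0.4,
                     dt_rec = log(65), sigma_rec = 0.3,
                     w_rec = c("1.25" = 2, "5" = 2))
  out <- predict_ffrec(p2, z)
  rec <- recurrent_course(log(65), 0.3, timebase = drives$time)
  expect_equal(unname(out[1, ]), 2 * rec)
  # each SF uses its own weight
  p3 <- p2; p3$w_rec <- c("1.25" = 1, "5" = 3)
  out3 <- predict_ffrec(p3, z)
  expect_equal(unname(out3[2, ]), 3 * rec)
  expect_error(predict_ffrec(ffrec_params(w_m = 1, w_p = 1, dt_m1 = log(15),
                                          sigma_m1 = 0.4,
                                          w_rec = c("1.25" = 1)), drives),
               "missing recurrent weight")
})

test_that("adjusted gof penalises parameters as stated", {
  expect_equal(adjusted_gof(1, 100, 10), 1)
  expect_equal(adjusted_gof(0.7, 100, 0), 0.7)
  expect_equal(adjusted_gof(0.9, 101, 20), 0.875)
  expect_error(adjusted_gof(0.9, 10, 9), "n > p")
})

test_that("model fitting is deterministic and identifies the variants", {
  drives <- make_input_drives()
  truth <- group_param_pack(2)$layers$L3
  resp <- predict_ffrec(truth, drives)
  f1 <- fit_model(resp, drives, variant = "ff", n_starts = 3,
                  polish_rounds = 1)
  f2 <- fit_model(resp, drives, variant = "ff", n_starts = 3,
                  polish_rounds = 1)
  expect_identical(tidy(f1), tidy(f2))
  expect_equal(f1$p_free, 12)
  f3 <- fit_model(resp, drives, variant = "ffrec", n_starts = 3,
                  polish_rounds = 1)
  expect_equal(f3$p_free, 14 + 7)
  # data generated with high-SF recurrence: FFREC wins on adjusted gof
  expect_gt(f3$gof_adj, f1$gof_adj)
  expect_error(fit_model(resp[, 1:10], drives), "matrix matching")
})

test_that("LAPs decompose the prediction and contributions normalize", {
  drives <- make_input_drives()
  truth <- group_param_pack(2)$layers$L2
  resp <- predict_ffrec(truth, drives)
  fit <- fit_model(resp, drives, variant = "ffrec", n_starts = 4,
                   polish_rounds = 1)
  laps <- laminar_activation_patterns(list(fit), drives, data = list(resp))
  total <- laps$m[, , 1] + laps$p[, , 1] + laps$rec[, , 1]
  expect_equal(total, unname(fit$fitted), tolerance = 1e-8)
  co <- contributions(laps)
  sums <- co |> dplyr::group_by(sf) |>
    dplyr::summarise(s = sum(contribution))
  expect_equal(sums$s, rep(1, 7))
  # recurrent contribution rises with SF for a group-2 site
  rec <- co$contribution[co$component == "rec"]
  expect_gt(cor(rank(co$sf[co$component == "rec"]), rank(rec)), 0)
  # per-site contributions normalize too
  sc <- site_contributions(laps)
  ssum <- sc |> dplyr::group_by(sf) |> dplyr::summarise(s = sum(contribution))
  expect_equal(ssum$s, rep(1, 7))
  # invalid fits are dropped with a warning
  bad <- fit; bad$gof_raw <- 0.1
  expect_warning(laminar_activation_patterns(list(fit, bad), drives,
                                             data = list(resp, resp)),
                 "dropping")
})

test_that("contribution scores behave on constructed cases", {
  drives <- make_input_drives(c(1, 8))
  rec <- recurrent_course(timebase = drives$time)
  laps <- structure(list(
    m = array(0, c(2, 76, 1)), p = array(0, c(2, 76, 1)),
    rec = array(rep(rec, each = 2), c(2, 76, 1)),
    data = array(rep(rec, each = 2), c(2, 76, 1)),
    sf = c(1, 8), time = drives$time, sites = 1), class = "lap_set")
  co <- contributions(laps)
  expect_equal(co$contribution[co$component == "rec"], c(1, 1))
  # three identical LAPs equal to the data: each 1/3
  laps$m <- laps$p <- laps$rec
  co2 <- contributions(laps)
  expect_equal(co2$contribution, rep(1 / 3, 6))
  sc <- site_contributions(laps)
  expect_equal(sc$contribution, rep(1 / 3, 6))
  # scaling all LAPs leaves normalized site contributions unchanged
  laps3 <- laps; for (q in c("m", "p", "rec")) laps3[[q]] <- laps3[[q]] * 4
  expect_equal(site_contributions(laps3)$contribution, sc$contribution)
})

test_that("MP index contrasts the pathway contributions", {
  expect_equal(mp_index(0.3, 0.3), 0)
  expect_equal(mp_index(0, 0.5), 1)
  expect_equal(mp_index(0.2, 0.6), 0.5)
  expect_error(mp_index(0, 0), "positive")
})

test_that("model parameters round-trip through JSON", {
  p <- group_param_pack(2)$layers$L2
  path <- tempfile(fileext = ".json")
  write_ffrec_params(p, path)
  q <- read_ffrec_params(path)
  expect_equal(unclass(q), unclass(p))
  # LAPs recompute identically from re-serialized parameters
  drives <- make_input_drives()
  expect_equal(predict_ffrec(q, drives), predict_ffrec(p, drives))
})
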