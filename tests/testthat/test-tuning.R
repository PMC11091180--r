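test_that("difference-of-Gaussians fits recover exact parameters", {
  sf <- c(0.5, 1, 2, 4, 6, 8, 12, 16, 20)
  truth <- c(a1 = 30, sigma1 = 6, a2 = 10, sigma2 = 2)
  r <- 30 * exp(-sf^2 / (2 * 36)) - 10 * exp(-sf^2 / (2 * 4))
  fit <- fit_sf_tuning(sf, r)
  expect_gte(fit$gof, 0.999)
  expect_lt(abs(fit$a1 - 30) / 30, 0.01)
  expect_lt(abs(fit$sigma1 - 6) / 6, 0.01)
  expect_lt(abs(fit$a2 - 10) / 10, 0.01)
  expect_lt(abs(fit$sigma2 - 2) / 2, 0.01)
  # curve value at SF = 0 equals A1 - A2
  expect_equal(fit$a1 * exp(0) - fit$a2 * exp(0), fit$a1 - fit$a2)
  expect_error(fit_sf_tuning(sf[1:3], r[1:3]), "at least 5")
  expect_error(fit_sf_tuning(sf, rep(0, length(sf))), "all-zero")
  # constant responses: zero total variance, gof undefined
  expect_error(fit_sf_tuning(sf, rep(3, length(sf))), "variance")
})

test_that("goodness of fit follows 1 - SSE/SStot", {
  d <- c(1, 3, 2, 5)
  expect_equal(goodness_of_fit(d, d), 1)
  expect_equal(goodness_of_fit(d, rep(mean(d), 4)), 0)
  expect_lt(goodness_of_fit(d, c(10, -10, 10, -10)), 0)
  expect_error(goodness_of_fit(c(2, 2), c(1, 2)), "variance")
})

test_that("cutoff SF matches the half-height closed form and a fine scan", {
  f <- list(a1 = 30, a2 = 0, sigma1 = 4, sigma2 = 1)
  expect_lt(abs(cutoff_sf(f) - 4 * sqrt(2 * log(2))), 0.02)
  # scale invariance
  f2 <- list(a1 = 3, a2 = 0, sigma1 = 4, sigma2 = 1)
  expect_equal(cutoff_sf(f2), cutoff_sf(f))
  # refinement oracle: 10x denser grid agrees within one coarse grid step
  f3 <- list(a1 = 20, a2 = 8, sigma1 = 7, sigma2 = 1.5)
  g1 <- exp(seq(log(0.1), log(25), length.out = 1000))
  g2 <- exp(seq(log(0.1), log(25), length.out = 10000))
  step <- log(25 / 0.1) / 999
  expect_lt(abs(log(cutoff_sf(f3, g1)) - log(cutoff_sf(f3, g2))), step)
  # monotone non-decreasing in sigma1 when A2 = 0
  cuts <- vapply(c(2, 3, 4, 6, 9),
                 function(s) cutoff_sf(list(a1 = 1, a2 = 0, sigma1 = s,
                                            sigma2 = 1)), numeric(1))
  expect_true(all(diff(cuts) >= 0))
  # invalid fits refuse to report a cutoff
  expect_error(cutoff_sf(list(a1 = 1, a2 = 0, sigma1 = 2, sigma2 = 1,
                              gof = 0.5)), "valid")
  expect_error(cutoff_sf(list(a1 = 0, a2 = 1, sigma1 = 2, sigma2 = 4)),
               "non-positive")
})

test_that("DoG fit dominates the nested single-Gaussian fit", {
  set.seed(7)
  sf <- c(0.5, 1, 2, 4, 8, 12, 16)
  for (i in 1:5) {
    r <- 20 * exp(-sf^2 / (2 * runif(1, 2, 8)^2)) + rnorm(7, 0, 1.5)
    dog <- fit_sf_tuning(sf, r)
    single <- function(par) sum((r - par[1] * exp(-sf^2 / (2 * par[2]^2)))^2)
    best1 <- optim(c(max(r), 4), single, method = "L-BFGS-B",
                   lower = c(0, 0.05), upper = c(10 * max(abs(r)), 50))
    gof1 <- 1 - best1$value / sum((r - mean(r))^2)
    expect_gte(dog$gof, gof1 - 1e-6)
  }
})

test_that("cutoff recovery stays accurate under noise", {
  sf <- c(0.5, 1, 2, 4, 6, 8, 12, 16, 20)
  r0 <- 30 * exp(-sf^2 / (2 * 36)) - 10 * exp(-sf^2 / (2 * 4))
  true_cut <- cutoff_sf(list(a1 = 30, a2 = 10, sigma1 = 6, sigma2 = 2))
  errs <- vapply(1:40, function(i) {
    set.seed(i)
    fit <- fit_sf_tuning(sf, r0 + rnorm(9, 0, max(r0) / 10))
    if (!fit$valid) return(NA_real_)
    abs(fit$cutoff_sf - true_cut) / true_cut
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)
})

test_that("low/high SF condition selection applies the 90% rule", {
  sel <- select_sf_conditions(c(10, 12, 11.5, 9), c(0.625, 4, 8, 12))
  expect_equal(sel$low_sf, 0.625)
  expect_equal(sel$high_sf, 8) # 11.5 >= 0.9*12 and 8 >= 6; 9 < 10.8 at 12
  # no SF >= 6 reaches 90% of the maximum: placement invalid
  sel2 <- select_sf_conditions(c(20, 10, 5), c(2, 6, 10))
  expect_true(is.na(sel2$high_sf) && !sel2$valid)
  # a single condition at 6 c/deg is both low and high
  sel3 <- select_sf_conditions(5, 6)
  expect_equal(sel3$low_sf, 6)
  expect_equal(sel3$high_sf, 6)
  expect_error(select_sf_conditions(numeric(0), numeric(0)), "empty")
})

test_that("relative cutoff SF is the log10 ratio", {
  expect_equal(relative_cutoff_sf(4, 4), 0)
  expect_equal(relative_cutoff_sf(8, 4), log10(2))
  expect_equal(relative_cutoff_sf(2, 4), -log10(2))
  expect_error(relative_cutoff_sf(0, 4), "positive")
})
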