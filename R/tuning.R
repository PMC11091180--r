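#' Fit a difference-of-Gaussians SF tuning curve
#'
#' Least-squares fit of
#' \deqn{R(SF) = A_1 e^{-SF^2/2\sigma_1^2} - A_2 e^{-SF^2/2\sigma_2^2}}
#' to baseline-subtracted responses, on the raw (not log) SF axis. A
#' deterministic multi-start bounded optimisation is used (12 restarts;
#' amplitudes bounded by 10x the peak response, widths in \[0.05, 50\]
#' c/deg). A fit is `valid` when its goodness of fit exceeds 0.8; the cutoff
#' SF is only reported for valid fits.
#'
#' @param sf_values SF conditions in cycles/degree (>= 5).
#' @param responses Baseline-subtracted mean responses (spikes/s).
#' @param n_starts Number of deterministic restarts (default 12).
#' @return Object of class `sf_tuning_fit`: `a1`, `a2`, `sigma1`, `sigma2`,
#'   `gof`, `valid`, `cutoff_sf` (`NA` when invalid), `fitted`, `sf`, `data`.
#' @export
fit_sf_tuning <- function(sf_values, responses, n_starts = 12) {
  if (length(sf_values) != length(responses)) {
    abort("`sf_values` and `responses` must have the same length")
  }
  if (length(sf_values) < 5) abort("need at least 5 SF conditions")
  if (all(responses == 0)) abort("all-zero responses; nothing to fit")
  rmax <- max(abs(responses))
  dog <- function(par, sf) {
    par[1] * exp(-sf^2 / (2 * par[3]^2)) - par[2] * exp(-sf^2 / (2 * par[4]^2))
  }
  obj <- function(par) sum((responses - dog(par, sf_values))^2)
  lower <- c(0, 0, 0.05, 0.05)
  upper <- c(10 * rmax, 10 * rmax, 50, 50)
  sig_grid <- c(1, 2, 4, 8, 16, 0.5, 3, 6, 12, 24, 1.5, 10)
  best <- NULL
  for (i in seq_len(n_starts)) {
    start <- c(rmax, 0.25 * rmax, sig_grid[i],
               sig_grid[(i %% n_starts) + 1] / 3)
    start <- pmin(pmax(start, lower), upper)
    res <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e2)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort("tuning-curve optimizer failed on all restarts")
  par <- best$par
  fitted <- dog(par, sf_values)
  gof <- goodness_of_fit(responses, fitted)
  out <- structure(
    list(a1 = par[1], a2 = par[2], sigma1 = par[3], sigma2 = par[4],
         gof = gof, valid = gof > 0.8, cutoff_sf = NA_real_,
         fitted = fitted, sf = sf_values, data = responses),
    class = "sf_tuning_fit"
  )
  if (out$valid) {
    out$cutoff_sf <- tryCatch(cutoff_sf(out), error = function(e) NA_real_)
  }
  out
}

#' @export
print.sf_tuning_fit <- function(x, ...) {
  cat(sprintf(paste0("<sf_tuning_fit: A1=%.3g sigma1=%.3g A2=%.3g sigma2=%.3g",
                     " | gof=%.3f%s>\n"),
              x$a1, x$sigma1, x$a2, x$sigma2, x$gof,
              if (x$valid) sprintf(", cutoff %.2f c/deg", x$cutoff_sf)
              else " (invalid)"))
  invisible(x)
}

#' Goodness of fit (variance explained about the data mean)
#'
#' `1 - SSE / SStot`; 1 for a perfect fit, 0 for a fit no better than the
#' data mean, negative for worse.
#'
#' @param data Observed values.
#' @param fitted Fitted values (same length, >= 2).
#' @return Scalar in (-Inf, 1\].
#' @export
goodness_of_fit <- function(data, fitted) {
  if (length(data) != length(fitted) || length(data) < 2) {
    abort("`data` and `fitted` must be equal-length vectors of length >= 2")
  }
  sstot <- sum((data - mean(data))^2)
  if (sstot <= 0) abort("zero total variance; gof undefined")
  1 - sum((data - fitted)^2) / sstot
}

#' Cutoff SF of a fitted tuning curve
#'
#' The maximal SF whose fitted response still reaches 50% of the curve
#' maximum, evaluated on a dense log-spaced grid (0.1-25 c/deg, 1000 points
#' by default).
#'
#' @param fit An `sf_tuning_fit` (must be valid: gof > 0.8), or a list with
#'   `a1`, `a2`, `sigma1`, `sigma2`.
#' @param sf_grid Evaluation grid (c/deg).
#' @param check_valid Enforce the gof > 0.8 validity filter (default TRUE
#'   when `fit` carries a `gof`).
#' @return Cutoff SF in cycles/degree.
#' @export
#' @examples
#' f <- list(a1 = 30, a2 = 0, sigma1 = 4, sigma2 = 1)
#' cutoff_sf(f) # ~ 4 * sqrt(2 * log(2)) = 4.71
cutoff_sf <- function(fit,
                      sf_grid = exp(seq(log(0.1), log(25), length.out = 1000)),
                      check_valid = TRUE) {
  if (check_valid && !is.null(fit$gof) && fit$gof <= 0.8) {
    abort("fit is not valid (gof <= 0.8); cutoff SF undefined")
  }
  r <- fit$a1 * exp(-sf_grid^2 / (2 * fit$sigma1^2)) -
    fit$a2 * exp(-sf_grid^2 / (2 * fit$sigma2^2))
  rmax <- max(r)
  if (rmax <= 0) abort("fitted curve is non-positive everywhere")
  sf_grid[max(which(r >= 0.5 * rmax))]
}

#' Relative cutoff SF (output vs input layer)
#'
#' `log10(cutoff_output / cutoff_input)`: positive when the output layer
#' resolves higher SFs than the input layer.
#'
#' @param cutoff_output,cutoff_input Cutoff SFs in c/deg (> 0).
#' @return Log10 ratio.
#' @export
#' @examples
#' relative_cutoff_sf(8, 4) # log10(2)
relative_cutoff_sf <- function(cutoff_output, cutoff_input) {
  if (any(c(cutoff_output, cutoff_input) <= 0)) {
    abort("cutoff SFs must be positive")
  }
  log10(cutoff_output / cutoff_input)
}

#' Select the low and high SF conditions of a placement
#'
#' Based on the SF tuning of the L4Cb input layer: the low condition is the
#' lowest SF tested; the high condition is the highest SF whose response
#' reaches 90% of the maximum response, restricted to SFs of at least
#' `min_high_sf` (6 c/deg). When no SF qualifies the placement is flagged
#' invalid (`high_sf = NA`).
#'
#' @param l4cb_responses Per-SF response amplitudes of the L4Cb sites.
#' @param sf_list SF conditions (c/deg), same length.
#' @param min_high_sf Minimum admissible high SF (default 6 c/deg).
#' @return A list with `low_sf`, `high_sf` (`NA` if none qualifies), and
#'   `valid`.
#' @export
select_sf_conditions <- function(l4cb_responses, sf_list, min_high_sf = 6) {
  if (length(sf_list) == 0) abort("empty `sf_list`")
  if (length(l4cb_responses) != length(sf_list)) {
    abort("`l4cb_responses` and `sf_list` must have the same length")
  }
  low <- min(sf_list)
  thr <- 0.9 * max(l4cb_responses)
  ok <- l4cb_responses >= thr & sf_list >= min_high_sf
  high <- if (any(ok)) max(sf_list[ok]) else NA_real_
  list(low_sf = low, high_sf = high, valid = !is.na(high))
}
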