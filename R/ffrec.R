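#' Log-normal temporal kernel
#'
#' Difference of two log-normal lobes in time, the temporal kernel used for
#' feedforward transmission from the input layers (L4C) to a target site:
#' \deqn{K(t) = e^{-(\ln t - \Delta t_1)^2 / 2\sigma_1^2} -
#'       g\, e^{-(\ln t - \Delta t_2)^2 / 2\sigma_2^2}, \quad t > 0,}
#' and \eqn{K(t) = 0} for \eqn{t \le 0}. With `g = 0` the kernel is a single
#' lobe peaking at `exp(dt1)` ms.
#'
#' Normalisation: `"none"` returns the raw formula values; `"peak"` scales to
#' maximum 1 (used for the recurrent course, whose weight then carries the
#' component's peak amplitude); `"area"` divides by the discrete area of the
#' positive first lobe, which is the scaling used for feedforward kernels
#' inside the model - with unit-area kernels the pathway weight carries the
#' transmitted response amplitude and stays identifiable (with unit-peak
#' kernels only the product of weight and kernel area is constrained by the
#' data when the kernel is narrow relative to the drive).
#'
#' @param dt1,dt2 Centres of the two lobes in log-ms (peak times `exp(dt)`).
#' @param sigma1,sigma2 Widths of the lobes in log-time units; must be > 0.
#' @param g Gain of the subtractive second lobe, in \[0, 1\].
#' @param timebase Delay grid in ms (default the causal fit window, 0-150 ms
#'   in 2-ms bins).
#' @param normalize `"none"` (default), `"peak"`, or `"area"` (see Details).
#' @return Numeric vector of kernel values on `timebase`.
#' @export
#' @examples
#' k <- lognormal_kernel(log(52), sigma1 = 0.4)
#' fit_timebase()[which.max(k)] # 52 ms
lognormal_kernel <- function(dt1, sigma1, dt2 = dt1, sigma2 = sigma1, g = 0,
                             timebase = fit_timebase(),
                             normalize = c("none", "peak", "area")) {
  normalize <- match.arg(normalize)
  if (sigma1 <= 0 || sigma2 <= 0) {
    abort("kernel widths `sigma1`, `sigma2` must be positive")
  }
  k <- numeric(length(timebase))
  pos <- timebase > 0
  lt <- log(timebase[pos])
  lobe1 <- exp(-(lt - dt1)^2 / (2 * sigma1^2))
  k[pos] <- lobe1 - g * exp(-(lt - dt2)^2 / (2 * sigma2^2))
  if (normalize == "peak" && max(k) > 0) {
    k <- k / max(k)
  } else if (normalize == "area") {
    # net area, floored at 2% of the positive lobe's area so strongly
    # biphasic kernels cannot blow up numerically
    a <- max(sum(k), 0.02 * sum(lobe1))
    if (a > 0) k <- k / a
  }
  k
}

#' Recurrent response time course
#'
#' Unit-peak log-normal time course of the local recurrent component; its
#' default centre `log(65)` places the peak near 65 ms, after the feedforward
#' drive peak (about 52 ms).
#'
#' @param dt_rec Centre in log-ms.
#' @param sigma_rec Width in log-time units.
#' @inheritParams lognormal_kernel
#' @return Numeric vector on `timebase`, maximum 1.
#' @export
recurrent_course <- function(dt_rec = log(65), sigma_rec = 0.35,
                             timebase = fit_timebase()) {
  lognormal_kernel(dt_rec, sigma_rec, g = 0, timebase = timebase,
                   normalize = "peak")
}

# causal discrete convolution on a shared uniform grid (no bin-width scaling;
# weights absorb the constant)
.conv_causal <- function(x, k) {
  n <- length(x)
  stopifnot(length(k) == n)
  out <- stats::convolve(x, rev(k), type = "open")
  out[seq_len(n)]
}

#' Feedforward-recurrent model parameters
#'
#' Bundle of all parameters of the three-component laminar response model for
#' one recording site: pathway weights `w_m`, `w_p`, the two log-normal kernel
#' parameter sets, the recurrent time-course parameters, and the SF-dependent
#' recurrent weights `w_rec` (one per SF condition; the only parameters allowed
#' to vary with SF).
#'
#' @param w_m,w_p Nonnegative feedforward weights for the M (L4Ca) and P
#'   (L4Cb) pathways.
#' @param dt_m1,dt_m2,sigma_m1,sigma_m2,g_m M-pathway kernel parameters.
#' @param dt_p1,dt_p2,sigma_p1,sigma_p2,g_p P-pathway kernel parameters.
#' @param dt_rec,sigma_rec Recurrent time-course parameters.
#' @param w_rec Named numeric vector of nonnegative recurrent weights, one per
#'   SF condition (names are SF values in cycles/degree).
#' @return An object of class `ffrec_params`.
#' @export
ffrec_params <- function(w_m, w_p,
                         dt_m1, sigma_m1, dt_m2 = dt_m1, sigma_m2 = sigma_m1,
                         g_m = 0,
                         dt_p1 = dt_m1, sigma_p1 = sigma_m1, dt_p2 = dt_p1,
                         sigma_p2 = sigma_p1, g_p = 0,
                         dt_rec = log(65), sigma_rec = 0.35,
                         w_rec = numeric(0)) {
  if (w_m < 0 || w_p < 0 || any(w_rec < 0)) {
    abort("weights must be nonnegative")
  }
  if (any(c(sigma_m1, sigma_m2, sigma_p1, sigma_p2, sigma_rec) <= 0)) {
    abort("all sigma parameters must be positive")
  }
  structure(
    list(
      w_m = w_m, w_p = w_p,
      dt_m1 = dt_m1, sigma_m1 = sigma_m1, dt_m2 = dt_m2, sigma_m2 = sigma_m2,
      g_m = g_m,
      dt_p1 = dt_p1, sigma_p1 = sigma_p1, dt_p2 = dt_p2, sigma_p2 = sigma_p2,
      g_p = g_p,
      dt_rec = dt_rec, sigma_rec = sigma_rec,
      w_rec = w_rec
    ),
    class = "ffrec_params"
  )
}

#' @export
print.ffrec_params <- function(x, ...) {
  cat("<ffrec_params>\n")
  cat(sprintf("  w_m = %.3g, w_p = %.3g\n", x$w_m, x$w_p))
  cat(sprintf("  M kernel peak %.1f ms, P kernel peak %.1f ms, rec peak %.1f ms\n",
              exp(x$dt_m1), exp(x$dt_p1), exp(x$dt_rec)))
  if (length(x$w_rec)) {
    cat("  w_rec:", paste(sprintf("%s:%.3g", names(x$w_rec), x$w_rec),
                          collapse = " "), "\n")
  } else {
    cat("  w_rec: (none; pure feedforward)\n")
  }
  invisible(x)
}

.check_drives <- function(drives) {
  stopifnot(is.list(drives), !is.null(drives$sf), !is.null(drives$time),
            is.matrix(drives$m), is.matrix(drives$p))
  if (!identical(dim(drives$m), dim(drives$p)) ||
      nrow(drives$m) != length(drives$sf) ||
      ncol(drives$m) != length(drives$time)) {
    abort("drive matrices must be [n_sf x n_time] and match `sf` and `time`")
  }
  invisible(drives)
}

#' Predict responses from the feedforward (FF) model
#'
#' The FF model predicts a site's dynamic response at every SF as the weighted
#' sum of the input-layer drives convolved with the pathway kernels:
#' \deqn{\hat R(sf,t) = w_m\, (R_m(sf,\cdot) * K_m)(t) +
#'                      w_p\, (R_p(sf,\cdot) * K_p)(t).}
#'
#' @param params An [ffrec_params()] object (its `w_rec` is ignored here).
#' @param drives Input drives as produced by [make_input_drives()]: a list with
#'   `sf`, `time`, and matrices `m`, `p` of dimension `[n_sf, n_time]`.
#' @return Matrix `[n_sf, n_time]` of predicted responses.
#' @export
predict_ff <- function(params, drives) {
  .check_drives(drives)
  tb <- drives$time
  km <- lognormal_kernel(params$dt_m1, params$sigma_m1, params$dt_m2,
                         params$sigma_m2, params$g_m, timebase = tb,
                         normalize = "area")
  kp <- lognormal_kernel(params$dt_p1, params$sigma_p1, params$dt_p2,
                         params$sigma_p2, params$g_p, timebase = tb,
                         normalize = "area")
  out <- params$w_m * t(apply(drives$m, 1, .conv_causal, k = km)) +
    params$w_p * t(apply(drives$p, 1, .conv_causal, k = kp))
  dimnames(out) <- dimnames(drives$m)
  out
}

#' Predict responses from the feedforward + recurrent (FF & Rec) model
#'
#' Adds to [predict_ff()] an SF-dependent recurrent component
#' \eqn{w_{rec}(sf)\, R_{rec}(t)} whose time course is shared across SFs and
#' whose weight varies per SF condition.
#'
#' @inheritParams predict_ff
#' @return Matrix `[n_sf, n_time]` of predicted responses.
#' @export
predict_ffrec <- function(params, drives) {
  .check_drives(drives)
  wr <- .match_wrec(params$w_rec, drives$sf)
  rec <- recurrent_course(params$dt_rec, params$sigma_rec,
                          timebase = drives$time)
  predict_ff(params, drives) + outer(wr, rec)
}

.match_wrec <- function(w_rec, sf) {
  if (length(w_rec) == 0) return(rep(0, length(sf)))
  nm <- names(w_rec)
  if (is.null(nm)) {
    if (length(w_rec) != length(sf)) {
      abort("`w_rec` must be named by SF or have one weight per SF condition")
    }
    return(as.numeric(w_rec))
  }
  idx <- match(as.character(sf), as.character(as.numeric(nm)))
  if (anyNA(idx)) {
    abort(paste("missing recurrent weight for SF condition(s):",
                paste(sf[is.na(idx)], collapse = ", ")))
  }
  as.numeric(w_rec[idx])
}

#' Adjusted goodness of fit
#'
#' Degrees-of-freedom adjusted goodness of fit used to compare the FF model
#' (12 parameters) with the richer FF & Rec model (14 + one recurrent weight
#' per SF condition):
#' \deqn{gof_{adj} = 1 - (N - 1)(1 - gof_{raw}) / (N - P - 1),}
#' with `N` the number of samples (time bins x SF conditions) and `P` the
#' number of free parameters.
#'
#' @param gof_raw Raw goodness of fit (1 - SSE/SStot).
#' @param n Number of samples.
#' @param p Number of free parameters.
#' @return Adjusted goodness of fit (scalar).
#' @export
#' @examples
#' adjusted_gof(0.9, 101, 20) # 0.875
adjusted_gof <- function(gof_raw, n, p) {
  if (n <= p + 1) abort("need n > p + 1 samples for the adjustment")
  1 - (n - 1) * (1 - gof_raw) / (n - p - 1)
}

# ---- fitting -----------------------------------------------------------

# stacked causal-convolution operator of the drives: X_q = Tq %*% kernel,
# rows ordered (sf slow, t fast); precomputed once per fit
.conv_operator <- function(drive_mat) {
  nsf <- nrow(drive_mat); nt <- ncol(drive_mat)
  ind <- outer(seq_len(nt), seq_len(nt), function(r, c) r - c + 1L)
  keep <- ind >= 1L
  out <- matrix(0, nsf * nt, nt)
  for (j in seq_len(nsf)) {
    block <- matrix(0, nt, nt)
    block[keep] <- drive_mat[j, ind[keep]]
    out[(j - 1) * nt + seq_len(nt), ] <- block
  }
  out
}

# design matrix columns for the linear weights given nonlinear kernel params
# theta: named vector; ops: precomputed .conv_operator list (optional)
.ffrec_design <- function(theta, drives, variant, ops = NULL) {
  tb <- drives$time
  nsf <- length(drives$sf)
  nt <- length(tb)
  km <- lognormal_kernel(theta[["dt_m1"]], theta[["sigma_m1"]],
                         theta[["dt_m2"]], theta[["sigma_m2"]],
                         theta[["g_m"]], timebase = tb, normalize = "area")
  kp <- lognormal_kernel(theta[["dt_p1"]], theta[["sigma_p1"]],
                         theta[["dt_p2"]], theta[["sigma_p2"]],
                         theta[["g_p"]], timebase = tb, normalize = "area")
  if (is.null(ops)) {
    ops <- list(m = .conv_operator(drives$m), p = .conv_operator(drives$p))
  }
  X <- cbind(m = as.vector(ops$m %*% km), p = as.vector(ops$p %*% kp))
  if (variant == "ffrec") {
    rec <- recurrent_course(theta[["dt_rec"]], theta[["sigma_rec"]],
                            timebase = tb)
    R <- matrix(0, nsf * nt, nsf)
    for (j in seq_len(nsf)) R[(j - 1) * nt + seq_len(nt), j] <- rec
    colnames(R) <- paste0("rec_", drives$sf)
    X <- cbind(X, R)
  }
  X
}

# nonnegative least squares, Lawson-Hanson active-set algorithm on the
# normal equations (the design has at most 2 + n_sf columns, so the small
# Gram-matrix solves dominate nothing)
.nnls_normal <- function(XtX, Xty, tol = 1e-10) {
  n <- length(Xty)
  beta <- numeric(n)
  passive <- logical(n)
  w <- Xty
  scale <- max(abs(w), 1)
  for (outer in seq_len(3 * n)) {
    cand <- which(!passive & w > tol * scale)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      b <- tryCatch(
        solve(XtX[passive, passive, drop = FALSE], Xty[passive]),
        error = function(e) NULL
      )
      if (is.null(b)) { passive[which(passive)[1]] <- FALSE; break }
      s[passive] <- b
      if (all(s[passive] > tol)) { beta <- s; break }
      neg <- passive & s <= tol
      alpha <- min(beta[neg] / (beta[neg] - s[neg]))
      beta <- beta + alpha * (s - beta)
      passive[passive & beta <= tol] <- FALSE
      beta[!passive] <- 0
    }
    w <- Xty - XtX %*% beta
  }
  beta
}

.nnls_fit <- function(X, y, tol = 1e-10) {
  .nnls_normal(crossprod(X), drop(crossprod(X, y)), tol = tol)
}

.ffrec_sse <- function(theta, drives, variant, y, ops = NULL, yty = NULL) {
  X <- .ffrec_design(theta, drives, variant, ops = ops)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  beta <- .nnls_normal(XtX, Xty)
  if (is.null(yty)) yty <- sum(y^2)
  max(yty - 2 * sum(beta * Xty) + drop(crossprod(beta, XtX %*% beta)), 0)
}

# deterministic multi-start grid over nonlinear parameters; the first start
# is the package's canonical kinetics (fast biphasic kernels, 65-ms
# recurrent course), the rest a fixed quasi-grid
.ffrec_starts <- function(variant, n_starts) {
  canonical <- c(
    dt_m1 = log(15), sigma_m1 = 0.4, dt_m2 = log(40), sigma_m2 = 0.3,
    g_m = 0.25,
    dt_p1 = log(18), sigma_p1 = 0.45, dt_p2 = log(45), sigma_p2 = 0.3,
    g_p = 0.2
  )
  if (variant == "ffrec") {
    canonical <- c(canonical, dt_rec = log(65), sigma_rec = 0.35)
  }
  if (n_starts == 1) return(list(canonical))
  dt_grid <- log(c(15, 25, 40, 52, 65, 80, 100, 120, 30, 55))
  sig_grid <- c(0.3, 0.5, 0.7, 0.4, 0.6, 0.35, 0.45, 0.55, 0.65, 0.5)
  g_grid <- c(0, 0.2, 0.4, 0.1, 0.3, 0, 0.2, 0.4, 0.1, 0.3)
  starts <- vector("list", n_starts - 1)
  for (i in seq_len(n_starts - 1)) {
    th <- c(
      dt_m1 = dt_grid[(i - 1) %% 10 + 1], sigma_m1 = sig_grid[(i - 1) %% 10 + 1],
      dt_m2 = dt_grid[i %% 10 + 1], sigma_m2 = sig_grid[i %% 10 + 1],
      g_m = g_grid[(i - 1) %% 10 + 1],
      dt_p1 = dt_grid[(i - 1) %% 10 + 1], sigma_p1 = sig_grid[(i - 1) %% 10 + 1],
      dt_p2 = dt_grid[i %% 10 + 1], sigma_p2 = sig_grid[i %% 10 + 1],
      g_p = g_grid[(i - 1) %% 10 + 1]
    )
    if (variant == "ffrec") {
      th <- c(th, dt_rec = log(c(65, 50, 80, 65, 90, 60, 70, 75, 55, 85))[(i - 1) %% 10 + 1],
              sigma_rec = sig_grid[(i - 1) %% 10 + 1])
    }
    starts[[i]] <- th
  }
  c(list(canonical), starts)
}

.ffrec_bounds <- function(variant) {
  lower <- c(dt_m1 = log(10), sigma_m1 = 0.05, dt_m2 = log(10), sigma_m2 = 0.05,
             g_m = 0, dt_p1 = log(10), sigma_p1 = 0.05, dt_p2 = log(10),
             sigma_p2 = 0.05, g_p = 0)
  upper <- c(dt_m1 = log(140), sigma_m1 = 1.5, dt_m2 = log(140), sigma_m2 = 1.5,
             g_m = 1, dt_p1 = log(140), sigma_p1 = 1.5, dt_p2 = log(140),
             sigma_p2 = 1.5, g_p = 1)
  if (variant == "ffrec") {
    lower <- c(lower, dt_rec = log(10), sigma_rec = 0.05)
    upper <- c(upper, dt_rec = log(140), sigma_rec = 1.5)
  }
  list(lower = lower, upper = upper)
}

#' Fit the FF or FF & Rec model to a site's dynamic responses
#'
#' Minimizes the summed squared error between observed and predicted responses
#' jointly over all SF conditions of one site. The linear weights (`w_m`,
#' `w_p`, and `w_rec(sf)` for the FF & Rec variant) are profiled out by
#' nonnegativity-constrained least squares inside a bounded multi-start
#' L-BFGS-B search over the nonlinear kernel parameters; the optimisation is
#' fully deterministic (fixed start grid).
#'
#' @param responses Matrix `[n_sf, n_time]` of observed responses (spikes/s)
#'   on the same grid as `drives$time` (the causal fit window, 0-150 ms).
#' @param drives Input-layer drives, see [make_input_drives()].
#' @param variant `"ff"` (feedforward only, 12 free parameters) or `"ffrec"`
#'   (feedforward + recurrent, 14 + `n_sf` free parameters).
#' @param n_starts Number of deterministic multi-starts (default 10).
#' @param polish_rounds Rounds of simplex + quasi-Newton polishing applied to
#'   the best restart (default 3; reduce for speed on noisy data).
#' @return An object of class `ffrec_fit` with elements `params`
#'   ([ffrec_params()]), `variant`, `gof_raw`, `gof_adj`, `sse`, `n`, `p_free`,
#'   and `fitted` (the predicted response matrix).
#' @export
fit_model <- function(responses, drives, variant = c("ffrec", "ff"),
                      n_starts = 10, polish_rounds = 3) {
  variant <- match.arg(variant)
  .check_drives(drives)
  if (!is.matrix(responses) || !identical(dim(responses), dim(drives$m))) {
    abort("`responses` must be a [n_sf x n_time] matrix matching the drives")
  }
  if (length(drives$sf) < 2) abort("need at least 2 SF conditions")
  y <- as.vector(t(responses))
  n <- length(y)
  p_free <- if (variant == "ff") 12L else 14L + length(drives$sf)
  if (n <= p_free + 1) abort("too few samples for the free-parameter count")

  bounds <- .ffrec_bounds(variant)
  ops <- list(m = .conv_operator(drives$m), p = .conv_operator(drives$p))
  clamp <- function(p) pmin(pmax(p, bounds$lower), bounds$upper)
  obj <- function(p) .ffrec_sse(clamp(p), drives, variant, y, ops = ops)
  best <- NULL
  for (th0 in .ffrec_starts(variant, n_starts)) {
    res <- tryCatch(
      optim(th0, .ffrec_sse, drives = drives, variant = variant, y = y,
            ops = ops, method = "L-BFGS-B", lower = bounds$lower,
            upper = bounds$upper, control = list(maxit = 250, factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
    if (!is.null(best) && best$value <= 1e-10 * sum(y^2)) break
  }
  if (is.null(best)) abort("optimizer failed on all restarts")
  # polish the best start: alternate simplex and bounded quasi-Newton rounds
  # (the SSE surface has narrow curved valleys in the kernel parameters)
  sse_floor <- 1e-10 * sum(y^2)
  for (round in seq_len(polish_rounds)) {
    if (best$value <= sse_floor) break
    nm <- tryCatch(
      optim(best$par, obj, method = "Nelder-Mead",
            control = list(maxit = 1200, reltol = 1e-14)),
      error = function(e) NULL
    )
    par0 <- if (!is.null(nm) && nm$value < best$value) clamp(nm$par) else
      best$par
    bb <- tryCatch(
      optim(par0, .ffrec_sse, drives = drives, variant = variant, y = y,
            ops = ops, method = "L-BFGS-B", lower = bounds$lower,
            upper = bounds$upper,
            control = list(maxit = 800, factr = 10, pgtol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(bb) && bb$value <= best$value) best <- bb
    else if (!is.null(nm) && nm$value < best$value)
      best <- list(par = clamp(nm$par), value = nm$value,
                   convergence = nm$convergence)
  }

  theta <- best$par
  X <- .ffrec_design(theta, drives, variant, ops = ops)
  beta <- .nnls_fit(X, y)
  sse <- sum((y - X %*% beta)^2)
  sstot <- sum((y - mean(y))^2)
  if (sstot <= 0) abort("responses have zero variance; nothing to fit")
  gof_raw <- 1 - sse / sstot

  w_rec <- if (variant == "ffrec") {
    setNames(beta[-(1:2)], as.character(drives$sf))
  } else numeric(0)
  params <- ffrec_params(
    w_m = beta[[1]], w_p = beta[[2]],
    dt_m1 = theta[["dt_m1"]], sigma_m1 = theta[["sigma_m1"]],
    dt_m2 = theta[["dt_m2"]], sigma_m2 = theta[["sigma_m2"]],
    g_m = theta[["g_m"]],
    dt_p1 = theta[["dt_p1"]], sigma_p1 = theta[["sigma_p1"]],
    dt_p2 = theta[["dt_p2"]], sigma_p2 = theta[["sigma_p2"]],
    g_p = theta[["g_p"]],
    dt_rec = if (variant == "ffrec") theta[["dt_rec"]] else log(65),
    sigma_rec = if (variant == "ffrec") theta[["sigma_rec"]] else 0.35,
    w_rec = w_rec
  )
  fitted <- if (variant == "ffrec") predict_ffrec(params, drives) else
    predict_ff(params, drives)
  structure(
    list(params = params, variant = variant, gof_raw = gof_raw,
         gof_adj = adjusted_gof(gof_raw, n, p_free), sse = sse, n = n,
         p_free = p_free, fitted = fitted, sf = drives$sf, time = drives$time,
         convergence = best$convergence),
    class = "ffrec_fit"
  )
}

#' @export
print.ffrec_fit <- function(x, ...) {
  cat(sprintf("<ffrec_fit: %s model, %d SFs x %d bins>\n",
              toupper(x$variant), length(x$sf), length(x$time)))
  cat(sprintf("  gof_raw = %.4f, gof_adj = %.4f (P = %d)\n",
              x$gof_raw, x$gof_adj, x$p_free))
  print(x$params)
  invisible(x)
}

# ---- decomposition -----------------------------------------------------

#' Laminar activation patterns of the three model components
#'
#' Splits each fitted site's FF & Rec prediction into its three mechanism
#' components: the M-pathway feedforward part
#' \eqn{LAP_m = w_m (R_m * K_m)}, the P-pathway part
#' \eqn{LAP_p = w_p (R_p * K_p)}, and the recurrent part
#' \eqn{LAP_{rec} = w_{rec}(sf) R_{rec}(t)}. The three sum pointwise to the
#' model prediction.
#'
#' @param fits List of `ffrec_fit` objects (one per site). Fits with
#'   `gof_raw <= gof_min` are dropped with a warning.
#' @param drives Shared input-layer drives.
#' @param data Optional list of observed response matrices (same order as
#'   `fits`), stored as the `data` field for contribution analysis.
#' @param gof_min Validity threshold on the raw goodness of fit (default 0.8).
#' @return An object of class `lap_set`: arrays `m`, `p`, `rec` (and `data` if
#'   supplied) of dimension `[n_sf, n_time, n_site]`, plus `sf`, `time`, and
#'   the indices of the sites kept.
#' @export
laminar_activation_patterns <- function(fits, drives, data = NULL,
                                        gof_min = 0.8) {
  .check_drives(drives)
  stopifnot(is.list(fits), length(fits) >= 1)
  ok <- vapply(fits, function(f) f$gof_raw > gof_min, logical(1))
  if (!all(ok)) {
    warn(sprintf("dropping %d site(s) with gof_raw <= %.2f", sum(!ok), gof_min))
  }
  if (!any(ok)) abort("no valid fits (all gof_raw below threshold)")
  keep <- which(ok)
  nsf <- length(drives$sf); nt <- length(drives$time); ns <- length(keep)
  dims <- c(nsf, nt, ns)
  arr <- function() array(0, dims)
  out <- list(m = arr(), p = arr(), rec = arr(),
              data = if (!is.null(data)) arr() else NULL,
              sf = drives$sf, time = drives$time, sites = keep)
  for (s in seq_along(keep)) {
    f <- fits[[keep[s]]]
    pm <- f$params
    ff_m <- ffrec_params(w_m = pm$w_m, w_p = 0, dt_m1 = pm$dt_m1,
                         sigma_m1 = pm$sigma_m1, dt_m2 = pm$dt_m2,
                         sigma_m2 = pm$sigma_m2, g_m = pm$g_m,
                         dt_p1 = pm$dt_p1, sigma_p1 = pm$sigma_p1)
    ff_p <- ffrec_params(w_m = 0, w_p = pm$w_p, dt_m1 = pm$dt_m1,
                         sigma_m1 = pm$sigma_m1,
                         dt_p1 = pm$dt_p1, sigma_p1 = pm$sigma_p1,
                         dt_p2 = pm$dt_p2, sigma_p2 = pm$sigma_p2,
                         g_p = pm$g_p)
    out$m[, , s] <- predict_ff(ff_m, drives)
    out$p[, , s] <- predict_ff(ff_p, drives)
    wr <- .match_wrec(pm$w_rec, drives$sf)
    out$rec[, , s] <- outer(wr, recurrent_course(pm$dt_rec, pm$sigma_rec,
                                                 timebase = drives$time))
    if (!is.null(data)) out$data[, , s] <- data[[keep[s]]]
  }
  structure(out, class = "lap_set")
}

#' Placement-level contributions of the three mechanisms
#'
#' For each SF condition, the contribution of mechanism
#' \eqn{q \in \{m, p, rec\}} is the variance-explained-style score
#' \deqn{C_q(sf) = 1 - \frac{\sum_{t,i} (LAP_{data} - LAP_q)^2}
#'                         {\sum_{t,i} (LAP_{data} - \overline{LAP_{data}})^2}.}
#' Raw scores can be negative; they are floored at 0 and then normalized to
#' sum to 1 across the three mechanisms.
#'
#' @param laps A `lap_set` from [laminar_activation_patterns()] with a `data`
#'   field, or pass `data` explicitly.
#' @param data Optional `[n_sf, n_time, n_site]` array of observed responses.
#' @return Tibble with columns `sf`, `component`, `contribution_raw`,
#'   `contribution` (normalized).
#' @export
contributions <- function(laps, data = laps$data) {
  stopifnot(inherits(laps, "lap_set"))
  if (is.null(data)) abort("observed data required (supply `data`)")
  nsf <- length(laps$sf)
  rows <- vector("list", nsf)
  for (j in seq_len(nsf)) {
    d <- data[j, , , drop = FALSE]
    sstot <- sum((d - mean(d))^2)
    if (sstot <= 0) abort("zero data variance at an SF condition")
    raw <- vapply(c("m", "p", "rec"), function(q) {
      1 - sum((d - laps[[q]][j, , , drop = FALSE])^2) / sstot
    }, numeric(1))
    flo <- pmax(raw, 0)
    tot <- sum(flo)
    norm <- if (tot > 0) flo / tot else rep(NA_real_, 3)
    rows[[j]] <- tibble::tibble(
      sf = laps$sf[j], component = c("m", "p", "rec"),
      contribution_raw = unname(raw), contribution = unname(norm)
    )
  }
  dplyr::bind_rows(rows)
}

#' MP index: relative M- vs P-pathway feedforward contribution
#'
#' \eqn{(C_p - C_m) / (C_p + C_m)}; -1 for a purely M-driven site, +1 for a
#' purely P-driven one.
#'
#' @param c_m,c_p Nonnegative contributions of the M and P mechanisms.
#' @return Index in \[-1, 1\].
#' @export
#' @examples
#' mp_index(0.2, 0.6) # 0.5
mp_index <- function(c_m, c_p) {
  if (any(c_m + c_p <= 0)) abort("C_m + C_p must be positive")
  (c_p - c_m) / (c_p + c_m)
}

#' Per-site contributions from peak component strengths
#'
#' For each site and SF condition, the raw contribution of each mechanism is
#' the maximum over time of its activation pattern; raw values are normalized
#' to sum to 1 across the three mechanisms.
#'
#' @inheritParams contributions
#' @return Tibble with columns `site`, `sf`, `component`, `contribution_raw`,
#'   `contribution`.
#' @export
site_contributions <- function(laps) {
  stopifnot(inherits(laps, "lap_set"))
  nsf <- length(laps$sf); ns <- dim(laps$m)[3]
  grid <- expand.grid(j = seq_len(nsf), s = seq_len(ns))
  rows <- purrr::pmap(grid, function(j, s) {
    raw <- vapply(c("m", "p", "rec"),
                  function(q) max(laps[[q]][j, , s]), numeric(1))
    tot <- sum(raw)
    if (tot <= 0) {
      norm <- rep(NA_real_, 3)
    } else {
      norm <- raw / tot
    }
    tibble::tibble(site = laps$sites[s], sf = laps$sf[j],
                   component = c("m", "p", "rec"),
                   contribution_raw = unname(raw), contribution = unname(norm))
  })
  dplyr::bind_rows(rows)
}
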