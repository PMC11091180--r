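#' Fit a vector autoregression by least squares
#'
#' Pools all trials of a laminar multichannel recording and estimates VAR
#' coefficient matrices per lag plus the innovation covariance by ordinary
#' least squares. The default order of 15 lags at the 500-Hz time base spans
#' 30 ms of history.
#'
#' @param series Array `[E, T, N]` (channels x time x trials) or a `[E, T]`
#'   matrix for a single trial.
#' @param order Model order (lags), default 15.
#' @return Object of class `var_fit`: `A` (`[E, E, order]`), `sigma`,
#'   `order`, `spectral_radius`, `n_obs`.
#' @export
fit_var <- function(series, order = 15) {
  if (is.matrix(series)) series <- array(series, c(dim(series), 1))
  stopifnot(length(dim(series)) == 3)
  e <- dim(series)[1]; tt <- dim(series)[2]; n <- dim(series)[3]
  p <- as.integer(order)
  if (tt <= p * e) abort("trial length too short for the requested order")
  # demean per channel (ensemble mean)
  mu <- rowMeans(series, dims = 1)
  series <- sweep(series, 1, mu)

  m_per <- tt - p
  mm <- m_per * n
  Y <- matrix(0, e, mm)
  Z <- matrix(0, e * p, mm)
  for (tr in seq_len(n)) {
    x <- series[, , tr]
    cols <- (tr - 1) * m_per + seq_len(m_per)
    Y[, cols] <- x[, (p + 1):tt, drop = FALSE]
    for (k in seq_len(p)) {
      Z[(k - 1) * e + seq_len(e), cols] <- x[, (p + 1 - k):(tt - k),
                                             drop = FALSE]
    }
  }
  ZZt <- Z %*% t(Z)
  ok <- tryCatch({
    ch <- chol(ZZt); TRUE
  }, error = function(err) FALSE)
  if (!ok) abort("rank-deficient regressors; cannot estimate the VAR")
  Astack <- t(solve(ZZt, Z %*% t(Y)))
  resid <- Y - Astack %*% Z
  sigma <- resid %*% t(resid) / (mm - 1)
  A <- array(Astack, c(e, e, p))
  rho <- .companion_radius(A)
  if (rho >= 1) {
    warn(sprintf("estimated VAR is unstable (spectral radius %.3f)", rho))
  }
  structure(list(A = A, sigma = sigma, order = p, spectral_radius = rho,
                 n_obs = mm, mean = mu),
            class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("<var_fit: %d channels, order %d, %d obs, spectral radius %.3f>\n",
              dim(x$A)[1], x$order, x$n_obs, x$spectral_radius))
  invisible(x)
}

# autocovariance sequence Gamma_k = E[X_t X_{t-k}'] of a VAR, k = 0..q,
# via the companion-form Lyapunov equation solved by doubling iteration
.var_autocov <- function(A, sigma, q = NULL, tol = 1e-8) {
  e <- dim(A)[1]; p <- dim(A)[3]
  comp <- .companion_matrix(A)
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) abort("non-stationary VAR; autocovariance undefined")
  if (is.null(q)) {
    q <- if (rho < .Machine$double.eps) p + 1 else
      ceiling(log(tol) / log(rho))
    q <- min(max(q, p + 1), 1000)
  }
  sigc <- matrix(0, e * p, e * p)
  sigc[1:e, 1:e] <- sigma
  S <- sigc; Q <- comp
  for (it in 1:100) {
    S <- S + Q %*% S %*% t(Q)
    Q <- Q %*% Q
    if (max(abs(Q)) < 1e-14) break
  }
  G <- array(0, c(e, e, q + 1))
  for (k in 0:min(p - 1, q)) G[, , k + 1] <- S[1:e, k * e + 1:e]
  if (q >= p) {
    for (k in p:q) {
      acc <- matrix(0, e, e)
      for (j in seq_len(p)) acc <- acc + A[, , j] %*% G[, , k - j + 1]
      G[, , k + 1] <- acc
    }
  }
  G
}

# solve the multivariate Yule-Walker system at full available order by
# Whittle's forward/backward recursion; returns the forward residual
# covariance (and coefficients)
.autocov_to_var <- function(G) {
  e <- dim(G)[1]; q <- dim(G)[3] - 1
  G0 <- G[, , 1]
  Gk <- lapply(seq_len(q), function(k) G[, , k + 1])
  A <- list(Gk[[1]] %*% solve(G0))
  B <- list(t(Gk[[1]]) %*% solve(G0))
  vf <- function(A) {
    acc <- G0
    for (k in seq_along(A)) acc <- acc - A[[k]] %*% t(Gk[[k]])
    acc
  }
  vb <- function(B) {
    acc <- G0
    for (k in seq_along(B)) acc <- acc - B[[k]] %*% Gk[[k]]
    acc
  }
  for (m in seq_len(q - 1)) {
    d_f <- Gk[[m + 1]]
    d_b <- t(Gk[[m + 1]])
    for (k in seq_len(m)) {
      d_f <- d_f - A[[k]] %*% Gk[[m + 1 - k]]
      d_b <- d_b - B[[k]] %*% t(Gk[[m + 1 - k]])
    }
    a_last <- d_f %*% solve(vb(B))
    b_last <- d_b %*% solve(vf(A))
    A_new <- vector("list", m + 1)
    B_new <- vector("list", m + 1)
    for (k in seq_len(m)) {
      A_new[[k]] <- A[[k]] - a_last %*% B[[m + 1 - k]]
      B_new[[k]] <- B[[k]] - b_last %*% A[[m + 1 - k]]
    }
    A_new[[m + 1]] <- a_last
    B_new[[m + 1]] <- b_last
    A <- A_new; B <- B_new
  }
  list(A = A, sigma = vf(A))
}

#' Pairwise-conditional Granger causality matrix
#'
#' Time-domain conditional Granger causality for every ordered channel pair
#' (from j to i), conditioning on all remaining channels:
#' \deqn{GC_{j \to i} = \ln \Sigma^{(restricted)}_{ii} / \Sigma^{(full)}_{ii},}
#' where the restricted model omits channel j. The restricted models are
#' solved from the full model's autocovariance sequence (Whittle recursion),
#' not refit to data, so full and restricted models are mutually consistent.
#'
#' @param series Array `[E, T, N]` or matrix `[E, T]`; alternatively pass a
#'   pre-computed [fit_var()] object as `fit`.
#' @param order VAR model order (default 15).
#' @param fit Optional `var_fit` (overrides `series`/`order`).
#' @return Object of class `gc_matrix`: matrix `values[to, from]` with `NA`
#'   diagonal, plus the underlying `var_fit`.
#' @export
pairwise_conditional_gc <- function(series = NULL, order = 15, fit = NULL) {
  if (is.null(fit)) fit <- fit_var(series, order = order)
  e <- dim(fit$A)[1]
  if (e < 2) abort("need at least 2 channels")
  if (any(diag(fit$sigma) <= 0)) abort("non-positive residual variances")
  G <- .var_autocov(fit$A, fit$sigma)
  vals <- matrix(NA_real_, e, e)
  for (j in seq_len(e)) {
    sub <- setdiff(seq_len(e), j)
    red <- .autocov_to_var(G[sub, sub, , drop = FALSE])
    for (pos in seq_along(sub)) {
      i <- sub[pos]
      vals[i, j] <- max(0, log(red$sigma[pos, pos] / fit$sigma[i, i]))
    }
  }
  dimnames(vals) <- list(to = paste0("ch", seq_len(e)),
                         from = paste0("ch", seq_len(e)))
  structure(list(values = vals, fit = fit), class = "gc_matrix")
}

#' @export
print.gc_matrix <- function(x, ...) {
  cat(sprintf("<gc_matrix: %d channels (rows = to, cols = from)>\n",
              nrow(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Aggregate a GC matrix into feedforward / recurrent strengths
#'
#' Recurrent strength is the mean GC over ordered output-layer to
#' output-layer pairs (L2/3 to L2/3, i != j); feedforward strength the mean
#' over input-layer to output-layer pairs (L4C to L2/3). The normalized GC
#' index is recurrent / (recurrent + feedforward), in \[0, 1\].
#'
#' @param gc A `gc_matrix` or a plain `[to, from]` matrix.
#' @param layer_map Character vector of layer labels per channel.
#' @param output_layers,input_layers Layer labels counted as output (L2/3)
#'   and input (L4C).
#' @return A one-row tibble: `recurrent`, `feedforward`, `normalized_gc`,
#'   `n_rec_pairs`, `n_ff_pairs`.
#' @export
aggregate_connections <- function(gc, layer_map,
                                  output_layers = c("L2", "L3"),
                                  input_layers = c("L4Ca", "L4Cb")) {
  vals <- if (inherits(gc, "gc_matrix")) gc$values else gc
  e <- nrow(vals)
  if (length(layer_map) != e) abort("layer map must cover all channels")
  out_idx <- which(layer_map %in% output_layers)
  in_idx <- which(layer_map %in% input_layers)
  rec_pairs <- expand.grid(to = out_idx, from = out_idx)
  rec_pairs <- rec_pairs[rec_pairs$to != rec_pairs$from, , drop = FALSE]
  ff_pairs <- expand.grid(to = out_idx, from = in_idx)
  if (nrow(rec_pairs) == 0 || nrow(ff_pairs) == 0) {
    abort("no qualifying layer pairs for aggregation")
  }
  rec <- mean(vals[cbind(rec_pairs$to, rec_pairs$from)])
  ff <- mean(vals[cbind(ff_pairs$to, ff_pairs$from)])
  norm <- if (rec + ff > 0) rec / (rec + ff) else NA_real_
  tibble::tibble(recurrent = rec, feedforward = ff, normalized_gc = norm,
                 n_rec_pairs = nrow(rec_pairs), n_ff_pairs = nrow(ff_pairs))
}

#' Surrogate significance threshold for GC values
#'
#' Destroys cross-channel temporal structure by independent random circular
#' shifts of each channel (per trial), recomputes the GC matrix, and returns
#' the requested quantile of the pooled off-diagonal surrogate values.
#'
#' @param series Array `[E, T, N]` or matrix.
#' @param order VAR order.
#' @param n_surrogate Number of surrogate datasets (default 20).
#' @param probs Quantile (default 0.95).
#' @param seed Integer seed.
#' @return Scalar threshold (nats).
#' @export
gc_surrogate_threshold <- function(series, order = 15, n_surrogate = 20,
                                   probs = 0.95, seed = 1) {
  if (is.matrix(series)) series <- array(series, c(dim(series), 1))
  e <- dim(series)[1]; tt <- dim(series)[2]; n <- dim(series)[3]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vals <- numeric(0)
  for (s in seq_len(n_surrogate)) {
    shifted <- series
    for (tr in seq_len(n)) {
      for (ch in seq_len(e)) {
        k <- sample.int(tt, 1)
        idx <- ((seq_len(tt) + k - 1) %% tt) + 1
        shifted[ch, , tr] <- series[ch, idx, tr]
      }
    }
    g <- pairwise_conditional_gc(shifted, order = order)
    vals <- c(vals, g$values[!is.na(g$values)])
  }
  unname(quantile(vals, probs))
}
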