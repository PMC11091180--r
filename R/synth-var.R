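#' Ground truth for a stationary vector autoregression
#'
#' @param A Coefficient array `[E, E, p]` (lag order p).
#' @param sigma Innovation covariance `[E, E]` (default identity).
#' @param layer_map Character vector of layer labels per channel.
#' @return Object of class `var_ground_truth`. Errors if the companion-form
#'   spectral radius is >= 1 (non-stationary).
#' @export
var_ground_truth <- function(A, sigma = NULL, layer_map = NULL) {
  if (is.matrix(A)) A <- array(A, c(nrow(A), ncol(A), 1))
  stopifnot(length(dim(A)) == 3, dim(A)[1] == dim(A)[2])
  e <- dim(A)[1]
  if (is.null(sigma)) sigma <- diag(e)
  stopifnot(all(dim(sigma) == e))
  rho <- .companion_radius(A)
  if (rho >= 1) {
    abort(sprintf("unstable coefficient matrices (spectral radius %.3f >= 1)",
                  rho))
  }
  structure(list(A = A, sigma = sigma, order = dim(A)[3],
                 layer_map = layer_map, spectral_radius = rho),
            class = "var_ground_truth")
}

.companion_matrix <- function(A) {
  e <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, e * p, e * p)
  for (k in seq_len(p)) comp[1:e, (k - 1) * e + 1:e] <- A[, , k]
  if (p > 1) comp[(e + 1):(e * p), 1:(e * (p - 1))] <- diag(e * (p - 1))
  comp
}

.companion_radius <- function(A) {
  max(Mod(eigen(.companion_matrix(A), only.values = TRUE)$values))
}

#' Simulate multichannel time series from a VAR ground truth
#'
#' Draws `n_trials` independent trials of length `n_samples` from the
#' stationary VAR, after a burn-in of 500 samples per trial.
#'
#' @param ground_truth A [var_ground_truth()].
#' @param n_samples Samples per trial (T).
#' @param n_trials Number of trials (N).
#' @param seed Integer seed.
#' @return Array `[E, T, N]`.
#' @export
simulate_var <- function(ground_truth, n_samples, n_trials = 1, seed = 1) {
  stopifnot(inherits(ground_truth, "var_ground_truth"))
  A <- ground_truth$A; sig <- ground_truth$sigma
  e <- dim(A)[1]; p <- dim(A)[3]
  burn <- 500L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  L <- t(chol(sig))
  out <- array(0, c(e, n_samples, n_trials))
  for (tr in seq_len(n_trials)) {
    total <- n_samples + burn
    eps <- L %*% matrix(rnorm(e * total), e)
    x <- matrix(0, e, total + p)
    for (t in seq_len(total)) {
      acc <- eps[, t]
      for (k in seq_len(p)) acc <- acc + A[, , k] %*% x[, t + p - k]
      x[, t + p] <- acc
    }
    out[, , tr] <- x[, p + burn + seq_len(n_samples)]
  }
  out
}

#' Synthetic laminar VAR fixtures for the two column groups
#'
#' Small stationary VARs emulating the directed laminar connectivity of the
#' two groups: group 1 has strong input-to-output (L4C to L2/3) drive and no
#' recurrent L2/3 coupling; group 2 has strong recurrent coupling among L2/3
#' channels plus weaker feedforward drive.
#'
#' @param group 1 or 2.
#' @param n_l23,n_l4c Channels in the output (L2/3) and input (L4C) layers.
#' @param ff,rec Feedforward and recurrent coupling strengths.
#' @return A [var_ground_truth()] with `layer_map` filled in.
#' @export
make_var_ground_truth <- function(group, n_l23 = 4, n_l4c = 2,
                                  ff = NULL, rec = NULL) {
  if (!group %in% c(1, 2)) abort("`group` must be 1 or 2")
  if (is.null(ff)) ff <- if (group == 1) 0.35 else 0.15
  if (is.null(rec)) rec <- if (group == 1) 0 else 0.22
  e <- n_l23 + n_l4c
  layer_map <- c(rep("L2", n_l23), rep("L4Cb", n_l4c))
  A <- array(0, c(e, e, 2))
  diag(A[, , 1]) <- 0.3
  # feedforward: every L4C channel drives every L2/3 channel at lag 2
  for (i in seq_len(n_l23)) {
    for (j in n_l23 + seq_len(n_l4c)) A[i, j, 2] <- ff / n_l4c
  }
  # recurrent: directed ring among L2/3 channels at lag 1
  if (rec > 0 && n_l23 > 1) {
    for (i in seq_len(n_l23)) {
      j <- if (i == n_l23) 1L else i + 1L
      A[j, i, 1] <- rec
    }
  }
  var_ground_truth(A, diag(e), layer_map = layer_map)
}
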