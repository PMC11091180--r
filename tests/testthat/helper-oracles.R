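# Independent brute-force oracles used across tests.

# second spatial difference of an LFP matrix, element by element
oracle_csd <- function(lfp, h = 100) {
  n <- nrow(lfp)
  out <- matrix(NA_real_, n, ncol(lfp))
  for (z in 2:(n - 1)) {
    for (t in seq_len(ncol(lfp))) {
      out[z, t] <- -(lfp[z + 1, t] - 2 * lfp[z, t] + lfp[z - 1, t]) / h^2
    }
  }
  out
}

# sliding-window laminar mean, computed directly
oracle_laminar <- function(values, depths, window = 0.1, step = 0.02) {
  grid <- seq(0, 1, by = step)
  sapply(grid, function(g) {
    sel <- abs(depths - g) <= window / 2
    if (any(sel)) mean(values[sel]) else NA_real_
  })
}

# Hartigan dip by direct minimisation over band half-widths on a fine grid,
# with convex/concave feasibility via chull() convex hulls. Independent of
# the package's bisection/monotone-chain implementation; O(n^2) per d and
# only suitable for small n.
oracle_dip <- function(x, d_tol = 1e-4) {
  x <- sort(x)
  n <- length(x)
  u <- unique(x)
  cum <- cumsum(tabulate(match(x, u), nbins = length(u))) / n
  m <- length(u)
  hi <- function(i, d) min(c(0, cum)[i] + d, 1)
  lo <- function(i, d) max(cum[i] - d, 0)

  hull_lower <- function(xs, ys) {
    # lower convex hull via chull on augmented points, evaluated at xs
    if (length(xs) == 1) return(ys)
    pts <- cbind(xs, ys)
    idx <- chull(rbind(pts, c(mean(range(xs)), max(ys) + 10 * diff(range(ys)) + 1)))
    idx <- sort(idx[idx <= nrow(pts)])
    hx <- xs[idx]; hy <- ys[idx]
    approx(hx, hy, xout = xs, rule = 2)$y
  }
  left_ok <- function(k, d, v) {
    if (k == 1) return(TRUE)
    ys <- c(sapply(seq_len(k - 1), hi, d = d), v)
    hv <- hull_lower(u[1:k], ys)
    all(hv[seq_len(k - 1)] >= sapply(seq_len(k - 1), lo, d = d) - 1e-9)
  }
  right_ok <- function(k, d, v) {
    if (k == m) return(v <= min(cum[k] + d, 1) + 1e-12)
    ys <- c(v, sapply((k + 1):m, lo, d = d))
    hv <- -hull_lower(u[k:m], -ys) # upper concave hull via negation
    all(hv[-1] <= sapply((k + 1):m, hi, d = d) + 1e-9)
  }
  feasible <- function(d) {
    for (k in seq_len(m)) {
      hik <- hi(k, d)
      if (!left_ok(k, d, hik)) next
      # smallest feasible terminal value of the convex part (grid search)
      vs <- seq(0, hik, length.out = 64)
      ok <- vapply(vs, left_ok, logical(1), k = k, d = d)
      vmin <- vs[which(ok)[1]]
      vplus <- max(lo(k, d), vmin)
      if (vplus > min(cum[k] + d, 1) + 1e-12) next
      if (right_ok(k, d, vplus)) return(TRUE)
    }
    FALSE
  }
  dlo <- 0.5 / n - 1e-9; dhi <- 0.2500001
  if (feasible(dlo)) return(0.5 / n)
  while (dhi - dlo > d_tol) {
    mid <- (dlo + dhi) / 2
    if (feasible(mid)) dhi <- mid else dlo <- mid
  }
  dhi
}
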