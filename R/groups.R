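#' Output/input activation index
#'
#' Ratio of the window-averaged output-layer (L2/3) response to the
#' window-averaged input-layer (L4C) response, averaged over 0-120 ms after
#' stimulus onset. Values above 1 indicate cross-layer amplification, below 1
#' suppression.
#'
#' @param resp_l23,resp_l4c Layer-mean responses: numeric vectors over time,
#'   or `[n_sf x n_time]` matrices (then one index per SF is returned).
#' @param time Time axis in ms matching the columns (default the full
#'   -20..150 grid).
#' @param window Averaging window in ms, default (0, 120).
#' @return Numeric activation index (one value, or one per SF).
#' @export
output_input_activation <- function(resp_l23, resp_l4c,
                                    time = response_timebase(),
                                    window = c(0, 120)) {
  if (is.vector(resp_l23)) resp_l23 <- matrix(resp_l23, 1)
  if (is.vector(resp_l4c)) resp_l4c <- matrix(resp_l4c, 1)
  idx <- which(time >= window[1] & time <= window[2])
  out_mean <- rowMeans(resp_l23[, idx, drop = FALSE])
  in_mean <- rowMeans(resp_l4c[, idx, drop = FALSE])
  if (any(in_mean <= 0)) {
    abort("input-layer mean response is not positive; activation undefined")
  }
  unname(out_mean / in_mean)
}

#' Per-SF activation indices of a placement
#'
#' Convenience wrapper: averages the responses of all L2/3 and all L4C sites
#' of a placement (keeping, per SF, only sites whose window-averaged response
#' is positive) and computes the output/input activation at every SF.
#'
#' @param placement A [simulate_placement()] object.
#' @param window Averaging window in ms.
#' @param clean Use noiseless responses.
#' @return Tibble with `sf` and `activation`.
#' @export
placement_activation <- function(placement, window = c(0, 120),
                                 clean = FALSE) {
  src <- if (clean) placement$clean else placement$responses
  idx <- which(placement$time >= window[1] & placement$time <= window[2])
  layer_vals <- function(layers) {
    sites <- which(placement$sites$layer %in% layers)
    vals <- vapply(sites, function(s) rowMeans(src[[s]][, idx, drop = FALSE]),
                   numeric(length(placement$sf)))
    vals <- matrix(vals, nrow = length(placement$sf))
    # per SF, only sites with positive window-averaged response enter
    apply(vals, 1, function(v) if (any(v > 0)) mean(v[v > 0]) else NA_real_)
  }
  out <- layer_vals(c("L2", "L3"))
  inp <- layer_vals(c("L4Ca", "L4Cb"))
  if (anyNA(inp) || any(inp <= 0, na.rm = TRUE)) {
    abort("input-layer mean response is not positive; activation undefined")
  }
  tibble::tibble(sf = placement$sf, activation = out / inp)
}

#' Bootstrap classification into suppression vs amplification groups
#'
#' Tests whether a placement's high-SF output/input activation exceeds what
#' its low-SF activation distribution produces: `n` samples are drawn with
#' replacement from the low-SF distribution and the upper-tail p-value is the
#' fraction of resampled values at least as large as the observed high-SF
#' index. `p < 0.05` labels the placement group 2 (significant
#' amplification), otherwise group 1. The `"literal"` tail reproduces the
#' count-below formulation (`p = 1 - K/n` with `K` the number of resamples
#' exceeding the observed value), which reverses the tail.
#'
#' @param high_sf_index Observed activation index at the high SF.
#' @param low_sf_distribution Numeric vector (>= 2 values) forming the null.
#' @param n Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level (default 0.05).
#' @param tail `"upper"` (default) or `"literal"`.
#' @return A list with `label` (`"group1"`/`"group2"`), `p`, `n`.
#' @export
bootstrap_classify <- function(high_sf_index, low_sf_distribution, n = 1000,
                               seed = 1, alpha = 0.05,
                               tail = c("upper", "literal")) {
  tail <- match.arg(tail)
  if (length(low_sf_distribution) < 2) {
    abort("need >= 2 values in the low-SF null distribution")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  res <- sample(low_sf_distribution, n, replace = TRUE)
  p <- if (tail == "upper") {
    mean(res >= high_sf_index)
  } else {
    1 - mean(high_sf_index < res)
  }
  list(label = if (p < alpha) "group2" else "group1", p = p, n = n)
}

# cache for null dip distributions (location/scale-free, so one per n)
.dip_null_cache <- new.env(parent = emptyenv())

#' Null distribution of the dip statistic under a unimodal reference
#'
#' Monte-Carlo distribution of the dip statistic for samples of size `n`
#' drawn from the calibration null (a normal distribution; the dip is
#' location/scale invariant, so matching mean and SD to data is implicit).
#' Results are cached per `(n, n_mc, seed)` within the session.
#'
#' @param n Sample size.
#' @param n_mc Number of Monte-Carlo replicates (default 2000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_mc` dip values.
#' @export
dip_null_distribution <- function(n, n_mc = 2000, seed = 1) {
  key <- sprintf("n%d_mc%d_s%d", n, n_mc, seed)
  if (!is.null(.dip_null_cache[[key]])) return(.dip_null_cache[[key]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null <- vapply(seq_len(n_mc), function(i) dip_statistic(rnorm(n)),
                 numeric(1))
  .dip_null_cache[[key]] <- null
  null
}

#' Hartigan dip statistic
#'
#' Maximal distance between the empirical CDF and the closest unimodal
#' (convex-then-concave) CDF, computed exactly by bisection on the band
#' half-width with greatest-convex-minorant / least-concave-majorant
#' feasibility checks.
#'
#' @param values Numeric vector (>= 2 distinct values).
#' @return The dip statistic (scalar, >= 1/(2n)).
#' @export
dip_statistic <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2) abort("all values identical; dip undefined")
  .dip_stat_cpp(values)
}

#' Calibrated dip test of unimodality
#'
#' Computes the dip statistic of `values` and a Monte-Carlo p-value
#' calibrated against a unimodal normal null with matched mean and SD
#' (better sensitivity than the classical uniform-null table). Small p
#' rejects unimodality.
#'
#' @param values Numeric vector, n >= 10.
#' @param n_mc Monte-Carlo replicates for the null (default 2000).
#' @param seed Integer seed.
#' @return A list with `statistic`, `p_value`, `n`, `n_mc`.
#' @export
dip_test_calibrated <- function(values, n_mc = 2000, seed = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 10) abort("need at least 10 values")
  if (length(unique(values)) < 2) abort("all values identical")
  stat <- dip_statistic(values)
  null <- dip_null_distribution(length(values), n_mc = n_mc, seed = seed)
  list(statistic = stat, p_value = mean(null >= stat), n = length(values),
       n_mc = n_mc)
}

#' Cluster placements by their layer response profiles
#'
#' K-means clustering (k = 2 by default, 20 restarts, seeded) of a
#' placements-by-layers response matrix (typically high-SF responses averaged
#' in a 50-ms window around the peak, one column per layer L2, L3, L4B,
#' L4Ca, L4Cb), plus the first two principal components for visualization.
#'
#' @param layer_response_matrix Numeric matrix `[placements x layers]`.
#' @param k Number of clusters (default 2).
#' @param seed Integer seed.
#' @param n_restarts K-means restarts (default 20).
#' @return A list with `labels`, `centers`, and `pca` (tibble with `PC1`,
#'   `PC2`, `label`).
#' @export
cluster_placements <- function(layer_response_matrix, k = 2, seed = 1,
                               n_restarts = 20) {
  m <- as.matrix(layer_response_matrix)
  if (nrow(m) < k) abort("fewer placements than clusters")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  km <- kmeans(m, centers = k, nstart = n_restarts)
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  pca <- tibble::tibble(
    PC1 = coords[, 1],
    PC2 = if (ncol(coords) > 1) coords[, 2] else 0,
    label = factor(km$cluster)
  )
  list(labels = km$cluster, centers = km$centers, pca = pca,
       within_ss = km$tot.withinss)
}
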