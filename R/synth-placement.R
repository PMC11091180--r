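#' Default laminar boundaries in relative depth
#'
#' Boundary breaks (top to bottom, relative cortical depth 0-1) delimiting
#' L2, L3, L4B, L4Ca, L4Cb, L5 and L6. L4Ca lies above L4Cb by construction.
#'
#' @return Numeric vector of 8 breaks from 0 to 1, named by the layer below
#'   each break.
#' @export
default_layer_boundaries <- function() {
  c(L2 = 0, L3 = 0.15, L4B = 0.35, L4Ca = 0.45, L4Cb = 0.55,
    L5 = 0.65, L6 = 0.80, bottom = 1)
}

#' Layer names used throughout the package
#' @return Character vector of the seven layer labels, top to bottom.
#' @export
layer_names <- function() c("L2", "L3", "L4B", "L4Ca", "L4Cb", "L5", "L6")

# boundary ties assign to the deeper layer
.layer_of_depth <- function(depth, breaks = default_layer_boundaries()) {
  inner <- breaks[2:(length(breaks) - 1)]
  idx <- vapply(depth, function(d) 1L + sum(d >= inner), integer(1))
  layer_names()[idx]
}

#' Simulate a laminar probe placement with ground-truth model structure
#'
#' Generates one synthetic 24-channel column: relative depths on \[0, 1\],
#' layer labels, input-layer drives, and per-site dynamic responses at every
#' SF condition. Input-layer sites (L4Ca, L4Cb) carry the M and P drives;
#' every other site's noiseless response is the FF & Rec forward model
#' evaluated with its stored ground-truth parameters (group 1: recurrent
#' weights ~0, suppression; group 2: L2/3 recurrent weights increasing with
#' SF, amplification at high SFs). I.i.d. Gaussian noise of SD `noise_sd` is
#' added per bin; pre-onset bins (t < 0) contain noise only.
#'
#' @param group 1 (suppression-dominated) or 2 (amplification-dominated).
#' @param sf_list SF conditions; must be a subset of the parameter pack's
#'   ladder (default: the full ladder).
#' @param noise_sd Gaussian response noise SD in spikes/s (default 2; 0 gives
#'   noiseless responses).
#' @param seed Integer seed.
#' @param n_channels Number of probe channels (default 24).
#' @param jitter_sd Log-normal SD of per-site weight jitter (default 0.15;
#'   0 reproduces the pack exactly).
#' @param ff_scale_sd,rec_scale_sd Log-normal SDs of placement-level scale
#'   factors applied to all feedforward weights (default 0.1) and all
#'   recurrent weights (default 0.4): columns genuinely differ in overall
#'   drive and in recurrent strength, which is what couples the recurrent
#'   contribution to the activation index across placements.
#' @return An object of class `placement`: `sites` tibble (`site`, `depth`,
#'   `layer`), `responses` and `clean` (lists of `[n_sf x n_time]` matrices on
#'   the full -20..150 ms grid), `params` (per-site ground truth), `drives`,
#'   `sf`, `time`, `group`, `noise_sd`, `seed`.
#' @export
simulate_placement <- function(group, sf_list = NULL, noise_sd = 2, seed = 1,
                               n_channels = 24, jitter_sd = 0.15,
                               ff_scale_sd = 0.1, rec_scale_sd = 0.4) {
  if (!length(group) == 1 || !group %in% c(1, 2)) {
    abort("unknown group label; `group` must be 1 or 2")
  }
  pack <- group_param_pack(group)
  if (is.null(sf_list)) sf_list <- pack$sf
  if (!all(sf_list %in% pack$sf)) {
    abort("`sf_list` must be a subset of the parameter pack's SF ladder")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # placement-level scale factors, shared by every site of the column
  ff_scale <- exp(rnorm(1, 0, ff_scale_sd))
  rec_scale <- exp(rnorm(1, 0, rec_scale_sd))

  drives <- make_input_drives(sf_list)
  time_full <- response_timebase()
  fit_cols <- .fit_idx(time_full)
  nsf <- length(sf_list)

  depths <- seq(0, 1, length.out = n_channels)
  layers <- .layer_of_depth(depths)
  sites <- tibble::tibble(site = seq_len(n_channels), depth = depths,
                          layer = layers)

  responses <- clean <- vector("list", n_channels)
  params <- vector("list", n_channels)
  for (s in seq_len(n_channels)) {
    lay <- layers[s]
    gain <- exp(rnorm(1, 0, jitter_sd))
    if (lay %in% c("L4Ca", "L4Cb")) {
      base <- gain * (if (lay == "L4Ca") drives$m else drives$p)
      params[s] <- list(NULL)
    } else {
      p0 <- pack$layers[[lay]]
      rec_gain <- exp(rnorm(1, 0, jitter_sd))
      p0$w_m <- ff_scale * gain * p0$w_m
      p0$w_p <- ff_scale * gain * p0$w_p
      p0$w_rec <- rec_scale * rec_gain * p0$w_rec[as.character(sf_list)]
      params[[s]] <- p0
      base <- predict_ffrec(p0, drives)
    }
    full <- matrix(0, nsf, length(time_full))
    full[, fit_cols] <- base
    clean[[s]] <- full
    noise <- if (noise_sd > 0)
      matrix(rnorm(length(full), 0, noise_sd), nsf) else 0
    responses[[s]] <- full + noise
    dimnames(responses[[s]]) <- dimnames(clean[[s]]) <-
      list(as.character(sf_list), NULL)
  }

  structure(
    list(sites = sites, responses = responses, clean = clean, params = params,
         drives = drives, sf = sf_list, time = time_full, group = group,
         noise_sd = noise_sd, seed = seed,
         boundaries = default_layer_boundaries()),
    class = "placement"
  )
}

#' @export
print.placement <- function(x, ...) {
  cat(sprintf("<placement: group %d, %d sites, %d SF conditions, noise SD %.2g>\n",
              x$group, nrow(x$sites), length(x$sf), x$noise_sd))
  print(dplyr::count(x$sites, .data$layer))
  invisible(x)
}

#' Layer-averaged responses of a placement
#'
#' @param placement A [simulate_placement()] object (or compatible list).
#' @param layers Character vector of layer labels to pool.
#' @param clean Use noiseless responses.
#' @return `[n_sf x n_time]` matrix, the mean response over sites in `layers`.
#' @export
layer_mean_response <- function(placement, layers, clean = FALSE) {
  idx <- which(placement$sites$layer %in% layers)
  if (!length(idx)) abort("no sites in the requested layers")
  src <- if (clean) placement$clean else placement$responses
  Reduce(`+`, src[idx]) / length(idx)
}

#' Unimodal circular orientation gain
#'
#' Gain of a synthetic site for a grating orientation, peaking at the site's
#' preferred orientation with baseline 0.2 and peak 1 (half-width `sigma_deg`
#' on the 180-degree orientation circle).
#'
#' @param ori_idx Orientation index 0-8 (9 orientations spaced 20 degrees).
#' @param pref_idx Preferred orientation index.
#' @param sigma_deg Tuning width in degrees (default 30).
#' @return Gains in \[0.2, 1\].
#' @export
orientation_gain <- function(ori_idx, pref_idx, sigma_deg = 30) {
  d <- abs(ori_idx - pref_idx) * 20
  d <- pmin(d, 180 - d)
  0.2 + 0.8 * exp(-d^2 / (2 * sigma_deg^2))
}

#' Simulate inhomogeneous-Poisson spike trains for a placement
#'
#' Drives each site with the stimulus sequence: the firing rate is
#' `baseline_rate` plus, for every non-blank frame, the site's orientation
#' gain times its (noiseless) per-SF response time course at the delay since
#' frame onset, clipped at zero. Spike counts in 2-ms bins are Poisson with
#' the integrated rate; spike times are uniform within their bin.
#'
#' @param placement A [simulate_placement()] object.
#' @param sequence A [make_stimulus_sequence()] tibble; its `sf_cpd` must be
#'   one of the placement's SF conditions.
#' @param seed Integer seed.
#' @param baseline_rate Baseline rate in spikes/s (>= 0).
#' @param kernel_scale Multiplier on the stimulus-locked kernel (0 gives a
#'   pure-baseline Poisson train).
#' @param sites Which sites to simulate (default all).
#' @return A named list of spike-time vectors (ms), one per site, with the
#'   per-site preferred orientation index in attribute `pref_idx` and the
#'   total duration in `duration_ms`.
#' @export
simulate_spike_trains <- function(placement, sequence, seed = 1,
                                  baseline_rate = 10, kernel_scale = 1,
                                  sites = NULL) {
  if (baseline_rate < 0) abort("negative baseline rate")
  sf <- sequence$sf_cpd[1]
  sf_row <- match(sf, placement$sf)
  if (is.na(sf_row)) abort("sequence SF not among the placement's conditions")
  if (is.null(sites)) sites <- placement$sites$site
  frame_ms <- attr(sequence, "frame_duration_ms") %||% 20

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  bin_ms <- 2
  t_kernel <- fit_timebase()
  duration <- max(sequence$onset_ms) + frame_ms + max(t_kernel) + bin_ms
  n_bins <- ceiling(duration / bin_ms)
  bin_t <- (seq_len(n_bins) - 1) * bin_ms

  active <- sequence[!sequence$blank, , drop = FALSE]
  out <- vector("list", length(sites))
  names(out) <- paste0("site", sites)
  fit_cols <- .fit_idx(placement$time)
  for (k in seq_along(sites)) {
    s <- sites[k]
    pref <- (s - 1L) %% 9L
    kern <- kernel_scale * placement$clean[[s]][sf_row, fit_cols]
    rate <- rep(baseline_rate, n_bins)
    if (nrow(active) > 0 && any(kern != 0)) {
      gains <- orientation_gain(active$orientation_idx, pref)
      for (f in seq_len(nrow(active))) {
        i0 <- floor(active$onset_ms[f] / bin_ms) + 1L
        idx <- i0:min(i0 + length(kern) - 1L, n_bins)
        rate[idx] <- rate[idx] + gains[f] * kern[seq_along(idx)]
      }
    }
    rate <- pmax(rate, 0)
    counts <- rpois(n_bins, rate * bin_ms / 1000)
    times <- sort(rep(bin_t, counts) + runif(sum(counts), 0, bin_ms))
    attr(times, "pref_idx") <- pref
    out[[k]] <- times
  }
  attr(out, "duration_ms") <- n_bins * bin_ms
  attr(out, "sf_cpd") <- sf
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
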