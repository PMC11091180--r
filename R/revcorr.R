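#' Reverse-correlate spikes with a flashed-grating sequence
#'
#' Computes the dynamic response `resp(orientation, delay)`: the mean firing
#' rate at each delay after frames of each orientation (spatial phases
#' pooled), minus the blank-triggered rate at the same delay. Blank frames
#' are the reference event class, so an unresponsive site gives a response
#' near zero everywhere.
#'
#' @param spikes Numeric vector of spike times in ms (same clock as the
#'   sequence onsets).
#' @param sequence A [make_stimulus_sequence()] tibble; must contain blank
#'   frames (baseline subtraction is otherwise unavailable).
#' @param delay_window Delay range in ms, within \[-20, 150\].
#' @param bin_ms Delay bin width (default 2).
#' @return Object of class `dynamic_response`: matrix `[9 x n_delays]`
#'   (spikes/s above blank baseline) with attributes `time` (delay bins),
#'   `sf_cpd`, `n_spikes`, and `empty` (TRUE when no spikes were supplied).
#' @export
reverse_correlate <- function(spikes, sequence, delay_window = c(-20, 150),
                              bin_ms = 2) {
  if (delay_window[1] < -20 || delay_window[2] > 150) {
    abort("`delay_window` must lie within [-20, 150] ms")
  }
  if (!any(sequence$blank)) {
    abort("sequence has no blank frames; baseline subtraction unavailable")
  }
  delays <- seq(delay_window[1], delay_window[2], by = bin_ms)
  nd <- length(delays)
  spikes <- sort(as.numeric(spikes))

  rate_for <- function(onsets) {
    if (length(onsets) == 0 || length(spikes) == 0) return(numeric(nd))
    counts <- numeric(nd)
    for (on in onsets) {
      lo <- findInterval(on + delays[1], spikes, left.open = TRUE)
      hi <- findInterval(on + delays[nd] + bin_ms, spikes)
      if (hi > lo) {
        rel <- spikes[(lo + 1):hi] - on
        idx <- floor((rel - delays[1]) / bin_ms) + 1
        idx <- idx[idx >= 1 & idx <= nd]
        tab <- tabulate(idx, nbins = nd)
        counts <- counts + tab
      }
    }
    counts / (length(onsets) * bin_ms / 1000)
  }

  blank_rate <- rate_for(sequence$onset_ms[sequence$blank])
  resp <- matrix(0, 9, nd)
  for (o in 0:8) {
    ons <- sequence$onset_ms[!sequence$blank &
                               sequence$orientation_idx == o]
    resp[o + 1, ] <- rate_for(ons) - blank_rate
  }
  dimnames(resp) <- list(orientation = 0:8, NULL)
  # the mean blank-triggered rate is kept so the SER can be computed on the
  # raw (un-subtracted) rate scale, where the pre-onset energy is stable
  structure(resp, time = delays, sf_cpd = sequence$sf_cpd[1],
            n_spikes = length(spikes), baseline_rate = mean(blank_rate),
            empty = length(spikes) == 0,
            class = c("dynamic_response", "matrix"))
}

#' Smooth a dynamic response along the delay axis
#'
#' Rectangular (moving-average) filter; a 20-ms width at the 2-ms time base
#' is a 10-sample window. At the edges the window shrinks rather than
#' zero-padding, so baseline bins are not artificially suppressed.
#'
#' @param resp Matrix `[orientations x delays]` (or numeric vector).
#' @param width_ms Filter width in ms; must be a positive even multiple of
#'   the bin width.
#' @param bin_ms Delay bin width (default 2 ms).
#' @return Smoothed object of the same shape (attributes preserved).
#' @export
smooth_response <- function(resp, width_ms = 20, bin_ms = 2) {
  w <- width_ms / bin_ms
  if (width_ms < bin_ms || w != round(w) || (width_ms / bin_ms) %% 2 != 0) {
    abort("`width_ms` must be a positive even multiple of the bin width")
  }
  w <- as.integer(w)
  half_l <- (w - 2L) %/% 2L  # 10-sample window: 4 left, 5 right of centre
  half_r <- w - 1L - half_l
  sm_vec <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half_l, 1L)
    hi <- pmin(seq_len(n) + half_r, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (is.matrix(resp)) {
    out <- t(apply(resp, 1, sm_vec))
    attributes(out) <- attributes(resp)
    out
  } else {
    sm_vec(resp)
  }
}

#' Stimulus-driven energy ratio (SER) and site quality
#'
#' For each SF condition the orientation-averaged energy
#' `Energy(t) = mean_theta Resp(theta, t)^2` is computed on the raw firing
#' rate (the blank-triggered baseline rate stored by [reverse_correlate()]
#' is added back, so the pre-onset energy is a stable positive reference);
#' `peak_time` is the delay of maximum energy (earliest on ties) and the SER
#' is the maximum energy divided by the mean energy in the pre-onset
#' baseline window. The site's final SER is the maximum across SF
#' conditions. Sites with final SER > 3 count as visually driven.
#'
#' @param responses Named list of (smoothed) `dynamic_response` matrices, one
#'   per SF condition.
#' @param baseline_window Baseline delay range in ms, default (-20, 0).
#' @return Object of class `site_quality`: tibble `per_sf` (`sf`, `ser`,
#'   `peak_time_ms`) and scalar `final_ser`.
#' @export
compute_ser <- function(responses, baseline_window = c(-20, 0)) {
  stopifnot(length(responses) >= 1)
  rows <- purrr::imap(responses, function(resp, nm) {
    tb <- attr(resp, "time")
    if (is.null(tb)) tb <- response_timebase()[seq_len(ncol(resp))]
    base_idx <- which(tb >= baseline_window[1] & tb < baseline_window[2])
    if (!length(base_idx)) abort("baseline window is empty")
    offset <- attr(resp, "baseline_rate") %||% 0
    energy <- colMeans((resp + offset)^2)
    base <- mean(energy[base_idx])
    if (base <= 0) {
      abort("zero baseline energy; SER undefined for this site")
    }
    pk <- which.max(energy) # which.max takes the earliest maximum
    sfv <- attr(resp, "sf_cpd") %||% suppressWarnings(as.numeric(nm))
    tibble::tibble(sf = sfv, ser = max(energy) / base,
                   peak_time_ms = tb[pk])
  })
  per_sf <- dplyr::bind_rows(rows)
  structure(list(per_sf = per_sf, final_ser = max(per_sf$ser)),
            class = "site_quality")
}

#' @export
print.site_quality <- function(x, ...) {
  cat(sprintf("<site_quality: final SER %.2f>\n", x$final_ser))
  print(x$per_sf)
  invisible(x)
}

#' Dynamic signal-to-noise ratio across orientations
#'
#' `SNR(t)` is the variance across orientations at each delay divided by the
#' mean of that variance over the baseline window.
#'
#' @param resp Matrix `[orientations x delays]` with a `time` attribute.
#' @param baseline_window Baseline delay range in ms.
#' @return Numeric vector of SNR values per delay (attribute `time`).
#' @export
compute_dynamic_snr <- function(resp, baseline_window = c(-20, 0)) {
  if (nrow(resp) < 2) abort("need at least 2 orientations")
  tb <- attr(resp, "time")
  if (is.null(tb)) tb <- response_timebase()[seq_len(ncol(resp))]
  v <- apply(resp, 2, var)
  base_idx <- which(tb >= baseline_window[1] & tb < baseline_window[2])
  base <- mean(v[base_idx])
  if (base <= 0) abort("zero baseline variance; SNR undefined")
  structure(v / base, time = tb)
}

#' Select visually driven sites by SER threshold
#'
#' A site is kept iff its final SER strictly exceeds the threshold
#' (default 3).
#'
#' @param quality A numeric vector of final SER values, or a list of
#'   `site_quality` objects.
#' @param threshold SER threshold (default 3; strict inequality).
#' @return Logical inclusion mask.
#' @export
select_sites <- function(quality, threshold = 3) {
  ser <- if (is.numeric(quality)) quality else
    vapply(quality, function(q) q$final_ser, numeric(1))
  if (any(!is.finite(ser))) abort("SER values must be finite")
  ser > threshold
}
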