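#' Standard response time base
#'
#' All dynamic responses in the package live on a fixed 2-ms grid (500 Hz) of
#' stimulus-relative delays from -20 to +150 ms, the resolution the analyses
#' assume throughout. Model fitting uses the causal part of the grid,
#' t in \[0, 150\] ms (76 samples).
#'
#' @param bin_ms Bin width in milliseconds (default 2).
#' @param from,to Delay range in ms.
#' @return Numeric vector of delay-bin left edges in ms.
#' @export
#' @examples
#' tb <- response_timebase()
#' length(tb) # 86 bins
response_timebase <- function(from = -20, to = 150, bin_ms = 2) {
  stopifnot(bin_ms > 0, to > from)
  seq(from, to, by = bin_ms)
}

#' Causal fit window of the standard time base
#'
#' @inheritParams response_timebase
#' @return Delay bins t in \[0, 150\] ms.
#' @export
fit_timebase <- function(bin_ms = 2) {
  response_timebase(from = 0, to = 150, bin_ms = bin_ms)
}

# index of the fit window inside a full timebase vector
.fit_idx <- function(timebase) which(timebase >= 0 & timebase <= 150)

# baseline (pre-onset) indices: t in [-20, 0)
.baseline_idx <- function(timebase, window = c(-20, 0)) {
  which(timebase >= window[1] & timebase < window[2])
}
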