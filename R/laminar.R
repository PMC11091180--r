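#' Current source density from laminar LFPs
#'
#' Second spatial difference of the LFP across equally spaced channels:
#' \deqn{CSD(z,t) = -(LFP(z+h) - 2\,LFP(z) + LFP(z-h)) / h^2,}
#' so current sinks are negative. Edge channels have no valid second
#' difference and are returned as `NA` (no padding).
#'
#' @param lfp Matrix `[channel, time]`, channels ordered by depth.
#' @param spacing_um Inter-channel spacing in micrometres (uniform; default
#'   100).
#' @return Matrix of CSD values, same shape as `lfp`, first and last rows
#'   `NA`.
#' @export
compute_csd <- function(lfp, spacing_um = 100) {
  if (!is.matrix(lfp) || nrow(lfp) < 3) abort("need >= 3 channels")
  if (length(spacing_um) != 1 || spacing_um <= 0) {
    abort("`spacing_um` must be a single positive spacing (uniform grid)")
  }
  h2 <- spacing_um^2
  n <- nrow(lfp)
  out <- matrix(NA_real_, n, ncol(lfp), dimnames = dimnames(lfp))
  core <- 2:(n - 1)
  out[core, ] <- -(lfp[core + 1, ] - 2 * lfp[core, ] + lfp[core - 1, ]) / h2
  out
}

#' Assign channels to relative cortical depth and layers
#'
#' Maps channel positions to normalized cortical depth in \[0, 1\] by linear
#' interpolation between the supplied top and bottom of cortex, and labels
#' each channel with the layer whose depth interval contains it (a channel
#' exactly on a boundary goes to the deeper layer). Optionally flags the
#' channel of the earliest CSD sink as a candidate L4Ca anchor - advisory
#' only, since laminar alignment is feature-guided in practice.
#'
#' @param channel_positions_um Channel positions in micrometres, increasing
#'   with depth.
#' @param cortex_span_um Length-2 vector: positions of the cortical top and
#'   bottom (defaults to the span of the channels).
#' @param layer_boundaries Breaks in relative depth delimiting the layers
#'   (default [default_layer_boundaries()]); must be ordered top to bottom.
#' @param csd Optional CSD matrix `[channel, time]` used for the
#'   earliest-sink heuristic.
#' @param sink_threshold Fraction of the most negative CSD value that counts
#'   as a sink (default 0.5).
#' @return Tibble with `channel`, `position_um`, `depth` (relative),
#'   `layer`, and logical `sink_anchor` if `csd` was supplied.
#' @export
assign_relative_depth <- function(channel_positions_um,
                                  cortex_span_um = range(channel_positions_um),
                                  layer_boundaries = default_layer_boundaries(),
                                  csd = NULL, sink_threshold = 0.5) {
  if (is.unsorted(layer_boundaries)) {
    abort("layer boundaries must be ordered top to bottom")
  }
  top <- cortex_span_um[1]; bottom <- cortex_span_um[2]
  if (any(channel_positions_um < top | channel_positions_um > bottom)) {
    abort("channels outside the cortical span")
  }
  depth <- (channel_positions_um - top) / (bottom - top)
  out <- tibble::tibble(
    channel = seq_along(channel_positions_um),
    position_um = channel_positions_um,
    depth = depth,
    layer = .layer_of_depth(depth, layer_boundaries)
  )
  if (!is.null(csd)) {
    out$sink_anchor <- FALSE
    anchor <- earliest_sink_channel(csd, sink_threshold)
    if (!is.na(anchor)) out$sink_anchor[anchor] <- TRUE
  }
  out
}

#' Earliest-sink channel of a CSD matrix
#'
#' Advisory L4Ca anchor: among CSD values at least `threshold` times the most
#' negative value (sinks), returns the channel whose sink occurs earliest.
#'
#' @param csd Matrix `[channel, time]` (edge rows may be `NA`).
#' @param threshold Sink depth fraction (default 0.5).
#' @return Channel index, or `NA` if there is no sink.
#' @export
earliest_sink_channel <- function(csd, threshold = 0.5) {
  mn <- suppressWarnings(min(csd, na.rm = TRUE))
  if (!is.finite(mn) || mn >= 0) return(NA_integer_)
  is_sink <- !is.na(csd) & csd <= threshold * mn
  if (!any(is_sink)) return(NA_integer_)
  first_t <- apply(is_sink, 1, function(r) if (any(r)) which(r)[1] else NA)
  which.min(first_t)
}

#' Build a normalized laminar response pattern
#'
#' Averages site responses in a sliding window over relative depth (window
#' length 0.1, step 0.02 by default) and normalizes each response column
#' (e.g. each SF condition or each delay) of the resulting pattern by its
#' maximum, so every per-condition pattern peaks at 1.
#'
#' @param values Numeric vector (one value per site) or matrix
#'   `[site, condition]` of site responses.
#' @param depths Relative depths of the sites, in \[0, 1\].
#' @param window Sliding-window length in relative depth (default 0.1; sites
#'   within +/- window/2 of a grid point are averaged).
#' @param step Depth-grid step (default 0.02).
#' @param normalize One of `"column"` (each condition scaled to peak 1),
#'   `"global"`, or `"none"`.
#' @return Tibble with `depth` and one column per condition; grid depths with
#'   no site in the window are `NA`.
#' @export
build_laminar_pattern <- function(values, depths, window = 0.1, step = 0.02,
                                  normalize = c("column", "global", "none")) {
  normalize <- match.arg(normalize)
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (nrow(values) != length(depths)) {
    abort("`values` must have one row per site depth")
  }
  if (nrow(values) < 1) abort("need at least one site")
  grid <- seq(0, 1, by = step)
  pat <- matrix(NA_real_, length(grid), ncol(values))
  for (gi in seq_along(grid)) {
    inwin <- abs(depths - grid[gi]) <= window / 2
    if (any(inwin)) {
      pat[gi, ] <- colMeans(values[inwin, , drop = FALSE])
    }
  }
  if (all(is.na(pat))) abort("no sites fall in any depth window")
  if (normalize == "column") {
    for (j in seq_len(ncol(pat))) {
      mx <- max(pat[, j], na.rm = TRUE)
      if (mx > 0) pat[, j] <- pat[, j] / mx
    }
  } else if (normalize == "global") {
    mx <- max(pat, na.rm = TRUE)
    if (mx > 0) pat <- pat / mx
  }
  colnames(pat) <- colnames(values) %||% paste0("V", seq_len(ncol(pat)))
  dplyr::bind_cols(tibble::tibble(depth = grid), tibble::as_tibble(pat))
}
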