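#' Synthesize input-layer drives for the M and P pathways
#'
#' Builds the noiseless dynamic responses of the two geniculate input
#' sublayers, \eqn{R_m(sf,t)} (L4Ca, magnocellular) and \eqn{R_p(sf,t)}
#' (L4Cb, parvocellular), as a separable product of an SF gain curve and a
#' unit-peak log-normal time course. The magnocellular drive is faster (peak
#' 46 ms) than the parvocellular one (peak 57 ms), reflecting the faster
#' conduction of the M stream; the pooled input-layer drive therefore peaks
#' near 52 ms. The M gain prefers low SFs (peak 1 c/deg) and the P gain peaks
#' at a higher SF (6 c/deg), so the M drive decays with SF beyond its
#' preferred SF while the P drive dominates at high SFs. The gain shapes are
#' qualitative stand-ins: no quantitative L4C SF gain is available to emulate.
#'
#' @param sf_list SF conditions in cycles/degree (non-empty).
#' @param m_gain_params,p_gain_params Lists with `amp` (spikes/s), `peak_sf`
#'   (c/deg), `sigma_oct` (log2-SF Gaussian width in octaves) and an optional
#'   `floor` (fraction of `amp` retained at all SFs; keeps weakly driven
#'   conditions positive, as real input-layer sites are).
#' @param kinetics List with `dt_m`, `sigma_m`, `dt_p`, `sigma_p`: log-ms
#'   centres and log-time widths of the two pathway time courses.
#' @param timebase Delay grid in ms; drives are zero at t <= 0.
#' @return A list of class `lsf_drives`: `sf`, `time`, and `[n_sf x n_time]`
#'   matrices `m` and `p` in spikes/s.
#' @export
#' @examples
#' d <- make_input_drives(default_sf_ladder())
#' pooled <- colMeans(d$m / max(d$m) + d$p / max(d$p))
#' d$time[which.max(pooled)] # pooled input drive peaks near 52 ms
make_input_drives <- function(sf_list = default_sf_ladder(),
                              m_gain_params = list(amp = 40, peak_sf = 1,
                                                   sigma_oct = 1.2,
                                                   floor = 0.06),
                              p_gain_params = list(amp = 35, peak_sf = 6,
                                                   sigma_oct = 1.4,
                                                   floor = 0.04),
                              kinetics = list(dt_m = log(46), sigma_m = 0.32,
                                              dt_p = log(57), sigma_p = 0.38),
                              timebase = fit_timebase()) {
  if (length(sf_list) == 0) abort("`sf_list` must be non-empty")
  if (any(sf_list <= 0)) abort("SFs must be positive")
  course_m <- lognormal_kernel(kinetics$dt_m, kinetics$sigma_m,
                               timebase = timebase)
  course_p <- lognormal_kernel(kinetics$dt_p, kinetics$sigma_p,
                               timebase = timebase)
  gm <- sf_gain(sf_list, m_gain_params)
  gp <- sf_gain(sf_list, p_gain_params)
  structure(
    list(sf = sf_list, time = timebase,
         m = outer(gm, course_m), p = outer(gp, course_p)),
    class = "lsf_drives"
  )
}

#' Log-Gaussian SF gain curve
#'
#' @param sf SFs in c/deg.
#' @param params List with `amp`, `peak_sf`, `sigma_oct`.
#' @return Gains (same units as `amp`), nonnegative.
#' @export
sf_gain <- function(sf, params) {
  if (params$amp < 0) abort("gain amplitude must be nonnegative")
  fl <- params$floor %||% 0
  params$amp * (fl + (1 - fl) *
                  exp(-(log2(sf / params$peak_sf))^2 / (2 * params$sigma_oct^2)))
}

#' Ground-truth parameter packs for the two column groups
#'
#' Loads the versioned JSON parameter pack shipped with the package that
#' defines, for each non-input layer, the ground-truth [ffrec_params()] used
#' by [simulate_placement()]. Group 1 (suppression-dominated) has recurrent
#' weights ~0 everywhere; group 2 (amplification-dominated) has L2/3
#' recurrent weights increasing with SF.
#'
#' @param group 1 or 2.
#' @return A list with `sf` (the SF ladder of the pack) and `layers`, a named
#'   list of [ffrec_params()] per layer (L2, L3, L4B, L5, L6).
#' @export
group_param_pack <- function(group) {
  if (!group %in% c(1, 2)) abort("`group` must be 1 or 2")
  path <- system.file("extdata",
                      sprintf("ffrec_params_group%d.json", group),
                      package = "laminarsf")
  if (path == "") abort("parameter pack not found; is the package installed?")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(raw$layers, function(l) {
    ffrec_params(
      w_m = l$w_m, w_p = l$w_p,
      dt_m1 = l$dt_m1, sigma_m1 = l$sigma_m1, dt_m2 = l$dt_m2,
      sigma_m2 = l$sigma_m2, g_m = l$g_m,
      dt_p1 = l$dt_p1, sigma_p1 = l$sigma_p1, dt_p2 = l$dt_p2,
      sigma_p2 = l$sigma_p2, g_p = l$g_p,
      dt_rec = l$dt_rec, sigma_rec = l$sigma_rec,
      w_rec = setNames(as.numeric(l$w_rec), names(l$w_rec))
    )
  })
  list(sf = as.numeric(raw$sf), layers = layers, version = raw$version)
}

#' Serialize model parameters to / from JSON
#'
#' @param params An [ffrec_params()] object.
#' @param path File path.
#' @return `write_ffrec_params()` returns `path` invisibly;
#'   `read_ffrec_params()` the reconstructed object.
#' @export
write_ffrec_params <- function(params, path) {
  stopifnot(inherits(params, "ffrec_params"))
  out <- unclass(params)
  out$w_rec <- as.list(out$w_rec) # keep SF names (objects, not arrays)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ffrec_params
#' @export
read_ffrec_params <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  ffrec_params(
    w_m = l$w_m, w_p = l$w_p,
    dt_m1 = l$dt_m1, sigma_m1 = l$sigma_m1, dt_m2 = l$dt_m2,
    sigma_m2 = l$sigma_m2, g_m = l$g_m,
    dt_p1 = l$dt_p1, sigma_p1 = l$sigma_p1, dt_p2 = l$dt_p2,
    sigma_p2 = l$sigma_p2, g_p = l$g_p,
    dt_rec = l$dt_rec, sigma_rec = l$sigma_rec,
    w_rec = setNames(as.numeric(l$w_rec), names(l$w_rec))
  )
}
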