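#' Tidy a fitted FF / FF & Rec model
#'
#' @param x An `ffrec_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.ffrec_fit <- function(x, ...) {
  p <- x$params
  base <- tibble::tibble(
    term = c("w_m", "w_p", "dt_m1", "sigma_m1", "dt_m2", "sigma_m2", "g_m",
             "dt_p1", "sigma_p1", "dt_p2", "sigma_p2", "g_p"),
    estimate = c(p$w_m, p$w_p, p$dt_m1, p$sigma_m1, p$dt_m2, p$sigma_m2,
                 p$g_m, p$dt_p1, p$sigma_p1, p$dt_p2, p$sigma_p2, p$g_p)
  )
  if (x$variant == "ffrec") {
    base <- dplyr::bind_rows(
      base,
      tibble::tibble(term = c("dt_rec", "sigma_rec"),
                     estimate = c(p$dt_rec, p$sigma_rec)),
      tibble::tibble(term = paste0("w_rec_", names(p$w_rec)),
                     estimate = unname(p$w_rec))
    )
  }
  base
}

#' @rdname tidy.ffrec_fit
#' @export
glance.ffrec_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant, gof_raw = x$gof_raw,
                 gof_adj = x$gof_adj, sse = x$sse, n = x$n,
                 p_free = x$p_free, convergence = x$convergence)
}

#' Tidy a fitted SF tuning curve
#'
#' @param x An `sf_tuning_fit`.
#' @param ... Unused.
#' @return Tibble of parameter estimates.
#' @export
tidy.sf_tuning_fit <- function(x, ...) {
  tibble::tibble(term = c("a1", "a2", "sigma1", "sigma2"),
                 estimate = c(x$a1, x$a2, x$sigma1, x$sigma2))
}

#' @rdname tidy.sf_tuning_fit
#' @export
glance.sf_tuning_fit <- function(x, ...) {
  tibble::tibble(gof = x$gof, valid = x$valid, cutoff_sf = x$cutoff_sf)
}

#' Tidy a GC matrix into ordered channel pairs
#'
#' @param x A `gc_matrix`.
#' @param ... Unused.
#' @return Tibble with `to`, `from`, `gc` (diagonal excluded).
#' @export
tidy.gc_matrix <- function(x, ...) {
  v <- x$values
  df <- tidyr::expand_grid(to = seq_len(nrow(v)), from = seq_len(ncol(v)))
  df$gc <- v[cbind(df$to, df$from)]
  df[df$to != df$from, ]
}

#' @rdname tidy.gc_matrix
#' @export
glance.gc_matrix <- function(x, ...) {
  tibble::tibble(n_channels = nrow(x$values), order = x$fit$order,
                 spectral_radius = x$fit$spectral_radius)
}
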