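#' Pipeline configuration
#'
#' Collects every tunable of the synthetic end-to-end analysis with the
#' package defaults: SF ladder, noise, SER and gof thresholds, bootstrap and
#' GC settings, laminar window/step. The configuration round-trips losslessly
#' through JSON ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed Master seed; all per-placement seeds derive from it.
#' @param n_group1,n_group2 Number of placements per group.
#' @param sf_list SF ladder (c/deg).
#' @param noise_sd Response noise SD (spikes/s).
#' @param jitter_sd Per-site weight jitter (log-normal SD).
#' @param ser_threshold SER inclusion threshold (strict).
#' @param gof_min Validity threshold for model fits and tuning cutoffs.
#' @param bootstrap_n Bootstrap resamples for group classification.
#' @param gc_order VAR model order.
#' @param gc_samples,gc_trials VAR simulation length and trial count.
#' @param laminar_window,laminar_step Depth window and step.
#' @param activation_window Averaging window in ms for activation indices.
#' @param fit_starts Multi-starts for model fitting inside the pipeline.
#' @param fit_polish Polish rounds per fit (see [fit_model()]).
#' @param site_level_fits Fit every L2/3 site (slow) instead of the layer
#'   mean.
#' @param run_gc Compute the Granger-causality stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_group1 = 5, n_group2 = 5,
                            sf_list = default_sf_ladder(), noise_sd = 2,
                            jitter_sd = 0.15, ser_threshold = 3,
                            gof_min = 0.8, bootstrap_n = 1000, gc_order = 15,
                            gc_samples = 1500, gc_trials = 4,
                            laminar_window = 0.1, laminar_step = 0.02,
                            activation_window = c(0, 120), fit_starts = 4,
                            fit_polish = 1, site_level_fits = FALSE,
                            run_gc = TRUE) {
  structure(
    list(seed = seed, n_group1 = n_group1, n_group2 = n_group2,
         sf_list = sf_list, noise_sd = noise_sd, jitter_sd = jitter_sd,
         ser_threshold = ser_threshold, gof_min = gof_min,
         bootstrap_n = bootstrap_n, gc_order = gc_order,
         gc_samples = gc_samples, gc_trials = gc_trials,
         laminar_window = laminar_window, laminar_step = laminar_step,
         activation_window = activation_window, fit_starts = fit_starts,
         fit_polish = fit_polish, site_level_fits = site_level_fits,
         run_gc = run_gc),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the JSON serialization.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, l[setdiff(names(l), character(0))])
  cfg
}

# window-averaged per-SF amplitudes of a layer
.layer_amplitudes <- function(placement, layers, window) {
  m <- layer_mean_response(placement, layers)
  idx <- which(placement$time >= window[1] & placement$time <= window[2])
  rowMeans(m[, idx, drop = FALSE])
}

# estimated drives: measured layer-mean input responses on the fit window
.estimated_drives <- function(placement) {
  fit_cols <- .fit_idx(placement$time)
  list(sf = placement$sf, time = placement$time[fit_cols],
       m = layer_mean_response(placement, "L4Ca")[, fit_cols, drop = FALSE],
       p = layer_mean_response(placement, "L4Cb")[, fit_cols, drop = FALSE])
}

.analyse_placement <- function(pl, cfg, id) {
  act <- placement_activation(pl, window = cfg$activation_window)
  l4cb_amp <- .layer_amplitudes(pl, "L4Cb", cfg$activation_window)
  cond <- select_sf_conditions(l4cb_amp, pl$sf)

  # per-site low-SF activation distribution for the bootstrap null
  fitw <- which(pl$time >= cfg$activation_window[1] &
                  pl$time <= cfg$activation_window[2])
  l23_sites <- which(pl$sites$layer %in% c("L2", "L3"))
  in_mean_by_sf <- rowMeans(
    (layer_mean_response(pl, c("L4Ca", "L4Cb")))[, fitw, drop = FALSE])
  low_row <- match(cond$low_sf, pl$sf)
  low_null <- vapply(l23_sites, function(s) {
    mean(pl$responses[[s]][low_row, fitw]) / in_mean_by_sf[low_row]
  }, numeric(1))

  high_row <- if (cond$valid) match(cond$high_sf, pl$sf) else NA_integer_
  boot <- if (cond$valid) {
    bootstrap_classify(act$activation[high_row], low_null,
                       n = cfg$bootstrap_n, seed = pl$seed)
  } else list(label = NA_character_, p = NA_real_)

  # SF tuning of output and input layers
  out_amp <- .layer_amplitudes(pl, c("L2", "L3"), cfg$activation_window)
  in_amp <- .layer_amplitudes(pl, c("L4Ca", "L4Cb"), cfg$activation_window)
  fit_out <- tryCatch(fit_sf_tuning(pl$sf, out_amp), error = function(e) NULL)
  fit_in <- tryCatch(fit_sf_tuning(pl$sf, in_amp), error = function(e) NULL)
  cut_out <- if (!is.null(fit_out)) fit_out$cutoff_sf else NA_real_
  cut_in <- if (!is.null(fit_in)) fit_in$cutoff_sf else NA_real_
  rel_cut <- if (!is.na(cut_out) && !is.na(cut_in))
    relative_cutoff_sf(cut_out, cut_in) else NA_real_

  # model fitting on estimated drives
  drives <- .estimated_drives(pl)
  fit_cols <- .fit_idx(pl$time)
  targets <- if (cfg$site_level_fits) {
    lapply(l23_sites, function(s) pl$responses[[s]][, fit_cols, drop = FALSE])
  } else {
    list(layer_mean_response(pl, c("L2", "L3"))[, fit_cols, drop = FALSE])
  }
  fits_ff <- lapply(targets, fit_model, drives = drives, variant = "ff",
                    n_starts = cfg$fit_starts, polish_rounds = cfg$fit_polish)
  fits_rec <- lapply(targets, fit_model, drives = drives,
                     variant = "ffrec", n_starts = cfg$fit_starts,
                     polish_rounds = cfg$fit_polish)
  gof_ff <- mean(vapply(fits_ff, `[[`, numeric(1), "gof_raw"))
  gof_rec <- mean(vapply(fits_rec, `[[`, numeric(1), "gof_raw"))
  gof_adj_ff <- mean(vapply(fits_ff, `[[`, numeric(1), "gof_adj"))
  gof_adj_rec <- mean(vapply(fits_rec, `[[`, numeric(1), "gof_adj"))

  contrib <- tryCatch({
    laps <- laminar_activation_patterns(fits_rec, drives, data = targets,
                                        gof_min = cfg$gof_min)
    co <- contributions(laps)
    co$placement <- id
    # an SF where every raw contribution floors at zero has no defined
    # normalized triple; emit only defined triples
    co[!is.na(co$contribution), , drop = FALSE]
  }, error = function(e) NULL)

  gc_row <- if (cfg$run_gc) {
    gt <- make_var_ground_truth(pl$group)
    series <- simulate_var(gt, cfg$gc_samples, cfg$gc_trials, seed = pl$seed)
    g <- pairwise_conditional_gc(series, order = cfg$gc_order)
    aggregate_connections(g, gt$layer_map)
  } else {
    tibble::tibble(recurrent = NA_real_, feedforward = NA_real_,
                   normalized_gc = NA_real_)
  }

  list(
    row = tibble::tibble(
      placement = id, group = pl$group, seed = pl$seed,
      low_sf = cond$low_sf, high_sf = cond$high_sf, valid = cond$valid,
      activation_low = act$activation[match(cond$low_sf, pl$sf)],
      activation_high = if (cond$valid) act$activation[high_row] else NA_real_,
      label = boot$label, p_boot = boot$p,
      cutoff_out = cut_out, cutoff_in = cut_in, relative_cutoff = rel_cut,
      gof_ff = gof_ff, gof_ffrec = gof_rec,
      gof_adj_ff = gof_adj_ff, gof_adj_ffrec = gof_adj_rec,
      gc_recurrent = gc_row$recurrent[1], gc_feedforward = gc_row$feedforward[1],
      normalized_gc = gc_row$normalized_gc[1]
    ),
    activation = dplyr::mutate(act, placement = id, group = pl$group),
    contributions = contrib
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a cohort of laminar placements from the two ground-truth groups
#' and runs every analysis stage: activation indices, SF-condition selection,
#' bootstrap group classification, SF tuning and cutoff statistics, FF vs
#' FF & Rec model fitting with contribution decomposition, laminar GC
#' summaries, cohort-level dip test and k-means clustering of layer response
#' profiles. Fully deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: tibbles `placements`,
#'   `activation`, `contributions`, `cluster` (labels + PCA), `dip`
#'   (cohort dip test), and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  n_total <- config$n_group1 + config$n_group2
  groups <- c(rep(1, config$n_group1), rep(2, config$n_group2))
  rows <- list(); acts <- list(); contribs <- list()
  layer_mat <- matrix(NA_real_, n_total, 5,
                      dimnames = list(NULL, c("L2", "L3", "L4B", "L4Ca",
                                              "L4Cb")))
  for (i in seq_len(n_total)) {
    pl <- simulate_placement(groups[i], sf_list = config$sf_list,
                             noise_sd = config$noise_sd,
                             seed = config$seed * 1000 + i,
                             jitter_sd = config$jitter_sd)
    res <- .analyse_placement(pl, config, id = i)
    rows[[i]] <- res$row
    acts[[i]] <- res$activation
    contribs[[i]] <- res$contributions
    # layer profile at the placement's high SF: 50-ms window around the peak
    hs <- res$row$high_sf
    if (!is.na(hs)) {
      layer_mat[i, ] <- .layer_profile(pl, hs)
    }
  }
  placements <- dplyr::bind_rows(rows)
  activation <- dplyr::bind_rows(acts)
  contributions <- dplyr::bind_rows(contribs)

  dip <- tryCatch({
    vals <- placements$activation_high[!is.na(placements$activation_high)]
    if (length(vals) >= 10) dip_test_calibrated(vals, seed = config$seed)
    else NULL
  }, error = function(e) NULL)

  ok_rows <- complete.cases(layer_mat)
  cluster <- if (sum(ok_rows) >= 4) {
    cl <- cluster_placements(layer_mat[ok_rows, , drop = FALSE],
                             k = 2, seed = config$seed)
    tibble::tibble(placement = which(ok_rows), label = cl$labels,
                   PC1 = cl$pca$PC1, PC2 = cl$pca$PC2)
  } else NULL

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  structure(
    list(placements = placements, activation = activation,
         contributions = contributions, dip = dip, cluster = cluster,
         provenance = list(
           config = config, config_json = as.character(cfg_json),
           package_version = as.character(utils::packageVersion("laminarsf"))
         )),
    class = "pipeline_result"
  )
}

# mean response per layer in a 50-ms window around the peak, at one SF
.layer_profile <- function(pl, sf,
                           layers = c("L2", "L3", "L4B", "L4Ca", "L4Cb")) {
  row <- match(sf, pl$sf)
  pooled <- layer_mean_response(pl, layers)[row, ]
  pk <- pl$time[which.max(pooled)]
  idx <- which(pl$time >= pk - 25 & pl$time <= pk + 25)
  vapply(layers, function(l) {
    mean(layer_mean_response(pl, l)[row, idx])
  }, numeric(1))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d placements>\n", nrow(x$placements)))
  print(dplyr::count(x$placements, .data$group, .data$label))
  if (!is.null(x$dip)) {
    cat(sprintf("cohort dip test: D = %.4f, p = %.3f\n",
                x$dip$statistic, x$dip$p_value))
  }
  invisible(x)
}

#' Write pipeline result tables as tab-separated text
#'
#' @param results A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(as.data.frame(df), file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wr(results$placements, "placements.tsv")
  wr(results$activation, "activation.tsv")
  wr(results$contributions, "contributions.tsv")
  wr(results$cluster, "cluster.tsv")
  writeLines(results$provenance$config_json, file.path(dir, "config.json"))
  invisible(dir)
}

#' Summary report of a pipeline run
#'
#' Assembles the headline figures from a [run_pipeline()] result: the
#' low-vs-high SF activation scatter, the input-vs-output cutoff-SF
#' comparison, and the per-SF contribution curves. Figure data tables are
#' returned alongside the plots.
#'
#' @param results A `pipeline_result`.
#' @return A list with `plots` (named ggplot objects) and `tables` (the data
#'   behind each plot); empty components are dropped with a warning.
#' @export
report <- function(results) {
  plots <- list(); tables <- list()
  pl <- results$placements
  if (!is.null(pl) && nrow(pl) > 0) {
    tables$activation_scatter <- pl[, c("placement", "group",
                                        "activation_low", "activation_high")]
    plots$activation_scatter <- plot_activation_scatter(results)
    if (any(!is.na(pl$relative_cutoff))) {
      tables$cutoff <- pl[, c("placement", "group", "cutoff_in", "cutoff_out",
                              "relative_cutoff")]
      plots$cutoff <- plot_cutoff_comparison(results)
    }
  }
  if (!is.null(results$contributions) && nrow(results$contributions) > 0) {
    tables$contributions <- results$contributions
    plots$contributions <- plot_contribution_curves(results)
  }
  if (!length(plots)) warn("empty result bundle; nothing to report")
  list(plots = plots, tables = tables)
}
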