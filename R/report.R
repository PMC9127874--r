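## Condition-vs-control statistics, run configuration, and the pipeline
## driver tying detection, tracking and dynamics together.

#' Two-group comparison with a Student's t-test
#'
#' Equal-variance two-sample t-test by default (Welch optional), with the
#' usual significance codes: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#' No multiple-testing correction is applied.
#'
#' @param values_a,values_b numeric vectors, n >= 2 each.
#' @param labels character(2) group labels.
#' @param var_equal pooled-variance (Student) test when `TRUE`; Welch
#'   otherwise.
#' @return list of class `nd_comparison` with `labels`, `n`, `mean`, `sd`,
#'   `t_statistic`, `df`, `p_value`, `significance_code`.
#' @export
compare_groups <- function(values_a, values_b,
                           labels = c("control", "treated"),
                           var_equal = TRUE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop_insufficient("each group needs >= 2 finite values")
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  p <- tt$p.value
  code <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  structure(list(labels = labels,
                 n = c(length(values_a), length(values_b)),
                 mean = c(mean(values_a), mean(values_b)),
                 sd = c(stats::sd(values_a), stats::sd(values_b)),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = p,
                 significance_code = code,
                 method = if (var_equal) "student" else "welch"),
            class = "nd_comparison")
}

#' @export
print.nd_comparison <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n=%d) vs %s: %.4g +/- %.4g (n=%d)\n",
              x$labels[1], x$mean[1], x$sd[1], x$n[1],
              x$labels[2], x$mean[2], x$sd[2], x$n[2]))
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g  [%s]\n",
              x$t_statistic, x$df, x$p_value, x$significance_code))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Run configuration (plain-text key = value files)

#' Default run configuration
#'
#' All tunable pipeline parameters with their defaults: calibration
#' (pixel size 0.1 um, frame interval 0.1 s, PSF sigma 1.3 px — typical for
#' 100x/1.45-NA TIRF), detection, linking (max displacement
#' `3 * sqrt(4 * D_max * dt) / pixel_size` for the fastest expected
#' population, D_max = 0.035 um^2/s), dynamics and FCS settings, and the
#' RNG seed.
#'
#' @return named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    pixel_size_um = 0.1,
    frame_interval_s = 0.1,
    detect_expected_sigma_px = 1.3,
    detect_snr_min = 5,
    detect_candidate_nsd = 3,
    link_max_disp_px = 3 * sqrt(4 * 0.035 * 0.1) / 0.1,
    link_max_gap = 1,
    msd_n_lags = 4,
    msd_max_lag_fraction = 1,
    peaks_n_bins = 30,
    peaks_max_components = 2,
    dwell_bin_width_s = 0.1,
    dwell_fit_floor_s = 0,
    dwell_exclude_censored = TRUE,
    coloc_match_radius_px = 2,
    fcs_w0_um = 0.25,
    seed = 1
  )
}

#' Write a run configuration as a plain-text key = value file
#'
#' Keys are written sorted so that write -> read -> write round-trips to an
#' identical file.
#'
#' @param config named list (numbers, logicals or strings).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (is.null(names(config)) || any(names(config) == ""))
    stop_invalid("`config` must be a fully named list")
  ks <- sort(names(config))
  fmt <- vapply(ks, function(k) {
    v <- config[[k]]
    vs <- if (is.logical(v)) ifelse(v, "true", "false")
    else if (is.numeric(v)) format(v, digits = 17, scientific = FALSE)
    else as.character(v)
    sprintf("%s = %s", k, vs)
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

#' Read a run configuration file
#'
#' @param path file written by [write_run_config()] (or hand-edited
#'   `key = value` lines; `#` starts a comment).
#' @return named list with numeric / logical / character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid(paste("config file not found:", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop_invalid(paste("malformed config line:", ln))
    k <- trimws(parts[1])
    v <- trimws(paste(parts[-1], collapse = "="))
    out[[k]] <- if (v %in% c("true", "false")) v == "true"
    else if (grepl("^-?[0-9.]+([eE][+-]?[0-9]+)?$", v)) as.numeric(v)
    else v
  }
  out
}

## ---------------------------------------------------------------------------
## Pipeline driver

#' Run the detection -> tracking -> dynamics pipeline on a movie
#'
#' Detects spots in every frame, links them into trajectories, computes
#' per-track diffusion coefficients, speeds and dwell times, and decomposes
#' the diffusion-coefficient distribution into characteristic peaks when
#' enough tracks are available.  Identical configuration and input give
#' identical outputs.
#'
#' @param movie an `nd_movie`; its `pixel_size`/`frame_interval` calibration
#'   must be positive and finite (missing calibration is a hard error, units
#'   are never assumed).
#' @param config configuration list, see [default_run_config()]; missing
#'   keys fall back to the defaults.
#' @param out_dir optional directory; when given, `spots.csv`, `tracks.csv`,
#'   `dynamics.csv` and `peaks.csv` are written there.
#' @return list of class `nd_pipeline` with `spots`, `tracks`, `dynamics`,
#'   `peaks` (NULL when < 30 usable tracks), `dwells`, `config`.
#' @export
run_pipeline <- function(movie, config = default_run_config(),
                         out_dir = NULL) {
  if (!inherits(movie, "nd_movie")) stop_invalid("`movie` must be an nd_movie")
  if (!is.finite(movie$pixel_size) || movie$pixel_size <= 0 ||
      !is.finite(movie$frame_interval) || movie$frame_interval <= 0)
    stop_invalid("movie calibration (pixel_size, frame_interval) is missing")
  cfg <- utils::modifyList(default_run_config(), config)
  set.seed(as.integer(cfg$seed))

  spots <- detect_movie(movie, expected_sigma = cfg$detect_expected_sigma_px,
                        snr_min = cfg$detect_snr_min,
                        candidate_nsd = cfg$detect_candidate_nsd)
  if (nrow(spots) == 0L) warning("no spots detected; outputs are empty")
  tracks <- link_trajectories(spots, max_disp = cfg$link_max_disp_px,
                              max_gap = cfg$link_max_gap,
                              frame_range = c(1L, dim(movie$stack)[3]))
  dyn <- track_dynamics(tracks, movie$pixel_size, movie$frame_interval,
                        n_lags = cfg$msd_n_lags,
                        max_lag_fraction = cfg$msd_max_lag_fraction)
  dwells <- dwell_times(tracks, movie$frame_interval,
                        exclude_censored = isTRUE(cfg$dwell_exclude_censored))
  peaks <- NULL
  d_pos <- dyn$D[dyn$D > 0]
  if (length(d_pos) >= 30L)
    peaks <- log_binned_peaks(d_pos, n_bins = cfg$peaks_n_bins,
                              max_components = cfg$peaks_max_components)
  res <- structure(list(spots = spots, tracks = tracks, dynamics = dyn,
                        dwells = dwells, peaks = peaks, config = cfg),
                   class = "nd_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                           row.names = FALSE)
    wr(spots, "spots.csv")
    wr(tracks, "tracks.csv")
    wr(dyn, "dynamics.csv")
    if (!is.null(peaks)) wr(peaks$peaks, "peaks.csv")
    write_run_config(cfg, file.path(out_dir, "run_config.txt"))
  }
  res
}

#' @export
print.nd_pipeline <- function(x, ...) {
  cat(sprintf("<nd_pipeline> %d spots, %d tracks, %d with dynamics\n",
              nrow(x$spots), length(unique(x$tracks$track_id)),
              nrow(x$dynamics)))
  if (!is.null(x$peaks)) print(x$peaks)
  invisible(x)
}
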