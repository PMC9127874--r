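## Per-track mobility analysis: time-averaged MSD, linear-fit diffusion
## coefficients, instantaneous speeds, characteristic-peak (G-hat)
## decomposition of log-binned distributions, and exponential dwell-time
## fits.

#' Time-averaged mean square displacement of one track
#'
#' MSD at lag `k` frames is averaged over all ordered point pairs of the
#' track separated by exactly `k` frames; gaps are respected (a pair across
#' a gap contributes at its true time difference).
#'
#' @param track data.frame with `frame` and either `x_um`/`y_um` (um) or
#'   `x`/`y` (px, converted with `pixel_size`).
#' @param pixel_size um per px (ignored when coordinates are already in um).
#' @param frame_interval s per frame.
#' @param max_lag_fraction use lags up to this fraction of the track
#'   duration, in (0, 1].
#' @return data.frame of class `nd_msd` with `lag_s`, `msd` (um^2),
#'   `n_pairs`.
#' @export
compute_msd <- function(track, pixel_size = 1, frame_interval = 1,
                        max_lag_fraction = 1) {
  if (is.null(track) || nrow(track) < 3L)
    stop_too_short("MSD needs a track with >= 3 points")
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop_invalid("`max_lag_fraction` must lie in (0, 1]")
  check_scalar_pos(frame_interval, "frame_interval")
  if (all(c("x_um", "y_um") %in% names(track))) {
    x <- track$x_um; y <- track$y_um
  } else {
    check_scalar_pos(pixel_size, "pixel_size")
    x <- track$x * pixel_size; y <- track$y * pixel_size
  }
  f <- track$frame
  ord <- order(f)
  f <- f[ord]; x <- x[ord]; y <- y[ord]
  n <- length(f)
  dur <- f[n] - f[1]
  max_lag <- max(1L, floor(max_lag_fraction * dur))
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  lag <- f[j] - f[i]
  keep <- lag <= max_lag
  sq <- (x[j[keep]] - x[i[keep]])^2 + (y[j[keep]] - y[i[keep]])^2
  lag <- lag[keep]
  msd <- tapply(sq, lag, mean)
  np <- tapply(sq, lag, length)
  lags <- as.integer(names(msd))
  out <- data.frame(lag_s = lags * frame_interval,
                    msd = as.numeric(msd), n_pairs = as.integer(np))
  out <- out[order(out$lag_s), ]
  rownames(out) <- NULL
  class(out) <- c("nd_msd", "data.frame")
  out
}

#' Diffusion coefficient from a linear MSD fit
#'
#' Ordinary least squares of MSD on lag time over the first `n_lags` points;
#' for 2D lateral diffusion `D = slope / 4`, with a free intercept absorbing
#' static localization error.
#'
#' @param msd an `nd_msd` from [compute_msd()].
#' @param n_lags number of initial lags fitted (default 4, the usual SPT
#'   bias/variance compromise).
#' @param track_id optional id carried into the result.
#' @return list of class `nd_diffusion` with `D` (um^2/s, clamped at 0),
#'   `slope`, `intercept` (um^2), `r2`, `n_lags_used`, `low_quality`
#'   (TRUE when the raw slope was negative), `track_id`.
#' @export
fit_diffusion <- function(msd, n_lags = 4L, track_id = NA) {
  if (!is.data.frame(msd) || nrow(msd) < 2L)
    stop_insufficient("need an MSD curve with >= 2 lags")
  if (n_lags < 2L) stop_invalid("`n_lags` must be >= 2")
  use <- msd[seq_len(min(n_lags, nrow(msd))), ]
  fit <- stats::lm(msd ~ lag_s, data = use)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  sst <- sum((use$msd - mean(use$msd))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(D = max(slope, 0) / 4, slope = slope, intercept = intercept,
                 r2 = r2, n_lags_used = nrow(use),
                 low_quality = slope < 0, track_id = track_id),
            class = "nd_diffusion")
}

#' Mean instantaneous speed of a track
#'
#' Mean frame-to-frame displacement magnitude divided by the elapsed time
#' between the points (so bridged gaps contribute at their true time
#' difference).  For pure Brownian motion the expected value is the Rayleigh
#' mean `sqrt(pi * D / frame_interval)`.
#'
#' @inheritParams compute_msd
#' @return speed in um/s.
#' @export
compute_velocity <- function(track, pixel_size = 1, frame_interval = 1) {
  if (is.null(track) || nrow(track) < 2L)
    stop_too_short("velocity needs >= 2 points")
  check_scalar_pos(frame_interval, "frame_interval")
  if (all(c("x_um", "y_um") %in% names(track))) {
    x <- track$x_um; y <- track$y_um
  } else {
    check_scalar_pos(pixel_size, "pixel_size")
    x <- track$x * pixel_size; y <- track$y * pixel_size
  }
  ord <- order(track$frame)
  f <- track$frame[ord]; x <- x[ord]; y <- y[ord]
  step <- sqrt(diff(x)^2 + diff(y)^2)
  dt <- diff(f) * frame_interval
  mean(step / dt)
}

## ---------------------------------------------------------------------------
## Characteristic peaks (G-hat): Gaussian mixture on log10 values

gmm1d_loglik <- function(x, w, mu, sd) {
  dens <- sapply(seq_along(w), function(g) w[g] * stats::dnorm(x, mu[g], sd[g]))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = 1)
  sum(log(pmax(rowSums(dens), 1e-300)))
}

gmm1d_em <- function(x, w, mu, sd, sd_floor = 1e-3, max_iter = 500,
                     tol = 1e-8) {
  n <- length(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- sapply(seq_along(w), function(g) w[g] * stats::dnorm(x, mu[g], sd[g]))
    tot <- rowSums(dens)
    tot[tot <= 0] <- 1e-300
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)        # collapsed component
    w <- nk / n
    mu <- colSums(r * x) / nk
    sd <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    sd <- pmax(sd, sd_floor)
    ll <- sum(log(tot))
    if (ll - ll_old < tol && it > 5) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd, loglik = gmm1d_loglik(x, w, mu, sd))
}

## numeric observed-information standard errors for the component means
gmm1d_mu_se <- function(x, w, mu, sd) {
  G <- length(w)
  ## free parameters: mu_g, log(sd_g), and logit weights for g < G
  pack <- c(mu, log(sd), if (G > 1) log(w[-G] / w[G]))
  llfun <- function(p) {
    mu_ <- p[seq_len(G)]
    sd_ <- exp(p[G + seq_len(G)])
    if (G > 1) {
      e <- exp(c(p[2 * G + seq_len(G - 1)], 0))
      w_ <- e / sum(e)
    } else w_ <- 1
    gmm1d_loglik(x, w_, mu_, sd_)
  }
  np <- length(pack)
  h <- 1e-4 * pmax(abs(pack), 1)
  H <- matrix(0, np, np)
  for (a in seq_len(np)) for (b in a:np) {
    pa <- pack; pb <- pack; pab <- pack
    pa[a] <- pa[a] + h[a]; pb[b] <- pb[b] + h[b]
    pab[a] <- pab[a] + h[a]; pab[b] <- pab[b] + h[b]
    H[a, b] <- H[b, a] <-
      (llfun(pab) - llfun(pa) - llfun(pb) + llfun(pack)) / (h[a] * h[b])
  }
  V <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, G))
  se <- sqrt(pmax(diag(V)[seq_len(G)], 0))
  se
}

#' Characteristic peaks of a log-binned distribution
#'
#' Fits Gaussian mixtures with 1..`max_components` components to the log10 of
#' the values and selects the component count by BIC.  Each peak position
#' `G_hat = 10^mean` is the characteristic value of its subpopulation (the
#' mode of the log-spaced histogram).  A 30-bin log-spaced histogram is
#' returned for display; the mixture is fitted to the raw log10 values.
#'
#' @param values positive diffusion coefficients (um^2/s) or speeds (um/s);
#'   non-positive entries are dropped and counted.
#' @param n_bins histogram bins (display only).
#' @param max_components maximum mixture size (1 or 2).
#' @param n_restarts EM restarts per component count (k-means plus random
#'   initializations; best likelihood kept).
#' @param sd_floor lower bound for component SDs on the log10 scale.
#' @return list of class `nd_peaks` with `peaks` (data.frame `G_hat`,
#'   `weight`, `log10_sd`, `se_log10_mu`, `se_G_hat`, sorted ascending),
#'   `n_components`, `bic` (per component count; smaller is better),
#'   `loglik`, `n_used`, `n_dropped`, `hist_breaks`, `hist_counts`.
#' @export
log_binned_peaks <- function(values, n_bins = 30L, max_components = 2L,
                             n_restarts = 10L, sd_floor = 1e-3) {
  values <- values[is.finite(values)]
  n_dropped <- sum(values <= 0)
  v <- values[values > 0]
  if (length(v) < 30L)
    stop_insufficient("peak decomposition needs >= 30 positive values")
  if (!max_components %in% 1:2)
    stop_invalid("`max_components` must be 1 or 2")
  x <- log10(v)
  n <- length(x)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  if (breaks[1] == breaks[n_bins + 1L])
    breaks <- breaks[1] + seq(-0.5, 0.5, length.out = n_bins + 1L)
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts

  fits <- list()
  ## one component: closed form
  sd1 <- max(stats::sd(x), sd_floor)
  fits[[1]] <- list(w = 1, mu = mean(x), sd = sd1,
                    loglik = gmm1d_loglik(x, 1, mean(x), sd1))
  degenerate <- stats::sd(x) < sd_floor
  if (max_components >= 2L && !degenerate) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      if (r == 1L) {
        km <- stats::kmeans(x, centers = 2L, nstart = 5L)
        mu0 <- as.numeric(km$centers)
        w0 <- as.numeric(table(km$cluster)) / n
        sd0 <- pmax(rep(stats::sd(x) / 2, 2), sd_floor)
      } else {
        mu0 <- sort(sample(x, 2L))
        w0 <- c(0.5, 0.5)
        sd0 <- pmax(rep(stats::sd(x) / 2, 2), sd_floor)
      }
      f <- gmm1d_em(x, w0, mu0, sd0, sd_floor = sd_floor)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
    }
    if (!is.null(best)) fits[[2]] <- best
  }

  bic <- vapply(seq_along(fits), function(g) {
    if (is.null(fits[[g]])) return(Inf)
    p <- 3 * g - 1
    -2 * fits[[g]]$loglik + p * log(n)
  }, numeric(1))
  g_sel <- which.min(bic)
  f <- fits[[g_sel]]
  ord <- order(f$mu)
  mu <- f$mu[ord]; w <- f$w[ord]; sdv <- f$sd[ord]
  se_mu <- if (degenerate) rep(NA_real_, g_sel) else
    tryCatch(gmm1d_mu_se(x, w, mu, sdv), error = function(e)
      rep(NA_real_, g_sel))
  g_hat <- 10^mu
  peaks <- data.frame(G_hat = g_hat, weight = w, log10_sd = sdv,
                      se_log10_mu = se_mu,
                      se_G_hat = log(10) * g_hat * se_mu)
  structure(list(peaks = peaks, n_components = g_sel, bic = bic,
                 loglik = f$loglik, n_used = n, n_dropped = n_dropped,
                 hist_breaks = breaks, hist_counts = counts),
            class = "nd_peaks")
}

#' @export
print.nd_peaks <- function(x, ...) {
  cat(sprintf("<nd_peaks> %d component(s), n = %d (%d non-positive dropped)\n",
              x$n_components, x$n_used, x$n_dropped))
  print(x$peaks, digits = 4)
  invisible(x)
}

#' Exponential fit of a dwell-time distribution
#'
#' Histograms the dwell times at `bin_width` and fits `A * exp(-t / tau)` to
#' the bin counts for bin centers at or above `fit_floor` (use the floor to
#' skip bins truncated by the minimum observable dwell).  The closed-form
#' maximum-likelihood mean of the (floored) sample is reported alongside as a
#' cross-check.
#'
#' @param dwells numeric vector of uncensored dwell times, s (>= 50 values).
#' @param bin_width histogram bin width, s.
#' @param fit_floor smallest bin center included in the fit, s.
#' @param r2_min fits with r-squared below this are flagged non-exponential.
#' @return list of class `nd_dwell_fit` with `tau` (s), `amplitude`,
#'   `sd_tau` (fit SE), `r2`, `ml_mean` (mean of dwells >= floor, minus the
#'   floor), `n_tracks`, `non_exponential`.
#' @export
fit_dwell_exponential <- function(dwells, bin_width, fit_floor = 0,
                                  r2_min = 0.8) {
  dwells <- dwells[is.finite(dwells)]
  if (length(dwells) < 50L)
    stop_insufficient("dwell fit needs >= 50 uncensored dwell times")
  check_scalar_pos(bin_width, "bin_width")
  breaks <- seq(0, max(dwells) + bin_width, by = bin_width)
  hh <- graphics::hist(dwells, breaks = breaks, plot = FALSE)
  centers <- hh$mids; counts <- hh$counts
  use <- centers >= fit_floor
  ml_mean <- mean(dwells[dwells >= fit_floor]) - fit_floor
  dfit <- data.frame(t = centers[use], n = counts[use])
  fit <- tryCatch(
    minpack.lm::nlsLM(n ~ A * exp(-t / tau), data = dfit,
                      start = list(A = max(dfit$n), tau = max(ml_mean, bin_width)),
                      lower = c(A = 0, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          sd_tau = NA_real_, r2 = NA_real_, ml_mean = ml_mean,
                          n_tracks = length(dwells), non_exponential = TRUE),
                     class = "nd_dwell_fit"))
  }
  cf <- stats::coef(fit)
  sst <- sum((dfit$n - mean(dfit$n))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 0
  se <- tryCatch(summary(fit)$coefficients["tau", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(tau = unname(cf[["tau"]]), amplitude = unname(cf[["A"]]),
                 sd_tau = se, r2 = r2, ml_mean = ml_mean,
                 n_tracks = length(dwells),
                 non_exponential = r2 < r2_min),
            class = "nd_dwell_fit")
}

#' Per-track dynamics table
#'
#' Convenience wrapper running [compute_msd()], [fit_diffusion()] and
#' [compute_velocity()] for every track.
#'
#' @param tracks track data.frame (`track_id`, `frame`, coordinates).
#' @param pixel_size um per px.
#' @param frame_interval s per frame.
#' @param n_lags lags used in the diffusion fit.
#' @param max_lag_fraction see [compute_msd()].
#' @return data.frame with one row per track: `track_id`, `n_points`, `D`,
#'   `intercept`, `r2`, `velocity`, `dwell_s`, `censored`.
#' @export
track_dynamics <- function(tracks, pixel_size, frame_interval, n_lags = 4L,
                           max_lag_fraction = 1) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < 3L) return(NULL)
    msd <- compute_msd(tr, pixel_size, frame_interval, max_lag_fraction)
    if (nrow(msd) < 2L) return(NULL)
    dfit <- fit_diffusion(msd, n_lags = n_lags, track_id = id)
    cen <- if (all(c("censored_start", "censored_end") %in% names(tr)))
      any(tr$censored_start) || any(tr$censored_end) else NA
    data.frame(track_id = id, n_points = nrow(tr), D = dfit$D,
               intercept = dfit$intercept, r2 = dfit$r2,
               velocity = compute_velocity(tr, pixel_size, frame_interval),
               dwell_s = (max(tr$frame) - min(tr$frame) + 1) * frame_interval,
               censored = cen)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), n_points = integer(0),
                      D = numeric(0), intercept = numeric(0), r2 = numeric(0),
                      velocity = numeric(0), dwell_s = numeric(0),
                      censored = logical(0))
  rownames(out) <- NULL
  out
}
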