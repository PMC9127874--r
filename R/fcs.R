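## Fluorescence correlation spectroscopy: multiple-tau autocorrelation and a
## 2D membrane-diffusion fit converting particle number to surface density.

## Direct fluctuation autocorrelation of one trace at integer lags:
## G(k) = <dF_t dF_{t+k}> / <F>^2, mean over all n-k pairs, global mean.
direct_autocorr <- function(x, lags) {
  m <- mean(x)
  dx <- x - m
  n <- length(x)
  vapply(lags, function(k) {
    if (k >= n) return(NA_real_)
    mean(dx[seq_len(n - k)] * dx[(k + 1):n]) / m^2
  }, numeric(1))
}

#' Multiple-tau autocorrelation of an intensity trace
#'
#' Computes the normalized fluctuation autocorrelation
#' `G(tau) = <dF(t) dF(t+tau)> / <F>^2` on a quasi-logarithmic lag grid:
#' cascade 1 covers lags `1..points_per_cascade` of the raw trace; every
#' further cascade halves the time resolution by pairwise binning and covers
#' lags `points_per_cascade/2 + 1 .. points_per_cascade` in binned units.
#' Optionally the trace is split into segments whose correlations are
#' averaged (SD across segments reported).
#'
#' @param trace an `nd_fcs_trace` from [simulate_fcs_trace()], or a list with
#'   `samples` and `sampling_dt`.
#' @param n_cascades number of cascades; each segment must hold at least
#'   `2^(n_cascades - 1) * points_per_cascade` samples.
#' @param points_per_cascade lags per cascade (even, >= 4).
#' @param n_segments number of equal segments averaged.
#' @return list of class `nd_fcs_curve` with `lags` (s), `G`, `G_sd`
#'   (across segments; NA for one segment), `n_segments`, `zero_variance`.
#' @export
autocorrelate <- function(trace, n_cascades = 8L, points_per_cascade = 8L,
                          n_segments = 1L) {
  x <- trace$samples
  dt <- trace$sampling_dt
  if (is.null(x) || is.null(dt)) stop_invalid("`trace` needs samples and sampling_dt")
  if (points_per_cascade < 4L || points_per_cascade %% 2L != 0L)
    stop_invalid("`points_per_cascade` must be even and >= 4")
  if (n_cascades < 1L || n_segments < 1L)
    stop_invalid("`n_cascades` and `n_segments` must be >= 1")
  seg_len <- floor(length(x) / n_segments)
  if (seg_len < 2^(n_cascades - 1L) * points_per_cascade)
    stop_invalid("trace too short for the requested cascades/segments")

  lag_units <- multiple_tau_lags(n_cascades, points_per_cascade)
  if (stats::var(x) == 0) {
    return(structure(list(lags = lag_units$lag_raw * dt,
                          G = rep(0, nrow(lag_units)),
                          G_sd = rep(NA_real_, nrow(lag_units)),
                          n_segments = n_segments, zero_variance = TRUE),
                     class = "nd_fcs_curve"))
  }
  seg_G <- sapply(seq_len(n_segments), function(s) {
    seg <- x[((s - 1L) * seg_len + 1L):(s * seg_len)]
    multiple_tau_one(seg, lag_units)
  })
  seg_G <- matrix(seg_G, nrow = nrow(lag_units))
  structure(list(lags = lag_units$lag_raw * dt,
                 G = rowMeans(seg_G),
                 G_sd = if (n_segments > 1) apply(seg_G, 1, stats::sd)
                 else rep(NA_real_, nrow(lag_units)),
                 n_segments = n_segments, zero_variance = FALSE),
            class = "nd_fcs_curve")
}

## lag grid: data.frame(cascade, lag_binned, bin_factor, lag_raw)
multiple_tau_lags <- function(n_cascades, m) {
  out <- list()
  for (cs in seq_len(n_cascades)) {
    bf <- 2^(cs - 1L)
    lb <- if (cs == 1L) seq_len(m) else (m %/% 2L + 1L):m
    out[[cs]] <- data.frame(cascade = cs, lag_binned = lb, bin_factor = bf,
                            lag_raw = lb * bf)
  }
  do.call(rbind, out)
}

## evaluate G on the multiple-tau grid for a single segment
multiple_tau_one <- function(x, lag_units) {
  G <- numeric(nrow(lag_units))
  binned <- x
  for (cs in unique(lag_units$cascade)) {
    if (cs > 1L) {
      n2 <- floor(length(binned) / 2L) * 2L
      binned <- (binned[seq(1L, n2, 2L)] + binned[seq(2L, n2, 2L)]) / 2
    }
    rows <- which(lag_units$cascade == cs)
    G[rows] <- direct_autocorr(binned, lag_units$lag_binned[rows])
  }
  G
}

#' Fit a 2D membrane-diffusion model to an autocorrelation curve
#'
#' Least-squares fit of `G(tau) = G0 / (1 + tau/tau_D)` (2D diffusion through
#' a Gaussian observation area, no triplet term).  The mean particle number
#' in the observation area is `N = 1/G0` and the surface density is
#' `N / obs_area`.
#'
#' @param curve an `nd_fcs_curve`.
#' @param obs_area effective observation area in um^2; the default is
#'   `pi * w0^2` for a 0.25 um beam waist.
#' @return list of class `nd_fcs_fit` with `N`, `tau_D` (s), `G0`,
#'   `density` (um^-2), `obs_area`, `r2`.
#' @export
fit_fcs_2d <- function(curve, obs_area = pi * 0.25^2) {
  if (!inherits(curve, "nd_fcs_curve"))
    stop_invalid("`curve` must come from autocorrelate()")
  check_scalar_pos(obs_area, "obs_area")
  ok <- is.finite(curve$G)
  lag <- curve$lags[ok]; G <- curve$G[ok]
  if (length(G) < 8L) stop_insufficient("FCS fit needs >= 8 lag points")
  g_small <- mean(G[seq_len(3L)])
  if (!is.finite(g_small) || g_small <= 0)
    stop_fit_failure("no positive correlation amplitude at small lags")
  tau0 <- lag[which.min(abs(G - g_small / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ G0 / (1 + lag / tauD),
                      data = data.frame(lag = lag, G = G),
                      start = list(G0 = g_small, tauD = max(tau0, lag[1])),
                      lower = c(G0 = 1e-12, tauD = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop_fit_failure(paste("FCS fit did not converge:",
                           conditionMessage(fit)))
  cf <- stats::coef(fit)
  G0 <- unname(cf[["G0"]])
  if (G0 <= 0) stop_fit_failure("fitted G0 is non-positive")
  sst <- sum((G - mean(G))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  N <- 1 / G0
  structure(list(N = N, tau_D = unname(cf[["tauD"]]), G0 = G0,
                 density = N / obs_area, obs_area = obs_area, r2 = r2),
            class = "nd_fcs_fit")
}

#' Surface density from total signal and per-particle brightness
#'
#' The alternative, correlation-free route: `density =
#' (total_signal / per_particle_brightness) / area`.
#'
#' @param total_signal summed fluorescence signal, counts.
#' @param area membrane area covered, um^2.
#' @param per_particle_brightness counts contributed by one particle.
#' @return density in particles/um^2.
#' @export
density_from_intensity <- function(total_signal, area,
                                   per_particle_brightness) {
  check_scalar_pos(area, "area")
  check_scalar_pos(per_particle_brightness, "per_particle_brightness")
  if (total_signal < 0) stop_invalid("`total_signal` must be >= 0")
  (total_signal / per_particle_brightness) / area
}
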