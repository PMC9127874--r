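## FRAP normalization and recovery kinetics.

#' Extract ROI / reference / background traces from a movie
#'
#' @param movie an `nd_movie`.
#' @param roi c(x, y, w, h) px of the bleached region.
#' @param reference_roi optional c(x, y, w, h); by default the reference is
#'   every pixel outside the ROI dilated by 5 px (an unbleached region that
#'   tracks acquisition bleaching).
#' @param background per-frame background level: a scalar, a trace, or a
#'   c(x, y, w, h) region to average.
#' @return data.frame with `frame`, `roi`, `reference`, `background` mean
#'   intensities.
#' @export
frap_traces <- function(movie, roi, reference_roi = NULL, background = 0) {
  if (!inherits(movie, "nd_movie")) stop_invalid("`movie` must be an nd_movie")
  d <- dim(movie$stack)
  roi <- as.numeric(roi)
  roi_idx <- roi_indices(roi, d)
  nF <- d[3]
  roi_tr <- vapply(seq_len(nF), function(f)
    mean(movie$stack[roi_idx$rows, roi_idx$cols, f]), numeric(1))
  if (is.null(reference_roi)) {
    mask <- matrix(TRUE, d[1], d[2])
    dil <- roi_indices(c(roi[1] - 5, roi[2] - 5, roi[3] + 10, roi[4] + 10),
                       d, clip = TRUE)
    mask[dil$rows, dil$cols] <- FALSE
    if (!any(mask)) stop_invalid("no reference pixels left outside the ROI")
    ref_tr <- vapply(seq_len(nF), function(f) {
      fr <- movie$stack[, , f]
      mean(fr[mask])
    }, numeric(1))
  } else {
    ref_idx <- roi_indices(as.numeric(reference_roi), d)
    ref_tr <- vapply(seq_len(nF), function(f)
      mean(movie$stack[ref_idx$rows, ref_idx$cols, f]), numeric(1))
  }
  bg_tr <- if (length(background) == 1L) {
    rep(as.numeric(background), nF)
  } else if (length(background) == nF) {
    as.numeric(background)
  } else if (length(background) == 4L) {
    bg_idx <- roi_indices(as.numeric(background), d)
    vapply(seq_len(nF), function(f)
      mean(movie$stack[bg_idx$rows, bg_idx$cols, f]), numeric(1))
  } else stop_invalid("`background` must be a scalar, a trace, or a region")
  data.frame(frame = seq_len(nF), roi = roi_tr, reference = ref_tr,
             background = bg_tr)
}

roi_indices <- function(roi, d, clip = FALSE) {
  if (length(roi) != 4L || any(!is.finite(roi)) || roi[3] < 1 || roi[4] < 1)
    stop_invalid("ROI must be c(x, y, w, h) with positive size")
  x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[1] + roi[3] - 1; y1 <- roi[2] + roi[4] - 1
  if (clip) {
    x0 <- max(1, x0); y0 <- max(1, y0); x1 <- min(d[2], x1); y1 <- min(d[1], y1)
  } else if (x0 < 1 || y0 < 1 || x1 > d[2] || y1 > d[1]) {
    stop_invalid("ROI falls outside the frame")
  }
  list(rows = y0:y1, cols = x0:x1)
}

#' Double-normalize a FRAP recovery trace
#'
#' After background subtraction, the ROI trace is divided by the reference
#' trace (correcting acquisition bleaching) and scaled so the pre-bleach mean
#' of the ratio is 1:
#' `F_norm(t) = [roi(t) - bg] / [ref(t) - bg] / mean_prebleach`.
#'
#' @param roi_trace,reference_trace,background_trace numeric traces of equal
#'   length (background may be a scalar).
#' @param bleach_index 1-based index of the bleach frame; at least 3
#'   pre-bleach samples (`bleach_index >= 4`) are required.
#' @param frame_interval s per frame (times are reported relative to the
#'   bleach frame, which sits at t = 0).
#' @return list of class `nd_frap_curve` with `times`, `normalized`,
#'   `raw_roi`, `raw_reference`, `raw_background`, `bleach_index`.
#' @export
normalize_frap <- function(roi_trace, reference_trace, background_trace = 0,
                           bleach_index, frame_interval = 1) {
  n <- length(roi_trace)
  if (length(background_trace) == 1L)
    background_trace <- rep(background_trace, n)
  if (length(reference_trace) != n || length(background_trace) != n)
    stop_invalid("all traces must have the same length")
  if (bleach_index < 4 || bleach_index > n)
    stop_invalid("`bleach_index` must allow >= 3 pre-bleach samples")
  check_scalar_pos(frame_interval, "frame_interval")
  ref <- reference_trace - background_trace
  if (any(ref <= 0))
    stop_division_guard("reference trace reaches the background level")
  ratio <- (roi_trace - background_trace) / ref
  pre <- mean(ratio[seq_len(bleach_index - 1L)])
  if (!is.finite(pre) || abs(pre) < 1e-12)
    stop_division_guard("pre-bleach ROI signal is zero; cannot normalize")
  structure(list(times = (seq_len(n) - bleach_index) * frame_interval,
                 normalized = ratio / pre,
                 raw_roi = roi_trace, raw_reference = reference_trace,
                 raw_background = background_trace,
                 bleach_index = bleach_index),
            class = "nd_frap_curve")
}

#' Fit single-exponential recovery kinetics to a FRAP curve
#'
#' Fits `F(t) = F0 + (P - F0) * (1 - exp(-k t))` to the post-bleach samples
#' (t > 0; the bleach frame itself is excluded).  The mobile fraction is
#' `100 * (P - F0) / (1 - F0)` and percent recovery is evaluated at the last
#' timepoint by default.
#'
#' @param curve an `nd_frap_curve` from [normalize_frap()].
#' @param recovery_at time (s, post-bleach) at which percent recovery is
#'   reported; defaults to the last sample.
#' @param t_max_fit optionally restrict the fit to post-bleach times up to
#'   this value (s), e.g. to isolate the fast local-exchange phase when
#'   comparing sub-regions.
#' @param fix_F0 optional known post-bleach floor.  With an effectively
#'   instantaneous bleach the bleach-frame sample itself (t = 0) observes
#'   the floor before any exchange; `fix_F0 = TRUE` uses it, a number uses
#'   that value, and `NULL` (default) leaves F0 as a free fit parameter.
#'   Fixing F0 avoids the downward mobile-fraction bias that arises when
#'   exchange across the ROI edge is faster than the frame interval, so the
#'   free F0 settles above the true floor.
#' @return list of class `nd_frap_fit` with `mobile_fraction` (%), `rate_k`
#'   (1/s), `F0`, `plateau`, `percent_recovery_at` (named c(t, value)),
#'   `r2`, `low_quality`.
#' @export
fit_recovery <- function(curve, recovery_at = NULL, t_max_fit = NULL,
                         fix_F0 = NULL) {
  if (!inherits(curve, "nd_frap_curve"))
    stop_invalid("`curve` must come from normalize_frap()")
  post <- curve$times > 0
  if (!is.null(t_max_fit)) post <- post & curve$times <= t_max_fit
  if (sum(post) < 5L)
    stop_insufficient("recovery fit needs >= 5 post-bleach samples")
  t <- curve$times[post]; yv <- curve$normalized[post]
  F0_fixed <- NULL
  if (isTRUE(fix_F0)) {
    at0 <- which(curve$times == 0)
    if (length(at0) != 1L)
      stop_invalid("fix_F0 = TRUE needs a sample at t = 0 (the bleach frame)")
    F0_fixed <- curve$normalized[at0]
  } else if (is.numeric(fix_F0)) {
    F0_fixed <- as.numeric(fix_F0)
  }
  t_end <- recovery_at %||% max(t)
  if (stats::sd(yv) < 1e-4) {
    ## flat curve: no measurable recovery
    F0 <- F0_fixed %||% mean(yv)
    return(structure(list(mobile_fraction = 0, rate_k = NA_real_, F0 = F0,
                          plateau = mean(yv),
                          percent_recovery_at = c(t = t_end, value = 0),
                          r2 = 0, low_quality = TRUE),
                     class = "nd_frap_fit"))
  }
  ## multi-start over rate scales: the recovery rate is unknown a priori and
  ## a single bad k start can strand the optimizer in a degenerate minimum
  F0_0 <- max(min(yv[1], 1), 0)
  P_0 <- mean(yv[t >= stats::quantile(t, 0.7)])
  fit <- NULL
  for (k0 in c(0.5, 2, 8, 32) / max(t)) {
    cand <- tryCatch(suppressWarnings({
      if (is.null(F0_fixed)) {
        minpack.lm::nlsLM(yv ~ F0 + (P - F0) * (1 - exp(-k * t)),
                          data = data.frame(t = t, yv = yv),
                          start = list(F0 = F0_0, P = P_0, k = k0),
                          lower = c(F0 = -0.5, P = -0.5, k = 1e-6),
                          upper = c(F0 = 1.5, P = 2, k = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(yv ~ F0_fixed + (P - F0_fixed) * (1 - exp(-k * t)),
                          data = data.frame(t = t, yv = yv,
                                            F0_fixed = F0_fixed),
                          start = list(P = P_0, k = k0),
                          lower = c(P = -0.5, k = 1e-6),
                          upper = c(P = 2, k = Inf),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }), error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit)))
      fit <- cand
  }
  if (is.null(fit))
    stop_fit_failure("recovery fit did not converge from any start")
  cf <- stats::coef(fit)
  F0 <- if (is.null(F0_fixed)) unname(cf[["F0"]]) else F0_fixed
  P <- unname(cf[["P"]]); k <- unname(cf[["k"]])
  denom <- 1 - F0
  ## if the plateau is never approached within the record (k * t_max small)
  ## the fitted P is an unconstrained extrapolation; use the recovery level
  ## actually reached instead and flag the fit
  extrapolated <- k * max(t) < 0.5
  if (extrapolated) P <- F0 + (P - F0) * (1 - exp(-k * max(t)))
  mf <- if (abs(denom) > 1e-9) 100 * (P - F0) / denom else NA_real_
  f_end <- F0 + (P - F0) * (1 - exp(-k * t_end))
  rec <- if (abs(denom) > 1e-9) 100 * (f_end - F0) / denom else NA_real_
  sst <- sum((yv - mean(yv))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  mf_clamped <- min(max(mf, 0), 100)
  structure(list(mobile_fraction = mf_clamped, rate_k = k, F0 = F0,
                 plateau = P,
                 percent_recovery_at = c(t = t_end, value = rec),
                 r2 = r2,
                 low_quality = r2 < 0.5 || extrapolated || is.na(mf) ||
                   mf < -5 || mf > 105),
            class = "nd_frap_fit")
}

#' Per-strip recovery within the bleached ROI
#'
#' Splits the bleach ROI into `parts` equal strips along `axis`, analyses
#' each independently (shared reference), and returns the per-strip curves
#' and fits.  With lateral diffusion only, the central strip recovers more
#' slowly than the peripheral ones.
#'
#' @param movie an `nd_movie`.
#' @param bleach_roi c(x, y, w, h) px.
#' @param parts number of strips (>= 1).
#' @param axis `"x"` (strips side by side along x) or `"y"`.
#' @param bleach_index bleach frame index.
#' @param background see [frap_traces()].
#' @param reference_roi see [frap_traces()].
#' @param t_max_fit see [fit_recovery()].
#' @return list of class `nd_frap_strips` with `curves` and `fits` (lists of
#'   length `parts`) and `strip_rois`.
#' @export
subroi_recovery <- function(movie, bleach_roi, parts = 3L, axis = c("x", "y"),
                            bleach_index, background = 0,
                            reference_roi = NULL, t_max_fit = NULL) {
  axis <- match.arg(axis)
  roi <- as.numeric(bleach_roi)
  ext <- if (axis == "x") roi[3] else roi[4]
  if (parts < 1 || ext < parts)
    stop_invalid("ROI is thinner than the requested number of strips")
  cuts <- round(seq(0, ext, length.out = parts + 1L))
  strips <- lapply(seq_len(parts), function(i) {
    if (axis == "x")
      c(roi[1] + cuts[i], roi[2], cuts[i + 1] - cuts[i], roi[4])
    else
      c(roi[1], roi[2] + cuts[i], roi[3], cuts[i + 1] - cuts[i])
  })
  curves <- lapply(strips, function(s) {
    tr <- frap_traces(movie, s, reference_roi = reference_roi,
                      background = background)
    normalize_frap(tr$roi, tr$reference, tr$background, bleach_index,
                   movie$frame_interval)
  })
  fits <- lapply(curves, function(cv)
    tryCatch(fit_recovery(cv, t_max_fit = t_max_fit), error = function(e) e))
  structure(list(curves = curves, fits = fits, strip_rois = strips,
                 parts = parts, axis = axis),
            class = "nd_frap_strips")
}
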