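## Spot detection and quantification.
##
## Candidate maxima come from a difference-of-Gaussians band-pass tuned to the
## expected PSF width; each candidate is refined by a local 2D Gaussian
## least-squares fit (constant local background), brightest first, and each
## accepted spot is subtracted from the working image (matching pursuit) so
## that close neighbors do not bias later fits.  A second pass over the
## residual recovers partners of merged pairs.  Spots failing the SNR cut or
## the fit sanity checks are discarded.

#' Detect diffraction-limited spots in a single frame
#'
#' @param image 2D numeric matrix of non-negative counts (rows = y,
#'   columns = x, pixel centers at integer coordinates).
#' @param expected_sigma expected PSF Gaussian sigma in px.
#' @param snr_min minimum fitted signal-to-noise ratio: fitted peak amplitude
#'   over the robust frame-wide pixel noise SD (median absolute difference of
#'   neighboring pixels / sqrt(2)).  Spots with expected SNR s are reliably
#'   kept only when `snr_min` sits clearly below s.
#' @param candidate_nsd band-pass threshold for candidate maxima, in robust
#'   SDs of the band-passed image.
#' @param n_passes detection passes; passes after the first search the
#'   residual image for spots hidden by brighter neighbors.
#' @return data.frame of spots sorted by decreasing integrated intensity with
#'   columns `x`, `y` (subpixel, px), `intensity` (background-subtracted
#'   integrated counts, `2*pi*sigma^2*A`), `sigma` (fitted width, px),
#'   `background`, `snr`.  A flat or empty image yields zero rows.
#' @details The fit window is `(6*expected_sigma + 1)` px on a side (odd,
#'   centered on the candidate); its border ring provides the local
#'   background estimate (median).  Overlapping candidates within
#'   `2*expected_sigma` px are resolved by keeping the brighter one.  Fits
#'   whose center leaves the window or whose width falls outside
#'   `[0.65, 2] * expected_sigma` are treated as divergent.
#' @export
detect_spots <- function(image, expected_sigma = 1.3, snr_min = 5,
                         candidate_nsd = 3, n_passes = 2L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_invalid("`image` must be a numeric matrix")
  if (any(image < 0)) stop_invalid("`image` must be non-negative")
  check_scalar_pos(expected_sigma, "expected_sigma")
  empty <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
                      sigma = numeric(0), background = numeric(0),
                      snr = numeric(0))
  nr <- nrow(image); nc <- ncol(image)
  if (min(nr, nc) < 5 || stats::sd(image) == 0) return(empty)

  ## robust frame-wide pixel-noise estimate: neighboring-pixel differences are
  ## insensitive to smooth background and to sparse spots
  frame_noise <- stats::mad(image[-1, ] - image[-nr, ]) / sqrt(2)
  h <- max(3L, round(3 * expected_sigma))
  sup2 <- (2 * expected_sigma)^2

  accepted <- list()
  acc_x <- numeric(0); acc_y <- numeric(0)
  work <- image
  for (pass in seq_len(max(1L, n_passes))) {
    cand <- dog_candidates(work, expected_sigma, candidate_nsd, sup2)
    if (nrow(cand) == 0L) break
    if (length(acc_x)) {
      d2 <- outer(acc_y, cand[, 1], "-")^2 + outer(acc_x, cand[, 2], "-")^2
      cand <- cand[apply(d2, 2, min) >= sup2, , drop = FALSE]
      if (nrow(cand) == 0L) break
    }
    n_new <- 0L
    for (i in seq_len(nrow(cand))) {
      cy <- cand[i, 1]; cx <- cand[i, 2]
      rr <- max(1L, cy - h):min(nr, cy + h)
      cc <- max(1L, cx - h):min(nc, cx + h)
      if (length(rr) < 5 || length(cc) < 5) next
      win <- work[rr, cc]
      ring <- c(win[1, ], win[nrow(win), ], win[-c(1, nrow(win)), 1],
                win[-c(1, nrow(win)), ncol(win)])
      bg0 <- stats::median(ring)
      fit <- fit_gaussian_window(win, as.numeric(cc), as.numeric(rr),
                                 x0 = cx, y0 = cy, sigma0 = expected_sigma,
                                 a0 = max(win) - bg0, b0 = bg0)
      if (is.null(fit)) next
      ## reject divergent fits: center outside the window, implausible width
      if (fit$x0 < cc[1] - 0.5 || fit$x0 > cc[length(cc)] + 0.5 ||
          fit$y0 < rr[1] - 0.5 || fit$y0 > rr[length(rr)] + 0.5) next
      ## diffraction-limited-width prior: single-pixel noise spikes fit at
      ## implausibly small widths, real PSFs scatter narrowly around
      ## expected_sigma
      if (fit$sigma < 0.65 * expected_sigma ||
          fit$sigma > 2 * expected_sigma) next
      if (fit$A <= 0) next
      snr <- if (frame_noise > 0) fit$A / frame_noise else Inf
      if (snr < snr_min) next
      accepted[[length(accepted) + 1L]] <-
        data.frame(x = fit$x0, y = fit$y0,
                   intensity = 2 * pi * fit$sigma^2 * fit$A,
                   sigma = fit$sigma, background = fit$b, snr = snr)
      acc_x <- c(acc_x, fit$x0); acc_y <- c(acc_y, fit$y0)
      n_new <- n_new + 1L
      sub_r <- max(1L, floor(fit$y0 - 4 * fit$sigma)):
        min(nr, ceiling(fit$y0 + 4 * fit$sigma))
      sub_c <- max(1L, floor(fit$x0 - 4 * fit$sigma)):
        min(nc, ceiling(fit$x0 + 4 * fit$sigma))
      gx <- exp(-(sub_c - fit$x0)^2 / (2 * fit$sigma^2))
      gy <- exp(-(sub_r - fit$y0)^2 / (2 * fit$sigma^2))
      work[sub_r, sub_c] <- work[sub_r, sub_c] - fit$A * outer(gy, gx)
    }
    if (n_new == 0L) break
  }
  out <- do.call(rbind, accepted)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[out$x >= 0.5 & out$x <= nc + 0.5 &
               out$y >= 0.5 & out$y <= nr + 0.5, , drop = FALSE]
  out <- out[order(out$intensity, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Difference-of-Gaussians local maxima above threshold, sorted bright-first,
## with neighbors within sqrt(sup2) suppressed (brighter kept).
dog_candidates <- function(img, expected_sigma, candidate_nsd, sup2) {
  nr <- nrow(img); nc <- ncol(img)
  band <- gaussian_blur(img, expected_sigma) -
    gaussian_blur(img, 1.6 * expected_sigma)
  thr <- candidate_nsd * stats::mad(band)
  r <- max(1L, round(expected_sigma))
  mx <- band
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(-Inf, nr, nc)
    ri <- seq_len(nr) + dr; ci <- seq_len(nc) + dc
    okr <- ri >= 1 & ri <= nr; okc <- ci >= 1 & ci <= nc
    sh[okr, okc] <- band[ri[okr], ci[okc]]
    mx <- pmax(mx, sh)
  }
  cand <- which(band >= mx & band > thr, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(cand)
  ord <- order(band[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i] || i == nrow(cand)) next
    j <- (i + 1):nrow(cand)
    d2 <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2
    keep[j][d2 < sup2] <- FALSE
  }
  cand[keep, , drop = FALSE]
}

## Local least-squares fit of b + A*exp(-((x-x0)^2+(y-y0)^2)/(2 sigma^2)).
## Returns NULL on non-convergence.
fit_gaussian_window <- function(win, xs, ys, x0, y0, sigma0, a0, b0) {
  x0 <- unname(as.numeric(x0)); y0 <- unname(as.numeric(y0))
  a0 <- unname(as.numeric(a0)); b0 <- unname(as.numeric(b0))
  X <- matrix(xs, nrow(win), ncol(win), byrow = TRUE)
  Y <- matrix(ys, nrow(win), ncol(win))
  df <- data.frame(z = as.vector(win), x = as.vector(X), y = as.vector(Y))
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sg^2)),
      data = df,
      start = list(b = b0, A = max(a0, 1e-6), x0 = x0, y0 = y0, sg = sigma0),
      lower = c(b = -Inf, A = 0, x0 = min(xs) - 1, y0 = min(ys) - 1,
                sg = 0.45 * sigma0),
      upper = c(b = Inf, A = Inf, x0 = max(xs) + 1, y0 = max(ys) + 1,
                sg = 2.5 * sigma0),
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  list(b = cf[["b"]], A = cf[["A"]], x0 = cf[["x0"]], y0 = cf[["y0"]],
       sigma = cf[["sg"]])
}

#' Detect spots in every frame of a movie
#'
#' @param movie an `nd_movie`.
#' @inheritParams detect_spots
#' @return data.frame of spots with a leading `frame` column.
#' @export
detect_movie <- function(movie, expected_sigma = 1.3, snr_min = 5,
                         candidate_nsd = 3, n_passes = 2L) {
  if (!inherits(movie, "nd_movie")) stop_invalid("`movie` must be an nd_movie")
  nF <- dim(movie$stack)[3]
  res <- lapply(seq_len(nF), function(f) {
    sp <- detect_spots(movie$stack[, , f], expected_sigma, snr_min,
                       candidate_nsd, n_passes)
    if (nrow(sp)) cbind(frame = f, sp) else NULL
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0), sigma = numeric(0),
                      background = numeric(0), snr = numeric(0))
  rownames(res) <- NULL
  res
}

#' Summary statistics of detected spots
#'
#' Spot size is reported as the side of the equivalent square footprint,
#' the Gaussian FWHM `2*sqrt(2*log(2))*sigma` in px, comparable to the
#' "n x n pixels" convention used for nanodomain sizes.
#'
#' @param spots spot data.frame from [detect_spots()].
#' @return list with `n`, `mean_intensity`, `sd_intensity`, `mean_sigma`,
#'   `sd_sigma`, `mean_size_px`, `sd_size_px`.  With no spots all statistics
#'   are `NA` and `n = 0` (an explicit empty-summary sentinel).
#' @export
spot_statistics <- function(spots) {
  if (is.null(spots) || nrow(spots) == 0L)
    return(list(n = 0L, mean_intensity = NA_real_, sd_intensity = NA_real_,
                mean_sigma = NA_real_, sd_sigma = NA_real_,
                mean_size_px = NA_real_, sd_size_px = NA_real_))
  fwhm <- 2 * sqrt(2 * log(2))
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  list(n = nrow(spots),
       mean_intensity = mean(spots$intensity),
       sd_intensity = sd0(spots$intensity),
       mean_sigma = mean(spots$sigma),
       sd_sigma = sd0(spots$sigma),
       mean_size_px = fwhm * mean(spots$sigma),
       sd_size_px = fwhm * sd0(spots$sigma))
}

#' Spot density per area
#'
#' @param spots spot data.frame (a `frame` column, if present, gives
#'   per-frame counts; otherwise all spots are treated as one frame).
#' @param area field area in the chosen unit (> 0).
#' @param unit unit label for reporting, `"um2"` or `"px2"`.
#' @param n_frames total number of frames examined (defaults to the frames
#'   present in `spots`; frames with zero spots then cannot be inferred).
#' @return list of class `nd_density` with `n_spots`, `area`, `unit`,
#'   `per_frame` (density per frame), `density` (mean across frames) and
#'   `sd` (SD across frames).
#' @export
compute_density <- function(spots, area, unit = c("um2", "px2"),
                            n_frames = NULL) {
  unit <- match.arg(unit)
  check_scalar_pos(area, "area")
  if (is.null(spots) || nrow(spots) == 0L) {
    nf <- n_frames %||% 1L
    per <- rep(0, nf)
  } else {
    fr <- if ("frame" %in% names(spots)) spots$frame else rep(1L, nrow(spots))
    frames <- if (is.null(n_frames)) sort(unique(fr)) else seq_len(n_frames)
    per <- as.numeric(table(factor(fr, levels = frames))) / area
  }
  structure(list(n_spots = if (is.null(spots)) 0L else nrow(spots),
                 area = area, unit = unit, per_frame = per,
                 density = mean(per),
                 sd = if (length(per) > 1) stats::sd(per) else 0),
            class = "nd_density")
}

#' Voronoi localization-density segmentation of spots
#'
#' Builds the Voronoi diagram of spot centers, assigns each spot the local
#' density `1/cell_area`, and joins spots whose density reaches
#' `density_threshold` into clusters via adjacency of their Voronoi cells
#' (Delaunay neighbors).  Cells touching the bounding region (unbounded
#' cells) and clusters smaller than `min_cluster_size` get label 0.
#'
#' @param spots spot data.frame with `x`, `y` (px).
#' @param density_threshold minimum local density (1/area unit) for a spot to
#'   seed or join a cluster; `Inf` labels everything 0.
#' @param min_cluster_size minimum spots per reported cluster.
#' @param pixel_size um per px; cell areas are reported in um^2 (use 1 for
#'   px^2).
#' @param region optional c(xmin, xmax, ymin, ymax) bounding rectangle in px;
#'   defaults to the spot bounding box padded by 2 px.
#' @return list of class `nd_voronoi` with `cell_area` (um^2),
#'   `local_density` (1/um^2), `labels` (0 = below threshold/unbounded),
#'   `boundary` (cell clipped by the region), `threshold`, `region`.
#' @export
voronoi_segment <- function(spots, density_threshold, min_cluster_size = 3,
                            pixel_size = 1, region = NULL) {
  if (is.null(spots) || nrow(spots) < 4L)
    stop_degenerate("Voronoi segmentation needs >= 4 spots")
  x <- spots$x; y <- spots$y
  if (any(duplicated(cbind(x, y))))
    stop_degenerate("duplicate spot positions make the tessellation degenerate")
  sv <- svd(cbind(x - mean(x), y - mean(y)))$d
  if (sv[2] < 1e-9 * sv[1])
    stop_degenerate("spots are collinear")
  if (is.null(region)) {
    region <- c(min(x) - 2, max(x) + 2, min(y) - 2, max(y) + 2)
  }
  dd <- deldir::deldir(x, y, rw = region)
  tl <- deldir::tile.list(dd)
  area_px2 <- vapply(tl, function(t) t$area, numeric(1))
  boundary <- vapply(tl, function(t) any(t$bp), logical(1))
  cell_area <- area_px2 * pixel_size^2
  local_density <- 1 / cell_area
  qual <- local_density >= density_threshold & !boundary
  labels <- integer(length(x))
  if (any(qual)) {
    edges <- dd$delsgs[, c("ind1", "ind2")]
    keep <- qual[edges$ind1] & qual[edges$ind2]
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$ind1[keep], to = edges$ind2[keep]),
      directed = FALSE,
      vertices = data.frame(name = which(qual)))
    comp <- igraph::components(g)
    memb <- comp$membership
    sizes <- comp$csize
    ok_comp <- which(sizes >= min_cluster_size)
    ## relabel surviving clusters 1..k by decreasing size
    ord <- ok_comp[order(sizes[ok_comp], decreasing = TRUE)]
    relab <- integer(length(sizes)); relab[ord] <- seq_along(ord)
    labels[as.integer(names(memb))] <- relab[memb]
  }
  structure(list(cell_area = cell_area, local_density = local_density,
                 labels = labels, boundary = boundary,
                 threshold = density_threshold, region = region,
                 pixel_size = pixel_size),
            class = "nd_voronoi")
}
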