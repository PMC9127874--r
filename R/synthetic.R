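## Synthetic VA-TIRFM data generator.
##
## Emitters live on a margin-extended field (so boundary depletion does not
## bias in-frame density), perform 2D Brownian motion with per-axis step
## variance 2*D*dt, carry exponentially distributed membrane dwell times, and
## are rendered as pixel-integrated 2D Gaussian point-spread functions on a
## noisy background (Poisson shot noise first, then additive Gaussian read
## noise, the EMCCD convention).

#' Describe one diffusive subpopulation of membrane particles
#'
#' @param D lateral diffusion coefficient, um^2/s (> 0; use 0 for immobile).
#' @param fraction fraction of all particles in this population, in (0, 1].
#' @param mean_dwell mean membrane dwell time in seconds before disappearance
#'   (endocytosis / departure from the surface); `Inf` means particles never
#'   leave and no turnover occurs.
#' @param mean_intensity mean integrated intensity per particle per frame
#'   (counts, > 0).
#' @param intensity_cv coefficient of variation of per-particle intensity
#'   (>= 0).
#' @return an object of class `nd_population`.
#' @export
population_spec <- function(D, fraction = 1, mean_dwell = Inf,
                            mean_intensity = 500, intensity_cv = 0.1) {
  if (length(D) != 1L || !is.numeric(D) || is.na(D) || D < 0)
    stop_invalid("`D` must be a single non-negative number")
  if (fraction <= 0 || fraction > 1)
    stop_invalid("`fraction` must lie in (0, 1]")
  check_scalar_pos(mean_dwell, "mean_dwell", allow_inf = TRUE)
  check_scalar_pos(mean_intensity, "mean_intensity")
  if (intensity_cv < 0) stop_invalid("`intensity_cv` must be >= 0")
  structure(list(D = D, fraction = fraction, mean_dwell = mean_dwell,
                 mean_intensity = mean_intensity, intensity_cv = intensity_cv),
            class = "nd_population")
}

#' Describe the imaging geometry and noise of a synthetic acquisition
#'
#' Defaults correspond to a typical 100x/1.45-NA TIRF setup: 0.1 um pixels,
#' 0.1 s frame interval, PSF sigma 1.3 px.
#'
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval s per frame (> 0).
#' @param n_frames number of frames (>= 2).
#' @param shape integer c(rows, cols) of the rendered frame.
#' @param psf_sigma Gaussian PSF standard deviation in px (> 0, less than a
#'   quarter of the smaller frame side).
#' @param background_mean mean background level, counts.
#' @param read_noise_sd additive Gaussian read-noise SD, counts (>= 0).
#' @param shot_noise apply Poisson shot noise?
#' @return an object of class `nd_imaging`.
#' @export
imaging_spec <- function(pixel_size = 0.1, frame_interval = 0.1,
                         n_frames = 50, shape = c(64L, 64L),
                         psf_sigma = 1.3, background_mean = 100,
                         read_noise_sd = 2, shot_noise = TRUE) {
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(frame_interval, "frame_interval")
  if (n_frames < 2) stop_invalid("`n_frames` must be >= 2")
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 4L))
    stop_invalid("`shape` must be c(rows, cols) with both >= 4")
  check_scalar_pos(psf_sigma, "psf_sigma")
  if (psf_sigma >= min(shape) / 4)
    stop_invalid("`psf_sigma` must be < min(shape)/4")
  if (background_mean < 0) stop_invalid("`background_mean` must be >= 0")
  if (read_noise_sd < 0) stop_invalid("`read_noise_sd` must be >= 0")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), shape = shape,
                 psf_sigma = psf_sigma, background_mean = background_mean,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise)),
            class = "nd_imaging")
}

#' Construct a calibrated movie object
#'
#' @param stack numeric array rows x cols x frames of non-negative counts.
#' @param pixel_size um per pixel.
#' @param frame_interval s per frame.
#' @param channel_label free-text channel name.
#' @return an object of class `nd_movie`.
#' @export
nd_movie <- function(stack, pixel_size, frame_interval,
                     channel_label = "ch1") {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop_invalid("`stack` must be a rows x cols x frames array")
  if (any(stack < 0)) stop_invalid("pixel values must be >= 0")
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(frame_interval, "frame_interval")
  structure(list(stack = stack, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_label = channel_label),
            class = "nd_movie")
}

#' @export
print.nd_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<nd_movie '%s'> %d x %d px, %d frames, %.4g um/px, %.4g s/frame\n",
              x$channel_label, d[1], d[2], d[3], x$pixel_size,
              x$frame_interval))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Emitter tables

## Draw birth frames, lifetimes and population labels so that the expected
## particle count is stationary: initial count ~ Poisson(N_exp) plus Poisson
## births at rate N_exp/mean_dwell per unit time.
draw_emitters <- function(populations, imaging, density, margin) {
  F <- imaging$n_frames
  dt <- imaging$frame_interval
  rows_e <- imaging$shape[1] + 2 * margin
  cols_e <- imaging$shape[2] + 2 * margin
  area_um2 <- rows_e * cols_e * imaging$pixel_size^2

  birth <- integer(0); pop <- integer(0)
  for (p in seq_along(populations)) {
    sp <- populations[[p]]
    n_exp <- density * area_um2 * sp$fraction
    n0 <- stats::rpois(1L, n_exp)
    nb <- if (is.finite(sp$mean_dwell))
      stats::rpois(F - 1L, n_exp * dt / sp$mean_dwell) else integer(F - 1L)
    birth <- c(birth, rep(1L, n0), rep(seq(2L, length.out = F - 1L), nb))
    pop <- c(pop, rep.int(p, n0 + sum(nb)))
  }
  n <- length(birth)
  if (n == 0L)
    return(data.frame(track_id = integer(0), population_id = integer(0),
                      birth = integer(0), death = integer(0),
                      censored_start = logical(0), censored_end = logical(0),
                      intensity = numeric(0)))
  dwell_mean <- vapply(populations, `[[`, numeric(1), "mean_dwell")[pop]
  life_frames <- ifelse(is.finite(dwell_mean),
                        floor(stats::rexp(n, 1 / dwell_mean) / dt) + 1L,
                        Inf)
  death <- pmin(birth + life_frames - 1, F)
  censored_end <- birth + life_frames - 1 > F
  int_mean <- vapply(populations, `[[`, numeric(1), "mean_intensity")[pop]
  int_cv <- vapply(populations, `[[`, numeric(1), "intensity_cv")[pop]
  intensity <- pmax(stats::rnorm(n, int_mean, int_cv * int_mean),
                    0.05 * int_mean)
  data.frame(track_id = seq_len(n), population_id = pop, birth = birth,
             death = as.integer(death), censored_start = birth == 1L,
             censored_end = censored_end, intensity = intensity)
}

## triangle-wave fold of coordinates into [lo, hi] (reflected Brownian motion)
reflect_fold <- function(z, lo, hi) {
  w <- hi - lo
  r <- (z - lo) %% (2 * w)
  lo + ifelse(r > w, 2 * w - r, r)
}

## Expand an emitter table into a long per-frame track table with Brownian
## positions (px) on the margin-extended field.
walk_emitters <- function(emitters, populations, imaging, margin) {
  if (nrow(emitters) == 0L)
    return(data.frame(track_id = integer(0), population_id = integer(0),
                      frame = integer(0), x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), censored_start = logical(0),
                      censored_end = logical(0)))
  dt <- imaging$frame_interval
  px <- imaging$pixel_size
  D <- vapply(populations, `[[`, numeric(1), "D")
  len <- emitters$death - emitters$birth + 1L
  total <- sum(len)
  id <- rep.int(emitters$track_id, len)
  popl <- rep.int(emitters$population_id, len)
  frame <- unlist(lapply(seq_len(nrow(emitters)),
                         function(i) seq.int(emitters$birth[i], emitters$death[i])),
                  use.names = FALSE)
  sd_px <- sqrt(2 * D[popl] * dt) / px
  first <- c(TRUE, id[-1L] != id[-total])
  dx <- stats::rnorm(total, 0, sd_px); dy <- stats::rnorm(total, 0, sd_px)
  x0 <- stats::runif(nrow(emitters), 0.5 - margin,
                     imaging$shape[2] + 0.5 + margin)
  y0 <- stats::runif(nrow(emitters), 0.5 - margin,
                     imaging$shape[1] + 0.5 + margin)
  dx[first] <- x0; dy[first] <- y0
  ## per-track cumulative sums without a loop: subtract the running offset at
  ## each track start
  cx <- cumsum(dx); cy <- cumsum(dy)
  starts <- which(first)
  off_x <- cumsum(c(0, dx))[starts]; off_y <- cumsum(c(0, dy))[starts]
  x <- cx - rep.int(off_x, len); y <- cy - rep.int(off_y, len)
  ## reflecting boundaries at the extended-domain edge: the field is a closed
  ## reservoir, so long records conserve particle density (reflection
  ## principle: fold the free path into the box)
  x <- reflect_fold(x, 0.5 - margin, imaging$shape[2] + 0.5 + margin)
  y <- reflect_fold(y, 0.5 - margin, imaging$shape[1] + 0.5 + margin)
  data.frame(track_id = id, population_id = popl, frame = frame,
             x_px = x, y_px = y,
             intensity = rep.int(emitters$intensity, len),
             censored_start = rep.int(emitters$censored_start, len),
             censored_end = rep.int(emitters$censored_end, len))
}

## ---------------------------------------------------------------------------
## Rendering

## Pixel-integrated Gaussian rendering: the counts deposited in a pixel are
## the emitter intensity times the product of 1D Gaussian integrals over the
## pixel extent, so the total rendered intensity equals the assigned intensity
## up to 4-sigma tail mass (< 0.02%).
render_stack <- function(tracks, imaging) {
  R <- imaging$shape[1]; C <- imaging$shape[2]; F <- imaging$n_frames
  stack <- numeric(R * C * F)
  if (nrow(tracks) > 0L) {
    s <- imaging$psf_sigma
    ## window covers > 4 sigma from the center of every border pixel, so the
    ## rendered mass is within 5e-4 of the assigned intensity
    h <- max(3L, ceiling(4 * s - 0.5))
    ## emitters whose window cannot touch the frame contribute nothing
    tracks <- tracks[tracks$x_px >= 1 - h - 1 & tracks$x_px <= C + h + 1 &
                       tracks$y_px >= 1 - h - 1 & tracks$y_px <= R + h + 1, ,
                     drop = FALSE]
    off <- -h:h
    cx <- round(tracks$x_px); cy <- round(tracks$y_px)
    ex <- outer(cx - tracks$x_px, off, "+")
    ey <- outer(cy - tracks$y_px, off, "+")
    WX <- stats::pnorm((ex + 0.5) / s) - stats::pnorm((ex - 0.5) / s)
    WY <- stats::pnorm((ey + 0.5) / s) - stats::pnorm((ey - 0.5) / s)
    rowm <- outer(cy, off, "+")
    base <- (tracks$frame - 1) * (R * C)
    idx_all <- vector("list", length(off))
    val_all <- vector("list", length(off))
    for (j in seq_along(off)) {
      colj <- cx + off[j]
      v <- (tracks$intensity * WX[, j]) * WY
      li <- base + (colj - 1) * R + rowm
      ok <- colj >= 1 & colj <= C
      okm <- ok & rowm >= 1 & rowm <= R
      idx_all[[j]] <- li[okm]
      val_all[[j]] <- v[okm]
    }
    idx <- as.integer(unlist(idx_all, use.names = FALSE))
    val <- unlist(val_all, use.names = FALSE)
    if (length(idx)) {
      ## aggregate duplicate pixel indices: radix order + grouped cumsum is
      ## considerably faster than hash-based rowsum at these volumes
      o <- order(idx, method = "radix")
      si <- idx[o]
      cs <- cumsum(val[o])
      last <- c(si[-1L] != si[-length(si)], TRUE)
      ends <- which(last)
      stack[si[ends]] <- diff(c(0, cs[ends]))
    }
  }
  dim(stack) <- c(R, C, F)
  stack <- stack + imaging$background_mean
  if (imaging$shot_noise) {
    stack[] <- stats::rpois(length(stack), stack)
  }
  if (imaging$read_noise_sd > 0) {
    stack <- stack + stats::rnorm(length(stack), 0, imaging$read_noise_sd)
    stack <- pmax(stack, 0)
  }
  stack
}

finish_ground_truth <- function(tracks, populations, imaging, density,
                                margin) {
  tracks$x_um <- tracks$x_px * imaging$pixel_size
  tracks$y_um <- tracks$y_px * imaging$pixel_size
  structure(list(tracks = tracks, populations = populations,
                 imaging = imaging, density = density, margin = margin),
            class = "nd_ground_truth")
}

#' @export
print.nd_ground_truth <- function(x, ...) {
  cat(sprintf("<nd_ground_truth> %d tracks, %d emitter-frames, %d population(s)\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks),
              length(x$populations)))
  invisible(x)
}

#' Simulate a VA-TIRFM movie of laterally diffusing membrane particles
#'
#' Particles appear by a Poisson birth process (rate = expected count /
#' mean dwell, keeping the expected particle number stationary), diffuse on a
#' field extended `margin` px beyond the frame, persist for an exponential
#' dwell time, and are rendered as pixel-integrated Gaussian spots over a
#' noisy background.
#'
#' @param populations an `nd_population` or list of them; `fraction`s must
#'   sum to 1.
#' @param imaging an [imaging_spec()].
#' @param density expected particle density, particles/um^2 (>= 0; 0 gives a
#'   pure-background movie).
#' @param seed optional RNG seed; identical seed and parameters give
#'   bit-identical output.
#' @param margin extension of the diffusion field beyond the frame, px.
#' @param render if `FALSE`, skip rendering and return `movie = NULL` (useful
#'   when only ground-truth tracks are needed).
#' @return list with elements `movie` (an `nd_movie`) and `ground_truth`
#'   (an `nd_ground_truth` whose `tracks` hold true per-frame positions in
#'   px and um, with censoring flags for tracks overlapping the movie start
#'   or end).
#' @export
simulate_movie <- function(populations, imaging, density, seed = NULL,
                           margin = 10, render = TRUE) {
  if (inherits(populations, "nd_population")) populations <- list(populations)
  if (!length(populations) ||
      !all(vapply(populations, inherits, logical(1), "nd_population")))
    stop_invalid("`populations` must be population_spec objects")
  fr <- sum(vapply(populations, `[[`, numeric(1), "fraction"))
  if (abs(fr - 1) > 1e-9)
    stop_invalid("population fractions must sum to 1")
  if (!inherits(imaging, "nd_imaging"))
    stop_invalid("`imaging` must be an imaging_spec()")
  if (length(density) != 1L || is.na(density) || density < 0)
    stop_invalid("`density` must be a single non-negative number")
  if (!is.null(seed)) set.seed(seed)
  emitters <- draw_emitters(populations, imaging, density, margin)
  tracks <- walk_emitters(emitters, populations, imaging, margin)
  gt <- finish_ground_truth(tracks, populations, imaging, density, margin)
  movie <- NULL
  if (render) {
    stack <- render_stack(tracks, imaging)
    movie <- nd_movie(stack, imaging$pixel_size, imaging$frame_interval)
  }
  list(movie = movie, ground_truth = gt)
}

#' Simulate ground-truth Brownian tracks without imaging
#'
#' Convenience generator for diffusion / velocity analyses that do not need
#' rendered movies: `n_tracks` independent 2D Brownian tracks of fixed length.
#'
#' @param n_tracks number of tracks.
#' @param n_steps number of steps per track (track length is `n_steps + 1`).
#' @param D diffusion coefficient, um^2/s.
#' @param dt frame interval, s.
#' @param sigma_loc static localization error SD added to each coordinate, um.
#' @param seed optional RNG seed.
#' @return data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @export
simulate_brownian_tracks <- function(n_tracks, n_steps, D, dt,
                                     sigma_loc = 0, seed = NULL) {
  if (n_tracks < 1 || n_steps < 1) stop_invalid("need >= 1 track and step")
  if (D < 0 || sigma_loc < 0) stop_invalid("`D` and `sigma_loc` must be >= 0")
  check_scalar_pos(dt, "dt")
  if (!is.null(seed)) set.seed(seed)
  npt <- n_steps + 1L
  sd_step <- sqrt(2 * D * dt)
  x <- apply(matrix(stats::rnorm(n_tracks * n_steps, 0, sd_step),
                    n_steps, n_tracks), 2, cumsum)
  y <- apply(matrix(stats::rnorm(n_tracks * n_steps, 0, sd_step),
                    n_steps, n_tracks), 2, cumsum)
  x <- rbind(0, matrix(x, n_steps, n_tracks))
  y <- rbind(0, matrix(y, n_steps, n_tracks))
  if (sigma_loc > 0) {
    x <- x + stats::rnorm(length(x), 0, sigma_loc)
    y <- y + stats::rnorm(length(y), 0, sigma_loc)
  }
  data.frame(track_id = rep(seq_len(n_tracks), each = npt),
             frame = rep(seq_len(npt), n_tracks),
             x_um = as.vector(x), y_um = as.vector(y))
}

#' Simulate a two-channel acquisition with controlled colocalization
#'
#' Channel-B particles are, with probability `coloc_fraction`, attached to a
#' randomly chosen channel-A track at a fixed offset within 1 px; the
#' remainder diffuse independently.
#'
#' @param populations_a,populations_b population specs for each channel.
#' @param coloc_fraction fraction of channel-B particles co-positioned with a
#'   channel-A particle, in [0, 1].
#' @param imaging an [imaging_spec()] shared by both channels.
#' @param density_a,density_b particle densities per channel, particles/um^2.
#' @param seed optional RNG seed.
#' @param margin field extension in px.
#' @return list with `movie_a`, `movie_b` and `ground_truth`; the ground-truth
#'   track table has a `channel` column and, for colocalized B tracks, the
#'   partner A `coloc_partner` id.
#' @export
simulate_two_channel <- function(populations_a, populations_b, coloc_fraction,
                                 imaging, density_a, density_b, seed = NULL,
                                 margin = 10) {
  check_fraction(coloc_fraction, "coloc_fraction")
  if (!is.null(seed)) set.seed(seed)
  sim_a <- simulate_movie(populations_a, imaging, density_a, seed = NULL,
                          margin = margin)
  if (inherits(populations_b, "nd_population"))
    populations_b <- list(populations_b)
  em_b <- draw_emitters(populations_b, imaging, density_b, margin)
  tr_b <- walk_emitters(em_b, populations_b, imaging, margin)
  tr_a <- sim_a$ground_truth$tracks
  ids_b <- unique(tr_b$track_id)
  ids_a <- unique(tr_a$track_id)
  partner <- rep(NA_integer_, length(ids_b))
  if (length(ids_a) > 0 && length(ids_b) > 0 && coloc_fraction > 0) {
    is_col <- stats::runif(length(ids_b)) < coloc_fraction
    ## partners drawn without replacement (recycled only if B outnumbers A)
    pool <- rep(sample(ids_a), length.out = sum(is_col))
    np <- 0L
    for (i in which(is_col)) {
      np <- np + 1L
      a_id <- pool[np]
      a_rows <- tr_a[tr_a$track_id == a_id, ]
      theta <- stats::runif(1, 0, 2 * pi)
      r <- sqrt(stats::runif(1))           # uniform in unit disk, offset <= 1 px
      keep <- tr_b$track_id != ids_b[i]
      b_int <- tr_b$intensity[tr_b$track_id == ids_b[i]][1]
      new_rows <- data.frame(track_id = ids_b[i],
                             population_id = tr_b$population_id[!keep][1],
                             frame = a_rows$frame,
                             x_px = a_rows$x_px + r * cos(theta),
                             y_px = a_rows$y_px + r * sin(theta),
                             intensity = b_int,
                             censored_start = a_rows$censored_start,
                             censored_end = a_rows$censored_end)
      tr_b <- rbind(tr_b[keep, ], new_rows)
      partner[i] <- a_id
    }
    tr_b <- tr_b[order(tr_b$track_id, tr_b$frame), ]
  }
  stack_b <- render_stack(tr_b, imaging)
  movie_b <- nd_movie(stack_b, imaging$pixel_size, imaging$frame_interval,
                      channel_label = "chB")
  sim_a$movie$channel_label <- "chA"
  tr_a <- tr_a[, setdiff(names(tr_a), c("x_um", "y_um"))]
  tr_a$channel <- "A"; tr_a$coloc_partner <- NA_integer_
  if (nrow(tr_b)) {
    tr_b$channel <- "B"
    tr_b$coloc_partner <- partner[match(tr_b$track_id, ids_b)]
  } else {
    tr_b$channel <- character(0); tr_b$coloc_partner <- integer(0)
  }
  gt <- finish_ground_truth(rbind(tr_a, tr_b),
                            list(A = populations_a, B = populations_b),
                            imaging, c(A = density_a, B = density_b), margin)
  list(movie_a = sim_a$movie, movie_b = movie_b, ground_truth = gt)
}

#' Simulate a FRAP experiment
#'
#' A field of particles (no turnover; a fraction immobile) diffuses on an
#' extended domain. At `bleach_frame`, particles inside the rectangular ROI
#' are switched dark with probability `bleach_depth`; fluorescence in the ROI
#' recovers only by lateral exchange with unbleached particles from outside.
#'
#' @param imaging an [imaging_spec()].
#' @param density particle density, particles/um^2.
#' @param D diffusion coefficient of the mobile fraction, um^2/s.
#' @param bleach_roi c(x, y, w, h) in px (column x, row y of the top-left
#'   pixel, width, height); must lie inside the frame.
#' @param bleach_frame frame index at which the bleach is applied (the frame
#'   is rendered post-bleach).
#' @param bleach_depth probability that an in-ROI particle is bleached.
#' @param immobile_fraction fraction of particles with D = 0.
#' @param mean_intensity,intensity_cv per-particle intensity model.
#' @param seed optional RNG seed.
#' @param margin field extension in px (default 20, a reservoir much larger
#'   than typical ROIs).
#' @return list with `movie`, `ground_truth` (tracks plus per-emitter
#'   `immobile`/`bleached` flags), and the bleach parameters.
#' @export
simulate_frap <- function(imaging, density, D, bleach_roi, bleach_frame,
                          bleach_depth = 1, immobile_fraction = 0,
                          mean_intensity = 300, intensity_cv = 0.1,
                          seed = NULL, margin = 20) {
  check_fraction(bleach_depth, "bleach_depth")
  check_fraction(immobile_fraction, "immobile_fraction")
  roi <- as.numeric(bleach_roi)
  if (length(roi) != 4L || any(!is.finite(roi)) || roi[3] < 1 || roi[4] < 1 ||
      roi[1] < 1 || roi[2] < 1 || roi[1] + roi[3] - 1 > imaging$shape[2] ||
      roi[2] + roi[4] - 1 > imaging$shape[1])
    stop_invalid("`bleach_roi` (x, y, w, h) must lie inside the frame")
  if (bleach_frame < 2 || bleach_frame > imaging$n_frames)
    stop_invalid("`bleach_frame` must be in 2..n_frames")
  if (!is.null(seed)) set.seed(seed)
  pops <- list(population_spec(D = D, fraction = 1, mean_dwell = Inf,
                               mean_intensity = mean_intensity,
                               intensity_cv = intensity_cv))
  emitters <- draw_emitters(pops, imaging, density, margin)
  immobile <- stats::runif(nrow(emitters)) < immobile_fraction
  tracks <- walk_emitters(emitters, pops, imaging, margin)
  if (any(immobile)) {
    ## freeze immobile emitters at their initial position
    im_ids <- emitters$track_id[immobile]
    sel <- tracks$track_id %in% im_ids
    first_idx <- !duplicated(tracks$track_id)
    x0 <- tracks$x_px[first_idx][match(tracks$track_id[sel],
                                       tracks$track_id[first_idx])]
    y0 <- tracks$y_px[first_idx][match(tracks$track_id[sel],
                                       tracks$track_id[first_idx])]
    tracks$x_px[sel] <- x0
    tracks$y_px[sel] <- y0
  }
  ## bleach decision from position at bleach_frame
  at_bleach <- tracks[tracks$frame == bleach_frame, ]
  in_roi <- at_bleach$x_px >= roi[1] - 0.5 &
    at_bleach$x_px <= roi[1] + roi[3] - 0.5 &
    at_bleach$y_px >= roi[2] - 0.5 &
    at_bleach$y_px <= roi[2] + roi[4] - 0.5
  hit <- at_bleach$track_id[in_roi &
                              stats::runif(nrow(at_bleach)) < bleach_depth]
  visible <- !(tracks$track_id %in% hit & tracks$frame >= bleach_frame)
  stack <- render_stack(tracks[visible, ], imaging)
  tracks$bleached <- tracks$track_id %in% hit
  tracks$immobile <- tracks$track_id %in% emitters$track_id[immobile]
  gt <- finish_ground_truth(tracks, pops, imaging, density, margin)
  gt$bleach_roi <- roi; gt$bleach_frame <- bleach_frame
  gt$bleach_depth <- bleach_depth; gt$immobile_fraction <- immobile_fraction
  list(movie = nd_movie(stack, imaging$pixel_size, imaging$frame_interval),
       ground_truth = gt)
}

#' Simulate an FCS intensity fluctuation trace
#'
#' Particles diffuse through a 2D Gaussian observation area (beam waist `w0`,
#' effective area pi*w0^2) on a periodic box much larger than the beam. The
#' per-sample emission of a particle at distance r from the beam axis is
#' `brightness * 2 * exp(-2 r^2 / w0^2)`, so `brightness` is the
#' area-averaged counts per particle per sample: the trace mean is
#' approximately `N_mean * brightness` and the fluctuation autocorrelation
#' amplitude is 1/N_mean.
#'
#' @param N_mean mean particle number in the effective observation area
#'   (pi*w0^2), > 0.
#' @param tau_D diffusion residence time w0^2/(4 D), s; `Inf` freezes the
#'   particles.
#' @param duration trace duration, s (>= 100 * sampling_dt).
#' @param sampling_dt sampling interval, s.
#' @param brightness mean counts per particle per sample.
#' @param seed optional RNG seed.
#' @param w0 beam waist (1/e^2 radius), um.
#' @param box_factor periodic box side, in units of w0.
#' @param shot_noise apply Poisson photon noise to the samples?
#' @return object of class `nd_fcs_trace` with `samples`, `sampling_dt`,
#'   `duration` and the generating parameters.
#' @export
simulate_fcs_trace <- function(N_mean, tau_D, duration, sampling_dt,
                               brightness, seed = NULL, w0 = 0.25,
                               box_factor = 8, shot_noise = TRUE) {
  check_scalar_pos(N_mean, "N_mean")
  check_scalar_pos(tau_D, "tau_D", allow_inf = TRUE)
  check_scalar_pos(sampling_dt, "sampling_dt")
  check_scalar_pos(brightness, "brightness")
  if (!is.numeric(duration) || duration < 100 * sampling_dt)
    stop_invalid("`duration` must be >= 100 * sampling_dt")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(duration / sampling_dt))
  L <- box_factor * w0
  conc <- N_mean / (pi * w0^2)
  n_part <- max(1L, stats::rpois(1L, conc * L^2))
  D <- if (is.finite(tau_D)) w0^2 / (4 * tau_D) else 0
  sd_step <- sqrt(2 * D * sampling_dt)
  wrap <- function(z) ((z + L / 2) %% L) - L / 2
  x <- stats::runif(n_part, -L / 2, L / 2)
  y <- stats::runif(n_part, -L / 2, L / 2)
  rate <- numeric(n)
  block <- max(1L, min(n, floor(2e6 / n_part)))
  done <- 0L
  while (done < n) {
    b <- min(block, n - done)
    if (sd_step > 0) {
      xs <- x + t(apply(matrix(stats::rnorm(n_part * b, 0, sd_step),
                               n_part, b), 1, cumsum))
      ys <- y + t(apply(matrix(stats::rnorm(n_part * b, 0, sd_step),
                               n_part, b), 1, cumsum))
      if (b == 1L) { xs <- matrix(xs, n_part, 1); ys <- matrix(ys, n_part, 1) }
      x <- wrap(xs[, b]); y <- wrap(ys[, b])
      xs <- wrap(xs); ys <- wrap(ys)
    } else {
      xs <- matrix(x, n_part, b); ys <- matrix(y, n_part, b)
    }
    W <- 2 * exp(-2 * (xs^2 + ys^2) / w0^2)
    rate[done + seq_len(b)] <- brightness * colSums(W)
    done <- done + b
  }
  samples <- if (shot_noise) stats::rpois(n, rate) else rate
  structure(list(samples = samples, sampling_dt = sampling_dt,
                 duration = n * sampling_dt, N_mean = N_mean, tau_D = tau_D,
                 brightness = brightness, w0 = w0, n_particles = n_part),
            class = "nd_fcs_trace")
}
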