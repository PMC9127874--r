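## Object-based two-channel colocalization.

mutual_nn_pairs <- function(ax, ay, bx, by, radius) {
  if (!length(ax) || !length(bx)) return(0L)
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  nn_b_of_a <- apply(d, 1, which.min)
  nn_a_of_b <- apply(d, 2, which.min)
  mutual <- which(nn_a_of_b[nn_b_of_a] == seq_along(ax))
  dist_ok <- d[cbind(mutual, nn_b_of_a[mutual])] <= radius
  sum(dist_ok)
}

#' Object-based colocalization of two spot sets
#'
#' Counts mutual-nearest-neighbor pairs of channel-A and channel-B spot
#' centers within `match_radius` px; the reported percentage is
#' `100 * n_matched / n_A` (channel A as reference).  If the field area is
#' known, the chance overlap expected for a random homogeneous channel B is
#' reported via the closed form `100 * (1 - exp(-rho_B * pi * r^2))`.
#'
#' @param spots_a,spots_b spot data.frames with `x`, `y` (px) and optionally
#'   `frame` (present in both: matching is then done within frames).
#' @param match_radius maximum center distance for a match, px (default 2,
#'   roughly the diffraction scale).
#' @param area field area in px^2 (per frame), for the chance estimate;
#'   `NULL` skips it.
#' @return list of class `nd_coloc` with `percent_overlap` (`NA` when
#'   channel A is empty), `n_A`, `n_B`, `n_matched`, `match_radius`,
#'   `chance_percent`.
#' @export
colocalize <- function(spots_a, spots_b, match_radius = 2, area = NULL) {
  check_scalar_pos(match_radius, "match_radius")
  n_a <- if (is.null(spots_a)) 0L else nrow(spots_a)
  n_b <- if (is.null(spots_b)) 0L else nrow(spots_b)
  by_frame <- n_a > 0 && n_b > 0 &&
    "frame" %in% names(spots_a) && "frame" %in% names(spots_b)
  n_matched <- 0L
  n_frames <- 1L
  if (n_a > 0 && n_b > 0) {
    if (by_frame) {
      frames <- union(unique(spots_a$frame), unique(spots_b$frame))
      n_frames <- length(frames)
      for (f in frames) {
        sa <- spots_a[spots_a$frame == f, ]
        sb <- spots_b[spots_b$frame == f, ]
        n_matched <- n_matched +
          mutual_nn_pairs(sa$x, sa$y, sb$x, sb$y, match_radius)
      }
    } else {
      n_matched <- mutual_nn_pairs(spots_a$x, spots_a$y,
                                   spots_b$x, spots_b$y, match_radius)
    }
  }
  chance <- NA_real_
  if (!is.null(area)) {
    check_scalar_pos(area, "area")
    rho_b <- n_b / (area * n_frames)
    chance <- 100 * (1 - exp(-rho_b * pi * match_radius^2))
  }
  structure(list(percent_overlap = if (n_a > 0) 100 * n_matched / n_a
                 else NA_real_,
                 n_A = n_a, n_B = n_b, n_matched = as.integer(n_matched),
                 match_radius = match_radius, chance_percent = chance),
            class = "nd_coloc")
}

#' Monte-Carlo chance colocalization by position shuffling
#'
#' Re-draws channel-B positions uniformly in the field and recomputes the
#' overlap percentage, giving an empirical chance distribution to compare
#' with the closed-form estimate of [colocalize()].
#'
#' @inheritParams colocalize
#' @param region c(xmin, xmax, ymin, ymax) of the field, px.
#' @param n_perm number of permutations.
#' @return numeric vector of `n_perm` chance overlap percentages.
#' @export
coloc_chance_perm <- function(spots_a, spots_b, match_radius = 2, region,
                              n_perm = 99L) {
  if (length(region) != 4L) stop_invalid("`region` must be c(xmin,xmax,ymin,ymax)")
  n_b <- nrow(spots_b)
  vapply(seq_len(n_perm), function(i) {
    shuf <- data.frame(x = stats::runif(n_b, region[1], region[2]),
                       y = stats::runif(n_b, region[3], region[4]))
    colocalize(spots_a[, c("x", "y")], shuf, match_radius)$percent_overlap
  }, numeric(1))
}

#' Paired fluorescence profiles along a line
#'
#' Samples both channels by bilinear interpolation on the same abscissa
#' (1-px spacing along the line).
#'
#' @param frame_a,frame_b numeric matrices of identical dimensions (single
#'   frames of the two channels).
#' @param line c(x0, y0, x1, y1) px, inside the frames.
#' @return data.frame with `distance_px`, `intensity_a`, `intensity_b`.
#' @export
line_profile <- function(frame_a, frame_b, line) {
  if (!is.matrix(frame_a) || !is.matrix(frame_b) ||
      !identical(dim(frame_a), dim(frame_b)))
    stop_invalid("channels must be matrices with identical dimensions")
  line <- as.numeric(line)
  if (length(line) != 4L) stop_invalid("`line` must be c(x0, y0, x1, y1)")
  d <- dim(frame_a)
  if (any(line[c(1, 3)] < 1) || any(line[c(1, 3)] > d[2]) ||
      any(line[c(2, 4)] < 1) || any(line[c(2, 4)] > d[1]))
    stop_invalid("`line` endpoints must lie inside the frame")
  len <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
  n_samp <- max(2L, ceiling(len) + 1L)
  t <- seq(0, 1, length.out = n_samp)
  sx <- line[1] + t * (line[3] - line[1])
  sy <- line[2] + t * (line[4] - line[2])
  data.frame(distance_px = t * len,
             intensity_a = bilinear_sample(frame_a, sx, sy),
             intensity_b = bilinear_sample(frame_b, sx, sy))
}
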