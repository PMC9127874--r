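## Trajectory linking, dwell times and kymographs.

#' Link per-frame spots into trajectories
#'
#' Frame-to-frame assignment is greedy on ascending distance (equivalent to
#' iterated mutual nearest neighbors) within `max_disp` px per frame; a track
#' that misses up to `max_gap` consecutive frames may be bridged with search
#' radius `max_disp * (gap + 1)`.  Unmatched spots start new tracks.
#'
#' @param spots data.frame with `frame`, `x`, `y` and optionally `intensity`.
#' @param max_disp maximum displacement per frame, px.
#' @param max_gap maximum number of bridged missing frames.
#' @param min_points minimum points for a reported track (default 2).
#' @param frame_range c(first, last) frame of the movie, used to flag tracks
#'   overlapping the movie start/end as censored; defaults to the range of
#'   `spots$frame`.
#' @return data.frame with `track_id`, `frame`, `x`, `y`, `intensity`,
#'   `censored_start`, `censored_end`, ordered by track then frame.  The
#'   attribute `n_unlinked` counts spots left in tracks shorter than
#'   `min_points`, so `nrow(result) + n_unlinked` equals the input spot
#'   count when `min_points = 2`.
#' @export
link_trajectories <- function(spots, max_disp, max_gap = 1L, min_points = 2L,
                              frame_range = NULL) {
  empty <- data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), intensity = numeric(0),
                      censored_start = logical(0), censored_end = logical(0))
  attr(empty, "n_unlinked") <- 0L
  if (is.null(spots) || nrow(spots) == 0L) return(empty)
  check_scalar_pos(max_disp, "max_disp")
  if (max_gap < 0) stop_invalid("`max_gap` must be >= 0")
  if (!all(c("frame", "x", "y") %in% names(spots)))
    stop_invalid("`spots` needs columns frame, x, y")
  if (!"intensity" %in% names(spots)) spots$intensity <- NA_real_
  spots <- spots[order(spots$frame), ]
  frames <- sort(unique(spots$frame))
  if (is.null(frame_range)) frame_range <- range(spots$frame)

  n <- nrow(spots)
  track_of <- integer(n)            # track id per spot row
  last_row <- integer(0)            # per active track: row index of its head
  last_frame <- integer(0)
  n_tracks <- 0L
  rows_by_frame <- split(seq_len(n), spots$frame)

  for (f in frames) {
    rows <- rows_by_frame[[as.character(f)]]
    active <- which(last_frame >= f - (max_gap + 1L) & last_frame < f)
    assigned_spot <- rep(FALSE, length(rows))
    assigned_track <- rep(FALSE, length(active))
    if (length(active) && length(rows)) {
      hx <- spots$x[last_row[active]]; hy <- spots$y[last_row[active]]
      gap1 <- f - last_frame[active]             # gap + 1
      radius <- max_disp * gap1
      dx <- outer(hx, spots$x[rows], "-")
      dy <- outer(hy, spots$y[rows], "-")
      d <- sqrt(dx^2 + dy^2)
      ok <- which(d <= radius, arr.ind = TRUE)
      if (nrow(ok)) {
        ord <- order(d[ok])
        for (k in ord) {
          ti <- ok[k, 1]; si <- ok[k, 2]
          if (assigned_track[ti] || assigned_spot[si]) next
          assigned_track[ti] <- TRUE
          assigned_spot[si] <- TRUE
          tr <- track_of[last_row[active[ti]]]
          track_of[rows[si]] <- tr
          last_row[active[ti]] <- rows[si]
          last_frame[active[ti]] <- f
        }
      }
    }
    if (any(!assigned_spot)) {
      new_rows <- rows[!assigned_spot]
      ids <- n_tracks + seq_along(new_rows)
      track_of[new_rows] <- ids
      n_tracks <- n_tracks + length(new_rows)
      last_row <- c(last_row, new_rows)
      last_frame <- c(last_frame, rep(f, length(new_rows)))
    }
  }

  out <- data.frame(track_id = track_of, frame = spots$frame,
                    x = spots$x, y = spots$y, intensity = spots$intensity)
  out <- out[order(out$track_id, out$frame), ]
  sizes <- table(out$track_id)
  keep_ids <- as.integer(names(sizes)[sizes >= min_points])
  n_unlinked <- sum(sizes[sizes < min_points])
  out <- out[out$track_id %in% keep_ids, , drop = FALSE]
  if (nrow(out)) {
    first <- tapply(out$frame, out$track_id, min)[as.character(out$track_id)]
    last <- tapply(out$frame, out$track_id, max)[as.character(out$track_id)]
    out$censored_start <- as.vector(first) <= frame_range[1]
    out$censored_end <- as.vector(last) >= frame_range[2]
    ## renumber tracks consecutively
    out$track_id <- as.integer(factor(out$track_id, levels = keep_ids))
  } else {
    out$censored_start <- logical(0); out$censored_end <- logical(0)
  }
  rownames(out) <- NULL
  attr(out, "n_unlinked") <- as.integer(n_unlinked)
  out
}

#' Membrane dwell times of trajectories
#'
#' The dwell time of a track is `(last_frame - first_frame + 1) *
#' frame_interval`, the full duration over which the particle was present.
#'
#' @param tracks track data.frame from [link_trajectories()] or a
#'   ground-truth track table (`track_id`, `frame`, plus censoring flags).
#' @param frame_interval s per frame.
#' @param exclude_censored drop tracks flagged censored at the movie start or
#'   end (their true dwell time is unknown)?
#' @return numeric vector of dwell times in seconds.
#' @export
dwell_times <- function(tracks, frame_interval, exclude_censored = TRUE) {
  check_scalar_pos(frame_interval, "frame_interval")
  if (is.null(tracks) || nrow(tracks) == 0L) return(numeric(0))
  first <- tapply(tracks$frame, tracks$track_id, min)
  last <- tapply(tracks$frame, tracks$track_id, max)
  dur <- (last - first + 1) * frame_interval
  if (exclude_censored &&
      all(c("censored_start", "censored_end") %in% names(tracks))) {
    cs <- tapply(tracks$censored_start, tracks$track_id, any)
    ce <- tapply(tracks$censored_end, tracks$track_id, any)
    dur <- dur[!(cs | ce)]
  }
  as.numeric(dur)
}

#' Build a kymograph along a line
#'
#' Intensity is sampled by bilinear interpolation at 1-px spacing along the
#' line and averaged over `width` perpendicular offsets (1 px apart, centered
#' on the line), for every frame; the result has one column per frame.
#'
#' @param movie an `nd_movie`.
#' @param line c(x0, y0, x1, y1) endpoints in px, inside the frame.
#' @param width number of perpendicular samples averaged (>= 1).
#' @return list of class `nd_kymograph` with `image`
#'   (distance-along-line x time), `line`, `px_per_sample`,
#'   `frame_interval`.
#' @export
make_kymograph <- function(movie, line, width = 1L) {
  if (!inherits(movie, "nd_movie")) stop_invalid("`movie` must be an nd_movie")
  if (width < 1) stop_invalid("`width` must be >= 1")
  line <- as.numeric(line)
  if (length(line) != 4L) stop_invalid("`line` must be c(x0, y0, x1, y1)")
  d <- dim(movie$stack)
  if (any(line[c(1, 3)] < 1) || any(line[c(1, 3)] > d[2]) ||
      any(line[c(2, 4)] < 1) || any(line[c(2, 4)] > d[1]))
    stop_invalid("`line` endpoints must lie inside the frame")
  len <- sqrt((line[3] - line[1])^2 + (line[4] - line[2])^2)
  n_samp <- max(2L, ceiling(len) + 1L)
  t <- seq(0, 1, length.out = n_samp)
  sx <- line[1] + t * (line[3] - line[1])
  sy <- line[2] + t * (line[4] - line[2])
  ux <- (line[3] - line[1]) / len; uy <- (line[4] - line[2]) / len
  offs <- seq_len(width) - (width + 1) / 2
  px <- as.vector(outer(sx, offs * -uy, "+"))
  py <- as.vector(outer(sy, offs * ux, "+"))
  px <- pmin(pmax(px, 1), d[2]); py <- pmin(pmax(py, 1), d[1])
  img <- matrix(0, n_samp, d[3])
  for (f in seq_len(d[3])) {
    v <- bilinear_sample(movie$stack[, , f], px, py)
    img[, f] <- rowMeans(matrix(v, n_samp, width))
  }
  structure(list(image = img, line = line,
                 px_per_sample = len / (n_samp - 1),
                 frame_interval = movie$frame_interval),
            class = "nd_kymograph")
}
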