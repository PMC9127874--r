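## Trajectory linking, dwell times and kymographs.

test_that("stationary well-separated emitters give one track each", {
  spots <- data.frame(frame = rep(1:20, each = 2),
                      x = rep(c(10, 20), 20), y = rep(c(10, 10), 20),
                      intensity = 1)
  tr <- link_trajectories(spots, max_disp = 3)
  expect_identical(length(unique(tr$track_id)), 2L)
  expect_true(all(table(tr$track_id) == 20))
  expect_identical(attr(tr, "n_unlinked"), 0L)
})

test_that("a one-frame blink is bridged when max_gap allows it", {
  spots <- data.frame(frame = c(1:5, 7:10), x = 10 + 0.05 * c(1:5, 7:10),
                      y = 10, intensity = 1)
  tr <- link_trajectories(spots, max_disp = 2, max_gap = 1)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 9L)
  tr0 <- link_trajectories(spots, max_disp = 2, max_gap = 0)
  expect_identical(length(unique(tr0$track_id)), 2L)
})

test_that("linking recovers >= 95% of true links on sparse Brownian fields", {
  img <- imaging_spec(n_frames = 60, shape = c(96, 96))
  pop <- population_spec(D = 0.035, mean_dwell = 2)
  gt <- simulate_movie(pop, img, density = 0.06, seed = 17,
                       render = FALSE)$ground_truth$tracks
  gt <- gt[gt$x_px >= 1 & gt$x_px <= 96 & gt$y_px >= 1 & gt$y_px <= 96, ]
  spots <- data.frame(frame = gt$frame, x = gt$x_px, y = gt$y_px,
                      intensity = gt$intensity)
  linked <- link_trajectories(spots, max_disp = 3.55, max_gap = 1,
                              frame_range = c(1, 40))
  ## count true consecutive-frame links that end up in the same linked track
  key <- paste(round(spots$x, 9), round(spots$y, 9), spots$frame)
  lk <- setNames(linked$track_id, paste(round(linked$x, 9),
                                        round(linked$y, 9), linked$frame))
  good <- 0; total <- 0
  for (id in unique(gt$track_id)) {
    t1 <- gt[gt$track_id == id, ]
    if (nrow(t1) < 2) next
    for (i in seq_len(nrow(t1) - 1)) {
      if (t1$frame[i + 1] - t1$frame[i] != 1) next
      total <- total + 1
      a <- lk[paste(round(t1$x_px[i], 9), round(t1$y_px[i], 9), t1$frame[i])]
      b <- lk[paste(round(t1$x_px[i + 1], 9), round(t1$y_px[i + 1], 9),
                    t1$frame[i + 1])]
      if (!is.na(a) && !is.na(b) && a == b) good <- good + 1
    }
  }
  expect_gt(total, 200)
  expect_gte(good / total, 0.95)
})

test_that("linking is invariant to spot order and conserves spots", {
  set.seed(23)
  spots <- data.frame(frame = rep(1:10, each = 5),
                      x = as.vector(replicate(10, runif(5, 0, 50))),
                      y = as.vector(replicate(10, runif(5, 0, 50))),
                      intensity = 1)
  tr1 <- link_trajectories(spots, max_disp = 4)
  shuf <- spots[sample(nrow(spots)), ]
  tr2 <- link_trajectories(shuf, max_disp = 4)
  k1 <- tr1[order(tr1$frame, tr1$x), c("frame", "x", "y", "track_id")]
  k2 <- tr2[order(tr2$frame, tr2$x), c("frame", "x", "y", "track_id")]
  expect_equal(k1$x, k2$x)
  ## same partition of spots into tracks (up to track relabeling)
  expect_identical(unname(split(paste(k1$frame, k1$x), k1$track_id)[
    order(vapply(split(paste(k1$frame, k1$x), k1$track_id), `[`, "", 1))]),
    unname(split(paste(k2$frame, k2$x), k2$track_id)[
      order(vapply(split(paste(k2$frame, k2$x), k2$track_id), `[`, "", 1))]))
  expect_identical(nrow(tr1) + attr(tr1, "n_unlinked"), nrow(spots))
})

test_that("greedy linking matches the exhaustive assignment oracle on
           well-separated fixtures", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    x1 <- runif(n, 0, 60); y1 <- runif(n, 0, 60)
    ## enforce >= 8 px separation so the optimal matching is unambiguous
    ok <- !any(dist(cbind(x1, y1)) < 8)
    if (!ok) next
    x2 <- x1 + runif(n, -1.5, 1.5); y2 <- y1 + runif(n, -1.5, 1.5)
    spots <- data.frame(frame = rep(1:2, each = n), x = c(x1, x2),
                        y = c(y1, y2), intensity = 1)
    tr <- link_trajectories(spots, max_disp = 3, min_points = 2)
    oracle <- assignment_oracle(x1, y1, x2, y2, max_disp = 3)
    expect_identical(length(unique(tr$track_id)), nrow(oracle))
    for (r in seq_len(nrow(oracle))) {
      id <- tr$track_id[tr$frame == 1 & tr$x == x1[oracle[r, 1]]]
      expect_equal(tr$x[tr$frame == 2 & tr$track_id == id],
                   x2[oracle[r, 2]])
    }
  }
})

test_that("dwell times use inclusive duration and respect censoring", {
  tr <- data.frame(track_id = c(1, 1, 2, 2), frame = c(1, 11, 5, 8),
                   x = 0, y = 0,
                   censored_start = c(TRUE, TRUE, FALSE, FALSE),
                   censored_end = FALSE)
  expect_equal(dwell_times(tr, 0.1, exclude_censored = FALSE),
               c(1.1, 0.4))
  expect_equal(dwell_times(tr, 0.1, exclude_censored = TRUE), 0.4)
  all_cen <- tr; all_cen$censored_start <- TRUE
  expect_length(dwell_times(all_cen, 0.1, exclude_censored = TRUE), 0)
})

test_that("kymographs trace stationary and moving emitters correctly", {
  img <- imaging_spec(n_frames = 20, shape = c(48, 48), background_mean = 10,
                      read_noise_sd = 0, shot_noise = FALSE)
  ## one stationary emitter on the line, one moving at 1 px/frame
  frames <- 1:20
  tracks <- data.frame(
    track_id = rep(1:2, each = 20), population_id = 1L,
    frame = rep(frames, 2),
    x_px = c(rep(10, 20), 5 + frames), y_px = 24,
    intensity = 500, censored_start = FALSE, censored_end = FALSE)
  movie <- nd_movie(nanodyn:::render_stack(tracks, img), 0.1, 0.1)
  ky <- make_kymograph(movie, line = c(2, 24, 47, 24), width = 3)
  expect_identical(ncol(ky$image), 20L)
  ## stationary ridge: constant position; moving ridge: slope 1 px/frame
  pos <- apply(ky$image, 2, which.max)   # global max is the brighter ridge?
  ## find the stationary emitter: intensity at its fixed sample index
  d_line <- seq(2, 47)                    # sample positions (1 px spacing)
  stat_idx <- which.min(abs(d_line - 10))
  expect_true(all(abs(ky$image[stat_idx, ] -
                        max(ky$image[stat_idx, ])) / max(ky$image) < 0.5))
  ## track the moving peak away from the crossing region
  mov_pos <- vapply(1:20, function(f) {
    prof <- ky$image[, f]
    prof[seq_len(stat_idx + 2)] <- 0     # mask the stationary ridge
    which.max(prof)
  }, integer(1))
  late <- 10:20
  fitl <- stats::lm(mov_pos[late] ~ late)
  expect_lt(abs(unname(stats::coef(fitl)[2]) - 1), 0.05)
  ## blank movie -> flat kymograph at background
  blank <- nd_movie(array(10, c(48, 48, 5)), 0.1, 0.1)
  kb <- make_kymograph(blank, c(2, 24, 47, 24))
  expect_true(all(abs(kb$image - 10) < 1e-9))
  expect_error(make_kymograph(movie, c(-3, 24, 47, 24)),
               class = "nd_invalid_parameter")
})
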