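## Generator: statistical structure of simulated tracks, rendering, noise,
## determinism.

test_that("spec constructors validate their inputs", {
  expect_error(population_spec(D = -1), class = "nd_invalid_parameter")
  expect_error(population_spec(D = 0.01, fraction = 0),
               class = "nd_invalid_parameter")
  expect_error(population_spec(D = 0.01, mean_dwell = -2),
               class = "nd_invalid_parameter")
  expect_error(imaging_spec(pixel_size = 0), class = "nd_invalid_parameter")
  expect_error(imaging_spec(n_frames = 1), class = "nd_invalid_parameter")
  expect_error(imaging_spec(psf_sigma = 40, shape = c(64, 64)),
               class = "nd_invalid_parameter")
  img <- imaging_spec()
  expect_error(simulate_movie(population_spec(0.01), img, density = -1),
               class = "nd_invalid_parameter")
  expect_error(simulate_movie(list(population_spec(0.01, fraction = 0.6)),
                              img, density = 1),
               class = "nd_invalid_parameter")
})

test_that("ground-truth step variance matches 2*D*dt per population", {
  img <- imaging_spec(n_frames = 60, shape = c(64, 64))
  pops <- list(population_spec(D = 0.035, fraction = 0.5,
                               mean_dwell = Inf),
               population_spec(D = 0.0018, fraction = 0.5,
                               mean_dwell = Inf))
  gt <- simulate_movie(pops, img, density = 4, seed = 11,
                       render = FALSE)$ground_truth
  for (p in 1:2) {
    tr <- gt$tracks[gt$tracks$population_id == p, ]
    steps <- unlist(lapply(split(tr, tr$track_id), function(t1) {
      c(diff(t1$x_um), diff(t1$y_um))
    }))
    expect_gt(length(steps), 1e4)
    D <- pops[[p]]$D
    expect_lt(abs(stats::var(steps) / (2 * D * 0.1) - 1), 0.05)
  }
})

test_that("uncensored track lifetimes average to the mean dwell", {
  img <- imaging_spec(n_frames = 400, shape = c(32, 32))
  pop <- population_spec(D = 0.005, mean_dwell = 1.11)
  gt <- simulate_movie(pop, img, density = 2, seed = 7,
                       render = FALSE)$ground_truth
  tr <- gt$tracks
  keep <- !(tr$censored_start | tr$censored_end)
  dw <- dwell_times(tr[keep, ], frame_interval = 0.1,
                    exclude_censored = FALSE)
  expect_gt(length(dw), 1000)
  ## dwell is discretised to frames: E[dwell] = tau + dt/2 + O(dt^2)
  expect_lt(abs(mean(dw) - 1.11) / 1.11, 0.10)
})

test_that("rendering conserves the photon budget without noise", {
  img <- imaging_spec(n_frames = 2, shape = c(41, 41), background_mean = 0,
                      read_noise_sd = 0, shot_noise = FALSE)
  tracks <- data.frame(track_id = 1L, population_id = 1L, frame = 1:2,
                       x_px = c(21.3, 20.7), y_px = c(20.8, 21.2),
                       intensity = 750,
                       censored_start = FALSE, censored_end = FALSE)
  stack <- nanodyn:::render_stack(tracks, img)
  for (f in 1:2)
    expect_lt(abs(sum(stack[, , f]) / 750 - 1), 1e-3)
})

test_that("zero diffusion freezes tracks and zero density gives background", {
  img <- imaging_spec(n_frames = 10, shape = c(48, 48))
  still <- simulate_movie(population_spec(D = 0), img, density = 0.4,
                          seed = 3)
  spread <- tapply(still$ground_truth$tracks$x_px,
                   still$ground_truth$tracks$track_id,
                   function(v) max(v) - min(v))
  expect_true(all(spread == 0))

  none <- simulate_movie(population_spec(D = 0.01), img, density = 0,
                         seed = 3)
  expect_identical(nrow(none$ground_truth$tracks), 0L)
  ## pure background: mean close to background_mean, no structure
  expect_lt(abs(mean(none$movie$stack) - img$background_mean), 1)
})

test_that("identical seed and parameters reproduce bit-identical output", {
  img <- imaging_spec(n_frames = 6, shape = c(48, 48))
  pop <- population_spec(D = 0.02, mean_dwell = 2)
  a <- simulate_movie(pop, img, density = 0.5, seed = 99)
  b <- simulate_movie(pop, img, density = 0.5, seed = 99)
  expect_identical(a$movie$stack, b$movie$stack)
  expect_identical(a$ground_truth$tracks, b$ground_truth$tracks)
})

test_that("FRAP simulator bleaches the ROI and validates geometry", {
  img <- imaging_spec(n_frames = 30, shape = c(48, 48), frame_interval = 0.25,
                      background_mean = 50)
  expect_error(simulate_frap(img, density = 4, D = 0.1,
                             bleach_roi = c(40, 40, 20, 20),
                             bleach_frame = 5),
               class = "nd_invalid_parameter")
  expect_error(simulate_frap(img, density = 4, D = 0.1,
                             bleach_roi = c(10, 10, 16, 16),
                             bleach_frame = 5, bleach_depth = 1.2),
               class = "nd_invalid_parameter")
  ## fully immobile + full bleach: ROI stays at post-bleach level
  sim <- simulate_frap(img, density = 6, D = 0.3,
                       bleach_roi = c(17, 17, 16, 16), bleach_frame = 6,
                       bleach_depth = 1, immobile_fraction = 1,
                       mean_intensity = 400, seed = 21)
  tr <- frap_traces(sim$movie, c(17, 17, 16, 16), background = 50)
  post <- tr$roi[10:30] - 50
  pre <- mean(tr$roi[1:5]) - 50
  expect_lt(mean(post) / pre, 0.3)          # no recovery beyond PSF spillover
  expect_lt(stats::sd(post) / pre, 0.1)     # and flat over time
})

test_that("FCS trace generator obeys its contracts", {
  expect_error(simulate_fcs_trace(10, 0.01, duration = 0.05,
                                  sampling_dt = 0.001, brightness = 3),
               class = "nd_invalid_parameter")
  tr <- simulate_fcs_trace(10, 0.01, duration = 20, sampling_dt = 0.001,
                           brightness = 3, seed = 4)
  expect_identical(length(tr$samples), 20000L)
  ## trace mean ~ N_mean * brightness (area-averaged brightness convention)
  expect_lt(abs(mean(tr$samples) / (10 * 3) - 1), 0.25)
  ## frozen particles without shot noise give a constant trace
  frozen <- simulate_fcs_trace(10, Inf, duration = 1, sampling_dt = 0.001,
                               brightness = 3, seed = 4, shot_noise = FALSE)
  expect_lt(stats::sd(frozen$samples), 1e-9)
})

test_that("two-channel generator controls the colocalized fraction", {
  img <- imaging_spec(n_frames = 4, shape = c(64, 64))
  pop <- population_spec(D = 0.01, mean_intensity = snr_intensity(10))
  sim <- simulate_two_channel(pop, pop, coloc_fraction = 1, imaging = img,
                              density_a = 0.1, density_b = 0.1, seed = 13)
  gt <- sim$ground_truth$tracks
  b <- gt[gt$channel == "B", ]
  expect_true(all(!is.na(b$coloc_partner)))
  ## every B emitter sits within 1 px of its A partner at every frame
  a <- gt[gt$channel == "A", ]
  for (id in unique(b$track_id)) {
    bb <- b[b$track_id == id, ]
    aa <- a[a$track_id == bb$coloc_partner[1], ]
    mm <- merge(bb, aa, by = "frame")
    expect_true(all(sqrt((mm$x_px.x - mm$x_px.y)^2 +
                           (mm$y_px.x - mm$y_px.y)^2) <= 1 + 1e-9))
  }
  expect_error(simulate_two_channel(pop, pop, coloc_fraction = 1.4,
                                    imaging = img, density_a = 1,
                                    density_b = 1),
               class = "nd_invalid_parameter")
})
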