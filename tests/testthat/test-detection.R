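## Spot detection, quantification, density and Voronoi segmentation.

test_that("well-separated bright emitters are found with subpixel accuracy", {
  set.seed(42)
  img <- imaging_spec(n_frames = 2, shape = c(128, 128), background_mean = 100,
                      read_noise_sd = 2)
  ## 20 emitters on a jittered grid, >= 10 px apart, SNR 10
  gx <- rep(seq(15, 115, by = 25), 5)[1:20] + runif(20, -2, 2)
  gy <- rep(seq(15, 115, by = 25), each = 5)[1:20] + runif(20, -2, 2)
  tracks <- data.frame(track_id = rep(1:20, each = 2), population_id = 1L,
                       frame = rep(1:2, 20),
                       x_px = rep(gx, each = 2), y_px = rep(gy, each = 2),
                       intensity = snr_intensity(10),
                       censored_start = FALSE, censored_end = FALSE)
  stack <- nanodyn:::render_stack(tracks, img)
  sp <- detect_spots(stack[, , 1], expected_sigma = 1.3, snr_min = 5)
  m <- match_truth(gx, gy, sp$x, sp$y)
  expect_gte(length(m$truth), 19)
  err <- c(gx[m$truth] - sp$x[m$det], gy[m$truth] - sp$y[m$det])
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("a noiseless centered emitter is localized to 1e-3 px", {
  img <- imaging_spec(n_frames = 2, shape = c(31, 31), background_mean = 10,
                      read_noise_sd = 0, shot_noise = FALSE)
  tracks <- data.frame(track_id = 1L, population_id = 1L, frame = 1:2,
                       x_px = 16, y_px = 16, intensity = 800,
                       censored_start = FALSE, censored_end = FALSE)
  stack <- nanodyn:::render_stack(tracks, img)
  sp <- detect_spots(stack[, , 1], expected_sigma = 1.3, snr_min = 5)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$x - 16), 1e-3)
  expect_lt(abs(sp$y - 16), 1e-3)
})

test_that("flat and pure-noise frames yield (almost) no spots", {
  expect_identical(nrow(detect_spots(matrix(5, 64, 64))), 0L)
  set.seed(31)
  fp <- vapply(1:3, function(i) {
    fr <- matrix(pmax(rnorm(512 * 512, 100, 10), 0), 512, 512)
    nrow(detect_spots(fr, expected_sigma = 1.3, snr_min = 5))
  }, integer(1))
  expect_lte(mean(fp), 1)
})

test_that("spot statistics follow the FWHM-square size convention", {
  sp <- data.frame(x = 1:2, y = 1:2, intensity = c(100, 300),
                   sigma = c(1.3, 1.3), background = 0, snr = 10)
  st <- spot_statistics(sp)
  expect_equal(st$mean_intensity, 200)
  expect_equal(st$sd_intensity, sd(c(100, 300)))
  expect_equal(st$mean_size_px, 2 * sqrt(2 * log(2)) * 1.3)
  ## identical spots: zero spread
  st1 <- spot_statistics(sp[c(1, 1), ])
  expect_equal(st1$sd_intensity, 0)
  ## empty sentinel
  st0 <- spot_statistics(sp[0, ])
  expect_identical(st0$n, 0L)
  expect_true(is.na(st0$mean_intensity))
})

test_that("fitted sigma recovers the rendered PSF width within 5%", {
  set.seed(8)
  img <- imaging_spec(n_frames = 2, shape = c(128, 128),
                      background_mean = 100, read_noise_sd = 2,
                      psf_sigma = 1.3)
  gx <- rep(seq(15, 115, by = 25), 5)[1:20] + runif(20, -2, 2)
  gy <- rep(seq(15, 115, by = 25), each = 5)[1:20] + runif(20, -2, 2)
  tracks <- data.frame(track_id = rep(1:20, each = 2), population_id = 1L,
                       frame = rep(1:2, 20),
                       x_px = rep(gx, each = 2), y_px = rep(gy, each = 2),
                       intensity = snr_intensity(12),
                       censored_start = FALSE, censored_end = FALSE)
  stack <- nanodyn:::render_stack(tracks, img)
  sp <- rbind(detect_spots(stack[, , 1]), detect_spots(stack[, , 2]))
  expect_gt(nrow(sp), 30)
  expect_lt(abs(mean(sp$sigma) / 1.3 - 1), 0.05)
})

test_that("density arithmetic, empty case and invariances hold", {
  sp <- data.frame(frame = rep(1, 15), x = runif(15, 0, 10),
                   y = runif(15, 0, 10))
  dn <- compute_density(sp, area = 100)
  expect_equal(dn$density, 0.15)
  expect_equal(compute_density(sp[0, ], area = 100)$density, 0)
  expect_error(compute_density(sp, area = 0), class = "nd_invalid_parameter")
  ## order and translation invariance
  dn2 <- compute_density(sp[sample(15), ], area = 100)
  expect_equal(dn2$density, dn$density)
  sp3 <- sp; sp3$x <- sp3$x + 7; sp3$y <- sp3$y - 2
  expect_equal(compute_density(sp3, area = 100)$density, dn$density)
})

test_that("detected spot density recovers the generator density", {
  sim <- snr_movie(10, seed = 5, density = 0.15, n_frames = 6)
  sp <- detect_movie(sim$movie)
  ## interior region, to avoid border losses: 88 x 88 px = 77.44 um^2
  inner <- sp[sp$x >= 5 & sp$x <= 92 & sp$y >= 5 & sp$y <= 92, ]
  dn <- compute_density(inner, area = (88 * 0.1)^2, n_frames = 6)
  ## measured density matches the realized ground-truth density within 10%
  gt <- sim$ground_truth$tracks
  realized <- sum(gt$x_px >= 5 & gt$x_px <= 92 &
                    gt$y_px >= 5 & gt$y_px <= 92) / 6 / (88 * 0.1)^2
  expect_lt(abs(dn$density / realized - 1), 0.10)
  ## and the generator itself is calibrated: with particle turnover the
  ## long-run mean density matches the request
  img <- imaging_spec(n_frames = 150, shape = c(96, 96))
  gt2 <- simulate_movie(population_spec(0.01, mean_dwell = 1),
                        img, density = 0.15, seed = 8,
                        render = FALSE)$ground_truth$tracks
  per <- tapply(gt2$frame, gt2$frame, length) /
    ((96 + 20)^2 * 0.01)            # extended-domain area in um^2
  expect_lt(abs(mean(per) / 0.15 - 1), 0.10)
})

test_that("Voronoi segmentation separates dense blobs from sparse fields", {
  set.seed(1)
  blob1 <- cbind(x = rnorm(25, 20, 1), y = rnorm(25, 20, 1))
  blob2 <- cbind(x = rnorm(25, 80, 1), y = rnorm(25, 80, 1))
  field <- cbind(x = runif(40, 0, 100), y = runif(40, 0, 100))
  ## keep field spots away from the blobs
  keep <- sqrt((field[, 1] - 20)^2 + (field[, 2] - 20)^2) > 15 &
    sqrt((field[, 1] - 80)^2 + (field[, 2] - 80)^2) > 15
  spots <- as.data.frame(rbind(blob1, blob2, field[keep, ]))
  vs <- voronoi_segment(spots, density_threshold = 0.5,
                        min_cluster_size = 5,
                        region = c(0, 100, 0, 100))
  labs <- vs$labels
  expect_identical(length(setdiff(unique(labs), 0L)), 2L)
  ## blob cores form the two clusters (rim cells open into the empty
  ## exclusion zone and legitimately fall below threshold)
  expect_gte(sum(labs[1:25] > 0), 12)
  expect_gte(sum(labs[26:50] > 0), 12)
  expect_identical(sort(unique(labs[1:25][labs[1:25] > 0])),
                   unique(labs[1:25][labs[1:25] > 0]))
  expect_false(any(labs[1:25][labs[1:25] > 0] %in% labs[26:50][labs[26:50] > 0]))
  expect_true(all(labs[-(1:50)][vs$local_density[-(1:50)] < 0.5] == 0))
})

test_that("Voronoi handles uniform, infinite-threshold and degenerate input", {
  set.seed(2)
  gr <- expand.grid(x = seq(5, 55, by = 5), y = seq(5, 55, by = 5))
  gr$x <- gr$x + runif(nrow(gr), -0.5, 0.5)
  gr$y <- gr$y + runif(nrow(gr), -0.5, 0.5)
  vs <- voronoi_segment(gr, density_threshold = 0.01, min_cluster_size = 3,
                        region = c(0, 60, 0, 60))
  interior <- !vs$boundary
  expect_true(all(vs$labels[interior] == 1))      # one all-inclusive cluster
  expect_true(all(voronoi_segment(gr, Inf, region = c(0, 60, 0, 60))$labels
                  == 0))
  expect_error(voronoi_segment(gr[1:3, ], 1), class = "nd_degenerate_input")
  col <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  expect_error(voronoi_segment(col, 1), class = "nd_degenerate_input")
})

test_that("Voronoi areas are bounded by the region and scale correctly", {
  set.seed(3)
  spots <- data.frame(x = runif(60, 0, 50), y = runif(60, 0, 50))
  vs <- voronoi_segment(spots, 0.1, region = c(0, 50, 0, 50))
  expect_lte(sum(vs$cell_area), 50 * 50 + 1e-6)
  ## scaling coordinates by c scales local densities by 1/c^2
  sc <- voronoi_segment(transform(spots, x = 3 * x, y = 3 * y), 0.1,
                        region = c(0, 150, 0, 150))
  expect_equal(sc$local_density, vs$local_density / 9, tolerance = 1e-6)
})
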