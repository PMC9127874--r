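## Shared fixtures and independent oracles used across the test files.

## integrated intensity giving a target peak-amplitude SNR at a given
## background (noise = sqrt(background + read^2), PSF sigma in px)
snr_intensity <- function(snr, background = 100, read_sd = 2, sigma = 1.3) {
  snr * sqrt(background + read_sd^2) * 2 * pi * sigma^2
}

## brute-force time-averaged MSD: literal double loop over ordered pairs
msd_bruteforce <- function(track, pixel_size = 1, frame_interval = 1,
                           max_lag_fraction = 1) {
  if (all(c("x_um", "y_um") %in% names(track))) {
    x <- track$x_um; y <- track$y_um
  } else {
    x <- track$x * pixel_size; y <- track$y * pixel_size
  }
  f <- track$frame
  ord <- order(f); f <- f[ord]; x <- x[ord]; y <- y[ord]
  n <- length(f)
  max_lag <- max(1, floor(max_lag_fraction * (f[n] - f[1])))
  acc <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    lag <- f[j] - f[i]
    if (lag > max_lag) next
    key <- as.character(lag)
    acc[[key]] <- c(acc[[key]], (x[j] - x[i])^2 + (y[j] - y[i])^2)
  }
  lags <- sort(as.integer(names(acc)))
  data.frame(lag_s = lags * frame_interval,
             msd = vapply(as.character(lags), function(k) mean(acc[[k]]),
                          numeric(1)),
             n_pairs = vapply(as.character(lags), function(k)
               length(acc[[k]]), integer(1)),
             row.names = NULL)
}

## exhaustive minimum-total-distance assignment between two frames of spots,
## pairs beyond max_disp forbidden; returns matrix (i, j) of matched indices
assignment_oracle <- function(xa, ya, xb, yb, max_disp) {
  na <- length(xa); nb <- length(xb)
  d <- sqrt(outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2)
  best <- NULL; best_cost <- Inf; best_n <- -1L
  subsets_b <- function(k) if (k == 0) list(integer(0)) else
    utils::combn(seq_len(nb), k, simplify = FALSE)
  for (k in seq(min(na, nb), 0)) {
    for (ia in (if (k == 0) list(integer(0)) else
                utils::combn(seq_len(na), k, simplify = FALSE))) {
      for (ib in subsets_b(k)) {
        if (k == 0) { perms <- list(integer(0)) } else {
          perms <- perm_all(k)
        }
        for (p in perms) {
          dd <- d[cbind(ia, ib[p])]
          if (any(dd > max_disp)) next
          cost <- sum(dd)
          if (k > best_n || (k == best_n && cost < best_cost)) {
            best <- cbind(ia, ib[p]); best_cost <- cost; best_n <- k
          }
        }
      }
    }
    if (best_n == k && !is.null(best)) break   # maximum cardinality found
  }
  best
}

perm_all <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perm_all(k - 1L)) for (pos in 0:(k - 1L)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos)
  }
  out
}

## mutual-nearest-neighbor matching of detections to ground truth in one
## frame; returns indices of matched truth rows and their matched detection
match_truth <- function(gx, gy, sx, sy, radius = 2) {
  if (!length(gx) || !length(sx))
    return(list(truth = integer(0), det = integer(0)))
  d <- sqrt(outer(gx, sx, "-")^2 + outer(gy, sy, "-")^2)
  nnb <- apply(d, 1, which.min); nna <- apply(d, 2, which.min)
  mut <- which(nna[nnb] == seq_along(gx))
  ok <- mut[d[cbind(mut, nnb[mut])] <= radius]
  list(truth = ok, det = nnb[ok])
}

## detection precision/recall bookkeeping over a movie within an interior
## region (border px excluded on every side)
detection_metrics <- function(sim, spots, border = 4, iso_radius = 6) {
  dims <- dim(sim$movie$stack)
  lo <- 1 + border; hix <- dims[2] - border; hiy <- dims[1] - border
  gt <- sim$ground_truth$tracks
  tp <- 0; fp <- 0; fn <- 0; errs <- c()
  for (f in seq_len(dims[3])) {
    ## match on the full field; restrict the bookkeeping to the interior so
    ## that an emitter just outside the region detected just inside it is
    ## neither a false positive nor a false negative
    ga <- gt[gt$frame == f, ]
    s_all <- spots[spots$frame == f, ]
    in_g <- ga$x_px >= lo & ga$x_px <= hix & ga$y_px >= lo & ga$y_px <= hiy
    in_s <- s_all$x >= lo & s_all$x <= hix & s_all$y >= lo & s_all$y <= hiy
    if (!nrow(ga)) { fp <- fp + sum(in_s); next }
    if (!nrow(s_all)) { fn <- fn + sum(in_g); next }
    dall <- sqrt(outer(ga$x_px, ga$x_px, "-")^2 +
                   outer(ga$y_px, ga$y_px, "-")^2)
    diag(dall) <- Inf
    nn2 <- if (nrow(ga) > 1) apply(dall, 1, min) else Inf
    ## emitters with a true neighbor inside the 2 px match radius are one
    ## diffraction-limited spot: not individually detectable targets
    resolv <- in_g & nn2 >= 2
    m <- match_truth(ga$x_px, ga$y_px, s_all$x, s_all$y)
    tp <- tp + sum(resolv[m$truth])
    fn <- fn + sum(resolv) - sum(resolv[m$truth])
    fp <- fp + sum(in_s) - sum(in_s[m$det])
    ## localization errors only for isolated emitters (single-emitter
    ## precision; neighbors within iso_radius px contaminate the fit window)
    if (length(m$truth)) {
      keep <- which(in_g[m$truth] & nn2[m$truth] > iso_radius)
      errs <- c(errs, ga$x_px[m$truth[keep]] - s_all$x[m$det[keep]],
                ga$y_px[m$truth[keep]] - s_all$y[m$det[keep]])
    }
  }
  list(tp = tp, fp = fp, fn = fn,
       f1 = 2 * tp / (2 * tp + fp + fn),
       rmse_axis = if (length(errs)) sqrt(mean(errs^2)) else NA_real_,
       n_err = length(errs))
}

## default SNR-controlled test movie
snr_movie <- function(snr, seed, density = 0.15, n_frames = 10,
                      shape = c(96, 96), D = 0.035) {
  img <- imaging_spec(n_frames = n_frames, shape = shape,
                      background_mean = 100, read_noise_sd = 2)
  pop <- population_spec(D = D, mean_intensity = snr_intensity(snr),
                         intensity_cv = 0.05)
  simulate_movie(pop, img, density = density, seed = seed)
}

## brute-force multiple-tau reference: direct correlation of block-binned
## traces on the same lag grid
multitau_bruteforce <- function(x, n_cascades, m) {
  out <- c()
  for (cs in seq_len(n_cascades)) {
    f <- 2^(cs - 1)
    b <- x
    if (f > 1) {
      ## successive pairwise halving, as a literal loop
      for (it in seq_len(cs - 1)) {
        n2 <- floor(length(b) / 2) * 2
        b <- (b[seq(1, n2, 2)] + b[seq(2, n2, 2)]) / 2
      }
    }
    lb <- if (cs == 1) seq_len(m) else (m %/% 2 + 1):m
    mu <- mean(b); d <- b - mu; n <- length(b)
    out <- c(out, vapply(lb, function(k)
      mean(d[1:(n - k)] * d[(k + 1):n]) / mu^2, numeric(1)))
  }
  out
}
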