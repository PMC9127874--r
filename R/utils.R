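#' @keywords internal
"_PACKAGE"

## Condition constructors -----------------------------------------------------
## All package errors carry a subclass so callers (and tests) can distinguish
## invalid parameters from data-driven failures.

nd_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nd_error")))
}

stop_invalid <- function(msg) nd_stop(msg, "nd_invalid_parameter")
stop_insufficient <- function(msg) nd_stop(msg, "nd_insufficient_data")
stop_degenerate <- function(msg) nd_stop(msg, "nd_degenerate_input")
stop_fit_failure <- function(msg) nd_stop(msg, "nd_fit_failure")
stop_too_short <- function(msg) nd_stop(msg, "nd_too_short")
stop_division_guard <- function(msg) nd_stop(msg, "nd_division_guard")

check_scalar_pos <- function(x, name, allow_inf = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (x > 0) && (allow_inf || is.finite(x))
  if (!ok) stop_invalid(sprintf("`%s` must be a single positive number", name))
  invisible(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_invalid(sprintf("`%s` must lie in [0, 1]", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Bilinear interpolation -----------------------------------------------------

#' Sample an image at continuous pixel coordinates
#'
#' Bilinear interpolation with the pixel-center convention: pixel `(i, j)`
#' (row i, column j, 1-based) has its center at coordinate `(x = j, y = i)`.
#' Coordinates must lie within `[1, ncol]` x `[1, nrow]`.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param x,y numeric vectors of equal length, continuous pixel coordinates.
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(x < 1 | x > nc | y < 1 | y > nr))
    stop_invalid("sample coordinates fall outside the image")
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

## Separable Gaussian blur ----------------------------------------------------
## Implemented as banded-matrix products with edge renormalisation (kernel mass
## lost at the border is redistributed, so flat images stay flat).

blur_matrix <- function(n, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (d in -radius:radius) {
    idx <- seq_len(n)
    j <- idx + d
    keep <- j >= 1 & j <= n
    B[cbind(idx[keep], j[keep])] <- k[d + radius + 1]
  }
  B / rowSums(B)
}

#' Gaussian blur of a matrix (separable, edge-renormalised)
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  Br <- blur_matrix(nrow(img), sigma)
  Bc <- blur_matrix(ncol(img), sigma)
  Br %*% img %*% t(Bc)
}
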