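# Internal numerics: zero-padded 2-D convolution via cached-FFT plans, and
# small array helpers shared by the filter and network stages.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Saturating linear activity function
#'
#' Piecewise-linear saturation used throughout the network: the identity on
#' \[0, 1), clamped to 0 below and to 1 at or above 1. Every population
#' activity in the model is constrained to \[0, 1\] through this function.
#'
#' @param x Numeric vector, matrix, or array of finite values.
#' @return Object of the same shape with values in \[0, 1\].
#' @examples
#' saturate(c(-0.5, 0.3, 2))
#' @export
saturate <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite activity value passed to saturate()", call. = FALSE)
  clamp01(x)
}

# Smallest padded size >= n that keeps the FFT fast (factors 2 and 3).
conv_pad_size <- function(n) stats::nextn(n, c(2L, 3L))

#' @noRd
# A convolution plan caches the padded-size FFT of one kernel so a field can
# be convolved repeatedly (once per Euler step) at the cost of two FFTs.
# Zero padding outside the field implements "nothing beyond the lattice".
conv_plan <- function(kernel, ny, nx) {
  stopifnot(is.matrix(kernel))
  ky <- nrow(kernel); kx <- ncol(kernel)
  if (ky %% 2L == 0L || kx %% 2L == 0L) stop("kernel must have odd dimensions", call. = FALSE)
  py <- conv_pad_size(ny + ky - 1L)
  px <- conv_pad_size(nx + kx - 1L)
  kp <- matrix(0, py, px)
  kp[seq_len(ky), seq_len(kx)] <- kernel
  list(
    Kf = stats::fft(kp),
    py = py, px = px, ny = ny, nx = nx,
    oy = (ky - 1L) %/% 2L, ox = (kx - 1L) %/% 2L,
    mass = sum(kernel)
  )
}

#' @noRd
conv_apply <- function(plan, x) {
  xp <- matrix(0, plan$py, plan$px)
  xp[seq_len(plan$ny), seq_len(plan$nx)] <- x
  full <- Re(stats::fft(stats::fft(xp) * plan$Kf, inverse = TRUE)) / (plan$py * plan$px)
  full[plan$oy + seq_len(plan$ny), plan$ox + seq_len(plan$nx)]
}

# Separable running maximum over a (2r+1)^2 neighbourhood, zero beyond the
# border; used for the end-stopped inhibition gate.
neighborhood_max <- function(x, r) {
  shift_pad <- function(m, dy, dx) {
    ny <- nrow(m); nx <- ncol(m)
    out <- matrix(0, ny, nx)
    ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
    oky <- ys >= 1L & ys <= ny; okx <- xs >= 1L & xs <= nx
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  rowmax <- x
  for (d in seq_len(r)) rowmax <- pmax(rowmax, shift_pad(x, d, 0L), shift_pad(x, -d, 0L))
  out <- rowmax
  for (d in seq_len(r)) out <- pmax(out, shift_pad(rowmax, 0L, d), shift_pad(rowmax, 0L, -d))
  out
}

# Isotropic Gaussian weights on an odd (2r+1)^2 grid, optionally with the
# centre removed, normalized to unit mass.
gaussian_patch <- function(r, sigma, exclude_center = FALSE, normalize = TRUE) {
  g <- seq(-r, r)
  d2 <- outer(g^2, g^2, "+")
  k <- exp(-d2 / (2 * sigma^2))
  if (exclude_center) k[r + 1L, r + 1L] <- 0
  if (normalize) k <- k / sum(k)
  k
}

# Annulus (ring) Gaussian-weighted kernel between radii (r_in, r_out],
# unit mass; used for long-range and surround interactions.
annulus_patch <- function(r_in, r_out, sigma = NULL, normalize = TRUE) {
  r <- ceiling(r_out)
  g <- seq(-r, r)
  d <- sqrt(outer(g^2, g^2, "+"))
  if (is.null(sigma)) sigma <- max(r_out / 2, 1)
  k <- exp(-d^2 / (2 * sigma^2))
  k[d <= r_in | d > r_out] <- 0
  if (all(k == 0)) stop("empty annulus kernel: r_in >= r_out on this lattice", call. = FALSE)
  if (normalize) k <- k / sum(k)
  k
}
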