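#' Oriented difference-of-Gaussians kernel
#'
#' The receptive field of the extra-classical-RF (ECRF) cells: a Mexican-hat
#' profile
#' \deqn{R(x_o, y_o) = A_C e^{-(x_o^2/\sigma_{xc}^2 + y_o^2/\sigma_{yc}^2)}
#'   - A_S e^{-(x_o^2/\sigma_{xs}^2 + y_o^2/\sigma_{ys}^2)}}
#' on coordinates rotated so `y_o` runs along the preferred orientation.
#' Standard deviations are in degrees and converted to lattice steps via
#' `config$px_per_deg`. At the origin both exponentials are 1, so the centre
#' value is `A_C - A_S`.
#'
#' @param config An [model_config()].
#' @param orientation Preferred orientation in degrees.
#' @param radius Kernel support radius in lattice steps (must hold at least
#'   4 surround standard deviations).
#' @return Matrix kernel of odd size.
#' @export
dog_kernel <- function(config = model_config(), orientation = 0,
                       radius = ceiling(4 * config$sigma_ys * config$px_per_deg)) {
  p <- config$px_per_deg
  sxc <- config$sigma_xc * p; syc <- config$sigma_yc * p
  sxs <- config$sigma_xs * p; sys <- config$sigma_ys * p
  if (min(sxc, syc, sxs, sys) <= 0) stop("DoG standard deviations must be > 0", call. = FALSE)
  if (radius < 4 * max(sxs, sys)) {
    stop("kernel support too small: needs >= 4 surround standard deviations", call. = FALSE)
  }
  g <- seq(-radius, radius)
  xs <- matrix(rep(g, each = length(g)), length(g), length(g))
  ys <- matrix(rep(g, length(g)), length(g), length(g))
  a <- orientation * pi / 180
  yo <- xs * cos(a) + ys * sin(a)   # along the bar axis
  xo <- -xs * sin(a) + ys * cos(a)  # across the bar
  config$A_C * exp(-(xo^2 / sxc^2 + yo^2 / syc^2)) -
    config$A_S * exp(-(xo^2 / sxs^2 + yo^2 / sys^2))
}

#' ECRF (centre-surround form) responses to one frame
#'
#' The oriented DoG kernels are convolved with the reversed intensity
#' `I = background - luminance` (dark bars on a white background become
#' positive drive) and passed through the saturating nonlinearity. The
#' suppressive surround makes these cells weakest where dark structure
#' covers a large area — notably at the crossing of two bars (the extrinsic
#' terminator) — and strongest along isolated edges and at intrinsic
#' terminators. The computation is memoryless (one frame at a time).
#'
#' @param frame Luminance matrix in \[0, 1\] `(y, x)`.
#' @param config An [model_config()].
#' @param background Background luminance (default 1, white).
#' @return An `orientation_field`: array `(y, x, orientation)` in \[0, 1\]
#'   with attribute `orientations` (degrees).
#' @export
ecrf_response <- function(frame, config = model_config(), background = 1) {
  I <- clamp01(background - frame)
  orients <- orientation_angles(config$N_dir)
  ny <- nrow(frame); nx <- ncol(frame)
  out <- array(0, dim = c(ny, nx, length(orients)))
  for (oi in seq_along(orients)) {
    k <- dog_kernel(config, orients[oi])
    out[, , oi] <- saturate(conv_apply(conv_plan(k, ny, nx), I))
  }
  structure(out, orientations = orients, class = c("orientation_field", "array"))
}

#' Gate complex motion signals by ECRF form signals
#'
#' Complex activity passes to MT only where the ECRF cell of the orientation
#' orthogonal to the motion direction is active: `kappa = v_cx` where
#' `v_cs(orth(theta)) > eps`, 0 elsewhere. The strict-positivity gate uses a
#' small `eps` to be robust to floating-point noise. Because ECRF activity
#' is suppressed at the extrinsic terminator, `kappa` silences the motion
#' signal there while leaving edge signals intact.
#'
#' @param v_cx Complex activity `(y, x, n_dir)` at one time point.
#' @param v_cs [ecrf_response()] output on the matching frame.
#' @param config An [model_config()].
#' @param eps Gate tolerance.
#' @return Array like `v_cx` with the gated activity kappa.
#' @export
gate_motion <- function(v_cx, v_cs, config = model_config(), eps = 1e-6) {
  nd <- dim(v_cx)[3]
  if (dim(v_cs)[3] != nd %/% 2L) {
    stop("orientation field must hold one slice per orientation (N_dir/2)", call. = FALSE)
  }
  out <- array(0, dim = dim(v_cx))
  for (d in seq_len(nd)) {
    oi <- orthogonal_orientation(d, nd)
    out[, , d] <- v_cx[, , d] * (v_cs[, , oi] > eps)
  }
  out
}
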