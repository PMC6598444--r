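#' Multi-stage low-pass temporal filter kernel
#'
#' The temporal impulse response of the motion-energy filters:
#' \deqn{g_n(t) = (t/\tau_g)^n e^{-t/\tau_g}
#'   \left[\frac{1}{n!} - \frac{(t/\tau_g)^2}{(n+2)!}\right],}
#' a biphasic kernel that is zero at \eqn{t = 0}, changes sign at
#' \eqn{t = \tau_g\sqrt{(n+2)!/n!} = \tau_g\sqrt{(n+1)(n+2)}}, and decays to
#' zero. Two stage counts (n = 6 fast, n = 9 slow) provide the temporal
#' quadrature pair of the energy model.
#'
#' @param n Number of filter stages (integer >= 1).
#' @param tau_g Time constant (> 0).
#' @param t_grid Non-negative, ascending time points.
#' @return `g_n` evaluated on `t_grid`.
#' @examples
#' temporal_kernel(6, 0.01, seq(0, 0.3, by = 0.01))
#' @export
temporal_kernel <- function(n, tau_g, t_grid) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (tau_g <= 0) stop("tau_g must be > 0", call. = FALSE)
  if (any(t_grid < 0)) stop("temporal kernel is causal: t_grid must be non-negative", call. = FALSE)
  if (is.unsorted(t_grid)) stop("t_grid must be ascending", call. = FALSE)
  s <- t_grid / tau_g
  s^n * exp(-s) * (1 / factorial(n) - s^2 / factorial(n + 2))
}

# zero-crossing time of the bracket term, closed form
temporal_kernel_zero <- function(n, tau_g) tau_g * sqrt(factorial(n + 2) / factorial(n))

# Quadrature Gabor pair for motion direction `dir_deg` (carrier varies along
# the direction of motion; orientation has period 180 so opposite directions
# share spatial kernels).
gabor_pair <- function(dir_deg, f_cpp, sigma_x_px, sigma_y_px, radius) {
  g <- seq(-radius, radius)
  xs <- matrix(rep(g, each = length(g)), length(g), length(g)) # columns = x
  ys <- matrix(rep(g, length(g)), length(g), length(g))        # rows = y
  a <- dir_deg * pi / 180
  xr <- xs * cos(a) + ys * sin(a)   # along motion
  yr <- -xs * sin(a) + ys * cos(a)  # along the edge
  env <- exp(-(xr^2 / (2 * sigma_x_px^2) + yr^2 / (2 * sigma_y_px^2)))
  ph <- 2 * pi * f_cpp * xr
  even <- env * cos(ph)
  odd <- env * sin(ph)
  # zero-mean even kernel so uniform luminance gives no response
  even <- even - env * sum(even) / sum(env)
  list(even = even, odd = odd)
}

#' Build the spatiotemporal filter bank
#'
#' One quadrature Gabor pair per orientation (shared by opposite directions)
#' plus the fast (n = 6) and slow (n = 9) temporal kernels sampled at the
#' movie frame interval. Spatial scale is set by `px_per_deg`: Gabor
#' frequency `f` (cycles/degree) and envelope standard deviations (degrees)
#' are converted to lattice steps.
#'
#' @param config An [model_config()].
#' @param dt_frame Frame interval the temporal kernels are sampled at.
#' @param t_support Temporal kernel support in time units (default spans the
#'   biphasic lobes of both kernels).
#' @return A `filter_bank` list: `gabors` (per orientation), `g_fast`,
#'   `g_slow`, sampling metadata.
#' @export
build_bank <- function(config = model_config(), dt_frame = config$dt,
                       t_support = 25 * config$tau_g) {
  f_cpp <- config$f / config$px_per_deg
  sx <- config$sigma_x * config$px_per_deg
  sy <- config$sigma_y * config$px_per_deg
  radius <- max(3L, ceiling(3 * max(sx, sy)))
  orients <- orientation_angles(config$N_dir)
  # direction of motion for orientation slice o is o + 90 (carrier along it)
  gabors <- lapply(orients, function(o) {
    gabor_pair((o + 90) %% 360, f_cpp, sx, sy, radius)
  })
  t_grid <- seq(0, t_support, by = dt_frame)
  if (length(t_grid) < 3L) {
    stop("temporal kernel support shorter than 3 frames; reduce dt_frame", call. = FALSE)
  }
  g_fast <- temporal_kernel(config$n_fast, config$tau_g, t_grid)
  g_slow <- temporal_kernel(config$n_slow, config$tau_g, t_grid)
  structure(
    list(gabors = gabors, orientations = orients, g_fast = g_fast,
         g_slow = g_slow, t_grid = t_grid, dt_frame = dt_frame,
         f_cpp = f_cpp, radius = radius, n_dir = config$N_dir,
         px_per_deg = config$px_per_deg),
    class = "filter_bank"
  )
}

# causal temporal convolution of a (npix x nt) response matrix with kernel g
temporal_convolve <- function(resp, g) {
  nt <- ncol(resp)
  L <- min(length(g), nt)
  Tm <- matrix(0, nt, nt)
  for (s in seq_len(L)) {
    idx <- seq_len(nt - s + 1L)
    Tm[cbind(idx + s - 1L, idx)] <- g[s]
  }
  resp %*% t(Tm)
}

# package-local cache for the motion-energy normalization constant
the <- new.env(parent = emptyenv())

energy_norm_key <- function(config, dt_frame) {
  paste(config$f, config$sigma_x, config$sigma_y, config$px_per_deg,
        config$tau_g, config$n_fast, config$n_slow, dt_frame, sep = "|")
}

# Peak unnormalized opponent energy for a full-contrast calibration drifting
# bar; fixes the scale so complex-cell activities live in [0, 1].
energy_norm_constant <- function(config, dt_frame) {
  key <- energy_norm_key(config, dt_frame)
  if (!is.null(the[[key]])) return(the[[key]])
  bar <- bar_spec(90, 0, speed = 0.5, length = 40, width = 3, contrast = 1,
                  center = c(24, 32))
  null_bar <- bar_spec(45, 180, contrast = 0, center = c(40, 32))
  movie <- render_crossing_bars(bar, null_bar, shape = c(64, 64), n_frames = 32,
                                dt_frame = dt_frame)
  e <- motion_energy_raw(movie$frames, build_bank(config, dt_frame), config)
  m <- max(e)
  if (m <= 0) stop("calibration stimulus produced no motion energy", call. = FALSE)
  the[[key]] <- m
  m
}

# Opponent motion energy, unnormalized; frames is (ny, nx, nt).
motion_energy_raw <- function(frames, bank, config) {
  ny <- dim(frames)[1]; nx <- dim(frames)[2]; nt <- dim(frames)[3]
  n_or <- length(bank$orientations)
  # reversed intensity drives the filters (dark bars on white background)
  I <- 1 - frames
  plans_e <- lapply(bank$gabors, function(g) conv_plan(g$even, ny, nx))
  plans_o <- lapply(bank$gabors, function(g) conv_plan(g$odd, ny, nx))
  energy <- array(0, dim = c(ny, nx, config$N_dir, nt))
  npix <- ny * nx
  for (oi in seq_len(n_or)) {
    re <- matrix(0, npix, nt); ro <- matrix(0, npix, nt)
    for (t in seq_len(nt)) {
      re[, t] <- conv_apply(plans_e[[oi]], I[, , t])
      ro[, t] <- conv_apply(plans_o[[oi]], I[, , t])
    }
    ef <- temporal_convolve(re, bank$g_fast)
    es <- temporal_convolve(re, bank$g_slow)
    of <- temporal_convolve(ro, bank$g_fast)
    os <- temporal_convolve(ro, bank$g_slow)
    e1 <- (ef + os)^2 + (of - es)^2
    e2 <- (ef - os)^2 + (of + es)^2
    opp <- e1 - e2
    d1 <- direction_index((bank$orientations[oi] + 90) %% 360, config$N_dir)
    d2 <- opposite_direction(d1, config$N_dir)
    energy[, , d1, ] <- array(pmax(opp, 0), dim = c(ny, nx, nt))
    energy[, , d2, ] <- array(pmax(-opp, 0), dim = c(ny, nx, nt))
  }
  energy
}

#' Complex V1 responses by opponent motion energy
#'
#' Direction-selective, phase-insensitive complex-cell activity from the
#' classical motion-energy construction: per orientation, four separable
#' space-time responses (even/odd Gabor x fast/slow temporal filter) are
#' combined into two quadrature pairs selective for the two opposite
#' directions, squared and summed, and opponent-subtracted. The rectified
#' opponent energy is normalized by the peak response to a full-contrast
#' calibration drifting bar so activities lie in \[0, 1\].
#'
#' When the movie is an occluded (cropped) stimulus, responses are computed
#' on the full frames and then cropped to the analysis window, so the
#' filters never see artificial bar ends at the window border.
#'
#' @param movie A `stimulus_movie`.
#' @param bank Optional [build_bank()] result (rebuilt from `config` if
#'   omitted).
#' @param config An [model_config()].
#' @param crop For occluded movies, crop the response field to the analysis
#'   window (set to `FALSE` by internal callers that apply further
#'   full-field interactions before cropping).
#' @return A `direction_field`: array `(y, x, direction, t)` with attributes
#'   `directions` (degrees) and `dt`.
#' @export
motion_energy <- function(movie, bank = NULL, config = model_config(), crop = TRUE) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (is.null(bank)) bank <- build_bank(config, movie$dt_frame)
  if (!isTRUE(all.equal(bank$dt_frame, movie$dt_frame))) {
    stop("filter bank was sampled at a different frame interval than the movie",
         call. = FALSE)
  }
  frames <- if (is.null(movie$full)) movie$frames else movie$full$frames
  e <- motion_energy_raw(frames, bank, config)
  e <- config$energy_gain * e / energy_norm_constant(config, movie$dt_frame)
  e <- clamp01(e)
  if (!is.null(movie$full) && crop) {
    d <- dim(movie$frames)
    ys <- movie$full$y0 + seq_len(d[1]) - 1L
    xs <- movie$full$x0 + seq_len(d[2]) - 1L
    e <- e[ys, xs, , , drop = FALSE]
  }
  direction_field(e, config, dt = movie$dt_frame, regime = "energy")
}

direction_field <- function(values, config, dt, regime = c("activity", "energy")) {
  regime <- match.arg(regime)
  structure(values,
            directions = direction_angles(config$N_dir),
            dt = dt, regime = regime,
            class = c("direction_field", "array"))
}

#' @export
print.direction_field <- function(x, ...) {
  d <- dim(x)
  cat("<direction_field>", d[1], "x", d[2], "lattice,", d[3], "directions,",
      if (length(d) > 3L) paste(d[4], "time points,") else "static,",
      attr(x, "regime"), "regime\n")
  invisible(x)
}
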