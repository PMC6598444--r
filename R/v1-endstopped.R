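#' End-stopped V1 stage
#'
#' End-stopped cells receive the same complex-cell drive as their location
#' but are inhibited by neighbouring complex cells of the same direction
#' preference whenever the neighbourhood is active above a threshold. Along
#' an extended edge the colinear neighbours suppress the cell; at a line end
#' (terminator) half the neighbourhood is silent and activity survives —
#' the unambiguous motion signal that later resolves the aperture problem.
#'
#' @name v1_endstopped
NULL

# Discretized Gaussian inhibitory connectivity over a (2r+1)^2 patch,
# centre excluded, sigma = r/2. Unit peak (not unit mass): the summed
# inhibition from an extended active neighbourhood must be strong enough to
# shut the cell down (G_escx2 multiplies it).
es_inhibition_kernel <- function(radius = 4L, sigma = radius / 2) {
  gaussian_patch(radius, sigma, exclude_center = TRUE, normalize = FALSE)
}

#' Lateral inhibition onto end-stopped cells
#'
#' Gaussian-weighted sum of same-direction complex activity over the
#' inhibition patch, gated per location: the sum contributes only where the
#' maximum complex activity over the inner gate neighbourhood exceeds the
#' threshold `rho_cx`.
#'
#' @param v_cx Complex activity, array `(y, x, n_dir)` (one time point) with
#'   values in \[0, 1\].
#' @param mu Inhibition kernel (matrix, from the configured patch radius).
#' @param rho_cx Gate threshold on complex activity.
#' @param gate_radius Inner neighbourhood radius for the gate.
#' @return Array like `v_cx` holding the inhibition field Gamma.
#' @export
lateral_inhibition <- function(v_cx, mu, rho_cx, gate_radius = 3L) {
  d <- dim(v_cx)
  out <- array(0, dim = d)
  plan <- conv_plan(mu, d[1], d[2])
  for (k in seq_len(d[3])) {
    g <- conv_apply(plan, v_cx[, , k])
    gate <- neighborhood_max(v_cx[, , k], gate_radius) > rho_cx
    out[, , k] <- g * gate
  }
  out
}

#' One Euler step of the end-stopped dynamics
#'
#' Shunting update
#' `dv/dt = (1 - v) * G_escx1 * v_cx - v * (tau_es + G_escx2 * Gamma)`,
#' which keeps `v` in \[0, 1\] for bounded inputs; the state is additionally
#' clipped as a numerical safeguard.
#'
#' @param v_es Current end-stopped activity `(y, x, n_dir)`.
#' @param v_cx Complex activity at the same time.
#' @param Gamma Lateral inhibition from [lateral_inhibition()].
#' @param config An [model_config()].
#' @param dt Euler step (> 0).
#' @return Updated activity array.
#' @export
endstopped_step <- function(v_es, v_cx, Gamma, config = model_config(), dt = config$dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  dv <- (1 - v_es) * (config$G_escx1 * v_cx) -
    v_es * (config$tau_es + config$G_escx2 * Gamma)
  clamp01(v_es + dt * dv)
}

#' Run the end-stopped population over a complex-cell trajectory
#'
#' Steps the end-stopped dynamics once per frame of the complex-cell input
#' and then relaxes for `n_settle` further steps with the final frame's
#' drive held constant, returning the full activity trajectory.
#'
#' @param v_cx A `direction_field` `(y, x, dir, t)` of complex activity.
#' @param config An [model_config()].
#' @param n_settle Extra settling steps under the held final drive.
#' @param Gamma Optional precomputed lateral-inhibition trajectory (same
#'   shape as `v_cx`); supplied by the front end when the complex field was
#'   cropped from a larger frame, so inhibition reflects the full field.
#' @return A `direction_field` `(y, x, dir, t + n_settle)` of end-stopped
#'   activity.
#' @export
run_endstopped <- function(v_cx, config = model_config(), n_settle = 300L,
                           Gamma = NULL) {
  d <- dim(v_cx)
  nt <- d[4]
  mu <- es_inhibition_kernel(config$es_patch_radius)
  v <- array(0, dim = d[1:3])
  out <- array(0, dim = c(d[1:3], nt + n_settle))
  Gam <- NULL
  for (t in seq_len(nt)) {
    cx <- array(v_cx[, , , t], dim = d[1:3])
    Gam <- if (is.null(Gamma)) {
      lateral_inhibition(cx, mu, config$c_cx, config$es_gate_radius)
    } else {
      array(Gamma[, , , t], dim = d[1:3])
    }
    v <- endstopped_step(v, cx, Gam, config)
    out[, , , t] <- v
  }
  cx <- array(v_cx[, , , nt], dim = d[1:3])
  for (s in seq_len(n_settle)) {
    v <- endstopped_step(v, cx, Gam, config)
    out[, , , nt + s] <- v
  }
  direction_field(out, config, dt = attr(v_cx, "dt"), regime = "activity")
}
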