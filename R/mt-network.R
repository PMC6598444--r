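#' MT interaction kernels
#'
#' Centre and surround kernels of the MT populations. MT receptive-field
#' areas are 7 times the V1 RF area (surround areas 10 times), so kernel
#' diameters scale with the square root: centre diameter
#' `sqrt(mt_rf_scale) * v1_rf_px`, surround annulus out to
#' `sqrt(mt_surround_scale) * v1_rf_px`. All kernels are Gaussian-weighted
#' (sigma = radius/2) and normalized to unit mass so the Table-of-constants
#' gains keep their scale.
#'
#' @param config An [model_config()].
#' @return List with `lambda` (centre, self excluded, total weight
#'   `lambda_mass`), `eta` (centre incl. self, unit mass), `zeta` (surround
#'   annulus, total weight `zeta_mass`), and `chi` (surround annulus, unit
#'   mass) kernels plus the radii.
#' @export
mt_kernels <- function(config = model_config()) {
  r_c <- max(2, sqrt(config$mt_rf_scale) * config$v1_rf_px / 2)
  r_s <- sqrt(config$mt_surround_scale) * config$v1_rf_px / 2
  rc <- ceiling(r_c)
  center <- gaussian_patch(rc, sigma = r_c / 2, exclude_center = TRUE)
  center_self <- gaussian_patch(rc, sigma = r_c / 2, exclude_center = FALSE)
  # clip the centre kernels to the centre radius
  g <- seq(-rc, rc)
  dist <- sqrt(outer(g^2, g^2, "+"))
  center[dist > r_c] <- 0
  center_self[dist > r_c] <- 0
  surround <- annulus_patch(r_c, r_s, sigma = r_s / 2)
  list(
    lambda = config$lambda_mass * center / sum(center),
    gamma = config$gamma_mass * center_self / sum(center_self),
    eta = center_self / sum(center_self),
    zeta = config$zeta_mass * surround,
    chi = surround,
    r_center = r_c, r_surround = r_s
  )
}

mt_conv_plans <- function(kernels, ny, nx) {
  list(
    lambda = conv_plan(kernels$lambda, ny, nx),
    gamma = conv_plan(kernels$gamma, ny, nx),
    eta = conv_plan(kernels$eta, ny, nx),
    zeta = conv_plan(kernels$zeta, ny, nx),
    chi = conv_plan(kernels$chi, ny, nx)
  )
}

# inter-directional weight matrix for gamma: w[d, d'] with zero diagonal
gamma_weights <- function(n_dir, weighting = "uniform") {
  ang <- direction_angles(n_dir) * pi / 180
  w <- matrix(1, n_dir, n_dir)
  if (weighting == "cosine") {
    w <- (1 - cos(outer(ang, ang, "-"))) / 2
  }
  diag(w) <- 0
  w
}

#' Lateral interaction terms of the MT populations
#'
#' Computes the six interaction fields entering the MT rate equations, all
#' from activity thresholded at `c_ig` (integration) or `c_sg`
#' (segmentation) so only supra-threshold units contribute:
#' * `lambda`: same-direction integration activity under the centre kernel
#'   (self excluded) — recurrent facilitation that propagates terminator
#'   motion.
#' * `gamma`: delayed inter-directional inhibition at the same location
#'   (sum over other directions, optionally cosine-weighted by angular
#'   difference).
#' * `zeta`: delayed same-direction integration activity over the long-range
#'   surround annulus.
#' * `eta`: integration activity summed over all directions under the
#'   centre kernel (drive to segmentation cells).
#' * `chi_e` / `chi_i`: segmentation surround activity in the same /
#'   opposite direction (centre-surround interaction of segmentation cells).
#'
#' @param v_ig Integration activity `(y, x, n_dir)` at the current time.
#' @param v_ig_delay Integration activity at `t - T_ig`.
#' @param v_sg Segmentation activity at the current time.
#' @param plans Convolution plans from `mt_conv_plans()` (internal); may be
#'   `NULL` to build them on the fly.
#' @param config An [model_config()].
#' @return List of arrays `lambda`, `gamma`, `zeta`, `eta`, `chi_e`,
#'   `chi_i` (`eta` is a matrix shared by all directions).
#' @export
lateral_terms <- function(v_ig, v_ig_delay, v_sg, plans = NULL,
                          config = model_config()) {
  d <- dim(v_ig)
  if (is.null(plans)) plans <- mt_conv_plans(mt_kernels(config), d[1], d[2])
  nd <- d[3]
  th_ig <- v_ig * (v_ig > config$c_ig)
  th_ig_del <- v_ig_delay * (v_ig_delay > config$c_ig)
  th_sg <- v_sg * (v_sg > config$c_sg)
  lambda <- array(0, dim = d)
  zeta <- array(0, dim = d)
  chi_e <- array(0, dim = d)
  gconv <- array(0, dim = d)
  for (k in seq_len(nd)) {
    lambda[, , k] <- conv_apply(plans$lambda, th_ig[, , k])
    zeta[, , k] <- conv_apply(plans$zeta, th_ig_del[, , k])
    chi_e[, , k] <- conv_apply(plans$chi, th_sg[, , k])
    gconv[, , k] <- conv_apply(plans$gamma, th_ig_del[, , k])
  }
  chi_i <- chi_e[, , opposite_direction(seq_len(nd), nd), drop = FALSE]
  # inter-directional inhibition pools delayed activity of the other
  # directions over the centre neighbourhood
  w <- gamma_weights(nd, config$gamma_weighting)
  flat <- matrix(gconv, ncol = nd)
  gamma <- array(flat %*% t(w), dim = d)
  eta <- conv_apply(plans$eta, apply(th_ig, c(1, 2), sum))
  list(lambda = lambda, gamma = gamma, zeta = zeta, eta = eta,
       chi_e = chi_e, chi_i = chi_i)
}

#' One Euler step of the MT network
#'
#' Leaky rate updates of the integration and segmentation populations:
#' \deqn{\Delta v^{ig} = dt\,(G_{igcx} v^{cx} + G_{iges} v^{es}
#'   + G_{igig2}\lambda + G_{igcs}\kappa - G_{igig1}\gamma(t-T_{ig})
#'   - G_{igig3}\zeta(t-T_{ig}) - G_{igsg} v^{sg} - \tau_{ig} v^{ig})}
#' \deqn{\Delta v^{sg} = dt\,(G_{sgcx} v^{cx} - G_{sges} v^{es}
#'   + G_{sgig}\eta + G_{sgsg1}\chi_e - G_{sgsg2}\chi_i - \tau_{sg} v^{sg})}
#' after which both activities are saturated to \[0, 1\].
#'
#' @param state List with `v_ig`, `v_sg`, and delay `history` (internal).
#' @param v_cx,v_es,kappa V1 drive arrays `(y, x, n_dir)` at this time.
#' @param config An [model_config()].
#' @param dt Euler step.
#' @param plans Convolution plans (built from `config` if `NULL`).
#' @return Updated state list.
#' @export
mt_step <- function(state, v_cx, v_es, kappa, config = model_config(),
                    dt = config$dt, plans = NULL) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  n_delay <- max(1L, round(config$T_ig / dt))
  d <- dim(state$v_ig)
  if (is.null(state$history)) {
    state$history <- array(0, dim = c(d, n_delay))
    state$h_ptr <- 0L
  }
  # oldest ring-buffer entry is the activity at t - T_ig
  slot <- state$h_ptr %% n_delay + 1L
  v_ig_delay <- array(state$history[, , , slot], dim = d)
  lt <- lateral_terms(state$v_ig, v_ig_delay, state$v_sg, plans, config)
  drive_ig <- config$G_igcx * v_cx + config$G_iges * v_es +
    config$G_igig2 * lt$lambda + config$G_igcs * kappa -
    config$G_igig1 * lt$gamma - config$G_igig3 * lt$zeta -
    config$G_igsg * state$v_sg - config$tau_ig * state$v_ig
  eta_full <- array(rep(lt$eta, d[3]), dim = d)
  drive_sg <- config$G_sgcx * v_cx - config$G_sges * v_es +
    config$G_sgig * eta_full + config$G_sgsg1 * lt$chi_e -
    config$G_sgsg2 * lt$chi_i - config$tau_sg * state$v_sg
  if (anyNA(drive_ig) || any(!is.finite(drive_ig))) {
    stop("non-finite value in the integration drive (check lambda/gamma/zeta inputs)",
         call. = FALSE)
  }
  if (anyNA(drive_sg) || any(!is.finite(drive_sg))) {
    stop("non-finite value in the segmentation drive (check eta/chi inputs)",
         call. = FALSE)
  }
  new_ig <- clamp01(state$v_ig + dt * drive_ig)
  state$v_sg <- clamp01(state$v_sg + dt * drive_sg)
  # store the *current* v_ig into the slot just consumed
  state$history[, , , slot] <- state$v_ig
  state$v_ig <- new_ig
  state$h_ptr <- state$h_ptr + 1L
  state
}

mt_init_state <- function(ny, nx, n_dir, n_delay) {
  list(
    v_ig = array(0, dim = c(ny, nx, n_dir)),
    v_sg = array(0, dim = c(ny, nx, n_dir)),
    history = array(0, dim = c(ny, nx, n_dir, n_delay)),
    h_ptr = 0L
  )
}

#' V1 front end of the network
#'
#' Computes everything upstream of MT for a stimulus movie: complex-cell
#' motion energy, ECRF form responses, the gated motion signal kappa, and
#' the end-stopped lateral-inhibition field (whose inputs do not depend on
#' MT, so they can be shared across gain sweeps).
#'
#' @param movie A `stimulus_movie`.
#' @param config An [model_config()].
#' @return A `v1_frontend` list: `v_cx` `(y, x, dir, t)`, `v_cs`
#'   `(y, x, orient, t)`, `kappa` `(y, x, dir, t)`, `Gamma` (same shape as
#'   `v_cx`), the movie, and the config.
#' @export
v1_frontend <- function(movie, config = model_config()) {
  # every interaction that looks at neighbours (ECRF surround, end-stopped
  # lateral inhibition, the form gate) is computed on the full, unoccluded
  # field; only then are the fields restricted to the analysis window, so an
  # occluding window never manufactures line ends at its border
  v_cx <- motion_energy(movie, config = config, crop = FALSE)
  d <- dim(v_cx)
  nt <- d[4]
  frames <- if (is.null(movie$full)) movie$frames else movie$full$frames
  n_or <- config$N_dir %/% 2L
  v_cs <- array(0, dim = c(d[1], d[2], n_or, nt))
  kappa <- array(0, dim = d)
  Gamma <- array(0, dim = d)
  mu <- es_inhibition_kernel(config$es_patch_radius)
  for (t in seq_len(nt)) {
    cs <- ecrf_response(frames[, , t], config, background = movie$background)
    v_cs[, , , t] <- cs
    cx_t <- array(v_cx[, , , t], dim = d[1:3])
    kappa[, , , t] <- gate_motion(cx_t, cs, config)
    Gamma[, , , t] <- lateral_inhibition(cx_t, mu, config$c_cx, config$es_gate_radius)
  }
  if (!is.null(movie$full)) {
    dw <- dim(movie$frames)
    ys <- movie$full$y0 + seq_len(dw[1]) - 1L
    xs <- movie$full$x0 + seq_len(dw[2]) - 1L
    v_cx <- direction_field(unclass(v_cx)[ys, xs, , , drop = FALSE], config,
                            dt = movie$dt_frame, regime = "energy")
    v_cs <- v_cs[ys, xs, , , drop = FALSE]
    kappa <- kappa[ys, xs, , , drop = FALSE]
    Gamma <- Gamma[ys, xs, , , drop = FALSE]
  }
  structure(
    list(v_cx = v_cx, v_cs = v_cs, kappa = kappa, Gamma = Gamma,
         movie = movie, config = config),
    class = "v1_frontend"
  )
}

#' Run the recurrent stage (end-stopped + MT) on precomputed V1 drive
#'
#' Steps the end-stopped and MT populations jointly: once per movie frame
#' with the time-varying V1 drive, then for `n_settle` further Euler steps
#' with the final frame's drive held constant, letting the recurrent MT
#' dynamics (terminator propagation, segmentation) reach steady state.
#'
#' @param v1 A [v1_frontend()] result.
#' @param config Configuration for the MT stage (may differ from the one
#'   used for V1 in its gain fields, e.g. during sweeps).
#' @param n_settle Settling steps after the last frame.
#' @param probes Optional tibble/data.frame with integer columns `x`, `y`
#'   (lattice coordinates) at which full per-direction activity traces are
#'   recorded every step.
#' @param history_stride Record full `v_ig` snapshots every this many steps
#'   (0 disables snapshots).
#' @param final_window Fraction of the final steps averaged into
#'   `v_ig_final` (damps residual oscillation).
#' @return An `mt_simulation` object: final fields, probe traces, snapshot
#'   history, supra-threshold area timecourse, and run metadata.
#' @export
run_mt <- function(v1, config = v1$config, n_settle = 600L, probes = NULL,
                   history_stride = 10L, final_window = 0.1) {
  d <- dim(v1$v_cx)
  ny <- d[1]; nx <- d[2]; nd <- d[3]; nt <- d[4]
  n_total <- nt + n_settle
  n_delay <- max(1L, round(config$T_ig / config$dt))
  plans <- mt_conv_plans(mt_kernels(config), ny, nx)
  state <- mt_init_state(ny, nx, nd, n_delay)
  v_es <- array(0, dim = c(ny, nx, nd))

  n_final <- max(1L, ceiling(final_window * n_total))
  acc_ig <- array(0, dim = c(ny, nx, nd))
  acc_es <- array(0, dim = c(ny, nx, nd))
  acc_sg <- array(0, dim = c(ny, nx, nd))

  keep_hist <- history_stride > 0L
  hist_idx <- if (keep_hist) seq(1L, n_total, by = history_stride) else integer()
  history <- if (keep_hist) array(0, dim = c(ny, nx, nd, length(hist_idx))) else NULL
  hi <- 0L

  has_probes <- !is.null(probes) && nrow(probes) > 0L
  if (has_probes) {
    traces <- array(0, dim = c(nrow(probes), nd, n_total))
  }
  area <- matrix(0, n_total, nd)

  cx_t <- es_gam <- kap_t <- NULL
  for (step in seq_len(n_total)) {
    t_in <- min(step, nt)
    if (step <= nt || is.null(cx_t)) {
      cx_t <- array(v1$v_cx[, , , t_in], dim = c(ny, nx, nd))
      es_gam <- array(v1$Gamma[, , , t_in], dim = c(ny, nx, nd))
      kap_t <- array(v1$kappa[, , , t_in], dim = c(ny, nx, nd))
    }
    v_es <- endstopped_step(v_es, cx_t, es_gam, config)
    state <- mt_step(state, cx_t, v_es, kap_t, config, plans = plans)
    if (keep_hist && hi < length(hist_idx) && step == hist_idx[hi + 1L]) {
      hi <- hi + 1L
      history[, , , hi] <- state$v_ig
    }
    if (has_probes) {
      for (p in seq_len(nrow(probes))) {
        traces[p, , step] <- state$v_ig[probes$y[p], probes$x[p], ]
      }
    }
    area[step, ] <- colSums(matrix(state$v_ig > config$c_ig, ncol = nd))
    if (step > n_total - n_final) {
      acc_ig <- acc_ig + state$v_ig
      acc_es <- acc_es + v_es
      acc_sg <- acc_sg + state$v_sg
    }
  }
  structure(
    list(
      v_ig_final = direction_field(acc_ig / n_final, config, config$dt),
      v_sg_final = direction_field(acc_sg / n_final, config, config$dt),
      v_es_final = direction_field(acc_es / n_final, config, config$dt),
      v_ig_last = direction_field(state$v_ig, config, config$dt),
      probes = probes,
      traces = if (has_probes) traces else NULL,
      history = history, history_steps = hist_idx,
      area_supra = area,
      n_frames = nt, n_settle = n_settle, dt = config$dt,
      movie = v1$movie, config = config
    ),
    class = "mt_simulation"
  )
}

#' Simulate the full V1-to-MT network on a stimulus movie
#'
#' Convenience wrapper: [v1_frontend()] followed by [run_mt()]. The run is
#' deterministic given the movie and configuration.
#'
#' @inheritParams run_mt
#' @param movie A `stimulus_movie`.
#' @param config An [model_config()].
#' @return An `mt_simulation` (see [run_mt()]) whose `v1` element holds the
#'   front-end fields.
#' @export
simulate_network <- function(movie, config = model_config(), n_settle = 600L,
                             probes = NULL, history_stride = 10L) {
  v1 <- v1_frontend(movie, config)
  sim <- run_mt(v1, config, n_settle = n_settle, probes = probes,
                history_stride = history_stride)
  sim$v1 <- v1
  sim
}

#' @export
print.mt_simulation <- function(x, ...) {
  d <- dim(x$v_ig_final)
  cat("<mt_simulation>", d[1], "x", d[2], "lattice,", d[3], "directions\n")
  cat("  ", x$n_frames, "stimulus frames +", x$n_settle, "settling steps, dt =",
      x$dt, "\n")
  cat("   gains: G_igcs =", x$config$G_igcs, " G_sges =", x$config$G_sges, "\n")
  invisible(x)
}
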