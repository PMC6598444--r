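#' V1 response maps and terminator statistics
#'
#' Runs the V1 front end (complex, end-stopped, ECRF populations) on a
#' stimulus preset and summarizes the activity at the annotated terminator
#' and mid-edge locations: end-stopped cells should respond at terminators
#' but not along edges, and ECRF cells should be suppressed at the extrinsic
#' terminator relative to the intrinsic ones.
#'
#' @param preset `"crossing"` (both terminator types visible) or `"pattern"`
#'   (intrinsic terminators occluded), or a ready `stimulus_movie`.
#' @param config An [model_config()].
#' @param n_settle Settling steps for the end-stopped dynamics.
#' @param disc_radius Radius of the measurement disc around each annotated
#'   point.
#' @return List with fields `v_cx`, `v_es`, `v_cs` (final-time maps), the
#'   movie, and `stats`, a one-row tibble with the contrast statistics:
#'   `es_term_edge_ratio`, `cx_term_edge_ratio`, `vcs_extrinsic`,
#'   `vcs_intrinsic`, `es_confinement_px` (occluded stimuli: max distance of
#'   supra-threshold end-stopped activity from the extrinsic terminator).
#' @export
run_v1_maps <- function(preset = c("crossing", "pattern"),
                        config = model_config(), n_settle = 300L,
                        disc_radius = 2) {
  movie <- if (inherits(preset, "stimulus_movie")) preset else {
    stim_preset(match.arg(preset), shape = config$grid_shape)
  }
  v1 <- v1_frontend(movie, config)
  d <- dim(v1$v_cx)
  nt <- d[4]
  v_es_traj <- run_endstopped(v1$v_cx, config, n_settle = n_settle,
                              Gamma = v1$Gamma)
  v_es <- array(v_es_traj[, , , dim(v_es_traj)[4]], dim = d[1:3])
  v_cx <- array(v1$v_cx[, , , nt], dim = d[1:3])
  v_cs <- array(v1$v_cs[, , , nt], dim = c(d[1], d[2], d[3] %/% 2L))

  ann <- dplyr::filter(movie$annotations, .data$frame == nt)
  best <- function(a) apply(a, c(1, 2), max) # most responsive direction/orientation
  disc_mean <- function(map, pts) {
    if (nrow(pts) == 0L) return(NA_real_)
    ny <- nrow(map); nx <- ncol(map)
    mean(purrr::map_dbl(seq_len(nrow(pts)), function(i) {
      xs <- pmax(1, round(pts$x[i]) - disc_radius):pmin(nx, round(pts$x[i]) + disc_radius)
      ys <- pmax(1, round(pts$y[i]) - disc_radius):pmin(ny, round(pts$y[i]) + disc_radius)
      mean(map[ys, xs])
    }))
  }
  term <- dplyr::filter(ann, .data$label %in% c("intrinsic", "extrinsic"))
  # keep terminators inside the frame
  term <- dplyr::filter(term, .data$x >= 1, .data$x <= d[2], .data$y >= 1, .data$y <= d[1])
  edge <- dplyr::filter(ann, .data$label == "edge")
  intr <- dplyr::filter(term, .data$label == "intrinsic")
  extr <- dplyr::filter(term, .data$label == "extrinsic")

  es_best <- best(v_es); cx_best <- best(v_cx); cs_best <- best(v_cs)
  es_term <- disc_mean(es_best, term); es_edge <- disc_mean(es_best, edge)
  cx_term <- disc_mean(cx_best, term); cx_edge <- disc_mean(cx_best, edge)

  # Confinement of supra-threshold end-stopped activity to the extrinsic
  # terminator (meaningful for occluded stimuli). The terminator is an
  # extended image feature — the overlap region of the two bars — and
  # end-stopped activity outlives the moving junction (tau_es is small), so
  # distance is measured to the overlap region's trajectory over all frames.
  conf <- NA_real_
  extr_traj <- dplyr::filter(movie$annotations, .data$label == "extrinsic")
  if (nrow(extr_traj) > 0L && length(movie$bars) >= 2L &&
      movie$bars[[2]]$contrast > 0) {
    ov <- Reduce(`|`, lapply(seq_len(nt), function(t) {
      movie_bar_footprint(movie, 1L, t) & movie_bar_footprint(movie, 2L, t)
    }))
    ovc <- which(ov, arr.ind = TRUE)
    thr <- 0.5 * max(es_best)
    idx <- which(es_best > thr, arr.ind = TRUE)
    if (nrow(idx) && nrow(ovc)) {
      dmat <- outer(idx[, 1], ovc[, 1], "-")^2 + outer(idx[, 2], ovc[, 2], "-")^2
      conf <- max(sqrt(apply(dmat, 1, min)))
    }
  }
  stats <- tibble::tibble(
    es_term_edge_ratio = es_term / es_edge,
    cx_term_edge_ratio = cx_term / cx_edge,
    vcs_extrinsic = disc_mean(cs_best, extr),
    vcs_intrinsic = disc_mean(cs_best, intr),
    es_confinement_px = conf
  )
  list(v_cx = v_cx, v_es = v_es, v_cs = v_cs, movie = movie, stats = stats,
       config = config)
}

#' Sweep the two variable gains and map the pattern index
#'
#' Simulates the network once per `(G_igcs, G_sges)` pair on a fixed
#' pattern (occluded-terminator) stimulus, computes the deviation of the
#' final integration activity from the pattern and component templates, and
#' normalizes over the whole grid to obtain `S_P`, `S_C`, and the pattern
#' index per cell. The V1 front end is shared across all cells of the sweep
#' (the swept gains act downstream of it).
#'
#' @param movie Stimulus movie (default: the pattern preset).
#' @param gigcs,gsges Numeric grids for the two variable gains.
#' @param config Base [model_config()].
#' @param n_settle Settling steps per simulation.
#' @param normalize Normalize deviations into `S_P`/`S_C`/`P_I` over this
#'   sweep's grid (`TRUE` unless the sweep is part of a larger ensemble).
#' @return An `mt_sweep` tibble with columns `G_igcs`, `G_sges`, `D_P`,
#'   `D_C` and (when normalized) `S_P`, `S_C`, `P_I`, plus attributes
#'   `config` and `movie`.
#' @export
run_gain_sweep <- function(movie = NULL, gigcs = seq(0, 1, length.out = 5),
                           gsges = seq(0, 1, length.out = 5),
                           config = model_config(), n_settle = 2500L,
                           normalize = TRUE) {
  if (is.null(movie)) movie <- stim_preset("pattern", shape = config$grid_shape)
  v1 <- v1_frontend(movie, config)
  templates <- build_templates(movie, config)
  grid <- tidyr::expand_grid(G_igcs = gigcs, G_sges = gsges)
  dev <- purrr::map(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$G_igcs <- grid$G_igcs[i]
    cfg$G_sges <- grid$G_sges[i]
    sim <- run_mt(v1, cfg, n_settle = n_settle, history_stride = 0L)
    template_deviation(sim$v_ig_final, templates)
  })
  dev <- do.call(rbind, dev)
  out <- dplyr::bind_cols(grid, tibble::as_tibble(dev))
  if (normalize) out <- dplyr::bind_cols(out, selectivity_levels(dev))
  attr(out, "config") <- config
  attr(out, "movie") <- movie
  class(out) <- c("mt_sweep", class(out))
  out
}

#' Contrast dependence of pattern selectivity
#'
#' Repeats the gain sweep for stimuli whose two bars have different
#' contrasts. All sweeps of the experiment form one ensemble for the
#' min-max normalization of the selectivity levels, so pattern indices are
#' comparable across contrast pairs; pattern selectivity is expected to
#' collapse when the bar contrasts differ.
#'
#' @param contrast_pairs List of length-2 contrast vectors.
#' @param gigcs,gsges Gain grids as in [run_gain_sweep()].
#' @param config Base [model_config()].
#' @param shape,n_frames,speed Stimulus geometry.
#' @param n_settle Settling steps per simulation.
#' @return Tibble: one sweep row per gain pair per contrast pair, with
#'   `contrast1`, `contrast2` columns; class `mt_contrast_sweep`.
#' @export
run_contrast_experiment <- function(contrast_pairs = list(c(1, 1), c(1, 0.5)),
                                    gigcs = seq(0, 1, length.out = 3),
                                    gsges = seq(0, 1, length.out = 3),
                                    config = model_config(),
                                    shape = config$grid_shape, n_frames = 32,
                                    speed = 0.5, n_settle = 2500L) {
  res <- purrr::map(contrast_pairs, function(cc) {
    if (all(cc == 0)) stop("both bars have zero contrast", call. = FALSE)
    movie <- stim_preset(if (cc[1] == cc[2]) "pattern" else "contrast",
                         shape = shape, n_frames = n_frames, speed = speed,
                         contrasts = cc)
    sweep <- run_gain_sweep(movie, gigcs, gsges, config, n_settle,
                            normalize = FALSE)
    dplyr::mutate(tibble::as_tibble(sweep), contrast1 = cc[1], contrast2 = cc[2],
                  .before = 1)
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::bind_cols(out, selectivity_levels(as.matrix(out[, c("D_P", "D_C")])))
  attr(out, "config") <- config
  class(out) <- c("mt_contrast_sweep", class(out))
  out
}

#' Temporal dynamics at an edge probe
#'
#' Simulates one gain regime on the pattern stimulus, recording the
#' integration activity at a probe on a bar edge, and returns the pattern-
#' versus component-direction traces with the dominance-crossing time.
#'
#' @param regime `"pattern"` (low `G_igcs`, high `G_sges`) or `"component"`
#'   (high `G_igcs`, low `G_sges`), or a full [model_config()].
#' @param movie Stimulus movie (default: pattern preset).
#' @param probe Optional `c(x, y)`; default: a point on bar 1's edge.
#' @param config Base configuration (for everything but the regime gains).
#' @param n_settle Settling steps.
#' @return The [probe_timecourse()] tibble, with attributes
#'   `crossing_time` and `sim`.
#' @export
run_timecourse <- function(regime = c("pattern", "component"), movie = NULL,
                           probe = NULL, config = model_config(),
                           n_settle = 2500L) {
  if (inherits(regime, "mt_config")) {
    cfg <- regime
  } else {
    regime <- match.arg(regime)
    cfg <- config
    if (regime == "pattern") { cfg$G_igcs <- 0.1; cfg$G_sges <- 0.8 }
    else { cfg$G_igcs <- 0.8; cfg$G_sges <- 0.1 }
  }
  if (is.null(movie)) movie <- stim_preset("pattern", shape = cfg$grid_shape)
  probes <- if (is.null(probe)) default_probe(movie) else {
    tibble::tibble(x = as.integer(probe[1]), y = as.integer(probe[2]))
  }
  sim <- simulate_network(movie, cfg, n_settle = n_settle, probes = probes,
                          history_stride = 0L)
  # component direction of the bar the probe sits on (bar 1: up-left)
  tc <- probe_timecourse(sim, c(probes$x[1], probes$y[1]),
                         dir_pattern = direction_index(90, cfg$N_dir),
                         dir_component = direction_index(135, cfg$N_dir))
  attr(tc, "sim") <- sim
  tc
}
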