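#' Desired-activity templates for pattern and component motion
#'
#' Builds the target activity maps the pattern index compares MT integration
#' activity against: `v_dp` is unit activity over the full stimulus
#' footprint in the pattern direction (straight up for the standard
#' crossing-bar stimuli); `v_dc1`/`v_dc2` are unit activity over each bar's
#' own footprint in that bar's aperture-component direction (the direction
#' orthogonal to the bar axis with an upward component: up-left for the
#' 45-degree bar moving left, up-right for the 135-degree bar moving right).
#'
#' @param movie An annotated `stimulus_movie` (from the stimulus
#'   generators; plain imported arrays carry no bar annotations and raise an
#'   error).
#' @param config An [model_config()].
#' @param frame Frame whose footprint is used (default: last).
#' @return List with matrices `v_dp`, `v_dc1`, `v_dc2` and the direction
#'   indices `dir_pattern`, `dir_comp1`, `dir_comp2`.
#' @export
build_templates <- function(movie, config = model_config(),
                            frame = dim(movie$frames)[3]) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (length(movie$bars) == 0L) {
    stop("movie carries no bar annotations; templates need the stimulus geometry",
         call. = FALSE)
  }
  fp1 <- movie_bar_footprint(movie, 1L, frame)
  fp2 <- movie_bar_footprint(movie, 2L, frame)
  comp_direction <- function(bar) {
    # aperture component: normal to the bar axis, with an upward component
    cand <- c((bar$orientation + 90) %% 360, (bar$orientation + 270) %% 360)
    cand[which(sin(cand * pi / 180) > 0)][1]
  }
  b1 <- movie$bars[[1]]; b2 <- movie$bars[[2]]
  nd <- config$N_dir
  list(
    v_dp = (fp1 | fp2) * 1,
    v_dc1 = fp1 * 1,
    v_dc2 = fp2 * 1,
    dir_pattern = direction_index(90, nd),
    dir_comp1 = direction_index(comp_direction(b1), nd),
    dir_comp2 = if (!is.null(b2) && b2$contrast > 0) {
      direction_index(comp_direction(b2), nd)
    } else NA_integer_
  )
}

# Summed absolute deviation between observed activity and a template,
# restricted to the template's stimulus footprint: the desired activities
# are defined on the stimulus, and restricting the sum keeps the measure
# sensitive to how well the stimulus is covered rather than to recurrent
# spread beyond it.
template_deviation <- function(v_ig_final, templates) {
  on1 <- templates$v_dc1 > 0
  on2 <- templates$v_dc2 > 0
  onp <- templates$v_dp > 0
  dp <- sum(abs(v_ig_final[, , templates$dir_pattern][onp] - 1))
  dc <- sum(abs(v_ig_final[, , templates$dir_comp1][on1] - 1))
  if (!is.na(templates$dir_comp2)) {
    dc <- dc + sum(abs(v_ig_final[, , templates$dir_comp2][on2] - 1))
  }
  c(D_P = dp, D_C = dc)
}

# min-max normalization over a sweep ensemble; a degenerate ensemble
# (max == min, e.g. a 1x1 sweep) maps everything to 0 so S = 1
ensemble_normalize <- function(v) {
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) {
    message("degenerate sweep ensemble (all deviations equal); selectivity set to 1")
    return(rep(0, length(v)))
  }
  (v - rng[1]) / diff(rng)
}

#' Pattern and component selectivity levels
#'
#' Converts template deviations into selectivity levels over a sweep
#' ensemble: `S = 1 - N(deviation)` where `N` is min-max normalization
#' across the ensemble (the full gain grid of one experiment), so the run
#' closest to the template scores 1 and the farthest scores 0.
#'
#' @param deviations Matrix or data frame with columns `D_P`, `D_C`, one row
#'   per sweep cell.
#' @return Tibble with columns `S_P`, `S_C`, `P_I = S_P - S_C`.
#' @export
selectivity_levels <- function(deviations) {
  dp <- deviations[, "D_P"]
  dc <- deviations[, "D_C"]
  sp <- 1 - ensemble_normalize(dp)
  sc <- 1 - ensemble_normalize(dc)
  tibble::tibble(S_P = sp, S_C = sc, P_I = pattern_index(sp, sc))
}

#' Pattern index
#'
#' `P_I = S_P - S_C`: positive values indicate pattern-motion selectivity,
#' negative values component-motion selectivity.
#'
#' @param S_P,S_C Selectivity levels in \[0, 1\].
#' @return Numeric pattern index in \[-1, 1\].
#' @examples
#' pattern_index(1, 0)
#' pattern_index(0.4, 0.4)
#' @export
pattern_index <- function(S_P, S_C) {
  stopifnot(all(S_P >= 0 & S_P <= 1), all(S_C >= 0 & S_C <= 1))
  S_P - S_C
}

#' Per-direction activity traces at a probe location
#'
#' Extracts the integration-activity timecourse at one lattice location for
#' the pattern direction and a component direction, and finds the dominance
#' crossing: the first time the pattern trace exceeds the component trace
#' after the component trace has been dominant. Pattern-selective dynamics
#' show such a crossing (component motion is signalled first, pattern motion
#' takes over after propagation from the extrinsic terminator); component
#' regimes show none.
#'
#' @param sim An `mt_simulation` run with `probes` containing the location.
#' @param location Integer `c(x, y)` lattice coordinates of the probe.
#' @param dir_pattern,dir_component Direction indices (defaults: up and
#'   up-left).
#' @return Tibble `(time, step, pattern, component)` with attribute
#'   `crossing_time` (numeric or `NA` if no crossing).
#' @export
probe_timecourse <- function(sim, location, dir_pattern = 3L, dir_component = 4L) {
  stopifnot(inherits(sim, "mt_simulation"))
  if (is.null(sim$traces)) stop("simulation was run without probes", call. = FALSE)
  p <- which(sim$probes$x == location[1] & sim$probes$y == location[2])
  if (length(p) != 1L) stop("no probe recorded at (", location[1], ", ",
                            location[2], ")", call. = FALSE)
  pat <- sim$traces[p, dir_pattern, ]
  com <- sim$traces[p, dir_component, ]
  n <- length(pat)
  tt <- seq_len(n) * sim$dt
  cross <- NA_real_
  lead <- cummax(c(0, (com - pat)[-n])) # component dominance seen so far
  hit <- which(pat > com & lead > 0.01)
  if (length(hit)) cross <- tt[hit[1]]
  out <- tibble::tibble(time = tt, step = seq_len(n), pattern = pat, component = com)
  attr(out, "crossing_time") <- cross
  out
}

# default probe: a point on bar 1's axis, on the bar footprint, well away
# from the crossing and from the window border
default_probe <- function(movie, offset = 9) {
  ann <- movie$annotations
  extr <- dplyr::filter(ann, .data$label == "extrinsic")
  extr <- extr[which.max(extr$frame), ]
  b <- movie$bars[[1]]
  a <- b$orientation * pi / 180
  d <- dim(movie$frames)
  for (s in c(-offset, offset, -offset + 2, offset - 2)) {
    x <- round(extr$x + s * cos(a)); y <- round(extr$y + s * sin(a))
    if (x >= 3 && x <= d[2] - 2 && y >= 3 && y <= d[1] - 2) {
      return(tibble::tibble(x = as.integer(x), y = as.integer(y)))
    }
  }
  stop("could not place a probe on the bar edge inside the frame", call. = FALSE)
}
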