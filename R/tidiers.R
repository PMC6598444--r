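#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a direction field into a long tibble
#'
#' @param x A `direction_field` (3-D snapshot or 4-D trajectory).
#' @param time Optional time index for 4-D fields (default: last).
#' @param ... Unused.
#' @return Tibble `(x, y, direction, activity)`.
#' @export
tidy.direction_field <- function(x, time = NULL, ...) {
  d <- dim(x)
  a <- if (length(d) == 4L) {
    t <- if (is.null(time)) d[4] else time
    array(x[, , , t], dim = d[1:3])
  } else x
  dirs <- attr(x, "directions")
  tidyr::expand_grid(direction = dirs, xx = seq_len(d[2]), yy = seq_len(d[1])) |>
    dplyr::transmute(
      x = .data$xx, y = .data$yy, direction = .data$direction,
      activity = as.vector(a)[(match(.data$direction, dirs) - 1L) * d[1] * d[2] +
                                (.data$xx - 1L) * d[1] + .data$yy]
    )
}

#' Tidy / summarize an MT simulation
#'
#' `tidy()` returns the final integration activity as a long tibble;
#' `glance()` returns a one-row summary with the dominant direction (argmax
#' of footprint-summed activity) and total activity per direction family.
#'
#' @param x An `mt_simulation`.
#' @param population `"integration"`, `"segmentation"`, or `"endstopped"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mt_simulation <- function(x, population = c("integration", "segmentation",
                                                 "endstopped"), ...) {
  population <- match.arg(population)
  f <- switch(population, integration = x$v_ig_final,
              segmentation = x$v_sg_final, endstopped = x$v_es_final)
  dplyr::mutate(tidy(f), population = population)
}

#' @rdname tidy.mt_simulation
#' @export
glance.mt_simulation <- function(x, ...) {
  d <- dim(x$v_ig_final)
  dirs <- attr(x$v_ig_final, "directions")
  # dominant direction is judged on the stimulus footprint when the movie
  # carries bar geometry; recurrent spread beyond the stimulus is ignored
  fp <- if (length(x$movie$bars)) {
    movie_bar_footprint(x$movie, 1L) | movie_bar_footprint(x$movie, 2L)
  } else {
    matrix(TRUE, d[1], d[2])
  }
  tot <- sapply(seq_len(d[3]), function(k) sum(x$v_ig_final[, , k][fp]))
  tibble::tibble(
    dominant_direction = dirs[which.max(tot)],
    footprint_activity = sum(tot),
    mean_activity = mean(x$v_ig_final),
    G_igcs = x$config$G_igcs,
    G_sges = x$config$G_sges,
    n_steps = x$n_frames + x$n_settle
  )
}

#' @rdname tidy.mt_simulation
#' @export
glance.mt_sweep <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    max_P_I = max(x$P_I),
    min_P_I = min(x$P_I),
    best_pattern_G_igcs = x$G_igcs[which.max(x$P_I)],
    best_pattern_G_sges = x$G_sges[which.max(x$P_I)]
  )
}

#' Plot methods for model results
#'
#' `autoplot()` renders the standard diagnostic figures: per-direction
#' activity maps for a `direction_field` or `mt_simulation`, the pattern-
#' index gain grid for an `mt_sweep`, and stimulus frames for a
#' `stimulus_movie`.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-mtpattern
NULL

#' @rdname autoplot-mtpattern
#' @importFrom ggplot2 autoplot
#' @export
autoplot.direction_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$activity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~direction, nrow = 2,
                        labeller = ggplot2::labeller(direction = function(v) paste0(v, "°"))) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activity")
}

#' @rdname autoplot-mtpattern
#' @export
autoplot.mt_simulation <- function(object, ...) {
  autoplot(object$v_ig_final) +
    ggplot2::ggtitle(sprintf("MT integration activity (G_igcs = %.2g, G_sges = %.2g)",
                             object$config$G_igcs, object$config$G_sges))
}

#' @rdname autoplot-mtpattern
#' @export
autoplot.mt_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$G_igcs, .data$G_sges, fill = .data$P_I)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, limits = c(-1, 1)) +
    ggplot2::labs(fill = "pattern index")
}

#' @rdname autoplot-mtpattern
#' @param frame Frame index to display.
#' @export
autoplot.stimulus_movie <- function(object, frame = 1L, ...) {
  d <- dim(object$frames)
  df <- tidyr::expand_grid(x = seq_len(d[2]), y = seq_len(d[1]))
  df$luminance <- as.vector(t(object$frames[, , frame]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$luminance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot probe timecourses
#'
#' Pattern- versus component-direction activity traces at the probe, with
#' the dominance-crossing time marked when present.
#'
#' @param tc A [probe_timecourse()] / [run_timecourse()] tibble.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc) {
  df <- tidyr::pivot_longer(tc, c("pattern", "component"),
                            names_to = "direction", values_to = "activity")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$activity,
                                        colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(pattern = "red", component = "blue")) +
    ggplot2::labs(x = "time (model units)", y = "integration activity")
  ct <- attr(tc, "crossing_time")
  if (!is.na(ct)) p <- p + ggplot2::geom_vline(xintercept = ct, linetype = 2)
  p
}
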