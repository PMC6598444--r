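#' Bar stimulus specification
#'
#' Describes one dark bar drifting rigidly over a white background.
#' Coordinates are lattice steps with `x` rightward and `y` upward;
#' `orientation` is the bar-axis angle in degrees from the +x axis
#' (45 and 135 for the standard crossing-bar stimuli) and `direction` the
#' true motion direction in degrees (180 = leftward, 0 = rightward).
#'
#' @param orientation Bar axis angle, degrees in \[0, 180).
#' @param direction True motion direction, degrees.
#' @param speed Lattice steps per frame (> 0).
#' @param length,width Bar dimensions in lattice steps.
#' @param contrast Bar darkness in \[0, 1\]: 1 is black on white; 0 removes
#'   the bar.
#' @param center Initial bar-centre coordinates `c(x, y)`.
#' @return A `bar_spec` list.
#' @export
bar_spec <- function(orientation, direction, speed = 0.5, length = 40, width = 3,
                     contrast = 1, center = c(32, 32)) {
  orientation <- orientation %% 180
  if (speed <= 0) stop("speed must be > 0", call. = FALSE)
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]", call. = FALSE)
  structure(
    list(orientation = orientation, direction = direction %% 360, speed = speed,
         length = length, width = width, contrast = contrast,
         center = as.numeric(center)),
    class = "bar_spec"
  )
}

bar_endpoints <- function(bar, offset = c(0, 0)) {
  a <- bar$orientation * pi / 180
  u <- c(cos(a), sin(a))
  c0 <- bar$center + offset
  list(p1 = c0 - u * bar$length / 2, p2 = c0 + u * bar$length / 2)
}

# Rigid per-frame displacement, accumulated as fractional offset and rounded
# per frame (hard-edged lattice rendering; no sub-pixel smoothing).
bar_offset <- function(bar, frame) {
  d <- bar$direction * pi / 180
  round(c(cos(d), sin(d)) * bar$speed * (frame - 1))
}

# Logical mask of a bar at a given frame on an (ny, nx) lattice (row = y,
# y increasing upward with the row index).
bar_mask <- function(bar, shape, frame = 1L) {
  ny <- shape[1]; nx <- shape[2]
  ep <- bar_endpoints(bar, bar_offset(bar, frame))
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  # distance from each lattice point to the segment p1-p2
  v <- ep$p2 - ep$p1
  L2 <- sum(v^2)
  tt <- ((xs - ep$p1[1]) * v[1] + (ys - ep$p1[2]) * v[2]) / L2
  tt <- pmin(pmax(tt, 0), 1)
  dx <- xs - (ep$p1[1] + tt * v[1])
  dy <- ys - (ep$p1[2] + tt * v[2])
  sqrt(dx^2 + dy^2) <= bar$width / 2
}

bar_intersection <- function(bar1, bar2, frame = 1L) {
  e1 <- bar_endpoints(bar1, bar_offset(bar1, frame))
  e2 <- bar_endpoints(bar2, bar_offset(bar2, frame))
  d1 <- e1$p2 - e1$p1; d2 <- e2$p2 - e2$p1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-9) return(NULL) # parallel bars
  w <- e2$p1 - e1$p1
  t1 <- (w[1] * d2[2] - w[2] * d2[1]) / den
  t2 <- (w[1] * d1[2] - w[2] * d1[1]) / den
  if (t1 < 0 || t1 > 1 || t2 < 0 || t2 > 1) return(NULL) # outside a segment
  e1$p1 + t1 * d1
}

new_stimulus_movie <- function(frames, dt_frame, background, annotations, bars,
                               full = NULL) {
  structure(
    list(frames = frames, dt_frame = dt_frame, background = background,
         annotations = annotations, bars = bars, full = full),
    class = "stimulus_movie"
  )
}

#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat("<stimulus_movie>", d[1], "x", d[2], "lattice,", d[3], "frames, dt_frame =",
      x$dt_frame, "\n")
  if (!is.null(x$full)) cat("  analysis window of a larger (occluded) frame\n")
  if (nrow(x$annotations)) {
    cat("  annotations:", paste(unique(x$annotations$label), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Import a stimulus movie from a plain array
#'
#' @param x Numeric array of luminance in \[0, 1\], ordered `(t, y, x)` (the
#'   conventional frame-stack order) or `(y, x, t)`.
#' @param dt_frame Time units per frame.
#' @param background Background luminance (1 = white).
#' @param order Either `"tyx"` (default) or `"yxt"`.
#' @return A `stimulus_movie` (without annotations).
#' @export
as_stimulus_movie <- function(x, dt_frame = 0.01, background = 1, order = c("tyx", "yxt")) {
  order <- match.arg(order)
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (any(x < 0) || any(x > 1)) stop("luminance values must lie in [0, 1]", call. = FALSE)
  if (order == "tyx") x <- aperm(x, c(2, 3, 1))
  if (dim(x)[3] < 2L) stop("a movie needs at least 2 frames", call. = FALSE)
  new_stimulus_movie(
    frames = x, dt_frame = dt_frame, background = background,
    annotations = tibble::tibble(frame = integer(), label = character(),
                                 bar = integer(), x = numeric(), y = numeric()),
    bars = list()
  )
}

annotate_bars <- function(bar1, bar2, shape, n_frames, require_cross = TRUE) {
  rows <- list()
  two <- bar2$contrast > 0
  for (t in seq_len(n_frames)) {
    for (b in seq_len(if (two) 2L else 1L)) {
      bar <- if (b == 1L) bar1 else bar2
      ep <- bar_endpoints(bar, bar_offset(bar, t))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        frame = t, label = "intrinsic", bar = b,
        x = c(ep$p1[1], ep$p2[1]), y = c(ep$p1[2], ep$p2[2])
      )
    }
    if (two) {
      p <- bar_intersection(bar1, bar2, t)
      if (is.null(p)) {
        if (require_cross) {
          stop("bars do not intersect at frame ", t,
               ": no extrinsic terminator exists", call. = FALSE)
        }
      } else {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          frame = t, label = "extrinsic", bar = NA_integer_, x = p[1], y = p[2]
        )
        # mid-edge reference points: halfway between the crossing and each
        # bar end, used by the terminator/edge contrast statistics
        for (b in 1:2) {
          bar <- if (b == 1L) bar1 else bar2
          ep <- bar_endpoints(bar, bar_offset(bar, t))
          for (e in list(ep$p1, ep$p2)) {
            m <- (e + p) / 2
            if (sqrt(sum((m - p)^2)) >= 5 && sqrt(sum((m - e)^2)) >= 5) {
              rows[[length(rows) + 1L]] <- tibble::tibble(
                frame = t, label = "edge", bar = b, x = m[1], y = m[2]
              )
            }
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Render a crossing-bars stimulus movie
#'
#' Two dark bars translate rigidly over a white background; where they
#' overlap the darker (minimum) luminance wins, so equal black bars form a
#' saturated crossing (the junction is not darker than the bars). The
#' crossing point — the extrinsic terminator, whose local motion is the
#' pattern motion — and the four bar ends (intrinsic terminators) are
#' annotated per frame.
#'
#' @param bar1,bar2 [bar_spec()] objects. Setting `bar2`'s contrast to 0
#'   renders a single-bar movie (no extrinsic terminator).
#' @param shape Lattice extent `c(rows, cols)`.
#' @param n_frames Number of frames (>= 2).
#' @param dt_frame Time units per frame.
#' @param overlap `"min"` (darker bar wins, the default) or `"front"` (the
#'   lower-contrast bar occludes the other, used for unequal contrasts).
#' @return A `stimulus_movie`.
#' @export
render_crossing_bars <- function(bar1, bar2, shape = c(64, 64), n_frames = 32,
                                 dt_frame = 0.01, overlap = c("min", "front")) {
  overlap <- match.arg(overlap)
  if (n_frames < 2L) stop("a movie needs at least 2 frames", call. = FALSE)
  if (bar1$contrast == 0 && bar2$contrast == 0) {
    stop("both bars have zero contrast: empty stimulus", call. = FALSE)
  }
  if (bar1$contrast == 0) { tmp <- bar1; bar1 <- bar2; bar2 <- tmp }
  ny <- shape[1]; nx <- shape[2]
  bg <- 1
  two <- bar2$contrast > 0
  lum1 <- bg - bar1$contrast
  lum2 <- bg - bar2$contrast
  front <- if (bar1$contrast <= bar2$contrast) 1L else 2L
  frames <- array(bg, dim = c(ny, nx, n_frames))
  for (t in seq_len(n_frames)) {
    f <- matrix(bg, ny, nx)
    m1 <- bar_mask(bar1, shape, t)
    f[m1] <- lum1
    if (two) {
      m2 <- bar_mask(bar2, shape, t)
      f[m2] <- pmin(f[m2], lum2)
      if (overlap == "front") {
        ov <- m1 & m2
        f[ov] <- if (front == 1L) lum1 else lum2
      }
    }
    frames[, , t] <- f
  }
  ann <- annotate_bars(bar1, bar2, shape, n_frames, require_cross = two)
  new_stimulus_movie(frames, dt_frame, bg, ann, bars = list(bar1, bar2))
}

#' Occlude the intrinsic terminators of a crossing-bars movie
#'
#' Restricts the simulated field to a rectangular analysis window around the
#' bar crossing, emulating occluders that hide the true bar ends so that
#' only the extrinsic terminator remains — the pattern-motion stimulus. The
#' returned movie is the crop; the full frames are retained internally so
#' the V1 filtering stages can compute responses with the unoccluded
#' stimulus in their receptive fields before the fields are cropped
#' (cropping luminance alone would cut the bars and fabricate new line
#' ends at the window border).
#'
#' @param movie A `stimulus_movie` from [render_crossing_bars()].
#' @param window List `list(x = c(x0, x1), y = c(y0, y1))` in lattice
#'   coordinates. Must contain the extrinsic terminator in every frame and
#'   exclude every intrinsic terminator in every frame.
#' @return A cropped `stimulus_movie` with only the extrinsic annotation,
#'   coordinates shifted to the window frame.
#' @export
occlude_intrinsic_terminators <- function(movie, window) {
  stopifnot(inherits(movie, "stimulus_movie"))
  ann <- movie$annotations
  x0 <- window$x[1]; x1 <- window$x[2]; y0 <- window$y[1]; y1 <- window$y[2]
  inside <- function(a) a$x >= x0 & a$x <= x1 & a$y >= y0 & a$y <= y1
  intr <- dplyr::filter(ann, .data$label == "intrinsic")
  extr <- dplyr::filter(ann, .data$label == "extrinsic")
  if (nrow(extr) == 0L) stop("movie has no extrinsic terminator to retain", call. = FALSE)
  if (!all(inside(extr))) {
    stop("window must contain the extrinsic terminator in every frame", call. = FALSE)
  }
  if (any(inside(intr))) {
    stop("window contains an intrinsic terminator: the cropped stimulus ",
         "would not be a pattern stimulus", call. = FALSE)
  }
  d <- dim(movie$frames)
  x0 <- max(1L, as.integer(ceiling(x0))); y0 <- max(1L, as.integer(ceiling(y0)))
  x1 <- min(d[2], as.integer(floor(x1))); y1 <- min(d[1], as.integer(floor(y1)))
  full <- if (is.null(movie$full)) {
    list(frames = movie$frames, x0 = x0, y0 = y0)
  } else {
    list(frames = movie$full$frames,
         x0 = movie$full$x0 + x0 - 1L, y0 = movie$full$y0 + y0 - 1L)
  }
  keep <- dplyr::filter(ann, .data$label != "intrinsic")
  keep <- keep[inside(keep), , drop = FALSE]
  keep$x <- keep$x - (x0 - 1L); keep$y <- keep$y - (y0 - 1L)
  bars <- lapply(movie$bars, function(b) {
    if (is.null(b)) return(b)
    b$center <- b$center - c(x0 - 1L, y0 - 1L)
    b
  })
  new_stimulus_movie(
    frames = movie$frames[y0:y1, x0:x1, , drop = FALSE],
    dt_frame = movie$dt_frame, background = movie$background,
    annotations = keep, bars = bars, full = full
  )
}

#' Crossing bars with per-bar contrasts
#'
#' Renders the crossing-bar stimulus with (possibly unequal) contrasts. With
#' unequal contrasts the low-contrast bar is drawn in front at the overlap
#' (it is perceived as moving in front of the high-contrast bar); with equal
#' contrasts the result is identical to [render_crossing_bars()].
#'
#' @param movie_spec List with elements `bar1`, `bar2` ([bar_spec()]s whose
#'   contrasts are replaced), `shape`, `n_frames`, `dt_frame`.
#' @param contrast1,contrast2 Contrasts in \[0, 1\]; not both zero.
#' @return A `stimulus_movie`.
#' @export
contrast_variant <- function(movie_spec, contrast1, contrast2) {
  if (contrast1 == 0 && contrast2 == 0) {
    stop("both bars have zero contrast: empty stimulus", call. = FALSE)
  }
  b1 <- movie_spec$bar1; b1$contrast <- contrast1
  b2 <- movie_spec$bar2; b2$contrast <- contrast2
  render_crossing_bars(
    b1, b2, shape = movie_spec$shape, n_frames = movie_spec$n_frames,
    dt_frame = movie_spec$dt_frame,
    overlap = if (contrast1 != contrast2 && contrast1 > 0 && contrast2 > 0) "front" else "min"
  )
}

#' Standard stimulus presets
#'
#' `"crossing"`: two equal-contrast black bars slanted at 45 and 135 degrees
#' from horizontal, moving left and right so their crossing point moves
#' straight up. `"pattern"`: the same movie with the intrinsic terminators
#' occluded (analysis window around the crossing) — the plaid-like pattern
#' stimulus. `"contrast"`: the pattern stimulus with unequal bar contrasts.
#' `"single"`: one bar only. `"blank"`: uniform white frames.
#'
#' @param preset One of `"crossing"`, `"pattern"`, `"contrast"`, `"single"`,
#'   `"blank"`.
#' @param shape Lattice extent.
#' @param n_frames,dt_frame Movie length and frame interval.
#' @param speed Bar speed, lattice steps per frame.
#' @param contrasts Length-2 contrasts (used by `"contrast"`; also applied
#'   to `"crossing"`/`"pattern"` when not `c(1, 1)`).
#' @return A `stimulus_movie`.
#' @export
stim_preset <- function(preset = c("crossing", "pattern", "contrast", "single", "blank"),
                        shape = c(64, 64), n_frames = 32, dt_frame = 0.01,
                        speed = 0.5, contrasts = c(1, 1)) {
  preset <- match.arg(preset)
  cx <- shape[2] / 2; cy <- shape[1] / 2
  disp <- speed * n_frames / 2
  b1 <- bar_spec(45, 180, speed = speed, length = 40, width = 3,
                 contrast = contrasts[1], center = c(cx + disp, cy))
  b2 <- bar_spec(135, 0, speed = speed, length = 40, width = 3,
                 contrast = contrasts[2], center = c(cx - disp, cy))
  if (preset == "blank") {
    return(as_stimulus_movie(array(1, dim = c(n_frames, shape[1], shape[2])),
                             dt_frame = dt_frame))
  }
  if (preset == "single") {
    b2$contrast <- 0
    return(render_crossing_bars(b1, b2, shape, n_frames, dt_frame))
  }
  if (preset == "contrast" && contrasts[1] == contrasts[2]) contrasts <- c(1, 0.5)
  spec <- list(bar1 = b1, bar2 = b2, shape = shape, n_frames = n_frames,
               dt_frame = dt_frame)
  movie <- contrast_variant(spec, contrasts[1], contrasts[2])
  if (preset == "crossing") return(movie)
  # pattern / contrast: occlude the intrinsic terminators
  ann <- movie$annotations
  intr <- dplyr::filter(ann, .data$label == "intrinsic")
  extr <- dplyr::filter(ann, .data$label == "extrinsic")
  margin <- 3
  ylo <- max(intr$y[intr$y < min(extr$y)]) + margin
  yhi <- min(intr$y[intr$y > max(extr$y)]) - margin
  window <- list(x = c(cx - 18, cx + 18), y = c(ylo, yhi))
  occlude_intrinsic_terminators(movie, window)
}

#' Stimulus footprints
#'
#' `movie_footprint()` returns the logical mask of pixels darker than the
#' background at a frame; `movie_bar_footprint()` the mask of one bar,
#' reconstructed from the stored bar geometry (in window coordinates for
#' occluded movies).
#'
#' @param movie A `stimulus_movie`.
#' @param bar Bar index (1 or 2).
#' @param frame Frame index (default: last).
#' @return Logical matrix `(y, x)`.
#' @export
movie_footprint <- function(movie, frame = dim(movie$frames)[3]) {
  movie$frames[, , frame] < movie$background - 1e-9
}

#' @rdname movie_footprint
#' @export
movie_bar_footprint <- function(movie, bar, frame = dim(movie$frames)[3]) {
  b <- movie$bars[[bar]]
  if (is.null(b) || b$contrast == 0) {
    return(matrix(FALSE, dim(movie$frames)[1], dim(movie$frames)[2]))
  }
  bar_mask(b, dim(movie$frames)[1:2], frame)
}
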