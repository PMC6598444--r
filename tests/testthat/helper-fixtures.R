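# Shared fixtures: small stimuli and configurations for fast unit tests.
# Full-size study-condition runs live in test-acceptance.R only.

small_config <- function(...) {
  model_config(grid_shape = c(32L, 32L), ...)
}

# single vertical bar drifting rightward on a 32x32 lattice
small_bar_movie <- function(n_frames = 28, speed = 0.5, contrast = 1,
                            orientation = 90, direction = 0) {
  bar <- bar_spec(orientation, direction, speed = speed, length = 20, width = 3,
                  contrast = contrast, center = c(12, 16))
  nul <- bar_spec(45, 180, contrast = 0, center = c(20, 16))
  render_crossing_bars(bar, nul, shape = c(32, 32), n_frames = n_frames)
}

# small crossing-bar stimulus (both terminator types in frame)
small_crossing_movie <- function(n_frames = 28, speed = 0.5,
                                 contrasts = c(1, 1)) {
  b1 <- bar_spec(45, 180, speed = speed, length = 20, width = 3,
                 contrast = contrasts[1], center = c(16 + speed * n_frames / 2, 16))
  b2 <- bar_spec(135, 0, speed = speed, length = 20, width = 3,
                 contrast = contrasts[2], center = c(16 - speed * n_frames / 2, 16))
  render_crossing_bars(b1, b2, shape = c(32, 32), n_frames = n_frames)
}

blank_movie <- function(shape = c(32, 32), n_frames = 28) {
  as_stimulus_movie(array(1, dim = c(n_frames, shape[1], shape[2])))
}
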