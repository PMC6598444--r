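test_that("crossing bars render with saturating overlap and full annotations", {
  mv <- small_crossing_movie()
  expect_s3_class(mv, "stimulus_movie")
  expect_true(all(mv$frames >= 0 & mv$frames <= 1))
  expect_gte(dim(mv$frames)[3], 2)
  # equal black bars: overlap pixels are 0, not darker than the bars
  f1 <- mv$frames[, , 1]
  expect_equal(min(f1), 0)
  ann <- mv$annotations
  expect_setequal(unique(ann$label), c("intrinsic", "extrinsic", "edge"))
  expect_equal(sum(ann$label == "intrinsic" & ann$frame == 1), 4)
  expect_equal(sum(ann$label == "extrinsic" & ann$frame == 1), 1)
})

test_that("the extrinsic terminator of crossing bars moves straight upward", {
  mv <- small_crossing_movie()
  extr <- mv$annotations[mv$annotations$label == "extrinsic", ]
  extr <- extr[order(extr$frame), ]
  expect_lt(diff(range(extr$x)), 1e-9)  # no horizontal drift
  expect_true(all(diff(extr$y) >= 0))   # never downward (plateaus from
  expect_gt(diff(range(extr$y)), 5)     # per-frame rounding), net upward
})

test_that("degenerate bar specifications reduce gracefully", {
  # one bar only: no extrinsic terminator
  single <- small_bar_movie()
  expect_false(any(single$annotations$label == "extrinsic"))
  # parallel bars never intersect
  b1 <- bar_spec(45, 180, center = c(10, 16), length = 20)
  b2 <- bar_spec(45, 0, center = c(22, 16), length = 20)
  expect_error(render_crossing_bars(b1, b2, shape = c(32, 32), n_frames = 8),
               "do not intersect")
  expect_error(
    render_crossing_bars(bar_spec(45, 0, contrast = 0),
                         bar_spec(135, 0, contrast = 0), c(32, 32), 8),
    "zero contrast")
})

test_that("single-bar movies translate rigidly at the nominal speed", {
  mv <- small_bar_movie(speed = 1)
  # frame t+1 equals frame t shifted one step along +x
  for (t in c(3, 10)) {
    a <- mv$frames[, , t]
    b <- mv$frames[, , t + 1]
    expect_equal(b[, 2:32], a[, 1:31])
  }
})

test_that("rendering commutes with left-right mirroring", {
  nx <- 32
  b1 <- bar_spec(45, 180, speed = 0.5, length = 20, center = c(20, 16))
  b2 <- bar_spec(135, 0, speed = 0.5, length = 20, center = c(12, 16))
  mv <- render_crossing_bars(b1, b2, shape = c(32, nx), n_frames = 16)
  m1 <- bar_spec(135, 0, speed = 0.5, length = 20, center = c(nx + 1 - 20, 16))
  m2 <- bar_spec(45, 180, speed = 0.5, length = 20, center = c(nx + 1 - 12, 16))
  mvm <- render_crossing_bars(m1, m2, shape = c(32, nx), n_frames = 16)
  for (t in c(1, 8, 16)) {
    expect_equal(mvm$frames[, , t], mv$frames[, nx:1, t])
  }
})

test_that("occlusion crops to the window and keeps only the extrinsic terminator", {
  mv <- stim_preset("crossing", shape = c(64, 64))
  occ <- stim_preset("pattern", shape = c(64, 64))
  expect_lt(prod(dim(occ$frames)[1:2]), prod(dim(mv$frames)[1:2]))
  expect_false(any(occ$annotations$label == "intrinsic"))
  expect_true(any(occ$annotations$label == "extrinsic"))
  expect_false(is.null(occ$full))
  # extrinsic coordinates are shifted into window coordinates
  d <- dim(occ$frames)
  extr <- occ$annotations[occ$annotations$label == "extrinsic", ]
  expect_true(all(extr$x >= 1 & extr$x <= d[2] & extr$y >= 1 & extr$y <= d[1]))
  # a window that contains an intrinsic terminator is refused
  expect_error(occlude_intrinsic_terminators(mv, list(x = c(1, 64), y = c(1, 64))),
               "intrinsic terminator")
  # a window missing the crossing is refused
  expect_error(occlude_intrinsic_terminators(mv, list(x = c(1, 10), y = c(28, 36))),
               "extrinsic")
})

test_that("occlusion with bar ends already outside the frame is the identity", {
  b1 <- bar_spec(45, 180, speed = 0.25, length = 80, center = c(18, 16))
  b2 <- bar_spec(135, 0, speed = 0.25, length = 80, center = c(14, 16))
  mv <- render_crossing_bars(b1, b2, shape = c(32, 32), n_frames = 8)
  occ <- occlude_intrinsic_terminators(mv, list(x = c(1, 32), y = c(1, 32)))
  expect_equal(occ$frames, mv$frames)
})

test_that("contrast variants put the low-contrast bar in front", {
  spec <- list(bar1 = bar_spec(45, 180, speed = 0.5, length = 20, center = c(20, 16)),
               bar2 = bar_spec(135, 0, speed = 0.5, length = 20, center = c(12, 16)),
               shape = c(32, 32), n_frames = 16, dt_frame = 0.01)
  mv <- contrast_variant(spec, 1, 0.4)
  # overlap pixels carry the front (low-contrast) bar's luminance 1 - 0.4
  for (t in c(1, 8)) {
    ov <- mtpattern:::movie_bar_footprint(mv, 1, t) &
      mtpattern:::movie_bar_footprint(mv, 2, t)
    expect_true(any(ov))
    expect_true(all(abs(mv$frames[, , t][ov] - 0.6) < 1e-12))
  }
  # equal contrasts reduce to the plain renderer
  expect_equal(contrast_variant(spec, 1, 1)$frames,
               render_crossing_bars(spec$bar1, spec$bar2, spec$shape,
                                    spec$n_frames)$frames)
  # zero contrast for one bar leaves a single-bar movie
  single <- contrast_variant(spec, 1, 0)
  expect_false(any(single$annotations$label == "extrinsic"))
  expect_error(contrast_variant(spec, 0, 0), "zero contrast")
})

test_that("movies import from plain (t, y, x) arrays with validation", {
  arr <- array(runif(5 * 8 * 9), dim = c(5, 8, 9))
  mv <- as_stimulus_movie(arr, dt_frame = 0.02)
  expect_equal(dim(mv$frames), c(8, 9, 5))
  expect_equal(mv$frames[, , 3], arr[3, , ])
  expect_error(as_stimulus_movie(array(2, dim = c(3, 4, 4))), "luminance")
  expect_error(as_stimulus_movie(array(0.5, dim = c(1, 4, 4))), "2 frames")
})
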