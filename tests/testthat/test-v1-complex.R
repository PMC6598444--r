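test_that("temporal kernel is causal, biphasic, and vanishing", {
  tg <- seq(0, 0.4, by = 0.001)
  for (n in c(6, 9)) {
    g <- temporal_kernel(n, 0.01, tg)
    expect_equal(g[1], 0)              # zero at t = 0
    expect_lt(abs(g[length(g)]), 1e-6) # decays to zero
    expect_gt(max(g), 0)               # positive lobe
    expect_lt(min(g), 0)               # negative lobe
  }
  expect_error(temporal_kernel(6, 0.01, c(-0.01, 0)), "causal")
  expect_error(temporal_kernel(0, 0.01, tg), "n must be")
  expect_error(temporal_kernel(6, 0, tg), "tau_g")
})

test_that("kernel zero-crossing matches the closed form sqrt((n+1)(n+2)) tau_g", {
  # bracket term 1/n! - s^2/(n+2)! vanishes at s = sqrt((n+1)(n+2))
  for (n in c(6L, 9L)) {
    tau <- 0.01
    analytic <- tau * sqrt((n + 1) * (n + 2))
    # numeric root of the kernel itself, bracketed around the sign change
    f <- function(t) temporal_kernel(n, tau, t)
    numeric_root <- uniroot(f, c(analytic - 0.02, analytic + 0.02),
                            tol = 1e-12)$root
    expect_equal(numeric_root, analytic, tolerance = 1e-9)
  }
  expect_equal(sqrt(7 * 8), sqrt(56))    # n = 6
  expect_lt(sqrt(56), sqrt(110))         # slow kernel crosses later
})

test_that("the filter bank holds quadrature pairs shared by opposite directions", {
  cfg <- small_config()
  bank <- build_bank(cfg, dt_frame = 0.01)
  expect_length(bank$gabors, 4)
  for (g in bank$gabors) {
    c0 <- (nrow(g$even) + 1) / 2
    expect_gt(g$even[c0, c0], 0)            # cosine phase peaks at the centre
    expect_lt(abs(g$odd[c0, c0]), 1e-12)    # sine phase is zero at the centre
    expect_equal(g$odd, -g$odd[nrow(g$odd):1, ncol(g$odd):1]) # antisymmetric
    expect_lt(abs(sum(g$even)), 1e-9)       # zero-mean (no DC response)
  }
  # slow kernel's zero crossing occurs at larger t than the fast kernel's
  zf <- which(diff(sign(bank$g_fast[-1])) != 0)[1]
  zs <- which(diff(sign(bank$g_slow[-1])) != 0)[1]
  expect_gt(zs, zf)
  expect_error(build_bank(cfg, dt_frame = 0.2), "3 frames")
})

test_that("motion energy is direction selective and opponently rectified", {
  cfg <- small_config()
  mv <- small_bar_movie(direction = 0, orientation = 90) # rightward
  e <- motion_energy(mv, config = cfg)
  expect_true(all(e >= 0 & e <= 1))
  nt <- dim(e)[4]
  tot <- colSums(matrix(e[, , , nt], ncol = 8))
  expect_equal(which.max(tot), 1L)   # rightward slice dominates
  expect_gt(tot[1], 10 * tot[5])     # opponency: opposite direction silent
})

test_that("static and blank movies produce no motion energy", {
  cfg <- small_config()
  frames <- array(1, dim = c(24, 32, 32))
  frames[, 10:20, 14:18] <- 0.2      # static dark patch
  mv <- as_stimulus_movie(frames)
  e <- motion_energy(mv, config = cfg)
  expect_lt(max(e), 1e-8)
  eb <- motion_energy(blank_movie(), config = cfg)
  expect_equal(max(eb), 0)
})

test_that("motion energy commutes with mirroring up to the direction map", {
  cfg <- small_config()
  nx <- 32
  mv <- small_bar_movie(direction = 0, orientation = 90)
  bar_m <- bar_spec(90, 180, speed = 0.5, length = 20, width = 3,
                    center = c(nx + 1 - 12, 16))
  nul <- bar_spec(45, 180, contrast = 0, center = c(5, 16))
  mvm <- render_crossing_bars(bar_m, nul, shape = c(32, nx), n_frames = 28)
  e <- motion_energy(mv, config = cfg)
  em <- motion_energy(mvm, config = cfg)
  # mirror direction map: d -> 180 - d
  for (d in 1:8) {
    dm <- ((4 - (d - 1)) %% 8) + 1 # index of (180 - angle)
    expect_equal(em[, nx:1, dm, 20], e[, , d, 20], tolerance = 1e-8)
  }
})

test_that("quadrature construction is phase insensitive on a drifting bar", {
  cfg <- small_config()
  e1 <- motion_energy(small_bar_movie(speed = 0.5), config = cfg)
  # same stimulus shifted by half the carrier period (~1.8 px -> use 2 px)
  bar2 <- bar_spec(90, 0, speed = 0.5, length = 20, width = 3, center = c(14, 16))
  nul <- bar_spec(45, 180, contrast = 0, center = c(24, 16))
  e2 <- motion_energy(render_crossing_bars(bar2, nul, c(32, 32), 28),
                      config = cfg)
  nt <- dim(e1)[4]
  # compare peak rightward response, which should be phase-stable
  p1 <- max(e1[, , 1, nt])
  p2 <- max(e2[, , 1, nt])
  expect_lt(abs(p1 - p2) / max(p1, p2), 0.05)
})
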