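zero_state <- function(n = 16, nd = 8, cfg = model_config()) {
  mtpattern:::mt_init_state(n, n, nd, max(1L, round(cfg$T_ig / cfg$dt)))
}

test_that("interaction kernels respect the centre/surround geometry", {
  cfg <- model_config()
  k <- mt_kernels(cfg)
  expect_equal(sum(k$lambda), cfg$lambda_mass, tolerance = 1e-9)
  expect_equal(sum(k$gamma), cfg$gamma_mass, tolerance = 1e-9)
  expect_equal(sum(k$zeta), cfg$zeta_mass, tolerance = 1e-9)
  expect_equal(sum(k$eta), 1, tolerance = 1e-9)
  c0 <- (nrow(k$lambda) + 1) / 2
  expect_equal(k$lambda[c0, c0], 0)        # self excluded
  expect_gt(k$eta[(nrow(k$eta) + 1) / 2, (ncol(k$eta) + 1) / 2], 0)
  s0 <- (nrow(k$zeta) + 1) / 2
  expect_equal(k$zeta[s0, s0], 0)          # annulus excludes the centre
  # surround area ratio 10 vs centre 7 gives sqrt(10/7) radius ratio
  expect_equal(k$r_surround / k$r_center, sqrt(10 / 7), tolerance = 1e-9)
})

test_that("lateral terms vanish on an all-zero state", {
  cfg <- model_config()
  z <- array(0, dim = c(16, 16, 8))
  lt <- lateral_terms(z, z, z, config = cfg)
  for (nm in c("lambda", "gamma", "zeta", "eta", "chi_e", "chi_i")) {
    expect_equal(max(abs(lt[[nm]])), 0, label = nm)
  }
})

test_that("a one-hot integration unit excites neighbours and inhibits other directions", {
  cfg <- model_config()
  kern <- mt_kernels(cfg)
  v <- array(0, dim = c(24, 24, 8))
  v[12, 12, 3] <- 0.8                      # above c_ig = 0.05
  z <- array(0, dim = c(24, 24, 8))
  lt <- lateral_terms(v, v, z, config = cfg)
  r <- (nrow(kern$lambda) - 1) / 2
  # lambda at an offset equals the kernel weight times the activity
  expect_equal(lt$lambda[12, 14, 3], kern$lambda[r + 1, r + 3] * 0.8,
               tolerance = 1e-9)
  expect_equal(lt$lambda[12, 12, 3], 0)    # no self excitation
  expect_equal(max(abs(lt$lambda[, , 4])), 0)  # other directions unaffected
  # gamma: other directions at/near the hot spot are inhibited, dir 3 is not
  expect_gt(lt$gamma[12, 12, 4], 0)
  expect_equal(lt$gamma[12, 12, 3], 0)
  # zeta: zero at the source, positive on the surround annulus
  expect_equal(lt$zeta[12, 12, 3], 0)
  ring <- round(ceiling(kern$r_center) + 1)
  expect_gt(lt$zeta[12, 12 + ring, 3], 0)
  # sub-threshold units contribute nothing
  v[12, 12, 3] <- 0.04
  lt0 <- lateral_terms(v, v, z, config = cfg)
  expect_equal(max(abs(lt0$lambda)), 0)
})

test_that("uniform one-direction segmentation activity yields zero opposite surround", {
  cfg <- model_config()
  z <- array(0, dim = c(16, 16, 8))
  sg <- array(0, dim = c(16, 16, 8))
  sg[, , 2] <- 0.5
  lt <- lateral_terms(z, z, sg, config = cfg)
  expect_gt(max(lt$chi_e[, , 2]), 0)
  expect_equal(max(abs(lt$chi_i[, , 2])), 0)  # opposite slice (dir 6) empty
  expect_gt(max(lt$chi_i[, , 6]), 0)          # and vice versa
})

test_that("the zero state with zero drive is a fixed point of the MT step", {
  cfg <- model_config()
  st <- zero_state(16)
  z <- array(0, dim = c(16, 16, 8))
  st2 <- mt_step(st, z, z, z, cfg)
  expect_equal(st2$v_ig, z)
  expect_equal(st2$v_sg, z)
})

test_that("MT activities remain in [0, 1] under random bounded drive", {
  cfg <- model_config()
  st <- zero_state(12)
  set.seed(99)
  for (i in 1:300) {
    v_cx <- array(runif(12 * 12 * 8), dim = c(12, 12, 8))
    v_es <- array(runif(12 * 12 * 8), dim = c(12, 12, 8))
    kap <- array(runif(12 * 12 * 8), dim = c(12, 12, 8))
    st <- mt_step(st, v_cx, v_es, kap, cfg)
    expect_true(all(st$v_ig >= 0 & st$v_ig <= 1))
    expect_true(all(st$v_sg >= 0 & st$v_sg <= 1))
  }
})

test_that("the inhibition delay buffer has length T_ig / dt", {
  cfg <- model_config()
  st <- zero_state(8, cfg = cfg)
  expect_equal(dim(st$history)[4], round(cfg$T_ig / cfg$dt))
  # inhibition from a transient arrives only after the delay: drive a unit
  # up, then watch gamma appear T_ig later at another direction
  z <- array(0, dim = c(8, 8, 8))
  drive <- z; drive[4, 4, 1] <- 1
  for (i in 1:30) st <- mt_step(st, drive, z, z, cfg)
  lt_now <- lateral_terms(st$v_ig, st$v_ig, st$v_sg, config = cfg)
  expect_gt(lt_now$gamma[4, 4, 2], 0)
})

test_that("non-finite drive aborts with a diagnostic", {
  cfg <- model_config()
  st <- zero_state(8)
  bad <- array(0, dim = c(8, 8, 8)); bad[1, 1, 1] <- NaN
  z <- array(0, dim = c(8, 8, 8))
  expect_error(mt_step(st, bad, z, z, cfg), "integration drive")
})

test_that("a blank movie yields identically zero trajectories", {
  cfg <- small_config()
  sim <- simulate_network(blank_movie(), cfg, n_settle = 50L,
                          history_stride = 0L)
  expect_equal(max(sim$v_ig_final), 0)
  expect_equal(max(sim$v_sg_final), 0)
  expect_equal(max(sim$v_es_final), 0)
})

test_that("simulation is deterministic", {
  cfg <- small_config()
  mv <- small_crossing_movie()
  s1 <- simulate_network(mv, cfg, n_settle = 80L, history_stride = 0L)
  s2 <- simulate_network(mv, cfg, n_settle = 80L, history_stride = 0L)
  expect_identical(unclass(s1$v_ig_final), unclass(s2$v_ig_final))
  expect_identical(unclass(s1$v_sg_final), unclass(s2$v_sg_final))
})
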