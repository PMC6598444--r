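# Brute-force evaluation of the lateral-inhibition sum for one direction
# slice: the independent oracle for lateral_inhibition().
brute_gamma <- function(v, mu, rho, gate_r) {
  ny <- nrow(v); nx <- ncol(v)
  r <- (nrow(mu) - 1) / 2
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    nb_max <- 0
    for (i in -gate_r:gate_r) for (j in -gate_r:gate_r) {
      yy <- y + i; xx <- x + j
      if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx) {
        nb_max <- max(nb_max, v[yy, xx])
      }
    }
    if (nb_max > rho) {
      s <- 0
      for (i in -r:r) for (j in -r:r) {
        yy <- y + i; xx <- x + j
        if (yy >= 1 && yy <= ny && xx >= 1 && xx <= nx) {
          s <- s + mu[i + r + 1, j + r + 1] * v[yy, xx]
        }
      }
      out[y, x] <- s
    }
  }
  out
}

test_that("lateral inhibition matches a brute-force evaluation exactly", {
  mu <- mtpattern:::es_inhibition_kernel(4)
  rho <- 0.12
  set.seed(7)
  cases <- list(
    random = matrix(runif(16 * 16), 16, 16),
    onehot = {
      m <- matrix(0, 16, 16); m[8, 9] <- 0.8; m
    },
    uniform = matrix(0.5, 16, 16),
    subthreshold = matrix(0.05, 16, 16)
  )
  for (nm in names(cases)) {
    v <- array(cases[[nm]], dim = c(16, 16, 1))
    got <- lateral_inhibition(v, mu, rho, gate_radius = 3L)
    want <- brute_gamma(cases[[nm]], mu, rho, 3L)
    expect_equal(got[, , 1], want, tolerance = 1e-12, label = nm)
  }
})

test_that("sub-threshold neighbourhoods produce zero inhibition", {
  mu <- mtpattern:::es_inhibition_kernel(4)
  v <- array(0.05, dim = c(16, 16, 2)) # everywhere below rho = 0.12
  expect_equal(max(lateral_inhibition(v, mu, 0.12)), 0)
})

test_that("uniform supra-threshold activity gives kernel-mass inhibition", {
  mu <- mtpattern:::es_inhibition_kernel(4)
  a <- 0.5
  v <- array(a, dim = c(20, 20, 1))
  got <- lateral_inhibition(v, mu, 0.12)
  # away from borders the sum is a * sum(mu)
  expect_equal(got[10, 10, 1], a * sum(mu), tolerance = 1e-12)
})

test_that("end-stopped dynamics reach the closed-form steady state", {
  cfg <- model_config()
  v_cx <- array(0.5, dim = c(4, 4, 1))
  Gam <- array(0, dim = c(4, 4, 1))
  v <- array(0, dim = c(4, 4, 1))
  for (i in 1:10000) v <- endstopped_step(v, v_cx, Gam, cfg)
  vstar <- cfg$G_escx1 * 0.5 / (cfg$G_escx1 * 0.5 + cfg$tau_es)
  expect_equal(vstar, 1 / 1.01, tolerance = 1e-12)
  expect_equal(v[1, 1, 1], vstar, tolerance = 1e-4)
})

test_that("quiescence is a fixed point and activity cannot leave [0, 1]", {
  cfg <- model_config()
  z <- array(0, dim = c(8, 8, 8))
  expect_equal(endstopped_step(z, z, z, cfg), z)
  set.seed(42)
  v <- array(0, dim = c(8, 8, 8))
  mu <- mtpattern:::es_inhibition_kernel(4)
  for (i in 1:200) {
    v_cx <- array(runif(8 * 8 * 8), dim = c(8, 8, 8))
    Gam <- lateral_inhibition(v_cx, mu, cfg$c_cx)
    v <- endstopped_step(v, v_cx, Gam, cfg)
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(endstopped_step(v, v, v, cfg, dt = 0), "dt")
})

test_that("stronger lateral inhibition never increases steady activity", {
  base <- model_config()
  mv <- small_bar_movie()
  cx <- motion_energy(mv, config = small_config())
  es1 <- run_endstopped(cx, model_config(G_escx2 = 3), n_settle = 150L)
  es2 <- run_endstopped(cx, model_config(G_escx2 = 6), n_settle = 150L)
  last <- dim(es1)[4]
  expect_true(all(es2[, , , last] <= es1[, , , last] + 1e-9))
})

test_that("end-stopped cells sharpen terminators relative to complex cells", {
  cfg <- small_config()
  mv <- small_bar_movie(speed = 0.5)
  cx <- motion_energy(mv, config = cfg)
  es <- run_endstopped(cx, cfg, n_settle = 200L)
  nt_cx <- dim(cx)[4]; nt_es <- dim(es)[4]
  best_cx <- apply(cx[, , , nt_cx], c(1, 2), max)
  best_es <- apply(es[, , , nt_es], c(1, 2), max)
  ann <- mv$annotations[mv$annotations$frame == nt_cx, ]
  ends <- ann[ann$label == "intrinsic", ]
  mid_x <- round(mean(ends$x)); mid_y <- round(mean(ends$y))
  disc <- function(m, x, y) mean(m[(y - 1):(y + 1), (x - 1):(x + 1)])
  term_es <- mean(mapply(function(x, y) disc(best_es, round(x), round(y)),
                         ends$x, ends$y))
  term_cx <- mean(mapply(function(x, y) disc(best_cx, round(x), round(y)),
                         ends$x, ends$y))
  ratio_es <- term_es / disc(best_es, mid_x, mid_y)
  ratio_cx <- term_cx / disc(best_cx, mid_x, mid_y)
  expect_gt(ratio_es, ratio_cx) # suppression acts along the edge interior
})
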