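test_that("high-pass removes DC exactly and obeys the Butterworth response", {
  cfg <- acq_config(40e6, 3500, seq(-3, 3))   # FR 500
  nt <- 200
  mk_ens <- function(series) {
    iq_ensemble(array(rep(series, 7), c(1, 1, nt, 7)), cfg)
  }
  ## constant series annihilated
  dc <- mk_ens(rep(3 + 4i, nt))
  out <- highpass_temporal(dc, 20)
  expect_lt(max(Mod(out$data)), 1e-8 * 5)
  ## tone at 5x cutoff: amplitude preserved within 1 dB
  f0 <- 20
  tone5 <- mk_ens(as.vector(tone_series(5 * f0, nt)))
  amp5 <- mean(Mod(highpass_temporal(tone5, f0)$data[1, 1, 50:150, 1]))
  expect_lt(abs(20 * log10(amp5)), 1)
  ## tone at the cutoff: ~6 dB attenuation (two 3 dB passes)
  tonec <- mk_ens(as.vector(tone_series(f0, nt)))
  ampc <- mean(Mod(highpass_temporal(tonec, f0)$data[1, 1, 50:150, 1]))
  expect_equal(-20 * log10(ampc), 6, tolerance = 1)
  ## guards
  expect_error(highpass_temporal(dc, 300), "cutoff")
  short <- iq_ensemble(array(1i, c(1, 1, 8, 7)), cfg)
  expect_error(highpass_temporal(short, 20), "length error")
})

test_that("lag-1 phase matches closed forms", {
  cfg <- acq_config(40e6, 3500, 0)
  tone <- tone_series(50, 100, 500)
  ens <- iq_ensemble(array(tone, c(1, 1, 100, 1)), cfg)
  pm <- lag1_phase(ens, NULL)
  expect_equal(pm$phase[1, 1, 1, 1], 2 * pi * 50 / 500, tolerance = 1e-10)
  ## conjugated series: negated phase
  ensc <- iq_ensemble(array(Conj(tone), c(1, 1, 100, 1)), cfg)
  expect_equal(lag1_phase(ensc, NULL)$phase[1, 1, 1, 1],
               -pm$phase[1, 1, 1, 1], tolerance = 1e-10)
  ## sliding windows agree with per-window direct sums
  pmw <- lag1_phase(ens, 10)
  expect_equal(dim(pmw$phase)[3], 91)
  expect_equal(pmw$phase[1, 1, 37, 1], 2 * pi * 50 / 500, tolerance = 1e-10)
  expect_error(lag1_phase(ens, 1), "at least 2")
})

test_that("white-noise lag-1 phase is unbiased around zero", {
  ## 1000 independent noise series, one per pixel row
  set.seed(77)
  n <- 1000; nt <- 64
  cfg <- acq_config(40e6, 3500, 0)
  arr <- array(complex(real = rnorm(n * nt), imaginary = rnorm(n * nt)),
               c(n, 1, nt, 1))
  pm <- lag1_phase(iq_ensemble(arr, cfg), NULL)
  ph <- pm$phase[, 1, 1, 1]
  se <- sd(ph) / sqrt(n)
  expect_lt(abs(mean(ph)), 3 * se + 0.01)
})

test_that("axial velocity follows the Doppler equation", {
  cfg <- acq_config(40e6, 3500, seq(-3, 3))
  expect_equal(axial_velocity(0, cfg), 0)
  expect_equal(axial_velocity(pi / 2, cfg), 2.40625e-3, tolerance = 1e-9)
  expect_equal(axial_velocity(pi, cfg), 4.8125e-3, tolerance = 1e-9)
})

test_that("multibeam solve matches a brute-force grid-search oracle", {
  angles <- seq(-3, 3)
  set.seed(21)
  for (k in 1:100) {
    v <- runif(1, 1e-3, 15e-3)
    th_d <- runif(1, -pi, pi)
    v_ax <- v * cos(th_d + angles * pi / 180)
    f <- solve_vector(matrix(v_ax, 1), angles)
    expect_lt(abs(f$v[1] - v) / v, 1e-4)
    ## against the independent grid search on a subset (it is slow)
    if (k <= 10) {
      g <- grid_search_vector(v_ax, angles)
      expect_lt(abs(f$v[1] - g["v"]) / v, 1e-3)
    }
  }
})

test_that("multibeam solve handles degenerate and two-angle cases", {
  angles <- seq(-3, 3)
  ## all-zero projections: v = 0, direction invalid
  f0 <- solve_vector(matrix(0, 1, 7), angles)
  expect_identical(f0$v[1], 0)
  expect_true(is.na(f0$theta[1]))
  expect_false(f0$valid[1])
  ## two angles: equals the closed-form 2x2 solve
  a2 <- c(-3, 3); th2 <- a2 * pi / 180
  v <- 8e-3; th_d <- 0.7
  y <- v * cos(th_d + th2)
  x <- rbind(c(cos(th2[1]), -sin(th2[1])), c(cos(th2[2]), -sin(th2[2])))
  ab <- solve(x, y)
  f2 <- solve_vector(matrix(y, 1), a2)
  expect_equal(f2$v[1], sqrt(sum(ab^2)), tolerance = 1e-10)
  expect_equal(f2$theta[1], atan2(ab[2], ab[1]), tolerance = 1e-10)
  ## errors
  expect_error(solve_vector(matrix(1, 1, 1), 0), "2 angles")
  expect_error(solve_vector(matrix(1, 1, 2), c(1, 1)), "distinct")
})

test_that("multibeam solve is equivariant and permutation-invariant", {
  angles <- seq(-3, 3)
  set.seed(31)
  for (k in 1:20) {
    v <- runif(1, 1e-3, 1e-2); th_d <- runif(1, -pi, pi)
    y <- v * cos(th_d + angles * pi / 180)
    f <- solve_vector(matrix(y, 1), angles)
    ## negated projections: same speed, direction flipped by 180 deg
    fn <- solve_vector(matrix(-y, 1), angles)
    expect_equal(fn$v[1], f$v[1], tolerance = 1e-9)
    dd <- (fn$theta[1] - f$theta[1]) %% (2 * pi)
    expect_equal(min(abs(dd - pi), abs(dd + pi)), 0, tolerance = 1e-9)
    ## permuting the angles leaves the estimate unchanged
    p <- sample(7)
    fp <- solve_vector(matrix(y[p], 1), angles[p])
    expect_equal(fp$v[1], f$v[1], tolerance = 1e-9)
    expect_equal(fp$theta[1], f$theta[1], tolerance = 1e-9)
  }
})

test_that("broadside flow stays numerically stable with symmetric angles", {
  angles <- seq(-3, 3)
  v <- 7.2e-3
  y <- v * cos(pi / 2 + angles * pi / 180)   # a component ~ 0
  f <- solve_vector(matrix(y, 1), angles)
  expect_true(f$valid[1])
  expect_equal(f$v[1], v, tolerance = 1e-9)
  expect_equal(f$theta[1], pi / 2, tolerance = 1e-9)
})

test_that("weighted solve ignores angles without coherent signal", {
  angles <- seq(-3, 3)
  v <- 3e-3
  y <- v * cos(pi / 2 + angles * pi / 180)
  y_bad <- y
  y_bad[4] <- 4e-3          # center angle replaced by garbage
  w <- rep(1, 7); w[4] <- 1e-6
  fw <- solve_vector(matrix(y_bad, 1), angles, weights = matrix(w, 1))
  expect_equal(fw$v[1], v, tolerance = 1e-3)
  ## and with uniform weights it matches the unweighted solve
  fu <- solve_vector(matrix(y_bad, 1), angles,
                     weights = matrix(rep(1, 7), 1))
  f0 <- solve_vector(matrix(y_bad, 1), angles)
  expect_equal(fu$v[1], f0$v[1], tolerance = 1e-9)
})

test_that("full vector flow recovers speed and direction on the phantom", {
  sim <- clean_sim(7.2e-3, nx = 48, nz = 48, nt = 64)
  field <- hvmudi_vector_flow(sim$ensemble, sim$truth$mask, cutoff_hz = 2,
                              window = NULL)
  sel <- sim$truth$mask & field$valid[, , 1]
  expect_gt(sum(sel), 100)
  expect_equal(mean(field$v[, , 1][sel]), 7.2e-3, tolerance = 0.05)
  dir <- circular_mean(field$theta[, , 1][sel]) * 180 / pi
  expect_lt(abs(dir - 90), 2)
  ## empty mask: empty field
  f0 <- hvmudi_vector_flow(sim$ensemble, matrix(FALSE, 48, 48),
                           cutoff_hz = 2, window = NULL)
  expect_true(all(f0$v == 0))
  expect_false(any(f0$valid))
})

test_that("sliding-window vector flow is time-resolved at the frame rate", {
  sim <- clean_sim(5e-3, nx = 24, nz = 24, nt = 48)
  field <- hvmudi_vector_flow(sim$ensemble, sim$truth$mask, cutoff_hz = 2,
                              window = 10)
  expect_equal(dim(field$v)[3], 48 - 10 + 1)
  expect_equal(field$frame_rate_hz, 500)
})
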