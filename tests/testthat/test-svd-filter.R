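test_that("svd_decompose is an exact ordered complex SVD", {
  set.seed(3)
  ## rank-1 block has exactly one nonzero singular value
  u <- complex(real = rnorm(12), imaginary = rnorm(12))
  v <- complex(real = rnorm(6), imaginary = rnorm(6))
  dec1 <- svd_decompose(u %o% Conj(v))
  expect_equal(sum(dec1$d > 1e-10 * dec1$d[1]), 1)
  ## full-range reconstruction
  a <- matrix(complex(real = rnorm(16 * 8), imaginary = rnorm(16 * 8)), 16, 8)
  dec <- svd_decompose(a)
  rec <- dec$u %*% (dec$d * t(Conj(dec$v)))
  expect_lt(sqrt(fnorm2(rec - a) / fnorm2(a)), 1e-6)
  expect_true(all(diff(dec$d) <= 0))
  ## singular values match an eigen-decomposition of A^H A
  ev <- sort(sqrt(pmax(Re(eigen(t(Conj(a)) %*% a)$values), 0)),
             decreasing = TRUE)
  expect_equal(dec$d, ev, tolerance = 1e-10)
})

test_that("filter_block reconstructs the retained order range", {
  set.seed(4)
  a <- matrix(complex(real = rnorm(20 * 6), imaginary = rnorm(20 * 6)), 20, 6)
  dec <- svd_decompose(a)
  ## full range: identity
  expect_equal(filter_block(dec, list(t_l = 1, t_h = 6)), a,
               tolerance = 1e-10)
  ## rank-1 block with its only component excluded: zero
  r1 <- svd_decompose(dec$u[, 1] %o% rep(1 + 0i, 6))
  af <- filter_block(r1, list(t_l = 2, t_h = 6))
  expect_lt(max(Mod(af)), 1e-10 * r1$d[1])
  expect_error(filter_block(dec, list(t_l = 4, t_h = 3)), "threshold")
  ## energy split: rejected and retained subspaces are orthogonal
  af2 <- filter_block(dec, list(t_l = 3, t_h = 6))
  expect_equal(fnorm2(a), fnorm2(af2) + fnorm2(a - af2))
})

test_that("adaptive thresholds separate clutter, flow and noise", {
  ## constructed Casorati block: strong 2-component clutter (<= 5 Hz), a
  ## weak 50 Hz flow component, white noise; frame rate 500 Hz
  set.seed(11)
  nt <- 100; npx <- 400; t <- 0:(nt - 1)
  sp <- function() complex(real = rnorm(npx), imaginary = rnorm(npx))
  a <- 200 * sp() %o% exp(1i * 2 * pi * 2 * t / 500) +
    60 * sp() %o% exp(1i * 2 * pi * 4.5 * t / 500) +
    3 * sp() %o% exp(1i * 2 * pi * 50 * t / 500) +
    0.3 * matrix(complex(real = rnorm(npx * nt),
                         imaginary = rnorm(npx * nt)), npx, nt)
  th <- adaptive_thresholds(svd_decompose(a), 500, f_clutter_hz = 10)
  expect_lte(th$t_l, 3)
  expect_gte(th$t_h, 3)          # the 50 Hz component (order 3) is retained
  expect_false(th$fallback)

  ## pure white noise: plateau from order 1, fallback (2, N_t)
  nz <- matrix(complex(real = rnorm(npx * nt),
                       imaginary = rnorm(npx * nt)), npx, nt)
  thn <- adaptive_thresholds(svd_decompose(nz), 500)
  expect_identical(thn$t_l, 2L)
  expect_identical(thn$t_h, as.integer(nt))
  expect_true(thn$fallback)

  ## noiseless single-tone flow: no clutter precedes it
  tone <- sp() %o% exp(1i * 2 * pi * 50 * t / 500)
  tht <- adaptive_thresholds(svd_decompose(tone), 500)
  expect_identical(tht$t_l, 1L)
})

test_that("adaptive cutoff reads the lag-1 frequency of the T_L-th vector", {
  t <- 0:99
  make_dec <- function(v) {
    v <- v / sqrt(sum(Mod(v)^2))
    structure(list(u = NULL, d = 1, v = cbind(v)),
              class = "svd_decomposition")
  }
  ## 50 Hz complex exponential at FR 500
  expect_equal(adaptive_cutoff(make_dec(exp(1i * 2 * pi * 50 * t / 500)),
                               1, 500), 50, tolerance = 1e-9)
  ## constant vector: DC
  expect_equal(adaptive_cutoff(make_dec(rep(1 + 0i, 100)), 1, 500), 0)
  ## Nyquist tone clips just below FR/2
  fn <- adaptive_cutoff(make_dec(exp(1i * pi * t)), 1, 500)
  expect_lt(fn, 250)
  expect_gt(fn, 249.99)
  ## invariant to rescaling of the vector
  v <- exp(1i * 2 * pi * 31 * t / 500)
  expect_equal(adaptive_cutoff(make_dec(v), 1, 500),
               adaptive_cutoff(make_dec(17 * v), 1, 500))
})

test_that("block-wise recombination preserves flow and partitions unity", {
  ## rank-1 single-tone series: every block keeps it (T_L = 1), so the
  ## Hann-weighted recombination must return the input exactly — this
  ## exercises both the per-block identity and the partition of unity
  set.seed(5)
  nx <- 48; nt <- 40; t <- 0:(nt - 1)
  sp <- matrix(complex(real = rnorm(nx * nx), imaginary = rnorm(nx * nx)),
               nx, nx)
  arr <- array(as.vector(sp) %o% exp(1i * 2 * pi * 50 * t / 500),
               c(nx, nx, nt))
  ser <- series_from_array(arr)
  out <- blockwise_filter(ser, block_size = 16, overlap = 0.5)
  expect_equal(out$data, arr, tolerance = 1e-8)
  blog <- attr(out, "block_log")
  expect_true(all(blog$t_l == 1))

  ## overlap 0 with a block covering the whole frame equals filter_block
  ser2 <- series_from_array(arr + 0.1 * array(
    complex(real = rnorm(nx * nx * nt), imaginary = rnorm(nx * nx * nt)),
    c(nx, nx, nt)))
  one <- blockwise_filter(ser2, block_size = 64, overlap = 0)
  dec <- svd_decompose(matrix(ser2$data, nx * nx, nt))
  th <- adaptive_thresholds(dec, 500)
  ref <- filter_block(dec, th)
  expect_equal(one$data, array(ref, c(nx, nx, nt)), tolerance = 1e-8)

  expect_error(blockwise_filter(ser, overlap = 1), "overlap")
})

test_that("power image sums squared magnitudes over time", {
  z <- series_from_array(array(0i, c(3, 4, 5)))
  expect_equal(power_image(z), matrix(0, 3, 4))
  ones <- series_from_array(array(1i, c(3, 4, 1)))
  expect_equal(power_image(ones), matrix(1, 3, 4))
  set.seed(8)
  arr <- array(complex(real = rnorm(60), imaginary = rnorm(60)), c(3, 4, 5))
  ref <- matrix(0, 3, 4)
  for (t in 1:5) ref <- ref + Mod(arr[, , t])^2
  expect_equal(power_image(series_from_array(arr)), ref)
})

test_that("grid artifacts stay bounded at interior block boundaries", {
  ## simulated phantom frame, 90 % overlap: no pixel on an interior block
  ## boundary deviates from its 8-neighborhood mean power by > 6 dB
  sim <- clean_sim(7.2e-3, nx = 48, nz = 48, nt = 40)
  noisy <- sim$ensemble
  set.seed(2)
  noisy$data <- noisy$data + 0.1 *
    array(complex(real = rnorm(length(noisy$data)),
                  imaginary = rnorm(length(noisy$data))),
          dim(noisy$data))
  filt <- blockwise_filter(compound(iq_ensemble(noisy$data, noisy$config)),
                           block_size = 24, overlap = 0.9,
                           f_clutter_hz = 2)
  pw <- power_image(filt)
  pw_db <- 10 * log10(pw + max(pw) * 1e-9)
  inner <- which(sim$truth$mask, arr.ind = TRUE)
  inner <- inner[inner[, 1] > 1 & inner[, 1] < 48 &
                   inner[, 2] > 1 & inner[, 2] < 48, , drop = FALSE]
  for (k in seq_len(nrow(inner))) {
    i <- inner[k, 1]; j <- inner[k, 2]
    nb <- pw_db[(i - 1):(i + 1), (j - 1):(j + 1)]
    expect_lt(abs(pw_db[i, j] - mean(nb[-5])), 6)
  }
})
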