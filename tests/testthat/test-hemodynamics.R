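test_that("vascular density is the in-ROI pixel ratio", {
  mask <- matrix(FALSE, 10, 10); mask[1:5, 1:5] <- TRUE   # 25 px
  expect_equal(vascular_density(mask), 25)
  expect_equal(vascular_density(mask, mask), 100)
  roi <- matrix(FALSE, 10, 10)
  expect_error(vascular_density(mask, roi), "ROI")
  sv <- synth_vector_field("straight_vessel")
  expect_equal(vascular_density(sv$mask), sv$truth$density_percent)
})

test_that("FWHM diameters match closed forms", {
  cfg <- paper_config()
  pitch <- cfg$pixel_pitch_m[1]
  n <- 64
  ## Gaussian cross-section, sigma 20 um -> FWHM = 2 sqrt(2 ln 2) sigma
  sigma_m <- 20e-6
  z <- ((1:n) - 32.5) * pitch
  img_g <- matrix(rep(exp(-z^2 / (2 * sigma_m^2)), each = n), n, n)
  vm <- binarize_and_skeletonize(img_g, dr_db = 3)
  dg <- vessel_diameters(vm, img_g, cfg)
  expect_equal(dg$mean_m, 2 * sqrt(2 * log(2)) * sigma_m,
               tolerance = pitch / (2 * sqrt(2 * log(2)) * sigma_m))
  ## rectangular profile of width 100 um
  img_r <- matrix(0, n, n)
  half_w <- 50e-6
  img_r[, abs(z) <= half_w] <- 1
  vmr <- binarize_and_skeletonize(img_r, dr_db = 3)
  dr <- vessel_diameters(vmr, img_r, cfg)
  expect_equal(dr$mean_m, 100e-6, tolerance = pitch / 100e-6)
})

test_that("diameters grow when the vessel is dilated", {
  cfg <- paper_config()
  n <- 64
  img <- matrix(0, n, n); img[, 30:33] <- 1
  vm <- binarize_and_skeletonize(img)
  d1 <- vessel_diameters(vm, img, cfg)$mean_m
  img2 <- matrix(0, n, n); img2[, 29:34] <- 1
  d2 <- vessel_diameters(binarize_and_skeletonize(img2), img2, cfg)$mean_m
  expect_gt(d2, d1)
})

test_that("simulated 280 um tube measures within 10 %", {
  ## averaged over seeded repetitions and lightly smoothed so the FWHM is
  ## read from the vessel envelope rather than individual speckle grains
  pw <- 0
  for (s in 1:10)
    pw <- pw + power_image(compound(
      clean_sim(7.2e-3, nx = 64, nz = 64, nt = 30, seed = s)$ensemble))
  pw <- hvmudi:::gauss_smooth(pw / 10, 2.5)
  mask <- clean_sim(7.2e-3, nx = 64, nz = 64, nt = 2, seed = 1)$truth$mask
  sk <- hvmudi:::thin_mask(mask)
  vm <- list(skeleton = sk,
             orientation = hvmudi:::skeleton_orientation(sk))
  d <- vessel_diameters(vm, pw, paper_config())
  expect_lt(abs(d$mean_m - 280e-6) / 280e-6, 0.10)
})

test_that("trajectories follow the field", {
  sv <- synth_vector_field("straight_vessel", n = 60, n_frames = 4)
  cfg <- sv$config
  seeds <- cbind(5, 30)
  tr <- trajectories_from_field(sv$field, sv$mask, cfg, seeds = seeds,
                                max_len = 20, smooth_sigma = 0)
  expect_length(tr, 1)
  steps <- diff(tr[[1]])
  fr <- effective_frame_rate(cfg)
  ## uniform lateral field of speed s: straight path with spacing s/FR
  expect_true(all(abs(steps[, 1] - 5e-3 / fr) < 1e-9))
  expect_true(all(abs(steps[, 2]) < 1e-9))
  ## seed outside the mask yields nothing
  tr0 <- trajectories_from_field(sv$field, sv$mask, cfg,
                                 seeds = cbind(5, 5))
  expect_length(tr0, 0)
})

test_that("circular streamlines recover the rotation radius", {
  n <- 80
  cfg <- acq_config(40e6, 3500, seq(-3, 3),
                    pixel_pitch_m = c(1e-4, 1e-4))
  cx <- 40.5; cz <- 40.5
  omega <- 2
  vx <- vz <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dx <- (i - cx) * 1e-4; dz <- (j - cz) * 1e-4
    vx[i, j] <- -omega * dz
    vz[i, j] <- omega * dx
  }
  v <- sqrt(vx^2 + vz^2)
  th <- atan2(vx, vz)
  field <- vector_field(array(v, c(n, n, 1)), array(th, c(n, n, 1)),
                        frame_rate_hz = 500)
  mask <- matrix(TRUE, n, n)
  tr <- trajectories_from_field(field, mask, cfg, seeds = cbind(60, 41),
                                max_len = 150, smooth_sigma = 0)
  pts <- tr[[1]]
  r_true <- sqrt(((60 - cx) * 1e-4)^2 + ((41 - cz) * 1e-4)^2)
  r_obs <- sqrt((pts[, 1] - cx * 1e-4)^2 + (pts[, 2] - cz * 1e-4)^2)
  expect_lt(max(abs(r_obs - r_true)) / r_true, 0.05)
})

test_that("SOAM matches hand-computed values and is rigid-motion invariant", {
  expect_equal(soam(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))), 0)
  lpath <- rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 2))
  expect_equal(soam(lpath), (pi / 2) / 3, tolerance = 1e-12)
  ## rotation + translation invariance
  set.seed(19)
  traj <- apply(matrix(rnorm(12, sd = 0.3), 6, 2), 2, cumsum)
  ang <- 0.83
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  traj2 <- sweep(traj %*% rot, 2, c(3.2, -1.5), "+")
  expect_equal(soam(traj), soam(traj2), tolerance = 1e-10)
  ## undefined below 3 points
  expect_true(is.na(soam(rbind(c(0, 0), c(1, 1)))))
  ## the L_bend fixture carries its own ground truth
  sv <- synth_vector_field("L_bend")
  expect_equal(soam(sv$truth$trajectory), sv$truth$soam)
})

test_that("pulsatility index matches its definition", {
  expect_equal(pulsatility_index(rep(3, 10)), 0)
  tt <- seq(0, 1, length.out = 401)[-401]
  expect_equal(pulsatility_index(2 + sin(2 * pi * tt)), 1,
               tolerance = 1e-4)
  expect_true(is.na(pulsatility_index(c(-1, 1))))
  ## scale invariance
  tr <- 2 + sin(2 * pi * tt)
  expect_equal(pulsatility_index(5 * tr), pulsatility_index(tr))
  ## fixture ground truth (exactly one sampled period)
  sv <- synth_vector_field("pulsatile_trace")
  px <- which(sv$mask, arr.ind = TRUE)[1, ]
  trace <- sv$field$v[px[1], px[2], ]
  expect_equal(pulsatility_index(trace), sv$truth$pulsatility_index,
               tolerance = 1e-12)
})

test_that("reversal ratio counts sign changes beyond two", {
  sv <- synth_vector_field("straight_vessel", n = 40, n_frames = 8)
  r0 <- reversal_flow_ratio(sv$field, sv$mask)
  expect_equal(r0$ratio, 0)
  ## alternating field: every pixel reverses
  alt <- sv$field
  for (t in seq_len(dim(alt$v)[3]))
    alt$theta[, , t] <- alt$theta[, , t] * (-1)^(t + 1)
  r1 <- reversal_flow_ratio(alt, sv$mask)
  expect_equal(r1$ratio, 1)
  ## fixture: exactly 40 % of vessel pixels reverse
  rv <- synth_vector_field("reversing_trace", n_frames = 8)
  rr <- reversal_flow_ratio(rv$field, rv$mask)
  expect_equal(rr$ratio, rv$truth$reversal_ratio, tolerance = 1e-12)
  expect_error(reversal_flow_ratio(sv$field, matrix(FALSE, 40, 40)),
               "empty")
})

test_that("vessel classification follows the mean axial flow sign", {
  n <- 40
  mask <- matrix(FALSE, n, n); mask[10:30, 18:22] <- TRUE
  mk_field <- function(theta_val) {
    v <- array(0, c(n, n, 4)); th <- array(NA_real_, c(n, n, 4))
    for (t in 1:4) { v[, , t][mask] <- 2e-3; th[, , t][mask] <- theta_val }
    vector_field(v, th, array(rep(mask, 4), c(n, n, 4)),
                 frame_rate_hz = 500)
  }
  ## descending (+z): penetrating arteriole
  cd <- classify_vessels(mk_field(0), mask)
  expect_equal(cd$class, "penetrating_arteriole")
  ## ascending (-z): ascending venule
  ca <- classify_vessels(mk_field(pi), mask)
  expect_equal(ca$class, "ascending_venule")
  ## zero-mean oscillation: unclassified
  fo <- mk_field(0)
  for (t in 1:4) fo$theta[, , t][mask] <- if (t %% 2) 0 else pi
  expect_equal(classify_vessels(fo, mask)$class, "unclassified")
  ## negating the axial component flips classes
  fneg <- mk_field(0)
  fneg$theta <- pi - fneg$theta
  expect_equal(classify_vessels(fneg, mask)$class, "ascending_venule")
})

test_that("metrics report aggregates per ROI", {
  sv <- synth_vector_field("straight_vessel", n = 40, n_frames = 4)
  enh <- matrix(0, 40, 40); enh[sv$mask] <- 1
  vm <- binarize_and_skeletonize(enh)
  rep <- metrics_report(vm, enh, sv$field, paper_config())
  expect_equal(nrow(rep), 1)
  expect_true(rep$density_percent > 0 && rep$density_percent <= 100)
  expect_gte(rep$soam, 0)
})
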