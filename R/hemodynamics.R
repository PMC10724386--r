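#' Vascular density within a region of interest
#'
#' `100 * (vessel pixels inside the ROI) / (ROI pixels)`.
#'
#' @param mask logical vessel mask.
#' @param roi logical region of interest of the same size (default: whole
#'   image).
#' @return density in percent, in `[0, 100]`.
#' @export
vascular_density <- function(mask, roi = NULL) {
  mask <- as.matrix(mask)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  roi <- as.matrix(roi)
  stopifnot(identical(dim(mask), dim(roi)))
  n_roi <- sum(roi)
  if (n_roi == 0) stop("invalid ROI: empty region")
  100 * sum(mask & roi) / n_roi
}

## sample img along the normal of a skeleton pixel; returns the FWHM in
## meters or NA if fewer than two half-maximum crossings are found
fwhm_at <- function(img, i, j, orient, half_len_m, pitch_m, step_m) {
  nx_dir <- -sin(orient); nz_dir <- cos(orient)   # unit normal to the tangent
  n_half <- max(2L, ceiling(half_len_m / step_m))
  s <- seq(-n_half, n_half) * step_m
  xs <- i + s * nx_dir / pitch_m[1]
  zs <- j + s * nz_dir / pitch_m[2]
  prof <- bilinear(img, xs, zs)
  pk <- which.max(prof)
  half <- prof[pk] / 2
  if (prof[pk] <= 0) return(NA_real_)
  ## walk outward from the peak to the first half-maximum crossing each side
  left <- NA_real_
  if (pk >= 2) for (k in pk:2) {
    if (prof[k - 1] < half && prof[k] >= half) {
      f <- (prof[k] - half) / (prof[k] - prof[k - 1])
      left <- s[k] - f * step_m
      break
    }
  }
  right <- NA_real_
  if (pk < length(prof)) {
    for (k in seq(pk, length(prof) - 1)) {
      if (prof[k] >= half && prof[k + 1] < half) {
        f <- (prof[k] - half) / (prof[k] - prof[k + 1])
        right <- s[k] + f * step_m
        break
      }
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  right - left
}

#' Vessel diameters by full width at half maximum
#'
#' For each skeleton pixel, the enhanced intensity is sampled along the
#' segment normal to the local vessel orientation, centered on the
#' centerline. The diameter is the distance between the two half-maximum
#' crossings (located by linear interpolation). The initial segment
#' half-length is one wavelength `c / f_c`; if fewer than two crossings are
#' found the segment grows by 10 um, up to `max_grow` times, after which
#' the pixel is recorded as unresolved (`NA`) and excluded from the mean.
#'
#' @param vm a `vessel_mask` from [binarize_and_skeletonize()] (or a list
#'   with `skeleton` and `orientation`).
#' @param img enhanced intensity image used for the profile.
#' @param config an [acq_config()] (pixel pitch and wavelength).
#' @param max_grow maximum number of 10-um growth steps (default 10).
#' @return list with `diameter_m` (matrix, `NA` off-skeleton/unresolved)
#'   and `mean_m`.
#' @export
vessel_diameters <- function(vm, img, config, max_grow = 10) {
  stopifnot(inherits(config, "acq_config"))
  skel <- vm$skeleton
  if (!any(skel)) stop("empty skeleton")
  img <- as.matrix(img)
  pitch <- config$pixel_pitch_m
  wavelength <- config$sound_speed_m_s / config$center_frequency_hz
  step_m <- min(pitch) / 4
  pts <- which(skel, arr.ind = TRUE)
  dia <- matrix(NA_real_, nrow(img), ncol(img))
  n_skipped <- 0L
  for (k in seq_len(nrow(pts))) {
    i <- pts[k, 1]; j <- pts[k, 2]
    orient <- vm$orientation[i, j]
    if (is.na(orient)) { n_skipped <- n_skipped + 1L; next }
    half <- wavelength
    for (g in 0:max_grow) {
      d <- fwhm_at(img, i, j, orient, half, pitch, step_m)
      if (!is.na(d)) { dia[i, j] <- d; break }
      half <- half + 10e-6
    }
  }
  if (n_skipped > 0)
    hvmudi_log("vessel_diameters: skipped ", n_skipped,
               " skeleton pixels with undefined orientation")
  list(diameter_m = dia, mean_m = mean(dia, na.rm = TRUE))
}

#' Flow trajectories from a vector field
#'
#' Integrates the time-averaged vector field forward from each seed pixel
#' with the explicit first-order update `P_{k+1} = P_k + v(P_k) * dt`,
#' `dt = 1/FR`, the velocity looked up by bilinear interpolation of the
#' Gaussian-smoothed (sigma 2 px) component fields. A trajectory terminates
#' on mask exit, on speed below `speed_floor`, or at `max_len` points.
#'
#' @param field a [vector_field()] (any temporal extent; the temporal mean
#'   of the valid frames is integrated).
#' @param mask logical vessel mask.
#' @param config an [acq_config()] (frame rate, pixel pitch).
#' @param seeds integer matrix of seed pixels (rows = `(i, j)`); default all
#'   mask pixels.
#' @param max_len maximum trajectory length in points (default 200).
#' @param speed_floor minimum speed in m/s to keep integrating (default
#'   1e-5).
#' @param smooth_sigma Gaussian smoothing of the component fields in pixels
#'   (default 2).
#' @return list of trajectories, each an `n x 2` matrix of physical `(x, z)`
#'   positions in meters (single-point trajectories are dropped).
#' @export
trajectories_from_field <- function(field, mask, config, seeds = NULL,
                                    max_len = 200, speed_floor = 1e-5,
                                    smooth_sigma = 2) {
  stopifnot(inherits(field, "vector_field"), inherits(config, "acq_config"))
  comp <- mean_components(field)
  vx <- gauss_smooth(comp$vx, smooth_sigma)
  vz <- gauss_smooth(comp$vz, smooth_sigma)
  mask <- as.matrix(mask)
  fr <- field$frame_rate_hz %||% effective_frame_rate(config)
  dt <- 1 / fr
  pitch <- config$pixel_pitch_m
  if (is.null(seeds)) seeds <- which(mask, arr.ind = TRUE)
  out <- list()
  for (k in seq_len(nrow(seeds))) {
    i <- seeds[k, 1]; j <- seeds[k, 2]
    if (!mask[i, j]) next
    pos <- matrix(NA_real_, max_len, 2)
    p <- c((i - 0.5) * pitch[1], (j - 0.5) * pitch[2])
    for (n in seq_len(max_len)) {
      pos[n, ] <- p
      gi <- p[1] / pitch[1] + 0.5; gj <- p[2] / pitch[2] + 0.5
      if (gi < 1 || gi > nrow(mask) || gj < 1 || gj > ncol(mask)) break
      if (!mask[round(pmin(pmax(gi, 1), nrow(mask))),
                round(pmin(pmax(gj, 1), ncol(mask)))]) break
      v <- c(bilinear(vx, gi, gj), bilinear(vz, gi, gj))
      if (sqrt(sum(v^2)) < speed_floor) break
      p <- p + v * dt
    }
    traj <- pos[!is.na(pos[, 1]), , drop = FALSE]
    if (nrow(traj) >= 2) out[[length(out) + 1L]] <- traj
  }
  out
}

## temporal-mean Cartesian components (vx lateral, vz axial) of a field;
## direction convention: theta from +z toward +x
mean_components <- function(field) {
  d <- dim(field$v)
  if (length(d) == 2) d <- c(d, 1L)
  v <- array(field$v, d); th <- array(field$theta, d)
  vx <- v * sin(th); vz <- v * cos(th)
  vx[!field$valid] <- NA; vz[!field$valid] <- NA
  mx <- apply(vx, 1:2, function(x) mean(x, na.rm = TRUE))
  mz <- apply(vz, 1:2, function(x) mean(x, na.rm = TRUE))
  mx[is.nan(mx)] <- 0; mz[is.nan(mz)] <- 0
  list(vx = mx, vz = mz)
}

#' Sum of angles metric (SOAM) tortuosity
#'
#' Sum of the in-plane angles between consecutive step vectors along a
#' trajectory, `IP_k = acos(<V_{k-1}, V_k> / (|V_{k-1}| |V_k|))`, divided by
#' the total path length. Straight paths give 0; the metric is invariant to
#' rigid rotation and translation. Undefined (`NA`) for fewer than 3
#' points.
#'
#' @param traj `n x 2` matrix of ordered positions in meters.
#' @return tortuosity in radians per meter (non-negative), or `NA`.
#' @export
soam <- function(traj) {
  traj <- as.matrix(traj)
  n <- nrow(traj)
  if (n < 3) return(NA_real_)
  steps <- diff(traj)
  lens <- sqrt(rowSums(steps^2))
  if (any(lens == 0)) {
    keep <- lens > 0
    steps <- steps[keep, , drop = FALSE]
    lens <- lens[keep]
    if (nrow(steps) < 2) return(NA_real_)
  }
  u <- steps / lens
  dots <- pmin(1, pmax(-1, rowSums(u[-nrow(u), , drop = FALSE] *
                                     u[-1, , drop = FALSE])))
  sum(acos(dots)) / sum(lens)
}

#' Pulsatility index of a velocity trace
#'
#' `(max - min) / mean` of the signed per-frame velocity trace; gauges the
#' modulation of flow over the observation window. Reversals (negative
#' excursions) deepen the minimum because the trace is signed.
#'
#' @param trace numeric per-frame velocity values.
#' @return dimensionless index, or `NA` if the mean is zero.
#' @export
pulsatility_index <- function(trace) {
  trace <- as.numeric(trace)
  if (length(trace) < 1) stop("empty trace")
  m <- mean(trace)
  if (m == 0) return(NA_real_)
  (max(trace) - min(trace)) / m
}

## per-component sign-change count over time; exact zeros do not count
count_sign_changes <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Reversal-flow ratio
#'
#' A vessel pixel shows reversal flow when the sign of its horizontal or
#' vertical velocity component changes more than twice over the observation
#' window (after Gaussian smoothing of the component fields, sigma 2 px per
#' frame). The ratio is the number of reversal pixels over the number of
#' vessel pixels considered. Ties at exactly zero velocity do not count as
#' changes.
#'
#' @param field a [vector_field()] with a temporal axis (>= 4 frames).
#' @param mask logical vessel mask (the pixels considered).
#' @param smooth_sigma spatial smoothing per frame (default 2 px).
#' @return list with `ratio` in `[0, 1]` and the logical `reversal` map.
#' @export
reversal_flow_ratio <- function(field, mask, smooth_sigma = 2) {
  stopifnot(inherits(field, "vector_field"))
  d <- dim(field$v)
  if (length(d) < 3 || d[3] < 4)
    stop("need at least 4 frames to assess flow reversal")
  mask <- as.matrix(mask)
  if (!any(mask)) stop("empty vessel region")
  vx <- field$v * sin(field$theta)
  vz <- field$v * cos(field$theta)
  vx[!field$valid] <- 0; vz[!field$valid] <- 0
  for (t in seq_len(d[3])) {
    vx[, , t] <- gauss_smooth(vx[, , t], smooth_sigma)
    vz[, , t] <- gauss_smooth(vz[, , t], smooth_sigma)
  }
  pts <- which(mask, arr.ind = TRUE)
  rev_map <- matrix(FALSE, d[1], d[2])
  for (k in seq_len(nrow(pts))) {
    i <- pts[k, 1]; j <- pts[k, 2]
    rev_map[i, j] <- count_sign_changes(vx[i, j, ]) > 2 ||
      count_sign_changes(vz[i, j, ]) > 2
  }
  list(ratio = sum(rev_map) / nrow(pts), reversal = rev_map)
}

#' Classify vessel components as arterioles or venules
#'
#' Per connected vessel component, the sign of the temporal-mean axial
#' (vertical) velocity decides the class: descending flow (positive axial
#' component, penetrating into the tissue) marks a penetrating arteriole,
#' ascending flow an ascending venule; components whose mean axial velocity
#' is within `eps_frac` of their mean speed stay unclassified.
#'
#' @param field a [vector_field()].
#' @param mask logical vessel mask.
#' @param eps_frac dead-band as a fraction of component mean speed
#'   (default 0.05).
#' @return list with `labels` (integer component-label matrix from
#'   connected-component analysis) and `class` (character vector per
#'   component: `"penetrating_arteriole"`, `"ascending_venule"`,
#'   `"unclassified"`).
#' @export
classify_vessels <- function(field, mask, eps_frac = 0.05) {
  stopifnot(inherits(field, "vector_field"))
  mask <- as.matrix(mask)
  labels <- as.matrix(EBImage::bwlabel(mask))
  comp <- mean_components(field)
  n_comp <- max(labels)
  cls <- character(n_comp)
  for (cc in seq_len(n_comp)) {
    sel <- labels == cc
    vz <- comp$vz[sel]
    spd <- sqrt(comp$vx[sel]^2 + comp$vz[sel]^2)
    eps <- eps_frac * mean(spd)
    m <- mean(vz)
    cls[cc] <- if (m > eps) "penetrating_arteriole"
    else if (m < -eps) "ascending_venule"
    else "unclassified"
  }
  list(labels = labels, class = cls)
}

#' Hemodynamic metrics report
#'
#' Convenience wrapper computing the per-ROI summary: vascular density,
#' mean FWHM diameter, SOAM tortuosity (pixel-count-weighted over
#' trajectories), and per-class pulsatility index and reversal ratio.
#'
#' @param vm a `vessel_mask`.
#' @param enh enhanced image (diameter profiles).
#' @param field a [vector_field()].
#' @param config an [acq_config()].
#' @param rois named list of logical ROI matrices (default: whole image).
#' @return data frame with one row per ROI.
#' @export
metrics_report <- function(vm, enh, field, config,
                           rois = list(full = NULL)) {
  rows <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]] %||% matrix(TRUE, nrow(vm$mask), ncol(vm$mask))
    dens <- vascular_density(vm$mask, roi)
    dia <- vessel_diameters(vm, enh, config)
    trajs <- trajectories_from_field(field, vm$mask & roi, config,
                                     seeds = which(vm$skeleton & roi,
                                                   arr.ind = TRUE))
    soams <- vapply(trajs, soam, numeric(1))
    wts <- vapply(trajs, nrow, numeric(1))
    ok <- !is.na(soams)
    soam_mean <- if (any(ok)) sum(soams[ok] * wts[ok]) / sum(wts[ok]) else NA
    data.frame(roi = nm, density_percent = dens,
               mean_diameter_m = dia$mean_m, soam = soam_mean)
  })
  do.call(rbind, rows)
}
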