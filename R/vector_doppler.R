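## ---- zero-phase Butterworth filtering -------------------------------------

## steady-state initial conditions for a step input (transposed direct form
## II), so that filtering a constant gives its steady-state response exactly
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b)) - 1L
  a <- c(a, rep(0, n + 1L - length(a))) / a[1]
  b <- c(b, rep(0, n + 1L - length(b))) / a[1]
  comp_t <- rbind(-a[2:(n + 1)], cbind(diag(1, n - 1), rep(0, n - 1)))
  bvec <- b[2:(n + 1)] - a[2:(n + 1)] * b[1]
  solve(diag(1, n) - t(comp_t), bvec)
}

## IIR filter along the columns of x (rows = independent series), transposed
## direct form II, vectorized across rows; zi scales the per-series initial
## state. Handles complex x with real coefficients.
iir_rows <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b)) - 1L
  a <- c(a, rep(0, n + 1L - length(a)))
  b <- c(b, rep(0, n + 1L - length(b)))
  b <- b / a[1]; a <- a / a[1]
  nr <- nrow(x); nt <- ncol(x)
  zero <- if (is.complex(x)) 0i else 0
  z <- matrix(zero, nr, n)
  if (!is.null(zi)) z <- x[, 1] %o% zi
  y <- x
  for (t in seq_len(nt)) {
    xt <- x[, t]
    yt <- b[1] * xt + z[, 1]
    for (k in seq_len(n - 1)) z[, k] <- b[k + 1] * xt + z[, k + 1] - a[k + 1] * yt
    z[, n] <- b[n + 1] * xt - a[n + 1] * yt
    y[, t] <- yt
  }
  y
}

## zero-phase (forward-backward) filtering along columns with odd-extension
## padding (maximal, nt - 1) and steady-state initial conditions; removes DC
## exactly for a high-pass design
filtfilt_rows <- function(b, a, x) {
  nt <- ncol(x)
  padlen <- nt - 1L
  zi <- lfilter_zi(b, a)
  left <- 2 * x[, 1] - x[, seq(padlen + 1L, 2L), drop = FALSE]
  right <- 2 * x[, nt] - x[, seq(nt - 1L, nt - padlen), drop = FALSE]
  ext <- cbind(left, x, right)
  y <- iir_rows(b, a, ext, zi = zi)
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y <- iir_rows(b, a, y, zi = zi)
  y <- y[, rev(seq_len(ncol(y))), drop = FALSE]
  y[, seq(padlen + 1L, padlen + nt), drop = FALSE]
}

## orthonormal basis of the filter's slow homogeneous (transient) modes over
## an nt-sample record: for every pole whose settling time exceeds a third
## of the record, the decaying exponentials anchored at either end. Edge
## transients excited by the padding mismatch live in this span; projecting
## it out (I - Q Q^H) removes them without touching content far above the
## cutoff. Returns NULL when every pole settles within the record.
slow_mode_basis <- function(b, a, nt) {
  poles <- polyroot(rev(a / a[1]))
  tau <- -1 / log(pmin(Mod(poles), 1 - 1e-12))
  slow <- poles[tau > nt / 3]
  if (!length(slow)) return(NULL)
  t <- seq_len(nt) - 1
  modes <- cbind(vapply(slow, function(p) p^t, complex(nt)),
                 vapply(slow, function(p) p^(nt - 1 - t), complex(nt)))
  qr.Q(qr(modes))
}

#' Temporal high-pass filtering of a per-angle IQ ensemble
#'
#' Applies a fifth-order Butterworth high-pass along the slow-time (frame)
#' axis, zero-phase (forward-backward, so no group-delay bias enters the
#' lag-1 phase), independently at every pixel and every transmit angle. DC
#' is removed exactly.
#'
#' When the cutoff is low enough that the filter's settling time rivals the
#' record length (a 2 Hz fifth-order high-pass settles over ~130 frames at
#' 500 Hz), edge transients excited by the padding survive into the record
#' and would anchor the lag-1 phase toward zero; the slow homogeneous modes
#' of the filter (known a priori from its poles, anchored at each record
#' end) are therefore projected out after filtering.
#'
#' @param ensemble an [iq_ensemble()].
#' @param cutoff_hz high-pass cutoff in Hz, typically from
#'   [estimate_cutoff()]; must satisfy `0 < cutoff < FR/2`.
#' @param order filter order (default 5).
#' @return a filtered [iq_ensemble()].
#' @export
highpass_temporal <- function(ensemble, cutoff_hz, order = 5) {
  stopifnot(inherits(ensemble, "iq_ensemble"))
  fr <- effective_frame_rate(ensemble$config)
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fr / 2)
    stop("config error: cutoff must be in (0, FR/2) = (0, ", fr / 2, ") Hz")
  d <- dim(ensemble$data)
  if (d[3] < 3 * order)
    stop("length error: need at least ", 3 * order, " frames, got ", d[3])
  t0 <- Sys.time()
  bf <- signal::butter(order, cutoff_hz / (fr / 2), type = "high")
  q <- slow_mode_basis(bf$b, bf$a, d[3])
  out <- ensemble$data
  for (a in seq_len(d[4])) {
    x <- matrix(out[, , , a], d[1] * d[2], d[3])
    y <- filtfilt_rows(bf$b, bf$a, x)
    if (!is.null(q)) y <- y - (y %*% Conj(q)) %*% t(q)
    out[, , , a] <- array(y, d[1:3])
  }
  hvmudi_log("highpass_temporal: order ", order, " cutoff ",
             signif(cutoff_hz, 4), " Hz, ",
             signif(as.numeric(Sys.time() - t0), 3), " s")
  iq_ensemble(out, ensemble$config)
}

#' Lag-1 phase-shift maps per transmit angle
#'
#' Per pixel and per angle, the inter-frame phase shift is estimated from
#' the lag-1 autocorrelation `arg(sum_t s[t+1] conj(s[t]))` over a temporal
#' window. A sliding window of unit stride yields time-resolved maps; with
#' `window = NULL` a single window spans the full ensemble (the
#' time-averaged map appropriate for steady flow).
#'
#' @param ensemble a high-pass-filtered [iq_ensemble()].
#' @param window window length in frames (>= 2), or `NULL` for one window
#'   covering all frames.
#' @return list of class `phase_shift_map`: `phase` array
#'   `(N_x, N_z, N_w, NA)` in `(-pi, pi]`, `power` (window signal power),
#'   `r1_mod` (lag-1 autocorrelation magnitude, a coherent-signal weight)
#'   and `valid` (logical, `FALSE` where the window power vanishes).
#' @export
lag1_phase <- function(ensemble, window = NULL) {
  stopifnot(inherits(ensemble, "iq_ensemble"))
  d <- dim(ensemble$data)
  nt <- d[3]
  if (is.null(window)) window <- nt
  if (window < 2) stop("window must span at least 2 frames")
  if (window > nt) stop("window longer than the ensemble")
  nw <- nt - window + 1L
  npx <- d[1] * d[2]
  phase <- array(NA_real_, c(d[1], d[2], nw, d[4]))
  power <- array(NA_real_, c(d[1], d[2], nw, d[4]))
  r1mod <- array(NA_real_, c(d[1], d[2], nw, d[4]))
  for (a in seq_len(d[4])) {
    s <- matrix(ensemble$data[, , , a], npx, nt)
    pr <- s[, 2:nt, drop = FALSE] * Conj(s[, 1:(nt - 1), drop = FALSE])
    pw <- Mod(s)^2
    if (nw == 1L) {
      r1 <- rowSums(pr)
      phase[, , 1, a] <- array(Arg(r1), d[1:2])
      power[, , 1, a] <- array(rowMeans(pw), d[1:2])
      r1mod[, , 1, a] <- array(Mod(r1), d[1:2])
    } else {
      cs <- cbind(0i, t(apply(pr, 1, cumsum)))
      cp <- cbind(0, t(apply(pw, 1, cumsum)))
      for (w in seq_len(nw)) {
        r1 <- cs[, w + window - 1L] - cs[, w]
        phase[, , w, a] <- array(Arg(r1), d[1:2])
        power[, , w, a] <- array((cp[, w + window] - cp[, w]) / window,
                                 d[1:2])
        r1mod[, , w, a] <- array(Mod(r1), d[1:2])
      }
    }
  }
  structure(list(phase = phase, power = power, r1_mod = r1mod,
                 valid = power > 0, window = window,
                 config = ensemble$config),
            class = "phase_shift_map")
}

#' Axial velocity from phase shift
#'
#' The narrowband Doppler relation `v_axial = c FR phi / (4 pi f_c)`:
#' converts an inter-frame phase shift (radians, one compounded frame apart)
#' into an axial velocity in m/s. Phase `pi` maps to the unambiguous
#' (Nyquist) axial velocity limit.
#'
#' @param phase phase shift(s) in radians, any numeric shape.
#' @param config an [acq_config()].
#' @return axial velocity in m/s, same shape as `phase`.
#' @export
axial_velocity <- function(phase, config) {
  stopifnot(inherits(config, "acq_config"))
  fr <- effective_frame_rate(config)
  config$sound_speed_m_s * fr * phase / (4 * pi * config$center_frequency_hz)
}

#' Vector field container
#'
#' @param v non-negative speed array (m/s).
#' @param theta direction array (radians, measured from the +z axial axis
#'   toward +x; descending flow has positive axial component).
#' @param valid logical array of the same shape.
#' @param residual optional least-squares residual array.
#' @param frame_rate_hz optional temporal sampling of the field.
#' @return object of class `vector_field`.
#' @export
vector_field <- function(v, theta, valid = NULL, residual = NULL,
                         frame_rate_hz = NULL) {
  if (is.null(valid)) valid <- array(TRUE, dim(v) %||% length(v))
  structure(list(v = v, theta = theta, valid = valid, residual = residual,
                 frame_rate_hz = frame_rate_hz),
            class = "vector_field")
}

#' Multibeam least-squares vector velocity solve
#'
#' Per voxel, the per-angle axial velocities follow
#' `v_axial(theta_i) = v cos(theta_D + theta_i) = a cos(theta_i) - b
#' sin(theta_i)` with `a = v cos(theta_D)`, `b = v sin(theta_D)`. The pair
#' `(a, b)` is solved by linear least squares over all angles (columns
#' normalized first for conditioning at small angular spans), then
#' `v = sqrt(a^2 + b^2)`, `theta_D = atan2(b, a)`. At least two distinct
#' angles are required; accuracy grows with the angle count.
#'
#' With `weights`, a per-voxel weighted least squares is solved instead —
#' the pipeline passes the lag-1 autocorrelation magnitude per angle, so
#' angles whose Doppler line fell below the high-pass cutoff (and therefore
#' carry only noise) barely influence the fit, the standard coherent-power
#' weighting of ensemble autocorrelation velocimetry.
#'
#' @param v_axial array of per-angle axial velocities whose *last* axis is
#'   the angle axis (e.g. `(N_x, N_z, N_w, NA)`), or a matrix
#'   `(n_voxels, NA)`.
#' @param angles_deg transmit tilt angles in degrees.
#' @param weights optional non-negative per-voxel per-angle weights, same
#'   shape as `v_axial`; `NULL` (default) for the ordinary unweighted
#'   solve.
#' @param condition_bound voxels are flagged invalid if the (weighted)
#'   design condition number exceeds this bound (default 1e6).
#' @param residual_tol voxels with least-squares residual RMS above this
#'   tolerance (m/s) are flagged invalid (default `Inf`, disabled).
#' @return a [vector_field()] whose `v`, `theta`, `valid`, `residual` drop
#'   the angle axis. Voxels with all-zero projections get `v = 0` and an
#'   invalid direction.
#' @export
solve_vector <- function(v_axial, angles_deg, weights = NULL,
                         condition_bound = 1e6, residual_tol = Inf) {
  angles_deg <- as.numeric(angles_deg)
  n_ang <- length(angles_deg)
  if (n_ang < 2) stop("config error: need at least 2 angles")
  if (anyDuplicated(angles_deg))
    stop("singular design: angles must be distinct")
  dims <- dim(v_axial) %||% c(length(v_axial))
  if (dims[length(dims)] != n_ang)
    stop("last axis of v_axial (", dims[length(dims)],
         ") must match the angle count (", n_ang, ")")
  out_dim <- if (length(dims) > 1) dims[-length(dims)] else 1L
  y <- matrix(v_axial, prod(out_dim), n_ang)

  th <- angles_deg * pi / 180
  cth <- cos(th); sth <- -sin(th)

  if (is.null(weights)) {
    x <- cbind(cth, sth)
    norms <- sqrt(colSums(x^2))
    xn <- sweep(x, 2, norms, "/")
    sv <- svd(xn, nu = 0, nv = 0)$d
    cond_ok <- sv[2] > 0 && (sv[1] / sv[2]) <= condition_bound
    w <- solve(crossprod(xn), t(xn))
    beta_n <- y %*% t(w)
    beta <- sweep(beta_n, 2, norms, "/")
    fit <- beta_n %*% t(xn)
    a <- beta[, 1]; b <- beta[, 2]
    cond_bad <- rep(!cond_ok, nrow(y))
  } else {
    q <- matrix(weights, prod(out_dim), n_ang)
    if (any(q < 0)) stop("weights must be non-negative")
    qs <- rowSums(q)
    qs[qs == 0] <- 1
    q <- q / qs
    scc <- q %*% cth^2
    scs <- q %*% (cth * sth)
    sss <- q %*% sth^2
    yc <- (y * q) %*% cth
    ys <- (y * q) %*% sth
    det <- scc * sss - scs^2
    tr2 <- (scc + sss) / 2
    disc <- sqrt(pmax(tr2^2 - det, 0))
    lam_lo <- tr2 - disc
    cond_bad <- !(lam_lo > 0 &
                    (tr2 + disc) / pmax(lam_lo, .Machine$double.xmin) <=
                    condition_bound^2)
    det[det <= 0] <- NA
    a <- as.vector((sss * yc - scs * ys) / det)
    b <- as.vector((scc * ys - scs * yc) / det)
    fit <- outer(a, cth) + outer(b, sth)
  }
  resid <- sqrt(rowMeans((y - fit)^2))
  v <- sqrt(a^2 + b^2)
  theta <- atan2(b, a)
  zero <- rowSums(abs(y)) == 0
  v[zero] <- 0
  theta[zero] <- NA_real_
  valid <- !cond_bad & !zero & resid <= residual_tol & is.finite(v)
  v[!is.finite(v)] <- 0
  shape <- function(vec) array(vec, out_dim)
  vector_field(shape(v), shape(theta), shape(valid), shape(resid))
}

#' Full vector micro-Doppler velocity pipeline
#'
#' Composition of the vector-flow stages on a raw per-angle ensemble:
#' adaptive-cutoff Butterworth high-pass, lag-1 phase estimation per angle,
#' axial-velocity conversion, and the multibeam least-squares solve,
#' restricted to a vessel mask. The output's temporal sampling equals the
#' effective frame rate (sliding lag-1 window of unit stride).
#'
#' @param ensemble a raw [iq_ensemble()].
#' @param mask logical vessel mask `(N_x, N_z)` (from
#'   [binarize_and_skeletonize()] or ground truth), or `NULL` for the whole
#'   image.
#' @param cutoff_hz high-pass cutoff in Hz (from [estimate_cutoff()]).
#' @param window lag-1 window length in frames (default 10, i.e. 20 ms at
#'   500 Hz), or `NULL` for a single full-ensemble window (time-averaged
#'   map).
#' @param order Butterworth order (default 5).
#' @param weight_by_power if `TRUE` (default), the least squares is
#'   weighted per angle by the lag-1 autocorrelation magnitude (see
#'   [solve_vector()]).
#' @param condition_bound,residual_tol forwarded to [solve_vector()].
#' @return a [vector_field()] with dimensions `(N_x, N_z, N_w)`; voxels
#'   outside the mask are invalid with `v = 0`.
#' @export
hvmudi_vector_flow <- function(ensemble, mask = NULL, cutoff_hz,
                               window = 10, order = 5,
                               weight_by_power = TRUE,
                               condition_bound = 1e6, residual_tol = Inf) {
  stopifnot(inherits(ensemble, "iq_ensemble"))
  t0 <- Sys.time()
  d <- dim(ensemble$data)
  fr <- effective_frame_rate(ensemble$config)
  if (!is.null(mask) && mean(mask) < 0.5) {
    ## restrict filtering and phase estimation to the masked pixels
    if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fr / 2)
      stop("config error: cutoff must be in (0, FR/2)")
    if (d[3] < 3 * order)
      stop("length error: need at least ", 3 * order, " frames")
    idx <- which(as.logical(mask))
    bf <- signal::butter(order, cutoff_hz / (fr / 2), type = "high")
    q <- slow_mode_basis(bf$b, bf$a, d[3])
    nt <- d[3]; nm <- length(idx)
    nw <- if (is.null(window)) 1L else nt - window + 1L
    sub_phase <- array(NA_real_, c(nm, nw, d[4]))
    sub_r1 <- array(NA_real_, c(nm, nw, d[4]))
    for (a in seq_len(d[4])) {
      s <- matrix(ensemble$data[, , , a], d[1] * d[2], nt)[idx, ,
                                                           drop = FALSE]
      s <- filtfilt_rows(bf$b, bf$a, s)
      if (!is.null(q)) s <- s - (s %*% Conj(q)) %*% t(q)
      pr <- s[, 2:nt, drop = FALSE] * Conj(s[, 1:(nt - 1), drop = FALSE])
      if (nw == 1L) {
        r1 <- rowSums(pr)
        sub_phase[, 1, a] <- Arg(r1); sub_r1[, 1, a] <- Mod(r1)
      } else {
        cs <- cbind(0i, t(apply(pr, 1, cumsum)))
        for (w in seq_len(nw)) {
          r1 <- cs[, w + window - 1L] - cs[, w]
          sub_phase[, w, a] <- Arg(r1); sub_r1[, w, a] <- Mod(r1)
        }
      }
    }
    va <- axial_velocity(sub_phase, ensemble$config)
    sub <- solve_vector(va, ensemble$config$tilt_angles_deg,
                        weights = if (weight_by_power) sub_r1,
                        condition_bound = condition_bound,
                        residual_tol = residual_tol)
    full <- function(x, fill) {
      out <- array(fill, c(d[1] * d[2], nw))
      out[idx, ] <- x
      array(out, c(d[1], d[2], nw))
    }
    field <- vector_field(full(sub$v, 0), full(sub$theta, NA_real_),
                          full(sub$valid, FALSE) > 0,
                          full(sub$residual, NA_real_),
                          frame_rate_hz = fr)
    hvmudi_log("vector_flow (masked): ", nm, " voxels, cutoff ",
               signif(cutoff_hz, 4), " Hz, ",
               signif(as.numeric(Sys.time() - t0), 3), " s")
    return(field)
  }
  hp <- highpass_temporal(ensemble, cutoff_hz, order)
  pm <- lag1_phase(hp, window)
  va <- axial_velocity(pm$phase, ensemble$config)
  field <- solve_vector(va, ensemble$config$tilt_angles_deg,
                        weights = if (weight_by_power) pm$r1_mod,
                        condition_bound = condition_bound,
                        residual_tol = residual_tol)
  field$frame_rate_hz <- effective_frame_rate(ensemble$config)
  if (!is.null(mask)) {
    nw <- dim(field$v)[3]
    m3 <- array(rep(as.logical(mask), nw), dim(field$v))
    field$v[!m3] <- 0
    field$theta[!m3] <- NA_real_
    field$valid <- field$valid & m3
  }
  hvmudi_log("vector_flow: cutoff ", signif(cutoff_hz, 4), " Hz, window ",
             pm$window, ", ", signif(as.numeric(Sys.time() - t0), 3), " s")
  field
}
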