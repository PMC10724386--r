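#' Casorati matrix of a spatial block
#'
#' Reshapes a spatial block of a compounded series into a Casorati matrix:
#' one row per pixel of the block, one column per frame.
#'
#' @param series a `compounded_series` (see [compound()]).
#' @param x0,z0 1-based block origin (lateral, axial).
#' @param size block side length in pixels (`n_x = n_z`); clipped to the
#'   image if larger.
#' @return list of class `casorati_block` with the complex matrix `a`
#'   (`size^2` rows, `N_t` columns) and the origin.
#' @export
casorati_block <- function(series, x0 = 1, z0 = 1,
                           size = min(dim(series$data)[1:2])) {
  d <- dim(series$data)
  size <- min(size, d[1], d[2])
  stopifnot(x0 >= 1, z0 >= 1, x0 + size - 1 <= d[1], z0 + size - 1 <= d[2])
  blk <- series$data[x0:(x0 + size - 1), z0:(z0 + size - 1), , drop = FALSE]
  structure(list(a = matrix(blk, size * size, d[3]),
                 x0 = x0, z0 = z0, size = size),
            class = "casorati_block")
}

#' Complex SVD of a Casorati block
#'
#' Exact thin singular value decomposition `A = U diag(d) V^H` of the complex
#' Casorati matrix, with singular values sorted non-increasingly. `U` holds
#' the spatial and `V` the temporal singular vectors.
#'
#' @param block a [casorati_block()] or a complex matrix.
#' @return list of class `svd_decomposition` with `u`, `d`, `v`.
#' @export
svd_decompose <- function(block) {
  a <- if (inherits(block, "casorati_block")) block$a else as.matrix(block)
  if (ncol(a) < 2) stop("need at least 2 frames (columns) for SVD filtering")
  s <- svd(a)
  structure(list(u = s$u, d = s$d, v = s$v), class = "svd_decomposition")
}

## lag-1 autocorrelation of the columns of v: complex R1 and real R0
lag1_cols <- function(v) {
  n <- nrow(v)
  r1 <- colSums(v[2:n, , drop = FALSE] * Conj(v[1:(n - 1), , drop = FALSE]))
  r0 <- colSums(Mod(v)^2)
  list(r1 = r1, r0 = r0)
}

## mean Doppler frequency (signed, Hz) of each temporal singular vector:
## FR * arg(R1) / (2 pi)
mean_doppler_freq <- function(v, frame_rate_hz) {
  frame_rate_hz * Arg(lag1_cols(v)$r1) / (2 * pi)
}

## characteristic Doppler frequency magnitude (Hz) of each temporal singular
## vector: the second spectral moment about zero, sqrt(sum f^2 S(f) / sum S),
## from a Hann-windowed periodogram. Unlike the signed lag-1 mean it reads
## the tone frequency of spectrally *symmetric* components correctly (the
## signature of broadside, beam-perpendicular flow, whose mean Doppler
## frequency is zero), and unlike a lag-1 width estimator it keeps its
## frequency resolution ~1/T for slowly varying clutter components.
char_doppler_freq <- function(v, frame_rate_hz) {
  n <- nrow(v)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  s <- Mod(stats::mvfft(v * w))^2
  k <- seq_len(n) - 1
  f <- ifelse(k <= n / 2, k, k - n) * frame_rate_hz / n
  tot <- colSums(s)
  sqrt(colSums(f^2 * s) / pmax(tot, .Machine$double.xmin)) *
    (tot > 0)
}

#' Adaptive singular-value thresholds
#'
#' Chooses the retained singular-order range for clutter filtering from two
#' curves: the log-magnitude singular-value curve and the Doppler-frequency
#' curve of the temporal singular vectors.
#'
#' The low cutoff `t_l` is the smallest order at/after the first turning
#' point of `log10` singular values whose temporal vector has a
#' characteristic Doppler frequency above the clutter band `f_clutter_hz`;
#' the high cutoff `t_h` is
#' the order at which the log-magnitude curve flattens into the noise
#' plateau (5-point moving slope above `-plateau_tol` per order). If no
#' order passes the frequency rule the fallback is `(2, N_t)`; if the
#' selected `t_l` lands at/after the plateau, `t_l` is kept (clamped to at
#' least 2) and `t_h` extends to `N_t`, so clutter-only blocks still reject
#' every clutter component.
#'
#' @param dec an [svd_decompose()] result.
#' @param frame_rate_hz effective frame rate in Hz.
#' @param f_clutter_hz clutter band parameter in Hz (default 10).
#' @param plateau_tol plateau slope tolerance per order (default 0.01).
#' @return list of class `svd_thresholds`: `t_l`, `t_h`, `cutoff_hz` (the
#'   lag-1 cutoff of the `t_l`-th vector, see [adaptive_cutoff()]),
#'   `clutter_top_hz` (largest characteristic frequency among the rejected
#'   low orders, a diagnostic) and `fallback` (logical).
#' @export
adaptive_thresholds <- function(dec, frame_rate_hz, f_clutter_hz = 10,
                                plateau_tol = 0.01) {
  stopifnot(inherits(dec, "svd_decomposition"))
  d <- dec$d
  n <- length(d)
  if (max(d) <= 0) {   # degenerate all-zero block
    return(structure(list(t_l = 2L, t_h = n, cutoff_hz = 0,
                          clutter_top_hz = 0, fallback = TRUE),
                     class = "svd_thresholds"))
  }
  dl <- log10(pmax(d, max(d) * 1e-15))

  ## first turning point of the log-magnitude curve: the order at which the
  ## curvature of log10(d) first changes sign (end of the steep descent)
  tp <- 1L
  if (n >= 4) {
    d2 <- diff(dl, differences = 2)        # d2[j]: curvature around order j+1
    s <- sign(d2)
    chg <- which(s[-1] != s[-length(s)] & s[-1] != 0)
    if (length(chg)) tp <- chg[1] + 1L
  }

  ## noise plateau: first order where the 5-point moving slope flattens
  t_h <- n
  if (n >= 5) {
    k <- seq_len(n - 4)
    slope <- (dl[k + 4] - dl[k]) / 4
    flat <- which(slope > -plateau_tol)
    if (length(flat)) t_h <- flat[1]
  }

  freqs <- char_doppler_freq(dec$v, frame_rate_hz)
  cand <- which(seq_len(n) >= tp & freqs > f_clutter_hz)
  fallback <- FALSE
  if (!length(cand)) {
    t_l <- 2L; t_h <- n; fallback <- TRUE
  } else if (cand[1] >= t_h) {
    ## the frequency rule only found orders inside the noise plateau
    fallback <- TRUE
    if (t_h <= 2) {
      t_l <- 2L                 # plateau from the start: pure noise
    } else {
      t_l <- max(2L, min(cand[1], n - 1L))   # clutter-only: reject it all
    }
    t_h <- n
  } else {
    t_l <- cand[1]
  }
  t_l <- max(1L, min(t_l, n - 1L))
  t_h <- max(t_l + 1L, min(t_h, n))
  top <- if (t_l > 1) max(freqs[seq_len(t_l - 1)]) else 0
  structure(list(t_l = as.integer(t_l), t_h = as.integer(t_h),
                 cutoff_hz = cutoff_from_vector(dec$v[, t_l], frame_rate_hz),
                 clutter_top_hz = top, fallback = fallback),
            class = "svd_thresholds")
}

## spec formula: FR * |arg(sum v[t+1] conj v[t])| / (2 pi), clipped < FR/2
cutoff_from_vector <- function(v, frame_rate_hz) {
  if (length(v) < 2) stop("invalid input: need at least 2 samples")
  r1 <- sum(v[-1] * Conj(v[-length(v)]))
  f <- frame_rate_hz * abs(Arg(r1)) / (2 * pi)
  min(f, frame_rate_hz / 2 * (1 - 1e-12))
}

#' Adaptive high-pass cutoff frequency
#'
#' Lag-1 autocorrelation frequency of the `t_l`-th temporal singular vector:
#' `f_cut = FR * |arg(sum_t v[t+1] conj(v[t]))| / (2 pi)`, clipped to just
#' below the Nyquist frequency `FR/2`. This frequency marks the slow edge of
#' the retained blood subspace and seeds the Butterworth high-pass of the
#' vector-Doppler stage. Invariant to rescaling of the vector.
#'
#' @param dec an [svd_decompose()] result.
#' @param t_l low singular-order threshold (column of `V` to analyze).
#' @param frame_rate_hz effective frame rate in Hz.
#' @return cutoff frequency in Hz, `0 <= f < FR/2`.
#' @export
adaptive_cutoff <- function(dec, t_l, frame_rate_hz) {
  stopifnot(inherits(dec, "svd_decomposition"),
            t_l >= 1, t_l <= ncol(dec$v))
  cutoff_from_vector(dec$v[, t_l], frame_rate_hz)
}

#' Reconstruct a block from a singular-order range
#'
#' `A_f = U_delta diag(d_delta) V_delta^H` with `delta = t_l..t_h`: the
#' clutter components (orders below `t_l`) and, when `t_h < N_t`, the deep
#' noise tail are removed.
#'
#' @param dec an [svd_decompose()] result.
#' @param thresholds an [adaptive_thresholds()] result (or a list with
#'   `t_l`, `t_h`).
#' @return filtered complex Casorati matrix.
#' @export
filter_block <- function(dec, thresholds) {
  stopifnot(inherits(dec, "svd_decomposition"))
  delta <- seq.int(thresholds$t_l, thresholds$t_h)
  if (length(delta) < 1 || thresholds$t_l > thresholds$t_h ||
      thresholds$t_l < 1 || thresholds$t_h > length(dec$d))
    stop("invalid thresholds: empty or out-of-range retained order range")
  dec$u[, delta, drop = FALSE] %*%
    (dec$d[delta] * t(Conj(dec$v[, delta, drop = FALSE])))
}

## strictly positive Hann taper (Hann on n+2 points, ends dropped)
hann_taper <- function(n) {
  i <- seq_len(n)
  0.5 * (1 - cos(2 * pi * i / (n + 1)))
}

## block origins covering 1..n with side b and the given overlap; the last
## block is shifted inward to keep full size (no zero padding)
block_origins <- function(n, b, overlap) {
  if (b >= n) return(1L)
  step <- max(1L, as.integer(round(b * (1 - overlap))))
  pos <- seq.int(1L, n - b + 1L, by = step)
  if (tail(pos, 1) != n - b + 1L) pos <- c(pos, n - b + 1L)
  as.integer(pos)
}

## eigen-based temporal decomposition: right singular vectors and singular
## values of A from the N_t x N_t Gram matrix (cheaper than a full SVD when
## rows >> columns; U is never formed)
temporal_svd <- function(a) {
  g <- t(Conj(a)) %*% a
  e <- eigen(g, symmetric = TRUE)
  d <- sqrt(pmax(Re(e$values), 0))
  d[d < max(d) * 1e-6] <- 0     # null components (eigen noise ~1e-12 rel.)
  structure(list(u = NULL, d = d, v = e$vectors),
            class = "svd_decomposition")
}

#' Block-wise adaptive SVD clutter filtering
#'
#' Slides a square block (default 64 px, 90 % overlap) across the compounded
#' series; each block is Casorati-reshaped, SVD-filtered with its own
#' adaptive thresholds, and the filtered blocks are recombined as a
#' pixel-wise weighted average (separable Hann taper, weights summing to 1
#' everywhere), which suppresses grid-pattern artifacts at block borders.
#' Border blocks are shifted inward to keep full size.
#'
#' @param series a `compounded_series`.
#' @param block_size block side in pixels (default 64). Images smaller than
#'   the block are processed as a single whole-image block.
#' @param overlap fractional block overlap in `[0, 1)` (default 0.9).
#' @param f_clutter_hz clutter band parameter passed to
#'   [adaptive_thresholds()].
#' @param plateau_tol plateau tolerance passed to [adaptive_thresholds()].
#' @return filtered `compounded_series`; attribute `"block_log"` holds a
#'   data frame with per-block `x0`, `z0`, `t_l`, `t_h`, `f_cut_hz`,
#'   `clutter_top_hz`, `fallback`, and attribute `"cutoff_hz"` the global
#'   adaptive cutoff (median of per-block cutoffs, floored at
#'   `f_clutter_hz`).
#' @export
blockwise_filter <- function(series, block_size = 64, overlap = 0.90,
                             f_clutter_hz = 10, plateau_tol = 0.01) {
  stopifnot(inherits(series, "compounded_series"))
  if (overlap < 0 || overlap >= 1)
    stop("config error: overlap must be in [0, 1)")
  t0 <- Sys.time()
  d <- dim(series$data)
  b <- min(block_size, d[1], d[2])
  xo <- block_origins(d[1], b, overlap)
  zo <- block_origins(d[2], b, overlap)
  fr <- effective_frame_rate(series$config)
  w1 <- hann_taper(b)
  w2 <- outer(w1, w1)
  acc <- array(0i, d)
  wsum <- matrix(0, d[1], d[2])
  log_rows <- vector("list", length(xo) * length(zo))
  i <- 0L
  for (x0 in xo) for (z0 in zo) {
    i <- i + 1L
    xs <- x0:(x0 + b - 1L); zs <- z0:(z0 + b - 1L)
    a <- matrix(series$data[xs, zs, ], b * b, d[3])
    dec <- temporal_svd(a)
    th <- adaptive_thresholds(dec, fr, f_clutter_hz, plateau_tol)
    vd <- dec$v[, th$t_l:th$t_h, drop = FALSE]
    af <- a %*% vd %*% t(Conj(vd))      # == U_d D_d V_d^H since U_d D_d = A V_d
    acc[xs, zs, ] <- acc[xs, zs, ] +
      array(as.vector(af), c(b, b, d[3])) * as.vector(w2)
    wsum[xs, zs] <- wsum[xs, zs] + w2
    log_rows[[i]] <- data.frame(x0 = x0, z0 = z0, t_l = th$t_l, t_h = th$t_h,
                                f_cut_hz = th$cutoff_hz,
                                clutter_top_hz = th$clutter_top_hz,
                                fallback = th$fallback)
  }
  acc <- acc / as.vector(wsum)
  blog <- do.call(rbind, log_rows)
  out <- structure(list(data = acc, config = series$config),
                   class = "compounded_series")
  attr(out, "block_log") <- blog
  attr(out, "cutoff_hz") <- global_cutoff(blog, f_clutter_hz)
  hvmudi_log("blockwise_filter: ", paste(d, collapse = "x"), ", ",
             nrow(blog), " blocks of ", b, ", cutoff ",
             signif(attr(out, "cutoff_hz"), 4), " Hz, ",
             signif(as.numeric(Sys.time() - t0), 3), " s")
  out
}

## global scalar cutoff: median per-block cutoff, floored by the declared
## clutter band (the high-pass never dips into the band the threshold rule
## treats as clutter); blocks where the adaptive rule identified a flow
## component (non-fallback) are preferred
global_cutoff <- function(block_log, floor_hz) {
  keep <- !block_log$fallback
  f <- if (any(keep)) block_log$f_cut_hz[keep] else block_log$f_cut_hz
  max(stats::median(f), floor_hz)
}

#' Adaptive cutoff estimation over a block tiling
#'
#' Runs the adaptive threshold selection (without reconstruction) on a
#' tiling of Casorati blocks and returns the global cutoff frequency for the
#' vector-Doppler high-pass: the median over blocks of the per-block lag-1
#' cutoff, floored at the declared clutter band `f_clutter_hz`.
#'
#' @inheritParams blockwise_filter
#' @return list with `cutoff_hz` and the per-block data frame `blocks`.
#' @export
estimate_cutoff <- function(series, block_size = 64, overlap = 0,
                            f_clutter_hz = 10, plateau_tol = 0.01) {
  stopifnot(inherits(series, "compounded_series"))
  if (overlap < 0 || overlap >= 1)
    stop("config error: overlap must be in [0, 1)")
  d <- dim(series$data)
  b <- min(block_size, d[1], d[2])
  fr <- effective_frame_rate(series$config)
  rows <- list()
  for (x0 in block_origins(d[1], b, overlap))
    for (z0 in block_origins(d[2], b, overlap)) {
      a <- matrix(series$data[x0:(x0 + b - 1L), z0:(z0 + b - 1L), ],
                  b * b, d[3])
      th <- adaptive_thresholds(temporal_svd(a), fr, f_clutter_hz,
                                plateau_tol)
      rows[[length(rows) + 1L]] <-
        data.frame(x0 = x0, z0 = z0, t_l = th$t_l, t_h = th$t_h,
                   f_cut_hz = th$cutoff_hz,
                   clutter_top_hz = th$clutter_top_hz,
                   fallback = th$fallback)
    }
  blog <- do.call(rbind, rows)
  cut <- global_cutoff(blog, f_clutter_hz)
  hvmudi_log("estimate_cutoff: ", nrow(blog), " blocks, cutoff ",
             signif(cut, 4), " Hz")
  list(cutoff_hz = cut, blocks = blog)
}

#' Power (temporal-energy) image
#'
#' Per-pixel sum over frames of the squared signal magnitude of a filtered
#' series: the power Doppler image mapping vascular presence.
#'
#' @param series a `compounded_series`.
#' @return non-negative matrix `(N_x, N_z)`.
#' @export
power_image <- function(series) {
  stopifnot(inherits(series, "compounded_series"))
  d <- dim(series$data)
  matrix(rowSums(matrix(Mod(series$data)^2, d[1] * d[2], d[3])), d[1], d[2])
}
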