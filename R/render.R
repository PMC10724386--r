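#' Flow visualization
#'
#' Renders a vector field within a flow region as an image sequence.
#'
#' * `hsv`: per frame, the hue encodes flow direction on a 360-degree wheel
#'   and the saturation the speed (clipped at `v_display_max`); returns RGB
#'   frames.
#' * `particles`: a randomized particle distribution is initialized inside
#'   the flow region and advected by the field; particles leaving the
#'   region are eliminated and the population is replenished so particle
#'   density stays at or above 10 % of the flow-region pixel count;
#'   particle size is proportional to the local speed.
#' * `arrows`: arrows on a subsampled grid, lengths proportional to speed.
#'
#' Deterministic under a fixed seed.
#'
#' @param field a [vector_field()] (2-D or 3-D `v`).
#' @param mask logical flow-region mask.
#' @param mode `"hsv"`, `"particles"` or `"arrows"`.
#' @param n_frames frames to render (default: the field's temporal extent).
#' @param v_display_max speed mapped to full saturation / unit arrow length
#'   (default: 95th percentile of in-mask speed).
#' @param min_density particle mode: minimum particle count as a fraction
#'   of flow-region pixels (default 0.10).
#' @param grid_step arrow mode: grid subsampling in pixels (default 5).
#' @param seed RNG seed for particle placement.
#' @return list of class `flow_render`; `$frames` holds per-frame RGB
#'   arrays (`hsv`) or intensity rasters, `$particles` / `$arrows` the
#'   per-frame tables for those modes.
#' @export
render_flow <- function(field, mask, mode = c("hsv", "particles", "arrows"),
                        n_frames = NULL, v_display_max = NULL,
                        min_density = 0.10, grid_step = 5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "vector_field"))
  mask <- as.matrix(mask)
  d <- dim(field$v)
  if (length(d) == 2) d <- c(d, 1L)
  v <- array(field$v, d); th <- array(field$theta, d)
  nt <- if (is.null(n_frames)) d[3] else min(n_frames, d[3])
  if (is.null(v_display_max)) {
    sp <- v[array(rep(mask, d[3]), d)]
    v_display_max <- if (any(sp > 0)) stats::quantile(sp[sp > 0], 0.95) else 1
  }
  out <- list(mode = mode, frames = list())
  if (mode == "hsv") {
    for (t in seq_len(nt)) {
      hue <- (th[, , t] %% (2 * pi)) / (2 * pi)
      hue[is.na(hue)] <- 0
      sat <- pmin(v[, , t] / v_display_max, 1)
      sat[!mask] <- 0
      val <- matrix(as.numeric(mask), d[1], d[2])
      cols <- grDevices::hsv(hue, sat, val)
      rgb <- grDevices::col2rgb(cols) / 255
      out$frames[[t]] <- array(t(rgb), c(d[1], d[2], 3))
    }
  } else if (mode == "particles") {
    flow_px <- which(mask, arr.ind = TRUE)
    n_min <- ceiling(min_density * nrow(flow_px))
    fr <- field$frame_rate_hz %||% 500
    out$particles <- with_seed(seed, {
      pick <- flow_px[sample.int(nrow(flow_px), n_min), , drop = FALSE]
      px <- pick[, 1] + runif(n_min) - 0.5
      pz <- pick[, 2] + runif(n_min) - 0.5
      frames <- vector("list", nt)
      for (t in seq_len(nt)) {
        vx <- bilinear(v[, , t] * sin(th[, , t]) |>
                         (\(m) { m[is.na(m)] <- 0; m })(), px, pz)
        vz <- bilinear(v[, , t] * cos(th[, , t]) |>
                         (\(m) { m[is.na(m)] <- 0; m })(), px, pz)
        spd <- sqrt(vx^2 + vz^2)
        frames[[t]] <- data.frame(x = px, z = pz,
                                  size = spd / v_display_max,
                                  dir = atan2(vx, vz))
        ## advect in pixel units (isotropic display pitch)
        px <- px + vx / v_display_max
        pz <- pz + vz / v_display_max
        ## eliminate particles beyond the flow region
        ii <- round(pmin(pmax(px, 1), d[1]))
        jj <- round(pmin(pmax(pz, 1), d[2]))
        keep <- px >= 1 & px <= d[1] & pz >= 1 & pz <= d[2] &
          mask[cbind(ii, jj)]
        px <- px[keep]; pz <- pz[keep]
        ## respawn to hold the density contract
        n_need <- n_min - length(px)
        if (n_need > 0) {
          pick <- flow_px[sample.int(nrow(flow_px), n_need,
                                     replace = TRUE), , drop = FALSE]
          px <- c(px, pick[, 1] + runif(n_need) - 0.5)
          pz <- c(pz, pick[, 2] + runif(n_need) - 0.5)
        }
      }
      frames
    })
    out$frames <- lapply(out$particles, function(pf) {
      ras <- matrix(0, d[1], d[2])
      ii <- round(pmin(pmax(pf$x, 1), d[1]))
      jj <- round(pmin(pmax(pf$z, 1), d[2]))
      ras[cbind(ii, jj)] <- pmax(ras[cbind(ii, jj)], pmin(pf$size, 1))
      ras
    })
  } else {
    gi <- seq(1, d[1], by = grid_step)
    gj <- seq(1, d[2], by = grid_step)
    out$arrows <- vector("list", nt)
    for (t in seq_len(nt)) {
      pts <- expand.grid(i = gi, j = gj)
      pts <- pts[mask[cbind(pts$i, pts$j)], , drop = FALSE]
      sp <- v[, , t][cbind(pts$i, pts$j)]
      ag <- th[, , t][cbind(pts$i, pts$j)]
      len <- sp / v_display_max * grid_step
      out$arrows[[t]] <- data.frame(i = pts$i, j = pts$j,
                                    di = len * sin(ag), dj = len * cos(ag))
      ras <- matrix(0, d[1], d[2])
      ras[cbind(pts$i, pts$j)] <- pmin(sp / v_display_max, 1)
      out$frames[[t]] <- ras
    }
  }
  structure(out, class = "flow_render")
}
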