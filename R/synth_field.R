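#' Synthetic mask / vector-field scenarios with known metrics
#'
#' Generates a vessel mask, a per-frame vector field, and the analytically
#' known hemodynamic metric values for a named scenario — fixtures for
#' metric-level tests independent of the imaging pipeline:
#'
#' * `straight_vessel`: one horizontal vessel of width 10 px spanning the
#'   frame; steady lateral flow. Density, diameter, SOAM = 0, PI = 0,
#'   reversal = 0 known exactly.
#' * `L_bend`: an L-shaped vessel; ground truth carries the canonical
#'   L-path trajectory and its SOAM.
#' * `pulsatile_trace`: straight vessel whose speed trace is
#'   `2 + sin(2 pi t / T)` (arbitrary units) sampled over exactly one
#'   period, so the pulsatility index is exactly `(3 - 1)/2 = 1`.
#' * `reversing_trace`: two disjoint parallel vessels; the smaller one
#'   (40 % of vessel pixels) alternates flow sign `+,-,+,-` (3 sign
#'   changes), the larger one is steady, so the reversal ratio is exactly
#'   0.40.
#' * `Y_junction`: a vessel bifurcating into two branches; density known by
#'   construction.
#'
#' @param scenario one of `"straight_vessel"`, `"L_bend"`,
#'   `"pulsatile_trace"`, `"reversing_trace"`, `"Y_junction"`.
#' @param n frame side in pixels (default 100).
#' @param n_frames temporal extent (default 40).
#' @param speed_m_s base flow speed (default 5e-3).
#' @param seed RNG seed (scenarios are deterministic given the seed).
#' @return list with `mask`, `field` (a [vector_field()] of shape
#'   `(n, n, n_frames)`), `config` (an [acq_config()]) and `truth`
#'   (named list of metric values; `NA` where a metric is not defined for
#'   the scenario).
#' @export
synth_vector_field <- function(scenario, n = 100, n_frames = 40,
                               speed_m_s = 5e-3, seed = 1) {
  scenarios <- c("straight_vessel", "L_bend", "pulsatile_trace",
                 "reversing_trace", "Y_junction")
  if (!scenario %in% scenarios)
    stop("config error: unknown scenario \"", scenario, "\"; choose one of ",
         paste(scenarios, collapse = ", "))
  config <- acq_config(40e6, 3500, seq(-3, 3))
  mask <- matrix(FALSE, n, n)
  v <- array(0, c(n, n, n_frames))
  th <- array(NA_real_, c(n, n, n_frames))
  truth <- list(density_percent = NA, diameter_px = NA, soam = NA,
                pulsatility_index = NA, reversal_ratio = NA)
  mid <- n %/% 2
  band <- (mid - 4):(mid + 5)                       # 10 px wide

  if (scenario == "straight_vessel") {
    mask[, band] <- TRUE
    v[rep(mask, n_frames)] <- speed_m_s
    th[rep(mask, n_frames)] <- pi / 2               # lateral (+x) flow
    truth$density_percent <- 100 * sum(mask) / n^2
    truth$diameter_px <- length(band)
    truth$soam <- 0
    truth$pulsatility_index <- 0
    truth$reversal_ratio <- 0
  } else if (scenario == "L_bend") {
    mask[1:mid, band] <- TRUE                       # horizontal arm
    mask[(mid - 4):(mid + 5), mid:n] <- TRUE        # vertical arm
    for (t in seq_len(n_frames)) {
      v[, , t][mask] <- speed_m_s
      horiz <- mask & col(mask) <= mid
      th[, , t][horiz] <- pi / 2
      th[, , t][mask & !horiz] <- 0                 # axial (+z) flow
    }
    lpath <- rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 2))
    truth$trajectory <- lpath
    truth$soam <- (pi / 2) / 3
    truth$density_percent <- 100 * sum(mask) / n^2
  } else if (scenario == "pulsatile_trace") {
    mask[, band] <- TRUE
    trace <- 2 + sin(2 * pi * (seq_len(n_frames) - 1) / n_frames)
    for (t in seq_len(n_frames)) {
      v[, , t][mask] <- speed_m_s * trace[t]
      th[, , t][mask] <- pi / 2
    }
    truth$speed_trace <- speed_m_s * trace
    truth$pulsatility_index <- (max(trace) - min(trace)) / mean(trace)
    truth$density_percent <- 100 * sum(mask) / n^2
  } else if (scenario == "reversing_trace") {
    stopifnot(n_frames >= 4)
    rev_band <- 11:20
    std_band <- 61:70
    rev_mask <- matrix(FALSE, n, n); rev_mask[1:40, rev_band] <- TRUE
    std_mask <- matrix(FALSE, n, n); std_mask[1:60, std_band] <- TRUE
    mask <- rev_mask | std_mask
    signs <- rep_len(c(1, -1), n_frames)            # +,-,+,- : 3+ changes
    for (t in seq_len(n_frames)) {
      v[, , t][mask] <- speed_m_s
      th[, , t][std_mask] <- pi / 2
      th[, , t][rev_mask] <- if (signs[t] > 0) pi / 2 else -pi / 2
    }
    truth$reversal_ratio <- sum(rev_mask) / sum(mask)
    truth$density_percent <- 100 * sum(mask) / n^2
  } else if (scenario == "Y_junction") {
    mask[1:mid, (mid - 2):(mid + 2)] <- TRUE        # stem
    for (k in 0:(mid - 6)) {                        # two diverging branches
      i <- mid + k
      mask[i, pmax(1, mid - 2 - k):pmin(n, mid + 2 - k)] <- TRUE
      mask[i, pmax(1, mid - 2 + k):pmin(n, mid + 2 + k)] <- TRUE
    }
    for (t in seq_len(n_frames)) {
      v[, , t][mask] <- speed_m_s
      stem <- mask & row(mask) <= mid
      th[, , t][stem] <- pi / 2
      upper <- mask & !stem & col(mask) < mid
      th[, , t][mask & !stem] <- pi / 2 + pi / 4
      th[, , t][upper] <- pi / 2 - pi / 4
    }
    truth$density_percent <- 100 * sum(mask) / n^2
  }

  valid <- array(rep(mask, n_frames), c(n, n, n_frames))
  v[!valid] <- 0
  field <- vector_field(v, th, valid,
                        frame_rate_hz = effective_frame_rate(config))
  list(mask = mask, field = field, config = config, truth = truth)
}
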