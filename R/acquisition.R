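#' Acquisition configuration
#'
#' Bundles the transmit and physics constants of an ultrafast plane-wave
#' acquisition: center frequency, pulse repetition frequency (PRF), the
#' ordered tilt angles of the transmitted plane waves, speed of sound, and
#' the pixel pitch of the beamformed grid. The effective (compounded) frame
#' rate derives from PRF and the number of angles; see
#' [effective_frame_rate()].
#'
#' @param center_frequency_hz transmit center frequency f_c in Hz
#'   (e.g. `40e6` for a 40 MHz high-frequency probe).
#' @param prf_hz pulse repetition frequency in Hz (per transmitted angle).
#' @param tilt_angles_deg strictly increasing vector of plane-wave tilt
#'   angles in degrees; a positive angle tilts the wavefront toward +x.
#' @param sound_speed_m_s speed of sound c in m/s (default 1540).
#' @param pixel_pitch_m length-2 numeric `(lateral, axial)` pixel pitch in
#'   meters; defaults to half a wavelength in both directions.
#' @return an object of class `acq_config`.
#' @examples
#' cfg <- acq_config(40e6, 3500, seq(-3, 3))
#' effective_frame_rate(cfg)  # 500 Hz
#' @export
acq_config <- function(center_frequency_hz, prf_hz, tilt_angles_deg,
                       sound_speed_m_s = 1540,
                       pixel_pitch_m = NULL) {
  stopifnot(is.numeric(center_frequency_hz), length(center_frequency_hz) == 1,
            is.finite(center_frequency_hz), center_frequency_hz > 0,
            is.numeric(prf_hz), length(prf_hz) == 1,
            is.finite(prf_hz), prf_hz > 0,
            is.numeric(sound_speed_m_s), sound_speed_m_s > 0)
  tilt_angles_deg <- as.numeric(tilt_angles_deg)
  if (length(tilt_angles_deg) < 1 || anyNA(tilt_angles_deg))
    stop("invalid config: need at least one finite tilt angle")
  if (length(tilt_angles_deg) > 1 && any(diff(tilt_angles_deg) <= 0))
    stop("invalid config: tilt angles must be strictly increasing")
  if (is.null(pixel_pitch_m)) {
    wl <- sound_speed_m_s / center_frequency_hz
    pixel_pitch_m <- c(wl / 2, wl / 2)
  }
  pixel_pitch_m <- as.numeric(pixel_pitch_m)
  stopifnot(length(pixel_pitch_m) == 2, all(pixel_pitch_m > 0))
  structure(
    list(center_frequency_hz = center_frequency_hz,
         prf_hz = prf_hz,
         tilt_angles_deg = tilt_angles_deg,
         sound_speed_m_s = sound_speed_m_s,
         pixel_pitch_m = pixel_pitch_m),
    class = "acq_config")
}

#' @export
print.acq_config <- function(x, ...) {
  cat("<acq_config>\n",
      "  fc    : ", x$center_frequency_hz / 1e6, " MHz\n",
      "  PRF   : ", x$prf_hz, " Hz\n",
      "  angles: ", paste(x$tilt_angles_deg, collapse = ", "), " deg\n",
      "  c     : ", x$sound_speed_m_s, " m/s\n",
      "  pitch : ", paste(signif(x$pixel_pitch_m * 1e6, 4), collapse = " x "),
      " um\n",
      "  FR    : ", effective_frame_rate(x), " Hz\n", sep = "")
  invisible(x)
}

#' Effective compounded frame rate
#'
#' One compounded frame needs one transmit per tilt angle, so the effective
#' frame rate is `prf_hz / NA` where `NA` is the number of angles (e.g.
#' PRF 3500 Hz with seven angles gives 500 Hz).
#'
#' @param config an [acq_config()].
#' @return frame rate in Hz.
#' @export
effective_frame_rate <- function(config) {
  stopifnot(inherits(config, "acq_config"))
  n_angles <- length(config$tilt_angles_deg)
  if (n_angles < 1) stop("invalid config: zero angle count")
  config$prf_hz / n_angles
}
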