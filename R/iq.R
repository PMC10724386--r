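#' Per-angle IQ ensemble
#'
#' A 4-D complex lattice of beamformed in-phase/quadrature data with axes
#' (lateral x, axial z, frame t, transmit angle), plus its acquisition
#' configuration. The pipeline's raw input.
#'
#' @param data complex 4-D array `(N_x, N_z, N_t, NA)`.
#' @param config an [acq_config()]; its angle count must equal `dim(data)[4]`.
#' @return an object of class `iq_ensemble`.
#' @export
iq_ensemble <- function(data, config) {
  stopifnot(inherits(config, "acq_config"))
  if (!is.array(data) || length(dim(data)) != 4)
    stop("data error: IQ data must be a 4-D array (x, z, t, angle)")
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (any(dim(data) < 1)) stop("data error: all four extents must be >= 1")
  if (dim(data)[4] != length(config$tilt_angles_deg))
    stop("data error: 4th extent (", dim(data)[4],
         ") does not match config angle count (",
         length(config$tilt_angles_deg), ")")
  if (anyNA(data) || any(!is.finite(Re(data)) | !is.finite(Im(data))))
    stop("data error: non-finite IQ values")
  structure(list(data = data, config = config), class = "iq_ensemble")
}

#' @export
print.iq_ensemble <- function(x, ...) {
  d <- dim(x$data)
  cat("<iq_ensemble> ", d[1], " x ", d[2], " px, ", d[3], " frames, ",
      d[4], " angles\n", sep = "")
  invisible(x)
}

#' Coherent plane-wave compounding
#'
#' Sums the complex per-angle IQ data over the angle axis, frame by frame,
#' producing one compounded movie at the effective frame rate. Compounding is
#' linear in the input.
#'
#' @param ensemble an [iq_ensemble()].
#' @return a `compounded_series`: list with complex 3-D `data`
#'   `(N_x, N_z, N_t)` and the `config`.
#' @export
compound <- function(ensemble) {
  stopifnot(inherits(ensemble, "iq_ensemble"))
  t0 <- Sys.time()
  d <- dim(ensemble$data)
  out <- array(0i, d[1:3])
  for (a in seq_len(d[4])) out <- out + ensemble$data[, , , a, drop = FALSE][, , , 1]
  hvmudi_log("compound: ", paste(d, collapse = "x"), " -> ",
             paste(d[1:3], collapse = "x"), " in ",
             signif(as.numeric(Sys.time() - t0), 3), " s")
  structure(list(data = out, config = ensemble$config),
            class = "compounded_series")
}

#' @export
print.compounded_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<compounded_series> ", d[1], " x ", d[2], " px, ", d[3],
      " frames @ ", effective_frame_rate(x$config), " Hz\n", sep = "")
  invisible(x)
}
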