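## Self-describing single-file container: 8-byte magic, 8-byte header length,
## UTF-8 JSON header (array names/dims/types + metadata attributes), then the
## raw payloads (little-endian, doubles; complex stored as re,im pairs).

CONTAINER_MAGIC <- "HVMUDI01"

CONFIG_KEYS <- c("center_frequency_hz", "prf_hz", "tilt_angles_deg",
                 "sound_speed_m_s", "pixel_pitch_m")

#' Write named arrays to an hvmudi container
#'
#' Low-level writer behind [write_iq()] and [write_vector_field()]. Arrays are
#' stored losslessly as little-endian doubles (complex as interleaved
#' real/imaginary); metadata travels in a JSON header.
#'
#' @param path destination file path.
#' @param arrays named list of numeric or complex arrays.
#' @param meta named list of metadata attributes (scalars or numeric
#'   vectors).
#' @return `path`, invisibly.
#' @export
write_hvm <- function(path, arrays, meta = list()) {
  stopifnot(is.list(arrays), length(arrays) > 0,
            !is.null(names(arrays)), all(nzchar(names(arrays))))
  header <- list(
    magic = CONTAINER_MAGIC,
    arrays = lapply(arrays, function(a) {
      list(dim = if (is.null(dim(a))) length(a) else dim(a),
           type = if (is.complex(a)) "complex" else "double")
    }),
    meta = meta)
  hjson <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA)
  hraw <- charToRaw(as.character(hjson))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  writeBin(as.numeric(length(hraw)), con, size = 8, endian = "little")
  writeBin(hraw, con)
  for (a in arrays) {
    if (is.complex(a)) {
      writeBin(as.vector(rbind(Re(a), Im(a))), con, size = 8,
               endian = "little")
    } else {
      writeBin(as.numeric(a), con, size = 8, endian = "little")
    }
  }
  invisible(path)
}

#' Read an hvmudi container
#'
#' @param path file written by [write_hvm()].
#' @return list with elements `arrays` (named list) and `meta`.
#' @export
read_hvm <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- rawToChar(readBin(con, "raw", 8))
  if (!identical(magic, CONTAINER_MAGIC))
    stop("format error: bad magic, not an hvmudi container: ", path)
  hlen <- readBin(con, "numeric", 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  arrays <- list()
  for (nm in names(header$arrays)) {
    spec <- header$arrays[[nm]]
    n <- prod(spec$dim)
    if (identical(spec$type, "complex")) {
      v <- readBin(con, "numeric", 2 * n, size = 8, endian = "little")
      a <- complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
    } else {
      a <- readBin(con, "numeric", n, size = 8, endian = "little")
    }
    if (length(spec$dim) > 1) dim(a) <- spec$dim
    arrays[[nm]] <- a
  }
  list(arrays = arrays, meta = as.list(header$meta))
}

#' Write an IQ ensemble to disk
#'
#' Stores the complex 4-D dataset under the name `"iq"` (axis order x, z, t,
#' angle) together with every acquisition attribute, so the file is
#' self-describing and round-trips bit-exactly through [read_iq()].
#'
#' @param ensemble an [iq_ensemble()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_iq <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "iq_ensemble"))
  cfg <- ensemble$config
  write_hvm(path, arrays = list(iq = ensemble$data),
            meta = cfg[CONFIG_KEYS])
  invisible(path)
}

#' Read an IQ ensemble from disk
#'
#' Validates that all acquisition attributes are present (a missing key is a
#' format error naming the key) and that the angle count matches the fourth
#' extent of the stored dataset.
#'
#' @param path file written by [write_iq()].
#' @return an [iq_ensemble()].
#' @export
read_iq <- function(path) {
  h <- read_hvm(path)
  if (is.null(h$arrays$iq))
    stop("format error: container has no \"iq\" dataset")
  for (key in CONFIG_KEYS) {
    if (is.null(h$meta[[key]]))
      stop("format error: missing metadata key \"", key, "\"")
  }
  n_angle_attr <- length(h$meta$tilt_angles_deg)
  n_angle_data <- dim(h$arrays$iq)[4]
  if (n_angle_attr != n_angle_data)
    stop("format error: angle-count attribute (", n_angle_attr,
         ") does not match 4th extent (", n_angle_data, ")")
  cfg <- acq_config(center_frequency_hz = h$meta$center_frequency_hz,
                    prf_hz = h$meta$prf_hz,
                    tilt_angles_deg = h$meta$tilt_angles_deg,
                    sound_speed_m_s = h$meta$sound_speed_m_s,
                    pixel_pitch_m = h$meta$pixel_pitch_m)
  iq_ensemble(h$arrays$iq, cfg)
}

#' Write a vector field container
#'
#' Stores the per-voxel speed (`"v_mag"`, m/s), direction (`"v_dir"`,
#' radians) and validity flag (`"valid"`) datasets of a [vector_field].
#'
#' @param field a `vector_field` (see [solve_vector()]).
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_vector_field <- function(field, path) {
  stopifnot(inherits(field, "vector_field"))
  write_hvm(path,
            arrays = list(v_mag = field$v, v_dir = field$theta,
                          valid = array(as.numeric(field$valid),
                                        dim(field$valid))),
            meta = list(frame_rate_hz = field$frame_rate_hz %||% NA_real_))
  invisible(path)
}
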