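#' Pipeline logging
#'
#' Stage-level INFO logging. Messages are emitted with [message()] when
#' `options(hvmudi.verbose = TRUE)` (default off so test output stays clean).
#'
#' @param ... objects pasted into the log line.
#' @return invisibly, the log line.
#' @export
hvmudi_log <- function(...) {
  line <- paste0("[hvmudi] ", paste0(..., collapse = ""))
  if (isTRUE(getOption("hvmudi.verbose", FALSE))) message(line)
  invisible(line)
}

## run expr with a private RNG stream seeded by `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

## complex circular Gaussian noise, unit mean power
crandn <- function(n) {
  complex(real = stats::rnorm(n, sd = sqrt(0.5)),
          imaginary = stats::rnorm(n, sd = sqrt(0.5)))
}

## 2-D Gaussian smoothing that tolerates complex matrices and images
## smaller than the nominal kernel (the kernel is clipped to the image)
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- ceiling(3 * sigma)
  half <- min(half, (min(dim(x)) - 1L) %/% 2L)
  if (half < 1) return(x)
  g <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  if (is.complex(x)) {
    re <- EBImage::filter2(Re(x), k, boundary = "replicate")
    im <- EBImage::filter2(Im(x), k, boundary = "replicate")
    matrix(complex(real = re, imaginary = im), nrow(x), ncol(x))
  } else {
    as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
  }
}

## bilinear interpolation of matrix img at fractional (x, z) 1-based indices
bilinear <- function(img, x, z) {
  nx <- nrow(img); nz <- ncol(img)
  x <- pmin(pmax(x, 1), nx); z <- pmin(pmax(z, 1), nz)
  x0 <- pmin(floor(x), nx - 1L); z0 <- pmin(floor(z), nz - 1L)
  fx <- x - x0; fz <- z - z0
  img[cbind(x0, z0)]         * (1 - fx) * (1 - fz) +
    img[cbind(x0 + 1, z0)]     * fx     * (1 - fz) +
    img[cbind(x0, z0 + 1)]     * (1 - fx) * fz +
    img[cbind(x0 + 1, z0 + 1)] * fx     * fz
}

`%||%` <- function(a, b) if (is.null(a)) b else a
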