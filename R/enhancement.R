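#' Bowler-hat morphological vessel transform
#'
#' Difference of two banks of grayscale openings: disk-shaped structuring
#' elements of radius `r = 1..r_max` versus line-shaped elements of
#' half-length `r` swept over `phi_count` orientations spanning
#' `[0, 180)` degrees. A line element fits inside an elongated structure and
#' preserves it where a disk of the same radius cannot, so
#' `max_r (max_phi open_line - open_disk)` responds on curvilinear (vessel)
#' structures and vanishes on flat fields and on blobs wider than `2 r_max`.
#' Negative responses are clipped to zero.
#'
#' @param img non-negative 2-D image matrix.
#' @param r_max maximum structuring radius in pixels (default 30).
#' @param phi_count number of line orientations (default 12, i.e. 15-degree
#'   steps).
#' @return enhanced image matrix, same size, with attribute
#'   `"provenance" = "bowlerhat"`.
#' @export
bowler_hat <- function(img, r_max = 30, phi_count = 12) {
  img <- as.matrix(img)
  if (any(img < 0)) stop("bowler_hat expects a non-negative image")
  if (r_max < 1 || phi_count < 4) stop("config error: r_max >= 1, phi_count >= 4")
  if (2 * r_max + 1 > min(dim(img)))
    stop("config error: r_max too large for the image")
  t0 <- Sys.time()
  angles <- seq(0, 180, length.out = phi_count + 1)[seq_len(phi_count)]
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(r_max)) {
    side <- 2L * r + 1L
    id_r <- EBImage::opening(img, EBImage::makeBrush(side, shape = "disc"))
    il_r <- matrix(-Inf, nrow(img), ncol(img))
    for (phi in angles) {
      il_r <- pmax(il_r, line_opening(img, r, phi))
    }
    out <- pmax(out, as.matrix(il_r) - as.matrix(id_r))
  }
  out <- pmax(out, 0)
  hvmudi_log("bowler_hat: r_max ", r_max, ", ", phi_count, " orientations, ",
             signif(as.numeric(Sys.time() - t0), 3), " s")
  attr(out, "provenance") <- "bowlerhat"
  out
}

#' Vesselness response for an eigenvalue pair
#'
#' The curvilinear-structure score for Hessian eigenvalues ordered
#' `|lambda2| >= |lambda1|`: zero when `lambda2 > 0` (dark tubular or no
#' structure), otherwise
#' `exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-(l1^2 + l2^2) / (2 alpha^2)))`.
#' The first factor favors elongated (anisotropic) curvature, the second
#' suppresses low-energy (background) responses. `lambda2 = 0` gives 0 (the
#' flat-field limit).
#'
#' @param l1,l2 eigenvalue arrays with `|l2| >= |l1|`.
#' @param alpha structureness sensitivity (default 2).
#' @param beta anisotropy sensitivity (default 1).
#' @return response in `[0, 1)`, same shape.
#' @export
vesselness_response <- function(l1, l2, alpha = 2, beta = 1) {
  stopifnot(alpha > 0, beta > 0)
  rb2 <- ifelse(l2 == 0, 0, (l1 / l2)^2)
  s2 <- l1^2 + l2^2
  out <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * alpha^2)))
  out[l2 >= 0] <- 0
  out
}

## Gaussian second-derivative kernels at scale sigma (sigma^2-normalized)
hessian_kernels <- function(sigma) {
  h <- ceiling(4 * sigma)
  x <- matrix(-h:h, 2 * h + 1, 2 * h + 1)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  list(gxx = sigma^2 * g * (x^2 - sigma^2) / sigma^4,
       gxy = sigma^2 * g * x * y / sigma^4,
       gyy = sigma^2 * g * (y^2 - sigma^2) / sigma^4)
}

#' Hessian-based vessel enhancement
#'
#' Multiscale Frangi-style vesselness: at each scale the image is convolved
#' with Gaussian second-derivative kernels (scale-normalized by `sigma^2`),
#' the Hessian eigenvalues are ordered by magnitude, and
#' [vesselness_response()] is evaluated; the output is the maximum over
#' scales. The input is normalized to unit maximum first so the fixed
#' sensitivity parameters act on a consistent intensity scale.
#'
#' @param img 2-D image matrix.
#' @param alpha,beta sensitivity parameters (defaults 2 and 1).
#' @param sigmas Gaussian scales in pixels (default `c(1, 1.5, 2)`).
#' @return vesselness image in `[0, 1)` with attribute
#'   `"provenance" = "vesselness"`.
#' @export
hessian_vesselness <- function(img, alpha = 2, beta = 1,
                               sigmas = c(1, 1.5, 2)) {
  img <- as.matrix(img)
  if (length(sigmas) < 1 || any(sigmas <= 0) || is.unsorted(sigmas))
    stop("config error: sigmas must be positive ascending")
  if (!all(is.finite(img))) stop("non-finite input image")
  mx <- max(img)
  if (mx > 0) img <- img / mx
  out <- matrix(0, nrow(img), ncol(img))
  for (sg in sigmas) {
    kk <- hessian_kernels(sg)
    hxx <- as.matrix(EBImage::filter2(img, kk$gxx, boundary = "replicate"))
    hxy <- as.matrix(EBImage::filter2(img, kk$gxy, boundary = "replicate"))
    hyy <- as.matrix(EBImage::filter2(img, kk$gyy, boundary = "replicate"))
    half <- (hxx + hyy) / 2
    rad <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    e_lo <- half - rad
    e_hi <- half + rad
    big <- abs(e_hi) >= abs(e_lo)             # |l2| >= |l1|
    l2 <- ifelse(big, e_hi, e_lo)
    l1 <- ifelse(big, e_lo, e_hi)
    out <- pmax(out, vesselness_response(l1, l2, alpha, beta))
  }
  attr(out, "provenance") <- "vesselness"
  out
}

#' Enhanced vascular image
#'
#' The enhancement chain applied to an SVD-filtered power image: bowler-hat
#' transform (suppresses non-elongated background) followed by Hessian
#' vesselness (penalizes residual noise). Output is non-negative.
#'
#' @param img power image from [power_image()].
#' @param r_max,phi_count bowler-hat parameters (see [bowler_hat()]).
#' @param alpha,beta,sigmas vesselness parameters (see
#'   [hessian_vesselness()]).
#' @return enhanced image with attribute `"provenance" = "enhanced"`.
#' @export
enhance <- function(img, r_max = 30, phi_count = 12,
                    alpha = 2, beta = 1, sigmas = c(1, 1.5, 2)) {
  bh <- bowler_hat(img, r_max, phi_count)
  out <- hessian_vesselness(bh, alpha, beta, sigmas)
  attr(out, "provenance") <- "enhanced"
  out
}

## pixel offsets of a rasterized line segment of half-length r at the given
## angle (degrees from the +x axis)
line_offsets <- function(r, angle_deg) {
  th <- angle_deg * pi / 180
  t <- seq(-r, r, by = 0.5)
  unique(cbind(round(t * cos(th)), round(t * sin(th))))
}

## shift with a constant fill value
shift_fill <- function(m, di, dj, fill) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(fill, n1, n2)
  si <- seq_len(n1) - di; sj <- seq_len(n2) - dj
  ok_i <- si >= 1 & si <= n1; ok_j <- sj >= 1 & sj <= n2
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

## grayscale opening by a line segment (erosion then dilation over the same
## symmetric segment), computed from shifted minima/maxima; pixels outside
## the image are ignored, so flat fields stay flat
line_opening <- function(img, r, angle_deg) {
  off <- line_offsets(r, angle_deg)
  er <- matrix(Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(off)))
    er <- pmin(er, shift_fill(img, -off[k, 1], -off[k, 2], Inf))
  op <- matrix(-Inf, nrow(img), ncol(img))
  for (k in seq_len(nrow(off)))
    op <- pmax(op, shift_fill(er, off[k, 1], off[k, 2], -Inf))
  op
}

## shift a logical/numeric matrix by (di, dj), zero fill
shift_mat <- function(m, di, dj) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  si <- seq_len(n1) - di; sj <- seq_len(n2) - dj
  ok_i <- si >= 1 & si <= n1; ok_j <- sj >= 1 & sj <= n2
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

## Zhang-Suen thinning to a 1-pixel medial-axis skeleton
thin_mask <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, -1, 1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, 1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- m == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- m == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  ## break any residual 2x2 all-on squares (keep the skeleton 1 px thin)
  repeat {
    sq <- m == 1 & shift_mat(m, -1, 0) == 1 & shift_mat(m, 0, -1) == 1 &
      shift_mat(m, -1, -1) == 1
    if (!any(sq)) break
    idx <- which(sq, arr.ind = TRUE)[1, , drop = FALSE]
    m[idx] <- 0
  }
  m == 1
}

## principal-axis orientation (radians from +x, in [0, pi)) of the skeleton
## neighborhood around each skeleton pixel, window w x w
skeleton_orientation <- function(skel, w = 7) {
  h <- (w - 1L) %/% 2L
  pts <- which(skel, arr.ind = TRUE)
  orient <- matrix(NA_real_, nrow(skel), ncol(skel))
  for (k in seq_len(nrow(pts))) {
    i <- pts[k, 1]; j <- pts[k, 2]
    ii <- max(1, i - h):min(nrow(skel), i + h)
    jj <- max(1, j - h):min(ncol(skel), j + h)
    nb <- which(skel[ii, jj, drop = FALSE], arr.ind = TRUE)
    if (nrow(nb) < 2) next
    xy <- cbind(nb[, 1], nb[, 2])
    xy <- sweep(xy, 2, colMeans(xy))
    cv <- crossprod(xy) / nrow(xy)
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
    ang <- atan2(ev[2], ev[1])
    if (ang < 0) ang <- ang + pi
    if (ang >= pi) ang <- ang - pi
    orient[i, j] <- ang
  }
  orient
}

#' Binarize and skeletonize an enhanced image
#'
#' The vascular mask keeps pixels within the top `dr_db` decibels below the
#' image maximum (`I > I_max * 10^(-dr_db/10)`); the mask is thinned to a
#' 1-pixel medial-axis skeleton and each skeleton pixel is assigned the
#' principal-axis orientation of its local skeleton neighborhood.
#'
#' @param enh enhanced image matrix.
#' @param dr_db dynamic-range threshold in dB (default 3).
#' @param orientation_window local window side for the orientation estimate
#'   (default 7).
#' @return list of class `vessel_mask`: logical `mask`, logical `skeleton`
#'   (a subset of the mask), and `orientation` (radians from +x in
#'   `[0, pi)`, `NA` off the skeleton). An all-zero image yields an empty
#'   mask.
#' @export
binarize_and_skeletonize <- function(enh, dr_db = 3, orientation_window = 7) {
  enh <- as.matrix(enh)
  mx <- max(enh)
  if (mx <= 0) {
    empty <- matrix(FALSE, nrow(enh), ncol(enh))
    return(structure(list(mask = empty, skeleton = empty,
                          orientation = matrix(NA_real_, nrow(enh),
                                               ncol(enh))),
                     class = "vessel_mask"))
  }
  mask <- enh > mx * 10^(-dr_db / 10)
  skel <- thin_mask(mask)
  structure(list(mask = mask, skeleton = skel,
                 orientation = skeleton_orientation(skel,
                                                    orientation_window)),
            class = "vessel_mask")
}
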