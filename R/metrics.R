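#' Signal-to-noise ratio (dB)
#'
#' \eqn{SNR = 10 \log_{10}(\sum T^2 / \sum (T - R)^2)}, with the squared
#' reconstructed image in the numerator. `reference = "true"` switches the
#' numerator to \eqn{\sum R^2}.
#'
#' @param T reconstructed image.
#' @param R true image.
#' @param reference `"recon"` (default, as-printed form) or `"true"`.
#' @return SNR in dB. Identical images are an error (infinite SNR).
#' @export
snr <- function(T, R, reference = c("recon", "true")) {
  reference <- match.arg(reference)
  stopifnot(identical(dim(T), dim(R)))
  den <- sum((T - R)^2)
  if (den == 0) stop("images are identical: SNR is infinite")
  num <- if (reference == "recon") sum(T^2) else sum(R^2)
  10 * log10(num / den)
}

#' Normalized mean squared error
#'
#' \eqn{NMSE = \sum (T_i - R_i)^2 / \sum T_i^2}.
#'
#' @inheritParams snr
#' @export
nmse <- function(T, R) {
  stopifnot(identical(dim(T), dim(R)))
  den <- sum(T^2)
  if (den == 0) stop("zero denominator: reconstructed image is all zero")
  sum((T - R)^2) / den
}

#' Structural similarity (global form)
#'
#' Single-window SSIM computed from the global means, variances and
#' covariance of the two images:
#' \deqn{SSIM = \frac{(2\bar T \bar R + c_1)(2\sigma_{TR} + c_2)}
#'   {(\bar T^2 + \bar R^2 + c_1)(\sigma_T^2 + \sigma_R^2 + c_2)}}
#' with \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2}. Equals 1 exactly for
#' identical images.
#'
#' @inheritParams snr
#' @param k1,k2 stability constants (defaults 0.01 and 0.03).
#' @param L dynamic range of the intensities; defaults to
#'   `max(R) - min(R)` (or 1 if the true image is constant).
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(T, R, k1 = 0.01, k2 = 0.03, L = NULL) {
  stopifnot(identical(dim(T), dim(R)))
  if (is.null(L)) L <- max(R) - min(R)
  if (L <= 0) L <- 1
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  mT <- mean(T); mR <- mean(R)
  vT <- var(as.numeric(T)); vR <- var(as.numeric(R))
  cTR <- stats::cov(as.numeric(T), as.numeric(R))
  ((2 * mT * mR + c1) * (2 * cTR + c2)) /
    ((mT^2 + mR^2 + c1) * (vT + vR + c2))
}

#' ROI standard deviation of reconstruction error
#'
#' \eqn{SD = \frac{1}{\bar R} \sqrt{\frac{1}{n-1} \sum_{i \in mask}
#' (T_i - R_i)^2}}, where \eqn{\bar R} is the true-image mean over the mask.
#' An SD of the pixel-wise differences normalized by the true mean — not an
#' ensemble SD over noise realizations; `roi_ensemble_sd()` provides that
#' alternative reading.
#'
#' @inheritParams snr
#' @param mask logical ROI mask with at least 2 pixels.
#' @export
roi_sd <- function(T, R, mask) {
  stopifnot(identical(dim(T), dim(R)), identical(dim(mask), dim(R)))
  n <- sum(mask)
  if (n < 2) stop("mask must contain at least 2 pixels")
  Rbar <- mean(R[mask])
  if (Rbar == 0) stop("true-image ROI mean is zero")
  sqrt(sum((T[mask] - R[mask])^2) / (n - 1)) / Rbar
}

#' Ensemble ROI standard deviation across realizations
#'
#' Mean over ROI pixels of the across-realization standard deviation,
#' normalized by the across-realization ROI mean.
#'
#' @param images list of reconstructed images (one per noise realization).
#' @param mask logical ROI mask.
#' @export
roi_ensemble_sd <- function(images, mask) {
  stopifnot(length(images) >= 2)
  vals <- vapply(images, function(im) im[mask], numeric(sum(mask)))
  mean(apply(vals, 1, sd)) / mean(vals)
}

#' Contrast recovery coefficient
#'
#' \deqn{CRC = \frac{\bar T_{ROI} / \bar T_{BGD} - 1}
#'              {\bar R_{ROI} / \bar R_{BGD} - 1}}
#' the reconstructed ROI contrast divided by the true ROI contrast; 1 when
#' the reconstruction reproduces the true contrast exactly, and invariant
#' to global scaling of the reconstructed image.
#'
#' @inheritParams snr
#' @param roi_mask logical ROI (e.g. tumor) mask.
#' @param bgd_mask logical background mask, disjoint from the ROI.
#' @export
crc <- function(T, R, roi_mask, bgd_mask) {
  stopifnot(identical(dim(T), dim(R)))
  if (!any(roi_mask) || !any(bgd_mask)) stop("ROI and background masks must be nonempty")
  true_contrast <- mean(R[roi_mask]) / mean(R[bgd_mask]) - 1
  if (true_contrast == 0) stop("true ROI and background means are equal")
  (mean(T[roi_mask]) / mean(T[bgd_mask]) - 1) / true_contrast
}

#' Line profile through an image
#'
#' Samples intensities along the segment from `p0` to `p1` (row, col
#' coordinates, endpoints inclusive) with bilinear interpolation.
#'
#' @param image numeric matrix.
#' @param p0,p1 numeric `c(row, col)` endpoints, inside the image.
#' @param n number of samples; default one per pixel of segment length.
#' @return data.frame with `distance`, `row`, `col`, `value`.
#' @export
line_profile <- function(image, p0, p1, n = NULL) {
  dm <- dim(image)
  for (p in list(p0, p1)) {
    if (p[1] < 1 || p[1] > dm[1] || p[2] < 1 || p[2] > dm[2]) {
      stop("profile endpoint (", p[1], ", ", p[2], ") outside image")
    }
  }
  len <- sqrt(sum((p1 - p0)^2))
  if (is.null(n)) n <- max(2L, ceiling(len) + 1L)
  tseq <- seq(0, 1, length.out = n)
  rr <- p0[1] + tseq * (p1[1] - p0[1])
  cc <- p0[2] + tseq * (p1[2] - p0[2])
  r0 <- pmin(floor(rr), dm[1] - 1); c0 <- pmin(floor(cc), dm[2] - 1)
  fr <- rr - r0; fc <- cc - c0
  v <- image[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
       image[cbind(r0 + 1, c0)] * fr * (1 - fc) +
       image[cbind(r0, c0 + 1)] * (1 - fr) * fc +
       image[cbind(r0 + 1, c0 + 1)] * fr * fc
  data.frame(distance = tseq * len, row = rr, col = cc, value = v)
}

#' Evaluation ROIs for the phantom
#'
#' Tumor ROI = the tumor mask. SD region = white matter. CRC background =
#' a white-matter annulus around the tumor: white-matter pixels whose
#' distance from the tumor centre lies in
#' `(tumor_radius + margin, tumor_radius + margin + width]`, keeping the
#' comparison local while excluding tumor spill-over.
#'
#' @param phantom a [brain_phantom()].
#' @param margin pixels excluded around the tumor rim (default 2).
#' @param width annulus width in pixels (default 10).
#' @return list of logical masks: `tumor`, `white_matter`, `crc_background`.
#' @export
roi_set <- function(phantom, margin = 2, width = 10) {
  stopifnot(inherits(phantom, "phantom"))
  g <- phantom$grid_size
  rw <- matrix(seq_len(g), g, g)
  cl <- matrix(seq_len(g), g, g, byrow = TRUE)
  d2 <- (rw - phantom$tumor_center[1])^2 + (cl - phantom$tumor_center[2])^2
  inner <- phantom$tumor_radius + margin
  outer <- inner + width
  ann <- phantom$masks$white_matter & d2 > inner^2 & d2 <= outer^2
  list(tumor = phantom$masks$tumor,
       white_matter = phantom$masks$white_matter,
       crc_background = ann)
}

#' Full metrics report for one reconstructed frame
#'
#' @param T reconstructed image.
#' @param R true image.
#' @param rois a [roi_set()].
#' @return one-row data.frame with `snr`, `nmse`, `ssim`, `sd`, `crc`.
#' @export
metrics_report <- function(T, R, rois) {
  data.frame(
    snr = if (identical(T, R)) Inf else snr(T, R),
    nmse = nmse(T, R),
    ssim = ssim(T, R),
    sd = roi_sd(T, R, rois$white_matter),
    crc = crc(T, R, rois$tumor, rois$crc_background)
  )
}
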