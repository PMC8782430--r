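#' Quantize a gray-level patch
#'
#' Normalizes a nonnegative patch to integer gray levels in `[1, n_levels]`
#' via `floor(f * n_levels / f_max) + 1`, where `f_max` is the patch maximum.
#' The raw formula yields `n_levels + 1` at the patch maximum; values are
#' clamped to `n_levels` so the co-occurrence and run-length matrices keep
#' exactly `n_levels` gray levels. A degenerate patch (`f_max = 0`) maps to
#' level 1 everywhere.
#'
#' @param patch nonnegative numeric matrix.
#' @param n_levels number of gray levels (default 8).
#' @return list with `levels` (integer matrix in `[1, n_levels]`) and
#'   `f_max`.
#' @export
quantize_gray <- function(patch, n_levels = 8) {
  if (length(patch) == 0) stop("patch must be nonempty")
  if (any(patch < 0)) stop("patch must be nonnegative")
  f_max <- max(patch)
  lev <- if (f_max <= 0) {
    array(1L, dim = dim(patch))
  } else {
    pmin.int(as.integer(floor(patch * n_levels / f_max)) + 1L, n_levels)
  }
  lev <- matrix(as.integer(lev), nrow(patch), ncol(patch))
  list(levels = lev, f_max = f_max)
}

# replicate-pad a matrix by one pixel on each side
pad_replicate1 <- function(m) {
  m <- m[c(1, seq_len(nrow(m)), nrow(m)), , drop = FALSE]
  m[, c(1, seq_len(ncol(m)), ncol(m)), drop = FALSE]
}

#' Sobel gradient magnitude of a patch
#'
#' Applies the 3x3 Sobel kernels to every pixel of the patch, replicating
#' the patch border for out-of-patch neighbours, and returns the gradient
#' magnitude `sqrt(gx^2 + gy^2)` together with its quantization to
#' `[1, n_levels]` (same normalization and degenerate rule as
#' [quantize_gray()]).
#'
#' @param patch numeric matrix (any size; the patch is replicate-padded, so
#'   1x1 works degenerately).
#' @param n_levels gradient quantization levels (default 8).
#' @return list with `g` (gradient magnitude), `gx`, `gy`, `levels`
#'   (quantized gradient) and `g_max`.
#' @export
sobel_gradient <- function(patch, n_levels = 8) {
  p <- pad_replicate1(patch)
  nr <- nrow(patch); nc <- ncol(patch)
  ri <- seq_len(nr) + 1L; ci <- seq_len(nc) + 1L
  # gx: derivative along rows; gy: along columns
  gx <- (p[ri + 1L, ci - 1L] + 2 * p[ri + 1L, ci] + p[ri + 1L, ci + 1L]) -
        (p[ri - 1L, ci - 1L] + 2 * p[ri - 1L, ci] + p[ri - 1L, ci + 1L])
  gy <- (p[ri - 1L, ci + 1L] + 2 * p[ri, ci + 1L] + p[ri + 1L, ci + 1L]) -
        (p[ri - 1L, ci - 1L] + 2 * p[ri, ci - 1L] + p[ri + 1L, ci - 1L])
  g <- sqrt(gx^2 + gy^2)
  q <- quantize_gray(g, n_levels)
  list(g = g, gx = gx, gy = gy, levels = q$levels, g_max = q$f_max)
}

#' Gray level-gradient co-occurrence matrix (GGCM)
#'
#' Joint histogram of quantized gray level and quantized Sobel gradient
#' magnitude over a patch: `H[i, j]` counts pixels with gray level `i` and
#' gradient level `j`; `P = H / sum(H)`.
#'
#' @param patch nonnegative numeric matrix.
#' @param n_gray gray levels (default 8).
#' @param n_gradient gradient levels (default 8).
#' @return list with integer count matrix `H` and normalized matrix `P`.
#' @export
ggcm <- function(patch, n_gray = 8, n_gradient = 8) {
  fl <- quantize_gray(patch, n_gray)$levels
  gl <- sobel_gradient(patch, n_gradient)$levels
  H <- matrix(0L, n_gray, n_gradient)
  for (t in seq_along(fl)) {
    H[fl[t], gl[t]] <- H[fl[t], gl[t]] + 1L
  }
  list(H = H, P = H / sum(H))
}

#' Inverse difference moment of a normalized GGCM
#'
#' \deqn{T_{idm} = \sum_i \sum_j \frac{P(i,j)}{1 + (i-j)^2}}
#' High values indicate mass concentrated near the gray-gradient diagonal,
#' i.e. homogeneous texture. Lies in (0, 1], and equals 1 exactly when all
#' mass sits on the diagonal.
#'
#' @param P normalized co-occurrence matrix (must sum to 1).
#' @return scalar in (0, 1].
#' @export
idm <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("P must be normalized (sum to 1)")
  i <- row(P); j <- col(P)
  sum(P / (1 + (i - j)^2))
}

# split a matrix into its 45-degree (anti-diagonal) or 135-degree
# (main-diagonal) scan lines
diag_lines <- function(m, anti) {
  idx <- if (anti) row(m) + col(m) else col(m) - row(m)
  ord <- order(idx, if (anti) -row(m) else row(m))
  split(m[ord], idx[ord])
}

#' Gray-level run length matrix (GLRLM)
#'
#' Counts maximal runs of equal gray level along one scan direction: a run
#' of length `j` contributes a single count at column `j` (the classical
#' Galloway definition), so
#' \eqn{\sum_{i,j} p(i,j) \cdot j} equals the patch pixel count.
#'
#' @param patch integer matrix already quantized to `[1, n_gray]`.
#' @param n_gray gray levels (default 8).
#' @param direction one of `"0"`, `"45"`, `"90"`, `"135"` degrees; 0 runs
#'   along rows, 90 along columns, 45/135 along anti-/main diagonals.
#' @param max_run number of run-length columns; defaults to the longest run
#'   the patch geometry admits in that direction.
#' @return list with count matrix `p` (`n_gray` x `max_run`), total run
#'   count `n_r`, and `direction`.
#' @export
glrlm <- function(patch, n_gray = 8, direction = c("0", "45", "90", "135"),
                  max_run = NULL) {
  direction <- match.arg(as.character(direction), c("0", "45", "90", "135"))
  if (!all(patch == round(patch)) || any(patch < 1) || any(patch > n_gray)) {
    stop("patch must be integer gray levels in [1, n_gray]")
  }
  if (is.null(max_run)) {
    max_run <- switch(direction,
      "0" = ncol(patch), "90" = nrow(patch),
      min(nrow(patch), ncol(patch)))
  }
  lines <- switch(direction,
    "0" = split(patch, row(patch)),
    "90" = split(patch, col(patch)),
    "45" = diag_lines(patch, anti = TRUE),
    "135" = diag_lines(patch, anti = FALSE))
  p <- matrix(0L, n_gray, max_run)
  for (v in lines) {
    r <- rle(as.integer(v))
    for (t in seq_along(r$lengths)) {
      p[r$values[t], r$lengths[t]] <- p[r$values[t], r$lengths[t]] + 1L
    }
  }
  list(p = p, n_r = sum(p), direction = direction)
}

#' Long-run low gray-level emphasis (LRLGE)
#'
#' \deqn{LRLGE = \frac{1}{n_r} \sum_i \sum_j p(i,j) \frac{j^2}{i^2}}
#' Emphasizes long runs of low gray levels. The per-pixel texture feature
#' used by the kernel is the mean of this statistic over the four scan
#' directions; see [feature_image()].
#'
#' @param rlm a run-length matrix as returned by [glrlm()], or a list of
#'   them (in which case the direction mean is returned).
#' @return positive scalar.
#' @export
lrlge <- function(rlm) {
  one <- function(m) {
    if (m$n_r == 0) stop("empty run-length matrix")
    i <- row(m$p); j <- col(m$p)
    sum(m$p * j^2 / i^2) / m$n_r
  }
  if (!is.null(rlm$p)) one(rlm) else mean(vapply(rlm, one, numeric(1)))
}

glcm_offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                     `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' GLCM correlation of a patch (baseline feature)
#'
#' Standard Haralick correlation of the symmetric gray-level co-occurrence
#' matrix at unit offset, averaged over the four canonical directions. The
#' patch is quantized window-locally as in [quantize_gray()]. A patch with a
#' zero-variance marginal has correlation defined as 0.
#'
#' @param patch nonnegative numeric matrix.
#' @param n_gray gray levels (default 8).
#' @param directions subset of `c("0", "45", "90", "135")` to average over.
#' @return scalar in \[-1, 1\].
#' @export
glcm_correlation <- function(patch, n_gray = 8,
                             directions = c("0", "45", "90", "135")) {
  q <- quantize_gray(patch, n_gray)$levels
  nr <- nrow(q); nc <- ncol(q)
  corr_one <- function(off) {
    C <- matrix(0, n_gray, n_gray)
    for (r in seq_len(nr)) {
      for (cc in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
          a <- q[r, cc]; b <- q[r2, c2]
          C[a, b] <- C[a, b] + 1
          C[b, a] <- C[b, a] + 1   # symmetric accumulation
        }
      }
    }
    if (sum(C) == 0) return(0)
    P <- C / sum(C)
    i <- row(P); j <- col(P)
    mu_i <- sum(i * P); mu_j <- sum(j * P)
    s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
    if (s_i * s_j < 1e-12) return(0)
    (sum(i * j * P) - mu_i * mu_j) / (s_i * s_j)
  }
  mean(vapply(directions, function(d) corr_one(glcm_offsets[[d]]), numeric(1)))
}

#' Sliding-window texture feature image
#'
#' Computes one texture descriptor per pixel over the odd-sided window
#' centred there, with replicate padding at the image borders. By default
#' the quantization maxima `f_max`/`g_max` are taken over the whole image
#' (`normalization = "global"`), so the descriptors keep absolute
#' gray-level information — in particular the "low gray-level" weighting of
#' LRLGE distinguishes low- from high-activity regions. With
#' `normalization = "window"` the maxima are recomputed per window, making
#' every descriptor a pure function of its local patch. Descriptors:
#' \describe{
#'   \item{`"idm"`}{inverse difference moment of the window's GGCM (window
#'     default 5x5).}
#'   \item{`"lrlge"`}{long-run low gray-level emphasis of the window's
#'     GLRLM, averaged over the four directions (window default 3x3).}
#'   \item{`"glcm_correlation"`}{Haralick GLCM correlation, averaged over
#'     the four directions (window default 5x5).}
#' }
#' The heavy lifting is done in compiled code; the single-patch R functions
#' ([ggcm()], [idm()], [glrlm()], [lrlge()], [glcm_correlation()]) define
#' the per-window semantics and are used to validate it.
#'
#' @param image nonnegative numeric matrix.
#' @param descriptor one of `"idm"`, `"lrlge"`, `"glcm_correlation"`.
#' @param window_size odd window side; defaults to 5 for `"idm"` and
#'   `"glcm_correlation"`, 3 for `"lrlge"`.
#' @param n_gray gray levels (default 8).
#' @param n_gradient gradient levels for the GGCM (default 8).
#' @param normalization `"global"` (image-level quantization maxima,
#'   default) or `"window"` (per-window maxima).
#' @param edge_policy border handling; only `"replicate"` is implemented.
#' @return numeric matrix of the same shape as `image`.
#' @export
feature_image <- function(image,
                          descriptor = c("idm", "lrlge", "glcm_correlation"),
                          window_size = NULL, n_gray = 8, n_gradient = 8,
                          normalization = c("global", "window"),
                          edge_policy = "replicate") {
  descriptor <- match.arg(descriptor)
  normalization <- match.arg(normalization)
  glob <- normalization == "global"
  edge_policy <- match.arg(edge_policy, "replicate")
  if (is.null(window_size)) {
    window_size <- if (descriptor == "lrlge") 3L else 5L
  }
  window_size <- as.integer(window_size)
  if (window_size %% 2 == 0 || window_size < 1) stop("window_size must be odd")
  if (window_size > min(dim(image))) stop("window larger than image")
  if (any(image < 0) || any(!is.finite(image))) {
    stop("image must be finite and nonnegative")
  }
  switch(descriptor,
    idm = idm_map_cpp(image, window_size, as.integer(n_gray),
                      as.integer(n_gradient), glob),
    lrlge = lrlge_map_cpp(image, window_size, as.integer(n_gray), glob),
    glcm_correlation = glcm_corr_map_cpp(image, window_size,
                                         as.integer(n_gray), glob)
  )
}
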