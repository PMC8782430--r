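#' Per-pixel feature field
#'
#' Stacks a list of same-shaped feature images (e.g. the three composite
#' prior intensities, their IDM maps and their LRLGE maps) into an
#' N-pixel x C-channel matrix and z-scores each channel over the
#' field-of-view mask, so that the Euclidean distance used by the kernel
#' treats channels on a common scale. A channel with standard deviation
#' below `1e-12` is set to zero (it carries no information).
#'
#' @param channels named list of numeric matrices, all the same shape.
#' @param mask logical matrix of in-FOV pixels; default all `TRUE`.
#' @param scaling `"zscore"` (default) or `"none"`.
#' @return An object of class `"feature_field"`: list with `F` (N x C
#'   matrix, column-major pixel order), `mask`, `image_dim`, `mean`, `sd`.
#' @export
build_feature_field <- function(channels, mask = NULL,
                                scaling = c("zscore", "none")) {
  scaling <- match.arg(scaling)
  stopifnot(is.list(channels), length(channels) >= 1)
  dm <- dim(channels[[1]])
  for (ch in channels) {
    if (!identical(dim(ch), dm)) stop("feature channels have mismatched shapes")
    if (any(!is.finite(ch))) stop("feature channels must be finite")
  }
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  stopifnot(identical(dim(mask), dm))
  Fm <- vapply(channels, as.numeric, numeric(prod(dm)))
  Fm <- matrix(Fm, nrow = prod(dm),
               dimnames = list(NULL, names(channels)))
  mv <- as.vector(mask)
  mu <- colMeans(Fm[mv, , drop = FALSE])
  sdv <- apply(Fm[mv, , drop = FALSE], 2, sd)
  if (scaling == "zscore") {
    for (k in seq_len(ncol(Fm))) {
      Fm[, k] <- if (sdv[k] < 1e-12) 0 else (Fm[, k] - mu[k]) / sdv[k]
    }
    Fm[!mv, ] <- 0
  }
  structure(list(F = Fm, mask = mask, image_dim = dm, mean = mu, sd = sdv,
                 scaling = scaling),
            class = "feature_field")
}

#' k-nearest feature neighbours within a spatial search window
#'
#' For every in-mask pixel, finds the `k` pixels in the surrounding
#' `search_window x search_window` spatial neighbourhood (self excluded)
#' with the smallest Euclidean distance in feature space. Ties are broken
#' by ascending linear pixel index. Pixels near the mask edge may have
#' fewer than `k` in-mask candidates; all available ones are kept.
#'
#' @param field a [build_feature_field()].
#' @param k neighbours per pixel (default 50).
#' @param search_window odd side of the spatial candidate window (default
#'   9, giving 80 candidates). Must satisfy `k <= search_window^2 - 1`.
#' @return list with integer matrix `idx` (N x k, NA-padded), `d2`
#'   (squared feature distances), `k`, `search_window`.
#' @export
knn_neighbors <- function(field, k = 50, search_window = 9) {
  stopifnot(inherits(field, "feature_field"))
  search_window <- as.integer(search_window)
  if (search_window %% 2 == 0 || search_window < 3) {
    stop("search_window must be odd and >= 3")
  }
  if (k > search_window^2 - 1) {
    stop("k = ", k, " exceeds the ", search_window^2 - 1,
         " candidates of a ", search_window, "x", search_window, " window")
  }
  n1 <- field$image_dim[1]; n2 <- field$image_dim[2]
  N <- n1 * n2
  h <- search_window %/% 2
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  maskv <- as.vector(field$mask)
  Fm <- field$F

  D <- matrix(Inf, N, nrow(offs))
  NB <- matrix(NA_integer_, N, nrow(offs))
  for (o in seq_len(nrow(offs))) {
    dr <- offs$dr[o]; dc <- offs$dc[o]
    ri <- max(1, 1 - dr):min(n1, n1 - dr)
    ci <- max(1, 1 - dc):min(n2, n2 - dc)
    src <- as.vector(outer(ri, (ci - 1) * n1, `+`))
    tgt <- src + dr + dc * n1
    ok <- maskv[src] & maskv[tgt]
    src <- src[ok]; tgt <- tgt[ok]
    if (!length(src)) next
    d2 <- rowSums((Fm[src, , drop = FALSE] - Fm[tgt, , drop = FALSE])^2)
    D[src, o] <- d2
    NB[src, o] <- tgt
  }

  idx <- matrix(NA_integer_, N, k)
  d2m <- matrix(NA_real_, N, k)
  for (p in which(maskv)) {
    fin <- which(is.finite(D[p, ]))
    if (!length(fin)) next
    dd <- D[p, fin]; nb <- NB[p, fin]
    ord <- order(dd, nb)[seq_len(min(k, length(fin)))]
    idx[p, seq_along(ord)] <- nb[ord]
    d2m[p, seq_along(ord)] <- dd[ord]
  }
  storage.mode(idx) <- "integer"
  list(idx = idx, d2 = d2m, k = as.integer(k), search_window = search_window)
}

#' Sparse Gaussian kernel matrix over feature neighbours
#'
#' Builds the N x N kernel \eqn{K_{jl} = \exp(-\|f'_j - f'_l\|^2 / 2\sigma^2)}
#' on the k-nearest-neighbour graph, with \eqn{K_{jj} = 1} (self-similarity)
#' and zeros elsewhere. With `row_normalize = TRUE` (default) each row is
#' divided by its sum, so `K` applied to a constant image returns that
#' constant — the property that keeps the kernelized reconstruction
#' quantitatively calibrated. Out-of-mask pixels get identity rows.
#'
#' @param field a [build_feature_field()].
#' @param neighbors result of [knn_neighbors()]; computed if `NULL`.
#' @param sigma Gaussian bandwidth on the (z-scored) feature distances;
#'   must be positive (default 1).
#' @param row_normalize divide rows by their sums (default `TRUE`).
#' @param k,search_window passed to [knn_neighbors()] when `neighbors` is
#'   `NULL`.
#' @return An object of class `"kernel_matrix"`: list with sparse matrix
#'   `K` (`dgCMatrix`), `sigma`, `k`, `search_window`, `row_normalized`,
#'   `image_dim`.
#' @export
build_kernel <- function(field, neighbors = NULL, sigma = 1,
                         row_normalize = TRUE, k = 50, search_window = 9) {
  stopifnot(inherits(field, "feature_field"))
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(neighbors)) neighbors <- knn_neighbors(field, k, search_window)
  N <- prod(field$image_dim)
  ok <- !is.na(neighbors$idx)
  i <- row(neighbors$idx)[ok]
  j <- neighbors$idx[ok]
  w <- exp(-neighbors$d2[ok] / (2 * sigma^2))
  K <- Matrix::sparseMatrix(i = c(i, seq_len(N)), j = c(j, seq_len(N)),
                            x = c(w, rep(1, N)), dims = c(N, N))
  if (row_normalize) {
    K <- Matrix::Diagonal(x = 1 / Matrix::rowSums(K)) %*% K
  }
  structure(list(K = as(K, "CsparseMatrix"), sigma = sigma,
                 k = neighbors$k, search_window = neighbors$search_window,
                 row_normalized = row_normalize,
                 image_dim = field$image_dim),
            class = "kernel_matrix")
}

#' Identity kernel (reduces KEM to MLEM)
#'
#' @param image_dim `c(rows, cols)` of the image grid.
#' @export
identity_kernel <- function(image_dim) {
  N <- prod(image_dim)
  structure(list(K = as(Matrix::Diagonal(N), "CsparseMatrix"), sigma = NA_real_,
                 k = 0L, search_window = NA_integer_, row_normalized = TRUE,
                 image_dim = as.integer(image_dim)),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf(
    "<kernel_matrix> %d x %d, %d nonzeros (k=%d, sigma=%s, window=%s, %s)\n",
    nrow(x$K), ncol(x$K), Matrix::nnzero(x$K), x$k, format(x$sigma),
    format(x$search_window),
    if (x$row_normalized) "row-normalized" else "raw"))
  invisible(x)
}
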