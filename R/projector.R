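#' Parallel-beam tomographic system model
#'
#' Builds the linear system operator \eqn{P} mapping a square activity image
#' to a sinogram of `n_radial x n_angles` expected counts. The geometry is
#' 2D parallel-beam: angles uniformly spaced over \[0, 180) degrees (angle
#' zero = rays parallel to the image y-axis), radial bins spanning the grid
#' diagonal. The discretization is pixel-driven with linear interpolation
#' onto the two nearest radial bins, and the back-projector is the exact
#' transpose of the same weights, so the pair is a true adjoint — the
#' property EM convergence relies on. Pixels outside the inscribed
#' reconstruction circle are masked to zero.
#'
#' Attenuation, when present, enters the operator itself: the forward model
#' is \eqn{y = A (P_{geo} x)} with bin-wise survival factors
#' \eqn{A \in (0,1]}, and the back-projection applies the matching
#' transpose.
#'
#' @param grid_size image pixels per side.
#' @param n_radial radial bins (default 249).
#' @param n_angles projection angles (default 210).
#' @param attenuation optional vector/matrix of per-bin survival factors in
#'   (0, 1]; see [attenuation_from_mumap()].
#' @return An object of class `"system_model"`.
#' @examples
#' m <- system_model(32, n_radial = 49, n_angles = 30)
#' sino <- forward_project(m, matrix(1, 32, 32))
#' @export
system_model <- function(grid_size, n_radial = 249, n_angles = 210,
                         attenuation = NULL) {
  stopifnot(grid_size >= 2, n_radial >= 2, n_angles >= 1)
  n <- as.integer(grid_size)
  ctr <- (n + 1) / 2
  rw <- rep(seq_len(n), times = n)        # row index, column-major order
  cl <- rep(seq_len(n), each = n)
  x <- cl - ctr
  y <- rw - ctr
  fov <- x^2 + y^2 <= (n / 2)^2
  px <- which(fov)
  xs <- x[px]; ys <- y[px]

  ds <- n * sqrt(2) / n_radial            # radial bin width in pixel units
  thetas <- (seq_len(n_angles) - 1) * pi / n_angles

  np <- length(px)
  ii <- vector("list", n_angles)
  jj <- vector("list", n_angles)
  xx <- vector("list", n_angles)
  for (a in seq_len(n_angles)) {
    s <- xs * cos(thetas[a]) + ys * sin(thetas[a])
    u <- s / ds + (n_radial + 1) / 2      # continuous bin coordinate
    k0 <- floor(u)
    w2 <- u - k0
    base <- (a - 1L) * n_radial
    ii[[a]] <- c(base + k0, base + k0 + 1L)
    jj[[a]] <- c(px, px)
    xx[[a]] <- c(1 - w2, w2)
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n_radial * n_angles, n * n)
  )

  model <- structure(
    list(grid_size = n, n_radial = as.integer(n_radial),
         n_angles = as.integer(n_angles), ds = ds,
         A = A, fov = matrix(fov, n, n), attenuation = NULL,
         image_dim = c(n, n), sino_dim = c(as.integer(n_radial),
                                           as.integer(n_angles))),
    class = "system_model"
  )
  if (!is.null(attenuation)) model <- with_attenuation(model, attenuation)
  model
}

#' System model from an explicit matrix
#'
#' Wraps an arbitrary (sparse or dense) nonnegative matrix as a system
#' model; useful for toy systems such as an identity operator.
#'
#' @param A matrix mapping vectorized images (length `prod(image_dim)`) to
#'   vectorized sinograms (length `prod(sino_dim)`).
#' @param image_dim `c(rows, cols)` of the image.
#' @param sino_dim `c(n_radial, n_angles)` of the sinogram.
#' @param attenuation optional per-bin survival factors.
#' @export
custom_system_model <- function(A, image_dim, sino_dim, attenuation = NULL) {
  A <- as(A, "CsparseMatrix")
  stopifnot(nrow(A) == prod(sino_dim), ncol(A) == prod(image_dim))
  model <- structure(
    list(grid_size = image_dim[1], n_radial = sino_dim[1],
         n_angles = sino_dim[2], ds = 1, A = A,
         fov = matrix(TRUE, image_dim[1], image_dim[2]), attenuation = NULL,
         image_dim = as.integer(image_dim), sino_dim = as.integer(sino_dim)),
    class = "system_model"
  )
  if (!is.null(attenuation)) model <- with_attenuation(model, attenuation)
  model
}

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf("<system_model> image %dx%d -> sinogram %dx%d (%s attenuation)\n",
              x$image_dim[1], x$image_dim[2], x$sino_dim[1], x$sino_dim[2],
              if (is.null(x$attenuation)) "no" else "with"))
  invisible(x)
}

#' Attach attenuation factors to a system model
#'
#' @param model a [system_model()].
#' @param factors per-bin survival factors in (0, 1], as a vector or a
#'   sinogram-shaped matrix.
#' @return The model with attenuation folded into the operator.
#' @export
with_attenuation <- function(model, factors) {
  stopifnot(inherits(model, "system_model"))
  a <- as.numeric(factors)
  if (length(a) != prod(model$sino_dim)) stop("attenuation length mismatch")
  if (any(a <= 0) || any(a > 1)) stop("attenuation factors must lie in (0, 1]")
  model$attenuation <- a
  model
}

#' Forward projection
#'
#' @param model a [system_model()].
#' @param image numeric matrix matching the model's image grid, nonnegative.
#' @return Sinogram matrix (`n_radial` x `n_angles`).
#' @export
forward_project <- function(model, image) {
  stopifnot(inherits(model, "system_model"))
  if (!identical(dim(image), as.integer(model$image_dim)) &&
      !identical(dim(image), model$image_dim)) {
    stop("image shape ", paste(dim(image), collapse = "x"),
         " does not match model grid ",
         paste(model$image_dim, collapse = "x"))
  }
  s <- as.numeric(model$A %*% as.numeric(image))
  if (!is.null(model$attenuation)) s <- s * model$attenuation
  matrix(s, model$sino_dim[1], model$sino_dim[2])
}

#' Back-projection (exact adjoint of the forward projector)
#'
#' @param model a [system_model()].
#' @param sinogram numeric matrix matching the model's sinogram shape.
#' @return Image matrix.
#' @export
back_project <- function(model, sinogram) {
  stopifnot(inherits(model, "system_model"))
  if (!identical(as.integer(dim(sinogram)), as.integer(model$sino_dim))) {
    stop("sinogram shape ", paste(dim(sinogram), collapse = "x"),
         " does not match model ", paste(model$sino_dim, collapse = "x"))
  }
  s <- as.numeric(sinogram)
  if (!is.null(model$attenuation)) s <- s * model$attenuation
  img <- as.numeric(Matrix::crossprod(model$A, s))
  matrix(img, model$image_dim[1], model$image_dim[2])
}

#' Attenuation factors from an attenuation-coefficient map
#'
#' Computes per-bin photon survival factors \eqn{\exp(-\int \mu \, dl)} by
#' projecting the \eqn{\mu}-map (units: 1/pixel) along each line of response.
#' The pixel-driven projector accumulates pixel values into radial strips of
#' width `ds`, so the strip sum is divided by `ds` to recover the line
#' integral in pixel-length units.
#'
#' @param model a [system_model()] (its geometric part is used; any attached
#'   attenuation is ignored).
#' @param mu nonnegative attenuation-coefficient image, 1/pixel.
#' @return Sinogram-shaped matrix of factors in (0, 1].
#' @export
attenuation_from_mumap <- function(model, mu) {
  stopifnot(inherits(model, "system_model"))
  if (any(mu < 0)) stop("attenuation coefficients must be nonnegative")
  geo <- model
  geo$attenuation <- NULL
  line_int <- forward_project(geo, mu) / model$ds
  exp(-line_int)
}
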