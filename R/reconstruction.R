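#' Reconstruction settings
#'
#' @param iterations EM iterations (default 100).
#' @param init initial coefficient/image value inside the support (default 1).
#' @param epsilon relative floor applied to denominators before division,
#'   as a fraction of their positive mean (default 1e-12); guards
#'   zero-count bins when the background term is zero.
#' @param save_every optional stride; when set, intermediate images are
#'   kept every `save_every` iterations (for iteration-path tradeoff plots).
#' @export
recon_settings <- function(iterations = 100, init = 1, epsilon = 1e-12,
                           save_every = NULL) {
  stopifnot(iterations >= 1, epsilon > 0, init > 0)
  if (!is.null(save_every)) stopifnot(save_every >= 1)
  structure(list(iterations = as.integer(iterations), init = init,
                 epsilon = epsilon,
                 save_every = if (is.null(save_every)) NULL else as.integer(save_every)),
            class = "recon_settings")
}

checkpoint_iters <- function(settings) {
  if (is.null(settings$save_every)) integer(0)
  else seq(settings$save_every, settings$iterations, by = settings$save_every)
}

guard_floor <- function(v, epsilon) {
  pos <- v[v > 0]
  if (!length(pos)) return(v)
  pmax(v, epsilon * mean(pos))
}

poisson_loglik <- function(y, ybar) {
  sum(ifelse(y > 0, y * log(pmax(ybar, 1e-300)), 0) - ybar)
}

#' MLEM reconstruction
#'
#' Maximum-likelihood EM for the Poisson model \eqn{y \sim Pois(Px + r)}
#' with known expected background \eqn{r}, using the multiplicative update
#' \deqn{x \leftarrow \frac{x}{P^T 1} \, P^T\!\left(\frac{y}{Px + r}\right).}
#' Iterates stay nonnegative and the Poisson log-likelihood is
#' non-decreasing. Pixels with zero sensitivity (\eqn{P^T 1 = 0}) are
#' frozen at zero, never divided.
#'
#' @param y observed sinogram (matrix matching the model).
#' @param model a [system_model()].
#' @param r expected background sinogram (matrix or scalar 0).
#' @param settings a [recon_settings()].
#' @return list with `image`, `loglik` (per-iteration trace), `iterations`.
#' @export
mlem <- function(y, model, r = 0, settings = recon_settings()) {
  stopifnot(inherits(model, "system_model"), inherits(settings, "recon_settings"))
  if (any(y < 0)) stop("sinogram must be nonnegative")
  if (length(r) == 1) r <- matrix(r, model$sino_dim[1], model$sino_dim[2])
  sens <- back_project(model, matrix(1, model$sino_dim[1], model$sino_dim[2]))
  live <- sens > 0
  x <- matrix(0, model$image_dim[1], model$image_dim[2])
  x[live] <- settings$init
  ll <- numeric(settings$iterations)
  cps <- checkpoint_iters(settings)
  checkpoints <- list()
  for (it in seq_len(settings$iterations)) {
    ybar <- forward_project(model, x) + r
    if (it > 1) ll[it - 1] <- poisson_loglik(y, ybar)  # loglik of iterate it-1
    ratio <- y / guard_floor(ybar, settings$epsilon)
    bp <- back_project(model, ratio)
    x[live] <- x[live] * bp[live] / sens[live]
    if (it %in% cps) checkpoints[[as.character(it)]] <- x
  }
  ll[settings$iterations] <- poisson_loglik(y, forward_project(model, x) + r)
  list(image = x, loglik = ll, iterations = settings$iterations,
       checkpoints = checkpoints)
}

#' Kernelized EM (KEM) reconstruction
#'
#' Represents the image as \eqn{x = K\alpha} and iterates EM on the
#' coefficients:
#' \deqn{\alpha \leftarrow \frac{\alpha}{K^T P^T 1}\,
#'   K^T P^T\!\left(\frac{y}{P K \alpha + r}\right), \qquad \hat x = K \hat\alpha.}
#' With `K` the identity this is iterate-for-iterate identical to [mlem()].
#'
#' @param y observed sinogram.
#' @param model a [system_model()].
#' @param K a [build_kernel()] result (or [identity_kernel()]).
#' @param r expected background sinogram (matrix or scalar 0).
#' @param settings a [recon_settings()].
#' @return list with `image` (\eqn{\hat x = K\hat\alpha}), `alpha`,
#'   `loglik`, `iterations`.
#' @export
kem <- function(y, model, K, r = 0, settings = recon_settings()) {
  stopifnot(inherits(model, "system_model"), inherits(K, "kernel_matrix"),
            inherits(settings, "recon_settings"))
  if (!identical(as.integer(K$image_dim), as.integer(model$image_dim))) {
    stop("kernel image_dim does not match the system model grid")
  }
  if (any(y < 0)) stop("sinogram must be nonnegative")
  if (length(r) == 1) r <- matrix(r, model$sino_dim[1], model$sino_dim[2])
  Km <- K$K
  Kt <- Matrix::t(Km)
  sens <- back_project(model, matrix(1, model$sino_dim[1], model$sino_dim[2]))
  ksens <- as.numeric(Kt %*% as.numeric(sens))
  live <- ksens > 0
  alpha <- numeric(prod(model$image_dim))
  alpha[live] <- settings$init
  ll <- numeric(settings$iterations)
  dimg <- model$image_dim
  cps <- checkpoint_iters(settings)
  checkpoints <- list()
  for (it in seq_len(settings$iterations)) {
    x <- matrix(as.numeric(Km %*% alpha), dimg[1], dimg[2])
    ybar <- forward_project(model, x) + r
    if (it > 1) ll[it - 1] <- poisson_loglik(y, ybar)  # loglik of iterate it-1
    ratio <- y / guard_floor(ybar, settings$epsilon)
    bp <- as.numeric(back_project(model, ratio))
    kb <- as.numeric(Kt %*% bp)
    alpha[live] <- alpha[live] * kb[live] / ksens[live]
    if (it %in% cps) {
      checkpoints[[as.character(it)]] <-
        matrix(as.numeric(Km %*% alpha), dimg[1], dimg[2])
    }
  }
  x <- matrix(as.numeric(Km %*% alpha), dimg[1], dimg[2])
  ll[settings$iterations] <- poisson_loglik(y, forward_project(model, x) + r)
  list(image = x, alpha = alpha, loglik = ll, iterations = settings$iterations,
       checkpoints = checkpoints)
}

#' Frame-by-frame dynamic reconstruction
#'
#' Reconstructs every frame of a sinogram series independently with a
#' shared system model and (for kernelized methods) a shared kernel.
#'
#' @param series sinogram-space [dynamic_series()].
#' @param model a [system_model()].
#' @param method `"mlem"` or `"kem"` (any kernelized variant: the kernel
#'   carries the method's features).
#' @param K a [build_kernel()] result; required for `method = "kem"`.
#' @param background expected background series ([dynamic_series()]) or 0.
#' @param settings a [recon_settings()].
#' @param frames integer subset of frames to reconstruct (default all).
#' @return list with `images` (named by frame index), `loglik` (list of
#'   traces), `frames`.
#' @export
reconstruct_dynamic <- function(series, model, method = c("mlem", "kem"),
                                K = NULL, background = 0,
                                settings = recon_settings(), frames = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dynamic_series"), series$kind == "sinogram")
  if (method == "kem" && is.null(K)) stop("method 'kem' requires a kernel")
  if (is.null(frames)) frames <- seq_along(series$frames)
  bg_frame <- function(t) {
    if (inherits(background, "dynamic_series")) background$frames[[t]] else background
  }
  res <- lapply(frames, function(t) {
    if (method == "mlem") {
      mlem(series$frames[[t]], model, bg_frame(t), settings)
    } else {
      kem(series$frames[[t]], model, K, bg_frame(t), settings)
    }
  })
  list(images = stats::setNames(lapply(res, `[[`, "image"), frames),
       loglik = stats::setNames(lapply(res, `[[`, "loglik"), frames),
       frames = frames)
}

#' Composite-frame prior images
#'
#' Reconstructs each high-count composite frame with MLEM (100 iterations
#' by default) to obtain the prior images from which kernel features are
#' extracted.
#'
#' @param composites sinogram-space [dynamic_series()] of composite frames.
#' @param model a [system_model()].
#' @param background expected background composite series or 0.
#' @param settings a [recon_settings()] (default 100 iterations).
#' @return list of prior images, one per composite.
#' @export
make_priors <- function(composites, model, background = 0,
                        settings = recon_settings(iterations = 100)) {
  stopifnot(inherits(composites, "dynamic_series"),
            composites$kind == "sinogram")
  bg_frame <- function(t) {
    if (inherits(background, "dynamic_series")) background$frames[[t]] else background
  }
  lapply(seq_along(composites$frames), function(t) {
    mlem(composites$frames[[t]], model, bg_frame(t), settings)$image
  })
}
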