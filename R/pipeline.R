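#' Experiment configuration
#'
#' Bundles and validates every stage's settings. The defaults reproduce the
#' full simulation study: 217x217 phantom, 24-frame 60-minute schedule,
#' 249x210 sinograms, 3e7 expected counts with 20% uniform background, 10
#' realizations, 8 gray/gradient levels, 5x5 GGCM and 3x3 GLRLM windows,
#' k = 50 neighbours, 100 EM iterations.
#'
#' @param grid_size phantom side in pixels.
#' @param tumor_radius tumor radius in pixels.
#' @param schedule a [frame_schedule()].
#' @param tacs a [tac_set()].
#' @param n_radial,n_angles sinogram dimensions.
#' @param attenuation_mu uniform attenuation coefficient (1/pixel) inside
#'   the head support used for the mu-map; 0 disables attenuation.
#' @param total_counts,background_fraction,realizations acquisition
#'   settings; see [acquisition_settings()].
#' @param n_gray,n_gradient texture quantization levels.
#' @param window_ggcm,window_glrlm texture window sides.
#' @param k,sigma,search_window kernel settings; see [build_kernel()].
#' @param iterations,prior_iterations EM iterations for frame and prior
#'   reconstructions.
#' @param methods subset of `c("mlem", "kem", "kem_glcm", "kem_dual")`.
#' @param frames integer frame subset to reconstruct (default all).
#' @param seed master seed; sub-streams are derived per stage/realization.
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(grid_size = 217, tumor_radius = 5,
                              schedule = default_schedule(),
                              tacs = default_tacs(),
                              n_radial = 249, n_angles = 210,
                              attenuation_mu = 0.01,
                              total_counts = 3e7, background_fraction = 0.2,
                              realizations = 10,
                              n_gray = 8, n_gradient = 8,
                              window_ggcm = 5, window_glrlm = 3,
                              k = 50, sigma = 1, search_window = 9,
                              iterations = 100, prior_iterations = 100,
                              methods = c("mlem", "kem", "kem_glcm", "kem_dual"),
                              frames = NULL, seed = 1L) {
  methods <- match.arg(methods, c("mlem", "kem", "kem_glcm", "kem_dual"),
                       several.ok = TRUE)
  cfg <- list(grid_size = grid_size, tumor_radius = tumor_radius,
              schedule = schedule, tacs = tacs,
              n_radial = n_radial, n_angles = n_angles,
              attenuation_mu = attenuation_mu,
              total_counts = total_counts,
              background_fraction = background_fraction,
              realizations = realizations,
              n_gray = n_gray, n_gradient = n_gradient,
              window_ggcm = window_ggcm, window_glrlm = window_glrlm,
              k = k, sigma = sigma, search_window = search_window,
              iterations = iterations, prior_iterations = prior_iterations,
              methods = methods, frames = frames, seed = as.integer(seed))
  structure(cfg, class = "experiment_config")
}

# feature channels per kernelized method, from the priors
method_feature_channels <- function(method, priors, cfg) {
  chans <- stats::setNames(priors, paste0("intensity", seq_along(priors)))
  if (method == "kem_glcm") {
    gc <- lapply(priors, feature_image, descriptor = "glcm_correlation",
                 window_size = cfg$window_ggcm, n_gray = cfg$n_gray)
    chans <- c(chans, stats::setNames(gc, paste0("glcm", seq_along(gc))))
  } else if (method == "kem_dual") {
    im <- lapply(priors, feature_image, descriptor = "idm",
                 window_size = cfg$window_ggcm, n_gray = cfg$n_gray,
                 n_gradient = cfg$n_gradient)
    lr <- lapply(priors, feature_image, descriptor = "lrlge",
                 window_size = cfg$window_glrlm, n_gray = cfg$n_gray)
    chans <- c(chans,
               stats::setNames(im, paste0("idm", seq_along(im))),
               stats::setNames(lr, paste0("lrlge", seq_along(lr))))
  }
  chans
}

#' Run the end-to-end simulation experiment
#'
#' Pipeline: phantom + TACs -> noiseless dynamic images -> forward
#' projection with Poisson noise and uniform background -> three
#' equal-duration composite frames -> MLEM priors -> texture feature maps
#' -> sparse Gaussian kernels -> per-frame reconstruction with each
#' requested method -> quality metrics against the count-calibrated truth.
#' Kernels are built lazily: a methods list of only `"mlem"` never touches
#' the texture or kernel stages.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, metrics CSV, a JSON
#'   manifest and (if RNifti is installed) reconstructed NIfTI volumes for
#'   the first realization are written there.
#' @param keep_images retain reconstructed images of the first realization
#'   in the result (default `TRUE`).
#' @param verbose print stage progress (default `FALSE`).
#' @return list with `metrics` (data.frame: realization, method, frame and
#'   the five metrics), `images` (first realization, per method), `priors`
#'   (first realization), `truth` (count-scaled true images of the
#'   reconstructed frames), `phantom`, `rois`, `config`, `timings`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           keep_images = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tick()

  phantom <- brain_phantom(config$grid_size, tumor_radius = config$tumor_radius)
  truth_series <- render_dynamic_images(phantom, config$tacs, config$schedule)
  model <- system_model(config$grid_size, config$n_radial, config$n_angles)
  if (config$attenuation_mu > 0) {
    mu <- matrix(0, config$grid_size, config$grid_size)
    mu[phantom$masks$support] <- config$attenuation_mu
    model <- with_attenuation(model, attenuation_from_mumap(model, mu))
  }
  timings["setup"] <- tick() - t0; t0 <- tick()
  say("simulating acquisition (%d realizations)", config$realizations)

  acq <- simulate_acquisition(
    truth_series, model,
    acquisition_settings(config$total_counts, config$background_fraction,
                         config$realizations, config$seed))
  timings["acquisition"] <- tick() - t0; t0 <- tick()

  frames <- if (is.null(config$frames)) seq_along(truth_series$frames) else config$frames
  truth <- stats::setNames(
    lapply(frames, function(t) truth_series$frames[[t]] * acq$scale), frames)
  rois <- roi_set(phantom)
  rset <- recon_settings(iterations = config$iterations)
  pset <- recon_settings(iterations = config$prior_iterations)

  metrics <- list()
  images1 <- list()
  priors1 <- NULL
  for (r in seq_len(config$realizations)) {
    say("realization %d: composite priors", r)
    composites <- rebin_composite_frames(acq$realizations[[r]], 3)
    comp_bg <- rebin_composite_frames(acq$background, 3)
    priors <- make_priors(composites, model, comp_bg, pset)
    if (r == 1) priors1 <- priors

    kernels <- list()
    for (method in config$methods) {
      if (method != "mlem" && is.null(kernels[[method]])) {
        chans <- method_feature_channels(method, priors, config)
        field <- build_feature_field(chans, mask = model$fov)
        kernels[[method]] <- build_kernel(field, sigma = config$sigma,
                                          k = config$k,
                                          search_window = config$search_window)
      }
      say("realization %d: %s on %d frames", r, method, length(frames))
      rec <- reconstruct_dynamic(acq$realizations[[r]], model,
                                 method = if (method == "mlem") "mlem" else "kem",
                                 K = kernels[[method]],
                                 background = acq$background,
                                 settings = rset, frames = frames)
      if (r == 1 && keep_images) images1[[method]] <- rec$images
      for (fi in seq_along(frames)) {
        m <- metrics_report(rec$images[[fi]], truth[[fi]], rois)
        metrics[[length(metrics) + 1]] <-
          cbind(data.frame(realization = r, method = method,
                           frame = frames[fi]), m)
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  timings["reconstruction"] <- tick() - t0

  result <- list(metrics = metrics, images = images1, priors = priors1,
                 truth = truth, phantom = phantom, rois = rois,
                 config = config, timings = timings)
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("texkem")),
    created = format(Sys.time(), tz = "UTC"),
    seed = result$config$seed,
    methods = result$config$methods,
    grid_size = result$config$grid_size,
    iterations = result$config$iterations,
    timings_sec = as.list(round(result$timings, 2))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (requireNamespace("RNifti", quietly = TRUE) && length(result$images)) {
    for (method in names(result$images)) {
      vol <- simplify2array(result$images[[method]])
      RNifti::writeNifti(vol, file.path(out_dir, paste0("recon_", method, ".nii.gz")))
    }
  }
  invisible(out_dir)
}
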