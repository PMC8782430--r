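#' Brain-like 2D digital phantom
#'
#' Builds a labelled 2D phantom emulating an axial brain slice: an elliptical
#' head support split into a gray-matter rim and a white-matter core, with a
#' small circular tumor embedded in the white matter. Region geometry is
#' deterministic given the arguments.
#'
#' @param grid_size pixels per side of the square grid (default 217).
#' @param tumor_center integer `c(row, col)` of the tumor centre; default is
#'   a location inside the white-matter core.
#' @param tumor_radius tumor disc radius in pixels (default 5). A pixel
#'   belongs to the tumor when its squared centre distance is `<= radius^2`;
#'   `tumor_radius = 0` yields an empty tumor mask.
#' @return An object of class `"phantom"`: a list with `grid_size`, `labels`
#'   (integer matrix; 0 background, 1 gray matter, 2 white matter, 3 tumor),
#'   `masks` (named list of logical matrices including `support`),
#'   `tumor_center` and `tumor_radius`.
#' @examples
#' ph <- brain_phantom(64)
#' table(ph$labels)
#' @export
brain_phantom <- function(grid_size = 217, tumor_center = NULL,
                          tumor_radius = 5) {
  if (grid_size < 32) stop("grid_size must be at least 32")
  if (tumor_radius < 0) stop("tumor_radius must be nonnegative")
  ctr <- (grid_size + 1) / 2
  rw <- matrix(seq_len(grid_size), grid_size, grid_size)
  cl <- matrix(seq_len(grid_size), grid_size, grid_size, byrow = TRUE)

  # head support and white-matter core as concentric ellipses (taller than
  # wide, like an axial head slice); gray matter is the rim between them
  in_ellipse <- function(a, b) {
    ((cl - ctr) / (a * grid_size))^2 + ((rw - ctr) / (b * grid_size))^2 <= 1
  }
  support <- in_ellipse(0.38, 0.45)
  white <- in_ellipse(0.26, 0.33)

  if (is.null(tumor_center)) {
    tumor_center <- c(round(ctr + 0.15 * grid_size), round(ctr + 0.08 * grid_size))
  }
  tumor <- if (tumor_radius == 0) {
    matrix(FALSE, grid_size, grid_size)
  } else {
    (rw - tumor_center[1])^2 + (cl - tumor_center[2])^2 <= tumor_radius^2
  }
  if (tumor_radius > 0 && !all(white[tumor])) {
    stop("tumor disc does not fit inside the white-matter region; ",
         "adjust tumor_center or tumor_radius")
  }

  labels <- matrix(0L, grid_size, grid_size)
  labels[support] <- 1L
  labels[white] <- 2L
  labels[tumor] <- 3L

  masks <- list(
    support = support,
    gray_matter = labels == 1L,
    white_matter = labels == 2L,
    tumor = labels == 3L
  )
  structure(
    list(grid_size = grid_size, labels = labels, masks = masks,
         tumor_center = tumor_center, tumor_radius = tumor_radius),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%d grid; tumor r=%g at (%d, %d)\n",
              x$grid_size, x$grid_size, x$tumor_radius,
              x$tumor_center[1], x$tumor_center[2]))
  cat(sprintf("  pixels: support %d, gray %d, white %d, tumor %d\n",
              sum(x$masks$support), sum(x$masks$gray_matter),
              sum(x$masks$white_matter), sum(x$masks$tumor)))
  invisible(x)
}

#' Dynamic frame schedule
#'
#' @param durations frame durations in seconds, ordered in scan time.
#' @return An object of class `"frame_schedule"` with `durations`,
#'   `start_times` (cumulative, starting at 0) and `end_times`.
#' @examples
#' sch <- default_schedule()
#' length(sch$durations)  # 24 frames spanning 60 min
#' @export
frame_schedule <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) == 0 || any(!is.finite(durations)) || any(durations <= 0)) {
    stop("all frame durations must be positive and finite")
  }
  ends <- cumsum(durations)
  structure(
    list(durations = durations, start_times = c(0, ends[-length(ends)]),
         end_times = ends),
    class = "frame_schedule"
  )
}

#' @rdname frame_schedule
#' @details `default_schedule()` returns the 24-frame, 60-minute dynamic
#'   protocol used throughout: 4 x 20 s, 4 x 40 s, 4 x 60 s, 4 x 180 s and
#'   8 x 300 s.
#' @export
default_schedule <- function() {
  frame_schedule(c(rep(20, 4), rep(40, 4), rep(60, 4), rep(180, 4), rep(300, 8)))
}

#' Regional time-activity curves
#'
#' A TAC set maps each phantom region to a piecewise-linear activity curve
#' (time in seconds, activity in arbitrary units). Curves are linearly
#' interpolated between control points and held constant beyond the last one.
#'
#' `default_tacs()` ships qualitative curves emulating tracer kinetics in a
#' dynamic brain study: a fast-rising, accumulating tumor curve that exceeds
#' gray matter, a gray-matter curve with an early peak and slow washout, and
#' a lower, slower white-matter curve. They are an emulation chosen for the
#' simulation study, not measured data.
#'
#' @param curves named list; each element a two-column matrix
#'   `cbind(time, activity)` with nondecreasing times and nonnegative
#'   activities.
#' @return An object of class `"tac_set"`.
#' @export
tac_set <- function(curves) {
  stopifnot(is.list(curves), length(names(curves)) == length(curves))
  for (nm in names(curves)) {
    cp <- curves[[nm]]
    if (!is.matrix(cp) || ncol(cp) != 2 || nrow(cp) < 1) {
      stop("TAC '", nm, "' must be a 2-column matrix of (time, activity)")
    }
    if (is.unsorted(cp[, 1])) stop("TAC '", nm, "' has unsorted times")
    if (any(cp[, 2] < 0)) stop("TAC '", nm, "' has negative activity")
  }
  structure(curves, class = "tac_set")
}

#' @rdname tac_set
#' @export
default_tacs <- function() {
  tac_set(list(
    gray_matter = cbind(c(0, 60, 240, 900, 3600), c(0, 14, 18, 15, 11)),
    white_matter = cbind(c(0, 120, 600, 3600), c(0, 5, 6.5, 6)),
    tumor = cbind(c(0, 90, 600, 1800, 3600), c(0, 16, 22, 27, 30))
  ))
}

# mean of a piecewise-linear curve over [t0, t1]; exact trapezoid over the
# knots, constant extrapolation beyond the last control point
tac_interval_mean <- function(cp, t0, t1) {
  stopifnot(t1 > t0)
  if (nrow(cp) == 1) return(cp[1, 2])
  knots <- sort(unique(c(t0, t1, cp[cp[, 1] > t0 & cp[, 1] < t1, 1])))
  vals <- approx(cp[, 1], cp[, 2], xout = knots, rule = 2, ties = "ordered")$y
  sum(diff(knots) * (vals[-1] + vals[-length(vals)]) / 2) / (t1 - t0)
}

#' Per-region frame-mean activities
#'
#' @param tacs a [tac_set()].
#' @param schedule a [frame_schedule()].
#' @return matrix of frame-mean activity rates, frames x regions.
#' @export
tac_frame_means <- function(tacs, schedule) {
  stopifnot(inherits(tacs, "tac_set"), inherits(schedule, "frame_schedule"))
  out <- sapply(names(tacs), function(nm) {
    mapply(function(t0, t1) tac_interval_mean(tacs[[nm]], t0, t1),
           schedule$start_times, schedule$end_times)
  })
  matrix(out, nrow = length(schedule$durations),
         dimnames = list(NULL, names(tacs)))
}

#' Dynamic series container
#'
#' An ordered stack of 2D frames (activity images or sinograms) tied to a
#' frame schedule.
#'
#' @param frames list of numeric matrices, one per frame, all the same shape.
#' @param schedule a [frame_schedule()] of matching length.
#' @param kind `"image"` or `"sinogram"`.
#' @return An object of class `"dynamic_series"`.
#' @export
dynamic_series <- function(frames, schedule, kind = c("image", "sinogram")) {
  kind <- match.arg(kind)
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(frames) != length(schedule$durations)) {
    stop("frame count (", length(frames), ") does not match schedule length (",
         length(schedule$durations), ")")
  }
  dm <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), dm)) stop("all frames must share one shape")
    if (any(!is.finite(f)) || any(f < 0)) stop("frames must be finite and nonnegative")
  }
  structure(list(frames = frames, schedule = schedule, kind = kind),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  dm <- dim(x$frames[[1]])
  cat(sprintf("<dynamic_series> %d %s frames of %dx%d, %g s total\n",
              length(x$frames), x$kind, dm[1], dm[2],
              sum(x$schedule$durations)))
  invisible(x)
}

#' Render noiseless dynamic activity images
#'
#' Each frame carries *expected emissions*: the pixel value is the frame-mean
#' activity rate of its region multiplied by the frame duration, so Poisson
#' sampling downstream needs no further time scaling. Background (outside
#' the head support) is zero.
#'
#' @param phantom a [brain_phantom()].
#' @param tacs a [tac_set()] with one curve per nonempty labelled region.
#' @param schedule a [frame_schedule()].
#' @return A `"dynamic_series"` of image-space frames.
#' @export
render_dynamic_images <- function(phantom, tacs = default_tacs(),
                                  schedule = default_schedule()) {
  stopifnot(inherits(phantom, "phantom"))
  regions <- c("gray_matter", "white_matter", "tumor")
  needed <- regions[vapply(phantom$masks[regions], any, logical(1))]
  missing <- setdiff(needed, names(tacs))
  if (length(missing)) {
    stop("no time-activity curve for region '", missing[1], "'")
  }
  fm <- tac_frame_means(tacs, schedule)
  frames <- lapply(seq_along(schedule$durations), function(t) {
    img <- matrix(0, phantom$grid_size, phantom$grid_size)
    for (nm in intersect(needed, colnames(fm))) {
      img[phantom$masks[[nm]]] <- fm[t, nm] * schedule$durations[t]
    }
    img
  })
  dynamic_series(frames, schedule, "image")
}

#' Acquisition settings
#'
#' @param total_counts expected total events (trues + background) summed over
#'   all frames (default 3e7, a 60-minute brain study count level).
#' @param background_fraction fraction of total events that are uniform
#'   random/scattered background (default 0.20).
#' @param realizations number of independent noisy realizations (default 10).
#' @param seed integer RNG seed; one sub-stream is derived per realization.
#' @return An object of class `"acquisition_settings"`.
#' @export
acquisition_settings <- function(total_counts = 3e7, background_fraction = 0.2,
                                 realizations = 10, seed = 1L) {
  if (!is.finite(total_counts) || total_counts <= 0) {
    stop("total_counts must be positive")
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    stop("background_fraction must be in [0, 1)")
  }
  if (realizations < 1) stop("realizations must be at least 1")
  structure(list(total_counts = total_counts,
                 background_fraction = background_fraction,
                 realizations = as.integer(realizations),
                 seed = as.integer(seed)),
            class = "acquisition_settings")
}

realization_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(r)) %% 2147483647)
}

#' Simulate a noisy dynamic PET acquisition
#'
#' Forward-projects every activity frame through the system model, rescales
#' globally so the expected event total (trues plus background) over the
#' whole scan equals `settings$total_counts`, adds a spatially uniform
#' background sinogram per frame (total background =
#' `background_fraction * total_counts`, apportioned across frames in
#' proportion to each frame's trues), and draws independent Poisson
#' realizations.
#'
#' @param images image-space [dynamic_series()].
#' @param model a [system_model()] matching the image grid.
#' @param settings an [acquisition_settings()].
#' @return list with `trues` (noiseless prompt sinogram series),
#'   `background` (expected background series), `realizations` (list of
#'   noisy sinogram series), and `scale` (the global count calibration
#'   factor applied to the activity images).
#' @export
simulate_acquisition <- function(images, model,
                                 settings = acquisition_settings()) {
  stopifnot(inherits(images, "dynamic_series"), images$kind == "image",
            inherits(settings, "acquisition_settings"))
  raw <- lapply(images$frames, function(img) forward_project(model, img))
  raw_tot <- sum(vapply(raw, sum, numeric(1)))
  if (raw_tot <= 0) stop("cannot calibrate counts: all-zero activity images")

  bf <- settings$background_fraction
  scale <- settings$total_counts * (1 - bf) / raw_tot
  trues <- lapply(raw, function(s) s * scale)
  trues_per_frame <- vapply(trues, sum, numeric(1))

  nbins <- prod(dim(trues[[1]]))
  bg_total <- settings$total_counts * bf
  background <- lapply(seq_along(trues), function(t) {
    frame_bg <- bg_total * trues_per_frame[t] / sum(trues_per_frame)
    matrix(frame_bg / nbins, nrow(trues[[t]]), ncol(trues[[t]]))
  })

  realizations <- lapply(seq_len(settings$realizations), function(r) {
    set.seed(realization_seed(settings$seed, r))
    noisy <- lapply(seq_along(trues), function(t) {
      lam <- trues[[t]] + background[[t]]
      matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
    })
    dynamic_series(noisy, images$schedule, "sinogram")
  })

  list(
    trues = dynamic_series(trues, images$schedule, "sinogram"),
    background = dynamic_series(background, images$schedule, "sinogram"),
    realizations = realizations,
    scale = scale
  )
}

#' Rebin a dynamic series into equal-duration composite frames
#'
#' Sums consecutive frames into `n_composite` composites of equal wall-clock
#' duration. Frame boundaries must align exactly with the composite interval
#' edges; otherwise an error names the offending edge (splitting a Poisson
#' frame is ill-defined). The default 24-frame schedule partitions cleanly
#' into three 20-minute composites.
#'
#' @param series a [dynamic_series()].
#' @param n_composite number of composites (default 3).
#' @return A `"dynamic_series"` of composites, with attribute `"groups"`
#'   giving the member frame indices of each composite.
#' @export
rebin_composite_frames <- function(series, n_composite = 3) {
  stopifnot(inherits(series, "dynamic_series"), n_composite >= 1)
  total <- sum(series$schedule$durations)
  edges <- total * seq_len(n_composite - 1) / n_composite
  ends <- series$schedule$end_times
  for (e in edges) {
    if (min(abs(ends - e)) > 1e-9 * total) {
      stop("composite interval edge at ", e,
           " s does not align with any frame boundary")
    }
  }
  cuts <- c(0, edges, total)
  group <- findInterval(ends - 1e-9 * total, cuts)  # composite index per frame
  groups <- split(seq_along(ends), group)
  frames <- lapply(groups, function(ix) Reduce(`+`, series$frames[ix]))
  comp <- dynamic_series(unname(frames),
                         frame_schedule(rep(total / n_composite, n_composite)),
                         series$kind)
  attr(comp, "groups") <- unname(groups)
  comp
}
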