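#' Rendering specification for synthetic fluorescence images
#'
#' Controls how synthetic fibrous cells are rasterized: image geometry,
#' fiber cross-section, intensity levels, and the noise model.  The
#' generators emulate collapsed confocal stacks of LifeAct-labelled
#' fibroblasts: oriented line segments of stress-fiber thickness, blob-like
#' F-actin reservoirs, background, and sensor noise.  Intensities are float
#' by default for test sharpness; optional 10-bit quantization mimics the
#' acquisition depth of the real recordings.
#'
#' @param n_pixels Image side length in pixels (square images).
#' @param pixel_size Micrometres per pixel.
#' @param fiber_width Fiber cross-section FWHM in micrometres; must be
#'   resolvable (at least 2 pixels).
#' @param fiber_intensity Peak intensity of a rendered fiber.
#' @param background Constant background level; the default emulates the
#'   diffuse cytoplasmic fluorescence of a LifeAct-labelled cell, which
#'   dominates mean intensity so that fibrosity stays linear in fiber
#'   content.
#' @param noise `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise standard deviation (ignored for Poisson,
#'   where the signal itself sets the variance).
#' @param quantize_10bit Quantize intensities to 1024 levels.
#' @param seed Integer RNG seed.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(n_pixels = 256L, pixel_size = 0.25, fiber_width = 0.6,
                        fiber_intensity = 1, background = 0.5,
                        noise = c("gaussian", "poisson"), noise_sd = 0.02,
                        quantize_10bit = FALSE, seed = 1L) {
  noise <- match.arg(noise)
  if (fiber_width < 2 * pixel_size) {
    stop("fiber width must span at least 2 pixels to be resolvable",
         call. = FALSE)
  }
  if (fiber_intensity < 0 || background < 0 || noise_sd < 0) {
    stop("intensities and noise level must be non-negative", call. = FALSE)
  }
  structure(list(n_pixels = as.integer(n_pixels), pixel_size = pixel_size,
                 fiber_width = fiber_width, fiber_intensity = fiber_intensity,
                 background = background, noise = noise, noise_sd = noise_sd,
                 quantize_10bit = isTRUE(quantize_10bit),
                 seed = as.integer(seed)),
            class = "render_spec")
}

#' Segment list describing a synthetic cell
#'
#' @param segments Data frame (or matrix) with columns `x1, y1, x2, y2`
#'   (um), and optionally `width` (um) and `intensity`; one row per fiber.
#'   May have zero rows.
#' @param blobs Optional data frame with columns `x, y, radius, intensity`
#'   describing blob-like F-actin reservoirs.
#' @return An object of class `segment_list` with the exact total contour
#'   length attached as `total_length`.
#' @export
segment_list <- function(segments = NULL, blobs = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(x1 = numeric(0), y1 = numeric(0),
                           x2 = numeric(0), y2 = numeric(0),
                           width = numeric(0), intensity = numeric(0))
  }
  segments <- as.data.frame(segments)
  need <- c("x1", "y1", "x2", "y2")
  if (!all(need %in% names(segments))) {
    stop("segments need columns x1, y1, x2, y2", call. = FALSE)
  }
  if (is.null(segments$width)) segments$width <- NA_real_
  if (is.null(segments$intensity)) segments$intensity <- NA_real_
  if (!is.null(blobs)) {
    blobs <- as.data.frame(blobs)
    if (!all(c("x", "y", "radius", "intensity") %in% names(blobs))) {
      stop("blobs need columns x, y, radius, intensity", call. = FALSE)
    }
  }
  len <- with(segments, sum(sqrt((x2 - x1)^2 + (y2 - y1)^2)))
  structure(list(segments = segments, blobs = blobs, total_length = len),
            class = "segment_list")
}

#' Render a synthetic fibrous-cell image
#'
#' Rasterizes each segment with a Gaussian cross-section of its stated width
#' (FWHM) and each reservoir blob as an isotropic Gaussian, adds background
#' and noise last, and returns the image together with the exact total
#' contour length of the segments -- the ground truth that the fibrosity
#' statistic is validated against.  Deterministic under `spec$seed`.
#'
#' @param segs A [segment_list()].
#' @param spec A [render_spec()].
#' @return A list with `image` (a [fib_image()]) and `ground_truth_length`
#'   (um).
#' @export
render_fibers <- function(segs, spec = render_spec()) {
  stopifnot(inherits(segs, "segment_list"), inherits(spec, "render_spec"))
  n <- spec$n_pixels
  px <- matrix(0, n, n)
  coords <- (seq_len(n) - 0.5) * spec$pixel_size  # pixel centres, um
  sg <- segs$segments
  for (i in seq_len(nrow(sg))) {
    w <- if (is.na(sg$width[i])) spec$fiber_width else sg$width[i]
    if (w < 2 * spec$pixel_size) {
      stop("segment width below the resolvable limit (2 pixels)", call. = FALSE)
    }
    amp <- if (is.na(sg$intensity[i])) spec$fiber_intensity else sg$intensity[i]
    px <- px + amp * segment_profile(coords, coords,
                                    sg$x1[i], sg$y1[i], sg$x2[i], sg$y2[i],
                                    fwhm_to_sd(w))
  }
  for (i in seq_len(NROW(segs$blobs))) {
    b <- segs$blobs[i, ]
    d2 <- outer((coords - b$y)^2, (coords - b$x)^2, `+`)
    px <- px + b$intensity * exp(-d2 / (2 * b$radius^2))
  }
  px <- px + spec$background
  px <- with_seed_(spec$seed, add_noise(px, spec))
  if (spec$quantize_10bit) {
    px <- round(pmin(px / max(px, 1e-12), 1) * 1023) / 1023
  }
  list(image = fib_image(px, spec$pixel_size),
       ground_truth_length = segs$total_length)
}

fwhm_to_sd <- function(w) w / (2 * sqrt(2 * log(2)))

# Gaussian-profile distance field of one segment over the pixel grid.
# rows index y, columns x.
segment_profile <- function(ys, xs, x1, y1, x2, y2, sd) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  if (len2 == 0) {
    d2 <- (X - x1)^2 + (Y - y1)^2
  } else {
    t <- ((X - x1) * vx + (Y - y1) * vy) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (X - (x1 + t * vx))^2 + (Y - (y1 + t * vy))^2
  }
  exp(-d2 / (2 * sd^2))
}

add_noise <- function(px, spec) {
  d <- dim(px)
  out <- if (spec$noise == "gaussian") {
    px + stats::rnorm(length(px), 0, spec$noise_sd)
  } else {
    scale <- 100  # photons per intensity unit
    stats::rpois(length(px), pmax(px, 0) * scale) / scale
  }
  matrix(pmax(out, 0), d[1L], d[2L])
}

#' Render an image time series from a simulator run
#'
#' Bridges the mechanical model to the image pipeline: for each requested
#' frame, every intact sector is drawn as chord-like line segments at the
#' sector orientation (count proportional to its density, rounded), and the
#' F-actin reservoir as a blob.  The blob absorbs exactly the fluorescence
#' flux released by depolymerized or not-yet-regrown fibers, so total
#' fluorescence is conserved across frames -- emulating redistribution of
#' the F-actin reporter between stress fibers and reservoirs rather than
#' creation or loss of fluorophore.  Layouts are drawn once per series so
#' that frames differ only through densities, then per-frame noise is
#' applied; everything is deterministic under `spec$seed`.
#'
#' @param sim A `sim_output` from [simulate_remodeling()] (run with
#'   `keep_densities = TRUE`).
#' @param spec A [render_spec()].
#' @param frame_times Times (min) at which to render frames; default every
#'   5 min including 0, matching the confocal stack interval.
#' @param fibers_per_density Segments drawn per unit density
#'   (`count = round(fibers_per_density * rho)`).
#' @param cell_radius Cell radius in micrometres.
#' @param blob_radius Reservoir blob Gaussian radius (um).
#' @param blob_intensity Baseline reservoir blob peak intensity (the blob
#'   gains, on top of this, the flux of every fiber missing relative to the
#'   frame with the most fiber content).
#' @return A list with `images` (list of [fib_image()]), `times`, and
#'   `lengths` (exact rendered contour length per frame).
#' @export
render_cell_series <- function(sim, spec = render_spec(),
                               frame_times = NULL,
                               fibers_per_density = 3,
                               cell_radius = 24,
                               blob_radius = 2,
                               blob_intensity = 0.5) {
  stopifnot(inherits(sim, "sim_output"))
  if (is.null(sim$densities)) {
    stop("simulate_remodeling() must be run with keep_densities = TRUE",
         call. = FALSE)
  }
  if (is.null(frame_times)) {
    frame_times <- seq(0, max(sim$times), by = 5)
  }
  idx <- vapply(frame_times, function(t) which.min(abs(sim$times - t)),
                integer(1L))
  n_sec <- length(sim$theta)
  centre <- spec$n_pixels * spec$pixel_size / 2
  # fixed per-sector fiber layout: chord offsets drawn once so frames
  # differ only through density-driven counts
  max_fibers <- max(1L, as.integer(ceiling(fibers_per_density *
                                             sim$params$rho_max)))
  offsets <- with_seed_(derive_seed(spec$seed, 7L),
                        matrix(stats::runif(n_sec * max_fibers, -0.7, 0.7),
                               n_sec, max_fibers))
  frame_segs <- vector("list", length(idx))
  lengths <- numeric(length(idx))
  for (f in seq_along(idx)) {
    rho <- sim$densities[idx[f], ]
    rows <- list()
    for (s in seq_len(n_sec)) {
      cnt <- round(fibers_per_density * rho[s])
      if (cnt < 1) next
      th <- sim$theta[s]
      # unit vector along the fiber and its normal
      ux <- cos(th); uy <- sin(th)
      nx <- -uy; ny <- ux
      for (j in seq_len(cnt)) {
        off <- offsets[s, j] * cell_radius
        x0 <- centre + off * nx; y0 <- centre + off * ny
        half <- cell_radius * sqrt(max(0, 1 - (off / cell_radius)^2))
        rows[[length(rows) + 1L]] <-
          c(x0 - half * ux, y0 - half * uy, x0 + half * ux, y0 + half * uy)
      }
    }
    frame_segs[f] <- list(if (length(rows)) {
      m <- do.call(rbind, rows)
      data.frame(x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4])
    })
    lengths[f] <- if (length(rows)) {
      sum(vapply(rows, function(r)
        sqrt((r[3] - r[1])^2 + (r[4] - r[2])^2), numeric(1L)))
    } else 0
  }
  # fluorescence flux conservation: a Gaussian fiber of length L carries
  # flux ~ L * peak * sd * sqrt(2*pi); the reservoir blob absorbs whatever
  # is missing relative to the fiber-richest frame
  per_um <- spec$fiber_intensity * fwhm_to_sd(spec$fiber_width) * sqrt(2 * pi)
  blob_flux0 <- blob_intensity * 2 * pi * blob_radius^2
  seg_flux <- lengths * per_um
  blob_amp <- (blob_flux0 + max(seg_flux) - seg_flux) /
    (2 * pi * blob_radius^2)
  images <- vector("list", length(idx))
  for (f in seq_along(idx)) {
    blob <- data.frame(x = centre + cell_radius * 0.5, y = centre,
                       radius = blob_radius, intensity = blob_amp[f])
    sl <- segment_list(frame_segs[[f]], blobs = blob)
    frame_spec <- spec
    frame_spec$seed <- derive_seed(spec$seed, 100L + f)
    images[[f]] <- render_fibers(sl, frame_spec)$image
  }
  list(images = images, times = frame_times, lengths = lengths)
}

#' Generate a synthetic bead displacement field
#'
#' Bead reference positions are uniform in a square field of view; deformed
#' positions are `F %*% x` plus isotropic Gaussian localization noise.
#'
#' @param n Number of beads (`>= 3`).
#' @param F 2x2 deformation gradient (e.g. `diag(c(1.05, 0.95))` for 5%
#'   axial strain at effective Poisson ratio 1).
#' @param noise_sd Localization noise standard deviation (um).
#' @param fov Field-of-view side length (um).
#' @param seed Integer RNG seed.
#' @return A [bead_field()].
#' @export
gen_beads <- function(n = 50L, F = diag(2), noise_sd = 0.1, fov = 200,
                      seed = 1L) {
  if (n < 3L) stop("need at least 3 beads", call. = FALSE)
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(2L, 2L)))
  with_seed_(seed, {
    before <- matrix(stats::runif(2L * n, 0, fov), n, 2L)
    after <- before %*% t(F) +
      matrix(stats::rnorm(2L * n, 0, noise_sd), n, 2L)
    bead_field(before, after)
  })
}

#' Generate a synthetic isometric force trace
#'
#' Emulates the force recorded while a construct is rapidly stretched and
#' held: a baseline, a step rise that relaxes as one or two exponentials
#' towards a plateau above baseline, an optional step decrement when a
#' contraction-blocking drug is added, and Gaussian sensor noise.
#'
#' @param baseline Baseline force (uN).
#' @param step Peak force rise above baseline at the stretch (uN).
#' @param tau Relaxation time constant(s) in minutes (one or two).
#' @param weights Relative weights of the exponential components (recycled
#'   to `length(tau)`; normalized to sum to 1).
#' @param plateau_frac Fraction of `step` remaining at infinite time
#'   (the force relaxes to slightly above baseline, not back to it).
#' @param duration Total record length (min).
#' @param sampling_rate Samples per minute.
#' @param noise_sd Gaussian noise standard deviation (uN).
#' @param drug_decrement Step force drop at `drug_onset` (uN); 0 disables.
#' @param drug_onset Drug addition time (min).
#' @param seed Integer RNG seed.
#' @return A data frame with columns `time_min` and `force` (uN), with the
#'   noise-free trace attached as attribute `"truth"`.
#' @export
gen_force_trace <- function(baseline = 100, step = 80, tau = 5,
                            weights = 1, plateau_frac = 0.1,
                            duration = 30, sampling_rate = 10,
                            noise_sd = 0.5, drug_decrement = 0,
                            drug_onset = Inf, seed = 1L) {
  if (any(c(baseline, step, noise_sd, drug_decrement) < 0)) {
    stop("amplitudes and noise must be non-negative", call. = FALSE)
  }
  if (any(tau <= 0)) stop("time constants must be positive", call. = FALSE)
  w <- rep_len(weights, length(tau))
  w <- w / sum(w)
  t <- seq(0, duration, by = 1 / sampling_rate)
  decay <- rowSums(vapply(seq_along(tau),
                          function(k) w[k] * exp(-t / tau[k]),
                          numeric(length(t))))
  truth <- baseline + step * (plateau_frac + (1 - plateau_frac) * decay) -
    drug_decrement * (t >= drug_onset)
  force <- with_seed_(seed, truth + stats::rnorm(length(t), 0, noise_sd))
  out <- data.frame(time_min = t, force = force)
  attr(out, "truth") <- truth
  out
}

#' Write a force trace as CSV
#'
#' @param trace Data frame with `time_min` and `force`.
#' @param path Output CSV path.
#' @export
write_force_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_min = trace$time_min, force = trace$force),
                   path, row.names = FALSE)
  invisible(path)
}
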