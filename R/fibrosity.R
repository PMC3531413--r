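#' Fluorescence image container
#'
#' A minimal container for a single-channel fluorescence image: a matrix of
#' non-negative intensities plus the physical pixel size.  Rows index y,
#' columns x; the orientation convention only matters for consistency
#' between the renderer and the spectral statistic, both of which are
#' isotropic.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size Pixel size in micrometres (`> 0`).  The default 0.25 um
#'   corresponds to a 20x long-working-distance objective with moderate scan
#'   zoom, as used for live construct imaging; it resolves the full
#'   stress-fiber thickness band (see [fiber_band()]) below Nyquist.
#' @return An object of class `fib_image`.
#' @export
fib_image <- function(pixels, pixel_size = 0.25) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels))) {
    stop("pixels must be a finite numeric matrix", call. = FALSE)
  }
  if (any(pixels < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be positive", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "fib_image")
}

#' @export
print.fib_image <- function(x, ...) {
  cat(sprintf("<fib_image> %d x %d pixels, %.3g um/pixel, mean intensity %.4g\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, mean(x$pixels)))
  invisible(x)
}

as_fib_image <- function(img, pixel_size = 0.25) {
  if (inherits(img, "fib_image")) img else fib_image(img, pixel_size)
}

#' Collapse a confocal z-stack
#'
#' Per-pixel maximum-intensity projection of a stack of same-sized slices,
#' the conventional way to collapse a confocal stack of a thin fluorescent
#' cell into one 2D image.  A sum projection is available via `method`.
#'
#' @param stack A list of [fib_image()]s (or matrices) with identical
#'   dimensions, or a 3D array with the third dimension indexing slices.
#' @param method `"max"` (default) or `"sum"`.
#' @param pixel_size Pixel size used when `stack` contains bare matrices.
#' @return A [fib_image()].
#' @export
collapse_zstack <- function(stack, method = c("max", "sum"), pixel_size = 0.25) {
  method <- match.arg(method)
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- lapply(seq_len(dim(stack)[3L]), function(k) stack[, , k])
  }
  if (!is.list(stack) || length(stack) == 0L) {
    stop("stack must be a non-empty list of images", call. = FALSE)
  }
  imgs <- lapply(stack, as_fib_image, pixel_size = pixel_size)
  dims <- vapply(imgs, function(i) dim(i$pixels), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("all slices must have identical dimensions", call. = FALSE)
  }
  acc <- imgs[[1L]]$pixels
  for (k in seq_along(imgs)[-1L]) {
    acc <- if (method == "max") pmax(acc, imgs[[k]]$pixels)
           else acc + imgs[[k]]$pixels
  }
  fib_image(acc, imgs[[1L]]$pixel_size)
}

#' Normalize an image to unit mean luminosity
#'
#' Stretch moves parts of the cell through the focal volume, changing total
#' fluorescence between frames; scaling every frame to unit mean intensity
#' removes that nuisance before the spectral statistic is computed.
#'
#' @param img A [fib_image()] with positive mean intensity.
#' @return The rescaled [fib_image()].
#' @export
normalize_luminosity <- function(img) {
  img <- as_fib_image(img)
  m <- mean(img$pixels)
  if (m <= 0) stop("cannot normalize an all-zero image", call. = FALSE)
  fib_image(img$pixels / m, img$pixel_size)
}

#' Stress-fiber thickness band
#'
#' Feature-thickness bounds (in micrometres) defining which spatial
#' wavelengths count as "stress-fiber-like".  A fiber of cross-sectional
#' width `w` contributes spectral power near the half-period frequency
#' `1 / (2 w)`, so the band maps to radial spatial frequencies
#' `[1 / (2 * w_max), 1 / (2 * w_min)]` cycles/um.
#'
#' @param w_min,w_max Thickness bounds in micrometres, `0 < w_min < w_max`.
#'   Defaults 0.3-1.0 um span typical stress-fiber thicknesses.
#' @return An object of class `fiber_band`.
#' @export
fiber_band <- function(w_min = 0.3, w_max = 1.0) {
  if (!(is.numeric(w_min) && is.numeric(w_max) && w_min > 0 && w_min < w_max)) {
    stop("need 0 < w_min < w_max", call. = FALSE)
  }
  structure(list(w_min = w_min, w_max = w_max,
                 f_lo = 1 / (2 * w_max), f_hi = 1 / (2 * w_min)),
            class = "fiber_band")
}

#' Band-pass spectral fibrosity of an image
#'
#' The fibrosity statistic: the band-pass power of an image's 2D power
#' spectral density over the annulus of radial spatial frequencies
#' corresponding to stress-fiber thicknesses.  The image is first converted
#' to relative contrast (`pixels / mean - 1`, the luminosity adjustment that
#' removes overall fluorescence changes), tapered by a 2D Hann window to
#' suppress edge leakage, and its periodogram summed over the annulus
#' `f in [1/(2 w_max), 1/(2 w_min)]` cycles/um and scaled by a fixed
#' per-pixel window factor.  Because a fiber's spectral power scales with
#' its footprint, the statistic grows linearly with the total contour
#' length of in-band fibrous features (at fixed contrast against a
#' background-dominated mean); the annular (isotropic) filter makes it
#' exactly invariant to 90-degree rotation, invariant to intensity
#' rescaling, and insensitive to translation (up to window-edge effects).
#'
#' @param img A [fib_image()].  Intensity scale does not matter; the
#'   statistic is computed on the unit-mean contrast image.
#' @param band A [fiber_band()].
#' @return A dimensionless non-negative scalar.
#' @export
fibrosity_value <- function(img, band = fiber_band()) {
  img <- as_fib_image(img)
  stopifnot(inherits(band, "fiber_band"))
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 8L || nc < 8L) stop("image too small for spectral analysis",
                               call. = FALSE)
  nyquist <- 1 / (2 * img$pixel_size)
  if (band$f_hi > nyquist + 1e-12) {
    stop(sprintf(paste0("band upper frequency %.3g cycles/um exceeds the ",
                        "Nyquist frequency %.3g; w_min must be >= pixel_size"),
                 band$f_hi, nyquist), call. = FALSE)
  }
  f_lo_res <- 1 / (min(nr, nc) * img$pixel_size)
  if (band$f_lo < f_lo_res / 2) {
    stop("band lower frequency is below the resolvable range of this image",
         call. = FALSE)
  }
  m <- mean(px)
  if (m <= 0) return(0)
  w <- outer(hann_window(nr), hann_window(nc))
  y <- (px / m - 1) * w
  P <- Mod(stats::fft(y))^2
  fr <- fft_freq(nr, img$pixel_size)
  fc <- fft_freq(nc, img$pixel_size)
  r2 <- outer(fr^2, fc^2, `+`)
  annulus <- r2 > 0 & r2 >= band$f_lo^2 & r2 <= band$f_hi^2
  # Parseval scale: for unit-variance contrast the expected total power is
  # nr*nc*sum(w^2), so this denominator makes the value a per-pixel band
  # power, comparable across image sizes
  sum(P[annulus]) / (sum(w^2) * nr * nc)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)  # periodic Hann
}

fft_freq <- function(n, pixel_size) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * pixel_size)
}

#' Fibrosity time series from an image sequence
#'
#' Computes the fibrosity of each frame (after luminosity normalization) and
#' divides by the value at the reference frame, yielding the normalized
#' trace used for temporal classification.  The default reference is the
#' pre-stretch frame (index 1).
#'
#' @param images Time-ordered list of [fib_image()]s (at least 2).
#' @param band A [fiber_band()].
#' @param times Frame times in minutes (defaults to 5-min spacing from 0,
#'   the standard stack interval).
#' @param reference_index Index of the frame whose fibrosity defines 1.
#' @param normalize Luminosity-normalize each frame first (recommended).
#' @return An object of class `fibrosity_trace` with `times`, normalized
#'   `values`, the raw per-frame `raw` fibrosities, and `reference_index`.
#' @export
fibrosity_trace <- function(images, band = fiber_band(), times = NULL,
                            reference_index = 1L, normalize = TRUE) {
  if (!is.list(images) || length(images) < 2L) {
    stop("need a time-ordered list of at least 2 images", call. = FALSE)
  }
  imgs <- lapply(images, as_fib_image)
  if (normalize) imgs <- lapply(imgs, normalize_luminosity)
  raw <- vapply(imgs, fibrosity_value, numeric(1L), band = band)
  if (is.null(times)) times <- (seq_along(imgs) - 1L) * 5
  if (reference_index < 1L || reference_index > length(raw)) {
    stop("reference_index out of range", call. = FALSE)
  }
  if (raw[reference_index] <= 0) {
    stop("reference frame has zero fibrosity; cannot normalize", call. = FALSE)
  }
  structure(list(times = times,
                 values = raw / raw[reference_index],
                 raw = raw,
                 reference_index = as.integer(reference_index)),
            class = "fibrosity_trace")
}

fibrosity_trace_from_values <- function(times, values, reference_index = 1L) {
  structure(list(times = times, values = values, raw = values,
                 reference_index = as.integer(reference_index)),
            class = "fibrosity_trace")
}

#' @export
print.fibrosity_trace <- function(x, ...) {
  cat(sprintf("<fibrosity_trace> %d frames over %.0f min: 1.00 -> %.3f (min %.3f)\n",
              length(x$values), max(x$times) - min(x$times),
              x$values[length(x$values)], min(x$values)))
  invisible(x)
}

#' Write a fibrosity trace as CSV
#'
#' @param trace A [fibrosity_trace()].
#' @param path Output CSV path (columns `time_min`, `fibrosity`).
#' @export
write_fibrosity_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_min = trace$times, fibrosity = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Integer-pixel image alignment by cross-correlation
#'
#' Finds the integer (row, column) shift of `moving` that maximizes its
#' cross-correlation with `fixed` (computed via FFT), and returns the
#' shifted image with vacated borders zero-filled.  Subpixel refinement is
#' deliberately omitted: aligned subtraction images are interpreted
#' qualitatively.
#'
#' @param moving,fixed Same-sized [fib_image()]s.
#' @return A list with `shift` (integer `c(dy, dx)`, the translation applied
#'   to `moving`) and `aligned` (the shifted [fib_image()]).
#' @export
align_translate <- function(moving, fixed) {
  moving <- as_fib_image(moving); fixed <- as_fib_image(fixed)
  if (!all(dim(moving$pixels) == dim(fixed$pixels))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  a <- moving$pixels - mean(moving$pixels)
  b <- fixed$pixels - mean(fixed$pixels)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  idx <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  n <- dim(a)
  sh <- (idx - 1L)
  sh <- ifelse(sh > n / 2, sh - n, sh)  # wrap to signed shifts
  aligned <- shift_image(moving$pixels, sh[1L], sh[2L])
  list(shift = as.integer(sh),
       aligned = fib_image(aligned, moving$pixel_size))
}

shift_image <- function(px, dy, dx) {
  n <- nrow(px); m <- ncol(px)
  out <- matrix(0, n, m)
  src_r <- seq_len(n) - dy
  src_c <- seq_len(m) - dx
  ok_r <- src_r >= 1L & src_r <= n
  ok_c <- src_c >= 1L & src_c <= m
  out[which(ok_r), which(ok_c)] <- px[src_r[ok_r], src_c[ok_c]]
  out
}

#' Signed difference of two aligned images
#'
#' Per-pixel `later - earlier`: positive values mark intensity gained (e.g.
#' newly formed stress fibers), negative values intensity lost.  Align the
#' frames with [align_translate()] first.
#'
#' @param later,earlier Same-sized [fib_image()]s.
#' @return A plain numeric matrix of signed differences.
#' @export
subtract_images <- function(later, earlier) {
  later <- as_fib_image(later); earlier <- as_fib_image(earlier)
  if (!all(dim(later$pixels) == dim(earlier$pixels))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
  later$pixels - earlier$pixels
}

#' Read or write TIFF image stacks
#'
#' Thin wrappers around the tiff package that return/accept [fib_image()]
#' lists.  Multi-page TIFFs map to multi-frame lists.  Intensities are
#' rescaled to the stored range on write (TIFF stores `[0, 1]`); pixel size
#' is not stored in the file and must be supplied on read.
#'
#' @param path TIFF file path.
#' @param pixel_size Micrometres per pixel to attach on read.
#' @return `read_tiff_stack` returns a list of [fib_image()]s.
#' @export
read_tiff_stack <- function(path, pixel_size = 0.25) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel
    fib_image(p, pixel_size)
  })
}

#' Write or read a signed difference image as TIFF
#'
#' TIFF stores intensities in `[0, 1]`, so a signed difference map is
#' encoded (up to 16-bit quantization) as three pages: the positive part
#' and the magnitude of the negative part, both divided by the maximum
#' absolute difference, plus a constant page carrying that scale as
#' `scale / (1 + scale)`.
#'
#' @param diff Numeric matrix of signed differences (see
#'   [subtract_images()]).
#' @param path TIFF file path.
#' @return `write_difference_tiff` returns `path` invisibly;
#'   `read_difference_tiff` returns the signed matrix.
#' @export
write_difference_tiff <- function(diff, path) {
  diff <- as.matrix(diff)
  scale <- max(abs(diff), 0)
  pages <- if (scale > 0) {
    list(pmax(diff, 0) / scale, pmax(-diff, 0) / scale)
  } else {
    list(diff * 0, diff * 0)
  }
  pages[[3L]] <- matrix(scale / (1 + scale), nrow(diff), ncol(diff))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_difference_tiff
#' @export
read_difference_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L) {
    stop("not a three-page difference TIFF", call. = FALSE)
  }
  v <- mean(pages[[3L]])
  scale <- v / (1 - v)
  (pages[[1L]] - pages[[2L]]) * scale
}

#' @rdname read_tiff_stack
#' @param images A [fib_image()] or list of them.
#' @export
write_tiff_stack <- function(images, path) {
  if (inherits(images, "fib_image")) images <- list(images)
  # one common scale across frames so relative frame intensities survive
  hi <- max(vapply(images, function(i) max(i$pixels), numeric(1L)), 0)
  mats <- lapply(images, function(i) if (hi > 0) i$pixels / hi else i$pixels)
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  invisible(path)
}
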