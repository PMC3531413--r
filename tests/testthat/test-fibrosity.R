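test_that("z-stack collapse takes the per-pixel maximum", {
  m1 <- matrix(runif(64, 0, 1), 8, 8)
  m2 <- matrix(runif(64, 0, 1), 8, 8)
  m3 <- matrix(runif(64, 0, 1), 8, 8)
  col <- collapse_zstack(list(m1, m2, m3))
  # plain-loop oracle
  oracle <- m1
  for (i in 1:8) for (j in 1:8) oracle[i, j] <- max(m1[i, j], m2[i, j], m3[i, j])
  expect_equal(col$pixels, oracle)
  # single slice is the identity
  expect_equal(collapse_zstack(list(m1))$pixels, m1)
  # a slice that dominates everywhere is returned unchanged
  expect_equal(collapse_zstack(list(m1, m1 + 2))$pixels, m1 + 2)
  # sum projection and 3D-array input
  expect_equal(collapse_zstack(array(c(m1, m2), c(8, 8, 2)), "sum")$pixels,
               m1 + m2)
  expect_error(collapse_zstack(list(m1, matrix(0, 4, 4))), "dimensions")
})

test_that("luminosity normalization is scale-invariant with unit mean", {
  m <- matrix(rexp(256), 16, 16)
  n1 <- normalize_luminosity(fib_image(m))
  expect_equal(mean(n1$pixels), 1)
  expect_equal(normalize_luminosity(fib_image(2 * m))$pixels, n1$pixels)
  expect_error(normalize_luminosity(fib_image(matrix(0, 8, 8))), "all-zero")
})

test_that("fibrosity vanishes for structure-free images and respects Nyquist", {
  expect_equal(fibrosity_value(fib_image(matrix(5, 64, 64))), 0)
  # band above Nyquist at a coarse pixel size
  expect_error(fibrosity_value(fib_image(matrix(runif(4096), 64, 64),
                                         pixel_size = 0.5)),
               "Nyquist")
  expect_error(fiber_band(1.0, 0.3), "w_min < w_max")
})

test_that("fibrosity is invariant to rotation and rescaling, stable under shift", {
  r <- render_fibers(segment_list(data.frame(x1 = 12, y1 = c(28, 36),
                                             x2 = 52, y2 = c(28, 36))),
                     render_spec(seed = 2))
  px <- r$image$pixels
  f0 <- fibrosity_value(r$image)
  expect_gt(f0, 0)
  # 90-degree rotation: exact (isotropic annulus, symmetric window)
  expect_equal(fibrosity_value(fib_image(t(px))), f0, tolerance = 1e-12)
  # intensity rescaling: contrast image unchanged
  expect_equal(fibrosity_value(fib_image(px * 3.7)), f0, tolerance = 1e-12)
  # cyclic translation: equal up to window-edge effects
  roll <- function(m, dy, dx) {
    m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
  }
  f_sh <- fibrosity_value(fib_image(roll(px, 6, -8)))
  expect_lt(abs(f_sh - f0) / f0, 0.10)
})

test_that("fibrosity doubles for two congruent disjoint fibers", {
  spec <- render_spec(seed = 2)
  one <- render_fibers(segment_list(data.frame(x1 = 12, y1 = 24,
                                               x2 = 52, y2 = 24)), spec)
  two <- render_fibers(segment_list(data.frame(x1 = 12, y1 = c(24, 40),
                                               x2 = 52, y2 = c(24, 40))), spec)
  ratio <- fibrosity_value(normalize_luminosity(two$image)) /
    fibrosity_value(normalize_luminosity(one$image))
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("fibrosity scales linearly with total contour length", {
  spec <- render_spec(seed = 1)
  vals <- c(); lens <- c()
  for (k in c(2, 4, 6, 8, 10)) for (s in 1:4) {
    sp <- spec; sp$seed <- 100L + s
    y <- linearity_rows(k)
    r <- render_fibers(segment_list(data.frame(x1 = 12, y1 = y,
                                               x2 = 52, y2 = y)), sp)
    vals <- c(vals, fibrosity_value(r$image))
    lens <- c(lens, r$ground_truth_length)
  }
  expect_gt(summary(lm(vals ~ lens))$r.squared, 0.95)
})

test_that("features much thicker than the band contribute little band power", {
  spec <- render_spec(seed = 3, noise_sd = 0)
  seg <- function(w) segment_list(data.frame(x1 = 6, y1 = 32, x2 = 58, y2 = 32,
                                             width = w, intensity = 1))
  f_in <- fibrosity_value(render_fibers(seg(0.6), spec)$image)
  f_thick <- fibrosity_value(render_fibers(seg(4.0), spec)$image)
  # same length, 4x w_max thickness: less than a quarter of the band power
  expect_lt(f_thick / f_in, 0.25)
})

test_that("fibrosity traces normalize to the reference frame", {
  imgs <- replicate(4, render_fibers(segment_list(
    data.frame(x1 = 12, y1 = c(28, 36), x2 = 52, y2 = c(28, 36))),
    render_spec(seed = 5, noise_sd = 0))$image, simplify = FALSE)
  tr <- fibrosity_trace(imgs)
  expect_equal(tr$values, rep(1, 4))
  expect_equal(tr$times, c(0, 5, 10, 15))
  tr2 <- fibrosity_trace(imgs, reference_index = 3L)
  expect_equal(tr2$values[3], 1)
  expect_error(fibrosity_trace(imgs[1]), "at least 2")
})

test_that("frames rendered from growing densities give a rising trace", {
  p <- sim_params(sigma_pre = 0.01, seed = 5L)
  sim <- simulate_remodeling(p, eps_o = 0.05, keep_densities = TRUE)
  ser <- render_cell_series(sim, render_spec(seed = 9))
  tr <- fibrosity_trace(ser$images, times = ser$times)
  expect_gt(tr$values[length(tr$values)], 1.05)
  # non-decreasing up to render/noise jitter
  expect_true(all(diff(tr$values) > -0.02))
  expect_identical(as.character(classify_trace(tr)),
                   "monotonic_reinforcement")
})

test_that("integer-pixel alignment recovers known shifts", {
  r <- render_fibers(segment_list(data.frame(x1 = c(12, 20), y1 = c(24, 40),
                                             x2 = c(52, 44), y2 = c(28, 40))),
                     render_spec(seed = 6, noise_sd = 0))
  px <- r$image$pixels
  shifted <- cytoremodel:::shift_image(px, 3, -2)
  al <- align_translate(fib_image(px), fib_image(shifted))
  expect_identical(al$shift, c(3L, -2L))
  expect_equal(al$aligned$pixels[10:50, 10:50], shifted[10:50, 10:50])
  expect_identical(align_translate(fib_image(px), fib_image(px))$shift,
                   c(0L, 0L))
})

test_that("alignment tolerates noise at moderate SNR", {
  r <- render_fibers(segment_list(data.frame(x1 = c(12, 20), y1 = c(24, 40),
                                             x2 = c(52, 44), y2 = c(28, 40))),
                     render_spec(seed = 6, noise_sd = 0))
  px <- r$image$pixels
  sig <- sd(px)
  hits <- 0L
  n_rep <- 60L
  for (k in seq_len(n_rep)) {
    noisy <- withr::with_seed(200L + k, {
      shifted <- cytoremodel:::shift_image(px, 4, -5)
      shifted + matrix(rnorm(length(px), 0, sig / 5), nrow(px))
    })
    al <- align_translate(fib_image(px), fib_image(pmax(noisy, 0)))
    hits <- hits + identical(al$shift, c(4L, -5L))
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("image subtraction is signed and shape-checked", {
  a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
  expect_equal(subtract_images(a, b), a - b)
  expect_equal(subtract_images(a, a), matrix(0, 8, 8))
  expect_equal(subtract_images(a, matrix(0, 8, 8)), a)
  expect_error(subtract_images(a, matrix(0, 4, 4)), "dimensions")
})

test_that("a reinforcement frame pair gains more intensity than it loses", {
  p <- sim_params(sigma_pre = 0.01, seed = 5L)
  sim <- simulate_remodeling(p, eps_o = 0.05, keep_densities = TRUE)
  ser <- render_cell_series(sim, render_spec(seed = 9, noise_sd = 0))
  d <- subtract_images(ser$images[[2]], ser$images[[1]])  # growth happens early
  # total fluorescence is conserved by construction (fiber gain drains the
  # reservoir blob), so mask out the blob before comparing signed mass
  n <- nrow(d); coords <- (seq_len(n) - 0.5) * 0.25
  centre <- n * 0.25 / 2
  blob_d2 <- outer((coords - centre)^2, (coords - (centre + 12))^2, `+`)
  keep <- blob_d2 > 8^2
  expect_gt(sum(d[keep & d > 0]), -sum(d[keep & d < 0]))
})

test_that("TIFF stacks round-trip within quantization error", {
  imgs <- list(fib_image(matrix(runif(256, 0, 2), 16, 16)),
               fib_image(matrix(runif(256, 0, 1), 16, 16)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_tiff_stack(imgs, path)
  back <- read_tiff_stack(path, pixel_size = 0.25)
  expect_length(back, 2L)
  hi <- max(imgs[[1]]$pixels, imgs[[2]]$pixels)
  for (k in 1:2) {
    expect_equal(back[[k]]$pixels, imgs[[k]]$pixels / hi, tolerance = 1e-4)
  }
})

test_that("signed difference maps round-trip through two-page TIFF", {
  d <- matrix(rnorm(256, 0, 0.4), 16, 16)
  path <- withr::local_tempfile(fileext = ".tif")
  write_difference_tiff(d, path)
  back <- read_difference_tiff(path)
  expect_equal(back, d, tolerance = 1e-3)
  # all-zero difference survives too
  write_difference_tiff(matrix(0, 4, 4), path)
  expect_equal(read_difference_tiff(path), matrix(0, 4, 4))
})
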