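#' Initialize a model cell
#'
#' Builds a cell as a population of oriented stress-fiber sectors.  Circular
#' cells have sectors uniformly spanning `[0, pi)` (orientations are
#' 180-degree periodic); spindle cells concentrate orientations about a
#' natural axis by drawing them from a wrapped normal distribution.  Each
#' sector receives a random pre-stretch drawn i.i.d. from a
#' `Normal(mu_pre, sigma_pre)` truncated to the allowable window, sampled by
#' inverse-CDF so that `sigma_pre = 0` degenerates exactly to `mu_pre`.
#'
#' @param shape `"circular"` or `"spindle"`.
#' @param params A [sim_params()].
#' @param spindle_axis Orientation of the spindle natural axis (radians);
#'   ignored for circular cells.
#' @return An object of class `cell_model` with per-sector orientation
#'   `theta`, angular `width`, pre-stretch `lambda_pre`, current stretch
#'   `lambda_total`, density `rho`, an `intact` flag, and the F-actin
#'   `reservoir` pool.
#' @export
init_cell <- function(shape = c("circular", "spindle"), params = sim_params(),
                      spindle_axis = 0) {
  shape <- match.arg(shape)
  validate_sim_params(params)
  n <- params$n_sectors
  width <- pi / n
  theta <- if (shape == "circular") {
    (seq_len(n) - 0.5) * width
  } else {
    with_seed_(derive_seed(params$seed, 1L),
               (spindle_axis + stats::rnorm(n, 0, params$spindle_sd)) %% pi)
  }
  lambda_pre <- with_seed_(derive_seed(params$seed, 2L),
                           rtruncnorm_(n, params$mu_pre, params$sigma_pre,
                                       params$lambda_min, params$lambda_max))
  structure(list(shape = shape,
                 theta = theta,
                 width = rep(width, n),
                 lambda_pre = lambda_pre,
                 lambda_total = lambda_pre,
                 rho = rep(params$rho0, n),
                 intact = rep(TRUE, n),
                 reservoir = params$reservoir_capacity,
                 spindle_axis = if (shape == "spindle") spindle_axis else NA_real_,
                 tensile_ref = NA_real_,
                 stretched = FALSE),
            class = "cell_model")
}

# Truncated-normal sampling by inverse CDF; exact degenerate limit at sd = 0.
rtruncnorm_ <- function(n, mean, sd, lower, upper) {
  if (sd < 0) stop("sigma_pre must be >= 0", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %s cell, %d sectors, %d intact, reservoir %.2f\n",
              x$shape, length(x$theta), sum(x$intact), x$reservoir))
  if (x$stretched) {
    cat(sprintf("  stretched; load share %.3f\n", load_share(x)))
  }
  invisible(x)
}

#' Apply a local stretch to a model cell
#'
#' Each sector's total stretch becomes
#' `lambda_pre * (1 + fiber_strain(eps_o, theta - axis, nu))`: the random
#' pre-stretch composes multiplicatively with the orientation-resolved ETC
#' strain.  Sectors whose total stretch leaves the allowable window
#' depolymerize instantly and irreversibly -- tensile rupture above
#' `lambda_max`, compressive buckling below `lambda_min` -- and their F-actin
#' is credited to the reservoir pool.  The pre-stretch total density of
#' tensile sectors is recorded as the reference for load sharing.
#'
#' @param cell A [cell_model()].
#' @param eps_o Local axial strain (dimensionless fraction, i.e. already
#'   calibrated from nominal via [local_strain()]).
#' @param params A [sim_params()] supplying the allowable window.
#' @param nu Effective Poisson ratio (default 1, as measured for these
#'   constructs).
#' @param axis Direction of ETC stretch (radians).
#' @return The updated `cell_model`.
#' @export
apply_stretch <- function(cell, eps_o, params = sim_params(), nu = 1, axis = 0) {
  stopifnot(inherits(cell, "cell_model"))
  eps_theta <- fiber_strain(eps_o, cell$theta - axis, nu)
  cell$lambda_total <- cell$lambda_pre * (1 + eps_theta)
  tensile <- cell$lambda_total > 1
  # reference tensile density before any rupture: the denominator of the
  # load-sharing factor
  cell$tensile_ref <- sum(cell$rho[tensile] * cell$width[tensile])
  out <- cell$lambda_total < params$lambda_min |
    cell$lambda_total > params$lambda_max
  newly <- out & cell$intact
  cell$reservoir <- cell$reservoir + sum(cell$rho[newly] * cell$width[newly])
  cell$rho[newly] <- 0
  cell$intact <- cell$intact & !out
  cell$stretched <- TRUE
  cell
}

# Fraction of the pre-rupture tensile density still borne by intact tensile
# sectors, clipped to [0, 1].  Rupture of tensile fibers releases stress in
# the surrounding matrix; this global factor passes that release on to every
# adhesion site.
load_share <- function(cell) {
  if (!cell$stretched || !is.finite(cell$tensile_ref) || cell$tensile_ref <= 0) {
    return(1)
  }
  ten <- cell$intact & cell$lambda_total > 1
  min(1, max(0, sum(cell$rho[ten] * cell$width[ten]) / cell$tensile_ref))
}

#' Adhesion-site stress per sector
#'
#' The stress a sector transmits to its adhesion is
#' `k_fiber * rho * max(lambda_total - 1, 0) * load_share`: proportional to
#' fiber density and tensile stretch, zero for compressed fibers (which bear
#' no adhesion tension), and scaled down globally by the load-sharing factor
#' when tensile sectors have ruptured.
#'
#' @param cell A stretched [cell_model()].
#' @param params A [sim_params()].
#' @return Numeric vector of per-sector stresses (arbitrary units), zero for
#'   depolymerized sectors; the load-sharing factor is attached as attribute
#'   `"load_share"`.
#' @export
adhesion_stress <- function(cell, params = sim_params()) {
  stopifnot(inherits(cell, "cell_model"))
  ls <- load_share(cell)
  s <- params$k_fiber * cell$rho * pmax(cell$lambda_total - 1, 0) * ls
  s[!cell$intact] <- 0
  attr(s, "load_share") <- ls
  s
}

#' Advance the model by one time step
#'
#' Intact sectors whose adhesion stress lies in the intermediate band
#' `[s_low, s_high]` polymerize by forward Euler:
#' `rho <- rho + dt * k_poly * (rho_max - rho)`.  Stress below the band
#' yields no growth (insufficient drive); stress above it arrests growth.
#' Polymerization is disabled entirely when `rock_inhibited`.  With a finite
#' reservoir, growth draws down the pool and is scaled back proportionally in
#' the step that would exhaust it.
#'
#' @param cell A stretched [cell_model()].
#' @param dt Time step in minutes (defaults to `params$dt`).
#' @param params A [sim_params()].
#' @return The updated `cell_model`.
#' @export
step_cell <- function(cell, dt = params$dt, params = sim_params()) {
  stopifnot(inherits(cell, "cell_model"))
  if (dt <= 0) stop("time step dt must be positive", call. = FALSE)
  if (params$rock_inhibited) return(cell)
  s <- adhesion_stress(cell, params)
  grow <- cell$intact & s >= params$s_low & s <= params$s_high
  if (!any(grow)) return(cell)
  d_rho <- dt * params$k_poly * (params$rho_max - cell$rho[grow])
  if (params$reservoir_finite) {
    demand <- sum(d_rho * cell$width[grow])
    if (demand > cell$reservoir) {
      scale <- if (demand > 0) cell$reservoir / demand else 0
      d_rho <- d_rho * scale
    }
    cell$reservoir <- max(0, cell$reservoir - sum(d_rho * cell$width[grow]))
  }
  cell$rho[grow] <- pmin(cell$rho[grow] + d_rho, params$rho_max)
  cell
}

#' Simulate the post-stretch remodeling of one cell
#'
#' Runs the full virtual experiment for a single cell: initialization,
#' instantaneous stretch with depolymerization, then forward-Euler
#' polymerization dynamics over the isometric hold.  The model analogue of
#' the fibrosity statistic is the width-weighted total stress-fiber density
#' `sum(rho_i * width_i)`, normalized to its pre-stretch value, so the trace
#' starts at exactly 1.
#'
#' @param params A [sim_params()].
#' @param shape Cell shape passed to [init_cell()].
#' @param eps_o Local axial strain (calibrated fraction).
#' @param nu Effective Poisson ratio.
#' @param axis Stretch direction (radians).
#' @param cell Optionally, an already-initialized (or previously stretched)
#'   `cell_model` to continue from, for chained stretch protocols.
#' @param delta Classification threshold forwarded to [classify_trace()].
#' @param keep_densities Keep the full time x sector density matrix.
#' @return An object of class `sim_output`: `times` (min),
#'   `model_fibrosity` (normalized trace), `response_class`, the final
#'   `cell`, `depolymerized` mask and per-sector `theta`, and optionally
#'   `densities`.
#' @export
simulate_remodeling <- function(params = sim_params(),
                                shape = "circular",
                                eps_o = 0.05,
                                nu = 1,
                                axis = 0,
                                cell = NULL,
                                delta = 0.10,
                                keep_densities = FALSE) {
  validate_sim_params(params)
  if (is.null(cell)) cell <- init_cell(shape, params)
  n_steps <- max(1L, as.integer(round(params$duration / params$dt)))
  times <- c(0, seq_len(n_steps) * params$dt)
  f0 <- sum(cell$rho * cell$width)
  if (f0 <= 0) stop("pre-stretch fibrosity is zero; cannot normalize",
                    call. = FALSE)
  fib <- numeric(n_steps + 1L)
  fib[1L] <- 1
  dens <- if (keep_densities) {
    matrix(NA_real_, n_steps + 1L, length(cell$theta))
  }
  if (keep_densities) dens[1L, ] <- cell$rho
  cell <- apply_stretch(cell, eps_o, params, nu = nu, axis = axis)
  for (k in seq_len(n_steps)) {
    cell <- step_cell(cell, params$dt, params)
    fib[k + 1L] <- sum(cell$rho * cell$width) / f0
    if (keep_densities) dens[k + 1L, ] <- cell$rho
  }
  trace <- fibrosity_trace_from_values(times, fib, reference_index = 1L)
  cls <- classify_trace(trace, delta = delta)
  structure(list(times = times,
                 model_fibrosity = fib,
                 response_class = cls,
                 theta = cell$theta,
                 depolymerized = !cell$intact,
                 densities = dens,
                 cell = cell,
                 params = params,
                 eps_o = eps_o,
                 nu = nu,
                 axis = axis),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> %s cell, eps_o = %.3f: %s\n",
              x$cell$shape, x$eps_o, x$response_class))
  cat(sprintf("  fibrosity 1.00 -> %.3f (min %.3f); %d/%d sectors depolymerized\n",
              x$model_fibrosity[length(x$model_fibrosity)],
              min(x$model_fibrosity),
              sum(x$depolymerized), length(x$depolymerized)))
  invisible(x)
}

#' Sweep the pre-stretch variability
#'
#' Repeats the virtual stretch experiment over a grid of pre-stretch standard
#' deviations, `n_reps` independently seeded cells per level, and tabulates
#' the temporal response classes.  Increasing variability moves the dominant
#' response from monotonic reinforcement through retraction-then-reinforcement
#' to monotonic retraction, because more fibers start near the rupture and
#' buckling limits.  The orientations of depolymerized sectors are pooled per
#' level for orientation-histogram analysis.
#'
#' @param sigma_values Numeric vector of `sigma_pre` levels.
#' @param n_reps Replicate cells per level (`>= 1`).
#' @param base_params A [sim_params()]; its `seed` seeds the whole sweep.
#' @param eps_o Local axial strain for every run.
#' @param shape,nu,axis Forwarded to [simulate_remodeling()].
#' @param delta Classification threshold.
#' @return An object of class `sweep_result`: a `counts` matrix
#'   (sigma level x response class), `frequencies`, a list
#'   `depolymerized_theta` of pooled orientations (radians) per level, a list
#'   `runs` of per-run classes, per-level counts of anomaly-flagged traces
#'   (`anomalies`; a reinforcement-then-retraction pattern, which the model
#'   cannot produce), and per-run final mean surviving-sector densities near
#'   the stretch axis and perpendicular (`polarization`).
#' @export
sweep_prestretch_sd <- function(sigma_values, n_reps = 50L,
                                base_params = sim_params(), eps_o = 0.05,
                                shape = "circular", nu = 1, axis = 0,
                                delta = 0.10) {
  stopifnot(n_reps >= 1L, length(sigma_values) >= 1L)
  classes <- response_class_levels()
  counts <- matrix(0L, length(sigma_values), length(classes),
                   dimnames = list(sigma = as.character(sigma_values),
                                   class = classes))
  depol_theta <- vector("list", length(sigma_values))
  names(depol_theta) <- as.character(sigma_values)
  runs <- vector("list", length(sigma_values))
  anomalies <- integer(length(sigma_values))
  polar <- vector("list", length(sigma_values))
  for (i in seq_along(sigma_values)) {
    p <- base_params
    p$sigma_pre <- sigma_values[i]
    th <- numeric(0)
    cls_i <- character(n_reps)
    anom_i <- logical(n_reps)
    pol_i <- matrix(NA_real_, n_reps, 2L,
                    dimnames = list(NULL, c("axis", "perpendicular")))
    for (r in seq_len(n_reps)) {
      p$seed <- derive_seed(base_params$seed, (i - 1L) * n_reps + r)
      out <- simulate_remodeling(p, shape = shape, eps_o = eps_o, nu = nu,
                                 axis = axis, delta = delta)
      cls_i[r] <- out$response_class
      anom_i[r] <- isTRUE(attr(out$response_class, "anomaly"))
      th <- c(th, out$theta[out$depolymerized])
      pol_i[r, ] <- polarization_densities(out, axis = axis)
    }
    tab <- table(factor(cls_i, levels = classes))
    counts[i, ] <- as.integer(tab)
    depol_theta[[i]] <- th
    runs[[i]] <- cls_i
    anomalies[i] <- sum(anom_i)
    polar[[i]] <- pol_i
  }
  structure(list(sigma_values = sigma_values,
                 n_reps = as.integer(n_reps),
                 eps_o = eps_o,
                 counts = counts,
                 frequencies = counts / n_reps,
                 depolymerized_theta = depol_theta,
                 runs = runs,
                 anomalies = anomalies,
                 polarization = polar),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> eps_o = %.3f, %d reps per level\n",
              x$eps_o, x$n_reps))
  print(x$frequencies)
  invisible(x)
}

# Final mean densities of surviving (intact) sectors within +/- 15 degrees
# of the stretch axis and of the perpendicular; the contrast between the two
# measures polarization.  Fibers aligned with the stretch that survive it
# are the carriers of the polarization response, so depolymerized sectors
# are excluded; a band with no survivors yields NA.
polarization_densities <- function(out, axis = 0, half_width = 15 * pi / 180) {
  keep <- out$cell$intact
  near_axis <- angle_dist(out$theta, axis) <= half_width & keep
  near_perp <- angle_dist(out$theta, axis + pi / 2) <= half_width & keep
  c(axis = if (any(near_axis)) mean(out$cell$rho[near_axis]) else NA_real_,
    perpendicular = if (any(near_perp)) mean(out$cell$rho[near_perp])
                    else NA_real_)
}

# Acute angular distance between orientations (180-degree periodic).
angle_dist <- function(theta, ref) {
  d <- abs((theta - ref) %% pi)
  pmin(d, pi - d)
}

#' Orientation histogram of depolymerized sectors
#'
#' Bins pooled orientations of depolymerized sectors into equal-width bins of
#' the folded orientation `[0, 90]` degrees (orientations at `theta` and
#' `180 - theta` degrees are mechanically equivalent under uniaxial stretch).
#'
#' @param theta Orientations in radians (e.g. an element of
#'   `sweep_prestretch_sd()$depolymerized_theta`).
#' @param n_bins Number of equal-width bins on `[0, 90]` degrees.
#' @param axis Stretch direction (radians).
#' @return A named integer vector of counts per bin.
#' @export
depoly_orientation_histogram <- function(theta, n_bins = 6L, axis = 0) {
  deg <- angle_dist(theta, axis) * 180 / pi  # folded to [0, 90]
  breaks <- seq(0, 90, length.out = n_bins + 1L)
  h <- table(cut(deg, breaks, include.lowest = TRUE, right = FALSE))
  out <- as.integer(h)
  names(out) <- levels(cut(deg, breaks, include.lowest = TRUE, right = FALSE))
  out
}
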