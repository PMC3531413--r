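#' Simulation parameters for the stress-fiber sector model
#'
#' Collects every tunable of the mechanical model of a cell as a population
#' of oriented stress-fiber sectors.  Two principles govern the dynamics:
#' stress fibers depolymerize when their total stretch leaves an allowable
#' window `[lambda_min, lambda_max]` (tensile rupture above, compressive
#' buckling below), and adhesion-site stress in an intermediate band
#' `[s_low, s_high]` drives polymerization towards a saturating density
#' `rho_max`.  Quantitative values for the allowable window and kinetics are
#' not uniquely established for fibroblasts in 3D constructs.  The defaults
#' below are documented placeholders, chosen in the range reported for
#' stress-fiber viability in cyclically stretched endothelial cells and
#' calibrated so that the model expresses its three characteristic temporal
#' regimes as pre-stretch variability grows (see the package vignette);
#' every one is config-exposed.  The default window is symmetric about the
#' mean pre-stretch, so the critical local strains for tensile rupture of an
#' axis-aligned mean fiber and compressive buckling of a transverse mean
#' fiber coincide at `lambda_max / mu_pre - 1` (about 7.2%).
#'
#' @param lambda_min,lambda_max Allowable total fiber stretch window
#'   (dimensionless stretch ratios), `lambda_min < lambda_max`.
#' @param mu_pre Mean fiber pre-stretch; must lie strictly inside the window.
#' @param sigma_pre Standard deviation of the pre-stretch distribution
#'   (before truncation to the window); `>= 0`.
#' @param n_sectors Number of orientation sectors spanning `[0, pi)`.
#' @param rho0 Initial stress-fiber density per sector (arbitrary units).
#' @param rho_max Saturating density, `>= rho0`.
#' @param k_poly First-order polymerization rate constant (1/min).
#' @param s_low,s_high Adhesion-stress band driving polymerization
#'   (arbitrary stress units), `0 <= s_low < s_high`.
#' @param k_fiber Fiber stiffness scale converting `density * (stretch - 1)`
#'   to adhesion stress.
#' @param dt Forward-Euler time step (min).
#' @param duration Total simulated isometric hold (min).
#' @param seed Integer RNG seed; every stochastic operation in the module
#'   draws from it.
#' @param rock_inhibited Logical; when `TRUE`, polymerization is disabled,
#'   emulating pharmacological inhibition of rho kinase.
#' @param reservoir_finite Logical; when `TRUE`, polymerization draws from a
#'   finite F-actin reservoir and stops when it is exhausted.  The default
#'   `FALSE` reflects the absence of a conservation law for stress-fiber
#'   actin: reservoirs are treated as an effectively unlimited pool.
#' @param reservoir_capacity Initial F-actin reservoir content (density x
#'   angular-width units); only consumed when `reservoir_finite = TRUE`.
#' @param spindle_sd Wrapped-normal angular spread (radians) of sector
#'   orientations about the spindle axis for spindle-shaped cells.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(lambda_min = 1.03,
                       lambda_max = 1.19,
                       mu_pre = 1.11,
                       sigma_pre = 0.045,
                       n_sectors = 36L,
                       rho0 = 1,
                       rho_max = 2.5,
                       k_poly = 0.15,
                       s_low = 0.14,
                       s_high = 0.28,
                       k_fiber = 1,
                       dt = 0.1,
                       duration = 30,
                       seed = 1L,
                       rock_inhibited = FALSE,
                       reservoir_finite = FALSE,
                       reservoir_capacity = 10,
                       spindle_sd = 0.25) {
  p <- list(lambda_min = lambda_min, lambda_max = lambda_max,
            mu_pre = mu_pre, sigma_pre = sigma_pre,
            n_sectors = as.integer(n_sectors),
            rho0 = rho0, rho_max = rho_max, k_poly = k_poly,
            s_low = s_low, s_high = s_high, k_fiber = k_fiber,
            dt = dt, duration = duration, seed = as.integer(seed),
            rock_inhibited = isTRUE(rock_inhibited),
            reservoir_finite = isTRUE(reservoir_finite),
            reservoir_capacity = reservoir_capacity,
            spindle_sd = spindle_sd)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  with(p, {
    if (!(lambda_min < lambda_max)) {
      stop("allowable window requires lambda_min < lambda_max", call. = FALSE)
    }
    if (!(lambda_min < mu_pre && mu_pre < lambda_max)) {
      stop("mean pre-stretch must lie inside the allowable window",
           call. = FALSE)
    }
    if (sigma_pre < 0) stop("sigma_pre must be >= 0", call. = FALSE)
    if (!(rho0 > 0 && rho0 <= rho_max)) {
      stop("initial density must satisfy 0 < rho0 <= rho_max", call. = FALSE)
    }
    if (!(s_low >= 0 && s_low < s_high)) {
      stop("stress band must satisfy 0 <= s_low < s_high", call. = FALSE)
    }
    if (dt <= 0) stop("time step dt must be positive", call. = FALSE)
    if (duration < 0) stop("duration must be >= 0", call. = FALSE)
    if (n_sectors < 2L) stop("need at least 2 sectors", call. = FALSE)
    if (k_poly < 0) stop("k_poly must be >= 0", call. = FALSE)
    if (reservoir_capacity < 0) stop("reservoir_capacity must be >= 0",
                                     call. = FALSE)
  })
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Stress-fiber sector model parameters\n")
  cat(sprintf("  allowable stretch window: [%.3f, %.3f]\n",
              x$lambda_min, x$lambda_max))
  cat(sprintf("  pre-stretch: truncated Normal(%.3f, %.3f)\n",
              x$mu_pre, x$sigma_pre))
  cat(sprintf("  sectors: %d; density: %.2f -> max %.2f; k_poly %.3f /min\n",
              x$n_sectors, x$rho0, x$rho_max, x$k_poly))
  cat(sprintf("  stress band: [%.3f, %.3f] (k_fiber %.2f)\n",
              x$s_low, x$s_high, x$k_fiber))
  cat(sprintf("  dt %.2f min over %.0f min; seed %d%s%s\n",
              x$dt, x$duration, x$seed,
              if (x$rock_inhibited) "; ROCK inhibited" else "",
              if (x$reservoir_finite)
                sprintf("; finite reservoir %.2f", x$reservoir_capacity)
              else ""))
  invisible(x)
}
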