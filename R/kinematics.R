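#' Nominal-to-local strain calibration
#'
#' Ring-shaped engineered tissue constructs (ETCs) mounted on loading bars are
#' far more compliant radially than circumferentially, so only part of the
#' nominal (grip-to-grip) stretch reaches the cells in the planar flanks.
#' A calibration maps nominal ETC strain to the local strain experienced by
#' cells, interpolated piecewise-linearly between measured knots.  The default
#' knots encode the measured relationship: a 10% nominal stretch produces a
#' local stretch of approximately 5%, and a 30% nominal stretch a local
#' stretch of approximately 10%.
#'
#' @param pairs A list (or 2-column matrix) of `(nominal, local)` strain
#'   pairs, both as dimensionless fractions.  Must include `(0, 0)`, have
#'   strictly increasing nominal values, and satisfy `local <= nominal`.
#' @return An object of class `strain_calibration`.
#' @examples
#' cal <- strain_calibration()
#' local_strain(0.10, cal)   # 0.05
#' local_strain(0.30, cal)   # 0.10
#' @export
strain_calibration <- function(pairs = list(c(0, 0), c(0.10, 0.05), c(0.30, 0.10))) {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1L)
  m <- do.call(rbind, lapply(pairs, function(p) {
    if (length(p) != 2L || !is.numeric(p)) {
      stop("each calibration pair must be numeric (nominal, local)", call. = FALSE)
    }
    as.numeric(p)
  }))
  ord <- order(m[, 1L])
  m <- m[ord, , drop = FALSE]
  nominal <- m[, 1L]
  local <- m[, 2L]
  if (anyDuplicated(nominal) || any(diff(nominal) <= 0)) {
    stop("nominal strains must be strictly increasing", call. = FALSE)
  }
  if (!any(nominal == 0 & local == 0)) {
    stop("calibration must contain the (0, 0) pair", call. = FALSE)
  }
  if (any(local > nominal + 1e-12)) {
    stop("local strain cannot exceed nominal strain", call. = FALSE)
  }
  structure(list(nominal = nominal, local = local,
                 interpolation = "piecewise_linear"),
            class = "strain_calibration")
}

#' @export
print.strain_calibration <- function(x, ...) {
  cat("Nominal-to-local strain calibration (piecewise linear)\n")
  print(data.frame(nominal = x$nominal, local = x$local), row.names = FALSE)
  invisible(x)
}

#' Local strain from nominal ETC strain
#'
#' Interpolates the calibration curve at the requested nominal strain.  No
#' extrapolation is performed beyond the calibrated range, because the
#' nominal-to-local relationship is nonlinear and measured at only a few
#' points.
#'
#' @param nominal Nominal ETC strain(s), dimensionless fraction(s) in
#'   `[0, max(calibrated nominal)]`.
#' @param cal A [strain_calibration()].
#' @return Local strain(s), dimensionless fraction(s); exact at the knots.
#' @export
local_strain <- function(nominal, cal = strain_calibration()) {
  stopifnot(is.numeric(nominal))
  if (any(!is.finite(nominal))) stop("nominal strain must be finite", call. = FALSE)
  if (any(nominal < 0) || any(nominal > max(cal$nominal))) {
    stop(sprintf("nominal strain outside calibrated range [0, %g]",
                 max(cal$nominal)), call. = FALSE)
  }
  stats::approx(cal$nominal, cal$local, xout = nominal, method = "linear",
                ties = "ordered")$y
}

#' Orientation-resolved fiber strain under uniaxial ETC stretch
#'
#' A uniaxial local strain `eps_o` applied along `theta = 0` imparts, in a
#' fiber oriented at angle `theta`, the strain
#' `eps(theta) = eps_o * (cos(theta)^2 - nu * sin(theta)^2)`,
#' where `nu` is the effective Poisson ratio of the construct.  For the
#' anisotropic collagen constructs studied here `nu` is approximately 1, so
#' the expression reduces to `eps_o * cos(2 * theta)`: transverse fibers are
#' compressed by as much as axial fibers are stretched, and fibers at
#' +/- 45 degrees to the load are essentially unstrained.
#'
#' @param eps_o Local axial strain (dimensionless fraction).
#' @param theta Fiber orientation(s) in radians, measured from the stretch
#'   axis.  The result is 180-degree periodic.
#' @param nu Effective Poisson ratio (dimensionless).  Values outside the
#'   thermodynamic bounds `[0, 1]` for the assumed transverse isotropy are
#'   accepted with a warning.
#' @return Fiber-direction strain(s), dimensionless fraction(s).
#' @examples
#' fiber_strain(0.10, 0)           #  0.10  (aligned with stretch)
#' fiber_strain(0.10, pi / 4)      #  0     (neutral orientation)
#' fiber_strain(0.05, pi / 2)      # -0.05  (transverse contraction)
#' @export
fiber_strain <- function(eps_o, theta, nu = 1) {
  stopifnot(is.numeric(eps_o), is.numeric(theta), is.numeric(nu))
  if (any(nu < 0 | nu > 1)) {
    warning("effective Poisson ratio outside [0, 1]: outside thermodynamic ",
            "bounds for a transversely isotropic construct", call. = FALSE)
  }
  eps_o * (cos(theta)^2 - nu * sin(theta)^2)
}

#' Bead displacement field
#'
#' Index-matched coordinates of fluorescent beads embedded in the construct,
#' imaged before and after stretch.  Used to estimate the local deformation
#' gradient by affine least squares.
#'
#' @param before,after Two-column matrices (or data frames) of bead
#'   coordinates in micrometres, row-matched between the two states.
#' @return An object of class `bead_field`: a data frame with columns
#'   `x_before`, `y_before`, `x_after`, `y_after`.
#' @export
bead_field <- function(before, after) {
  before <- as.matrix(before)
  after <- as.matrix(after)
  if (!is.numeric(before) || !is.numeric(after) ||
      ncol(before) != 2L || ncol(after) != 2L) {
    stop("bead coordinates must be numeric n x 2 matrices", call. = FALSE)
  }
  if (nrow(before) != nrow(after)) {
    stop("before/after bead sets must be index-matched (equal lengths)",
         call. = FALSE)
  }
  structure(data.frame(x_before = before[, 1L], y_before = before[, 2L],
                       x_after = after[, 1L], y_after = after[, 2L]),
            class = c("bead_field", "data.frame"))
}

#' Read or write a bead field as CSV
#'
#' The on-disk format is a CSV with header
#' `x_before,y_before,x_after,y_after`, coordinates in micrometres.
#'
#' @param path File path.
#' @return `read_bead_field` returns a [bead_field()];
#'   `write_bead_field` returns `path` invisibly.
#' @export
read_bead_field <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_before", "y_before", "x_after", "y_after")
  if (!all(need %in% names(d))) {
    stop("bead CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  bead_field(d[, c("x_before", "y_before")], d[, c("x_after", "y_after")])
}

#' @rdname read_bead_field
#' @param beads A [bead_field()].
#' @export
write_bead_field <- function(beads, path) {
  utils::write.csv(as.data.frame(unclass(beads)), path, row.names = FALSE)
  invisible(path)
}

#' Affine strain estimation from bead displacements
#'
#' Fits `after = F %*% before + t` by least squares over all beads and
#' extracts engineering strains from the deformation gradient `F` as
#' `diag(F) - 1` (small-strain extraction, adequate for the <= 10% local
#' strains of interest).
#'
#' @param beads A [bead_field()] with at least 3 non-collinear beads.
#' @return A list with elements `F` (2x2 deformation gradient),
#'   `translation` (length-2), `axial` and `transverse` strains
#'   (`F[1,1] - 1`, `F[2,2] - 1`), and `n` (bead count).
#' @export
estimate_affine <- function(beads) {
  stopifnot(inherits(beads, "bead_field"))
  n <- nrow(beads)
  if (n < 3L) stop("affine fitting requires at least 3 beads", call. = FALSE)
  X <- cbind(beads$x_before, beads$y_before)
  # collinearity check on the centred reference configuration
  sv <- svd(scale(X, center = TRUE, scale = FALSE))$d
  if (sv[2L] <= max(sv[1L], 1) * 1e-10) {
    stop("bead configuration is collinear or degenerate; affine fit is singular",
         call. = FALSE)
  }
  D <- cbind(X, 1)
  coef <- qr.solve(D, cbind(beads$x_after, beads$y_after))
  Fg <- t(coef[1:2, , drop = FALSE])
  dimnames(Fg) <- NULL
  list(F = Fg,
       translation = as.numeric(coef[3L, ]),
       axial = Fg[1L, 1L] - 1,
       transverse = Fg[2L, 2L] - 1,
       n = n)
}

#' Effective Poisson ratio from measured strains
#'
#' @param axial Axial strain (dimensionless fraction, nonzero).
#' @param transverse Transverse strain (dimensionless fraction).
#' @return `-transverse / axial`.
#' @export
poisson_ratio <- function(axial, transverse) {
  stopifnot(is.numeric(axial), is.numeric(transverse))
  if (any(axial == 0)) {
    stop("Poisson ratio is undefined at zero axial strain", call. = FALSE)
  }
  -transverse / axial
}

#' Passive cell area change under uniaxial stretch
#'
#' First-order estimate of the relative area change of a passive inclusion
#' deforming in registry with the construct:
#' `(1 + eps_o) * (1 - nu * eps_o) - 1`.  At `nu = 1` this is `-eps_o^2`,
#' i.e. negligible for the strains studied, which is why fibrosity changes
#' cannot be attributed to passive area change.
#'
#' @inheritParams fiber_strain
#' @return Relative area change (dimensionless fraction).
#' @examples
#' area_change(0.05, 1)   # -0.0025
#' area_change(0.10, 0)   #  0.10
#' @export
area_change <- function(eps_o, nu = 1) {
  stopifnot(is.numeric(eps_o), is.numeric(nu))
  (1 + eps_o) * (1 - nu * eps_o) - 1
}
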