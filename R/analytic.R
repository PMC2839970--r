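#' Exact potential of two parallel cylindrical electrodes
#'
#' Closed-form solution of the Laplace equation for two equal-radius
#' cylinders held at potentials -C/2 and +C/2 in an unbounded homogeneous
#' medium, by the classical two-wire image construction: a pair of image
#' line charges at `(+-a, 0)` with `a = sqrt(1/4 - r^2)` makes both
#' electrode circles (centers `(+-1/2, 0)`, radius `r`) exact
#' equipotentials.  The potential is
#' \deqn{\phi^*(x, y) = \frac{C/2}{\cosh^{-1}(1/(2r))}
#'   \ln\frac{\rho_-}{\rho_+}}
#' with \eqn{\rho_{\pm}} the distances to the image charges at
#' \eqn{(\pm a, 0)}, and the field is its analytic gradient magnitude.
#' This is the validation oracle for [solve_potential()].
#'
#' @param config a dimensionless [electrode_config()] with equal radii and
#'   centers at `(+-1/2, 0)`.
#' @return an object of class `"two_cylinder_analytic"`: a list with
#'   vectorised functions `potential(x, y)` and `field(x, y)` (dimensionless
#'   field magnitude), plus the construction constants `a` (image-charge
#'   abscissa), `tau0` (electrode bipolar coordinate), `r` and `C`.
#' @examples
#' cfg <- electrode_config(radii = 0.05, applied_voltage = 1)
#' sol <- analytic_two_cylinder(cfg)
#' sol$potential(0, 0)      # 0 by antisymmetry
#' sol$potential(0.45, 0)   # 0.5 = +C/2 on the right electrode surface
#' @export
analytic_two_cylinder <- function(config) {
  stopifnot(inherits(config, "electrode_config"))
  if (inherits(config, "plate_config"))
    stop("unsupported geometry: the image-charge oracle needs two cylinders",
         call. = FALSE)
  if (config$mode != "dimensionless")
    stop("config must be dimensionless (see nondimensionalize_config)",
         call. = FALSE)
  r <- config$radius_1
  if (abs(config$radius_2 - r) > 1e-12 * r)
    stop("unsupported geometry: the image-charge oracle requires equal radii",
         call. = FALSE)
  if (r >= 0.5)
    stop("radius must be < 1/2 (electrodes must not touch)", call. = FALSE)
  C <- config$applied_voltage
  a <- sqrt(0.25 - r^2)
  tau0 <- acosh(0.5 / r)   # = log((0.5 + a)/r)
  K <- (C / 2) / tau0

  potential <- function(x, y) {
    rp2 <- (x - a)^2 + y^2
    rm2 <- (x + a)^2 + y^2
    0.5 * K * (log(rm2) - log(rp2))
  }
  field <- function(x, y) {
    rp2 <- (x - a)^2 + y^2
    rm2 <- (x + a)^2 + y^2
    gx <- K * ((x + a) / rm2 - (x - a) / rp2)
    gy <- K * (y / rm2 - y / rp2)
    sqrt(gx^2 + gy^2)
  }
  structure(list(potential = potential, field = field,
                 a = a, tau0 = tau0, r = r, C = C),
            class = "two_cylinder_analytic")
}

#' @export
print.two_cylinder_analytic <- function(x, ...) {
  cat("Two-cylinder image-charge solution\n")
  cat(sprintf("  r = %g, C = %g, image charges at x = %+.6f, tau0 = %.6f\n",
              x$r, x$C, x$a, x$tau0))
  invisible(x)
}
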