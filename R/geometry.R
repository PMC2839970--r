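# Electrode geometry for the two-needle (parallel cylinder) configuration.
# Canonical frame: origin at the midpoint between the electrode centers,
# x-axis through both centers, so the centers sit at (-L/2, 0), (+L/2, 0).

#' Two-electrode configuration
#'
#' Describes a pair of parallel cylindrical electrodes (a 2-D cross
#' section: two disks) in a rectangular tissue domain, either in
#' dimensional units (meters, volts, S/m) or in dimensionless form where
#' the center separation is the unit of length and the applied voltage is
#' the dimensionless `C = V / (Eco L)`.
#'
#' @param separation center-to-center distance `L`: meters in dimensional
#'   mode, exactly 1 in dimensionless mode.
#' @param radii electrode radii, length-2 (or length-1, recycled), in the
#'   same length unit as `separation`.
#' @param applied_voltage potential difference between the electrodes:
#'   volts in dimensional mode, the dimensionless `C` otherwise.  The
#'   solver gauges the pair antisymmetrically at -V/2 (left electrode,
#'   negative x) and +V/2 (right).
#' @param conductivity tissue conductivity in S/m (dimensional mode only;
#'   it cancels from the homogeneous field equation but is carried for
#'   provenance and current computations).
#' @param domain_extent rectangle `c(xmin, xmax, ymin, ymax)` in the same
#'   length unit; default 4L x 4L centered on the electrode pair.
#' @param mode `"dimensionless"` or `"dimensional"`.
#' @return an object of class `"electrode_config"`.
#' @examples
#' # two 1 mm diameter needles, 1 cm apart, in 0.42 S/m tissue at 2250 V
#' cfg <- electrode_config(separation = 0.01, radii = 5e-4,
#'                         applied_voltage = 2250, conductivity = 0.42,
#'                         mode = "dimensional")
#' nondimensionalize_config(cfg, Eco = 1.5e5)  # C = 1.5
#' @export
electrode_config <- function(separation = 1, radii = 0.05,
                             applied_voltage = 1, conductivity = NULL,
                             domain_extent = NULL,
                             mode = c("dimensionless", "dimensional")) {
  mode <- match.arg(mode)
  if (!is.finite(separation) || separation <= 0)
    stop("'separation' must be > 0", call. = FALSE)
  radii <- rep_len(as.numeric(radii), 2L)
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("'radii' must be > 0", call. = FALSE)
  if (separation <= sum(radii))
    stop("electrodes overlap: separation (", separation,
         ") must exceed the sum of radii (", sum(radii), ")", call. = FALSE)
  if (mode == "dimensional") {
    if (is.null(conductivity) || !is.finite(conductivity) || conductivity <= 0)
      stop("dimensional mode requires conductivity > 0 (S/m)", call. = FALSE)
  } else {
    conductivity <- NULL
    if (abs(separation - 1) > 1e-12)
      stop("dimensionless mode fixes the separation at 1 ",
           "(lengths are in units of L)", call. = FALSE)
  }
  if (is.null(domain_extent))
    domain_extent <- separation * c(-2, 2, -2, 2)
  domain_extent <- as.numeric(domain_extent)
  if (length(domain_extent) != 4L || domain_extent[1] >= domain_extent[2] ||
      domain_extent[3] >= domain_extent[4])
    stop("'domain_extent' must be c(xmin, xmax, ymin, ymax)", call. = FALSE)
  centers <- rbind(c(-separation / 2, 0), c(separation / 2, 0))
  for (k in 1:2) {
    if (centers[k, 1] - radii[k] <= domain_extent[1] ||
        centers[k, 1] + radii[k] >= domain_extent[2] ||
        centers[k, 2] - radii[k] <= domain_extent[3] ||
        centers[k, 2] + radii[k] >= domain_extent[4])
      stop("electrode ", k, " is not strictly inside the domain",
           call. = FALSE)
  }
  structure(
    list(center_1 = centers[1, ], center_2 = centers[2, ],
         radius_1 = radii[1], radius_2 = radii[2],
         applied_voltage = as.numeric(applied_voltage),
         conductivity = conductivity, L = as.numeric(separation),
         domain_extent = domain_extent, mode = mode),
    class = "electrode_config")
}

#' @export
print.electrode_config <- function(x, ...) {
  u <- if (x$mode == "dimensional") "m" else "(units of L)"
  cat(sprintf("Two-electrode configuration [%s]\n", x$mode))
  cat(sprintf("  centers: (%g, %g), (%g, %g) %s;  radii: %g, %g %s\n",
              x$center_1[1], x$center_1[2], x$center_2[1], x$center_2[2], u,
              x$radius_1, x$radius_2, u))
  cat(sprintf("  applied voltage: %g %s\n", x$applied_voltage,
              if (x$mode == "dimensional") "V" else "(C, dimensionless)"))
  if (!is.null(x$conductivity))
    cat(sprintf("  conductivity: %g S/m\n", x$conductivity))
  cat(sprintf("  domain: [%g, %g] x [%g, %g]\n", x$domain_extent[1],
              x$domain_extent[2], x$domain_extent[3], x$domain_extent[4]))
  invisible(x)
}

#' Cast a dimensional configuration into dimensionless form
#'
#' Space is rescaled by the electrode separation `L` and field quantities
#' by the reference field `Eco` (the n = 0 midpoint of the survival
#' model), giving centers at (-1/2, 0), (1/2, 0) and the dimensionless
#' applied voltage `C = V / (Eco L)`.  [dimensionalize_config()] inverts
#' the transformation exactly.
#'
#' @param config a dimensional [electrode_config()].
#' @param Eco reference field, V/m, > 0.
#' @return a dimensionless `electrode_config` whose `applied_voltage` is
#'   `C`; the original `L`, `Eco` and conductivity are kept in attributes
#'   `"dimensional"` for the round trip.
#' @export
nondimensionalize_config <- function(config, Eco) {
  stopifnot(inherits(config, "electrode_config"))
  if (config$mode != "dimensional")
    stop("config is already dimensionless", call. = FALSE)
  if (!is.finite(Eco) || Eco <= 0) stop("'Eco' must be > 0", call. = FALSE)
  L <- config$L
  if (L <= 0) stop("zero electrode separation", call. = FALSE)
  out <- electrode_config(
    separation = 1, radii = c(config$radius_1, config$radius_2) / L,
    applied_voltage = config$applied_voltage / (Eco * L),
    domain_extent = config$domain_extent / L,
    mode = "dimensionless")
  attr(out, "dimensional") <- list(L = L, Eco = Eco,
                                   conductivity = config$conductivity,
                                   applied_voltage = config$applied_voltage)
  out
}

#' @rdname nondimensionalize_config
#' @param L electrode separation in meters; defaults to the value recorded
#'   by [nondimensionalize_config()].
#' @param conductivity tissue conductivity, S/m; same default.
#' @export
dimensionalize_config <- function(config, Eco, L = NULL,
                                  conductivity = NULL) {
  stopifnot(inherits(config, "electrode_config"))
  if (config$mode != "dimensionless")
    stop("config is already dimensional", call. = FALSE)
  dim_attr <- attr(config, "dimensional")
  if (is.null(L)) L <- dim_attr$L
  if (is.null(conductivity)) conductivity <- dim_attr$conductivity
  if (is.null(L)) stop("supply 'L' (meters)", call. = FALSE)
  electrode_config(
    separation = L, radii = c(config$radius_1, config$radius_2) * L,
    applied_voltage = config$applied_voltage * Eco * L,
    conductivity = conductivity,
    domain_extent = config$domain_extent * L, mode = "dimensional")
}

#' Parallel-plate configuration
#'
#' Degenerate 1-D geometry in which the left and right edges of the
#' rectangular domain act as the electrodes at -C/2 and +C/2 (no
#' cylinders).  The exact solution is a linear potential with uniform
#' field `|E*| = C / width`; with the default unit-width domain,
#' `|E*| = C`.  Used for solver verification and uniform-exposure maps.
#'
#' @param C dimensionless applied voltage.
#' @param domain_extent rectangle `c(xmin, xmax, ymin, ymax)`; default the
#'   unit square centered at the origin.
#' @return object of classes `"plate_config"` and `"electrode_config"`.
#' @export
plate_config <- function(C = 1, domain_extent = c(-0.5, 0.5, -0.5, 0.5)) {
  domain_extent <- as.numeric(domain_extent)
  if (length(domain_extent) != 4L || domain_extent[1] >= domain_extent[2] ||
      domain_extent[3] >= domain_extent[4])
    stop("'domain_extent' must be c(xmin, xmax, ymin, ymax)", call. = FALSE)
  structure(
    list(applied_voltage = as.numeric(C), domain_extent = domain_extent,
         mode = "dimensionless"),
    class = c("plate_config", "electrode_config"))
}
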