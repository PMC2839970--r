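# Finite-difference solution of the dimensionless steady-state field
# equation (Laplace, homogeneous conductivity) on a uniform node-centered
# grid.  Electrode disks are Dirichlet at -C/2 / +C/2; the outer rectangle
# is insulating (homogeneous Neumann via mirror ghost nodes) by default.
# Interior nodes with a neighbor inside an electrode disk use
# Shortley-Weller fractional arms to the exact circle intersection, which
# restores second-order accuracy at the curved Dirichlet boundaries.
# The linear system is solved by a sparse direct factorization; the
# reported relative residual is the contract (tolerance checked, one step
# of iterative refinement if needed).

MASK_INTERIOR <- 0L
MASK_ELECTRODE_1 <- 1L
MASK_ELECTRODE_2 <- 2L

# exact fractional distance (in units of h) from outside node (px,py) to
# the circle (cx,cy,r) along direction (ux,uy); segment end is inside
.arm_theta <- function(px, py, cx, cy, r, ux, uy, h) {
  dx <- px - cx; dy <- py - cy
  B <- 2 * h * (dx * ux + dy * uy)
  Cq <- dx^2 + dy^2 - r^2
  disc <- B^2 - 4 * h^2 * Cq
  if (disc < 0) disc <- 0
  s <- (-B - sqrt(disc)) / (2 * h^2)
  if (!is.finite(s) || s > 1) s <- 1
  max(s, 1e-6)
}

#' Solve the dimensionless potential for an electrode configuration
#'
#' Finite-difference (5-point, Shortley-Weller at the electrode circles)
#' solution of the Laplace equation for the potential, with the electrodes
#' held at -C/2 and +C/2 and insulating outer boundaries.  Deterministic
#' for fixed inputs.
#'
#' @param config a dimensionless [electrode_config()] (or
#'   [plate_config()]).  Dimensional configurations must first go through
#'   [nondimensionalize_config()].
#' @param h grid spacing, in units of the electrode separation `L`.  Each
#'   electrode disk must cover at least 4 grid nodes.
#' @param tol relative residual tolerance of the linear solve.
#' @param outer_bc `"neumann"` (insulating outer rectangle, the physical
#'   boundary condition) or `"analytic"` (Dirichlet trace of the
#'   unbounded-medium image-charge solution on the outer rectangle; used
#'   to validate the solver against [analytic_two_cylinder()], whose
#'   solution lives in an unbounded medium).
#' @return an object of class `"field_solution"`: list with node
#'   coordinate vectors `x`, `y`, spacing `h`, matrices `potential` and
#'   `field_magnitude` (`[i, j]` is node `(x[i], y[j])`), integer `mask`
#'   (0 tissue, 1/2 electrode disks), the achieved relative `residual`,
#'   the dimensionless voltage `C`, and the `config`.
#' @examples
#' cfg <- electrode_config(radii = 0.05, applied_voltage = 1)
#' sol <- solve_potential(cfg, h = 0.04)
#' range(sol$potential)   # -0.5, 0.5: extremes on the electrodes
#' @export
solve_potential <- function(config, h = 0.01, tol = 1e-8,
                            outer_bc = c("neumann", "analytic")) {
  stopifnot(inherits(config, "electrode_config"))
  outer_bc <- match.arg(outer_bc)
  if (config$mode != "dimensional") {
    # ok: dimensionless expected
  } else {
    stop("config is dimensional; apply nondimensionalize_config() first ",
         "(the solver works in dimensionless form)", call. = FALSE)
  }
  is_plate <- inherits(config, "plate_config")
  if (is_plate && outer_bc == "analytic")
    stop("analytic outer boundary applies to the two-cylinder geometry only",
         call. = FALSE)
  ext <- config$domain_extent
  nx <- round((ext[2] - ext[1]) / h) + 1L
  ny <- round((ext[4] - ext[3]) / h) + 1L
  if (abs((ext[2] - ext[1]) - (nx - 1L) * h) > 1e-9 * h ||
      abs((ext[4] - ext[3]) - (ny - 1L) * h) > 1e-9 * h)
    stop("'h' must divide the domain extent evenly", call. = FALSE)
  if (nx < 3L || ny < 3L) stop("grid too coarse", call. = FALSE)
  xs <- ext[1] + (seq_len(nx) - 1L) * h
  ys <- ext[3] + (seq_len(ny) - 1L) * h
  C <- config$applied_voltage

  mask <- matrix(MASK_INTERIOR, nx, ny)
  circles <- NULL
  if (!is_plate) {
    circles <- list(
      list(c = config$center_1, r = config$radius_1,
           code = MASK_ELECTRODE_1, value = -C / 2),
      list(c = config$center_2, r = config$radius_2,
           code = MASK_ELECTRODE_2, value = +C / 2))
    X <- matrix(xs, nx, ny)
    Y <- matrix(ys, nx, ny, byrow = TRUE)
    for (cc in circles) {
      inside <- (X - cc$c[1])^2 + (Y - cc$c[2])^2 <= cc$r^2
      if (sum(inside) < 4L)
        stop("electrode under-resolved: disk at (", cc$c[1], ", ", cc$c[2],
             ") covers ", sum(inside), " nodes; decrease h", call. = FALSE)
      if (cc$c[1] - cc$r < ext[1] + h || cc$c[1] + cc$r > ext[2] - h ||
          cc$c[2] - cc$r < ext[3] + h || cc$c[2] + cc$r > ext[4] - h)
        stop("electrode clearance to the outer boundary is below one ",
             "grid cell", call. = FALSE)
      mask[inside] <- cc$code
    }
  }

  # Dirichlet values per node (NA = unknown)
  dirichlet <- matrix(NA_real_, nx, ny)
  dirichlet[mask == MASK_ELECTRODE_1] <- -C / 2
  dirichlet[mask == MASK_ELECTRODE_2] <- +C / 2
  if (is_plate) {
    dirichlet[1L, ] <- -C / 2
    dirichlet[nx, ] <- +C / 2
    mask[1L, ] <- MASK_ELECTRODE_1
    mask[nx, ] <- MASK_ELECTRODE_2
  }
  oracle <- NULL
  if (outer_bc == "analytic") {
    oracle <- analytic_two_cylinder(config)
    dirichlet[1L, ] <- oracle$potential(xs[1L], ys)
    dirichlet[nx, ] <- oracle$potential(xs[nx], ys)
    dirichlet[, 1L] <- oracle$potential(xs, ys[1L])
    dirichlet[, ny] <- oracle$potential(xs, ys[ny])
    # electrode disks keep their values
    dirichlet[mask == MASK_ELECTRODE_1] <- -C / 2
    dirichlet[mask == MASK_ELECTRODE_2] <- +C / 2
  }

  is_dir <- !is.na(dirichlet)
  unknown <- which(!is_dir)
  map <- integer(nx * ny)
  map[unknown] <- seq_along(unknown)
  nun <- length(unknown)

  # classify unknown nodes: regular (4 in-grid unknown neighbors) vs special
  ii <- ((unknown - 1L) %% nx) + 1L
  jj <- ((unknown - 1L) %/% nx) + 1L
  on_edge <- ii == 1L | ii == nx | jj == 1L | jj == ny
  ngb_dir <- logical(nun)
  interior_sel <- !on_edge
  if (any(interior_sel)) {
    idx <- unknown[interior_sel]
    ngb_dir[interior_sel] <- is_dir[idx - 1L] | is_dir[idx + 1L] |
      is_dir[idx - nx] | is_dir[idx + nx]
  }
  regular <- !on_edge & !ngb_dir
  special <- which(!regular)

  # triplets for regular nodes (equations scaled by h^2)
  reg_idx <- unknown[regular]
  ti <- c(map[reg_idx], map[reg_idx], map[reg_idx], map[reg_idx],
          map[reg_idx])
  tj <- c(map[reg_idx], map[reg_idx - 1L], map[reg_idx + 1L],
          map[reg_idx - nx], map[reg_idx + nx])
  tv <- c(rep(-4, length(reg_idx)), rep(1, 4L * length(reg_idx)))
  b <- numeric(nun)

  if (length(special)) {
    sp_i <- list(); sp_j <- list(); sp_v <- list()
    push <- function(row, col, val) {
      k <- length(sp_i) + 1L
      sp_i[[k]] <<- row; sp_j[[k]] <<- col; sp_v[[k]] <<- val
    }
    for (s in special) {
      lin <- unknown[s]
      i <- ii[s]; j <- jj[s]
      row <- map[lin]
      px <- xs[i]; py <- ys[j]
      get_arm <- function(di, dj) {
        i2 <- i + di; j2 <- j + dj
        if (i2 < 1L || i2 > nx || j2 < 1L || j2 > ny)
          return(list(type = "mirror"))
        lin2 <- i2 + (j2 - 1L) * nx
        if (is_dir[lin2]) {
          theta <- 1
          if (!is.null(circles) && mask[i2, j2] > MASK_INTERIOR) {
            cc <- circles[[mask[i2, j2]]]
            theta <- .arm_theta(px, py, cc$c[1], cc$c[2], cc$r, di, dj, h)
          }
          list(type = "dirichlet", value = dirichlet[i2, j2], theta = theta)
        } else {
          list(type = "unknown", id = map[lin2], theta = 1)
        }
      }
      for (axis in 1:2) {
        if (axis == 1L) {
          ap <- get_arm(1L, 0L); am <- get_arm(-1L, 0L)
        } else {
          ap <- get_arm(0L, 1L); am <- get_arm(0L, -1L)
        }
        if (ap$type == "mirror") ap <- am
        if (am$type == "mirror") am <- ap
        tp <- ap$theta; tm <- am$theta
        cp <- 2 / (tp * (tp + tm))
        cm <- 2 / (tm * (tp + tm))
        c0 <- -2 / (tp * tm)
        push(row, row, c0)
        if (ap$type == "unknown") push(row, ap$id, cp)
        else b[row] <- b[row] - cp * ap$value
        if (am$type == "unknown") push(row, am$id, cm)
        else b[row] <- b[row] - cm * am$value
      }
    }
    ti <- c(ti, unlist(sp_i)); tj <- c(tj, unlist(sp_j))
    tv <- c(tv, unlist(sp_v))
  }

  # RHS contributions from Dirichlet neighbors of regular nodes
  for (off in c(-1L, 1L, -nx, nx)) {
    nb <- reg_idx + off
    has <- is_dir[nb]
    if (any(has))
      b[map[reg_idx[has]]] <- b[map[reg_idx[has]]] - dirichlet[nb[has]]
  }

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(nun, nun))
  u <- as.numeric(Matrix::solve(A, b))
  bnorm <- max(sqrt(sum(b^2)), .Machine$double.xmin)
  resid <- sqrt(sum((as.numeric(A %*% u) - b)^2)) / bnorm
  if (resid > tol) {          # one step of iterative refinement
    u <- u + as.numeric(Matrix::solve(A, b - as.numeric(A %*% u)))
    resid <- sqrt(sum((as.numeric(A %*% u) - b)^2)) / bnorm
  }
  if (resid > tol)
    stop("linear solve did not reach the residual tolerance: residual = ",
         signif(resid, 3), " > ", tol, call. = FALSE)

  potential <- dirichlet
  potential[unknown] <- u

  sol <- structure(
    list(x = xs, y = ys, h = h, potential = potential,
         field_magnitude = NULL, mask = mask, residual = resid, C = C,
         outer_bc = outer_bc, config = config),
    class = "field_solution")
  sol$field_magnitude <- field_magnitude(sol)
  sol
}

#' Dimensionless field magnitude of a solved potential
#'
#' `E* = sqrt((d phi*/dx*)^2 + (d phi*/dy*)^2)` by central differences at
#' interior nodes and one-sided differences at nodes adjacent to electrode
#' disks or to the outer rectangle.  Electrode-interior nodes get 0 (they
#' are not tissue and are excluded from all metrics).
#'
#' @param solution a [solve_potential()] result (or any list with
#'   `potential`, `h`, `mask`).
#' @return matrix of non-negative field magnitudes, same shape as the
#'   potential.
#' @export
field_magnitude <- function(solution) {
  phi <- solution$potential
  h <- solution$h
  usable <- solution$mask == MASK_INTERIOR
  # Dirichlet plate/outer-edge nodes hold valid tissue potentials except
  # electrode disks; for plates the edge columns ARE the electrodes, whose
  # surface field is still physical, so keep them usable for one-sided use
  nx <- nrow(phi); ny <- ncol(phi)
  d_axis <- function(phi, usable, along_rows) {
    if (!along_rows) { phi <- t(phi); usable <- t(usable) }
    n <- nrow(phi)
    dp <- matrix(0, nrow(phi), ncol(phi))
    up <- rbind(usable[-1, , drop = FALSE], FALSE)   # east neighbor usable
    um <- rbind(FALSE, usable[-n, , drop = FALSE])   # west neighbor usable
    pe <- rbind(phi[-1, , drop = FALSE], NA)
    pw <- rbind(NA, phi[-n, , drop = FALSE])
    central <- up & um
    dp[central] <- (pe[central] - pw[central]) / (2 * h)
    east_only <- up & !um
    dp[east_only] <- (pe[east_only] - phi[east_only]) / h
    west_only <- um & !up
    dp[west_only] <- (phi[west_only] - pw[west_only]) / h
    if (!along_rows) dp <- t(dp)
    dp
  }
  # a neighbor is usable for differencing iff it is a tissue node OR an
  # outer-edge node carrying a Dirichlet trace (analytic validation mode);
  # electrode-disk nodes are never differenced across
  tissue <- solution$mask == MASK_INTERIOR
  dx <- d_axis(phi, tissue, TRUE)
  dy <- d_axis(phi, tissue, FALSE)
  E <- sqrt(dx^2 + dy^2)
  E[!tissue] <- 0
  E
}

#' Scale a field solution to a different applied voltage
#'
#' The field equation is linear, so the solution at voltage `C2` is the
#' unit solution times `C2`.  Used by [parametric_sweep()] to solve once
#' per geometry.
#'
#' @param solution a [solve_potential()] result.
#' @param C2 target dimensionless voltage.
#' @return a `field_solution` at voltage `C2`.
#' @export
scale_field_solution <- function(solution, C2) {
  stopifnot(inherits(solution, "field_solution"))
  f <- C2 / solution$C
  if (!is.finite(f))
    stop("cannot rescale a zero-voltage solution", call. = FALSE)
  solution$potential <- solution$potential * f
  solution$field_magnitude <- solution$field_magnitude * abs(f)
  solution$C <- C2
  solution$config$applied_voltage <- C2
  solution
}

#' @export
print.field_solution <- function(x, ...) {
  cat("Dimensionless field solution\n")
  cat(sprintf("  grid: %d x %d nodes, h = %g; C = %g; outer boundary: %s\n",
              length(x$x), length(x$y), x$h, x$C, x$outer_bc))
  cat(sprintf("  potential range: [%.4g, %.4g]; max |E*| = %.4g\n",
              min(x$potential), max(x$potential),
              max(x$field_magnitude)))
  cat(sprintf("  relative residual: %.3g\n", x$residual))
  invisible(x)
}

#' Plot a field solution
#'
#' Filled image of the dimensionless field magnitude (or potential) with
#' electrode outlines.
#'
#' @param x a [solve_potential()] result.
#' @param what `"field"` or `"potential"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.field_solution <- function(x, what = c("field", "potential"), ...) {
  what <- match.arg(what)
  z <- if (what == "field") x$field_magnitude else x$potential
  graphics::image(x$x, x$y, z, asp = 1, xlab = "x*", ylab = "y*",
                  main = if (what == "field")
                    "dimensionless field magnitude |E*|"
                  else "dimensionless potential", useRaster = TRUE, ...)
  graphics::contour(x$x, x$y, z, add = TRUE, nlevels = 12,
                    col = "grey30")
  invisible(x)
}
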