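# finite-difference field solver and its analytic oracle

test_that("parallel-plate geometry reproduces the 1-D closed form", {
  C <- 1.8
  sol <- solve_potential(plate_config(C), h = 0.05)
  # linear potential in x, independent of y
  X <- matrix(sol$x, length(sol$x), length(sol$y))
  expect_equal(sol$potential, C * X, tolerance = 1e-10,
               ignore_attr = TRUE)
  # uniform field |E*| = C on all tissue nodes (domain width 1)
  tissue <- sol$mask == 0L
  expect_equal(unname(sol$field_magnitude[tissue]),
               rep(C, sum(tissue)), tolerance = 1e-10)
})

test_that("constant and linear potentials give exact field magnitudes", {
  # field_magnitude is exact for linear fields under central differences
  sol <- list(potential = matrix(0.7, 11, 11), h = 0.1,
              mask = matrix(0L, 11, 11))
  expect_true(all(field_magnitude(sol) == 0))
  x <- seq(0, 1, 0.1)
  sol$potential <- matrix(3 * x, 11, 11)
  expect_equal(field_magnitude(sol), matrix(3, 11, 11),
               tolerance = 1e-12)
})

test_that("the analytic oracle has equipotential electrode surfaces", {
  an <- analytic_two_cylinder(small_cylinder_config(C = 1))
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  right <- an$potential(0.5 + 0.05 * cos(th), 0.05 * sin(th))
  left <- an$potential(-0.5 + 0.05 * cos(th), 0.05 * sin(th))
  expect_lt(max(abs(right - 0.5)), 1e-10)
  expect_lt(max(abs(left + 0.5)), 1e-10)
  expect_identical(an$potential(0, 0), 0)   # midpoint, by antisymmetry
  expect_error(analytic_two_cylinder(
    electrode_config(radii = c(0.04, 0.06), applied_voltage = 1)),
    "equal radii")
})

test_that("the analytic potential is discretely harmonic to O(h^2)", {
  an <- analytic_two_cylinder(small_cylinder_config(C = 1))
  pts <- rbind(c(0.1, 0.2), c(-0.3, 0.15), c(0.2, -0.4), c(0, 0.3))
  lap <- function(h) max(abs(apply(pts, 1, function(p) {
    (an$potential(p[1] + h, p[2]) + an$potential(p[1] - h, p[2]) +
       an$potential(p[1], p[2] + h) + an$potential(p[1], p[2] - h) -
       4 * an$potential(p[1], p[2])) / h^2
  })))
  l1 <- lap(1e-2); l2 <- lap(5e-3)
  expect_lt(l1, 1e-2)
  expect_lt(l2 / l1, 0.3)   # ~ quartered when h is halved
})

test_that("two-cylinder solve matches the oracle away from the collar", {
  cfg <- small_cylinder_config(C = 1)
  sol <- solve_potential(cfg, h = 0.025, outer_bc = "analytic")
  an <- analytic_two_cylinder(cfg)
  sel <- outside_collar(sol)
  expect_lt(rel_l2(sol$potential, eval_on_grid(an, sol), sel), 0.01)
  Ee <- eval_on_grid(an, sol, "field")
  expect_lt(max(abs(sol$field_magnitude[sel] - Ee[sel]) / Ee[sel]), 0.05)
})

test_that("solution is antisymmetric and obeys the maximum principle", {
  sol <- solve_potential(small_cylinder_config(C = 1), h = 0.025)
  # electrode potentials are the extremes; tissue strictly inside
  expect_identical(range(sol$potential), c(-0.5, 0.5))
  tissue <- sol$mask == 0L
  expect_true(all(abs(sol$potential[tissue]) < 0.5))
  # phi(-x, y) = -phi(x, y) for the symmetric geometry and boundary data
  flipped <- sol$potential[rev(seq_along(sol$x)), ]
  expect_lt(max(abs(sol$potential + flipped)), 1e-6)
  expect_lt(sol$residual, 1e-8)
  expect_true(all(sol$field_magnitude >= 0))
})

test_that("the solve is linear in the applied voltage", {
  s1 <- solve_potential(small_cylinder_config(C = 1), h = 0.025)
  s2 <- solve_potential(small_cylinder_config(C = 2), h = 0.025)
  expect_equal(s2$potential, 2 * s1$potential, tolerance = 1e-12)
  sc <- scale_field_solution(s1, 2)
  expect_equal(sc$potential, s2$potential, tolerance = 1e-12)
  expect_equal(sc$field_magnitude, s2$field_magnitude, tolerance = 1e-12)
})

test_that("dimensional geometry nondimensionalizes to the expected C", {
  # 1 mm diameter needles, 1 cm apart, 0.42 S/m tissue
  cfg <- electrode_config(separation = 0.01, radii = 5e-4,
                          applied_voltage = 2250, conductivity = 0.42,
                          mode = "dimensional")
  dl <- nondimensionalize_config(cfg, Eco = 1.5e5)
  expect_equal(dl$applied_voltage, 1.5, tolerance = 1e-12)  # C = V/(Eco L)
  expect_equal(c(dl$center_1, dl$center_2), c(-0.5, 0, 0.5, 0))
  expect_equal(c(dl$radius_1, dl$radius_2), c(0.05, 0.05))
  # V = Eco * L => C = 1
  cfg1 <- electrode_config(separation = 0.01, radii = 5e-4,
                           applied_voltage = 1.5e5 * 0.01,
                           conductivity = 0.42, mode = "dimensional")
  expect_equal(nondimensionalize_config(cfg1, 1.5e5)$applied_voltage, 1)
  # round trip is the identity
  back <- dimensionalize_config(dl, Eco = 1.5e5)
  expect_equal(back$L, cfg$L)
  expect_equal(back$applied_voltage, cfg$applied_voltage)
  expect_equal(back$radius_1, cfg$radius_1)
  expect_equal(back$domain_extent, cfg$domain_extent)
  # conductivity cancels from the homogeneous problem: the dimensionless
  # solve depends only on geometry and C
  dl2 <- nondimensionalize_config(
    electrode_config(separation = 0.01, radii = 5e-4,
                     applied_voltage = 2250, conductivity = 4.2,
                     mode = "dimensional"), Eco = 1.5e5)
  sa <- solve_potential(dl, h = 0.025)
  sb <- solve_potential(dl2, h = 0.025)
  expect_identical(sa$potential, sb$potential)
})

test_that("geometry errors are caught before solving", {
  expect_error(electrode_config(radii = 0.6, applied_voltage = 1),
               "overlap")
  expect_error(
    electrode_config(radii = 0.05, applied_voltage = 1,
                     domain_extent = c(-0.5, 0.5, -0.5, 0.5)),
    "inside the domain")
  expect_error(
    electrode_config(separation = 0.01, radii = 5e-4, applied_voltage = 1,
                     mode = "dimensional"),
    "conductivity")
  # dimensional configs must be nondimensionalized before solving
  cfg <- electrode_config(separation = 0.01, radii = 5e-4,
                          applied_voltage = 1, conductivity = 0.42,
                          mode = "dimensional")
  expect_error(solve_potential(cfg, h = 0.05), "nondimensionalize")
  # under-resolved electrode disk
  expect_error(solve_potential(small_cylinder_config(1), h = 0.2),
               "under-resolved")
})
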