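# shared fixtures: small geometries and datasets built in code

# compact two-cylinder geometry for fast solves (41 x 41 nodes at h = 0.05)
small_cylinder_config <- function(C = 1)
  electrode_config(radii = 0.05, applied_voltage = C,
                   domain_extent = c(-1, 1, -1, 1))

# reference illustrative truth used across fitting tests
truth_model <- function() default_illustrative_model()

noise_free_dataset <- function(truth = truth_model())
  generate_dataset(generator_spec(truth, noise_model = "none"))

# evaluate an analytic two-cylinder solution on a solution's grid
eval_on_grid <- function(an, sol, what = c("potential", "field")) {
  what <- match.arg(what)
  X <- matrix(sol$x, length(sol$x), length(sol$y))
  Y <- matrix(sol$y, length(sol$x), length(sol$y), byrow = TRUE)
  an[[what]](X, Y)
}

# tissue nodes outside a 2h collar around both electrode surfaces
outside_collar <- function(sol, r = 0.05, width = 2 * sol$h) {
  X <- matrix(sol$x, length(sol$x), length(sol$y))
  Y <- matrix(sol$y, length(sol$x), length(sol$y), byrow = TRUE)
  rho1 <- sqrt((X + 0.5)^2 + Y^2)
  rho2 <- sqrt((X - 0.5)^2 + Y^2)
  sol$mask == 0L & rho1 > r + width & rho2 > r + width
}

# shared scratch space so expensive acceptance artifacts are computed once
.acceptance_cache <- new.env(parent = emptyenv())

rel_l2 <- function(approx, exact, sel) {
  sqrt(sum((approx[sel] - exact[sel])^2) / sum(exact[sel]^2))
}
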