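# Synthetic survival data with known Fermi structure.  Emulates the shape
# of published single-cell IRE survival experiments (DU-145 prostate cells:
# fields of 0.1-3.3 kV/cm, 1-10 pulses, pulse lengths of tens of
# microseconds to milliseconds) so that every fitting and planning stage
# can be exercised against a known ground truth.

#' Specification for a synthetic survival dataset
#'
#' @param truth a [fermi_protocol_model()]: the generating ground truth.
#' @param field_levels applied field magnitudes, V/m.  Default: 12 levels
#'   evenly spanning 0.1 to 3.3 kV/cm (1e4 to 3.3e5 V/m), the envelope of
#'   the published single-cell experiments this generator emulates.
#' @param n_values pulse counts (positive integers).  Default
#'   `c(1, 2, 4, 10)`, the published pulse-count series.
#' @param pulse_length pulse length in seconds; defaults to the truth
#'   model's.
#' @param noise_model one of `"none"`, `"gaussian_clipped"` (additive
#'   Gaussian on the survival fraction, clipped to \[0,1\]), `"binomial"`
#'   (counting noise: killed/alive cells drawn binomially out of
#'   `n_cells`).  Binomial is the default: survival assays count cells.
#' @param sigma standard deviation for `gaussian_clipped`, in \[0, 0.2\].
#' @param n_cells cells per assay well for `binomial`, >= 10.
#' @param seed integer seed.  The seed expands to an independent substream
#'   per (field, n) cell, so adding field levels or pulse counts does not
#'   perturb the draws of existing cells.
#' @return an object of class `"generator_spec"`.
#' @export
generator_spec <- function(truth = default_illustrative_model(),
                           field_levels = seq(1e4, 3.3e5, length.out = 12),
                           n_values = c(1, 2, 4, 10),
                           pulse_length = truth$pulse_length,
                           noise_model = c("binomial", "gaussian_clipped",
                                           "none"),
                           sigma = 0.03, n_cells = 200, seed = 1L) {
  stopifnot(inherits(truth, "fermi_protocol_model"))
  noise_model <- match.arg(noise_model)
  if (length(field_levels) == 0L || any(!is.finite(field_levels)) ||
      any(field_levels < 0))
    stop("'field_levels' must be non-empty, finite and >= 0", call. = FALSE)
  if (length(n_values) == 0L || any(n_values < 1) ||
      any(n_values != round(n_values)))
    stop("'n_values' must be positive integers", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0 || sigma > 0.2)
    stop("'sigma' must lie in [0, 0.2]", call. = FALSE)
  if (!is.finite(n_cells) || n_cells < 10)
    stop("'n_cells' must be >= 10", call. = FALSE)
  if (!is.finite(pulse_length) || pulse_length <= 0)
    stop("'pulse_length' must be > 0", call. = FALSE)
  structure(
    list(truth = truth, field_levels = as.numeric(field_levels),
         n_values = as.numeric(n_values),
         pulse_length = as.numeric(pulse_length),
         noise_model = noise_model, sigma = sigma,
         n_cells = as.integer(n_cells), seed = as.integer(seed)),
    class = "generator_spec")
}

# deterministic substream seed for one (field, n) cell: depends only on the
# cell's own values and the master seed, never on list positions
.cell_seed <- function(seed, field, n) {
  (abs(as.numeric(seed)) %% 1000003) * 2017 +
    (as.numeric(n) %% 1009) * 7919 +
    (round(as.numeric(field)) %% 999983) * 31
}

#' Generate a synthetic survival dataset
#'
#' One record per (field level, pulse count) pair.  The noise-free survival
#' is [protocol_survival()] under the spec's truth model; observation noise
#' is then applied per the spec's noise model and the result clipped to
#' \[0, 1\].  Identical spec (including seed) always yields the identical
#' dataset.
#'
#' @param spec a [generator_spec()].
#' @return data frame with columns `field` (V/m), `n_pulses`,
#'   `pulse_length_s`, `survival`; the generating spec is attached as
#'   attribute `"generator_spec"`.
#' @examples
#' d <- generate_dataset(generator_spec(noise_model = "none"))
#' nrow(d)  # 12 field levels x 4 pulse counts = 48
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  grid <- expand.grid(field = spec$field_levels, n_pulses = spec$n_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$n_pulses, grid$field), ]
  s_true <- protocol_survival(grid$field, grid$n_pulses, spec$truth)
  s_obs <- if (spec$noise_model == "none") {
    s_true
  } else {
    vapply(seq_len(nrow(grid)), function(i) {
      with_preserved_seed(
        .cell_seed(spec$seed, grid$field[i], grid$n_pulses[i]),
        switch(spec$noise_model,
               gaussian_clipped = s_true[i] + stats::rnorm(1, 0, spec$sigma),
               binomial = stats::rbinom(1, spec$n_cells, s_true[i]) /
                 spec$n_cells))
    }, numeric(1))
  }
  out <- data.frame(field = grid$field, n_pulses = grid$n_pulses,
                    pulse_length_s = spec$pulse_length,
                    survival = pmin(pmax(s_obs, 0), 1),
                    row.names = NULL)
  attr(out, "generator_spec") <- spec
  out
}

#' Illustrative Peleg-Fermi parameter sets
#'
#' A fixed, versioned catalog of Peleg-Fermi parameters, one set per pulse
#' length, used by the documentation, demos and tests.  Values are chosen
#' inside the published experimental envelope (midpoint fields between 0.1
#' and 3.3 kV/cm), with longer pulses given lower thresholds and faster
#' per-pulse decay, the qualitative trend seen experimentally.  They are
#' illustrative stand-ins, not measurements: real planning requires
#' parameters fitted to data for the actual cell type and pulse shape.
#'
#' @param pulse_length one of `5e-5`, `1e-4`, `1e-3`, `1e-2` seconds.
#' @return a [fermi_protocol_model()].
#' @examples
#' default_illustrative_model()        # 100 us preset
#' default_illustrative_model(1e-3)    # 1 ms preset
#' @export
default_illustrative_model <- function(pulse_length = 1e-4) {
  presets <- list(
    `5e-05` = c(Eco = 1.7e5, k1 = 0.025, Ao = 4.5e4, k2 = 0.025),
    `1e-04` = c(Eco = 1.5e5, k1 = 0.030, Ao = 4.0e4, k2 = 0.030),
    `0.001` = c(Eco = 1.2e5, k1 = 0.040, Ao = 3.2e4, k2 = 0.040),
    `0.01`  = c(Eco = 1.0e5, k1 = 0.045, Ao = 2.8e4, k2 = 0.045))
  key <- format(pulse_length)
  if (!key %in% names(presets))
    stop("no illustrative preset for pulse length ", pulse_length,
         " s; available: 5e-05, 1e-04, 0.001, 0.01", call. = FALSE)
  p <- presets[[key]]
  fermi_protocol_model(
    Eco = p[["Eco"]], k1 = p[["k1"]], Ao = p[["Ao"]], k2 = p[["k2"]],
    pulse_length = pulse_length,
    provenance = list(source = "illustrative preset v1"))
}

#' Simulate survival datasets from a protocol model
#'
#' Draws `nsim` synthetic survival datasets with the model as ground
#' truth, under the default experimental envelope of [generator_spec()].
#'
#' @param object a [fermi_protocol_model()].
#' @param nsim number of datasets.
#' @param seed integer; dataset `i` uses `seed + i - 1`.
#' @param ... passed on to [generator_spec()] (e.g. `noise_model`,
#'   `n_cells`, `field_levels`).
#' @return a list of `nsim` data frames (a single data frame if
#'   `nsim = 1`).
#' @export
simulate.fermi_protocol_model <- function(object, nsim = 1, seed = 1L, ...) {
  out <- lapply(seq_len(nsim), function(i)
    generate_dataset(generator_spec(truth = object,
                                    seed = as.integer(seed) + i - 1L, ...)))
  if (nsim == 1L) out[[1L]] else out
}
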