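#' Classical pulsed-field inactivation models
#'
#' A small catalog of the inactivation laws that preceded the Peleg-Fermi
#' model in the pulsed-electric-field literature, evaluated as survival
#' fractions clamped to \[0, 1\]:
#' \describe{
#'   \item{`first_order`}{first-order kinetics, `S = exp(-k t)`; `k` is the
#'     kinetic constant (per second), `t` the total treatment time.}
#'   \item{`hulsheger`}{`ln S = -b_e (E - E_c)`; `b_e` a regression
#'     constant, `E_c` the critical field extrapolated to 100 percent
#'     survival.}
#'   \item{`hulsheger_extended`}{`S = (t/t_c)^(-(E - E_c)/k)`, bringing the
#'     treatment time in through the critical time `t_c`.}
#'   \item{`weibull`}{`ln S = -b t^shape`, a Weibull survival curve in
#'     treatment time with field-dependent constants.}
#' }
#'
#' @param model a [classical_model_params()] object.
#' @param E applied field, V/m.
#' @param t total treatment time, seconds.
#' @return survival fraction clamped to \[0, 1\].  Each model returns 1 at
#'   its zero-dose point (`k = 0`, `E = E_c`, `t = t_c`, `b = 0`
#'   respectively).
#' @examples
#' m <- classical_model_params("weibull", c(b = 0.5, shape = 1))
#' classical_survival(m, E = 1e5, t = 2)  # exp(-1)
#' @export
classical_survival <- function(model, E, t) {
  stopifnot(inherits(model, "classical_model_params"))
  p <- model$parameters
  lnS <- switch(model$model_id,
    first_order = -p[["k"]] * t,
    hulsheger = -p[["b_e"]] * (E - p[["E_c"]]),
    hulsheger_extended = {
      if (any(t <= 0)) stop("treatment time 't' must be > 0", call. = FALSE)
      -((E - p[["E_c"]]) / p[["k"]]) * log(t / p[["t_c"]])
    },
    weibull = {
      if (any(t < 0)) stop("treatment time 't' must be >= 0", call. = FALSE)
      -p[["b"]] * t^p[["shape"]]
    },
    stop("unknown model_id: ", model$model_id, call. = FALSE))
  pmin(pmax(exp(pmin(lnS, 0)), 0), 1)
}

#' @describeIn classical_survival validated parameter container.
#' @param model_id one of `"first_order"`, `"hulsheger"`,
#'   `"hulsheger_extended"`, `"weibull"`.
#' @param parameters named numeric vector of the parameters listed above
#'   for the chosen model.
#' @export
classical_model_params <- function(model_id, parameters) {
  required <- switch(model_id,
    first_order = "k",
    hulsheger = c("b_e", "E_c"),
    hulsheger_extended = c("t_c", "E_c", "k"),
    weibull = c("b", "shape"),
    stop("unknown model_id: must be one of first_order, hulsheger, ",
         "hulsheger_extended, weibull", call. = FALSE))
  parameters <- unlist(parameters)
  missing <- setdiff(required, names(parameters))
  if (length(missing))
    stop("missing parameters for '", model_id, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  parameters <- parameters[required]
  if (any(!is.finite(parameters)))
    stop("all parameters must be finite", call. = FALSE)
  if (any(parameters < 0))
    stop("all parameters must be non-negative", call. = FALSE)
  structure(list(model_id = model_id, parameters = parameters),
            class = "classical_model_params")
}

#' @export
print.classical_model_params <- function(x, ...) {
  cat("Classical inactivation model:", x$model_id, "\n")
  print(x$parameters)
  invisible(x)
}
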