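#' Peleg-Fermi cell survival law
#'
#' Survival fraction of a cell population exposed to a local electric field
#' `E`, under the Fermi (logistic) inactivation law
#' \deqn{S(E) = \frac{1}{1 + \exp[(E - E_c)/A]}}{S(E) = 1 / (1 + exp((E - Ec)/A))}
#' where `Ec` is the field at which half of the population is killed and `A`
#' sets the width of the transition between full survival and full kill.
#'
#' The exponent is evaluated as-is; for |exponent| beyond roughly 700 the
#' result saturates cleanly to 0 or 1 without overflow warnings or `NaN`.
#'
#' @param E electric field magnitude, V/m (vectorised, must be >= 0).
#' @param Ec midpoint field (50 percent kill), V/m, > 0.
#' @param A transition width parameter, V/m, > 0.
#' @return survival fraction in \[0, 1\], same length as the broadcast of the
#'   arguments.  Exactly 0.5 where `E == Ec`.
#' @examples
#' fermi_survival(1.5e5, Ec = 1.5e5, A = 4e4)   # 0.5 by definition of Ec
#' fermi_survival(0,     Ec = 1.5e5, A = 1e4)   # ~1: far below threshold
#' @seealso [ec_of_n()], [a_of_n()], [protocol_survival()]
#' @export
fermi_survival <- function(E, Ec, A) {
  if (any(!is.finite(A)) || any(A <= 0))
    stop("transition width 'A' must be positive and finite", call. = FALSE)
  if (any(!is.finite(Ec)) || any(Ec <= 0))
    stop("midpoint field 'Ec' must be positive and finite", call. = FALSE)
  if (any(!is.finite(E)) || any(E < 0))
    stop("field magnitude 'E' must be finite and non-negative", call. = FALSE)
  z <- (E - Ec) / A
  # saturate far tails so exp() never overflows to Inf
  z <- pmin(pmax(z, -745), 745)
  1 / (1 + exp(z))
}

#' Pulse-number decay of the Fermi midpoint and width parameters
#'
#' The midpoint field `Ec` and transition width `A` both decrease with the
#' number of delivered pulses `n` following an exponential decay,
#' \deqn{E_c(n) = E_{co} e^{-k_1 n}, \qquad A(n) = A_o e^{-k_2 n}.}
#' `Eco` and `Ao` are the extrapolated intercepts at `n = 0`; `k1` and `k2`
#' are per-pulse decay rates.  `n` is accepted as a non-negative real so
#' fitted curves can be extrapolated continuously beyond the experimental
#' pulse counts.
#'
#' @param n number of pulses, >= 0 (real-valued allowed).
#' @param Eco,Ao intercepts at `n = 0`, V/m, > 0.
#' @param k1,k2 per-pulse decay rates, >= 0.
#' @return field parameter in V/m, always > 0; equals the intercept at
#'   `n = 0` and is non-increasing in `n`.
#' @examples
#' ec_of_n(0, Eco = 1e5, k1 = 0.1)    # 1e5: the intercept
#' ec_of_n(10, Eco = 1e5, k1 = 0.1)   # 1e5 * exp(-1)
#' @export
ec_of_n <- function(n, Eco, k1) {
  .check_decay_args(n, Eco, k1, "Eco", "k1")
  Eco * exp(-k1 * n)
}

#' @rdname ec_of_n
#' @export
a_of_n <- function(n, Ao, k2) {
  .check_decay_args(n, Ao, k2, "Ao", "k2")
  Ao * exp(-k2 * n)
}

.check_decay_args <- function(n, intercept, rate, iname, rname) {
  if (any(!is.finite(n)) || any(n < 0))
    stop("pulse count 'n' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(intercept)) || any(intercept <= 0))
    stop("intercept '", iname, "' must be positive and finite", call. = FALSE)
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("decay rate '", rname, "' must be finite and >= 0", call. = FALSE)
  invisible(NULL)
}

#' Construct a Peleg-Fermi protocol model
#'
#' Bundles the four parameters of the pulse-number-dependent Peleg-Fermi
#' survival law for one pulse length: the `n = 0` intercepts `Eco` and `Ao`
#' and the per-pulse decay rates `k1` and `k2` of the midpoint field
#' `Ec(n) = Eco exp(-k1 n)` and transition width `A(n) = Ao exp(-k2 n)`.
#'
#' @param Eco intercept of `Ec(n)` at `n = 0`, V/m, > 0.
#' @param k1 per-pulse decay rate of `Ec`, >= 0.
#' @param Ao intercept of `A(n)` at `n = 0`, V/m, > 0.
#' @param k2 per-pulse decay rate of `A`, >= 0.
#' @param pulse_length pulse duration in seconds, > 0.
#' @param provenance optional list of fitting metadata (per-n fits,
#'   residuals, bootstrap intervals); kept verbatim.
#' @return an object of class `"fermi_protocol_model"`.
#' @examples
#' m <- fermi_protocol_model(Eco = 1.5e5, k1 = 0.03, Ao = 4e4, k2 = 0.03,
#'                           pulse_length = 1e-4)
#' protocol_survival(1.2e5, n = 10, model = m)
#' @export
fermi_protocol_model <- function(Eco, k1, Ao, k2, pulse_length,
                                 provenance = list()) {
  stopifnot(length(Eco) == 1L, length(k1) == 1L, length(Ao) == 1L,
            length(k2) == 1L, length(pulse_length) == 1L)
  if (!is.finite(Eco) || Eco <= 0) stop("'Eco' must be > 0", call. = FALSE)
  if (!is.finite(Ao) || Ao <= 0) stop("'Ao' must be > 0", call. = FALSE)
  if (!is.finite(k1) || k1 < 0)
    stop("'k1' must be >= 0: survival must not increase with pulse number",
         call. = FALSE)
  if (!is.finite(k2) || k2 < 0)
    stop("'k2' must be >= 0: survival must not increase with pulse number",
         call. = FALSE)
  if (!is.finite(pulse_length) || pulse_length <= 0)
    stop("'pulse_length' must be > 0 seconds", call. = FALSE)
  structure(
    list(Eco = as.numeric(Eco), k1 = as.numeric(k1),
         Ao = as.numeric(Ao), k2 = as.numeric(k2),
         pulse_length = as.numeric(pulse_length),
         provenance = provenance),
    class = "fermi_protocol_model")
}

#' Survival under a full pulse protocol
#'
#' Composes the Fermi law with the pulse-number decay of its parameters:
#' `S(E, n) = fermi_survival(E, Ec(n), A(n))`.  `n = 0` is permitted for
#' diagnostic use (it reduces to the intercept parameters `Eco`, `Ao`).
#'
#' @param E local electric field magnitude, V/m (vectorised).
#' @param n number of pulses, >= 0.
#' @param model a [fermi_protocol_model()].
#' @return survival fraction(s) in \[0, 1\].
#' @export
protocol_survival <- function(E, n, model) {
  stopifnot(inherits(model, "fermi_protocol_model"))
  fermi_survival(E,
                 Ec = ec_of_n(n, model$Eco, model$k1),
                 A  = a_of_n(n, model$Ao, model$k2))
}

#' Dimensionless form of a protocol model
#'
#' Rescales all field quantities by `Eco`, the natural field scale of the
#' protocol: `Ec*(n) = Ec(n)/Eco = exp(-k1 n)` and
#' `A*(n) = A(n)/Eco = (Ao/Eco) exp(-k2 n)`, so `Ec*(0) = 1` exactly.
#' Survival is invariant under this rescaling: the dimensional survival at
#' `(E, n)` equals the dimensionless survival at `(E/Eco, n)`.
#'
#' @param model a [fermi_protocol_model()].
#' @return an object of class `"fermi_protocol_dimensionless"`: a list with
#'   `Ec_star(n)` and `A_star(n)` evaluators, the width ratio `Ao_star =
#'   Ao/Eco`, the decay rates, and the reference scale `Eco`.
#' @export
normalize_model <- function(model) {
  stopifnot(inherits(model, "fermi_protocol_model"))
  k1 <- model$k1; k2 <- model$k2; Ao_star <- model$Ao / model$Eco
  structure(
    list(Ec_star = function(n) exp(-k1 * n),
         A_star = function(n) Ao_star * exp(-k2 * n),
         Ao_star = Ao_star, k1 = k1, k2 = k2,
         Eco = model$Eco, pulse_length = model$pulse_length),
    class = "fermi_protocol_dimensionless")
}

#' @export
print.fermi_protocol_model <- function(x, digits = 4, ...) {
  cat("Peleg-Fermi protocol survival model\n")
  cat(sprintf("  pulse length: %g s\n", x$pulse_length))
  cat(sprintf("  Ec(n) = Eco * exp(-k1 n):  Eco = %s V/m, k1 = %s /pulse\n",
              format(x$Eco, digits = digits), format(x$k1, digits = digits)))
  cat(sprintf("  A(n)  = Ao  * exp(-k2 n):  Ao  = %s V/m, k2 = %s /pulse\n",
              format(x$Ao, digits = digits), format(x$k2, digits = digits)))
  if (!is.null(x$provenance$per_n)) {
    cat(sprintf("  fitted from %d pulse-number groups (n = %s)\n",
                nrow(x$provenance$per_n),
                paste(x$provenance$per_n$n_pulses, collapse = ", ")))
  }
  if (!is.null(x$provenance$boot_ci)) {
    ci <- x$provenance$boot_ci
    cat(sprintf("  bootstrap 95%% CIs (%d replicates):\n",
                x$provenance$boot_replicates))
    for (p in rownames(ci))
      cat(sprintf("    %-3s [%s, %s]\n", p,
                  format(ci[p, 1], digits = digits),
                  format(ci[p, 2], digits = digits)))
  }
  invisible(x)
}

#' @export
coef.fermi_protocol_model <- function(object, ...) {
  c(Eco = object$Eco, k1 = object$k1, Ao = object$Ao, k2 = object$k2)
}

#' Predict survival from a fitted protocol model
#'
#' @param object a [fermi_protocol_model()].
#' @param field electric field magnitude(s), V/m.
#' @param n_pulses pulse count(s); recycled against `field`.
#' @param ... unused.
#' @return vector of survival fractions.
#' @export
predict.fermi_protocol_model <- function(object, field, n_pulses, ...) {
  protocol_survival(E = field, n = n_pulses, model = object)
}

#' @export
summary.fermi_protocol_model <- function(object, ...) {
  out <- list(coef = coef(object), pulse_length = object$pulse_length,
              per_n = object$provenance$per_n,
              boot_ci = object$provenance$boot_ci,
              boot_replicates = object$provenance$boot_replicates,
              warnings = object$provenance$warnings)
  class(out) <- "summary.fermi_protocol_model"
  out
}

#' @export
print.summary.fermi_protocol_model <- function(x, digits = 4, ...) {
  cat("Peleg-Fermi protocol survival model\n\n")
  cat(sprintf("Pulse length: %g s\n\nParameters:\n", x$pulse_length))
  print(signif(x$coef, digits))
  if (!is.null(x$per_n)) {
    cat("\nPer-pulse-number Fermi fits:\n")
    print(x$per_n, digits = digits, row.names = FALSE)
  }
  if (!is.null(x$boot_ci)) {
    cat(sprintf("\nBootstrap 95%% percentile intervals (%d replicates):\n",
                x$boot_replicates))
    print(signif(x$boot_ci, digits))
  }
  if (length(x$warnings))
    cat("\nFitting notes:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Plot the fitted parameter decay curves
#'
#' Draws `Ec(n)` and `A(n)` against pulse number, overlaying the per-n
#' fitted values stored in the model's provenance when present.
#'
#' @param x a [fermi_protocol_model()].
#' @param n_max largest pulse number to draw; defaults to 1.5x the largest
#'   fitted `n`, or 20.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fermi_protocol_model <- function(x, n_max = NULL, ...) {
  per_n <- x$provenance$per_n
  if (is.null(n_max))
    n_max <- if (!is.null(per_n)) 1.5 * max(per_n$n_pulses) else 20
  n <- seq(0, n_max, length.out = 200)
  graphics::matplot(n, cbind(ec_of_n(n, x$Eco, x$k1), a_of_n(n, x$Ao, x$k2)),
                    type = "l", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "number of pulses n", ylab = "field parameter [V/m]",
                    main = "Peleg-Fermi parameter decay", ...)
  if (!is.null(per_n)) {
    graphics::points(per_n$n_pulses, per_n$Ec, col = "firebrick", pch = 19)
    graphics::points(per_n$n_pulses, per_n$A, col = "steelblue", pch = 17)
  }
  graphics::legend("topright", c("Ec(n)", "A(n)"), lty = 1, pch = c(19, 17),
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
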