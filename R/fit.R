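# Two-stage Peleg-Fermi fitting:
#   stage 1 - per-pulse-number logistic (Fermi) fits of survival vs field
#   stage 2 - exponential-decay fits of Ec(n) and A(n), extrapolated to n = 0
# Least squares is taken on the survival scale throughout: survival
# observations near 0/1 have bounded error there, unlike on the logit scale.

#' Fit the Fermi survival curve for a single pulse number
#'
#' Nonlinear least squares of `S = 1/(1 + exp((E - Ec)/A))` against observed
#' survival fractions sharing one pulse number and pulse length.
#' Levenberg-Marquardt with an analytic Jacobian; starting values are
#' data-driven (the field whose observed survival is nearest 0.5 for `Ec`,
#' a quarter of the field span for `A`), so no user tuning is needed.
#'
#' @param records data frame with columns `field` (V/m), `survival`
#'   (fraction in \[0,1\]), and optionally `n_pulses`/`pulse_length_s`
#'   (must each be constant if present).
#' @return an object of class `"fermi_pair_fit"`: list with `n_pulses`,
#'   `Ec`, `A` (V/m), `fit_residual` (sum of squared survival residuals),
#'   `se` (asymptotic standard errors, `NA` if singular) and `n_records`.
#' @examples
#' E <- seq(5e4, 2.5e5, length.out = 8)
#' rec <- data.frame(field = E, survival = fermi_survival(E, 1.2e5, 3e4))
#' fit_fermi_single_n(rec)
#' @export
fit_fermi_single_n <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("field", "survival") %in% names(records)))
    stop("records must have columns 'field' and 'survival'", call. = FALSE)
  n_lab <- if ("n_pulses" %in% names(records)) {
    nu <- unique(records$n_pulses)
    if (length(nu) != 1L)
      stop("records mix several pulse numbers: ",
           paste(nu, collapse = ", "), call. = FALSE)
    nu
  } else NA_real_
  if ("pulse_length_s" %in% names(records) &&
      length(unique(records$pulse_length_s)) != 1L)
    stop("records mix several pulse lengths", call. = FALSE)
  E <- as.numeric(records$field)
  S <- as.numeric(records$survival)
  if (any(!is.finite(E)) || any(E < 0))
    stop("field values must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(S)) || any(S < 0) || any(S > 1))
    stop("survival values must lie in [0, 1]", call. = FALSE)
  if (nrow(records) < 4L)
    stop("fit infeasible for n = ", n_lab,
         ": need at least 4 records", call. = FALSE)
  if (length(unique(E)) < 3L)
    stop("fit infeasible for n = ", n_lab,
         ": need at least 3 distinct field values", call. = FALSE)
  if (all(S > 0.95) || all(S < 0.05))
    stop("fit infeasible for n = ", n_lab,
         ": degenerate span, all survival values on one side of the ",
         "transition (no information on Ec)", call. = FALSE)

  Ec0 <- E[which.min(abs(S - 0.5))]
  if (Ec0 <= 0) Ec0 <- max(mean(E), .Machine$double.eps)
  A0 <- max((max(E) - min(E)) / 4, 1e-12)

  resid_fn <- function(p) fermi_survival(E, p[1], p[2]) - S
  jac_fn <- function(p) {
    Sm <- fermi_survival(E, p[1], p[2])
    w <- Sm * (1 - Sm)
    cbind(w / p[2], w * (E - p[1]) / p[2]^2)
  }
  fit <- minpack.lm::nls.lm(
    par = c(Ec0, A0), fn = resid_fn, jac = jac_fn,
    lower = c(1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- fit$par
  rss <- sum(fit$fvec^2)
  se <- tryCatch({
    dof <- max(length(E) - 2L, 1L)
    sqrt(diag(solve(fit$hessian)) * rss / dof)
  }, error = function(e) c(NA_real_, NA_real_))
  structure(
    list(n_pulses = n_lab, Ec = p[1], A = p[2], fit_residual = rss,
         se = c(Ec = se[1], A = se[2]), n_records = nrow(records),
         info = fit$info),
    class = "fermi_pair_fit")
}

#' @export
print.fermi_pair_fit <- function(x, digits = 5, ...) {
  cat(sprintf(
    "Fermi fit (n = %s): Ec = %s V/m, A = %s V/m  (RSS = %s, %d records)\n",
    format(x$n_pulses), format(x$Ec, digits = digits),
    format(x$A, digits = digits), format(x$fit_residual, digits = 3),
    x$n_records))
  invisible(x)
}

#' @export
coef.fermi_pair_fit <- function(object, ...) c(Ec = object$Ec, A = object$A)

# Exponential-decay fit y = y0 * exp(-k n), ordinary least squares on the
# y scale; log-linear regression supplies the start, Levenberg-Marquardt
# refines.  Returns c(y0, k); k may come out negative, callers apply the
# clamp policy.
.fit_exp_decay <- function(n, y) {
  stopifnot(length(n) == length(y), length(n) >= 2L, all(y > 0))
  init <- stats::lm.fit(cbind(1, n), log(y))$coefficients
  p0 <- c(exp(init[1]), -init[2])
  resid_fn <- function(p) p[1] * exp(-p[2] * n) - y
  jac_fn <- function(p) {
    e <- exp(-p[2] * n)
    cbind(e, -p[1] * n * e)
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  unname(fit$par)
}

# Clamp policy for stage-2 decay rates: the survival law requires
# non-increasing Ec(n), A(n).  Small negative rates are sampling noise and
# are clamped to zero (recorded); large ones indicate data inconsistent
# with the model and abort.
.apply_rate_policy <- function(rate, label, clamp_tol) {
  warn <- NULL
  if (rate < 0) {
    if (abs(rate) < clamp_tol) {
      warn <- sprintf(
        "fitted %s = %.3g /pulse was negative within tolerance; clamped to 0",
        label, rate)
      rate <- 0
    } else {
      stop("fitted ", label, " = ", signif(rate, 4),
           " /pulse is negative beyond the clamp tolerance (", clamp_tol,
           "): data are inconsistent with a non-increasing decay law",
           call. = FALSE)
    }
  }
  list(rate = rate, warning = warn)
}

# core two-stage fit on a validated, single-pulse-length dataset;
# returns list(model params, per_n table, warnings)
.fit_protocol_core <- function(data, clamp_tol) {
  groups <- split(data, data$n_pulses)
  fits <- lapply(groups, fit_fermi_single_n)
  per_n <- data.frame(
    n_pulses = as.numeric(names(groups)),
    Ec = vapply(fits, `[[`, numeric(1), "Ec"),
    A = vapply(fits, `[[`, numeric(1), "A"),
    fit_residual = vapply(fits, `[[`, numeric(1), "fit_residual"),
    n_records = vapply(fits, `[[`, numeric(1), "n_records"),
    row.names = NULL)
  per_n <- per_n[order(per_n$n_pulses), ]

  ec_fit <- .fit_exp_decay(per_n$n_pulses, per_n$Ec)
  a_fit <- .fit_exp_decay(per_n$n_pulses, per_n$A)
  k1p <- .apply_rate_policy(ec_fit[2], "k1", clamp_tol)
  k2p <- .apply_rate_policy(a_fit[2], "k2", clamp_tol)
  # re-fit the intercept with the rate pinned at zero when clamped
  Eco <- if (k1p$rate == 0 && ec_fit[2] != 0) mean(per_n$Ec) else ec_fit[1]
  Ao <- if (k2p$rate == 0 && a_fit[2] != 0) mean(per_n$A) else a_fit[1]
  list(Eco = Eco, k1 = k1p$rate, Ao = Ao, k2 = k2p$rate, per_n = per_n,
       warnings = c(k1p$warning, k2p$warning))
}

#' Fit a full Peleg-Fermi protocol model
#'
#' Two-stage fitting of survival-versus-field data across several pulse
#' numbers, for one pulse length.  Stage 1 fits the Fermi curve
#' independently for each pulse number ([fit_fermi_single_n()]), giving a
#' series of midpoints `Ec(n)` and widths `A(n)`.  Stage 2 fits
#' exponential decays `Eco exp(-k1 n)` and `Ao exp(-k2 n)` to those series
#' by least squares (log-linear regression initialises, Levenberg-Marquardt
#' refines) and extrapolates to `n = 0` to obtain the intercepts `Eco` and
#' `Ao`.
#'
#' Parameter uncertainty is quantified by a nonparametric bootstrap:
#' records are resampled with replacement within each pulse-number group
#' and the whole two-stage pipeline is refit; 95 percent percentile
#' intervals are stored in the returned model's provenance.
#'
#' @param dataset a survival dataset: data frame with columns `field`
#'   (V/m), `n_pulses`, `pulse_length_s`, `survival`, as returned by
#'   [read_survival_data()] or [generate_dataset()].
#' @param pulse_length pulse length (seconds) selecting the records to fit;
#'   may be omitted when the dataset contains a single pulse length.
#' @param boot number of bootstrap replicates (0 disables the bootstrap).
#' @param seed integer seed for the bootstrap resampling; the global RNG
#'   state is left untouched.
#' @param clamp_tol negative stage-2 decay rates with absolute value below
#'   this are treated as noise and clamped to 0 (with a recorded note);
#'   larger negative rates abort with a data-quality error.
#' @return a [fermi_protocol_model()] whose `provenance` holds the per-n
#'   fits, bootstrap intervals, any clamp notes, and the seed used.
#' @examples
#' truth <- fermi_protocol_model(1.5e5, 0.03, 4e4, 0.03, 1e-4)
#' d <- generate_dataset(generator_spec(truth, noise_model = "none"))
#' fit_protocol(d, boot = 0)
#' @export
fit_protocol <- function(dataset, pulse_length = NULL, boot = 200,
                         seed = 1234L, clamp_tol = 1e-3) {
  dataset <- validate_survival_dataset(dataset)
  if (is.null(pulse_length)) {
    pl <- unique(dataset$pulse_length_s)
    if (length(pl) != 1L)
      stop("dataset contains several pulse lengths (",
           paste(signif(pl, 4), collapse = ", "),
           " s); supply 'pulse_length'", call. = FALSE)
    pulse_length <- pl
  }
  sel <- abs(dataset$pulse_length_s - pulse_length) <=
    1e-9 * max(pulse_length, 1e-12)
  data <- dataset[sel, , drop = FALSE]
  if (nrow(data) == 0L)
    stop("no records with pulse length ", pulse_length, " s", call. = FALSE)
  if (length(unique(data$n_pulses)) < 2L)
    stop("cannot identify the decay rates k1, k2: need at least 2 ",
         "distinct pulse numbers, found ",
         length(unique(data$n_pulses)), call. = FALSE)

  core <- .fit_protocol_core(data, clamp_tol)

  boot_ci <- NULL; boot_ok <- 0L
  if (boot > 0) {
    reps <- with_preserved_seed(seed, {
      groups <- split(seq_len(nrow(data)), data$n_pulses)
      replicate(boot, {
        idx <- unlist(lapply(groups, function(g)
          g[sample.int(length(g), length(g), replace = TRUE)]),
          use.names = FALSE)
        tryCatch(
          unlist(.fit_protocol_core(data[idx, , drop = FALSE],
                                    clamp_tol)[c("Eco", "k1", "Ao", "k2")]),
          error = function(e) rep(NA_real_, 4))
      })
    })
    rownames(reps) <- c("Eco", "k1", "Ao", "k2")
    ok <- colSums(is.na(reps)) == 0
    boot_ok <- sum(ok)
    if (boot_ok >= 2L) {
      # Normal-theory intervals (estimate +/- z * bootstrap SE), truncated
      # at the parameter-space bound 0.  With ~a dozen records per
      # pulse-number group, raw percentile intervals of the resampling
      # distribution are noticeably too short for these smooth estimators;
      # the symmetric normal-theory form is the better-calibrated default.
      est <- c(core$Eco, core$k1, core$Ao, core$k2)
      se <- apply(reps[, ok, drop = FALSE], 1, stats::sd)
      z <- stats::qnorm(0.975)
      boot_ci <- cbind(lower = pmax(est - z * se, 0), upper = est + z * se)
      rownames(boot_ci) <- rownames(reps)
      attr(boot_ci, "se") <- se
    }
  }

  fermi_protocol_model(
    Eco = core$Eco, k1 = core$k1, Ao = core$Ao, k2 = core$k2,
    pulse_length = pulse_length,
    provenance = list(per_n = core$per_n, warnings = core$warnings,
                      boot_ci = boot_ci, boot_replicates = as.integer(boot),
                      boot_successful = boot_ok, boot_seed = as.integer(seed),
                      n_records = nrow(data)))
}

#' Residuals of a fitted protocol model
#'
#' Survival-scale residuals `observed - predicted` for the records the
#' model was fitted to (requires the fitting dataset).
#'
#' @param object a [fermi_protocol_model()].
#' @param dataset the dataset the model was fitted to.
#' @param ... unused.
#' @export
residuals.fermi_protocol_model <- function(object, dataset, ...) {
  dataset <- validate_survival_dataset(dataset)
  dataset$survival -
    protocol_survival(dataset$field, dataset$n_pulses, object)
}
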