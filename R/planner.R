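# Composition of the field solution and the Peleg-Fermi survival law into
# spatial cell-death probability maps, and the zone metrics derived from
# them.  Everything here is dimensionless: fields in units of Eco, lengths
# in units of the electrode separation L, areas in units of L^2.

#' Survival probability map
#'
#' Looks up the statistical survival law at every tissue node of a solved
#' field: `S(node) = fermi_survival(E*(node), Ec*(n), A*(n))` with the
#' dimensionless parameter curves `Ec*(n) = exp(-k1 n)`,
#' `A*(n) = (Ao/Eco) exp(-k2 n)`.  Electrode-interior nodes are not tissue
#' and are flagged `NA`.
#'
#' @param field a [solve_potential()] result (dimensionless).
#' @param model a [fermi_protocol_model()] or its [normalize_model()]
#'   form.  A dimensional model is normalized by its own `Eco` — the same
#'   reference field must have been used to non-dimensionalize the
#'   geometry.
#' @param n number of pulses, >= 1.
#' @return an object of class `"survival_map"`: list with `survival`
#'   matrix (NA on electrodes), the grid (`x`, `y`, `h`), `mask`,
#'   `field_magnitude`, and the protocol descriptor
#'   (`n`, `C`, `pulse_length`, dimensionless parameters).
#' @export
survival_map <- function(field, model, n) {
  stopifnot(inherits(field, "field_solution"))
  if (inherits(model, "fermi_protocol_model")) model <- normalize_model(model)
  if (!inherits(model, "fermi_protocol_dimensionless"))
    stop("'model' must be a fermi_protocol_model or its normalized form",
         call. = FALSE)
  if (!is.finite(n) || n < 1)
    stop("'n' must be >= 1 pulses", call. = FALSE)
  Ec_star <- model$Ec_star(n)
  A_star <- model$A_star(n)
  S <- fermi_survival(field$field_magnitude, Ec = Ec_star, A = A_star)
  tissue <- field$mask == MASK_INTERIOR
  S[!tissue] <- NA_real_
  structure(
    list(survival = S, x = field$x, y = field$y, h = field$h,
         mask = field$mask, field_magnitude = field$field_magnitude,
         protocol = list(n = n, C = field$C,
                         pulse_length = model$pulse_length,
                         Ec_star = Ec_star, A_star = A_star,
                         Eco = model$Eco)),
    class = "survival_map")
}

#' @export
print.survival_map <- function(x, ...) {
  p <- x$protocol
  cat("Cell survival probability map (S = survival fraction)\n")
  cat(sprintf("  protocol: n = %g pulses, C = %g, pulse length = %g s\n",
              p$n, p$C, p$pulse_length))
  cat(sprintf("  dimensionless Ec*(n) = %.4g, A*(n) = %.4g\n",
              p$Ec_star, p$A_star))
  cat(sprintf("  grid: %d x %d, h = %g; S range on tissue: [%.3g, %.3g]\n",
              length(x$x), length(x$y), x$h,
              min(x$survival, na.rm = TRUE), max(x$survival, na.rm = TRUE)))
  invisible(x)
}

#' Plot a survival map
#'
#' Image of the survival fraction `S` (1 = all cells alive, 0 = complete
#' kill) with iso-contours at the kill/live thresholds and `S = 0.5`.
#'
#' @param x a [survival_map()].
#' @param s_kill,s_live contour levels to highlight.
#' @param ... passed to [graphics::image()].
#' @export
plot.survival_map <- function(x, s_kill = 0.05, s_live = 0.95, ...) {
  z <- x$survival
  graphics::image(x$x, x$y, z, asp = 1, xlab = "x*", ylab = "y*",
                  zlim = c(0, 1), useRaster = TRUE,
                  main = sprintf("survival fraction S (n = %g, C = %g)",
                                 x$protocol$n, x$protocol$C), ...)
  graphics::contour(x$x, x$y, z, levels = c(s_kill, 0.5, s_live),
                    add = TRUE, lty = c(1, 2, 1), col = "grey20")
  invisible(x)
}

#' Deterministic (single-threshold) ablation map
#'
#' The classical demarcation-line model: a node is killed iff its local
#' field magnitude reaches a single critical value.  With threshold
#' `Ec*(n)` its kill region coincides node-exactly with the `S <= 0.5`
#' region of the statistical map — but it carries no transition zone.
#'
#' @param field a [solve_potential()] result.
#' @param threshold dimensionless critical field, > 0.
#' @return object of class `"deterministic_map"`: list with logical
#'   matrix `killed` (NA on electrodes), `threshold` and the grid.
#' @export
deterministic_map <- function(field, threshold) {
  stopifnot(inherits(field, "field_solution"))
  if (!is.finite(threshold) || threshold <= 0)
    stop("'threshold' must be > 0", call. = FALSE)
  killed <- field$field_magnitude >= threshold
  killed[field$mask != MASK_INTERIOR] <- NA
  structure(list(killed = killed, threshold = threshold, x = field$x,
                 y = field$y, h = field$h, mask = field$mask, C = field$C),
            class = "deterministic_map")
}

#' @export
print.deterministic_map <- function(x, ...) {
  cat(sprintf(
    "Deterministic demarcation map: threshold E* >= %g, killed area = %g L^2\n",
    x$threshold, sum(x$killed, na.rm = TRUE) * x$h^2))
  invisible(x)
}

#' Kill / transition / survive zone metrics
#'
#' Partitions the tissue (non-electrode) nodes of a survival map into
#' complete-kill (`S <= s_kill`), transition (`s_kill < S < s_live`) and
#' survive (`S >= s_live`) zones, and reports their areas in units of
#' `L^2` (node count times `h^2`).  The three areas partition the tissue
#' domain exactly: every node is counted once.  The deterministic
#' single-threshold area at `Ec*(n)` is reported alongside for contrast;
#' it always lies between the kill area and kill + transition when
#' `s_kill <= 0.5 <= s_live`.
#'
#' @param map a [survival_map()].
#' @param s_kill survival at or below which tissue counts as completely
#'   ablated; default 0.05.
#' @param s_live survival at or above which tissue counts as unaffected;
#'   default 0.95.  Must satisfy `0 < s_kill < s_live < 1`.
#' @param L_mm optional electrode separation in millimeters; when given,
#'   areas are additionally reported in mm^2.
#' @return object of class `"ablation_metrics"`: a one-row data frame
#'   with `n`, `C`, `pulse_length`, `kill_area`, `transition_area`,
#'   `survive_area`, `deterministic_area`, `total_area`, `s_kill`,
#'   `s_live` (and `*_mm2` columns when `L_mm` is given).
#' @export
ablation_metrics <- function(map, s_kill = 0.05, s_live = 0.95,
                             L_mm = NULL) {
  stopifnot(inherits(map, "survival_map"))
  if (!(is.finite(s_kill) && is.finite(s_live) &&
        0 < s_kill && s_kill < s_live && s_live < 1))
    stop("thresholds must satisfy 0 < s_kill < s_live < 1", call. = FALSE)
  S <- map$survival
  tissue <- !is.na(S)
  a <- map$h^2
  kill <- sum(S[tissue] <= s_kill)
  live <- sum(S[tissue] >= s_live)
  total <- sum(tissue)
  det <- sum(map$field_magnitude[tissue] >= map$protocol$Ec_star)
  out <- data.frame(
    n = map$protocol$n, C = map$protocol$C,
    pulse_length = map$protocol$pulse_length,
    kill_area = kill * a,
    transition_area = (total - kill - live) * a,
    survive_area = live * a,
    deterministic_area = det * a,
    total_area = total * a,
    s_kill = s_kill, s_live = s_live)
  if (!is.null(L_mm)) {
    for (col in c("kill_area", "transition_area", "survive_area",
                  "deterministic_area", "total_area"))
      out[[paste0(col, "_mm2")]] <- out[[col]] * L_mm^2
  }
  class(out) <- c("ablation_metrics", "data.frame")
  out
}

#' @export
print.ablation_metrics <- function(x, digits = 4, ...) {
  cat("Ablation zone metrics (areas in units of L^2)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Parametric protocol sweep
#'
#' Evaluates ablation metrics over a grid of protocols `(n, C,
#' pulse_length)` for one electrode geometry.  The field equation is
#' linear in the applied voltage, so the geometry is solved once at
#' `C = 1` and rescaled to each requested `C` ([scale_field_solution()]);
#' the rescaled solution agrees with a direct solve to solver tolerance.
#'
#' @param config a dimensionless [electrode_config()].
#' @param models a [fermi_protocol_model()], or a list of them covering
#'   every pulse length appearing in `protocols` (matched on
#'   `pulse_length`; no interpolation across pulse lengths is attempted).
#' @param protocols data frame with columns `n`, `C` and optionally
#'   `pulse_length` (seconds; defaults to the single model's).
#' @param s_kill,s_live zone thresholds, as in [ablation_metrics()].
#' @param h,tol solver grid spacing and residual tolerance.
#' @return data frame of class `"ablation_sweep"`: one [ablation_metrics()]
#'   row per protocol, in the order given.
#' @examples
#' cfg <- electrode_config(radii = 0.05, applied_voltage = 1)
#' m <- default_illustrative_model()
#' parametric_sweep(cfg, m, data.frame(n = c(10, 50), C = 1.5), h = 0.05)
#' @export
parametric_sweep <- function(config, models, protocols, s_kill = 0.05,
                             s_live = 0.95, h = 0.01, tol = 1e-8) {
  stopifnot(inherits(config, "electrode_config"))
  if (inherits(models, "fermi_protocol_model")) models <- list(models)
  if (!length(models) ||
      !all(vapply(models, inherits, logical(1), "fermi_protocol_model")))
    stop("'models' must be fermi_protocol_model objects", call. = FALSE)
  protocols <- as.data.frame(protocols)
  if (nrow(protocols) == 0L)
    stop("empty protocol list", call. = FALSE)
  if (!all(c("n", "C") %in% names(protocols)))
    stop("'protocols' needs columns 'n' and 'C'", call. = FALSE)
  model_pl <- vapply(models, `[[`, numeric(1), "pulse_length")
  if (!"pulse_length" %in% names(protocols)) {
    if (length(models) != 1L)
      stop("'protocols' must carry 'pulse_length' when several models are ",
           "given", call. = FALSE)
    protocols$pulse_length <- model_pl[1L]
  }
  pick_model <- function(pl) {
    hit <- which(.near(model_pl, pl))
    if (length(hit) != 1L)
      stop("no fitted model for pulse length ", pl, " s (available: ",
           paste(signif(model_pl, 4), collapse = ", "),
           "); models are per pulse length, no interpolation", call. = FALSE)
    models[[hit]]
  }

  base_cfg <- config
  base_cfg$applied_voltage <- 1
  unit_sol <- solve_potential(base_cfg, h = h, tol = tol)

  rows <- lapply(seq_len(nrow(protocols)), function(k) {
    p <- protocols[k, ]
    sol <- scale_field_solution(unit_sol, p$C)
    m <- survival_map(sol, pick_model(p$pulse_length), n = p$n)
    ablation_metrics(m, s_kill = s_kill, s_live = s_live)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ablation_sweep", "data.frame")
  attr(out, "h") <- h
  out
}
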