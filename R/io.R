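# File formats.  Survival datasets travel as comma-delimited text with a
# header row and optional leading "# key: value" directive lines; fitted
# models as JSON; grids as delimited text matrices and legacy-VTK
# STRUCTURED_POINTS files; run configurations as YAML (or JSON).
# Fields are V/m internally everywhere; readers convert declared units at
# the boundary (kV/cm multiplies by 1e5) so no 100x unit error can leak in.

.FIELD_UNIT_FACTORS <- c("V/m" = 1, "kV/cm" = 1e5)

#' Read a survival dataset file
#'
#' Comma-delimited text with a header row and columns `field`, `n_pulses`,
#' `pulse_length_s`, `survival`.  Leading comment lines of the form
#' `# field_units: V/m` (or `kV/cm`) declare the field unit; fields are
#' converted to V/m on read.  Missing required columns are an error;
#' unknown columns are kept with a warning.
#'
#' @param path file path.
#' @return validated data frame (fields in V/m).
#' @export
read_survival_data <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  units <- "V/m"
  um <- grep("^#\\s*field_units\\s*:", hdr, value = TRUE)
  if (length(um)) {
    units <- trimws(sub("^#\\s*field_units\\s*:", "", um[length(um)]))
    if (!units %in% names(.FIELD_UNIT_FACTORS))
      stop("unknown field_units '", units, "'; expected one of: ",
           paste(names(.FIELD_UNIT_FACTORS), collapse = ", "), call. = FALSE)
  }
  d <- utils::read.csv(text = lines[!grepl("^#", lines)],
                       stringsAsFactors = FALSE)
  required <- c("field", "n_pulses", "pulse_length_s", "survival")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("survival dataset ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(d), required)
  if (length(extra))
    warning("ignoring unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  d$field <- d$field * .FIELD_UNIT_FACTORS[[units]]
  validate_survival_dataset(d[required])
}

#' Write a survival dataset file
#'
#' @param dataset a validated survival data frame (fields in V/m).
#' @param path output path.
#' @param field_units `"V/m"` or `"kV/cm"`; fields are converted on write
#'   and the unit recorded in a `# field_units:` directive.
#' @return `path`, invisibly.
#' @export
write_survival_data <- function(dataset, path, field_units = "V/m") {
  dataset <- validate_survival_dataset(dataset)
  if (!field_units %in% names(.FIELD_UNIT_FACTORS))
    stop("unknown field_units '", field_units, "'", call. = FALSE)
  dataset$field <- dataset$field / .FIELD_UNIT_FACTORS[[field_units]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ireplan survival dataset, version ",
                      as.character(utils::packageVersion("ireplan"))),
               paste0("# field_units: ", field_units)), con)
  utils::write.csv(format(dataset, digits = 15, trim = TRUE,
                          scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a fitted protocol model file
#'
#' JSON with keys `Eco`, `k1`, `Ao`, `k2`, `pulse_length_s`,
#' `field_units` (always `"V/m"`) and a `provenance` block (per-n fits,
#' bootstrap intervals, seed, package version).  The round trip
#' `read_fermi_model(write_fermi_model(m, p))` reproduces the model
#' parameters exactly.
#'
#' @param model a [fermi_protocol_model()].
#' @param path file path.
#' @return `write_fermi_model`: `path` invisibly; `read_fermi_model`: the
#'   model.
#' @export
write_fermi_model <- function(model, path) {
  stopifnot(inherits(model, "fermi_protocol_model"))
  prov <- model$provenance
  doc <- list(
    format = "ireplan-fermi-model",
    version = as.character(utils::packageVersion("ireplan")),
    Eco = model$Eco, k1 = model$k1, Ao = model$Ao, k2 = model$k2,
    pulse_length_s = model$pulse_length, field_units = "V/m",
    provenance = list(
      per_n = prov$per_n, warnings = prov$warnings,
      boot_ci = if (!is.null(prov$boot_ci))
        list(parameter = rownames(prov$boot_ci),
             lower = unname(prov$boot_ci[, 1]),
             upper = unname(prov$boot_ci[, 2])),
      boot_replicates = prov$boot_replicates,
      boot_successful = prov$boot_successful,
      boot_seed = prov$boot_seed, n_records = prov$n_records,
      source = prov$source))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_fermi_model
#' @export
read_fermi_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "ireplan-fermi-model"))
    stop(path, " is not an ireplan fitted-model file", call. = FALSE)
  prov <- doc$provenance
  if (!is.null(prov$boot_ci)) {
    ci <- cbind(lower = prov$boot_ci$lower, upper = prov$boot_ci$upper)
    rownames(ci) <- prov$boot_ci$parameter
    prov$boot_ci <- ci
  }
  fermi_protocol_model(Eco = doc$Eco, k1 = doc$k1, Ao = doc$Ao, k2 = doc$k2,
                       pulse_length = doc$pulse_length_s,
                       provenance = prov[!vapply(prov, is.null, logical(1))])
}

#' Export a grid as a delimited text matrix
#'
#' One row per y node, one column per x node, tab-separated, with `#`
#' comment lines recording the grid geometry and provenance.
#'
#' @param values numeric matrix, `[i, j]` = node `(x[i], y[j])`.
#' @param path output path.
#' @param x,y node coordinate vectors.
#' @param what short description recorded in the header.
#' @return `path`, invisibly.
#' @export
write_matrix_txt <- function(values, path, x = NULL, y = NULL,
                             what = "grid values") {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(paste0("# ireplan ", what, ", version ",
                  as.character(utils::packageVersion("ireplan"))),
           "# layout: rows = y nodes (ascending), columns = x nodes")
  if (!is.null(x)) hdr <- c(hdr, sprintf(
    "# x: %d nodes from %g to %g", length(x), min(x), max(x)))
  if (!is.null(y)) hdr <- c(hdr, sprintf(
    "# y: %d nodes from %g to %g", length(y), min(y), max(y)))
  writeLines(hdr, con)
  utils::write.table(t(values), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Export grids as a legacy VTK structured-points file
#'
#' ASCII legacy VTK (`DATASET STRUCTURED_POINTS`) with one `SCALARS`
#' record per named matrix, for visualization in ParaView and similar
#' tools.  `NA` values (electrode interiors) are written as -1.
#'
#' @param grids named list of numeric matrices, all the same shape,
#'   `[i, j]` = node `(x[i], y[j])`.
#' @param path output path.
#' @param x,y node coordinate vectors.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(grids, path, x, y, title = "ireplan field") {
  stopifnot(is.list(grids), length(grids) >= 1L,
            !is.null(names(grids)), all(nzchar(names(grids))))
  nx <- length(x); ny <- length(y)
  for (g in grids) stopifnot(nrow(g) == nx, ncol(g) == ny)
  h <- if (nx > 1L) x[2] - x[1] else 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", x[1], y[1]),
               sprintf("SPACING %g %g 1", h, h),
               sprintf("POINT_DATA %d", nx * ny)), con)
  for (nm in names(grids)) {
    v <- as.vector(grids[[nm]])       # x fastest, matching VTK ordering
    v[is.na(v)] <- -1
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default",
                 format(v, digits = 9, trim = TRUE, scientific = NA)), con)
  }
  invisible(path)
}

# ---- run configuration -----------------------------------------------------

.RUNCONFIG_KEYS <- list(
  top = c("geometry", "protocol", "model", "numerics", "output", "seed"),
  geometry = c("units", "separation", "radii", "domain_extent",
               "conductivity"),
  protocol = c("n_pulses", "C", "pulse_length_s"),
  model = c("path", "Eco", "k1", "Ao", "k2", "pulse_length_s"),
  numerics = c("h", "tol", "s_kill", "s_live"),
  output = c("dir", "formats"))

.check_keys <- function(x, section) {
  allowed <- .RUNCONFIG_KEYS[[section]]
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) in run config ",
         if (section == "top") "" else paste0("section '", section, "'"),
         ": ", paste(bad, collapse = ", "), call. = FALSE)
}

#' Read and validate a run configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON document describing one planning run:
#' a `geometry` section (units are mandatory; `mm` or `dimensionless`),
#' a `protocol` section (vectors `n`, `C`, `pulse_length_s`), a `model`
#' section (path to a fitted-model JSON, or inline `Eco/k1/Ao/k2/
#' pulse_length_s`), a `numerics` section (`h`, `tol`, `s_kill`,
#' `s_live`), an `output` section (`dir`, `formats` among csv/vtk), and a
#' `seed`.  Unknown keys are rejected by name; referenced file paths must
#' exist (relative to the config file's directory).
#'
#' @param path config file path.
#' @return a validated list of class `"run_config"` with the geometry as
#'   an [electrode_config()] (dimensionless, with `$models` resolved to
#'   [fermi_protocol_model()] objects keyed by pulse length).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  .check_keys(raw, "top")
  for (sec in c("geometry", "protocol", "model"))
    if (is.null(raw[[sec]]))
      stop("run config is missing required section '", sec, "'",
           call. = FALSE)
  for (sec in intersect(names(raw), c("geometry", "protocol", "model",
                                      "numerics", "output")))
    .check_keys(raw[[sec]], sec)

  # YAML 1.1 floats require a signed exponent ("1.5e+5"); plain "1.5e5"
  # arrives as a string, so numeric fields are coerced explicitly
  num <- function(x) {
    if (is.null(x)) return(NULL)
    v <- suppressWarnings(as.numeric(unlist(x)))
    if (any(is.na(v)))
      stop("non-numeric value where a number was expected: ",
           paste(unlist(x), collapse = ", "), call. = FALSE)
    v
  }

  geo <- raw$geometry
  if (is.null(geo$units))
    stop("geometry section must declare 'units' (mm or dimensionless)",
         call. = FALSE)
  if (!geo$units %in% c("mm", "dimensionless"))
    stop("geometry units must be 'mm' or 'dimensionless', got '",
         geo$units, "'", call. = FALSE)

  mod <- raw$model
  models <- NULL
  if (!is.null(mod$path)) {
    mpath <- mod$path
    if (!file.exists(mpath))
      mpath <- file.path(dirname(path), mod$path)
    if (!file.exists(mpath))
      stop("model file does not exist: ", mod$path, call. = FALSE)
    models <- list(read_fermi_model(mpath))
  } else {
    need <- c("Eco", "k1", "Ao", "k2", "pulse_length_s")
    if (!all(need %in% names(mod)))
      stop("model section needs either 'path' or inline parameters ",
           paste(need, collapse = ", "), call. = FALSE)
    for (k in need) mod[[k]] <- num(mod[[k]])
    models <- lapply(seq_along(mod$Eco), function(i)
      fermi_protocol_model(mod$Eco[i], mod$k1[i], mod$Ao[i], mod$k2[i],
                           mod$pulse_length_s[i]))
  }
  Eco_ref <- models[[1L]]$Eco

  if (geo$units == "mm") {
    cfg <- electrode_config(
      separation = num(geo$separation) * 1e-3,
      radii = num(geo$radii) * 1e-3,
      applied_voltage = 0,   # voltage comes from the protocol C values
      conductivity = if (is.null(geo$conductivity)) 1
      else num(geo$conductivity),
      domain_extent = if (!is.null(geo$domain_extent))
        num(geo$domain_extent) * 1e-3,
      mode = "dimensional")
    L_m <- cfg$L
    cfg <- electrode_config(
      separation = 1, radii = c(cfg$radius_1, cfg$radius_2) / L_m,
      applied_voltage = 1,
      domain_extent = cfg$domain_extent / L_m, mode = "dimensionless")
    attr(cfg, "dimensional") <- list(L = L_m, Eco = Eco_ref,
                                     conductivity = geo$conductivity)
  } else {
    cfg <- electrode_config(
      separation = 1, radii = num(geo$radii), applied_voltage = 1,
      domain_extent = if (is.null(geo$domain_extent)) NULL
      else num(geo$domain_extent),
      mode = "dimensionless")
  }

  pr <- raw$protocol
  if (is.null(pr$n_pulses) || is.null(pr$C))
    stop("protocol section needs 'n_pulses' and 'C'", call. = FALSE)
  protocols <- expand.grid(
    n = num(pr$n_pulses), C = num(pr$C),
    pulse_length = if (is.null(pr$pulse_length_s))
      vapply(models, `[[`, numeric(1), "pulse_length")
    else num(pr$pulse_length_s),
    KEEP.OUT.ATTRS = FALSE)

  nm <- raw$numerics
  numerics <- list(
    h = if (is.null(nm$h)) 0.01 else num(nm$h),
    tol = if (is.null(nm$tol)) 1e-8 else num(nm$tol),
    s_kill = if (is.null(nm$s_kill)) 0.05 else num(nm$s_kill),
    s_live = if (is.null(nm$s_live)) 0.95 else num(nm$s_live))

  out <- raw$output
  output <- list(
    dir = if (is.null(out$dir)) "." else out$dir,
    formats = if (is.null(out$formats)) c("csv", "vtk")
    else unlist(out$formats))
  bad_fmt <- setdiff(output$formats, c("csv", "vtk"))
  if (length(bad_fmt))
    stop("unknown output format(s): ", paste(bad_fmt, collapse = ", "),
         call. = FALSE)

  structure(
    list(config = cfg, models = models, protocols = protocols,
         numerics = numerics, output = output,
         seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
         path = path),
    class = "run_config")
}
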