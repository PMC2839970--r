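# internal helpers

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream; restores (or removes) .Random.seed afterwards.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Validate a survival dataset
#'
#' Checks the tidy survival-table contract: columns `field` (V/m, >= 0),
#' `n_pulses` (integer >= 1), `pulse_length_s` (> 0), `survival` (in
#' \[0, 1\]), all finite.  Returns the data frame (with columns coerced to
#' numeric) invisibly usable in a pipeline.
#'
#' @param dataset a data frame.
#' @return the validated data frame.
#' @export
validate_survival_dataset <- function(dataset) {
  dataset <- as.data.frame(dataset)
  required <- c("field", "n_pulses", "pulse_length_s", "survival")
  missing <- setdiff(required, names(dataset))
  if (length(missing))
    stop("survival dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in required) dataset[[col]] <- as.numeric(dataset[[col]])
  if (any(!is.finite(as.matrix(dataset[required]))))
    stop("survival dataset contains non-finite values", call. = FALSE)
  if (any(dataset$field < 0))
    stop("'field' must be >= 0 (V/m)", call. = FALSE)
  if (any(dataset$n_pulses < 1) ||
      any(dataset$n_pulses != round(dataset$n_pulses)))
    stop("'n_pulses' must be integer >= 1", call. = FALSE)
  if (any(dataset$pulse_length_s <= 0))
    stop("'pulse_length_s' must be > 0", call. = FALSE)
  if (any(dataset$survival < 0) || any(dataset$survival > 1))
    stop("'survival' must lie in [0, 1]", call. = FALSE)
  dataset
}

# near-equality for matching pulse lengths etc.
.near <- function(x, y, tol = 1e-9) abs(x - y) <= tol * pmax(abs(x), abs(y), 1e-300)
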