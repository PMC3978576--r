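# internal validation helpers

REGIONS <- c("lateral", "central", "medial")

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("enthesomorph_parameter_error", "error")))
}

stop_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("enthesomorph_geometry_error", "error")))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(name, " must be a single positive finite number")
  invisible(x)
}

check_region <- function(region) {
  if (!is.character(region) || length(region) != 1L || !region %in% REGIONS)
    stop_param("region must be one of ", paste(REGIONS, collapse = ", "))
  region
}

check_fraction <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(name, " must be a single finite number")
  if (open && (x <= 0 || x >= 1)) stop_param(name, " must lie strictly between 0 and 1")
  if (!open && (x < 0 || x > 1)) stop_param(name, " must lie in [0, 1]")
  x
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# match a log-normal to a target mean and sd on the natural scale
lnorm_pars <- function(mean, sd) {
  sdlog2 <- log1p((sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}
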