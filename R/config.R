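#' Run configuration
#'
#' Bundles the handful of tunables shared across pipeline stages. All
#' randomized operations in the package take their seed explicitly (here or
#' per call); no global RNG state is consumed.
#'
#' @param significance_level Alpha for significance flags and FDR thresholds
#'   (default 0.05).
#' @param robust_correlation_threshold Absolute-correlation cutoff for the
#'   cross-dataset robust co-expression partner filter (default 0.4; the
#'   comparison is strict, `|rho| > threshold`).
#' @param rng_seed Integer seed for the synthetic-data generators, or `NULL`.
#' @param ci_level Confidence level for all interval estimates (default 0.95).
#' @return An object of class `vntr_config` (a validated list).
#' @export
runConfig <- function(significance_level = 0.05,
                      robust_correlation_threshold = 0.4,
                      rng_seed = NULL,
                      ci_level = 0.95) {
  stopifnot(is.numeric(significance_level), length(significance_level) == 1,
            significance_level > 0, significance_level < 1,
            is.numeric(robust_correlation_threshold),
            robust_correlation_threshold >= 0,
            is.numeric(ci_level), ci_level > 0, ci_level < 1)
  if (!is.null(rng_seed)) rng_seed <- as.integer(rng_seed)
  structure(list(significance_level = significance_level,
                 robust_correlation_threshold = robust_correlation_threshold,
                 rng_seed = rng_seed,
                 ci_level = ci_level),
            class = "vntr_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path Path to the configuration file.
#' @return A [runConfig()] object.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml/.yml or .json: ", path)
  }
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(runConfig, vals)
}

#' @export
print.vntr_config <- function(x, ...) {
  cat("vntrtools run configuration\n")
  cat("  significance level:          ", x$significance_level, "\n")
  cat("  robust correlation threshold:", x$robust_correlation_threshold, "\n")
  cat("  CI level:                    ", x$ci_level, "\n")
  cat("  RNG seed:                    ",
      if (is.null(x$rng_seed)) "none" else x$rng_seed, "\n")
  invisible(x)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# (or removing) the caller's .Random.seed afterwards. Generators built on
# this are pure functions of their arguments.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
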