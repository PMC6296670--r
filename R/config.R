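#' Load and validate a planning/run configuration
#'
#' Reads a YAML or JSON configuration file whose keys mirror the
#' conventional program-specification names used in published planning
#' code for this test -- `alpha`, `power`, `n1`, `n2`, `beta11`,
#' `beta12`, `sigsq1`, `sigsq2`, `tausq1`, `tausq2`, `rn21`, `reps`,
#' `seed`, `method` -- so a specification block can be transferred
#' verbatim.  Long-form aliases (`sigma2_1`, `tau2_1`, `ratio`,
#' `target_power`, ...) are accepted and normalized to the short keys.
#' Values supplied in `overrides` (e.g. from command-line flags) win
#' over file values; each override of a file value is reported with
#' `message()`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` to
#'   use `overrides` alone.
#' @param overrides named list of values taking precedence over the
#'   file.
#'
#' @return A named list of validated configuration values, of class
#'   `"run_config"`.  Only keys that were supplied are present.
#'
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' writeLines(c("alpha: 0.05", "power: 0.80", "beta11: 15.9286",
#'              "beta12: 3.8398", "sigsq1: 10124.8980",
#'              "sigsq2: 9097.9625", "tausq1: 31.1111",
#'              "tausq2: 23.8600", "rn21: 1"), tf)
#' load_run_config(tf)
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else
      yaml::read_yaml(path)
    if (!is.list(vals) || (length(vals) && is.null(names(vals))))
      stop("config file must define a mapping of key: value pairs",
           call. = FALSE)
  }
  vals <- normalize_config_keys(vals)
  overrides <- normalize_config_keys(overrides)
  for (k in names(overrides)) {
    if (!is.null(vals[[k]]) && !identical(vals[[k]], overrides[[k]]))
      message("config key '", k, "': flag value ", overrides[[k]],
              " overrides file value ", vals[[k]])
    vals[[k]] <- overrides[[k]]
  }
  validate_run_config(vals)
}

config_key_aliases <- c(
  sigma2_1 = "sigsq1", sigma2_2 = "sigsq2",
  tau2_1 = "tausq1", tau2_2 = "tausq2",
  ratio = "rn21", target_power = "power",
  nominal_power = "power", significance = "alpha")

normalize_config_keys <- function(vals) {
  if (!length(vals)) return(vals)
  nm <- names(vals)
  hit <- nm %in% names(config_key_aliases)
  nm[hit] <- config_key_aliases[nm[hit]]
  names(vals) <- nm
  vals[!duplicated(nm, fromLast = TRUE)]
}

config_numeric_keys <- c("alpha", "power", "n1", "n2", "beta11", "beta12",
                         "sigsq1", "sigsq2", "tausq1", "tausq2", "rn21",
                         "reps", "seed")

validate_run_config <- function(vals) {
  known <- c(config_numeric_keys, "method")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys are ", paste(known, collapse = ", "),
         call. = FALSE)
  problems <- character()
  for (k in intersect(names(vals), config_numeric_keys)) {
    v <- suppressWarnings(as.numeric(vals[[k]]))
    if (length(v) != 1L || is.na(v)) {
      problems <- c(problems, paste0(k, " must be a single number"))
      next
    }
    vals[[k]] <- v
    bad <- switch(k,
      alpha = v <= 0 || v >= 1,
      power = v <= 0 || v >= 1,
      n1 = , n2 = v != round(v) || v < 3,
      sigsq1 = , sigsq2 = , tausq1 = , tausq2 = v <= 0,
      rn21 = v <= 0,
      reps = v != round(v) || v < 100,
      seed = v != round(v),
      FALSE)
    if (bad) problems <- c(problems, paste0(k, " = ", v, " is out of range"))
  }
  if (!is.null(vals$method)) {
    vals$method <- toupper(as.character(vals$method))
    if (!vals$method %in% c("ST", "MT"))
      problems <- c(problems, "method must be 'ST' or 'MT'")
  }
  if (!is.null(vals$alpha) && !is.null(vals$power) &&
      is.numeric(vals$alpha) && is.numeric(vals$power) &&
      vals$power <= vals$alpha)
    problems <- c(problems, "power must exceed alpha")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(vals, class = "run_config")
}

require_config_keys <- function(cfg, keys, command) {
  missing <- setdiff(keys, names(cfg))
  if (length(missing))
    stop("command '", command, "' needs config key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

# planning_config from the short config keys
config_to_planning <- function(cfg) {
  planning_config(beta11 = cfg$beta11, beta12 = cfg$beta12,
                  sigma2_1 = cfg$sigsq1, sigma2_2 = cfg$sigsq2,
                  tau2_1 = cfg$tausq1, tau2_2 = cfg$tausq2,
                  alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha)
}
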