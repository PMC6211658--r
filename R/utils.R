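# Input checking + small formatting helpers shared across the package.

check_positive <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric and non-missing.", name),
          class = "occudyn_domain_error")
  }
  bad <- if (allow_zero) any(x < 0) else any(x <= 0)
  if (bad) {
    abort(sprintf("`%s` must be %s.", name,
                  if (allow_zero) ">= 0" else "> 0"),
          class = "occudyn_domain_error")
  }
  invisible(x)
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || anyNA(tau) || any(tau < 0)) {
    abort("`tau` must be numeric and >= 0 (dimensionless time).",
          class = "occudyn_domain_error")
  }
  invisible(tau)
}

check_scenario <- function(scenario) {
  if (length(scenario) != 1 || !scenario %in% c(1L, 2L)) {
    abort("`scenario` must be 1 (species turnover) or 2 (state gating).",
          class = "occudyn_domain_error")
  }
  as.integer(scenario)
}

#' Format a duration in seconds with an auto-scaled human unit
#'
#' Reports use seconds internally; this picks ms/s/min/hr for display,
#' mirroring the mixed units conventional in kinetics tables.
#'
#' @param seconds Duration in seconds.
#' @param digits Significant digits for the scaled value.
#' @return A character vector like `"19.25 hr"`.
#' @examples
#' format_duration(c(0.3, 300, 69315))
#' @export
format_duration <- function(seconds, digits = 4) {
  vapply(seconds, function(s) {
    if (is.na(s)) return(NA_character_)
    if (s < 1) {
      sprintf("%s ms", signif(s * 1e3, digits))
    } else if (s < 120) {
      sprintf("%s s", signif(s, digits))
    } else if (s < 7200) {
      sprintf("%s min", signif(s / 60, digits))
    } else {
      sprintf("%s hr", signif(s / 3600, digits))
    }
  }, character(1))
}

# seconds-per-unit conversions accepted on CLI / config input
.time_unit_factors <- c(ms = 1e-3, s = 1, min = 60, hr = 3600, h = 3600)

#' Parse a time value with an optional unit suffix
#'
#' Accepts `"300"` (seconds), `"14.4 min"`, `"19.25hr"`, `"350 ms"`.
#'
#' @param x Character or numeric vector.
#' @return Numeric vector of seconds.
#' @examples
#' parse_time("14.4 min")
#' @export
parse_time <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(x, function(v) {
    m <- regmatches(v, regexec("^\\s*([0-9eE.+-]+)\\s*([a-zA-Z]*)\\s*$", v))[[1]]
    if (length(m) != 3) {
      abort(sprintf("Cannot parse time value '%s'.", v),
            class = "occudyn_domain_error")
    }
    val <- as.numeric(m[2])
    unit <- if (nzchar(m[3])) m[3] else "s"
    if (!unit %in% names(.time_unit_factors)) {
      abort(sprintf("Unknown time unit '%s' in '%s'.", unit, v),
            class = "occudyn_domain_error")
    }
    val * .time_unit_factors[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
}
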