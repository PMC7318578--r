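# Gas constant, kJ mol^-1 K^-1
R_GAS_KJ <- 8.3145e-3

# Conversion between the slope of a ln-ratio vs 1000/T line (units: K, per
# 10^3/T abscissa) and an energy in kJ/mol: E = -slope * R * 1000 [J] / 1000.
slope_to_kj <- function(slope) -slope * 8.3145

abort_validation <- function(msg, ...) {
  abort(msg, class = c("p450thermo_validation_error", "p450thermo_error"), ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = c("p450thermo_format_error", "p450thermo_validation_error",
                       "p450thermo_error"), ...)
}

abort_parse <- function(msg, ...) {
  abort(msg, class = c("p450thermo_parse_error", "p450thermo_validation_error",
                       "p450thermo_error"), ...)
}

abort_usage <- function(msg, ...) {
  abort(msg, class = c("p450thermo_usage_error", "p450thermo_error"), ...)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x)) abort_validation(sprintf("`%s` must be numeric.", name))
  if (finite && any(!is.finite(x))) {
    abort_validation(sprintf("`%s` must be finite.", name))
  }
  if (positive && any(x <= 0)) {
    abort_validation(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# Celsius to kelvin; the only temperature conversion the package performs.
celsius_to_kelvin <- function(x) x + 273.15

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort_format(sprintf("%s is missing required column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
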