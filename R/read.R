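#' Read a raw velocity table
#'
#' Reads a delimited text file of per-incubation reaction velocities, one row
#' per (temperature, substrate concentration, metabolite) observation, as
#' produced by enzyme kinetic assays run at several temperatures. The
#' temperature unit is never guessed: it must be declared explicitly.
#'
#' The file must contain the columns `temperature`, `substrate_conc`,
#' `metabolite` and `velocity`; a `replicate` column is optional. Comma or tab
#' delimiters are auto-detected from the header line. Temperatures are
#' converted to kelvin on read.
#'
#' @param path Path to a delimited text file (UTF-8).
#' @param temperature_unit Unit of the `temperature` column, `"C"` (degrees
#'   Celsius) or `"K"` (kelvin). No default: the unit must be stated.
#' @param conc_unit Unit of `substrate_conc`; only `"uM"` (micromolar) is
#'   supported and declared for explicitness.
#'
#' @return A tibble with columns `temperature_K`, `substrate_uM`,
#'   `metabolite`, `velocity` (nmol product min^-1 (nmol enzyme)^-1) and,
#'   when present in the input, `replicate`.
#'
#' @details Malformed numeric cells are reported with their file line number
#'   (header = line 1). Velocities must be non-negative and concentrations
#'   and temperatures strictly positive.
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("temperature,substrate_conc,metabolite,velocity",
#'              "25,100,4'-OH-MF,608"), f)
#' read_velocity_table(f, temperature_unit = "C")
#' @export
read_velocity_table <- function(path, temperature_unit, conc_unit = "uM") {
  if (missing(temperature_unit)) {
    abort_usage("`temperature_unit` must be declared explicitly (\"C\" or \"K\").")
  }
  temperature_unit <- rlang::arg_match(temperature_unit, c("C", "K"))
  conc_unit <- rlang::arg_match(conc_unit, "uM")

  raw <- read_delimited_chr(path, what = "Velocity table")
  require_columns(raw, c("temperature", "substrate_conc", "metabolite", "velocity"),
                  "Velocity table")

  tab <- tibble::tibble(
    temperature_K = parse_numeric_col(raw$temperature, "temperature", raw$.line),
    substrate_uM  = parse_numeric_col(raw$substrate_conc, "substrate_conc", raw$.line),
    metabolite    = as.character(raw$metabolite),
    velocity      = parse_numeric_col(raw$velocity, "velocity", raw$.line)
  )
  if (temperature_unit == "C") {
    tab$temperature_K <- celsius_to_kelvin(tab$temperature_K)
  }
  if ("replicate" %in% names(raw)) {
    tab$replicate <- as.integer(parse_numeric_col(raw$replicate, "replicate", raw$.line))
  }

  bad <- which(tab$temperature_K <= 0)
  if (length(bad) > 0) {
    abort_validation(sprintf("Non-positive absolute temperature at line(s) %s.",
                             paste(raw$.line[bad], collapse = ", ")))
  }
  bad <- which(tab$substrate_uM <= 0)
  if (length(bad) > 0) {
    abort_validation(sprintf("Non-positive substrate concentration at line(s) %s.",
                             paste(raw$.line[bad], collapse = ", ")))
  }
  bad <- which(tab$velocity < 0)
  if (length(bad) > 0) {
    abort_validation(sprintf("Negative velocity at line(s) %s.",
                             paste(raw$.line[bad], collapse = ", ")))
  }
  tab
}

#' Read a pre-fitted kinetic parameter table
#'
#' Reads a delimited table of per-temperature, per-metabolite Michaelis-Menten
#' parameters (Vmax and KM with their standard errors), the direct entry point
#' for published kinetic tables. Required columns: `temperature_K`,
#' `metabolite`, `Vmax`, `Vmax_SE`, `KM`, `KM_SE`; an `enzyme` column is
#' optional and carried through.
#'
#' @param path Path to a delimited text file (comma or tab, auto-detected).
#' @return A validated tibble, one row per (enzyme, temperature, metabolite).
#' @export
read_param_table <- function(path) {
  raw <- read_delimited_chr(path, what = "Parameter table")
  required <- c("temperature_K", "metabolite", "Vmax", "Vmax_SE", "KM", "KM_SE")
  require_columns(raw, required, "Parameter table")

  tab <- tibble::tibble(
    temperature_K = parse_numeric_col(raw$temperature_K, "temperature_K", raw$.line),
    metabolite    = as.character(raw$metabolite),
    Vmax          = parse_numeric_col(raw$Vmax, "Vmax", raw$.line),
    Vmax_SE       = parse_numeric_col(raw$Vmax_SE, "Vmax_SE", raw$.line),
    KM            = parse_numeric_col(raw$KM, "KM", raw$.line),
    KM_SE         = parse_numeric_col(raw$KM_SE, "KM_SE", raw$.line)
  )
  if ("enzyme" %in% names(raw)) {
    tab <- tibble::add_column(tab, enzyme = as.character(raw$enzyme), .before = 1)
  }
  validate_param_table(tab)
}

validate_param_table <- function(tab) {
  if (any(tab$temperature_K <= 0)) abort_validation("Temperatures must be > 0 K.")
  if (any(tab$Vmax <= 0)) abort_validation("All Vmax values must be > 0.")
  if (any(tab$KM <= 0)) abort_validation("All KM values must be > 0.")
  if (any(tab$Vmax_SE < 0) || any(tab$KM_SE < 0)) {
    abort_validation("Standard errors must be >= 0.")
  }
  keys <- if ("enzyme" %in% names(tab)) {
    paste(tab$enzyme, tab$temperature_K, tab$metabolite, sep = "\r")
  } else {
    paste(tab$temperature_K, tab$metabolite, sep = "\r")
  }
  if (anyDuplicated(keys) > 0) {
    dup <- keys[duplicated(keys)][1]
    abort_validation(sprintf("Duplicate (temperature, metabolite) key: %s",
                             gsub("\r", " / ", dup)))
  }
  tab
}

# Read a delimited file with all columns as character plus a .line column of
# original file line numbers, so parse errors can be located precisely.
read_delimited_chr <- function(path, what) {
  if (!file.exists(path)) {
    abort_usage(sprintf("File not found: %s", path))
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0 || !nzchar(trimws(header))) {
    abort_format(sprintf("%s file is empty: %s", what, path))
  }
  delim <- if (grepl("\t", header)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  if (nrow(tab) == 0) {
    abort_format(sprintf("%s contains a header but no data rows: %s", what, path))
  }
  tab$.line <- seq_len(nrow(tab)) + 1L
  tab
}

parse_numeric_col <- function(x, col, line) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "Non-numeric value in column `%s` at line %d: \"%s\"",
      col, line[bad[1]], x[bad[1]]))
  }
  if (anyNA(out)) {
    abort_parse(sprintf("Missing value in column `%s` at line %d.",
                        col, line[which(is.na(out))[1]]))
  }
  out
}
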