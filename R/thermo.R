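#' Curtin-Hammett estimate of the overall activation free-energy difference
#'
#' Under fast interconversion of reactive binding poses, the product ratio of
#' two competing pathways reflects only the free-energy difference of their
#' transition states: \eqn{\Delta\Delta G_{overall} = -RT \ln(v_1/v_2)}.
#'
#' @param vmax1,vmax2 Maximal velocities (any common unit), pathway 1 first.
#' @param temperature Absolute temperature in kelvin (default 300).
#' @return \eqn{\Delta\Delta G_{overall}} in kJ/mol (vectorised).
#' @examples
#' curtin_hammett(463, 608, 300) # ~0.7 kJ/mol
#' @export
curtin_hammett <- function(vmax1, vmax2, temperature = 300) {
  check_number(vmax1, "vmax1", positive = TRUE)
  check_number(vmax2, "vmax2", positive = TRUE)
  check_number(temperature, "temperature", positive = TRUE)
  -R_GAS_KJ * temperature * log(vmax1 / vmax2)
}

#' Curtin-Hammett estimate from a kinetic parameter table
#'
#' Picks, for a metabolite pair, the measured temperature nearest
#' `target_T`, and evaluates [curtin_hammett()] on that row's Vmax values
#' with the fixed `formula_T` in the formula (the convention of using a
#' round reference temperature with the nearest measured Vmax pair).
#'
#' @inheritParams build_ratio_series
#' @param target_T Temperature (K) whose nearest measured row supplies the
#'   Vmax pair; default 300.
#' @param formula_T Temperature (K) inserted in \eqn{-RT\ln(v_1/v_2)};
#'   default 300.
#' @return One-row tibble: the pair, the measured temperature used, both
#'   Vmax values and `ddG_overall` (kJ/mol).
#' @examples
#' mefenamic_params("BM3 M11") |>
#'   curtin_hammett_from_params(c("3'-OH-MF", "4'-OH-MF"))
#' @export
curtin_hammett_from_params <- function(params, pair, enzyme = NULL,
                                       target_T = 300, formula_T = 300) {
  require_columns(params, c("temperature_K", "metabolite", "Vmax"),
                  "Parameter table")
  if (length(pair) != 2 || pair[1] == pair[2]) {
    abort_usage("`pair` must be two distinct metabolite labels.")
  }
  params <- select_enzyme(params, enzyme)
  wide <- params |>
    dplyr::filter(.data$metabolite %in% pair) |>
    dplyr::select("temperature_K", "metabolite", "Vmax") |>
    tidyr::pivot_wider(names_from = "metabolite", values_from = "Vmax")
  if (!all(pair %in% names(wide))) {
    abort_validation("Both pair members must be present in the table.")
  }
  wide <- tidyr::drop_na(wide, dplyr::all_of(pair))
  if (nrow(wide) == 0) abort_validation("No common temperatures for the pair.")
  row <- wide[which.min(abs(wide$temperature_K - target_T)), ]
  tibble::tibble(
    metabolite_1 = pair[1], metabolite_2 = pair[2],
    measured_T = row$temperature_K, formula_T = formula_T,
    Vmax_1 = row[[pair[1]]], Vmax_2 = row[[pair[2]]],
    ddG_overall = curtin_hammett(row[[pair[1]]], row[[pair[2]]], formula_T))
}

#' Decompose the composite selectivity energy
#'
#' Splits the modified-Arrhenius composite \eqn{\Delta = \Delta\Delta
#' G_{bind} + \Delta E_a} into its binding component, \eqn{\Delta\Delta
#' G_{bind} = \Delta - \Delta E_a} (with \eqn{\Delta E_a} supplied
#' externally, e.g. from SMARTCyp or DFT), and estimates the relative
#' entropy of transition-state formation as \eqn{T\Delta\Delta S^{\ne} =
#' \Delta - \Delta\Delta G_{overall}}. The latter identity treats the
#' relative activation enthalpy as equal to \eqn{\Delta E_a}
#' (\eqn{\Delta\Delta H^{\ne} \approx \Delta E_a}); that approximation is
#' recorded in the output.
#'
#' All differences are pathway-1-minus-pathway-2.
#'
#' @param fit An `arrhenius_fit`, or a bare numeric \eqn{\Delta} in kJ/mol.
#' @param ddG_overall Curtin-Hammett \eqn{\Delta\Delta G_{overall}} in
#'   kJ/mol (`NA` to skip the entropy term).
#' @param dEa Externally computed activation-energy difference in kJ/mol
#'   (`NA` to skip the binding term).
#' @param reference_T Reference temperature in kelvin (metadata; default 300).
#' @param dEa_source Free-text provenance of `dEa` (e.g. "SMARTCyp v2/v3").
#' @return One-row tibble with `delta`, `ddG_overall`, `dEa`, `ddG_bind`,
#'   `TddS`, `reference_T`, `dEa_source` and an `approximation` note.
#' @examples
#' decompose_selectivity(8.1, ddG_overall = 0.7, dEa = -1.8)
#' @export
decompose_selectivity <- function(fit, ddG_overall = NA_real_, dEa = NA_real_,
                                  reference_T = 300, dEa_source = NA_character_) {
  pair <- c(NA_character_, NA_character_)
  if (inherits(fit, "arrhenius_fit")) {
    pair <- fit$pair %||% pair
    delta <- fit$delta
  } else {
    delta <- as.numeric(fit)
  }
  if (!is.finite(delta)) abort_validation("`delta` must be finite.")
  if (length(delta) != 1) abort_usage("`fit` must yield a single delta.")
  check_number(reference_T, "reference_T", positive = TRUE)
  tibble::tibble(
    metabolite_1 = pair[1], metabolite_2 = pair[2],
    delta = delta,
    ddG_overall = as.numeric(ddG_overall),
    dEa = as.numeric(dEa),
    ddG_bind = delta - as.numeric(dEa),
    TddS = delta - as.numeric(ddG_overall),
    reference_T = reference_T,
    dEa_source = dEa_source,
    approximation = "TddS assumes ddH_ts == dEa")
}

#' Kinetic isotope effect ratio from peak areas
#'
#' Ratio of non-deuterated (D0) to deuterated (Dn) metabolite peak areas
#' from a competitive incubation with an equimolar labelled/unlabelled
#' substrate mixture.
#'
#' @param area_d0,area_dn Positive peak areas (vectorised).
#' @return `area_d0 / area_dn`.
#' @examples
#' kie_ratio(384, 100)
#' @export
kie_ratio <- function(area_d0, area_dn) {
  check_number(area_d0, "area_d0", positive = TRUE)
  check_number(area_dn, "area_dn", positive = TRUE)
  area_d0 / area_dn
}

#' Summarise replicate KIE measurements
#'
#' Computes per-group mean and SD of the D0/Dn ratio over replicates.
#'
#' @param data Data frame with columns `area_d0`, `area_dn` and any grouping
#'   columns named in `...` (e.g. `metabolite`, `temperature_K`).
#' @param ... Grouping columns (tidy-select); default none (one overall row).
#' @return Tibble with `kie_mean`, `kie_sd`, `n` per group.
#' @export
kie_summary <- function(data, ...) {
  require_columns(data, c("area_d0", "area_dn"), "KIE table")
  data |>
    dplyr::mutate(.kie = kie_ratio(.data$area_d0, .data$area_dn)) |>
    dplyr::group_by(...) |>
    dplyr::summarise(kie_mean = mean(.data$.kie),
                     kie_sd = stats::sd(.data$.kie),
                     n = dplyr::n(), .groups = "drop")
}
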