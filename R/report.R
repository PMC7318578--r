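#' Thermodynamic comparison report for metabolite pairs
#'
#' One-stop summary table: for each requested metabolite pair, the modified
#' Arrhenius intercept/slope/R^2 and \eqn{\Delta}, optionally joined with
#' the Curtin-Hammett \eqn{\Delta\Delta G_{overall}} and with an externally
#' supplied \eqn{\Delta E_a} map, in which case the binding
#' (\eqn{\Delta\Delta G_{bind}}) and entropic (\eqn{T\Delta\Delta S^{\ne}})
#' decompositions are appended.
#'
#' @inheritParams build_ratio_series
#' @param pairs A list of two-element character vectors, each a
#'   (pathway 1, pathway 2) metabolite pair.
#' @param dEa Optional named numeric vector of activation-energy differences
#'   (kJ/mol), named `"met1 vs met2"`; or `NULL` to skip the decomposition.
#' @param dEa_source Provenance string for `dEa` values.
#' @param curtin_hammett If `TRUE`, append `ddG_overall` evaluated with
#'   [curtin_hammett_from_params()] at `reference_T`.
#' @param reference_T Reference temperature (K) for the Curtin-Hammett
#'   column; default 300.
#' @param weighted Passed to [fit_modified_arrhenius()].
#' @return A tibble, one row per pair.
#' @examples
#' mefenamic_params("BM3 M11") |>
#'   arrhenius_report(list(c("3'-OH-MF", "4'-OH-MF"), c("4'-OH-MF", "5-OH-MF")),
#'                    curtin_hammett = TRUE)
#' @export
arrhenius_report <- function(params, pairs, enzyme = NULL, dEa = NULL,
                             dEa_source = NA_character_,
                             curtin_hammett = FALSE, reference_T = 300,
                             weighted = FALSE) {
  if (is.character(pairs)) pairs <- list(pairs)
  params <- select_enzyme(params, enzyme)
  rows <- purrr::map(pairs, function(pair) {
    fit <- params |>
      build_ratio_series(pair) |>
      fit_modified_arrhenius(weighted = weighted)
    row <- glance(fit)
    if (curtin_hammett) {
      ch <- curtin_hammett_from_params(params, pair, target_T = reference_T,
                                       formula_T = reference_T)
      row$ddG_overall <- ch$ddG_overall
      row$curtin_hammett_T <- ch$measured_T
    }
    if (!is.null(dEa)) {
      key <- paste(pair, collapse = " vs ")
      de <- if (key %in% names(dEa)) unname(dEa[[key]]) else NA_real_
      dec <- decompose_selectivity(
        fit,
        ddG_overall = if (curtin_hammett) row$ddG_overall else NA_real_,
        dEa = de, reference_T = reference_T, dEa_source = dEa_source)
      row$dEa <- dec$dEa
      row$ddG_bind <- dec$ddG_bind
      row$TddS <- dec$TddS
      row$dEa_source <- dec$dEa_source
    }
    row
  })
  dplyr::bind_rows(rows)
}
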