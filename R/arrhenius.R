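#' Build a ln(Vmax ratio) vs 1000/T series for a metabolite pair
#'
#' For two parallel product pathways of the same enzyme, forms one point per
#' common temperature with abscissa \eqn{x = 1000/T} (in 10^3 K^-1) and
#' ordinate \eqn{y = \ln(V_{max,1}/V_{max,2})}. The ordinate SE is obtained
#' by first-order (delta-method) propagation of the Vmax standard errors:
#' \eqn{SE_y = \sqrt{(SE_1/V_1)^2 + (SE_2/V_2)^2}}.
#'
#' Temperatures measured for only one pathway are dropped with a warning;
#' ratios are always formed from fitted Vmax values, never raw velocities.
#'
#' @param params Kinetic parameter tibble ([read_param_table()],
#'   [fit_kinetics()] or [mefenamic_params()]).
#' @param pair Character vector of two distinct metabolite labels,
#'   pathway 1 first (all derived signs are pathway-1-minus-pathway-2).
#' @param enzyme Which enzyme to use when `params` has an `enzyme` column
#'   with more than one level; otherwise ignored.
#' @return A tibble of class `ratio_series` with columns `temperature_K`,
#'   `inv_kK` (1000/T), `log_vmax_ratio`, `log_vmax_ratio_se`, and a
#'   `pair` attribute.
#' @examples
#' mefenamic_params("BM3 M11") |>
#'   build_ratio_series(c("3'-OH-MF", "4'-OH-MF"))
#' @export
build_ratio_series <- function(params, pair, enzyme = NULL) {
  require_columns(params, c("temperature_K", "metabolite", "Vmax", "Vmax_SE"),
                  "Parameter table")
  if (length(pair) != 2 || anyNA(pair)) {
    abort_usage("`pair` must be two metabolite labels.")
  }
  if (pair[1] == pair[2]) {
    abort_usage("`pair` must name two distinct metabolites.")
  }
  params <- select_enzyme(params, enzyme)
  missing_met <- setdiff(pair, unique(params$metabolite))
  if (length(missing_met) > 0) {
    abort_validation(sprintf("Metabolite(s) not present in the data: %s",
                             paste(missing_met, collapse = ", ")))
  }
  if (any(params$Vmax <= 0)) abort_validation("All Vmax values must be > 0.")

  m1 <- dplyr::filter(params, .data$metabolite == pair[1])
  m2 <- dplyr::filter(params, .data$metabolite == pair[2])
  joined <- dplyr::inner_join(
    dplyr::select(m1, "temperature_K", V1 = "Vmax", S1 = "Vmax_SE"),
    dplyr::select(m2, "temperature_K", V2 = "Vmax", S2 = "Vmax_SE"),
    by = "temperature_K")
  dropped <- setdiff(union(m1$temperature_K, m2$temperature_K),
                     joined$temperature_K)
  if (length(dropped) > 0) {
    warn(sprintf("Dropping %d temperature(s) measured for only one metabolite: %s K",
                 length(dropped), paste(sort(dropped), collapse = ", ")))
  }
  if (nrow(joined) == 0) {
    abort_validation("The two metabolites share no common temperatures.")
  }

  out <- joined |>
    dplyr::arrange(.data$temperature_K) |>
    dplyr::transmute(
      temperature_K = .data$temperature_K,
      inv_kK = 1000 / .data$temperature_K,
      log_vmax_ratio = log(.data$V1 / .data$V2),
      log_vmax_ratio_se = sqrt((.data$S1 / .data$V1)^2 + (.data$S2 / .data$V2)^2))
  new_ratio_series(out, pair)
}

new_ratio_series <- function(tbl, pair) {
  structure(tbl, pair = pair,
            class = c("ratio_series", class(tibble::as_tibble(tbl))))
}

#' Fit the modified Arrhenius line to a ratio series
#'
#' Ordinary least squares of \eqn{\ln(V_{max,1}/V_{max,2})} on 1000/T. The
#' slope (in K, per 10^3/T unit) encodes the composite selectivity energy
#' \eqn{\Delta = \Delta\Delta G_{bind} + \Delta E_a} via
#' \eqn{\Delta = -slope \times R \times 10^3} (reported in kJ/mol with
#' R = 8.3145 J mol^-1 K^-1), and the intercept is the relative collision
#' efficiency \eqn{\ln(A_1/A_2)}, an entropic measure of transition-state
#' accessibility.
#'
#' @param series A `ratio_series` from [build_ratio_series()], or any data
#'   frame with columns `inv_kK`, `log_vmax_ratio` (and, for weighted fits,
#'   `log_vmax_ratio_se`).
#' @param weighted If `TRUE`, weight points by `1 / log_vmax_ratio_se^2`.
#'   The default, matching standard practice for these plots, is unweighted.
#' @return An object of class `arrhenius_fit`; see [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @details Two-point series are permitted for exploratory use: the line is
#'   exact, SEs are undefined (`NA`) and the fit is flagged
#'   non-inferential. All abscissa values identical is a singular design
#'   and an error.
#' @examples
#' mefenamic_params("BM3 M11") |>
#'   build_ratio_series(c("3'-OH-MF", "4'-OH-MF")) |>
#'   fit_modified_arrhenius()
#' @export
fit_modified_arrhenius <- function(series, weighted = FALSE) {
  require_columns(series, c("inv_kK", "log_vmax_ratio"), "Ratio series")
  x <- series$inv_kK
  y <- series$log_vmax_ratio
  check_number(x, "inv_kK", positive = TRUE)
  check_number(y, "log_vmax_ratio")
  n <- length(x)
  if (n < 2) abort_validation("At least 2 points are required.")
  if (length(unique(x)) == 1) {
    abort_validation("All abscissa values are identical: singular design.")
  }
  w <- NULL
  if (weighted) {
    require_columns(series, "log_vmax_ratio_se", "Weighted ratio series")
    se <- series$log_vmax_ratio_se
    if (any(se <= 0)) abort_validation("Weights need strictly positive SEs.")
    w <- 1 / se^2
  }
  df <- data.frame(x = x, y = y)
  fit <- if (weighted) lm(y ~ x, data = df, weights = w) else lm(y ~ x, data = df)
  cf <- coef(fit)
  # summary.lm warns on exactly collinear data; a perfect line is legitimate here
  sm <- suppressWarnings(summary(fit))
  inferential <- n >= 3
  ses <- if (inferential) sm$coefficients[, "Std. Error"] else c(NA_real_, NA_real_)
  r2 <- if (stats::var(y) == 0) 1 else sm$r.squared

  structure(
    list(pair = attr(series, "pair", exact = TRUE),
         slope = unname(cf[2]), slope_se = unname(ses[2]),
         intercept = unname(cf[1]), intercept_se = unname(ses[1]),
         r_squared = r2,
         delta = slope_to_kj(unname(cf[2])),
         delta_se = abs(unname(ses[2])) * 8.3145,
         ln_A_ratio = unname(cf[1]), ln_A_ratio_se = unname(ses[1]),
         n = n, weighted = weighted, inferential = inferential,
         series = tibble::as_tibble(series), lm = fit),
    class = "arrhenius_fit")
}

#' Classic Arrhenius diagnostic for a single pathway
#'
#' OLS of ln(Vmax) on 1000/T for one metabolite. For multistep P450
#' catalysis these single-pathway plots are typically strongly nonlinear
#' (membrane fluidity, redox-partner coupling, denaturation), so this fit is
#' a linearity diagnostic, not a thermodynamic estimate: compare its R^2
#' with that of the pairwise ratio fit, in which the shared factors cancel.
#'
#' @param params Kinetic parameter tibble.
#' @param metabolite Metabolite label to fit.
#' @param enzyme Enzyme selector as in [build_ratio_series()].
#' @return An object of class `classic_arrhenius_fit` with `slope`,
#'   `intercept`, `r_squared` and `apparent_Ea` (kJ/mol).
#' @export
fit_classic_arrhenius <- function(params, metabolite, enzyme = NULL) {
  require_columns(params, c("temperature_K", "metabolite", "Vmax"),
                  "Parameter table")
  params <- select_enzyme(params, enzyme)
  sub <- dplyr::filter(params, .data$metabolite == !!metabolite)
  if (nrow(sub) < 3) {
    abort_validation("At least 3 temperatures are required for a classic Arrhenius fit.")
  }
  if (any(sub$Vmax <= 0)) abort_validation("All Vmax values must be > 0.")
  x <- 1000 / sub$temperature_K
  y <- log(sub$Vmax)
  fit <- lm(y ~ x)
  cf <- coef(fit)
  structure(
    list(metabolite = metabolite,
         slope = unname(cf[2]), intercept = unname(cf[1]),
         r_squared = suppressWarnings(summary(fit))$r.squared,
         apparent_Ea = slope_to_kj(unname(cf[2])),
         n = nrow(sub), lm = fit),
    class = "classic_arrhenius_fit")
}

select_enzyme <- function(params, enzyme) {
  if (!"enzyme" %in% names(params)) {
    if (!is.null(enzyme)) warn("`enzyme` given but the table has no enzyme column; ignored.")
    return(params)
  }
  if (is.null(enzyme)) {
    if (length(unique(params$enzyme)) > 1) {
      abort_usage("The table contains several enzymes; pass `enzyme = ` to pick one.")
    }
    return(params)
  }
  out <- dplyr::filter(params, .data$enzyme == !!enzyme)
  if (nrow(out) == 0) {
    abort_validation(sprintf("No rows for enzyme \"%s\".", enzyme))
  }
  out
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  pair <- x$pair %||% c("1", "2")
  cat(sprintf("Modified Arrhenius fit: %s vs %s (%d points%s)\n",
              pair[1], pair[2], x$n, if (x$weighted) ", weighted" else ""))
  cat(sprintf("  slope     = %7.3f +/- %.3f K\n", x$slope, x$slope_se))
  cat(sprintf("  intercept = %7.3f +/- %.3f   (ln A1/A2)\n",
              x$intercept, x$intercept_se))
  cat(sprintf("  R^2       = %7.3f\n", x$r_squared))
  cat(sprintf("  Delta     = %7.2f +/- %.2f kJ/mol\n", x$delta, x$delta_se))
  if (!x$inferential) cat("  (two-point fit: SEs undefined, non-inferential)\n")
  invisible(x)
}

#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$intercept_se, x$slope_se))
}

#' @export
glance.arrhenius_fit <- function(x, ...) {
  pair <- x$pair %||% c(NA_character_, NA_character_)
  tibble::tibble(metabolite_1 = pair[1], metabolite_2 = pair[2],
                 intercept = x$intercept, intercept_se = x$intercept_se,
                 slope = x$slope, slope_se = x$slope_se,
                 r_squared = x$r_squared,
                 delta = x$delta, delta_se = x$delta_se,
                 n = x$n, weighted = x$weighted)
}

#' @export
print.classic_arrhenius_fit <- function(x, ...) {
  cat(sprintf("Classic Arrhenius diagnostic: %s (%d temperatures)\n",
              x$metabolite, x$n))
  cat(sprintf("  slope = %.3f K, intercept = %.3f, R^2 = %.3f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  apparent Ea = %.2f kJ/mol (diagnostic only)\n", x$apparent_Ea))
  invisible(x)
}

#' @export
glance.classic_arrhenius_fit <- function(x, ...) {
  tibble::tibble(metabolite = x$metabolite, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 apparent_Ea = x$apparent_Ea, n = x$n)
}
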