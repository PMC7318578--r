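#' Fit the Michaelis-Menten equation to one velocity group
#'
#' Fits \eqn{v = V_{max} S / (K_M + S)} to the (substrate concentration,
#' velocity) points of a single temperature and metabolite by damped
#' (Levenberg-Marquardt) least squares with an analytic residual Jacobian
#' and positivity bounds on both parameters. Replicate points are pooled
#' into one regression, preserving degrees of freedom.
#'
#' Standard errors are the asymptotic SEs reported by common curve-fitting
#' software: the inverse of the Gauss-Newton approximation to the Hessian
#' at the optimum, scaled by the residual variance.
#'
#' @param data A data frame with columns `substrate_uM` and `velocity`
#'   (additional columns are ignored). At least four distinct substrate
#'   concentrations are required.
#' @return An object of class `mm_fit` with components `Vmax`, `Vmax_SE`,
#'   `KM`, `KM_SE`, `converged`, `rss`, `n` and the fitted data. Use
#'   [tidy()] / [glance()] for tibble views.
#'
#' @details Initialisation: \eqn{V_{max,0}} is the largest observed velocity
#'   and \eqn{K_{M,0}} the concentration whose velocity is nearest half of
#'   \eqn{V_{max,0}}. Convergence: relative change in the objective below
#'   1e-10, at most 500 iterations; non-convergence is flagged, not fatal.
#'
#' @examples
#' s <- c(10, 25, 50, 100, 250, 500, 750)
#' d <- data.frame(substrate_uM = s, velocity = 230 * s / (76 + s))
#' fit_michaelis_menten(d)
#' @export
fit_michaelis_menten <- function(data) {
  require_columns(data, c("substrate_uM", "velocity"), "Velocity group")
  s <- as.numeric(data$substrate_uM)
  v <- as.numeric(data$velocity)
  check_number(s, "substrate_uM", positive = TRUE)
  check_number(v, "velocity")
  if (any(v < 0)) abort_validation("Velocities must be >= 0.")
  if (length(unique(s)) < 4) {
    abort_validation(
      "At least 4 distinct substrate concentrations are required for a Michaelis-Menten fit.")
  }
  if (all(v == 0)) abort_validation("All velocities are zero; nothing to fit.")
  if (length(unique(v)) == 1) {
    abort_validation("All velocities are identical; the fit is degenerate.")
  }

  fit <- mm_lm_engine(s, v)
  structure(
    list(Vmax = fit$par[1], Vmax_SE = fit$se[1],
         KM = fit$par[2], KM_SE = fit$se[2],
         converged = fit$converged, rss = fit$rss,
         n = length(v), niter = fit$niter,
         data = tibble::tibble(substrate_uM = s, velocity = v)),
    class = "mm_fit")
}

# Damped least-squares core: residual r = v - Vmax*S/(KM+S), analytic
# Jacobian, lower bounds keeping both parameters positive.
mm_lm_engine <- function(s, v) {
  resid_fn <- function(p) v - p[1] * s / (p[2] + s)
  jac_fn <- function(p) {
    den <- p[2] + s
    cbind(-s / den, p[1] * s / den^2)
  }
  vmax0 <- max(v)
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  out <- minpack.lm::nls.lm(
    par = c(vmax0, km0), lower = c(1e-12, 1e-12),
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500))

  p <- out$par
  r <- resid_fn(p)
  rss <- sum(r^2)
  n <- length(v)
  dof <- n - 2L
  J <- jac_fn(p)
  jtj <- crossprod(J)
  se <- c(NA_real_, NA_real_)
  cv <- tryCatch(solve(jtj), error = function(e) NULL)
  if (!is.null(cv) && dof > 0) {
    sigma2 <- rss / dof
    se <- sqrt(pmax(diag(cv) * sigma2, 0))
  }
  # nls.lm info codes 1:3 indicate convergence in ftol/xtol/both
  converged <- out$info %in% 1:4
  list(par = p, se = se, rss = rss, converged = converged, niter = out$niter)
}

#' Fit Michaelis-Menten parameters for every temperature and metabolite
#'
#' Splits a velocity table into (temperature, metabolite) groups (and enzyme,
#' if an `enzyme` column is present), fits each group with
#' [fit_michaelis_menten()], and returns a kinetic parameter table ready for
#' modified Arrhenius analysis. Groups that fail the fitting preconditions
#' or do not converge are flagged (`converged = FALSE`) so downstream steps
#' can exclude them.
#'
#' @param data A velocity tibble as returned by [read_velocity_table()] or
#'   [simulate_kinetics()]: columns `temperature_K`, `substrate_uM`,
#'   `metabolite`, `velocity`.
#' @return A tibble with one row per group: `temperature_K`, `metabolite`
#'   (and `enzyme` if present), `Vmax`, `Vmax_SE`, `KM`, `KM_SE`,
#'   `converged`, `rss`, `n_points`.
#' @examples
#' sim <- simulate_kinetics(seed = 1)
#' fit_kinetics(sim$velocities)
#' @export
fit_kinetics <- function(data) {
  require_columns(data, c("temperature_K", "substrate_uM", "metabolite", "velocity"),
                  "Velocity table")
  keys <- c(intersect("enzyme", names(data)), "temperature_K", "metabolite")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(g, k) {
      fit <- fit_michaelis_menten(g)
      tibble::tibble(Vmax = fit$Vmax, Vmax_SE = fit$Vmax_SE,
                     KM = fit$KM, KM_SE = fit$KM_SE,
                     converged = fit$converged, rss = fit$rss,
                     n_points = fit$n)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c("metabolite", "temperature_K"))))
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (", x$n, " points, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat(sprintf("  Vmax = %.4g +/- %.3g\n  KM   = %.4g +/- %.3g uM\n",
              x$Vmax, x$Vmax_SE, x$KM, x$KM_SE))
  invisible(x)
}

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(term = c("Vmax", "KM"),
                 estimate = c(x$Vmax, x$KM),
                 std.error = c(x$Vmax_SE, x$KM_SE))
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, converged = x$converged,
                 niter = x$niter)
}

#' Predicted Michaelis-Menten velocities
#'
#' @param object An `mm_fit` object.
#' @param newdata Optional data frame with a `substrate_uM` column; defaults
#'   to the fitted data.
#' @param ... Unused.
#' @return Numeric vector of predicted velocities.
#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) object$data$substrate_uM else newdata$substrate_uM
  object$Vmax * s / (object$KM + s)
}
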