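test_that("ratio series points carry ln(Vmax ratio) and delta-method SEs", {
  series <- build_ratio_series(bm3(), c(MET3, MET4))
  expect_s3_class(series, "ratio_series")
  expect_equal(nrow(series), 8)

  p277 <- series[series$temperature_K == 277, ]
  expect_equal(p277$inv_kK, 1000 / 277)
  expect_equal(p277$log_vmax_ratio, log(135 / 230))
  expect_equal(p277$log_vmax_ratio_se, sqrt((10 / 135)^2 + (19 / 230)^2),
               tolerance = 1e-12)

  # independent Monte-Carlo oracle for the delta-method propagation
  withr::local_seed(1)
  n <- 1e5
  mc <- stats::sd(log(rnorm(n, 135, 10) / rnorm(n, 230, 19)))
  expect_equal(p277$log_vmax_ratio_se, mc, tolerance = 0.02)
})

test_that("identical pathways give an identically zero series", {
  p <- bm3()
  twin <- p[p$metabolite == MET4, ]
  twin$metabolite <- "4'-copy"
  series <- build_ratio_series(rbind(p[p$metabolite == MET4, ], twin),
                               c(MET4, "4'-copy"))
  expect_true(all(series$log_vmax_ratio == 0))
  fit <- fit_modified_arrhenius(series)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$delta, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
})

test_that("temperatures present for one pathway only are dropped with a warning", {
  p <- bm3()
  p <- p[!(p$metabolite == MET4 & p$temperature_K == 277), ]
  expect_warning(series <- build_ratio_series(p, c(MET3, MET4)), "277")
  expect_equal(nrow(series), 7)
})

test_that("pair validation rejects degenerate or unknown pairs", {
  expect_error(build_ratio_series(bm3(), c(MET3, MET3)),
               class = "p450thermo_usage_error")
  expect_error(build_ratio_series(bm3(), c(MET3, "nope")),
               class = "p450thermo_validation_error")
  expect_error(build_ratio_series(mefenamic_params(), c(MET4, MET5)),
               class = "p450thermo_usage_error") # two enzymes, none chosen
})

test_that("an exact line is fitted exactly and delta converts by -slope*R", {
  x <- c(3.2, 3.3, 3.4, 3.5, 3.6)
  series <- tibble::tibble(temperature_K = 1000 / x, inv_kK = x,
                           log_vmax_ratio = 2.0 - 1.5 * x,
                           log_vmax_ratio_se = 0.1)
  fit <- fit_modified_arrhenius(series)
  expect_equal(fit$slope, -1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 2.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$delta, 1.5 * 8.3145, tolerance = 1e-12)
  expect_equal(fit$ln_A_ratio, fit$intercept)

  # singular design
  bad <- series
  bad$inv_kK <- 3.4
  expect_error(fit_modified_arrhenius(bad), class = "p450thermo_validation_error")
})

test_that("two-point fits are flagged non-inferential with undefined SEs", {
  series <- tibble::tibble(inv_kK = c(3.2, 3.6),
                           log_vmax_ratio = c(0.5, 0.9))
  fit <- fit_modified_arrhenius(series)
  expect_false(fit$inferential)
  expect_true(is.na(fit$slope_se))
  expect_equal(fit$slope, (0.9 - 0.5) / 0.4, tolerance = 1e-12)
})

test_that("pair swap negates every y, the slope, intercept and delta", {
  p <- bm3()
  pairs <- list(c(MET3, MET4), c(MET3, MET5), c(MET4, MET5))
  for (pair in pairs) {
    fwd <- build_ratio_series(p, pair)
    rev <- build_ratio_series(p, rev(pair))
    expect_equal(rev$log_vmax_ratio, -fwd$log_vmax_ratio, tolerance = 1e-12)
    expect_equal(rev$log_vmax_ratio_se, fwd$log_vmax_ratio_se, tolerance = 1e-12)
    ff <- fit_modified_arrhenius(fwd)
    fr <- fit_modified_arrhenius(rev)
    expect_equal(fr$slope, -ff$slope, tolerance = 1e-10)
    expect_equal(fr$intercept, -ff$intercept, tolerance = 1e-10)
    expect_equal(fr$delta, -ff$delta, tolerance = 1e-10)
    expect_equal(abs(fr$delta), abs(ff$delta))
  }
})

test_that("slopes, intercepts and delta are additive along a metabolite chain", {
  p <- bm3()
  f12 <- fit_modified_arrhenius(build_ratio_series(p, c(MET3, MET4)))
  f23 <- fit_modified_arrhenius(build_ratio_series(p, c(MET4, MET5)))
  f13 <- fit_modified_arrhenius(build_ratio_series(p, c(MET3, MET5)))
  expect_equal(f12$slope + f23$slope, f13$slope, tolerance = 1e-9)
  expect_equal(f12$intercept + f23$intercept, f13$intercept, tolerance = 1e-9)
  expect_equal(f12$delta + f23$delta, f13$delta, tolerance = 1e-9)
})

test_that("classic Arrhenius fit recovers an exact activation energy", {
  T <- c(280, 290, 300, 310)
  Ea <- 50 # kJ/mol
  p <- tibble::tibble(temperature_K = T, metabolite = "m",
                      Vmax = 1e9 * exp(-Ea / (8.3145e-3 * T)),
                      Vmax_SE = 1, KM = 100, KM_SE = 1)
  fit <- fit_classic_arrhenius(p, "m")
  expect_lt(abs(fit$apparent_Ea - 50) / 50, 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_classic_arrhenius(p[1, ], "m"),
               class = "p450thermo_validation_error")
})

test_that("single-pathway plots are far less linear than the pairwise ratio plot", {
  p <- bm3()
  single <- fit_classic_arrhenius(p, MET4)
  ratio <- fit_modified_arrhenius(build_ratio_series(p, c(MET3, MET4)))
  # the rise-and-fall of absolute Vmax destroys single-pathway linearity,
  # while shared factors cancel in the ratio
  expect_lt(single$r_squared, 0.5)
  expect_gt(ratio$r_squared, 0.9)
  expect_lt(single$r_squared, ratio$r_squared - 0.4)
})

test_that("weighted fits honour 1/SE^2 weights", {
  series <- build_ratio_series(bm3(), c(MET3, MET4))
  fw <- fit_modified_arrhenius(series, weighted = TRUE)
  # independent check via lm with explicit weights
  ref <- lm(log_vmax_ratio ~ inv_kK, data = series,
            weights = 1 / series$log_vmax_ratio_se^2)
  expect_equal(fw$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_true(fw$weighted)
})
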