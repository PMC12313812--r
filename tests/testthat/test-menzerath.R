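# closed-form OLS via the normal equations; independent of lm/lmer
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

test_that("parametric curve fit recovers generating parameters exactly", {
  x <- rep(2:10, each = 3)

  fit <- fit_menzerath_nonlinear(x, 1 * x^(-0.5))
  expect_equal(c(fit$a, fit$b, fit$c), c(1, -0.5, 0), tolerance = 1e-8)

  fit <- fit_menzerath_nonlinear(x, 2 * x^(-0.3) * exp(-0.05 * x))
  expect_equal(c(fit$a, fit$b, fit$c), c(2, -0.3, -0.05), tolerance = 1e-6)
  expect_equal(fit$curve(4), 2 * 4^(-0.3) * exp(-0.2), tolerance = 1e-6)

  flat <- fit_menzerath_nonlinear(x, rep(0.7, length(x)))
  expect_equal(c(flat$a, flat$b, flat$c), c(0.7, 0, 0), tolerance = 1e-8)

  expect_error(fit_menzerath_nonlinear(c(2, 2, 3, 3), c(1, 1, 2, 2)),
               "underdetermined")
})

test_that("fixing c at zero reduces the curve fit to log-log OLS", {
  set.seed(61)
  x <- sample(2:12, 200, replace = TRUE)
  y <- 1.5 * x^(-0.4) * exp(rnorm(200, sd = 0.2))
  fit <- fit_menzerath_nonlinear(x, y, fix_c = TRUE)
  beta <- ols_oracle(cbind(1, log(x)), log(y))
  expect_equal(log(fit$a), beta[1, 1], tolerance = 1e-8)
  expect_equal(fit$b, beta[2, 1], tolerance = 1e-8)
  expect_equal(fit$c, 0)

  # and on noiseless data the two routes agree to machine-level precision
  yn <- 1.5 * x^(-0.4)
  fit <- fit_menzerath_nonlinear(x, yn, fix_c = TRUE)
  expect_equal(c(log(fit$a), fit$b),
               unname(ols_oracle(cbind(1, log(x)), log(yn))[, 1]),
               tolerance = 1e-6)
})

sim_fit_data <- function(seed, n_ind = 6, n_seq = 25, b = -0.5,
                         sd_ind = 0.2, sd_seq = 0.1, sd_res = 0.3) {
  cfg <- sim_config(seed = seed, n_individuals = n_ind, n_groups = 2,
                    sequences_per_individual = n_seq,
                    law = list(a = 1, b = b, c = 0),
                    sd_individual = sd_ind, sd_sequence = sd_seq,
                    sd_residual = sd_res)
  d <- generate_dataset(cfg)
  list(kept = apply_exclusions(segment_sequences(d$calls))$kept, data = d)
}

test_that("with all random-effect variances pinned at zero the mixed model collapses to OLS", {
  sim <- sim_fit_data(71, sd_ind = 0, sd_seq = 0, sd_res = 0.3)
  fit <- fit_simple(sim$kept, zero_variance = TRUE)
  beta <- ols_oracle(cbind(1, log(sim$kept$length)), log(sim$kept$duration_s))
  expect_equal(unname(fit$estimates$estimate), unname(beta[, 1]),
               tolerance = 1e-8)
  expect_true(all(fit$variance_components$variance[
    fit$variance_components$grouping != "Residual"] == 0))
  # and the freely optimized fit on the same grouping-free data lands
  # close to the OLS solution too
  free <- fit_simple(sim$kept)
  expect_equal(unname(free$estimates$estimate), unname(beta[, 1]),
               tolerance = 0.02)
})

test_that("simple fit recovers the generating slope and reports Wald intervals", {
  sim <- sim_fit_data(72, n_ind = 10, n_seq = 40)
  fit <- fit_simple(sim$kept)
  b <- fit$estimates[fit$estimates$term == "ln_len", ]
  expect_lt(b$ci_lower, -0.5)
  expect_gt(b$ci_upper, -0.5)
  expect_true(b$strong)
  # Wald arithmetic on every term
  expect_equal(fit$estimates$ci_upper - fit$estimates$ci_lower,
               2 * 1.96 * fit$estimates$se)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
})

test_that("degenerate inputs are handled explicitly", {
  # constant durations: no signal, slope 0 with CI containing 0
  kept <- sim_fit_data(73, n_ind = 4, n_seq = 10)$kept
  kept$duration_s <- 0.5
  expect_warning(fit <- fit_simple(kept), "identical")
  b <- fit$estimates[fit$estimates$term == "ln_len", ]
  expect_equal(unname(b$estimate), 0, tolerance = 1e-6)
  expect_true(b$ci_lower <= 0 && b$ci_upper >= 0)

  # a single individual: model drops the unidentifiable level, with warning
  noisy <- sim_fit_data(73, n_ind = 4, n_seq = 10)$kept
  one <- noisy[noisy$individual == noisy$individual[1], ]
  expect_warning(fit1 <- fit_simple(one), "single individual")
  expect_false("individual" %in% fit1$variance_components$grouping)

  # singletons must have been excluded upstream
  bad <- kept
  bad$length[1] <- 1L
  expect_error(fit_simple(bad), "singleton")
  expect_error(fit_simple(kept[0, ]), "no fittable sequences")
})

complex_frame <- function(seed = 81, effects = list(), n_ind = 12,
                          n_seq = 30, sd_slope = 0) {
  cfg <- sim_config(seed = seed, n_individuals = n_ind, n_groups = 4,
                    sequences_per_individual = n_seq, sd_slope = sd_slope,
                    covariate_effects = effects)
  d <- generate_dataset(cfg)
  kept <- apply_exclusions(segment_sequences(d$calls))$kept
  build_model_frame(kept, d$meta, ref_year = 2013)
}

test_that("complex model ladder is nested in likelihood and parameters", {
  frame <- complex_frame(81, effects = list(sex = 0.3, `ln_len:sex` = 0.25),
                         sd_slope = 0.1)
  f4 <- fit_complex(frame, "eq4")
  f5 <- fit_complex(frame, "eq5")
  f6 <- fit_complex(frame, "eq6")
  # nested in likelihood, up to optimizer convergence tolerance
  expect_gte(f5$loglik - f4$loglik, -1e-6)
  expect_gte(f6$loglik - f5$loglik, -1e-6)
  expect_true(f4$n_params < f5$n_params && f5$n_params < f6$n_params)
  # eq4 carries no interactions; eq5/eq6 do
  expect_false(any(grepl(":", f4$estimates$term)))
  expect_true("ln_len:sexM" %in% f5$estimates$term)
  expect_true("ln_len:sexM" %in% f6$estimates$term)

  cmp <- compare_models(f4, f5, f6)
  expect_equal(sum(cmp$aic$best), 1)
  expect_equal(min(cmp$aic$delta_aic), 0)
  expect_true(all(cmp$lrt$statistic >= 0))
  expect_equal(cmp$lrt$df, c(f5$n_params - f4$n_params,
                             f6$n_params - f5$n_params))
})

test_that("model comparison refuses invalid likelihood-ratio tests", {
  frame <- complex_frame(82, n_ind = 8, n_seq = 15)
  f4 <- fit_complex(frame, "eq4")
  f5 <- fit_complex(frame, "eq5")
  simple <- fit_simple(frame)
  expect_error(vocaleff:::lrt_pair(simple, f4), "not nested")
  f5_sub <- fit_complex(frame[frame$individual != frame$individual[1], ], "eq5")
  expect_error(vocaleff:::lrt_pair(f4, f5_sub), "different data")
  f4_reml <- fit_complex(frame, "eq4", method = "REML")
  expect_error(vocaleff:::lrt_pair(f4_reml, f5), "must use ML")

  # identical fits: zero AIC gap, a single arbitrary best flag
  cmp <- compare_models(list(f4, f4))
  expect_equal(cmp$aic$delta_aic, c(0, 0))
})

test_that("a zero-variance covariate is dropped with notice, never silently", {
  frame <- complex_frame(83, n_ind = 8, n_seq = 15)
  frame$sex <- "F"
  expect_message(fit <- fit_complex(frame, "eq4"), "zero-variance.*sex")
  expect_false(any(grepl("sex", fit$estimates$term)))
  expect_equal(fit$dropped_terms, "sex")
})

test_that("predicted curves obey the fixed-effect arithmetic", {
  frame <- complex_frame(84, effects = list(sex = 0.4, `ln_len:sex` = 0.3))
  fit <- fit_complex(frame, "eq5")
  est <- setNames(fit$estimates$estimate, fit$estimates$term)

  lens <- c(2, 4, 8)
  f_curve <- predict_curves(fit, list(sex = "F"), lengths = lens)
  m_curve <- predict_curves(fit, list(sex = "M"), lengths = lens)
  # female slope = b_length; male slope = b_length + b_length:sexM
  slope_f <- diff(f_curve$ln_duration) / diff(log(lens))
  slope_m <- diff(m_curve$ln_duration) / diff(log(lens))
  expect_equal(unname(slope_f), rep(est[["ln_len"]], 2), tolerance = 1e-8)
  expect_equal(unname(slope_m),
               rep(est[["ln_len"]] + est[["ln_len:sexM"]], 2),
               tolerance = 1e-8)
  # at the reference profile the curve is exp(intercept + b * ln x)
  # (continuous covariates sit at their sample mean, i.e. 0 after z-scoring)
  expect_equal(f_curve$duration,
               exp(est[["(Intercept)"]] + est[["ln_len"]] * log(lens)),
               tolerance = 1e-6)
  expect_true(all(diff(f_curve$duration) < 0))  # monotone when slope < 0

  expect_warning(predict_curves(fit, list(sex = "M", age = 120), lengths = lens),
                 "outside the observed range")
})

test_that("permuting durations across sequences destroys the length effect", {
  sim <- sim_fit_data(91, n_ind = 8, n_seq = 30)
  kept <- sim$kept
  set.seed(91)
  covers <- vapply(1:100, function(i) {
    shuffled <- kept |>
      dplyr::group_by(.data$individual) |>
      dplyr::mutate(duration_s = sample(.data$duration_s)) |>
      dplyr::ungroup()
    est <- fit_simple(shuffled)$estimates
    b <- est[est$term == "ln_len", ]
    b$ci_lower <= 0 && b$ci_upper >= 0
  }, logical(1))
  expect_gte(mean(covers), 0.90)
})
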