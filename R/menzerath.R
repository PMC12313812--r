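# Menzerath-Altmann law fitting: the law's parametric form is
#   y = a * x^b * exp(c * x)
# with y the duration of elements in a sequence of x elements. Setting
# c = 0 and taking natural logs gives the linear form
#   ln(y) = ln(a) + b * ln(x)
# which is what the hierarchical models below estimate, with every call's
# duration as a response row (the "full distribution" choice, avoiding
# regression-to-the-mean artifacts of fitting sequence means).

#' Least-squares fit of the parametric Menzerath-Altmann curve
#'
#' Estimates `(a, b, c)` of `y = a * x^b * exp(c * x)` by ordinary least
#' squares on the log scale, `ln(y) = ln(a) + b ln(x) + c x`, which is
#' linear in the parameters. With `fix_c = TRUE` the exponential term is
#' dropped and the fit is exactly the log-log regression used by the
#' linearised form of the law. Recovery is exact on noiseless data.
#'
#' @param x Sequence lengths (construct sizes), one per element; at
#'   least 3 distinct values (2 when `fix_c = TRUE`).
#' @param y Element durations, strictly positive, same length as `x`.
#' @param fix_c Fix the exponential rate `c` at 0.
#' @return An object of class `menzerath_params`: list with `a`, `b`,
#'   `c`, the underlying `lm` fit, and `curve`, a function evaluating
#'   the fitted duration at given lengths.
#' @export
#' @examples
#' x <- rep(2:10, each = 3)
#' y <- 1 * x^(-0.5)
#' fit_menzerath_nonlinear(x, y)
fit_menzerath_nonlinear <- function(x, y, fix_c = FALSE) {
  stopifnot(length(x) == length(y), all(y > 0), all(x >= 1))
  needed <- if (fix_c) 2L else 3L
  if (length(unique(x)) < needed) {
    stop_vocaleff("underdetermined: need at least ", needed,
                  " distinct sequence lengths",
                  class = "vocaleff_validation_error")
  }
  d <- data.frame(ln_y = log(y), ln_x = log(x), x = x)
  model <- if (fix_c) lm(ln_y ~ ln_x, data = d) else lm(ln_y ~ ln_x + x, data = d)
  cf <- coef(model)
  a <- unname(exp(cf[["(Intercept)"]]))
  b <- unname(cf[["ln_x"]])
  cc <- if (fix_c) 0 else unname(cf[["x"]])
  structure(
    list(a = a, b = b, c = cc, model = model,
         curve = function(x) a * x^b * exp(cc * x)),
    class = "menzerath_params"
  )
}

#' @exportS3Method base::print
print.menzerath_params <- function(x, ...) {
  cat(sprintf("Menzerath-Altmann curve: y = %.4g * x^%.4g * exp(%.4g x)\n",
              x$a, x$b, x$c))
  invisible(x)
}

# Wald interval half-width multiplier; intervals are estimate +/- 1.96 se
WALD_Z <- 1.96

new_menzerath_fit <- function(model, spec, method, scaling = NULL,
                              dropped = character(), messages = character()) {
  if (inherits(model, "merMod")) {
    sm <- summary(model)$coefficients
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- tibble::tibble(
      grouping = vc$grp,
      term = ifelse(is.na(vc$var1), "(Intercept)", vc$var1),
      variance = vc$vcov,
      sd = vc$sdcor
    )
    varcomp <- varcomp[is.na(vc$var2), , drop = FALSE]
    n_groups <- lme4::ngrps(model)
    conv <- length(model@optinfo$conv$lme4$messages) == 0
    singular <- lme4::isSingular(model)
  } else {
    sm <- summary(model)$coefficients[, 1:2, drop = FALSE]
    varcomp <- tibble::tibble(grouping = "Residual", term = "",
                              variance = summary(model)$sigma^2,
                              sd = summary(model)$sigma)
    n_groups <- integer()
    conv <- TRUE
    singular <- FALSE
  }
  est <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    se = unname(sm[, "Std. Error"]),
    ci_lower = estimate - WALD_Z * se,
    ci_upper = estimate + WALD_Z * se
  )
  est$strong <- est$ci_lower > 0 | est$ci_upper < 0
  ll <- logLik(model)
  n_params <- attr(ll, "df")
  structure(
    list(
      spec = spec,
      estimates = est,
      variance_components = varcomp,
      loglik = as.numeric(ll),
      n_params = n_params,
      aic = 2 * n_params - 2 * as.numeric(ll),
      n_obs = stats::nobs(model),
      n_groups = n_groups,
      method = method,
      converged = conv,
      singular = singular,
      scaling = scaling,
      dropped_terms = dropped,
      notes = messages,
      model = model
    ),
    class = "menzerath_fit"
  )
}

#' @exportS3Method base::print
print.menzerath_fit <- function(x, ...) {
  cat("Menzerath-Altmann model fit (", x$spec, ", ", x$method, ")\n", sep = "")
  cat("  observations:", x$n_obs, "\n")
  if (length(x$n_groups) > 0) {
    cat("  groups:", paste(names(x$n_groups), x$n_groups, sep = "=",
                           collapse = ", "), "\n")
  }
  cat(sprintf("  logLik %.1f   AIC %.1f   params %d\n",
              x$loglik, x$aic, x$n_params))
  if (!x$converged) cat("  WARNING: optimizer did not report clean convergence\n")
  est <- x$estimates
  est$` ` <- ifelse(est$strong, "*", "")
  est[c("estimate", "se", "ci_lower", "ci_upper")] <-
    lapply(est[c("estimate", "se", "ci_lower", "ci_upper")], round, 3)
  print(as.data.frame(est), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method stats::logLik
logLik.menzerath_fit <- function(object, ...) logLik(object$model)

lmer_control <- function(optimizer = "nloptwrap") {
  lme4::lmerControl(check.conv.singular = "ignore", optimizer = optimizer,
                    optCtrl = if (optimizer == "bobyqa") list(maxfun = 1e5) else list())
}

# mixed model evaluated with every random-effect variance pinned at 0:
# the GLS solve at the boundary, which must coincide with OLS
fit_theta_zero <- function(form, d, reml) {
  lf <- lme4::lFormula(form, data = d, REML = reml,
                       control = lmer_control())
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  theta0 <- rep(0, length(lf$reTrms$theta))
  opt <- list(par = theta0, fval = devfun(theta0), conv = 0L, feval = 1L)
  lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
}

#' Fit the simple hierarchical Menzerath model
#'
#' Gaussian linear mixed model of log call duration on log sequence
#' length with nested random intercepts for individual and for sequence
#' within individual:
#' `ln(duration) ~ ln(length) + (1 | individual/sequence_id)`.
#' Every call contributes one response row; singleton (length-1)
#' sequences must already have been excluded. This is the model used to
#' assess the presence of the law separately within each subspecies.
#'
#' With a single individual the individual-level variance is
#' unidentifiable; the fit proceeds on `(1 | sequence_id)` alone with a
#' warning. Fixed effects carry Wald 95% confidence intervals
#' (estimate +/- 1.96 se); an interval excluding zero is flagged as a
#' strong effect.
#'
#' @param data Call-level tibble with columns `duration_s`, `length`,
#'   `individual`, `sequence_id` (e.g. the `kept` table of
#'   [apply_exclusions()]).
#' @param method `"ML"` (default; required for AIC/LRT comparison) or
#'   `"REML"`.
#' @param zero_variance Evaluate the model with all random-effect
#'   variances pinned at 0 instead of optimizing them; in this limit
#'   the fixed effects coincide with ordinary least squares of
#'   `ln(duration)` on `ln(length)`. Mainly a diagnostic.
#' @return An object of class `menzerath_fit`; see
#'   [fit_complex()] for the shared structure.
#' @export
fit_simple <- function(data, method = c("ML", "REML"), zero_variance = FALSE) {
  method <- match.arg(method)
  assert_columns(data, c("duration_s", "length", "individual", "sequence_id"),
                 "call-level data")
  check_fittable(data)
  d <- data.frame(
    ln_dur = log(data$duration_s),
    ln_len = log(data$length),
    individual = factor(data$individual),
    sequence_id = factor(data$sequence_id)
  )
  if (var(d$ln_dur) == 0) {
    # constant response: the Gaussian likelihood degenerates as the
    # residual variance goes to 0; the limiting fit is the exact
    # interpolation with zero slope
    warning("all call durations identical: degenerate fit with zero variance")
    model <- lm(ln_dur ~ ln_len, data = d)
    return(new_menzerath_fit(model, spec = "simple", method = method))
  }
  if (nlevels(d$individual) < 2) {
    warning("single individual: individual-level variance unidentifiable; ",
            "fitting (1 | sequence_id) only")
    form <- ln_dur ~ ln_len + (1 | sequence_id)
  } else {
    form <- ln_dur ~ ln_len + (1 | individual / sequence_id)
  }
  model <- if (zero_variance) {
    fit_theta_zero(form, d, reml = method == "REML")
  } else {
    lme4::lmer(form, data = d, REML = method == "REML",
               control = lmer_control())
  }
  new_menzerath_fit(model, spec = "simple", method = method)
}

check_fittable <- function(data) {
  if (nrow(data) == 0) {
    stop_vocaleff("no fittable sequences (empty call-level data)",
                  class = "vocaleff_fit_error")
  }
  if (any(data$length < 2)) {
    stop_vocaleff("singleton sequences present; exclude length-1 sequences ",
                  "before fitting", class = "vocaleff_validation_error")
  }
  if (any(data$duration_s <= 0)) {
    stop_vocaleff("non-positive call durations", class = "vocaleff_validation_error")
  }
  invisible(data)
}

complex_covariates <- c("sex", "group_size", "age", "elo", "csi")
continuous_covariates <- c("group_size", "age", "elo", "csi")

#' Fit the complex hierarchical Menzerath models with covariates
#'
#' Three nested specifications of demographic and social modulation of
#' the law, fit to call-level data from one subspecies:
#'
#' * `"eq4"` — main effects only:
#'   `ln(dur) ~ ln(len) + sex + group_size + age + elo + csi +
#'   (1 | population/group/individual/sequence_id)`
#' * `"eq5"` — adds interactions of every covariate with `ln(len)`, so
#'   covariates can change the strength of the law, not just call
#'   duration.
#' * `"eq6"` — adds a nested random slope on `ln(len)` per
#'   population:group:individual (no intercept at that level), allowing
#'   individual variation in the law beyond the covariates.
#'
#' Continuous covariates (`group_size`, `age`, `elo`, `csi`) are
#' z-scored before fitting (recorded in `$scaling` for
#' back-transformation); sex is coded with female as the reference
#' level. A covariate with zero variance in the data cannot be estimated
#' and is dropped with an explicit message. Estimation is maximum
#' likelihood by default so that AIC and likelihood-ratio comparisons
#' across the three forms are valid.
#'
#' @param data Call-level tibble with `duration_s`, `length`,
#'   `individual`, `sequence_id`, `population`, `group` and the
#'   covariates `sex`, `group_size`, `age`, `elo`, `csi` (see
#'   [build_model_frame()]).
#' @param spec One of `"eq4"`, `"eq5"`, `"eq6"`.
#' @param method `"ML"` (default) or `"REML"`.
#' @param standardize Z-score the continuous covariates (default TRUE).
#' @return An object of class `menzerath_fit`: fixed-effect `estimates`
#'   with Wald CIs and strong-effect flags, `variance_components`,
#'   `loglik`, `aic`, `n_obs`, `n_groups`, `method`, convergence state,
#'   covariate `scaling`, and the underlying `lmerMod` in `$model`.
#' @export
fit_complex <- function(data, spec = c("eq6", "eq5", "eq4"),
                        method = c("ML", "REML"), standardize = TRUE) {
  spec <- match.arg(spec)
  method <- match.arg(method)
  assert_columns(data, c("duration_s", "length", "individual", "sequence_id",
                         "population", "group", complex_covariates),
                 "call-level data")
  check_fittable(data)
  d <- data.frame(
    ln_dur = log(data$duration_s),
    ln_len = log(data$length),
    individual = factor(data$individual),
    sequence_id = factor(data$sequence_id),
    population = factor(data$population),
    group = factor(data$group),
    sex = factor(data$sex, levels = c("F", "M")),
    group_size = as.numeric(data$group_size),
    age = as.numeric(data$age),
    elo = as.numeric(data$elo),
    csi = as.numeric(data$csi)
  )
  scaling <- NULL
  if (standardize) {
    scaling <- tibble::tibble(term = character(), center = double(),
                              scale = double())
    for (v in continuous_covariates) {
      center <- mean(d[[v]])
      scale_ <- sd(d[[v]])
      if (is.na(scale_) || scale_ == 0) scale_ <- 1  # left for the var check below
      d[[v]] <- (d[[v]] - center) / scale_
      scaling <- dplyr::bind_rows(scaling,
                                  tibble::tibble(term = v, center = center,
                                                 scale = scale_))
    }
  }
  covs <- complex_covariates
  dropped <- character()
  for (v in covs) {
    value <- if (v == "sex") as.integer(d$sex) else d[[v]]
    if (var(value) == 0 || anyNA(value)) {
      dropped <- c(dropped, v)
    }
  }
  if (length(dropped) > 0) {
    message("dropping zero-variance covariate(s): ",
            paste(dropped, collapse = ", "))
    covs <- setdiff(covs, dropped)
  }
  if (length(covs) == 0) {
    fixed <- "ln_dur ~ ln_len"
  } else {
    cov_sum <- paste(covs, collapse = " + ")
    fixed <- switch(spec,
      eq4 = paste0("ln_dur ~ ln_len + ", cov_sum),
      eq5 = ,
      eq6 = paste0("ln_dur ~ ln_len * (", cov_sum, ")")
    )
  }
  ranef <- "(1 | population/group/individual/sequence_id)"
  if (spec == "eq6") {
    ranef <- paste0(ranef, " + (0 + ln_len | population:group:individual)")
  }
  form <- stats::as.formula(paste(fixed, "+", ranef))
  # the random-slope surface can trap a single optimizer in a local
  # optimum; fit with two and keep the better likelihood so the model
  # ladder stays nested in practice, not just in theory
  model <- lme4::lmer(form, data = d, REML = method == "REML",
                      control = lmer_control())
  alt <- tryCatch(
    lme4::lmer(form, data = d, REML = method == "REML",
               control = lmer_control("bobyqa")),
    error = function(e) NULL
  )
  if (!is.null(alt) && as.numeric(logLik(alt)) > as.numeric(logLik(model))) {
    model <- alt
  }
  new_menzerath_fit(model, spec = spec, method = method, scaling = scaling,
                    dropped = dropped)
}

#' Compare fitted Menzerath models by AIC and likelihood ratio
#'
#' Tabulates AIC and delta-AIC over a set of fits on the same data rows
#' and, for pairs nested in the likelihood-ratio sense (eq4 within eq5
#' within eq6), the likelihood-ratio statistic `2 * delta logLik` with a
#' chi-square reference on the difference in parameter count. The best
#' model is the one with the lowest AIC, flagged as decisive when its
#' lead exceeds 2 AIC units. LRTs require maximum-likelihood fits;
#' requesting one for a non-nested pair, different data sizes, or REML
#' fits is refused with an explanation.
#'
#' @param ... `menzerath_fit` objects (or one list of them), typically
#'   named.
#' @return An object of class `menzerath_comparison`: list with `aic`
#'   (tibble: spec, n_params, loglik, aic, delta_aic, best) and `lrt`
#'   (tibble of nested-pair tests, possibly empty).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "menzerath_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, TRUE, "menzerath_fit")))
  specs <- vapply(fits, `[[`, "", "spec")
  names(fits) <- specs
  aic_tab <- tibble::tibble(
    spec = unname(specs),
    n_params = unname(vapply(fits, `[[`, 0, "n_params")),
    loglik = unname(vapply(fits, `[[`, 0, "loglik")),
    aic = unname(vapply(fits, `[[`, 0, "aic"))
  )
  aic_tab$delta_aic <- aic_tab$aic - min(aic_tab$aic)
  aic_tab$best <- aic_tab$delta_aic == 0
  decisive <- sum(aic_tab$delta_aic > 2) == (nrow(aic_tab) - 1) &&
    sum(aic_tab$best) == 1
  ladder <- c("eq4", "eq5", "eq6")
  present <- ladder[ladder %in% specs]
  lrt <- tibble::tibble(null = character(), alternative = character(),
                        statistic = double(), df = double(), p_value = double())
  if (length(present) >= 2) {
    for (i in seq_len(length(present) - 1)) {
      lrt <- dplyr::bind_rows(
        lrt, lrt_pair(fits[[present[i]]], fits[[present[i + 1]]])
      )
    }
  }
  structure(list(aic = aic_tab, lrt = lrt, decisive = decisive),
            class = "menzerath_comparison")
}

lrt_pair <- function(null_fit, alt_fit) {
  ladder <- c(simple = 0, eq4 = 1, eq5 = 2, eq6 = 3)
  rank_null <- ladder[null_fit$spec]
  rank_alt <- ladder[alt_fit$spec]
  if (is.na(rank_null) || is.na(rank_alt) ||
      !(null_fit$spec %in% c("eq4", "eq5") && rank_alt > rank_null)) {
    stop_vocaleff("likelihood-ratio test refused: '", null_fit$spec,
                  "' is not nested within '", alt_fit$spec,
                  "' (only eq4 within eq5 within eq6 are nested)",
                  class = "vocaleff_validation_error")
  }
  if (null_fit$n_obs != alt_fit$n_obs) {
    stop_vocaleff("likelihood-ratio test refused: fits use different data (",
                  null_fit$n_obs, " vs ", alt_fit$n_obs, " rows)",
                  class = "vocaleff_validation_error")
  }
  if (null_fit$method != "ML" || alt_fit$method != "ML") {
    stop_vocaleff("likelihood-ratio test refused: both fits must use ML ",
                  "(REML likelihoods are not comparable across fixed effects)",
                  class = "vocaleff_validation_error")
  }
  stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  df <- alt_fit$n_params - null_fit$n_params
  tibble::tibble(
    null = null_fit$spec, alternative = alt_fit$spec,
    statistic = stat, df = df,
    p_value = pchisq(stat, df = df, lower.tail = FALSE)
  )
}

#' @exportS3Method base::print
print.menzerath_comparison <- function(x, ...) {
  cat("Model comparison (lowest AIC is best",
      if (x$decisive) "; lead > 2 AIC units" else "", ")\n", sep = "")
  tab <- x$aic
  tab[c("loglik", "aic", "delta_aic")] <-
    lapply(tab[c("loglik", "aic", "delta_aic")], round, 1)
  print(as.data.frame(tab), row.names = FALSE)
  if (nrow(x$lrt) > 0) {
    cat("Likelihood-ratio tests:\n")
    print(as.data.frame(x$lrt), row.names = FALSE)
  }
  invisible(x)
}

#' Predicted duration-versus-length curves at a covariate profile
#'
#' Evaluates the fixed-effect (population-level) prediction of a fitted
#' model over the observed range of sequence lengths, at a chosen
#' covariate profile; unspecified covariates sit at their reference
#' level (sex: female) or sample mean. Profile values are given on the
#' original covariate scale and are standardized internally using the
#' scaling stored in the fit. Predictions are returned on the duration
#' scale, `exp(predicted ln duration)`; the curve is monotone decreasing
#' whenever the effective slope at the profile is negative. A profile
#' outside the observed covariate range still returns a curve, with an
#' extrapolation warning.
#'
#' @param fit A `menzerath_fit` from [fit_complex()] (or [fit_simple()],
#'   in which case `profile` must be empty).
#' @param profile Named list of covariate values, e.g.
#'   `list(sex = "M", age = 10)`.
#' @param lengths Sequence lengths at which to predict; default the
#'   observed range.
#' @return Tibble with `length`, `ln_duration` and `duration`.
#' @export
predict_curves <- function(fit, profile = list(), lengths = NULL) {
  stopifnot(inherits(fit, "menzerath_fit"))
  frame <- fit$model@frame
  if (is.null(lengths)) {
    obs_len <- sort(unique(exp(frame$ln_len)))
    lengths <- seq(min(obs_len), max(obs_len))
  }
  newdata <- data.frame(ln_len = log(lengths))
  for (v in setdiff(names(frame), c("ln_dur", "ln_len", "individual",
                                    "sequence_id", "population", "group"))) {
    if (is.factor(frame[[v]])) {
      level <- profile[[v]] %||% levels(frame[[v]])[1]
      if (!level %in% levels(frame[[v]])) {
        stop_vocaleff("profile level '", level, "' not observed for ", v,
                      class = "vocaleff_validation_error")
      }
      newdata[[v]] <- factor(level, levels = levels(frame[[v]]))
    } else {
      value <- profile[[v]]
      if (is.null(value)) {
        newdata[[v]] <- mean(frame[[v]])  # standardized scale: ~0
      } else {
        sc <- fit$scaling[fit$scaling$term == v, ]
        z <- if (nrow(sc) == 1) (value - sc$center) / sc$scale else value
        if (z < min(frame[[v]]) || z > max(frame[[v]])) {
          warning("profile value for ", v,
                  " lies outside the observed range; extrapolating")
        }
        newdata[[v]] <- z
      }
    }
  }
  pred <- if (inherits(fit$model, "merMod")) {
    stats::predict(fit$model, newdata = newdata, re.form = NA)
  } else {
    stats::predict(fit$model, newdata = newdata)
  }
  tibble::tibble(length = lengths, ln_duration = unname(pred),
                 duration = exp(unname(pred)))
}

#' Assemble the call-level model frame for complex fits
#'
#' Joins filtered sequences with per-individual metadata and derived
#' covariates into the one-row-per-call table [fit_complex()] consumes.
#' Age is the recording year minus hatch year; individuals of unknown
#' hatch year receive the mean age of the known ones. Group size is the
#' number of individuals in the call's group: from overlapping
#' membership intervals when `memberships` and a `session_date` column
#' are available, otherwise the count of metadata individuals assigned
#' to that group.
#'
#' @param sequences Filtered sequence table (post [apply_exclusions()])
#'   with `population` and `group` columns filled.
#' @param meta Metadata with `sex`, `hatch_year` and numeric `elo` and
#'   `csi` columns (e.g. effort-corrected indices joined on).
#' @param memberships Optional membership intervals for date-resolved
#'   group sizes.
#' @param ref_year Recording year used for age when the sequence table
#'   has no `session_date`; default the median membership year or, failing
#'   that, the current year.
#' @return Call-level tibble ready for [fit_complex()].
#' @export
build_model_frame <- function(sequences, meta, memberships = NULL,
                              ref_year = NULL) {
  assert_columns(sequences, c("individual", "population", "group",
                              "sequence_id", "length", "duration_s"),
                 "sequence table")
  validate_metadata(meta)
  assert_columns(meta, c("elo", "csi"), "metadata (with indices)")
  unmatched <- setdiff(unique(sequences$individual), meta$individual)
  if (length(unmatched) > 0) {
    stop_vocaleff("individual(s) missing from metadata: ",
                  paste(unmatched, collapse = ", "),
                  class = "vocaleff_validation_error")
  }
  d <- dplyr::left_join(
    sequences,
    meta[, c("individual", "sex", "hatch_year", "elo", "csi")],
    by = "individual"
  )
  if (is.null(ref_year)) {
    ref_year <- if (!is.null(memberships)) {
      as.integer(format(median(memberships$date_end), "%Y"))
    } else {
      as.integer(format(Sys.Date(), "%Y"))
    }
  }
  year <- if ("session_date" %in% names(d)) {
    ifelse(is.na(d$session_date), ref_year,
           as.integer(format(as.Date(d$session_date), "%Y")))
  } else {
    rep(ref_year, nrow(d))
  }
  d$age <- year - d$hatch_year
  known <- !is.na(d$age)
  if (!all(known)) {
    d$age[!known] <- mean(unique(d[known, c("individual", "age")])$age)
  }
  if (!is.null(memberships) && "session_date" %in% names(d)) {
    d$group_size <- mapply(function(grp, date) {
      m <- memberships[memberships$group == grp, ]
      sum(m$date_start <= date & m$date_end >= date)
    }, d$group, as.Date(d$session_date))
  } else {
    sizes <- if ("group" %in% names(meta)) {
      table(meta$group)
    } else if (!is.null(memberships)) {
      tapply(memberships$individual, memberships$group,
             function(x) length(unique(x)))
    } else {
      stop_vocaleff("cannot derive group_size: supply meta$group or memberships",
                    class = "vocaleff_validation_error")
    }
    d$group_size <- as.numeric(sizes[d$group])
  }
  d$hatch_year <- NULL
  d
}
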