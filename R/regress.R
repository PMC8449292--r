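# Regression battery: covariate-adjusted OLS per domain, per-diagnosis
# logistic models of the dichotomized length of stay, and a secondary Cox
# model of time to discharge (one fit per domain, not mutually adjusted).
#
# Conventions shared by all models:
#   * domain scores enter regressions in percentage points (score * 100);
#   * sex is coded female = 1, male = 0 (female is the majority class);
#   * logistic/Cox CIs are Wald intervals on the link scale, exponentiated.

.sex_female <- function(sex) as.integer(sex == "female")

.wald_ci <- function(est, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  list(low = est - z * se, high = est + z * se)
}

#' Covariate-adjusted linear regression of domain scores
#'
#' Fits one ordinary least-squares model per domain:
#' `score * scale ~ age + sex + cci`, reporting the slope, Wald 95% CI and p
#' value of every term. A model whose design is rank-deficient (constant or
#' collinear covariate) is flagged `degenerate` and its terms reported as
#' `NA`; the remaining domains still fit.
#'
#' @param cohort Cohort tibble with joined score columns (admission unit).
#' @param domains Score columns; autodetected if `NULL`.
#' @param scale Multiplier applied to scores before fitting (default 100,
#'   i.e. percentage points).
#' @return A tibble with columns `model` (domain), `outcome`, `term`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `n_used`, `degenerate`.
#' @export
covariate_regression <- function(cohort, domains = NULL, scale = 100) {
  cohort <- as_tibble(cohort)
  domains <- score_columns(cohort, domains)
  if (nrow(cohort) < 10L) {
    stop_validation("covariate_regression needs >= 10 records")
  }
  dat <- tibble(
    age = cohort$age,
    sex_female = .sex_female(cohort$sex),
    cci = cohort$cci
  )
  purrr::map_dfr(domains, function(d) {
    dat$y <- cohort[[d]] * scale
    fit <- lm(y ~ age + sex_female + cci, data = dat)
    cf <- summary(fit)$coefficients
    degenerate <- any(is.na(coef(fit)))
    terms_all <- names(coef(fit))
    purrr::map_dfr(terms_all, function(tm) {
      if (degenerate || !tm %in% rownames(cf)) {
        return(tibble(model = d, outcome = paste0(d, "_x", scale), term = tm,
                      estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      n_used = nrow(dat), degenerate = TRUE))
      }
      ci <- .wald_ci(cf[tm, "Estimate"], cf[tm, "Std. Error"])
      tibble(
        model = d, outcome = paste0(d, "_x", scale), term = tm,
        estimate = cf[tm, "Estimate"], ci_low = ci$low, ci_high = ci$high,
        p_value = cf[tm, "Pr(>|t|)"], n_used = nrow(dat),
        degenerate = FALSE
      )
    })
  })
}

#' Fit the per-diagnosis logistic model of length of stay
#'
#' For one diagnosis group at admission level, fits
#' `long_stay ~ <domains, in percentage points> + age + cci + sex(female=1)`
#' by maximum likelihood, where `long_stay = 1` iff the stay strictly
#' exceeds `threshold` days ([los_binary()]). Convergence uses a relative
#' log-likelihood tolerance of 1e-8 with at most 100 iterations. Complete or
#' quasi-complete separation and non-convergence are detected and flagged in
#' [glance()]; a group with fewer than 20 admissions triggers a warning
#' (such groups exist in practice).
#'
#' @param cohort Cohort tibble with joined score columns (admission unit).
#' @param group One diagnosis label; `NULL` uses the cohort as given.
#' @param domains Score columns; autodetected if `NULL`.
#' @param threshold Dichotomization threshold in days (default 3).
#' @param scale Score multiplier before fitting (default 100).
#' @return An object of class `rdoc_los_fit`. [tidy()] gives per-term
#'   log-odds, odds ratios with Wald 95% CIs and p values; [glance()] gives
#'   n, number of long stays, convergence and separation flags; [autoplot()]
#'   draws a forest plot of the odds ratios.
#' @export
fit_los_model <- function(cohort, group = NULL, domains = NULL,
                          threshold = 3, scale = 100) {
  cohort <- as_tibble(cohort)
  if (!is.null(group)) {
    if (!group %in% cohort$diagnosis) {
      stop_validation(paste0("no admissions with diagnosis ", group))
    }
    cohort <- cohort[cohort$diagnosis == group, , drop = FALSE]
  }
  domains <- score_columns(cohort, domains)
  n <- nrow(cohort)
  if (n < 20L) {
    warn(sprintf("logistic LOS model for %s fit on only %d admissions",
                 group %||% "cohort", n))
  }
  dat <- as.data.frame(cohort[, domains, drop = FALSE] * scale)
  names(dat) <- domains
  dat$age <- cohort$age
  dat$cci <- cohort$cci
  dat$sex_female <- .sex_female(cohort$sex)
  dat$long_stay <- los_binary(cohort$los_days, threshold)

  form <- stats::as.formula(paste(
    "long_stay ~", paste(c(domains, "age", "cci", "sex_female"), collapse = " + ")
  ))
  fit <- suppressWarnings(
    glm(form, family = binomial(), data = dat,
        control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  # fitted probabilities indistinguishable from 0/1 mean the likelihood is
  # still climbing along a separating direction
  mu <- fit$fitted.values
  separation <- any(mu > 1 - 1e-8 | mu < 1e-8)
  structure(
    list(fit = fit, group = group %||% "all", domains = domains,
         threshold = threshold, scale = scale, n = n,
         n_long = sum(dat$long_stay),
         converged = fit$converged, separation = separation),
    class = "rdoc_los_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname fit_los_model
#' @param x,object An `rdoc_los_fit`.
#' @param ... Unused.
#' @export
tidy.rdoc_los_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  ci <- .wald_ci(est, se)
  tibble(
    model = x$group, outcome = sprintf("los_gt_%g_days", x$threshold),
    term = rownames(cf),
    estimate = unname(est),
    or = unname(exp(est)),
    ci_low = unname(exp(ci$low)),
    ci_high = unname(exp(ci$high)),
    p_value = unname(cf[, "Pr(>|z|)"]),
    n_used = x$n
  )
}

#' @rdname fit_los_model
#' @export
glance.rdoc_los_fit <- function(x, ...) {
  tibble(
    model = x$group, n = x$n, n_long = x$n_long,
    converged = x$converged, separation = x$separation,
    deviance = x$fit$deviance, aic = x$fit$aic
  )
}

#' @rdname fit_los_model
#' @export
autoplot.rdoc_los_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("odds ratio for stay > %g days (95%% CI)", object$threshold),
      y = NULL,
      title = sprintf("Length-of-stay model: %s (n = %d)", object$group, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.rdoc_los_fit <- function(x, ...) {
  cat(sprintf("<rdoc_los_fit> %s: stay > %g days ~ %d domains + age + cci + sex, n = %d\n",
              x$group, x$threshold, length(x$domains), x$n))
  if (!x$converged) cat("  WARNING: did not converge\n")
  if (x$separation) cat("  WARNING: separation suspected\n")
  print(tidy(x))
  invisible(x)
}

#' Per-diagnosis logistic regression of length of stay
#'
#' Convenience wrapper: [fit_los_model()] then [tidy()]. Fits one model per
#' requested diagnosis group and binds the per-term odds-ratio tables.
#'
#' @inheritParams fit_los_model
#' @param groups Diagnosis groups to fit (default: all present).
#' @return A tibble of per-term effects with columns `model`, `outcome`,
#'   `term`, `estimate` (log-odds), `or`, `ci_low`, `ci_high`, `p_value`,
#'   `n_used`, plus `converged` and `separation` flags per model.
#' @export
los_logistic <- function(cohort, groups = NULL, domains = NULL,
                         threshold = 3, scale = 100) {
  groups <- groups %||% intersect(diagnosis_levels, unique(cohort$diagnosis))
  purrr::map_dfr(groups, function(g) {
    fit <- fit_los_model(cohort, group = g, domains = domains,
                         threshold = threshold, scale = scale)
    out <- tidy(fit)
    out$converged <- fit$converged
    out$separation <- fit$separation
    out
  })
}

#' Secondary Cox model: per-domain hazard of discharge
#'
#' For each domain separately (not controlling the other four), fits a Cox
#' proportional-hazards model of time to discharge:
#' `Surv(los_days) ~ score*scale + age + sex(female=1) + cci + diagnosis`,
#' with depression as the diagnosis reference and Efron handling of ties.
#' Every admission ends in discharge, so all events are observed (no
#' censoring). A hazard ratio below 1 for a domain means slower discharge —
#' i.e. the domain is associated with a longer stay. A zero-variance domain
#' score is flagged and returns `NA` estimates.
#'
#' @inheritParams covariate_regression
#' @return A tibble, one row per domain, with the domain term's `estimate`
#'   (log hazard), `hr`, `ci_low`, `ci_high`, `p_value`, `n_used`,
#'   `degenerate`.
#' @export
cox_secondary <- function(cohort, domains = NULL, scale = 100) {
  cohort <- as_tibble(cohort)
  domains <- score_columns(cohort, domains)
  groups_present <- intersect(diagnosis_levels, unique(cohort$diagnosis))
  dat <- data.frame(
    los_days = cohort$los_days,
    age = cohort$age,
    sex_female = .sex_female(cohort$sex),
    cci = cohort$cci,
    diagnosis = factor(cohort$diagnosis, levels = groups_present)
  )
  adjust <- c("age", "sex_female", "cci",
              if (length(groups_present) > 1L) "diagnosis")
  purrr::map_dfr(domains, function(d) {
    x <- cohort[[d]] * scale
    if (stats::sd(x) == 0) {
      return(tibble(domain = d, term = "score", estimate = NA_real_,
                    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_, n_used = nrow(dat),
                    degenerate = TRUE))
    }
    dat$score <- x
    form <- stats::as.formula(paste(
      "survival::Surv(los_days, rep(1, length(los_days))) ~ score +",
      paste(adjust, collapse = " + ")
    ))
    fit <- survival::coxph(form, data = dat, ties = "efron",
                           control = survival::coxph.control(eps = 1e-8,
                                                             iter.max = 100))
    cf <- summary(fit)$coefficients
    est <- cf["score", "coef"]
    se <- cf["score", "se(coef)"]
    ci <- .wald_ci(est, se)
    tibble(
      domain = d, term = "score", estimate = unname(est),
      hr = unname(exp(est)), ci_low = unname(exp(ci$low)),
      ci_high = unname(exp(ci$high)),
      p_value = unname(cf["score", "Pr(>|z|)"]),
      n_used = nrow(dat), degenerate = FALSE
    )
  })
}
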