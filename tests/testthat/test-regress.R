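test_that("covariate OLS matches the closed-form normal equations", {
  # 3 covariate patterns, hand-checkable design
  co <- make_cohort(12, seed = 41)
  co$age <- rep(c(20, 40, 60), 4)
  co$sex <- rep(c("female", "male"), 6)
  co$cci <- rep(c(0, 1), each = 6)
  set.seed(42)
  co$dom <- (2 + 0.03 * co$age + 0.5 * (co$sex == "female") + rnorm(12)) / 100
  eff <- covariate_regression(co, domains = "dom")
  X <- cbind(1, co$age, as.integer(co$sex == "female"), co$cci)
  beta <- oracle_ols(X, co$dom * 100)
  expect_equal(eff$estimate, beta, tolerance = 1e-10)
})

test_that("noiseless linear data is recovered to machine precision", {
  co <- make_cohort(30, seed = 43)
  co$age <- seq(20, 78, by = 2)
  co$dom <- (1 + 0.5 * co$age + 0.2 * (co$sex == "female") + 0.1 * co$cci) / 100
  eff <- suppressWarnings(covariate_regression(co, domains = "dom"))
  expect_equal(eff$estimate[eff$term == "age"], 0.5, tolerance = 1e-10)
  ci_width <- eff$ci_high[eff$term == "age"] - eff$ci_low[eff$term == "age"]
  expect_lt(ci_width, 1e-8)
})

test_that("a constant covariate flags only the affected model", {
  co <- make_cohort(25, seed = 44)
  co$cci <- 1 # constant -> rank-deficient
  co$dom <- runif(25, 0, 0.3)
  eff <- covariate_regression(co, domains = "dom")
  expect_true(all(eff$degenerate))
  # other inputs still fit: small-n guard
  expect_error(covariate_regression(co[1:5, ], domains = "dom"),
               class = "rdocscore_validation_error")
})

test_that("one-binary-predictor logistic OR equals the 2x2 cross-product ratio", {
  # exposed: 30 long / 20 short; unexposed: 10 long / 40 short -> OR 6
  co <- make_cohort(100, seed = 45)
  exposed <- rep(c(1, 0), each = 50)
  long <- c(rep(c(1, 0), c(30, 20)), rep(c(1, 0), c(10, 40)))
  co$los_days <- ifelse(long == 1, 10, 2)
  co$dom <- exposed / 100 # so dom * 100 is the 0/1 exposure
  co$age <- 50; co$cci <- 0; co$sex <- "female" # constants drop out of the MLE
  fit <- fit_los_model(cohort = co, domains = "dom")
  td <- tidy(fit)
  expect_equal(td$or[td$term == "dom"],
               oracle_or_2x2(long, exposed), tolerance = 1e-6)
  expect_equal(oracle_or_2x2(long, exposed), 6)
})

test_that("logistic LOS fit reports Wald CIs, glance diagnostics, forest plot", {
  set.seed(46)
  co <- make_cohort(200, seed = 46)
  co$dom <- rbinom(200, 10, 0.15) / 10
  co$los_days <- ifelse(runif(200) < plogis(0.4 * co$dom * 10 - 0.5), 8, 2)
  fit <- fit_los_model(co, group = "depression", domains = "dom")
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "dom", "age", "cci", "sex_female"))
  expect_equal(td$or, exp(td$estimate))
  expect_true(all(td$ci_low < td$or & td$or < td$ci_high))
  g <- glance(fit)
  expect_true(g$converged)
  expect_identical(g$n, 200L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("small groups and separation are flagged, never silent", {
  co <- make_cohort(10, seed = 47)
  co$dom <- runif(10)
  expect_warning(fit_los_model(co, domains = "dom"), "only 10")

  co2 <- make_cohort(40, seed = 48)
  co2$dom <- rep(c(0, 0.5), each = 20)
  co2$los_days <- rep(c(1, 10), each = 20) # perfectly separated
  co2$age <- 30; co2$cci <- 0; co2$sex <- "male"
  fit <- suppressWarnings(fit_los_model(co2, domains = "dom"))
  expect_true(glance(fit)$separation)
})

test_that("Cox beta-hat equals the grid-searched Efron partial likelihood argmax", {
  # 4 subjects, one binary covariate, one tie
  time <- c(2, 2, 5, 7)
  x <- c(1, 0, 1, 0)
  co <- make_cohort(4, seed = 49)
  co$los_days <- time
  co$dom <- x / 100
  co$age <- 40; co$cci <- 0; co$sex <- "female" # constants: flagged NA by coxph
  got <- suppressWarnings(cox_secondary(co, domains = "dom"))
  beta_oracle <- oracle_cox_efron_beta(time, x)
  expect_equal(got$estimate, beta_oracle, tolerance = 2e-3)
})

test_that("Cox recovers a known exponential rate ratio of 2", {
  set.seed(50)
  n <- 1000
  co <- make_cohort(n)
  x <- rbinom(n, 1, 0.5)
  co$los_days <- rexp(n, rate = exp(log(2) * x))
  co$dom <- x / 100
  fit <- cox_secondary(co, domains = "dom")
  se <- (log(fit$ci_high) - log(fit$ci_low)) / (2 * qnorm(0.975))
  expect_lt(abs(fit$estimate - log(2)), 3 * se)
})

test_that("a zero-variance domain is flagged degenerate in the Cox battery", {
  co <- make_cohort(30, seed = 51)
  co$flat <- 0.1
  co$vary <- runif(30, 0, 0.3)
  got <- cox_secondary(co, domains = c("flat", "vary"))
  expect_true(got$degenerate[got$domain == "flat"])
  expect_false(got$degenerate[got$domain == "vary"])
  expect_true(is.na(got$hr[got$domain == "flat"]))
})

test_that("los_logistic binds per-group tidy tables", {
  set.seed(52)
  co <- make_cohort(120, diagnosis = rep(c("depression", "schizophrenia"), 60))
  co$dom <- rbinom(120, 20, 0.15) / 20
  out <- los_logistic(co, domains = "dom")
  expect_setequal(unique(out$model), c("depression", "schizophrenia"))
  expect_true(all(c("or", "ci_low", "ci_high", "converged") %in% names(out)))
})
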