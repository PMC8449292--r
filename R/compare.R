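# Group comparisons: baseline table (ANOVA for continuous variables,
# chi-square homogeneity for categorical), per-domain ANOVA with pairwise
# post hoc t tests.

fmt_mean_sd <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
          mean(x), stats::sd(x))
}

fmt_n_pct <- function(x) {
  sprintf("%d (%.1f)", sum(x == 1), 100 * mean(x == 1))
}

# one-way equal-variance ANOVA across groups; returns F, df, p and a
# degeneracy flag (all residual variance zero -> statistic undefined)
.anova_oneway <- function(value, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L || stats::sd(value) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE))
  }
  fit <- lm(value ~ group)
  an <- anova(fit)
  f <- an[["F value"]][1L]
  p <- an[["Pr(>F)"]][1L]
  if (!is.finite(f)) {
    return(list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE))
  }
  list(statistic = unname(f), p_value = unname(p), degenerate = FALSE)
}

# chi-square homogeneity test of a binary variable across groups,
# without continuity correction; identical groups -> statistic 0, p 1
.chisq_homogeneity <- function(flag, group) {
  tab <- table(factor(group), factor(flag, levels = c(0, 1)))
  if (all(tab[, "1"] == 0) || all(tab[, "0"] == 0)) {
    return(list(statistic = 0, p_value = 1, degenerate = FALSE))
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       degenerate = FALSE)
}

#' Baseline characteristics table across diagnosis groups
#'
#' One row per baseline variable (age, length of stay, Charlson Comorbidity
#' Index, sex, and five medical-history flags), with per-group summaries
#' (mean (SD) for continuous variables, n (%) for binary) and an omnibus
#' test across groups: one-way ANOVA for continuous variables and the
#' Pearson chi-square test of homogeneity for categorical ones (the package
#' also exports a literal [cochran_q()] for matched repeated-measures binary
#' layouts). Baseline tables are conventionally computed at the patient
#' level — pass the output of [to_patient_baseline()].
#'
#' @param cohort Cohort tibble, typically at patient-baseline unit.
#' @return A tibble with columns `variable`, `type`, one formatted summary
#'   column per diagnosis group, `test`, `statistic`, `p_value`,
#'   `degenerate`.
#' @export
baseline_table <- function(cohort) {
  cohort <- as_tibble(cohort)
  groups <- intersect(diagnosis_levels, unique(cohort$diagnosis))
  if (length(groups) < 2L) {
    stop_validation("baseline_table needs at least two diagnosis groups")
  }
  grp <- factor(cohort$diagnosis, levels = groups)

  continuous <- c(age = "age", los_days = "los_days", cci = "cci")
  binary <- c(sex_female = "sex", setNames(history_flags, history_flags))

  rows <- list()
  for (v in names(continuous)) {
    col <- cohort[[continuous[[v]]]]
    res <- .anova_oneway(col, grp)
    summaries <- vapply(groups, function(g) fmt_mean_sd(col[grp == g]),
                        character(1))
    rows[[v]] <- tibble(
      variable = v, type = "continuous",
      !!!setNames(as.list(summaries), groups),
      test = "anova", statistic = res$statistic,
      p_value = res$p_value, degenerate = res$degenerate
    )
  }
  for (v in names(binary)) {
    raw <- cohort[[binary[[v]]]]
    flag <- if (identical(binary[[v]], "sex")) as.integer(raw == "female") else as.integer(raw)
    res <- .chisq_homogeneity(flag, grp)
    summaries <- vapply(groups, function(g) fmt_n_pct(flag[grp == g]),
                        character(1))
    rows[[v]] <- tibble(
      variable = v, type = "categorical",
      !!!setNames(as.list(summaries), groups),
      test = "categorical_homogeneity", statistic = res$statistic,
      p_value = res$p_value, degenerate = res$degenerate
    )
  }
  dplyr::bind_rows(rows)
}

#' Cochran Q test for matched binary data
#'
#' The literal Cochran Q statistic for a subjects-by-conditions 0/1 matrix
#' (repeated measures). For comparing independent groups — the layout of the
#' baseline table — the homogeneity chi-square in [baseline_table()] is the
#' operational test; this function is provided for genuinely matched
#' layouts. Identical columns give Q = 0, p = 1.
#'
#' @param x A 0/1 matrix, rows = subjects, columns = conditions (k >= 2).
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
cochran_q <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop_validation("cochran_q needs >= 2 columns")
  if (!all(x %in% c(0, 1))) stop_validation("cochran_q needs a 0/1 matrix")
  k <- ncol(x)
  col_tot <- colSums(x)
  row_tot <- rowSums(x)
  denom <- k * sum(row_tot) - sum(row_tot^2)
  if (denom == 0) {
    return(tibble(statistic = 0, df = k - 1L, p_value = 1))
  }
  q <- k * (k - 1) * sum((col_tot - mean(col_tot))^2) / denom
  tibble(statistic = q, df = k - 1L,
         p_value = stats::pchisq(q, df = k - 1L, lower.tail = FALSE))
}

#' Per-domain comparison of RDoC scores across diagnosis groups
#'
#' For each domain score: one-way ANOVA across the diagnosis groups,
#' followed by all pairwise two-sample t tests (pooled-variance Student form
#' by default, unadjusted for multiplicity — a Bonferroni option is
#' available). Post hoc rows are reported only for domains whose omnibus
#' ANOVA is significant at `alpha` (set `posthoc = "always"` to report all
#' pairs regardless). Direction is taken from the sample means. Pairs
#' involving a group with fewer than two records are skipped with a warning.
#'
#' @param cohort Cohort tibble with joined score columns.
#' @param domains Character vector of score columns; autodetected if `NULL`.
#' @param alpha Omnibus significance level gating post hoc reporting.
#' @param posthoc `"significant"` (default) or `"always"`.
#' @param var_equal Pooled-variance t test (default `TRUE`).
#' @param bonferroni Multiply post hoc p values by the number of pairwise
#'   comparisons per domain (default `FALSE`; the raw p values are the
#'   convention here).
#' @return An object of class `rdoc_comparison`: a list with tibbles
#'   `omnibus` (domain, per-group `mean (SD)`, F, p) and `posthoc` (domain,
#'   group pair, direction, t, p). Use [tidy()] to extract either tibble.
#' @export
rdoc_group_comparison <- function(cohort, domains = NULL, alpha = 0.05,
                                  posthoc = c("significant", "always"),
                                  var_equal = TRUE, bonferroni = FALSE) {
  posthoc <- match.arg(posthoc)
  cohort <- as_tibble(cohort)
  domains <- score_columns(cohort, domains)
  groups <- intersect(diagnosis_levels, unique(cohort$diagnosis))
  grp <- factor(cohort$diagnosis, levels = groups)
  pairs <- utils::combn(groups, 2L, simplify = FALSE)

  omnibus <- purrr::map_dfr(domains, function(d) {
    col <- cohort[[d]]
    res <- .anova_oneway(col, grp)
    summaries <- vapply(groups, function(g) fmt_mean_sd(col[grp == g], digits = 3),
                        character(1))
    tibble(
      domain = d, !!!setNames(as.list(summaries), groups),
      statistic = res$statistic, p_value = res$p_value,
      degenerate = res$degenerate
    )
  })

  post <- purrr::map_dfr(domains, function(d) {
    om_p <- omnibus$p_value[omnibus$domain == d]
    if (posthoc == "significant" && (!is.finite(om_p) || om_p >= alpha)) {
      return(tibble())
    }
    purrr::map_dfr(pairs, function(pr) {
      a <- cohort[[d]][grp == pr[[1]]]
      b <- cohort[[d]][grp == pr[[2]]]
      if (length(a) < 2L || length(b) < 2L) {
        warn(sprintf("post hoc %s: group pair %s/%s has <2 records, skipped",
                     d, pr[[1]], pr[[2]]))
        return(tibble())
      }
      if (stats::sd(c(a, b)) == 0) {
        tt <- list(statistic = c(t = 0), p.value = 1)
      } else {
        tt <- t.test(a, b, var.equal = var_equal)
      }
      p <- tt$p.value
      if (bonferroni) p <- min(1, p * length(pairs))
      tibble(
        domain = d, group_a = pr[[1]], group_b = pr[[2]],
        direction = if (mean(a) >= mean(b)) {
          paste(pr[[1]], ">", pr[[2]])
        } else {
          paste(pr[[2]], ">", pr[[1]])
        },
        t_statistic = unname(tt$statistic), p_value = p
      )
    })
  })
  if (nrow(post) == 0L) {
    post <- tibble(domain = character(), group_a = character(),
                   group_b = character(), direction = character(),
                   t_statistic = double(), p_value = double())
  }

  structure(
    list(omnibus = omnibus, posthoc = post, groups = groups, alpha = alpha),
    class = "rdoc_comparison"
  )
}

#' @export
print.rdoc_comparison <- function(x, ...) {
  cat("<rdoc_comparison> omnibus ANOVA across",
      paste(x$groups, collapse = ", "), "\n")
  print(x$omnibus)
  if (nrow(x$posthoc)) {
    cat("post hoc pairwise t tests:\n")
    print(x$posthoc)
  } else {
    cat("no post hoc rows (no omnibus test significant at alpha =",
        x$alpha, ")\n")
  }
  invisible(x)
}

#' @rdname rdoc_group_comparison
#' @param x An `rdoc_comparison` object.
#' @param which `"omnibus"` or `"posthoc"`.
#' @param ... Unused.
#' @export
tidy.rdoc_comparison <- function(x, which = c("omnibus", "posthoc"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname rdoc_group_comparison
#' @param object An `rdoc_comparison` object.
#' @export
autoplot.rdoc_comparison <- function(object, ...) {
  groups <- object$groups
  long <- object$omnibus |>
    tidyr::pivot_longer(dplyr::all_of(groups),
                        names_to = "group", values_to = "summary") |>
    tidyr::extract("summary", into = c("mean", "sd"),
                   regex = "([0-9.]+) \\(([0-9.]+)\\)", convert = TRUE)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~domain, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "domain score (mean ± SD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
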