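# Pipeline runners behind the command-line interface: score a note corpus,
# run the full analysis battery and write the report-table set, and write
# synthetic fixtures. All file formats are those declared by the upstream
# modules (lexicon CSV, notes txt dir / CSV, cohort CSV, report CSV + JSON
# sidecar).

#' Score a note corpus from files
#'
#' Reads a lexicon and a note corpus, prepares the documents (translation,
#' normalization, tokenization) and writes the score matrix CSV, optionally
#' with the matched-term audit file. Deterministic: rerunning on the same
#' inputs reproduces the output byte for byte.
#'
#' @param lexicon_path Lexicon CSV path.
#' @param notes_path Notes directory (`<admission_id>.txt` files) or CSV.
#' @param out_path Output score-matrix CSV path.
#' @param translator Translation provider (identity by default).
#' @param audit_path Optional path for the `admission_id,domain,term` audit
#'   CSV.
#' @param quiet Suppress the per-domain summary message.
#' @return The score tibble, invisibly.
#' @export
run_scoring <- function(lexicon_path, notes_path, out_path,
                        translator = translator_identity(),
                        audit_path = NULL, quiet = FALSE) {
  lexicon <- read_lexicon(lexicon_path)
  notes <- read_notes(notes_path)
  prepared <- prepare_notes(notes, translator = translator)
  scores <- score_notes(prepared, lexicon, audit = !is.null(audit_path))
  write_scores(scores, out_path)
  if (!is.null(audit_path)) {
    readr::write_csv(attr(scores, "matched_terms"), audit_path, progress = FALSE)
  }
  if (!quiet) {
    doms <- setdiff(names(scores), "admission_id")
    summ <- vapply(doms, function(d) {
      sprintf("%s %.3f (%.3f)", d, mean(scores[[d]]), stats::sd(scores[[d]]))
    }, character(1))
    inform(paste0("scored ", nrow(scores), " documents; mean (SD): ",
                  paste(summ, collapse = ", ")))
  }
  invisible(scores)
}

#' Run the full analysis battery and write report tables
#'
#' Joins domain scores onto the admission-level cohort (unless the cohort
#' file already carries score columns), then writes:
#' `table1.csv` (patient-level baseline characteristics),
#' `table2.csv` + `table2_posthoc.csv` (per-domain group comparison),
#' `covariate_regression.csv`, one `table3_<group>.csv` per diagnosis group
#' (logistic length-of-stay models), `cox_secondary.csv`, a JSON sidecar
#' `analysis.json` with full-precision estimates and model diagnostics, and
#' `run.log`.
#'
#' @param cohort_path Cohort CSV path.
#' @param out_dir Output directory (created if needed).
#' @param scores_path Optional score-matrix CSV to join on `admission_id`;
#'   required when the cohort file has no score columns.
#' @param threshold LOS dichotomization threshold in days (default 3).
#' @param scale Score multiplier for regressions (default 100).
#' @param alpha Omnibus significance level gating post hoc rows.
#' @param bonferroni Bonferroni-adjust post hoc p values (default `FALSE`).
#' @param seed Recorded in the run log (the analysis itself is
#'   deterministic).
#' @return Invisible list of all result tables.
#' @export
run_analysis <- function(cohort_path, out_dir, scores_path = NULL,
                         threshold = 3, scale = 100, alpha = 0.05,
                         bonferroni = FALSE, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cohort_path)
  if (!is.null(scores_path)) {
    cohort <- join_scores(cohort, read_scores(scores_path))
  }
  domains <- score_columns(cohort)

  baseline <- baseline_table(to_patient_baseline(cohort))
  comparison <- rdoc_group_comparison(to_patient_baseline(cohort),
                                      domains = domains, alpha = alpha,
                                      bonferroni = bonferroni)
  covariates <- covariate_regression(cohort, domains = domains, scale = scale)
  groups <- intersect(diagnosis_levels, unique(cohort$diagnosis))
  logistic <- lapply(setNames(groups, groups), function(g) {
    fit <- fit_los_model(cohort, group = g, domains = domains,
                         threshold = threshold, scale = scale)
    list(tidy = tidy(fit), glance = glance(fit))
  })
  cox <- cox_secondary(cohort, domains = domains, scale = scale)

  readr::write_csv(baseline, file.path(out_dir, "table1.csv"), progress = FALSE)
  readr::write_csv(comparison$omnibus, file.path(out_dir, "table2.csv"),
                   progress = FALSE)
  readr::write_csv(comparison$posthoc, file.path(out_dir, "table2_posthoc.csv"),
                   progress = FALSE)
  readr::write_csv(covariates, file.path(out_dir, "covariate_regression.csv"),
                   progress = FALSE)
  for (g in groups) {
    readr::write_csv(logistic[[g]]$tidy,
                     file.path(out_dir, paste0("table3_", g, ".csv")),
                     progress = FALSE)
  }
  readr::write_csv(cox, file.path(out_dir, "cox_secondary.csv"),
                   progress = FALSE)

  diagnostics <- dplyr::bind_rows(lapply(logistic, `[[`, "glance"))
  sidecar <- list(
    config = list(threshold = threshold, scale = scale, alpha = alpha,
                  bonferroni = bonferroni, seed = seed),
    n = list(admissions = nrow(cohort),
             patients = dplyr::n_distinct(cohort$patient_id),
             per_group = as.list(table(cohort$diagnosis))),
    baseline = baseline,
    group_comparison = comparison$omnibus,
    posthoc = comparison$posthoc,
    covariate_regression = covariates,
    los_logistic = dplyr::bind_rows(lapply(logistic, `[[`, "tidy")),
    los_logistic_diagnostics = diagnostics,
    cox_secondary = cox
  )
  jsonlite::write_json(sidecar, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  degen <- c(
    baseline$variable[baseline$degenerate],
    comparison$omnibus$domain[comparison$omnibus$degenerate],
    unique(covariates$model[covariates$degenerate]),
    cox$domain[cox$degenerate],
    rownames(diagnostics)[!diagnostics$converged | diagnostics$separation]
  )
  log_lines <- c(
    sprintf("rdocscore analysis run: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("cohort: %s (%d admissions, %d patients)", cohort_path,
            nrow(cohort), dplyr::n_distinct(cohort$patient_id)),
    sprintf("group sizes: %s",
            paste(sprintf("%s=%d", groups,
                          as.integer(table(cohort$diagnosis)[groups])),
                  collapse = ", ")),
    sprintf("config: threshold=%g scale=%g alpha=%g bonferroni=%s seed=%s",
            threshold, scale, alpha, bonferroni,
            if (is.null(seed)) "NA" else seed),
    sprintf("degeneracy flags: %s",
            if (length(degen)) paste(degen, collapse = ", ") else "none")
  )
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(baseline = baseline, comparison = comparison,
                 covariates = covariates, logistic = logistic, cox = cox))
}

#' Write a full synthetic study to disk
#'
#' Generates a lexicon, cohort and note corpus from one seed and writes
#' `lexicon.csv`, `notes.csv`, `cohort.csv` (demographics only, per the
#' cohort schema), `scores_true.csv` (the planted score columns) and
#' `truth.json`; with a bilingual spec, also `dictionary.csv`. Files are
#' written only after the whole study generates, so an invalid spec leaves
#' no partial output.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec An [`rdoc_sim_spec`][simulate_spec].
#' @return Invisible list of the generated study objects.
#' @export
run_simulation <- function(out_dir, spec = simulate_spec()) {
  study <- simulate_study(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_lexicon(study$lexicon, file.path(out_dir, "lexicon.csv"))
  readr::write_csv(study$notes, file.path(out_dir, "notes.csv"),
                   progress = FALSE)
  write_cohort(study$cohort[, cohort_columns],
               file.path(out_dir, "cohort.csv"))
  write_scores(study$cohort[, c("admission_id", spec$domains)],
               file.path(out_dir, "scores_true.csv"))
  write_truth(study$truth, file.path(out_dir, "truth.json"))
  if (!is.null(study$dictionary)) {
    readr::write_csv(
      tibble(from = names(study$dictionary), to = unname(study$dictionary)),
      file.path(out_dir, "dictionary.csv"), progress = FALSE
    )
  }
  invisible(study)
}

#' Plot the distribution of domain scores by diagnosis group
#'
#' @param cohort Cohort tibble with joined score columns.
#' @param domains Score columns; autodetected if `NULL`.
#' @return A ggplot object (boxplots per domain and group).
#' @export
plot_score_distribution <- function(cohort, domains = NULL) {
  cohort <- as_tibble(cohort)
  domains <- score_columns(cohort, domains)
  long <- tidyr::pivot_longer(cohort[, c("diagnosis", domains)],
                              dplyr::all_of(domains),
                              names_to = "domain", values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$diagnosis, y = .data$score,
                                     fill = .data$diagnosis)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~domain, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "presence-fraction score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
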