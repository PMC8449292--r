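# Synthetic study generator: lexicons, admission cohorts and note corpora
# with analytically known ground truth.
#
# Design: each lexicon term is included in an admission's note independently
# with a per-(group, domain) probability p, so the expected presence-fraction
# score equals p exactly. The cohort generator realizes those Bernoulli draws
# and the note generator plants exactly the realized terms (plus filler), so
# the scores carried in the cohort and the scores recovered by the text
# pipeline agree exactly. The binary long-stay outcome is drawn from a
# logistic model on the realized scores (percentage points) and covariates;
# stay durations are then drawn log-normally within outcome arm so the
# 3-day dichotomization reproduces the drawn outcome.

# default per-(group, domain) term-inclusion probabilities, i.e. expected
# domain score means by diagnosis group
.default_term_probs <- function(domains) {
  m <- rbind(
    depression       = c(0.112, 0.146, 0.156, 0.112, 0.101),
    schizophrenia    = c(0.108, 0.099, 0.189, 0.168, 0.080),
    bipolar_disorder = c(0.098, 0.100, 0.189, 0.176, 0.102)
  )
  colnames(m) <- rdoc_domains
  if (!identical(domains, rdoc_domains)) {
    m2 <- matrix(0.12, nrow = 3, ncol = length(domains),
                 dimnames = list(rownames(m), domains))
    shared <- intersect(domains, rdoc_domains)
    m2[, shared] <- m[, shared]
    m <- m2
  }
  m
}

.default_demographics <- function() {
  list(
    depression = list(age_mean = 36.4, age_sd = 18.3, female_p = 0.630,
                      cci_lambda = 0.3,
                      flag_probs = c(htn = 0.133, dm = 0.052, stroke = 0.015,
                                     renal = 0.022, pneumonia = 0.045)),
    schizophrenia = list(age_mean = 31.3, age_sd = 15.3, female_p = 0.534,
                         cci_lambda = 0.1,
                         flag_probs = c(htn = 0.068, dm = 0.027, stroke = 0,
                                        renal = 0.014, pneumonia = 0.027)),
    bipolar_disorder = list(age_mean = 34.8, age_sd = 14.7, female_p = 0.667,
                            cci_lambda = 0.1,
                            flag_probs = c(htn = 0.121, dm = 0, stroke = 0,
                                           renal = 0.03, pneumonia = 0.03))
  )
}

#' Specification of a synthetic study
#'
#' Collects every parameter of the generator: cohort sizes, the
#' per-(group, domain) term-inclusion probabilities that become the expected
#' domain scores, lexicon shape, note-length distribution, per-group
#' demographics, and the logistic long-stay outcome model with its
#' arm-specific log-normal stay-duration model. Defaults emulate the
#' three-group inpatient study structure the package targets: 732
#' admissions over 571 patients (612/83/37 admissions, 465/73/33 patients
#' for depression / schizophrenia / bipolar disorder), group score means in
#' the 0.08–0.19 range, and a long-stay fraction around 70–75%.
#'
#' @param seed Integer seed; fully determines every generated artifact.
#'   Per-stage substreams are derived from it, so each stage is independently
#'   reproducible.
#' @param group_sizes Named admission counts per diagnosis group.
#' @param patients_per_group Named patient counts (<= admissions; the
#'   surplus admissions become repeat admissions of random patients).
#' @param domains Domain names for the generated lexicon.
#' @param terms_per_domain Terms per domain (denominator of the score).
#' @param phrase_frac Fraction of terms generated as two-word phrases.
#' @param filler_vocab_size Number of distinct non-lexicon filler words.
#' @param note_tokens_mean,note_tokens_sd Target note length (tokens).
#' @param term_probs Matrix `group x domain` of term-inclusion
#'   probabilities; the expected score of (group, domain) equals this entry.
#' @param demographics Per-group list: `age_mean`, `age_sd`, `female_p`,
#'   `cci_lambda`, `flag_probs`.
#' @param los_model List with `intercept` and named `coef` (log-odds per
#'   score percentage point for domains; per unit for `age`, `cci`,
#'   `sex_female`) for the long-stay (> threshold days) outcome.
#' @param los_dist List with `short = c(meanlog, sdlog)` (log-normal,
#'   rejection-sampled below the threshold) and `long = c(meanlog, sdlog)`
#'   (threshold + log-normal).
#' @param threshold Dichotomization threshold in days (default 3).
#' @param bilingual_frac Fraction of note tokens replaced by "foreign" stub
#'   forms invertible via the dictionary translator (default 0).
#' @return A validated list of class `rdoc_sim_spec`.
#' @export
simulate_spec <- function(
    seed = 1L,
    group_sizes = c(depression = 612, schizophrenia = 83, bipolar_disorder = 37),
    patients_per_group = c(depression = 465, schizophrenia = 73, bipolar_disorder = 33),
    domains = rdoc_domains,
    terms_per_domain = 30L,
    phrase_frac = 0.2,
    filler_vocab_size = 500L,
    note_tokens_mean = 120,
    note_tokens_sd = 25,
    term_probs = NULL,
    demographics = NULL,
    los_model = NULL,
    los_dist = NULL,
    threshold = 3,
    bilingual_frac = 0) {
  groups <- names(group_sizes)
  if (is.null(groups) || any(groups == "")) {
    stop_validation("`group_sizes` must be a fully named vector")
  }
  if (!identical(sort(groups), sort(names(patients_per_group)))) {
    stop_validation("`patients_per_group` must name the same groups as `group_sizes`")
  }
  if (any(group_sizes < 1)) stop_validation("group sizes must be >= 1")
  if (any(patients_per_group < 1) ||
      any(patients_per_group[groups] > group_sizes[groups])) {
    stop_validation("patients_per_group must be in [1, group_sizes] per group")
  }
  term_probs <- term_probs %||% .default_term_probs(domains)[groups, , drop = FALSE]
  if (!all(rownames(term_probs) == groups) ||
      !all(colnames(term_probs) == domains)) {
    stop_validation("`term_probs` must be a group x domain matrix matching names")
  }
  if (any(term_probs < 0 | term_probs > 1)) {
    stop_validation("term-inclusion probabilities must lie in [0, 1]")
  }
  demographics <- demographics %||% .default_demographics()[groups]
  los_model <- los_model %||% list(
    intercept = 0.7,
    coef = c(
      setNames(log(c(0.975, 1.058, 1.01, 1.010, 0.957))[seq_along(domains)],
               domains),
      age = 0, cci = 0, sex_female = 0
    )
  )
  los_dist <- los_dist %||% list(
    short = c(meanlog = log(1.5), sdlog = 0.45),
    long = c(meanlog = 1.69, sdlog = 0.9)
  )
  # the short arm must be able to produce stays <= threshold
  p_below <- stats::plnorm(threshold, los_dist$short[["meanlog"]],
                           los_dist$short[["sdlog"]])
  if (p_below < 0.01) {
    stop_validation(
      "infeasible stay-duration model: the short-stay log-normal places almost no mass below the threshold"
    )
  }
  if (terms_per_domain < 1) stop_validation("terms_per_domain must be >= 1")
  if (phrase_frac < 0 || phrase_frac > 1 ||
      bilingual_frac < 0 || bilingual_frac > 1) {
    stop_validation("fractions must lie in [0, 1]")
  }
  structure(
    list(
      seed = as.integer(seed), groups = groups,
      group_sizes = group_sizes, patients_per_group = patients_per_group,
      domains = domains, terms_per_domain = as.integer(terms_per_domain),
      phrase_frac = phrase_frac,
      filler_vocab_size = as.integer(filler_vocab_size),
      note_tokens_mean = note_tokens_mean, note_tokens_sd = note_tokens_sd,
      term_probs = term_probs, demographics = demographics,
      los_model = los_model, los_dist = los_dist, threshold = threshold,
      bilingual_frac = bilingual_frac
    ),
    class = "rdoc_sim_spec"
  )
}

# deterministic per-stage substream: every stage reseeds from the global
# seed so stages can be regenerated independently
.stage_seed <- function(seed, stage) {
  offsets <- c(vocab = 104729L, cohort = 224737L, notes = 350377L)
  (abs(as.integer(seed)) * 7919L + offsets[[stage]]) %% 2147483562L + 1L
}

# deterministic pseudo-word pool; all segments pairwise disjoint
.sim_vocab <- function(spec) {
  n_terms <- length(spec$domains) * spec$terms_per_domain
  n_phrase <- ceiling(spec$phrase_frac * n_terms)
  n_need <- n_terms + n_phrase + spec$filler_vocab_size
  consonants <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p",
                  "r", "s", "t", "v", "w", "z")
  vowels <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(consonants, vowels, paste0))
  max_words <- length(syll)^3
  if (n_need > max_words) {
    stop_validation("requested lexicon/filler size exceeds generable unique strings")
  }
  withr_seed <- .stage_seed(spec$seed, "vocab")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  words <- character(0)
  while (length(words) < n_need) {
    batch <- paste0(sample(syll, 2L * (n_need - length(words)), replace = TRUE),
                    sample(syll, 2L * (n_need - length(words)), replace = TRUE),
                    sample(syll, 2L * (n_need - length(words)), replace = TRUE))
    words <- unique(c(words, batch))
  }
  words <- words[seq_len(n_need)]
  list(
    term_words = words[seq_len(n_terms)],
    phrase_extras = words[n_terms + seq_len(n_phrase)],
    filler = words[n_terms + n_phrase + seq_len(spec$filler_vocab_size)],
    phrase_idx = if (n_phrase > 0) {
      sort(sample(n_terms, n_phrase))
    } else integer(0)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic lexicon
#'
#' Pseudo-word term sets, pairwise disjoint across domains and disjoint from
#' the filler vocabulary used by [simulate_notes()], with a configurable
#' fraction of two-word phrases. Deterministic given the spec seed.
#'
#' @param spec An [`rdoc_sim_spec`][simulate_spec].
#' @return An `rdoc_lexicon` with `length(spec$domains) * spec$terms_per_domain`
#'   terms.
#' @export
simulate_lexicon <- function(spec) {
  stopifnot(inherits(spec, "rdoc_sim_spec"))
  voc <- .sim_vocab(spec)
  terms <- voc$term_words
  if (length(voc$phrase_idx)) {
    terms[voc$phrase_idx] <- paste(terms[voc$phrase_idx], voc$phrase_extras)
  }
  as_lexicon(tibble(
    domain = rep(spec$domains, each = spec$terms_per_domain),
    term = terms
  ), quiet = TRUE)
}

#' Generate a synthetic admission cohort with planted truth
#'
#' Draws demographics per group, realizes the per-term Bernoulli inclusion
#' draws that define each admission's domain scores, draws the binary
#' long-stay outcome from the logistic model in the spec, and draws stay
#' durations log-normally within outcome arm so that dichotomizing at the
#' threshold reproduces the drawn outcome exactly. Repeat admissions are
#' created by assigning surplus admissions to existing patients.
#'
#' @param spec An [`rdoc_sim_spec`][simulate_spec].
#' @return An object of class `rdoc_simulation`: a list with
#'   \describe{
#'     \item{cohort}{validated admission-level cohort tibble with the domain
#'       score columns joined,}
#'     \item{term_draws}{tibble `admission_id, domain, term_idx` (list-column
#'       of realized term indices) consumed by [simulate_notes()],}
#'     \item{truth}{the planted generating parameters: the spec, the expected
#'       score mean per (group, domain) (equal to the inclusion
#'       probabilities), and the outcome-model coefficients.}
#'   }
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "rdoc_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.stage_seed(spec$seed, "cohort"))

  m <- spec$terms_per_domain
  n_total <- sum(spec$group_sizes)
  adm_width <- max(5L, nchar(as.character(n_total)))
  pat_width <- max(4L, nchar(as.character(sum(spec$patients_per_group))))

  adm_counter <- 0L
  pat_counter <- 0L
  per_group <- lapply(spec$groups, function(g) {
    n_adm <- spec$group_sizes[[g]]
    n_pat <- spec$patients_per_group[[g]]
    dem <- spec$demographics[[g]]

    pat_ids <- sprintf(paste0("P%0", pat_width, "d"), pat_counter + seq_len(n_pat))
    pat_counter <<- pat_counter + n_pat
    # patient-level draws
    page <- pmin(95, pmax(10, round(rnorm(n_pat, dem$age_mean, dem$age_sd))))
    psex <- ifelse(runif(n_pat) < dem$female_p, "female", "male")
    pcci <- rpois(n_pat, dem$cci_lambda)
    pflags <- vapply(history_flags, function(fl) {
      rbinom(n_pat, 1L, dem$flag_probs[[fl]])
    }, integer(n_pat))
    pflags <- matrix(pflags, nrow = n_pat,
                     dimnames = list(NULL, history_flags))

    # first admission per patient, surplus admissions to random patients
    owner <- c(seq_len(n_pat),
               if (n_adm > n_pat) sample(n_pat, n_adm - n_pat, replace = TRUE))
    owner <- sort(owner)
    adm_ids <- sprintf(paste0("A%0", adm_width, "d"), adm_counter + seq_len(n_adm))
    adm_counter <<- adm_counter + n_adm

    scores <- matrix(NA_real_, n_adm, length(spec$domains),
                     dimnames = list(NULL, spec$domains))
    draws <- vector("list", length(spec$domains))
    names(draws) <- spec$domains
    for (d in spec$domains) {
      inc <- matrix(rbinom(n_adm * m, 1L, spec$term_probs[g, d]), nrow = n_adm)
      scores[, d] <- rowSums(inc) / m
      draws[[d]] <- apply(inc == 1L, 1L, which, simplify = FALSE)
    }

    tab <- tibble(
      patient_id = pat_ids[owner],
      admission_id = adm_ids,
      diagnosis = g,
      age = as.numeric(page[owner]),
      sex = psex[owner],
      cci = as.numeric(pcci[owner])
    )
    for (fl in history_flags) tab[[fl]] <- as.numeric(pflags[owner, fl])
    for (d in spec$domains) tab[[d]] <- scores[, d]
    list(tab = tab, draws = draws)
  })

  cohort <- dplyr::bind_rows(lapply(per_group, `[[`, "tab"))

  # long-stay outcome from the logistic model on realized scores/covariates
  cf <- spec$los_model$coef
  lp <- spec$los_model$intercept +
    as.matrix(cohort[, spec$domains, drop = FALSE] * 100) %*%
      cf[spec$domains] +
    cohort$age * (cf[["age"]] %||% 0) +
    cohort$cci * (cf[["cci"]] %||% 0) +
    .sex_female(cohort$sex) * (cf[["sex_female"]] %||% 0)
  long_stay <- rbinom(nrow(cohort), 1L, plogis(as.vector(lp)))

  los <- numeric(nrow(cohort))
  short_i <- which(long_stay == 0L)
  long_i <- which(long_stay == 1L)
  if (length(long_i)) {
    los[long_i] <- spec$threshold +
      rlnorm(length(long_i), spec$los_dist$long[["meanlog"]],
             spec$los_dist$long[["sdlog"]])
  }
  if (length(short_i)) {
    draw <- rlnorm(length(short_i), spec$los_dist$short[["meanlog"]],
                   spec$los_dist$short[["sdlog"]])
    for (iter in seq_len(1000L)) {
      bad <- draw > spec$threshold
      if (!any(bad)) break
      draw[bad] <- rlnorm(sum(bad), spec$los_dist$short[["meanlog"]],
                          spec$los_dist$short[["sdlog"]])
    }
    draw[draw > spec$threshold] <- spec$threshold # exact ties code short
    los[short_i] <- draw
  }
  cohort$los_days <- los
  cohort <- cohort[, c(cohort_columns, spec$domains)]

  term_draws <- dplyr::bind_rows(lapply(seq_along(spec$groups), function(i) {
    tab <- per_group[[i]]$tab
    dplyr::bind_rows(lapply(spec$domains, function(d) {
      tibble(admission_id = tab$admission_id, domain = d,
             term_idx = per_group[[i]]$draws[[d]])
    }))
  }))

  truth <- list(
    seed = spec$seed,
    group_sizes = as.list(spec$group_sizes),
    patients_per_group = as.list(spec$patients_per_group),
    expected_scores = spec$term_probs,
    los_model = spec$los_model,
    threshold = spec$threshold,
    n_admissions = nrow(cohort),
    n_patients = dplyr::n_distinct(cohort$patient_id)
  )

  structure(
    list(cohort = suppressMessages(validate_cohort(cohort)),
         term_draws = term_draws, truth = truth, spec = spec),
    class = "rdoc_simulation"
  )
}

#' Generate synthetic admission notes for a simulated cohort
#'
#' Each admission's note contains exactly the lexicon terms realized for it
#' by [simulate_cohort()] (each term once, phrase tokens kept contiguous),
#' padded with filler words (disjoint from the lexicon) to a drawn target
#' length, in shuffled order. With `bilingual_frac > 0`, that fraction of
#' tokens is replaced by invertible "foreign" stub forms; the returned
#' dictionary maps them back, for use with [translator_dictionary()].
#'
#' @param sim An `rdoc_simulation` from [simulate_cohort()].
#' @param lexicon The lexicon from [simulate_lexicon()] (same spec).
#' @return A list with `notes` (tibble `admission_id, text`) and
#'   `dictionary` (named character vector, or `NULL` when monolingual).
#' @export
simulate_notes <- function(sim, lexicon) {
  stopifnot(inherits(sim, "rdoc_simulation"))
  spec <- sim$spec
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.stage_seed(spec$seed, "notes"))
  voc <- .sim_vocab(spec)

  term_by_domain <- split(lexicon$term, factor(lexicon$domain,
                                               levels = unique(lexicon$domain)))
  adm_ids <- sim$cohort$admission_id
  by_adm <- split(sim$term_draws, sim$term_draws$admission_id)

  texts <- vapply(adm_ids, function(aid) {
    td <- by_adm[[aid]]
    units <- unlist(purrr::map2(td$domain, td$term_idx, function(d, idx) {
      term_by_domain[[d]][idx]
    }), use.names = FALSE)
    n_term_tokens <- sum(lengths(stringi::stri_split_fixed(units, " ")))
    target <- max(n_term_tokens,
                  round(rnorm(1L, spec$note_tokens_mean, spec$note_tokens_sd)))
    n_fill <- max(0L, target - n_term_tokens)
    units <- c(units, if (n_fill > 0) sample(voc$filler, n_fill, replace = TRUE))
    units <- sample(units)
    paste(units, collapse = " ")
  }, character(1), USE.NAMES = FALSE)

  dictionary <- NULL
  if (spec$bilingual_frac > 0) {
    all_words <- unique(c(voc$term_words, voc$phrase_extras, voc$filler))
    foreign <- paste0("q", all_words)
    dictionary <- setNames(all_words, foreign)
    texts <- vapply(texts, function(tx) {
      toks <- stringi::stri_split_fixed(tx, " ")[[1]]
      swap <- runif(length(toks)) < spec$bilingual_frac
      toks[swap] <- paste0("q", toks[swap])
      paste(toks, collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }

  list(notes = tibble(admission_id = adm_ids, text = texts),
       dictionary = dictionary)
}

#' Generate a full synthetic study
#'
#' Convenience wrapper: lexicon, cohort (with planted truth) and notes from
#' one spec. Identical seed and spec give byte-identical output.
#'
#' @param spec An [`rdoc_sim_spec`][simulate_spec].
#' @return A list: `lexicon`, `cohort`, `notes`, `dictionary`, `term_draws`,
#'   `truth`.
#' @export
simulate_study <- function(spec = simulate_spec()) {
  lexicon <- simulate_lexicon(spec)
  sim <- simulate_cohort(spec)
  notes <- simulate_notes(sim, lexicon)
  list(lexicon = lexicon, cohort = sim$cohort, notes = notes$notes,
       dictionary = notes$dictionary, term_draws = sim$term_draws,
       truth = sim$truth)
}

#' Write planted truth as JSON
#'
#' @param truth The `truth` element of an `rdoc_simulation` /
#'   [simulate_study()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  truth$expected_scores <- as.data.frame(truth$expected_scores) |>
    (\(df) cbind(group = rownames(df), df))() |>
    as_tibble()
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
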