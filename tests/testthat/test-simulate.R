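small_spec <- function(seed = 1, ...) {
  simulate_spec(
    seed = seed,
    group_sizes = c(depression = 40, schizophrenia = 15, bipolar_disorder = 10),
    patients_per_group = c(depression = 30, schizophrenia = 12,
                           bipolar_disorder = 9),
    terms_per_domain = 10L,
    filler_vocab_size = 60L,
    note_tokens_mean = 40, note_tokens_sd = 8,
    ...
  )
}

test_that("the generator is fully deterministic given the seed", {
  s1 <- simulate_study(small_spec(seed = 5))
  s2 <- simulate_study(small_spec(seed = 5))
  expect_identical(s1$lexicon, s2$lexicon)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$notes, s2$notes)
  s3 <- simulate_study(small_spec(seed = 6))
  expect_false(identical(s1$notes$text, s3$notes$text))
})

test_that("generated lexicons have the requested shape, disjoint domains", {
  lex <- simulate_lexicon(simulate_spec(seed = 1, terms_per_domain = 10L))
  expect_identical(unname(domain_sizes(lex)), rep(10L, 5))
  expect_identical(anyDuplicated(lex$term), 0L)
  # unigram components of different domains never collide
  words <- unlist(strsplit(lex$term, " "))
  expect_identical(anyDuplicated(words), 0L)
  expect_error(simulate_lexicon(simulate_spec(terms_per_domain = 1e7)),
               class = "rdocscore_validation_error")
})

test_that("default spec reproduces the target cohort multiplicities", {
  sim <- suppressMessages(simulate_cohort(simulate_spec(seed = 3)))
  co <- sim$cohort
  expect_identical(nrow(co), 732L)
  expect_identical(dplyr::n_distinct(co$patient_id), 571L)
  counts <- table(co$diagnosis)
  expect_identical(as.integer(counts[c("depression", "schizophrenia",
                                       "bipolar_disorder")]),
                   c(612L, 83L, 37L))
  expect_identical(nrow(to_patient_baseline(co)), 571L)
})

test_that("degenerate inclusion probabilities give all-zero / all-one scores", {
  sp0 <- small_spec(seed = 2)
  sp0$term_probs[] <- 0
  st0 <- simulate_study(sp0)
  sc0 <- score_notes(prepare_notes(st0$notes), st0$lexicon)
  expect_true(all(sc0[, sp0$domains] == 0))

  sp1 <- small_spec(seed = 2)
  sp1$term_probs[] <- 1
  st1 <- simulate_study(sp1)
  sc1 <- score_notes(prepare_notes(st1$notes), st1$lexicon)
  expect_true(all(sc1[, sp1$domains] == 1))
})

test_that("pipeline scores of generated notes equal the planted cohort scores", {
  st <- simulate_study(small_spec(seed = 9))
  sc <- score_notes(prepare_notes(st$notes), st$lexicon)
  sc <- sc[match(st$cohort$admission_id, sc$admission_id), ]
  for (d in rdoc_domains) expect_equal(sc[[d]], st$cohort[[d]])
})

test_that("bilingual notes score identically once the stub translates them back", {
  st <- simulate_study(small_spec(seed = 12, bilingual_frac = 0.4))
  expect_false(is.null(st$dictionary))
  stub <- translator_dictionary(st$dictionary)
  sc <- score_notes(prepare_notes(st$notes, translator = stub), st$lexicon)
  sc <- sc[match(st$cohort$admission_id, sc$admission_id), ]
  for (d in rdoc_domains) expect_equal(sc[[d]], st$cohort[[d]])
  # without translation the foreign tokens hide some terms
  sc_raw <- score_notes(prepare_notes(st$notes), st$lexicon)
  expect_lt(mean(as.matrix(sc_raw[, rdoc_domains])),
            mean(as.matrix(sc[, rdoc_domains])))
})

test_that("stay durations respect the drawn dichotomy and the tie rule", {
  sim <- simulate_cohort(small_spec(seed = 4))
  co <- sim$cohort
  expect_true(all(co$los_days > 0))
  # arm-specific durations: anything above threshold is long, at/below short
  expect_identical(los_binary(co$los_days, sim$spec$threshold),
                   as.integer(co$los_days > sim$spec$threshold))
})

test_that("an infeasible short-stay duration model is rejected", {
  expect_error(
    small_spec(los_dist = list(short = c(meanlog = log(500), sdlog = 0.05),
                               long = c(meanlog = 1.7, sdlog = 0.9))),
    "infeasible", class = "rdocscore_validation_error"
  )
})

test_that("expected pipeline score equals the inclusion probability", {
  # E[score] = p for each (group, domain); checked at moderate n here
  sp <- simulate_spec(
    seed = 13,
    group_sizes = c(depression = 400, schizophrenia = 5, bipolar_disorder = 5),
    patients_per_group = c(depression = 400, schizophrenia = 5,
                           bipolar_disorder = 5),
    terms_per_domain = 10L
  )
  sp$term_probs["depression", ] <- 0.2
  sim <- suppressMessages(simulate_cohort(sp))
  dep <- sim$cohort[sim$cohort$diagnosis == "depression", ]
  se <- sqrt(0.2 * 0.8 / 10) / sqrt(400)
  for (d in sp$domains) expect_lt(abs(mean(dep[[d]]) - 0.2), 3 * se)
})

test_that("planted truth records the generating parameters", {
  sim <- simulate_cohort(small_spec(seed = 8))
  expect_identical(sim$truth$n_admissions, nrow(sim$cohort))
  expect_equal(sim$truth$expected_scores, sim$spec$term_probs)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$los_model$intercept, sim$spec$los_model$intercept)
})
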