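prep <- function(...) {
  texts <- c(...)
  prepare_notes(tibble::tibble(
    admission_id = paste0("A", seq_along(texts)), text = texts
  ))
}

test_that("a 10-term domain with 2 terms present scores 2/10", {
  lex <- as_lexicon(list(dom = paste0("term", 1:10)))
  notes <- prep("term3 filler words here term7 more filler")
  expect_equal(score_notes(notes, lex)$dom, 0.2)
})

test_that("empty documents score zero in every domain", {
  lex <- random_lexicon()
  notes <- prep("")
  sc <- score_notes(notes, lex)
  expect_true(all(sc[, unique(lex$domain)] == 0))
})

test_that("presence semantics: 50 repetitions of one matched term count once", {
  lex <- as_lexicon(list(dom = paste0("term", 1:10)))
  notes <- prep(paste(rep("term1", 50), collapse = " "))
  expect_equal(score_notes(notes, lex)$dom, 0.1)
})

test_that("multi-word terms match only as contiguous ordered subsequences", {
  lex <- as_lexicon(list(dom = c("suicidal ideation", "other")))
  reversed <- prep("ideation suicidal")
  forward <- prep("x suicidal ideation y")
  gapped <- prep("suicidal severe ideation")
  expect_equal(score_notes(reversed, lex)$dom, 0)
  expect_equal(score_notes(forward, lex)$dom, 0.5)
  expect_equal(score_notes(gapped, lex)$dom, 0)
})

test_that("scorer matches the brute-force n-gram oracle on random pairs", {
  set.seed(123)
  for (i in 1:200) {
    vocab <- random_vocab(sample(c(30, 60), 1))
    lex <- random_lexicon(n_domains = sample(1:4, 1),
                          terms_per_domain = sample(1:6, 1),
                          phrase_frac = 0.4, vocab = vocab)
    tokens <- random_tokens(sample(0:60, 1), vocab)
    notes <- tibble::tibble(admission_id = "A1", text = NA_character_,
                            tokens = list(tokens))
    got <- score_notes(notes, lex)
    want <- oracle_score(tokens, lex)
    expect_equal(unlist(got[1, names(want)]), want, ignore_attr = TRUE)
  }
})

test_that("corpus scoring equals looped per-document scoring, order preserved", {
  set.seed(7)
  vocab <- random_vocab(30)
  lex <- random_lexicon(vocab = vocab)
  texts <- replicate(15, paste(random_tokens(sample(5:30, 1), vocab),
                               collapse = " "))
  notes <- prep(texts)
  all_at_once <- score_notes(notes, lex)
  looped <- purrr::map_dfr(seq_len(nrow(notes)), function(i) {
    score_notes(notes[i, ], lex)
  })
  expect_equal(all_at_once, looped)
  expect_identical(all_at_once$admission_id, notes$admission_id)
})

test_that("appending an unmatched term of one domain raises only that score", {
  vocab <- random_vocab(50)
  set.seed(99)
  lex <- random_lexicon(n_domains = 3, terms_per_domain = 5, phrase_frac = 0,
                        vocab = vocab)
  tokens <- random_tokens(20, setdiff(vocab, lex$term))
  doms <- unique(lex$domain)
  base <- score_notes(tibble::tibble(admission_id = "a", tokens = list(tokens)), lex)
  new_term <- lex$term[lex$domain == doms[2]][1]
  richer <- score_notes(tibble::tibble(
    admission_id = "a", tokens = list(c(tokens, new_term))
  ), lex)
  expect_gt(richer[[doms[2]]], base[[doms[2]]])
  expect_equal(richer[[doms[1]]], base[[doms[1]]])
  expect_equal(richer[[doms[3]]], base[[doms[3]]])
})

test_that("growing a domain's lexicon with unmatched terms dilutes its score", {
  lex <- as_lexicon(list(dom = c("alpha", "beta")))
  bigger <- as_lexicon(list(dom = c("alpha", "beta", "zeta")))
  notes <- prep("alpha filler")
  expect_gt(score_notes(notes, lex)$dom, score_notes(notes, bigger)$dom)
})

test_that("unigram-only scores are invariant under token permutation", {
  set.seed(31)
  vocab <- random_vocab(40)
  lex <- random_lexicon(phrase_frac = 0, vocab = vocab)
  tokens <- random_tokens(30, vocab)
  doms <- unique(lex$domain)
  s1 <- score_notes(tibble::tibble(admission_id = "a", tokens = list(tokens)), lex)
  s2 <- score_notes(tibble::tibble(
    admission_id = "a", tokens = list(sample(tokens))
  ), lex)
  expect_equal(s1[doms], s2[doms])
})

test_that("scoring guards its preconditions", {
  lex <- random_lexicon()
  expect_error(score_notes(tibble::tibble(admission_id = "a", text = "x"), lex),
               "prepare_notes", class = "rdocscore_validation_error")
  notes <- tibble::tibble(admission_id = c("a", "a"),
                          tokens = list("x", "y"))
  expect_error(score_notes(notes, lex), "duplicate",
               class = "rdocscore_validation_error")
})

test_that("the audit trail lists exactly the matched (domain, term) pairs", {
  lex <- as_lexicon(list(d1 = c("alpha", "suicidal ideation"),
                         d2 = c("beta")))
  notes <- prep("alpha beta suicidal ideation gamma")
  audit <- match_terms(notes, lex)
  expect_setequal(paste(audit$domain, audit$term),
                  c("d1 alpha", "d1 suicidal ideation", "d2 beta"))
})

test_that("score matrices round-trip through CSV at six decimals", {
  lex <- as_lexicon(list(dom = paste0("t", 1:3)))
  notes <- prep("t1 x", "t1 t2 t3")
  sc <- score_notes(notes, lex)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(sc, path)
  expect_match(readLines(path)[2], "0\\.333333")
  back <- read_scores(path)
  expect_equal(back$dom, sc$dom, tolerance = 1e-6)
})
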