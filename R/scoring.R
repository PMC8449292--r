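# Presence-fraction scoring: the score of domain d for a document is
# |matched terms of d| / |terms of d|. A term matches iff its token sequence
# occurs contiguously in the document's tokens; each term counts at most once
# however often it occurs.

# match one prepared token vector against a pre-split lexicon;
# returns logical vector over lexicon rows
.match_tokens <- function(tokens, term_tokens, term_len) {
  n_terms <- length(term_tokens)
  hit <- logical(n_terms)
  if (length(tokens) == 0L) return(hit)
  tokset <- unique(tokens)
  uni <- term_len == 1L
  if (any(uni)) {
    hit[uni] <- vapply(term_tokens[uni], function(tt) tt[[1]] %in% tokset,
                       logical(1))
  }
  multi <- which(!uni)
  if (length(multi)) {
    ntok <- length(tokens)
    for (j in multi) {
      tt <- term_tokens[[j]]
      k <- length(tt)
      if (k > ntok || !all(tt %in% tokset)) next
      starts <- which(tokens == tt[[1]])
      starts <- starts[starts <= ntok - k + 1L]
      for (s in starts) {
        if (all(tokens[s:(s + k - 1L)] == tt)) { hit[j] <- TRUE; break }
      }
    }
  }
  hit
}

.split_lexicon <- function(lexicon) {
  term_tokens <- stringi::stri_split_fixed(lexicon$term, " ", omit_empty = TRUE)
  list(
    domain = lexicon$domain,
    domains = unique(lexicon$domain),
    term = lexicon$term,
    term_tokens = term_tokens,
    term_len = lengths(term_tokens),
    sizes = domain_sizes(lexicon)
  )
}

#' Score prepared notes against a lexicon
#'
#' Computes, for every document and every lexicon domain, the
#' presence-fraction score: the fraction of the domain's terms that appear
#' at least once in the document. A multi-word term matches as a contiguous
#' token subsequence; repeated occurrences of a term still count once
#' (a 10-term domain with 2 distinct terms present scores 2/10 = 0.20).
#' Scores are fractions in \[0, 1\]; rescaling to percentage points happens
#' only at the regression stage.
#'
#' @param notes A tibble prepared by [prepare_notes()] (must carry a
#'   `tokens` list-column and unique `admission_id`s).
#' @param lexicon An `rdoc_lexicon` (or coercible input).
#' @param audit If `TRUE`, attach the matched-term audit trail (a tibble
#'   `admission_id, domain, term`) as attribute `"matched_terms"`.
#' @return A tibble with `admission_id` plus one numeric column per domain,
#'   rows in input order.
#' @export
#' @examples
#' lex <- as_lexicon(list(negval = c("hopeless", "worthless")))
#' notes <- prepare_notes(tibble::tibble(admission_id = "A1",
#'                                       text = "Feels hopeless today."))
#' score_notes(notes, lex)
score_notes <- function(notes, lexicon, audit = FALSE) {
  if (!is.data.frame(notes) || is.null(notes[["tokens"]])) {
    stop_validation("`notes` has no `tokens` column; run prepare_notes() first")
  }
  if (anyDuplicated(notes$admission_id)) {
    dup <- unique(notes$admission_id[duplicated(notes$admission_id)])
    stop_validation(paste0("duplicate admission_id in notes: ",
                           paste(dup, collapse = ", ")))
  }
  lexicon <- as_lexicon(lexicon, quiet = TRUE)
  lx <- .split_lexicon(lexicon)

  hits <- vapply(
    notes$tokens,
    .match_tokens,
    logical(length(lx$term)),
    term_tokens = lx$term_tokens,
    term_len = lx$term_len
  )
  hits <- matrix(hits, nrow = length(lx$term)) # terms x docs

  scores <- tibble(admission_id = as.character(notes$admission_id))
  for (d in lx$domains) {
    rows <- lx$domain == d
    scores[[d]] <- colSums(hits[rows, , drop = FALSE]) / sum(rows)
  }
  if (audit) {
    idx <- which(hits, arr.ind = TRUE)
    attr(scores, "matched_terms") <- tibble(
      admission_id = scores$admission_id[idx[, 2L]],
      domain = lx$domain[idx[, 1L]],
      term = lx$term[idx[, 1L]]
    )
  }
  scores
}

#' Matched-term audit trail
#'
#' Long-format record of which lexicon terms matched in which document,
#' for auditing the scores produced by [score_notes()].
#'
#' @inheritParams score_notes
#' @return A tibble `admission_id, domain, term`, one row per matched term.
#' @export
match_terms <- function(notes, lexicon) {
  attr(score_notes(notes, lexicon, audit = TRUE), "matched_terms")
}

#' Write a score matrix to CSV
#'
#' Header `admission_id,<domain1>,...,<domainK>`; fractions are written with
#' six decimal places.
#'
#' @param scores Output of [score_notes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.6f", v))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a score matrix written by [write_scores()]
#'
#' @param path CSV path with header `admission_id,<domain...>`.
#' @return A tibble with `admission_id` and numeric domain columns.
#' @export
read_scores <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    admission_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  as_tibble(df)
}
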