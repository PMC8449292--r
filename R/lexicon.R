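#' The five canonical RDoC domains
#'
#' Domain identifiers used throughout the package for the five Research
#' Domain Criteria dimensions: positive valence systems, negative valence
#' systems, cognitive systems, systems for social processes, and
#' arousal/regulatory systems. Arbitrary domain sets are accepted everywhere
#' a lexicon is accepted; this constant is the default set the synthetic
#' generator and the reporting helpers use.
#'
#' @format Character vector of length 5.
#' @export
rdoc_domains <- c(
  "positive_valence",
  "negative_valence",
  "cognitive_systems",
  "social_processes",
  "arousal_regulatory"
)

#' Build a term lexicon from a data frame or named list
#'
#' A lexicon maps each named domain to a set of lowercase terms; a term may
#' be a multi-word phrase. Terms are normalized with the same rules applied
#' to documents ([normalize_text()]) so that matching is consistent, and
#' duplicates within a domain are collapsed (set semantics).
#'
#' @param x Either a data frame with columns `domain` and `term`, or a named
#'   list of character vectors (one element per domain).
#' @param quiet If `FALSE` (default), collapsing duplicate `(domain, term)`
#'   entries emits a warning.
#'
#' @return A tibble with columns `domain` (character) and `term` (character,
#'   normalized), of class `rdoc_lexicon`. Domain order follows first
#'   appearance.
#' @export
#' @examples
#' lex <- as_lexicon(list(
#'   negative_valence = c("hopeless", "worthless", "suicidal ideation"),
#'   arousal_regulatory = c("insomnia")
#' ))
#' domain_sizes(lex)
as_lexicon <- function(x, quiet = FALSE) {
  if (is.data.frame(x)) {
    if (!all(c("domain", "term") %in% names(x))) {
      stop_format("lexicon data frame must have columns `domain` and `term`")
    }
    df <- tibble(domain = as.character(x$domain), term = as.character(x$term))
  } else if (is.list(x) && !is.null(names(x))) {
    df <- tibble(
      domain = rep(names(x), lengths(x)),
      term = as.character(unlist(x, use.names = FALSE))
    )
  } else {
    stop_format("`x` must be a data frame or a named list of character vectors")
  }
  df$term <- normalize_text(df$term)
  validate_lexicon(df, quiet = quiet)
}

validate_lexicon <- function(df, quiet = FALSE) {
  if (nrow(df) == 0L) stop_validation("lexicon has no terms")
  if (anyNA(df$domain) || any(df$domain == "")) {
    stop_validation("lexicon contains empty or missing domain names")
  }
  if (any(df$term == "" | is.na(df$term))) {
    bad <- unique(df$domain[df$term == "" | is.na(df$term)])
    stop_validation(paste0(
      "lexicon terms empty after normalization in domain(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  dup <- duplicated(paste(df$domain, df$term, sep = "\r"))
  if (any(dup)) {
    if (!quiet) {
      warn(sprintf("collapsed %d duplicate (domain, term) entr%s",
                   sum(dup), if (sum(dup) == 1L) "y" else "ies"))
    }
    df <- df[!dup, , drop = FALSE]
  }
  # preserve first-appearance domain order
  df$domain <- factor(df$domain, levels = unique(df$domain))
  df <- df[order(df$domain), , drop = FALSE]
  df$domain <- as.character(df$domain)
  out <- as_tibble(df)
  class(out) <- c("rdoc_lexicon", class(out))
  out
}

#' Read a lexicon from a CSV file
#'
#' The on-disk format is a two-column UTF-8 CSV with header exactly
#' `domain,term`, one term per row; multi-word terms are quoted per RFC 4180.
#' Terms are normalized on load and duplicate rows collapsed with a warning.
#'
#' @param path Path to the lexicon CSV.
#' @return An `rdoc_lexicon` tibble (see [as_lexicon()]).
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop_format(paste0("lexicon file not found: ", path))
  header <- readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE)
  if (length(header) == 0L ||
      gsub("\\s", "", header) != "domain,term") {
    stop_format(paste0(
      "lexicon file must start with header `domain,term`, got: ",
      if (length(header)) header else "<empty file>"
    ))
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    domain = readr::col_character(),
    term = readr::col_character()
  ), progress = FALSE)
  df$term <- normalize_text(df$term)
  validate_lexicon(df)
}

#' Write a lexicon to a CSV file
#'
#' Inverse of [read_lexicon()]: `read_lexicon(write_lexicon(lex, path))`
#' reproduces `lex` exactly, because terms are stored already normalized.
#'
#' @param lexicon An `rdoc_lexicon` (or coercible data frame / named list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  lexicon <- as_lexicon(lexicon, quiet = TRUE)
  # multi-word terms are written as one quoted field (RFC 4180)
  esc <- function(x) {
    x <- gsub('"', '""', x, fixed = TRUE)
    ifelse(grepl('[ ",]', x), paste0('"', x, '"'), x)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("domain,term",
               paste0(esc(lexicon$domain), ",", esc(lexicon$term))),
             con)
  invisible(path)
}

#' Number of terms per lexicon domain
#'
#' The per-domain term count is the denominator of every presence-fraction
#' score.
#'
#' @param lexicon An `rdoc_lexicon` (or coercible input).
#' @return Named integer vector, one element per domain, in domain order.
#' @export
domain_sizes <- function(lexicon) {
  lexicon <- as_lexicon(lexicon, quiet = TRUE)
  tab <- table(factor(lexicon$domain, levels = unique(lexicon$domain)))
  setNames(as.integer(tab), names(tab))
}

#' @export
print.rdoc_lexicon <- function(x, ...) {
  sizes <- domain_sizes(x)
  cat("<rdoc_lexicon> ", length(sizes), " domain(s), ",
      nrow(x), " term(s)\n", sep = "")
  for (d in names(sizes)) {
    terms <- x$term[x$domain == d]
    shown <- paste(head(terms, 4L), collapse = ", ")
    if (length(terms) > 4L) shown <- paste0(shown, ", ...")
    cat("  ", d, " (", sizes[[d]], "): ", shown, "\n", sep = "")
  }
  invisible(x)
}
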