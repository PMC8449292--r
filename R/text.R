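#' Normalize raw note text for term matching
#'
#' Applies the single normalization used for both lexicon terms and note
#' text: NFKC Unicode normalization, casefolding to lower case, replacement
#' of every character that is not a letter, digit, or internal apostrophe by
#' a space, collapsing of whitespace runs, and trimming. The function is
#' total (never errors) and idempotent.
#'
#' @param x Character vector.
#' @param keep_apostrophes Keep apostrophes that sit between letters
#'   (`"can't"` stays one token). Default `TRUE`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_text("Suicidal ideation; severe INSOMNIA.")
normalize_text <- function(x, keep_apostrophes = TRUE) {
  x <- as.character(x)
  out <- stringi::stri_trans_nfkc(x)
  out <- stringi::stri_trans_tolower(out)
  # unify typographic apostrophes before the internal-apostrophe rule
  out <- stringi::stri_replace_all_fixed(out, "’", "'")
  if (keep_apostrophes) {
    out <- stringi::stri_replace_all_regex(out, "[^\\p{L}\\p{N}']+", " ")
    # apostrophes only survive between letters/digits
    out <- stringi::stri_replace_all_regex(out, "(?<![\\p{L}\\p{N}])'|'(?![\\p{L}\\p{N}])", " ")
  } else {
    out <- stringi::stri_replace_all_regex(out, "[^\\p{L}\\p{N}]+", " ")
  }
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  out <- stringi::stri_trim_both(out)
  out[is.na(x)] <- NA_character_
  out
}

#' Split normalized text into tokens
#'
#' Splits on single spaces, preserving order (order matters for multi-word
#' phrase matching) and duplicates (presence-deduplication happens at the
#' scoring stage). Empty text gives an empty token vector.
#'
#' @param x Character vector of already-normalized text.
#' @return A list of character vectors, one per input element.
#' @export
tokenize_text <- function(x) {
  x <- as.character(x)
  out <- stringi::stri_split_fixed(x, " ", omit_empty = TRUE)
  out[x == "" & !is.na(x)] <- list(character(0))
  out
}

#' Translation providers
#'
#' Translation sits behind a provider contract: a provider is a list with a
#' `name` and a pure `translate(text)` function (deterministic within a run,
#' and `translate("") == ""`). Two providers ship with the package:
#' `translator_identity()` (the default; returns its input unchanged) and
#' `translator_dictionary()`, a word-for-word substitution stub used for
#' testing bilingual corpora without any live machine-translation service.
#'
#' @param mapping For `translator_dictionary()`: a named character vector
#'   (`c(foreign = "english", ...)`), a two-column data frame
#'   (`from`, `to`), or a path to a two-column CSV with header `from,to`.
#'
#' @return An object of class `rdoc_translator`.
#' @name translators
#' @export
translator_identity <- function() {
  structure(
    list(name = "identity", translate = function(text) text),
    class = "rdoc_translator"
  )
}

#' @rdname translators
#' @export
translator_dictionary <- function(mapping) {
  if (is.character(mapping) && is.null(names(mapping)) && length(mapping) == 1L) {
    df <- readr::read_csv(mapping, col_types = readr::cols(
      from = readr::col_character(), to = readr::col_character()
    ), progress = FALSE)
    mapping <- setNames(df$to, df$from)
  } else if (is.data.frame(mapping)) {
    mapping <- setNames(as.character(mapping$to), as.character(mapping$from))
  }
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop_validation("dictionary mapping must be a fully named character vector")
  }
  force(mapping)
  structure(
    list(
      name = "dictionary",
      mapping = mapping,
      translate = function(text) {
        vapply(text, function(one) {
          if (is.na(one) || one == "") return(one)
          words <- stringi::stri_split_regex(one, "\\s+", omit_empty = TRUE)[[1]]
          hit <- words %in% names(mapping)
          words[hit] <- unname(mapping[words[hit]])
          paste(words, collapse = " ")
        }, character(1), USE.NAMES = FALSE)
      }
    ),
    class = "rdoc_translator"
  )
}

#' @export
print.rdoc_translator <- function(x, ...) {
  cat("<rdoc_translator: ", x$name, ">\n", sep = "")
  invisible(x)
}

#' Read admission notes
#'
#' Notes are read either from a directory of UTF-8 `.txt` files named
#' `<admission_id>.txt`, or from a two-column CSV `admission_id,text`.
#'
#' @param path Directory or CSV file path.
#' @return A tibble with columns `admission_id` and `text`.
#' @export
read_notes <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop_validation(paste0("no documents found in ", path))
    tibble(
      admission_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f) {
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
      }, character(1), USE.NAMES = FALSE)
    )
  } else if (file.exists(path)) {
    df <- readr::read_csv(path, col_types = readr::cols(
      admission_id = readr::col_character(), text = readr::col_character()
    ), progress = FALSE)
    if (nrow(df) == 0L) stop_validation(paste0("no documents found in ", path))
    as_tibble(df)
  } else {
    stop_validation(paste0("notes path does not exist: ", path))
  }
}

#' Prepare notes for scoring
#'
#' Runs each raw note through the translation provider, then normalization
#' and tokenization, adding a `tokens` list-column. With the default
#' identity provider the result depends only on `text` (no randomness
#' anywhere in the text pipeline). A provider failure aborts with the
#' offending `admission_id` — documents are never silently skipped.
#'
#' @param notes A data frame with columns `admission_id` and `text`.
#' @param translator An [`rdoc_translator`][translators]; identity by default.
#' @param keep_apostrophes Passed to [normalize_text()].
#' @return `notes` as a tibble with an added list-column `tokens`.
#' @export
#' @examples
#' notes <- tibble::tibble(admission_id = "A1", text = "Low mood.")
#' prepare_notes(notes)$tokens[[1]]
prepare_notes <- function(notes, translator = translator_identity(),
                          keep_apostrophes = TRUE) {
  if (!is.data.frame(notes) || !all(c("admission_id", "text") %in% names(notes))) {
    stop_validation("`notes` must have columns `admission_id` and `text`")
  }
  if (!inherits(translator, "rdoc_translator")) {
    stop_validation("`translator` must be an rdoc_translator")
  }
  notes <- as_tibble(notes)
  translated <- tryCatch(
    translator$translate(notes$text),
    error = function(e) {
      # retry element-wise to name the failing document
      for (i in seq_len(nrow(notes))) {
        ok <- tryCatch({ translator$translate(notes$text[[i]]); TRUE },
                       error = function(e2) FALSE)
        if (!ok) {
          stop_pipeline(sprintf(
            "translation failed for admission_id '%s' (provider '%s'): %s",
            notes$admission_id[[i]], translator$name, conditionMessage(e)
          ))
        }
      }
      stop_pipeline(sprintf("translation failed (provider '%s'): %s",
                            translator$name, conditionMessage(e)))
    }
  )
  notes$tokens <- tokenize_text(normalize_text(translated,
                                               keep_apostrophes = keep_apostrophes))
  notes
}
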