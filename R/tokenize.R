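#' Normalize a surface form for dictionary lookup
#'
#' Lowercases, collapses internal whitespace to single spaces, and strips
#' surrounding (but not internal) punctuation. No stemming is applied:
#' chemistry nomenclature ("aralkylamino compound", "venlafaxine") must
#' match exactly.
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized forms.
#' @export
#' @examples
#' normalize_surface("  Aralkylamino   Compound. ")
normalize_surface <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  # strip leading/trailing punctuation runs, keep internal hyphens etc.
  x <- gsub("^[[:punct:]]+(?=[[:alnum:]])", "", x, perl = TRUE)
  x <- gsub("(?<=[[:alnum:]])[[:punct:]]+$", "", x, perl = TRUE)
  trimws(x)
}

#' Tokenize plain text
#'
#' Splits on whitespace and peels punctuation off as single-character
#' tokens. Word-internal hyphens, apostrophes and underscores are kept
#' inside a token (so "is_a" and "beta-blocker" stay single tokens).
#'
#' @param x a single character string.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize_text <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("[[:alnum:]_]+(?:['-][[:alnum:]_]+)*|[^[:space:][:alnum:]_]",
                x, perl = TRUE)
  toks <- regmatches(x, m)[[1]]
  toks[nzchar(toks)]
}

#' Is a token pure punctuation?
#'
#' Punctuation-class tokens never take part in span matching and act as
#' span separators.
#'
#' @param tokens character vector.
#' @return logical vector.
#' @export
is_punct_token <- function(tokens) {
  grepl("^[[:punct:]]+$", tokens) & !grepl("_", tokens, fixed = TRUE)
}

#' Tokenize an entity-tagged sentence
#'
#' Parses a sentence in which the two candidate-relation entities are
#' delimited by `<e>`/`</e>` tags, returning the token sequence with the
#' tags removed and the 1-based inclusive token ranges of the two
#' entities. The tags themselves never become tokens and never take part
#' in matching.
#'
#' @param text a single character string containing exactly two
#'   `<e>...</e>` pairs.
#' @param label optional relation label to attach.
#' @param keep_markers retain the entity delimiters as punctuation-class
#'   sentinel tokens around each entity span, so the classifier can tell
#'   the candidate pair apart from other mentions. Sentinels are pure
#'   punctuation, hence still excluded from span matching.
#' @return an object of class `re_sentence`: list with `tokens`,
#'   `entity_spans` (2x2 integer matrix, rows = entities, cols =
#'   start/end, 1-based inclusive) and `label`.
#' @export
#' @examples
#' s <- tag_tokenize("<e>venlafaxine</e> may cause a <e>seizure</e> .")
#' s$tokens
#' s$entity_spans
tag_tokenize <- function(text, label = NA_character_,
                         keep_markers = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  n_open  <- lengths(regmatches(text, gregexpr("<e>",  text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr("</e>", text, fixed = TRUE)))
  if (n_open != 2L || n_close != 2L)
    stop("sentence must contain exactly two <e>...</e> entity pairs, found ",
         n_open, " openers / ", n_close, " closers", call. = FALSE)
  # sentinel characters survive tokenization as punctuation singletons
  x <- gsub("<e>",  " \u2039 ", text, fixed = TRUE)
  x <- gsub("</e>", " \u203a ", x,    fixed = TRUE)
  toks <- tokenize_text(x)
  open  <- which(toks == "\u2039")
  close <- which(toks == "\u203a")
  if (length(open) != 2L || length(close) != 2L ||
      any(close <= open) || open[2] <= close[1])
    stop("malformed or nested entity tags", call. = FALSE)
  if (any(close - open < 2L))
    stop("empty entity between <e> and </e>", call. = FALSE)
  if (keep_markers) {
    spans <- rbind(c(open[1] + 1L, close[1] - 1L),
                   c(open[2] + 1L, close[2] - 1L))
    tokens <- toks   # delimiters stay, as pure-punctuation sentinels
  } else {
    keep <- !(seq_along(toks) %in% c(open, close))
    # map old positions to new positions after dropping the 4 sentinels
    newpos <- cumsum(keep)
    spans <- rbind(c(newpos[open[1] + 1L], newpos[close[1] - 1L]),
                   c(newpos[open[2] + 1L], newpos[close[2] - 1L]))
    tokens <- toks[keep]
  }
  storage.mode(spans) <- "integer"
  colnames(spans) <- c("start", "end")
  structure(list(tokens = tokens, entity_spans = spans, label = label),
            class = "re_sentence")
}

#' @export
print.re_sentence <- function(x, ...) {
  cat("<re_sentence> ", length(x$tokens), " tokens, label=",
      x$label, "\n", sep = "")
  cat("  ", paste(x$tokens, collapse = " "), "\n", sep = "")
  for (i in 1:2) {
    sp <- x$entity_spans[i, ]
    cat("  entity ", i, ": [", sp[1], ",", sp[2], "] ",
        paste(x$tokens[sp[1]:sp[2]], collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
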