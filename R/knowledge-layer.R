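#' Enumerate candidate multi-token spans
#'
#' Generates every contiguous span of one or more tokens that contains no
#' punctuation-class token; punctuation acts as a separator between
#' matchable regions. For n punctuation-free tokens the count is
#' n(n+1)/2. Spans are emitted in (start ascending, length descending)
#' order, so for any start position the most specific (longest) candidate
#' comes first.
#'
#' @param tokens character vector of tokens.
#' @return integer matrix with columns `start`, `end` (1-based
#'   inclusive), one row per span.
#' @export
#' @examples
#' nrow(enumerate_spans(letters[1:10]))  # 55
enumerate_spans <- function(tokens) {
  stopifnot(length(tokens) >= 1L)
  punct <- is_punct_token(tokens)
  n <- length(tokens)
  out <- vector("list", n)
  # runs of punctuation-free tokens
  r <- rle(!punct)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- 0L
  res <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    for (s in starts[i]:ends[i]) {
      for (e in ends[i]:s) {   # length descending for this start
        k <- k + 1L
        res[[k]] <- c(s, e)
      }
    }
  }
  if (!k)
    return(matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("start", "end"))))
  m <- do.call(rbind, res)
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}

span_surface <- function(tokens, start, end) {
  paste(tokens[start:end], collapse = " ")
}

spans_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

#' Match sentence spans against knowledge-base lookup tables
#'
#' In `"targeted"` mode only the two candidate-entity spans are queried,
#' each as a whole unit. In `"contextual"` mode every enumerated span is
#' queried against every table; among matched spans that overlap, only
#' maximal-length ones are kept (ties broken by leftmost start, then by
#' higher summed tail information content), so surviving matches are
#' pairwise non-overlapping and no kept match is a proper sub-span of any
#' matched span. Entity delimiter tags never participate: they are
#' removed by [tag_tokenize()] before matching.
#'
#' @param tokens character vector of sentence tokens (tags removed).
#' @param tables list of `lookup_table`.
#' @param mode `"targeted"` or `"contextual"`.
#' @param entity_spans 2x2 integer matrix of the candidate entity spans
#'   (required in targeted mode).
#' @return list of matches; each match is a list with `span`
#'   (integer start/end) and `hits` (data.frame as from
#'   [query_surface()], may pool several sources).
#' @export
match_spans <- function(tokens, tables, mode = c("targeted", "contextual"),
                        entity_spans = NULL) {
  mode <- match.arg(mode)
  if (inherits(tables, "lookup_table")) tables <- list(tables)
  if (mode == "targeted") {
    stopifnot(is.matrix(entity_spans), nrow(entity_spans) == 2L)
    out <- list()
    for (i in 1:2) {
      s <- unname(entity_spans[i, 1]); e <- unname(entity_spans[i, 2])
      hits <- query_surface(tables, span_surface(tokens, s, e))
      if (nrow(hits))
        out[[length(out) + 1L]] <- list(span = c(start = s, end = e),
                                        hits = hits)
    }
    return(out)
  }
  cand <- enumerate_spans(tokens)
  if (!nrow(cand)) return(list())
  surfaces <- vapply(seq_len(nrow(cand)), function(i)
    span_surface(tokens, cand[i, 1], cand[i, 2]), character(1))
  keys <- normalize_surface(surfaces)   # one vectorized pass
  matched <- list()
  for (i in seq_len(nrow(cand))) {
    s <- unname(cand[i, 1]); e <- unname(cand[i, 2])
    hits <- query_norm(tables, keys[i])
    if (nrow(hits))
      matched[[length(matched) + 1L]] <-
        list(span = c(start = s, end = e), hits = hits,
             len = e - s + 1L, sum_ic = sum(hits$tail_ic))
  }
  if (!length(matched)) return(list())
  # greedy resolution: longest first, then leftmost, then summed tail IC
  ord <- order(-vapply(matched, `[[`, integer(1), "len"),
               vapply(matched, function(m) m$span[["start"]], integer(1)),
               -vapply(matched, `[[`, numeric(1), "sum_ic"))
  kept <- list()
  for (i in ord) {
    m <- matched[[i]]
    clash <- any(vapply(kept, function(k)
      spans_overlap(m$span[1], m$span[2], k$span[1], k$span[2]),
      logical(1)))
    if (!clash)
      kept[[length(kept) + 1L]] <- list(span = m$span, hits = m$hits)
  }
  # report anchors left-to-right
  kept[order(vapply(kept, function(k) k$span[["start"]], integer(1)))]
}

#' Cap knowledge branches per anchor by information content
#'
#' Pools the candidate triples of each anchor across sources, removes
#' exact duplicates, sorts by descending tail information content (ties:
#' source name, then tail label) and keeps at most `max_entities` of
#' them. Anchors with fewer candidates keep all of them.
#'
#' @param matches list of matches from [match_spans()].
#' @param max_entities maximum knowledge-base entities injected per
#'   anchor, typically 2-5; `Inf` for unbounded.
#' @return the matches with each `hits` truncated.
#' @export
select_branches <- function(matches, max_entities = 3) {
  if (!is.infinite(max_entities)) {
    max_entities <- as.integer(max_entities)
    if (is.na(max_entities) || max_entities < 1L)
      stop("max_entities must be a positive integer or Inf", call. = FALSE)
  }
  lapply(matches, function(m) {
    h <- m$hits
    h <- h[!duplicated(h[, c("head", "relation", "tail")]), , drop = FALSE]
    h <- h[order(-h$tail_ic, h$source, h$tail), , drop = FALSE]
    if (is.finite(max_entities) && nrow(h) > max_entities)
      h <- h[seq_len(max_entities), , drop = FALSE]
    rownames(h) <- NULL
    m$hits <- h
    m
  })
}

#' Expand a sentence into a depth-1 knowledge sentence tree
#'
#' Composition of [match_spans()] and [select_branches()]: each surviving
#' match becomes an anchor of the tree and each of its triples becomes a
#' branch (relation token, tail token). Branch depth is fixed at 1 - no
#' branch of a branch - so the original sentence meaning is preserved.
#' Relation labels stay single tokens (`is_a`); by default a multi-word
#' tail label is likewise kept as a single vocabulary token (a token may
#' stand for several words), with `split_tails = TRUE` splitting tails on
#' whitespace instead. With `mode = "none"` (no knowledge) the tree is
#' the bare trunk.
#'
#' @param sentence an `re_sentence` from [tag_tokenize()].
#' @param tables list of `lookup_table` (ignored when `mode = "none"`).
#' @param mode `"targeted"`, `"contextual"` or `"none"`.
#' @param max_entities branch cap per anchor, see [select_branches()].
#' @param split_tails tokenize tail labels on whitespace instead of
#'   keeping each tail as one token.
#' @return object of class `sentence_tree`: list with `trunk` (tokens),
#'   `anchors` (list of anchor records: `span`, `branches`; each branch
#'   has `tokens` and `ic`), `entity_spans` and `label`.
#' @export
build_sentence_tree <- function(sentence, tables = list(),
                                mode = c("targeted", "contextual", "none"),
                                max_entities = 3, split_tails = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(sentence, "re_sentence"))
  anchors <- list()
  if (mode != "none" && length(tables)) {
    matches <- match_spans(sentence$tokens, tables, mode,
                           entity_spans = sentence$entity_spans)
    matches <- select_branches(matches, max_entities)
    anchors <- lapply(matches, function(m) {
      branches <- lapply(seq_len(nrow(m$hits)), function(i) {
        tail_tok <- if (split_tails)
          tokenize_text(m$hits$tail[i]) else m$hits$tail[i]
        list(tokens = c(m$hits$relation[i], tail_tok),
             ic = m$hits$tail_ic[i])
      })
      list(span = m$span, branches = branches)
    })
  }
  structure(list(trunk = sentence$tokens, anchors = anchors,
                 entity_spans = sentence$entity_spans,
                 label = sentence$label),
            class = "sentence_tree")
}

#' @export
print.sentence_tree <- function(x, ...) {
  cat("<sentence_tree> ", length(x$trunk), " trunk tokens, ",
      length(x$anchors), " anchor(s), label=", x$label, "\n", sep = "")
  for (a in x$anchors) {
    cat("  [", a$span[1], ",", a$span[2], "] ",
        paste(x$trunk[a$span[1]:a$span[2]], collapse = " "), "\n", sep = "")
    for (b in a$branches)
      cat("    -> ", paste(b$tokens, collapse = " "),
          sprintf("  (ic %.3f)", b$ic), "\n", sep = "")
  }
  invisible(x)
}
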