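#' Specification of a synthetic ontology/corpus fixture
#'
#' Captures the study conditions of the desk-scale benchmark: a rooted
#' `is_a` DAG with multi-word concept labels, and a corpus of
#' entity-tagged sentences whose gold label is a deterministic-plus-noise
#' function of the two entities' ontology ancestry, so that injected
#' `is_a` branches carry real signal.
#'
#' @param concepts number of ontology concepts (incl. the root).
#' @param branching target `is_a` branching factor (children per node).
#' @param multiword_frac fraction of concept labels made of 2-3 words.
#' @param sentences number of corpus sentences.
#' @param labels ordered label set; the second label marks related pairs.
#' @param beta knowledge-signal strength in [0, 1]: a surface cue token
#'   agrees with the gold label with probability 0.5 + beta/2, so lexical
#'   features alone recover the label only partially and the remainder is
#'   recoverable solely through ontology ancestry.
#' @param epsilon label noise in [0, 0.5]: probability that the gold
#'   label is flipped relative to the ancestry predicate.
#' @param vocab_size filler vocabulary size.
#' @param pos_frac fraction of sentences drawn from ancestry-related
#'   pairs.
#' @param direct_pos_frac among related pairs, the fraction drawn from
#'   pairs whose shared ancestor is a direct parent (including
#'   parent-child pairs). Depth-1 triple injection can expose exactly
#'   these through overlapping branch tails, so this dial sets how much
#'   of the planted signal the injected knowledge can in principle
#'   express.
#' @param extra_mention_frac fraction of sentences also mentioning 1-3
#'   untagged concepts (exercising contextual injection).
#' @param seed seed fixing all randomness.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(concepts = 40L, branching = 3L,
                         multiword_frac = 0.4, sentences = 2000L,
                         labels = c("false", "true"), beta = 0.1,
                         epsilon = 0.05, vocab_size = 120L,
                         pos_frac = 0.45, direct_pos_frac = 0.7,
                         extra_mention_frac = 0.3,
                         seed = 1L) {
  stopifnot(concepts >= 1, branching >= 1, sentences >= 1,
            multiword_frac >= 0, multiword_frac <= 1,
            beta >= 0, beta <= 1, epsilon >= 0, epsilon <= 0.5,
            vocab_size >= 10, length(labels) == 2L,
            pos_frac > 0, pos_frac < 1,
            direct_pos_frac >= 0, direct_pos_frac <= 1)
  structure(list(concepts = as.integer(concepts),
                 branching = as.integer(branching),
                 multiword_frac = multiword_frac,
                 sentences = as.integer(sentences), labels = labels,
                 beta = beta, epsilon = epsilon,
                 vocab_size = as.integer(vocab_size),
                 pos_frac = pos_frac,
                 direct_pos_frac = direct_pos_frac,
                 extra_mention_frac = extra_mention_frac,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

SYLLABLES <- c("ba", "cor", "dex", "fen", "gly", "hep", "kin", "lom",
               "mer", "nil", "oxa", "pra", "quin", "rol", "sta", "tri",
               "ul", "vex", "wil", "zan", "bro", "cil", "dol", "fam",
               "gos", "hyl", "jor", "keb", "lun", "mog")

# unique pseudowords; draws from the current RNG stream
make_words <- function(n, avoid = character(), min_syl = 2L,
                       max_syl = 3L) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    k <- sample(min_syl:max_syl, 1L)
    w <- paste(sample(SYLLABLES, k, replace = TRUE), collapse = "")
    if (!(w %in% out) && !(w %in% avoid)) out <- c(out, w)
    guard <- guard + 1L
    if (guard > 200L * n)
      stop("pseudoword pool exhausted; lower the requested count",
           call. = FALSE)
  }
  out
}

#' Generate a seeded toy ontology
#'
#' Builds a rooted `is_a` DAG: every non-root concept gets one parent
#' among earlier concepts (respecting the branching factor), plus
#' occasionally a second parent so the hierarchy is a genuine DAG, and
#' exactly `round(multiword_frac * concepts)` labels are 2-3 words long
#' (exercising multi-token matching). Give two specs different seeds
#' and prefixes to obtain sources with disjoint label spaces
#' (exercising multi-source lookup).
#'
#' @param spec a `fixture_spec`.
#' @param name source name (also the id prefix).
#' @param path optional file path; when given, the ontology is also
#'   written as a valid OBO file (see [write_obo()]).
#' @return a `knowledge_source`.
#' @export
generate_ontology <- function(spec, name = "toy", path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$concepts
  src <- withr::with_seed(spec$seed, {
    n_multi <- round(spec$multiword_frac * n)
    multi <- rep(FALSE, n)
    if (n_multi > 0) multi[sample.int(n, n_multi)] <- TRUE
    singles <- make_words(sum(!multi))
    words <- make_words(3L * sum(multi), avoid = singles)
    labels <- character(n)
    labels[!multi] <- singles
    wi <- 1L
    for (i in which(multi)) {
      k <- sample(2:3, 1L)
      labels[i] <- paste(words[wi:(wi + k - 1L)], collapse = " ")
      wi <- wi + k
    }
    ids <- sprintf("%s:%04d", toupper(name), seq_len(n))
    child <- integer(0); parent <- integer(0)
    kids <- integer(n)                     # children per node so far
    for (i in seq_len(n)[-1]) {
      open <- which(kids[seq_len(i - 1L)] < spec$branching)
      if (!length(open))
        stop("branching factor ", spec$branching,
             " incompatible with ", n, " concepts", call. = FALSE)
      p <- if (length(open) == 1L) open else sample(open, 1L)
      child <- c(child, i); parent <- c(parent, p)
      kids[p] <- kids[p] + 1L
      if (i > 2L && stats::runif(1) < 0.2) {   # second parent -> DAG
        others <- setdiff(seq_len(i - 1L), p)
        if (length(others)) {
          q <- if (length(others) == 1L) others else sample(others, 1L)
          child <- c(child, i); parent <- c(parent, q)
        }
      }
    }
    list(name = name,
         concepts = data.frame(id = ids, label = labels,
                               stringsAsFactors = FALSE),
         synonyms = data.frame(id = character(), synonym = character(),
                               stringsAsFactors = FALSE),
         triples = data.frame(head_id = ids[child], head = labels[child],
                              relation = rep("is_a", length(child)),
                              tail_id = ids[parent], tail = labels[parent],
                              stringsAsFactors = FALSE),
         relations = if (length(child)) "is_a" else character(0))
  })
  src$ic <- compute_ic(src)
  class(src) <- "knowledge_source"
  if (!is.null(path)) write_obo(src, path)
  src
}

#' Write a knowledge source as an OBO flat file
#'
#' Emits a minimal valid OBO 1.2 document: a `format-version` header and
#' one `[Term]` stanza per concept with `id:`, `name:`, `synonym:` and
#' `is_a:`/`relationship:` lines, round-trippable through
#' [load_knowledge_source()].
#'
#' @param source a `knowledge_source`.
#' @param path output file.
#' @export
write_obo <- function(source, path) {
  stopifnot(inherits(source, "knowledge_source"))
  lab <- stats::setNames(source$concepts$label, source$concepts$id)
  out <- c("format-version: 1.2",
           paste0("ontology: ", tolower(source$name)), "")
  for (i in seq_len(nrow(source$concepts))) {
    id <- source$concepts$id[i]
    out <- c(out, "[Term]", paste0("id: ", id),
             paste0("name: ", source$concepts$label[i]))
    syn <- source$synonyms$synonym[source$synonyms$id == id]
    for (s in syn)
      out <- c(out, sprintf("synonym: \"%s\" EXACT []", s))
    tr <- source$triples[source$triples$head_id == id, , drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      if (tr$relation[j] == "is_a")
        out <- c(out, paste0("is_a: ", tr$tail_id[j], " ! ",
                             lab[tr$tail_id[j]]))
      else
        out <- c(out, paste0("relationship: ", tr$relation[j], " ",
                             tr$tail_id[j], " ! ", lab[tr$tail_id[j]]))
    }
    out <- c(out, "")
  }
  writeLines(out, file(path, encoding = "UTF-8"))
  invisible(path)
}

is_a_parents <- function(source) {
  isa <- source$triples[source$triples$relation == "is_a", , drop = FALSE]
  split(isa$tail_id, factor(isa$head_id, levels = source$concepts$id))
}

#' Ancestry predicate between two concepts
#'
#' TRUE when the two concepts share a common `is_a` ancestor within
#' `depth` edges (each concept counts as its own depth-0 ancestor, so a
#' parent-child pair is related). This is the planted relation that the
#' synthetic corpus encodes, and an oracle for the ceiling accuracy of a
#' knowledge-aware classifier.
#'
#' @param source a `knowledge_source`.
#' @param a,b concept ids.
#' @param depth maximum number of `is_a` edges climbed (default 2).
#' @return logical.
#' @export
ancestry_predicate <- function(source, a, b, depth = 2L) {
  par <- is_a_parents(source)
  up <- function(ids) unique(unlist(par[ids], use.names = FALSE))
  anc <- function(x) {
    seen <- x
    frontier <- x
    for (d in seq_len(depth)) {
      frontier <- setdiff(up(frontier), seen)
      if (!length(frontier)) break
      seen <- c(seen, frontier)
    }
    seen
  }
  length(intersect(anc(a), anc(b))) > 0L
}

#' Generate a planted-signal relation-extraction corpus
#'
#' Every sentence embeds two sampled concept labels (tagged `<e>`) amid
#' pseudoword filler; the gold label is "related" iff the two concepts
#' share a common `is_a` ancestor within depth 2, flipped with
#' probability `epsilon`. A surface cue token agrees with the gold label
#' with probability `0.5 + beta/2`, giving lexical features partial -
#' but only partial - predictive power, and a fraction of sentences
#' additionally mention 1-3 untagged concepts that only contextual
#' injection picks up.
#'
#' @param source a `knowledge_source` from [generate_ontology()].
#' @param spec the same `fixture_spec`.
#' @param path optional TSV output path (see [write_corpus()]).
#' @return an `re_corpus`.
#' @export
generate_corpus <- function(source, spec, path = NULL) {
  stopifnot(inherits(source, "knowledge_source"),
            inherits(spec, "fixture_spec"))
  ids <- source$concepts$id
  lab_of <- stats::setNames(source$concepts$label, ids)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 concepts to build a corpus",
                   call. = FALSE)
  par <- is_a_parents(source)
  direct_related <- function(i, j) {
    pi <- par[[ids[i]]]; pj <- par[[ids[j]]]
    length(intersect(pi, pj)) > 0L || ids[j] %in% pi || ids[i] %in% pj
  }
  pred <- matrix(FALSE, n, n)
  direct <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      pred[i, j] <- ancestry_predicate(source, ids[i], ids[j])
      direct[i, j] <- pred[i, j] && direct_related(i, j)
    }
  pos_pairs <- which(pred, arr.ind = TRUE)
  pos_direct <- which(direct, arr.ind = TRUE)
  pos_indirect <- which(pred & !direct, arr.ind = TRUE)
  neg_pairs <- which(!pred & upper.tri(pred), arr.ind = TRUE)
  if (!nrow(pos_pairs) || !nrow(neg_pairs))
    stop("fixture spec infeasible: no ",
         if (!nrow(pos_pairs)) "ancestry-related" else "unrelated",
         " concept pairs available", call. = FALSE)
  lab_false <- spec$labels[1]; lab_true <- spec$labels[2]
  corpus <- withr::with_seed(spec$seed + 1L, {
    filler <- make_words(spec$vocab_size, avoid = unlist(
      strsplit(source$concepts$label, " ", fixed = TRUE)))
    cue <- list(filler[1], filler[2])   # cue[[1]] ~ false, cue[[2]] ~ true
    names(cue) <- c(lab_false, lab_true)
    filler <- filler[-(1:2)]
    lines_lab <- character(spec$sentences)
    lines_txt <- character(spec$sentences)
    for (s in seq_len(spec$sentences)) {
      want_pos <- stats::runif(1) < spec$pos_frac
      pair <- if (want_pos) {
        pool <- if (nrow(pos_direct) && nrow(pos_indirect)) {
          if (stats::runif(1) < spec$direct_pos_frac) pos_direct
          else pos_indirect
        } else pos_pairs
        pool[sample.int(nrow(pool), 1L), ]
      } else neg_pairs[sample.int(nrow(neg_pairs), 1L), ]
      is_rel <- pred[pair[1], pair[2]]
      if (stats::runif(1) < spec$epsilon) is_rel <- !is_rel
      gold <- if (is_rel) lab_true else lab_false
      agree <- stats::runif(1) < 0.5 + spec$beta / 2
      cue_tok <- if (agree) cue[[gold]] else
        cue[[setdiff(c(lab_false, lab_true), gold)]]
      pieces <- sample(filler, sample(6:10, 1L), replace = FALSE)
      ents <- sample(c(
        paste0("<e>", lab_of[ids[pair[1]]], "</e>"),
        paste0("<e>", lab_of[ids[pair[2]]], "</e>")))
      extras <- character(0)
      if (stats::runif(1) < spec$extra_mention_frac) {
        k <- sample(1:3, 1L)
        others <- setdiff(seq_len(n), pair)
        extras <- unname(lab_of[ids[sample(others, min(k, length(others)))]])
      }
      ins <- c(ents, cue_tok, extras)
      slots <- sort(sample(seq_len(length(pieces) + 1L), length(ins),
                           replace = TRUE))
      words <- pieces
      for (t in rev(seq_along(ins)))   # insert back to front
        words <- append(words, ins[t], after = slots[t] - 1L)
      lines_lab[s] <- gold
      lines_txt[s] <- paste(c(words, "."), collapse = " ")
    }
    structure(list(examples = data.frame(label = lines_lab,
                                         text = lines_txt,
                                         stringsAsFactors = FALSE),
                   labels = spec$labels),
              class = "re_corpus")
  })
  if (!is.null(path)) write_corpus(corpus, path)
  corpus
}
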