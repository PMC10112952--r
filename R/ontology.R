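#' Load a knowledge source
#'
#' Reads an ontology in OBO 1.2/1.4 flat-file format or a plain TSV triple
#' list and returns a `knowledge_source`: concepts (id, primary label,
#' synonyms), one triple per declared relationship, and an intrinsic
#' information-content score per concept (see [information_content()]).
#'
#' For OBO input every `is_a:` and `relationship:` line of a non-obsolete
#' term becomes one triple (child label, relation, parent label). Obsolete
#' terms are excluded from the concept set and from all triples. A
#' relationship pointing at an undefined term is dropped with a warning.
#' For TSV input the file has three tab-separated columns
#' (head, relation, tail), UTF-8, no header; concept ids are the labels
#' themselves.
#'
#' @param path file path.
#' @param format `"obo"` or `"tsv"`.
#' @param name identifier for the source; defaults to the file base name.
#' @return an object of class `knowledge_source`: list with `name`,
#'   `concepts` (data.frame id/label), `synonyms` (data.frame id/synonym),
#'   `triples` (data.frame head_id/head/relation/tail_id/tail),
#'   `relations` (character), and `ic` (named numeric, one score per
#'   concept id).
#' @seealso [build_lookup()], [information_content()]
#' @export
load_knowledge_source <- function(path, format = c("obo", "tsv"),
                                  name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read knowledge source: ", path, call. = FALSE)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  src <- switch(format,
                obo = parse_obo(path, name),
                tsv = parse_tsv_triples(path, name))
  src$ic <- compute_ic(src)
  class(src) <- "knowledge_source"
  src
}

parse_obo <- function(path, name) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # split into stanzas; only [Term] stanzas carry concepts
  starts <- grep("^\\[", lines)
  if (!length(starts))
    stop("no stanzas found in OBO file: ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(); labels <- character()
  syn_id <- character(); syn_label <- character()
  rel_child <- character(); rel_type <- character(); rel_parent <- character()
  obsolete <- character()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    block <- sub("\\s*!.*$", "", block)   # strip trailing comments
    val <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      trimws(v)
    }
    id <- val("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (length(v <- val("is_obsolete")) && any(v == "true")) {
      obsolete <- c(obsolete, id)
      next
    }
    nm <- val("name")[1]
    if (is.na(nm) || !nzchar(nm)) next
    ids <- c(ids, id); labels <- c(labels, nm)
    for (s in val("synonym")) {
      m <- regmatches(s, regexpr('"(\\\\.|[^"\\\\])*"', s))
      if (length(m)) {
        syn_id <- c(syn_id, id)
        syn_label <- c(syn_label, gsub('\\\\(.)', "\\1",
                                       substr(m, 2L, nchar(m) - 1L)))
      }
    }
    for (p in val("is_a")) {
      rel_child <- c(rel_child, id)
      rel_type <- c(rel_type, "is_a")
      rel_parent <- c(rel_parent, p)
    }
    for (r in val("relationship")) {
      parts <- strsplit(r, "\\s+")[[1]]
      if (length(parts) >= 2L) {
        rel_child <- c(rel_child, id)
        rel_type <- c(rel_type, parts[1])
        rel_parent <- c(rel_parent, parts[2])
      }
    }
  }
  concepts <- data.frame(id = ids, label = labels,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(concepts$id))
    concepts <- concepts[!duplicated(concepts$id), ]
  known <- function(x) x %in% concepts$id
  ok <- known(rel_child) & known(rel_parent)
  if (any(!ok)) {
    bad <- unique(c(rel_child[!known(rel_child)],
                    rel_parent[!known(rel_parent)]))
    warning("dropping ", sum(!ok), " relationship(s) referencing ",
            "undefined or obsolete term(s): ",
            paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  lab <- stats::setNames(concepts$label, concepts$id)
  triples <- data.frame(
    head_id = rel_child[ok],
    head = unname(lab[rel_child[ok]]),
    relation = rel_type[ok],
    tail_id = rel_parent[ok],
    tail = unname(lab[rel_parent[ok]]),
    stringsAsFactors = FALSE)
  list(name = name,
       concepts = concepts,
       synonyms = data.frame(id = syn_id, synonym = syn_label,
                             stringsAsFactors = FALSE),
       triples = triples,
       relations = unique(triples$relation))
}

parse_tsv_triples <- function(path, name) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  if (ncol(df) != 3L)
    stop("TSV triple file must have exactly 3 columns, found ",
         ncol(df), call. = FALSE)
  names(df) <- c("head", "relation", "tail")
  df <- df[nzchar(df$head) & nzchar(df$relation) & nzchar(df$tail), ]
  labels <- unique(c(df$head, df$tail))
  concepts <- data.frame(id = labels, label = labels,
                         stringsAsFactors = FALSE)
  triples <- data.frame(head_id = df$head, head = df$head,
                        relation = df$relation,
                        tail_id = df$tail, tail = df$tail,
                        stringsAsFactors = FALSE)
  list(name = name, concepts = concepts,
       synonyms = data.frame(id = character(), synonym = character(),
                             stringsAsFactors = FALSE),
       triples = triples, relations = unique(triples$relation))
}

# intrinsic IC over the is_a subsumption graph: for each concept,
# -log((descendants + 1) / N) with descendants counted through the
# transitive closure (igraph reachability on child -> parent edges)
compute_ic <- function(src) {
  n <- nrow(src$concepts)
  ic <- stats::setNames(rep(-log(1 / n), n), src$concepts$id)
  isa <- src$triples[src$triples$relation == "is_a", , drop = FALSE]
  if (!nrow(isa)) return(ic)
  g <- igraph::graph_from_data_frame(
    isa[, c("head_id", "tail_id")], directed = TRUE,
    vertices = src$concepts$id)
  if (!igraph::is_dag(g))
    stop("cycle detected in the is_a graph of source '", src$name, "'",
         call. = FALSE)
  # descendants of v = vertices that reach v along is_a edges
  reach <- igraph::subcomponent
  for (v in src$concepts$id) {
    ndesc <- length(reach(g, v, mode = "in")) - 1L
    ic[v] <- -log((ndesc + 1) / n)
  }
  ic
}

#' Intrinsic information content of a concept
#'
#' Specificity score used to rank competing knowledge triples: the
#' intrinsic (descendant-count) information content
#' \deqn{IC(c) = -\log\frac{|\mathrm{desc}(c)| + 1}{N}}
#' where descendants are counted through the transitive closure of the
#' `is_a` hierarchy and \eqn{N} is the number of concepts in the source.
#' Leaves attain the maximum \eqn{-\log(1/N)}; a root from which every
#' concept descends scores 0. Scores are computed once at load time;
#' this accessor simply retrieves them.
#'
#' @param source a `knowledge_source`.
#' @param concept concept id (or vector of ids).
#' @return non-negative numeric score(s).
#' @export
information_content <- function(source, concept) {
  stopifnot(inherits(source, "knowledge_source"))
  missing <- setdiff(concept, names(source$ic))
  if (length(missing))
    stop("unknown concept id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unname(source$ic[concept])
}

#' @export
print.knowledge_source <- function(x, ...) {
  cat("<knowledge_source> '", x$name, "': ", nrow(x$concepts),
      " concepts, ", nrow(x$triples), " triples, relations {",
      paste(x$relations, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Build a surface-form lookup table
#'
#' Maps every normalized concept label (and, optionally, every synonym)
#' of a knowledge source to the triples whose head is that concept,
#' ordered by descending information content of the tail. Two concepts
#' sharing a surface form merge their triple lists.
#'
#' @param source a `knowledge_source`.
#' @param index_synonyms index OBO synonym labels as additional surface
#'   forms (default `TRUE`).
#' @return an object of class `lookup_table`: environment-backed map from
#'   normalized surface form to a data.frame with columns
#'   `source`, `head`, `relation`, `tail`, `tail_id`, `tail_ic`.
#' @seealso [query_surface()], [normalize_surface()]
#' @export
build_lookup <- function(source, index_synonyms = TRUE) {
  stopifnot(inherits(source, "knowledge_source"))
  tr <- source$triples
  tail_ic <- if (nrow(tr)) unname(source$ic[tr$tail_id]) else numeric()
  payload <- data.frame(source = rep(source$name, nrow(tr)),
                        head = tr$head, relation = tr$relation,
                        tail = tr$tail, tail_id = tr$tail_id,
                        tail_ic = tail_ic, stringsAsFactors = FALSE)
  # surface forms: primary label always; synonyms optionally
  forms <- data.frame(id = source$concepts$id,
                      surface = source$concepts$label,
                      stringsAsFactors = FALSE)
  if (index_synonyms && nrow(source$synonyms))
    forms <- rbind(forms, data.frame(id = source$synonyms$id,
                                     surface = source$synonyms$synonym,
                                     stringsAsFactors = FALSE))
  forms$key <- normalize_surface(forms$surface)
  env <- new.env(parent = emptyenv(), hash = TRUE)
  by_head <- split(seq_len(nrow(payload)), tr$head_id)
  for (k in unique(forms$key)) {
    if (!nzchar(k)) next
    ids <- unique(forms$id[forms$key == k])
    rows <- unlist(by_head[ids], use.names = FALSE)
    if (is.null(rows) || !length(rows)) next
    hits <- payload[rows, , drop = FALSE]
    hits <- hits[order(-hits$tail_ic, hits$tail), , drop = FALSE]
    rownames(hits) <- NULL
    assign(k, hits, envir = env)
  }
  structure(list(entries = env, source = source$name,
                 normalization = "lowercase; collapse whitespace; strip surrounding punctuation"),
            class = "lookup_table")
}

#' @export
print.lookup_table <- function(x, ...) {
  cat("<lookup_table> source '", x$source, "': ",
      length(ls(x$entries)), " surface forms (",
      x$normalization, ")\n", sep = "")
  invisible(x)
}

EMPTY_HITS <- data.frame(source = character(), head = character(),
                         relation = character(), tail = character(),
                         tail_id = character(), tail_ic = numeric(),
                         stringsAsFactors = FALSE)

empty_hits <- function() EMPTY_HITS

# lookup with an already-normalized key; hot path for match_spans()
query_norm <- function(tables, key) {
  res <- NULL
  for (tb in tables) {
    if (nzchar(key) && exists(key, envir = tb$entries, inherits = FALSE)) {
      h <- get(key, envir = tb$entries)
      res <- if (is.null(res)) h else rbind(res, h)
    }
  }
  if (is.null(res)) EMPTY_HITS else res
}

#' Query one or more lookup tables for a surface form
#'
#' Performs exactly one lookup per table (one pass over the sentence per
#' knowledge base) and concatenates the per-table results, each row
#' tagged with its source name. An absent form yields zero rows.
#'
#' @param tables a `lookup_table` or list of them.
#' @param surface surface form (normalized internally).
#' @return data.frame with columns `source`, `head`, `relation`, `tail`,
#'   `tail_id`, `tail_ic` (zero rows if unmatched).
#' @export
query_surface <- function(tables, surface) {
  if (inherits(tables, "lookup_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "lookup_table")))
  res <- query_norm(tables, normalize_surface(surface))
  rownames(res) <- NULL
  res
}

#' Serialize lookup tables to a sorted TSV
#'
#' Writes one row per (surface, triple) pair with columns surface,
#' source, head, relation, tail, tail IC, sorted lexicographically for
#' diffability.
#'
#' @param tables list of `lookup_table`.
#' @param path output file.
#' @return invisibly, the data.frame written.
#' @export
write_lookup_tsv <- function(tables, path) {
  if (inherits(tables, "lookup_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    keys <- sort(ls(tb$entries))
    do.call(rbind, lapply(keys, function(k) {
      h <- get(k, envir = tb$entries)
      cbind(surface = rep(k, nrow(h)), h[, c("source", "head", "relation",
                                             "tail", "tail_ic")])
    }))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$surface, df$source, df$head, df$relation, df$tail), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(df)
}
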