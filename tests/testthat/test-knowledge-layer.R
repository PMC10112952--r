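test_that("span enumeration follows the n(n+1)/2 combinatorics", {
  expect_equal(nrow(enumerate_spans(letters[1:10])), 55)
  expect_equal(nrow(enumerate_spans("one")), 1)
  # punctuation separates matchable regions: {a b} , {c d} -> 3 + 3
  sp <- enumerate_spans(c("a", "b", ",", "c", "d"))
  expect_equal(nrow(sp), 6)
  expect_false(any(sp[, "start"] <= 3 & sp[, "end"] >= 3))
  # ordering contract: start ascending, length descending within start
  sp10 <- enumerate_spans(letters[1:4])
  expect_true(!is.unsorted(sp10[, "start"]))
  first <- sp10[sp10[, "start"] == 1, ]
  expect_equal(first[, "end"], c(4L, 3L, 2L, 1L), ignore_attr = TRUE)
})

test_that("entity tags delimit spans and never become tokens", {
  s <- tag_tokenize("<e>dopamine</e> binds the <e>dopamine receptor</e> .",
                    label = "true")
  expect_equal(s$tokens,
               c("dopamine", "binds", "the", "dopamine", "receptor", "."))
  expect_equal(unname(s$entity_spans[1, ]), c(1L, 1L))
  expect_equal(unname(s$entity_spans[2, ]), c(4L, 5L))
  expect_error(tag_tokenize("only <e>one</e> tag pair"), "exactly two")
})

mini_tables <- function() {
  src <- source_from_triples(data.frame(
    h = c("amino", "aralkylamino compound", "dopamine"),
    r = "is_a",
    t = c("group", "organic amino compound", "aralkylamino compound")),
    name = "chem")
  list(build_lookup(src))
}

test_that("longest overlapping match wins in contextual mode", {
  toks <- c("dopamine", "is", "an", "aralkylamino", "compound")
  m <- match_spans(toks, mini_tables(), "contextual")
  spans <- t(vapply(m, function(x) x$span, c(start = 0L, end = 0L)))
  # "aralkylamino compound" (2 tokens) beats its sub-span "amino"... which
  # doesn't even occur as a token here; "dopamine" matches as a singleton
  expect_equal(nrow(spans), 2)
  expect_true(any(spans[, "start"] == 4 & spans[, "end"] == 5))
  tails <- unlist(lapply(m, function(x) x$hits$tail))
  expect_true("organic amino compound" %in% tails)
})

test_that("targeted mode queries only the two candidate entities", {
  s <- tag_tokenize("<e>dopamine</e> resembles aralkylamino compound and <e>amino</e> x .")
  m <- match_spans(s$tokens, mini_tables(), "targeted",
                   entity_spans = s$entity_spans)
  heads <- unlist(lapply(m, function(x) unique(x$hits$head)))
  expect_setequal(heads, c("dopamine", "amino"))
  # the non-entity mention matches only contextually
  mc <- match_spans(s$tokens, mini_tables(), "contextual")
  heads_c <- unlist(lapply(mc, function(x) unique(x$hits$head)))
  expect_true("aralkylamino compound" %in% heads_c)
})

test_that("contextual matching equals the exhaustive greedy oracle", {
  sp <- fixture_spec(concepts = 25, seed = 42, sentences = 1)
  src <- generate_ontology(sp)
  tabs <- list(build_lookup(src))
  for (seed in 1:40) {
    toks <- withr::with_seed(seed, {
      pool <- c(src$concepts$label[sample.int(25, 6)], "qq", "zz", ",",
                "yy")
      unlist(strsplit(sample(pool, 12, replace = TRUE), " ", fixed = TRUE))
    })
    got <- match_spans(toks, tabs, "contextual")
    # oracle: test every span, then keep maximal non-overlapping matched
    # spans (length, then leftmost, then summed tail IC)
    cand <- enumerate_spans(toks)
    hitrows <- list()
    for (i in seq_len(nrow(cand))) {
      h <- query_surface(tabs, paste(toks[cand[i, 1]:cand[i, 2]],
                                     collapse = " "))
      if (nrow(h))
        hitrows[[length(hitrows) + 1]] <-
          c(cand[i, 1], cand[i, 2], sum(h$tail_ic))
    }
    keep <- list()
    if (length(hitrows)) {
      hm <- do.call(rbind, hitrows)
      ord <- order(-(hm[, 2] - hm[, 1]), hm[, 1], -hm[, 3])
      for (r in ord) {
        ok <- !any(vapply(keep, function(k)
          hm[r, 1] <= k[2] && k[1] <= hm[r, 2], logical(1)))
        if (ok) keep[[length(keep) + 1]] <- hm[r, 1:2]
      }
    }
    oracle_spans <- if (length(keep)) {
      m <- do.call(rbind, keep); m[order(m[, 1]), , drop = FALSE]
    } else matrix(numeric(), ncol = 2)
    got_spans <- if (length(got)) {
      t(vapply(got, function(x) as.numeric(x$span), numeric(2)))
    } else matrix(numeric(), ncol = 2)
    expect_equal(unname(got_spans), unname(oracle_spans))
    # maximality: no kept match is a proper sub-span of any matched span
    if (length(hitrows) && length(got)) {
      hm <- do.call(rbind, hitrows)
      for (g in seq_len(nrow(got_spans))) {
        proper_super <- hm[, 1] <= got_spans[g, 1] &
          hm[, 2] >= got_spans[g, 2] &
          (hm[, 2] - hm[, 1]) > (got_spans[g, 2] - got_spans[g, 1])
        expect_false(any(proper_super))
      }
    }
  }
})

test_that("branch caps keep the highest-IC tails", {
  src <- source_from_triples(data.frame(
    h = rep("drug", 3), r = "is_a",
    t = c("role", "chemical entity", "specific chemical")), name = "m")
  # make tails differ in IC by giving them descendants
  tabs <- list(build_lookup(src))
  m <- match_spans(c("drug"), tabs, "contextual")
  capped <- select_branches(m, max_entities = 2)
  expect_equal(nrow(capped[[1]]$hits), 2)
  dropped <- setdiff(m[[1]]$hits$tail, capped[[1]]$hits$tail)
  expect_length(dropped, 1)
  expect_true(all(m[[1]]$hits$tail_ic[m[[1]]$hits$tail == dropped] <=
                    capped[[1]]$hits$tail_ic))
  # cap >= available is the identity
  expect_equal(select_branches(m, 10)[[1]]$hits$tail,
               m[[1]]$hits$tail)
  expect_error(select_branches(m, 0), "max_entities")
})

test_that("cap and IC-ordering hold for every cap in the 2-5 range", {
  sp <- fixture_spec(concepts = 30, seed = 9, sentences = 1)
  src <- generate_ontology(sp)
  tabs <- list(build_lookup(src))
  toks <- unlist(strsplit(src$concepts$label[1:8], " ", fixed = TRUE))
  m <- match_spans(toks, tabs, "contextual")
  for (cap in 2:5) {
    capped <- select_branches(m, cap)
    for (i in seq_along(capped)) {
      expect_lte(nrow(capped[[i]]$hits), cap)
      kept <- capped[[i]]$hits
      pool <- m[[i]]$hits[!duplicated(m[[i]]$hits[, c("head", "relation",
                                                      "tail")]), ]
      drop <- pool[!(paste(pool$relation, pool$tail) %in%
                       paste(kept$relation, kept$tail)), ]
      if (nrow(drop))
        expect_lte(max(drop$tail_ic), min(kept$tail_ic))
    }
  }
  # monotonicity: raising the cap never removes a kept branch
  prev <- NULL
  for (cap in 2:5) {
    now <- lapply(select_branches(m, cap), function(x)
      paste(x$hits$head, x$hits$tail))
    if (!is.null(prev))
      for (i in seq_along(now)) expect_true(all(prev[[i]] %in% now[[i]]))
    prev <- now
  }
})

test_that("sentence trees compose matching, capping and tokenization", {
  do_like <- source_from_triples(data.frame(
    h = "seizure", r = "is_a", t = "abnormal nervous system physiology"),
    name = "do")
  chebi_like <- source_from_triples(data.frame(
    h = "venlafaxine", r = "is_a", t = "organic amino compound"),
    name = "chebi")
  tabs <- list(build_lookup(chebi_like), build_lookup(do_like))
  s <- tag_tokenize(
    "<e>venlafaxine</e> may provoke a <e>seizure</e> in patients .",
    label = "effect")
  tree <- build_sentence_tree(s, tabs, mode = "targeted", max_entities = 3)
  expect_length(tree$anchors, 2)
  b1 <- tree$anchors[[1]]$branches[[1]]
  b2 <- tree$anchors[[2]]$branches[[1]]
  expect_equal(b1$tokens, c("is_a", "organic amino compound"))
  expect_equal(b2$tokens, c("is_a", "abnormal nervous system physiology"))
  # split_tails recovers whitespace tokenization of the tail
  tree_split <- build_sentence_tree(s, tabs, mode = "targeted",
                                    split_tails = TRUE)
  expect_equal(tree_split$anchors[[2]]$branches[[1]]$tokens,
               c("is_a", "abnormal", "nervous", "system", "physiology"))
  # empty tables -> branchless tree; trunk always preserved
  bare <- build_sentence_tree(s, list(), mode = "none")
  expect_length(bare$anchors, 0)
  expect_equal(bare$trunk, s$tokens)
  expect_equal(tree$trunk, s$tokens)
})

test_that("retained entity delimiters are punctuation-class bystanders", {
  s <- tag_tokenize("<e>dopamine</e> binds the <e>receptor</e> .",
                    keep_markers = TRUE)
  expect_length(s$tokens, 9)
  expect_equal(s$tokens[s$entity_spans[1, 1]], "dopamine")
  expect_equal(s$tokens[s$entity_spans[2, 1]], "receptor")
  # sentinels are punctuation, so they never enter any candidate span
  sent <- s$tokens[c(1, 3)]
  expect_true(all(is_punct_token(sent)))
  m <- match_spans(s$tokens, mini_tables(), "contextual")
  for (x in m)
    expect_false(any(is_punct_token(s$tokens[x$span[1]:x$span[2]])))
})

test_that("contextual trees anchor more entities than targeted ones", {
  src <- source_from_triples(data.frame(
    h = c("prazosin", "terodiline", "ventricular arrhythmia"),
    r = "is_a",
    t = c("antihypertensive", "vasodilator", "heart disorder")),
    name = "m")
  tabs <- list(build_lookup(src))
  s <- tag_tokenize(paste("<e>ventricular arrhythmia</e> risk rises when",
                          "<e>prazosin</e> is combined with terodiline ."))
  t_tree <- build_sentence_tree(s, tabs, mode = "targeted")
  c_tree <- build_sentence_tree(s, tabs, mode = "contextual")
  expect_length(t_tree$anchors, 2)
  expect_length(c_tree$anchors, 3)
})
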