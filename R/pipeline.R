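#' Read a relation-extraction corpus
#'
#' Parses a two-column TSV (label, sentence) where each sentence carries
#' exactly one pair of candidate entities delimited by `<e>`/`</e>`.
#' Malformed lines (wrong column count, tag count other than two pairs,
#' or - when a label set is supplied - an unknown label) are collected
#' into an error report attached as the `"errors"` attribute; valid lines
#' are kept. A file with zero valid lines is an error.
#'
#' @param path TSV file, UTF-8, optional `label<TAB>sentence` header.
#' @param labels optional ordered label set; defaults to the sorted
#'   labels observed.
#' @return object of class `re_corpus`: list with `examples` (data.frame
#'   `label`, `text`) and `labels`.
#' @export
read_corpus <- function(path, labels = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(tolower(lines[1]), "label\tsentence"))
    lines <- lines[-1]
  errs <- data.frame(line = integer(), reason = character(),
                     stringsAsFactors = FALSE)
  keep_lab <- character(); keep_txt <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      errs <- rbind(errs, data.frame(line = i, reason = "not 2 columns"))
      next
    }
    lab <- trimws(parts[1]); txt <- parts[2]
    n_open  <- lengths(regmatches(txt, gregexpr("<e>",  txt, fixed = TRUE)))
    n_close <- lengths(regmatches(txt, gregexpr("</e>", txt, fixed = TRUE)))
    if (n_open != 2L || n_close != 2L) {
      errs <- rbind(errs, data.frame(
        line = i, reason = sprintf("expected 2 <e>...</e> pairs, found %d/%d",
                                   n_open, n_close)))
      next
    }
    if (!is.null(labels) && !(lab %in% labels)) {
      errs <- rbind(errs, data.frame(
        line = i, reason = paste0("unknown label '", lab, "'")))
      next
    }
    keep_lab <- c(keep_lab, lab); keep_txt <- c(keep_txt, txt)
  }
  if (!length(keep_lab))
    stop("no valid examples in ", path, call. = FALSE)
  corpus <- structure(
    list(examples = data.frame(label = keep_lab, text = keep_txt,
                               stringsAsFactors = FALSE),
         labels = if (is.null(labels)) sort(unique(keep_lab)) else labels),
    class = "re_corpus")
  attr(corpus, "errors") <- errs
  corpus
}

#' Write a relation-extraction corpus
#'
#' @param corpus an `re_corpus`.
#' @param path output TSV.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(paste(corpus$examples$label, corpus$examples$text,
                   sep = "\t"),
             file(path, encoding = "UTF-8"))
  invisible(path)
}

#' @export
print.re_corpus <- function(x, ...) {
  cat("<re_corpus> ", nrow(x$examples), " examples, labels {",
      paste(x$labels, collapse = ", "), "}\n", sep = "")
  print(table(x$examples$label))
  invisible(x)
}

subset_corpus <- function(corpus, idx) {
  structure(list(examples = corpus$examples[idx, , drop = FALSE],
                 labels = corpus$labels),
            class = "re_corpus")
}

#' Split a corpus into train / validation / test
#'
#' Label-stratified, seeded, disjoint and exhaustive partition, 60/10/30
#' by default. Per-label quotas use largest-remainder rounding, and a
#' final adjustment pass makes the global split sizes match the same
#' rounding of the corpus size, so 100 examples at 0.6/0.1/0.3 always
#' give 60/10/30. A label with fewer examples than splits is assigned
#' round-robin with a warning.
#'
#' @param corpus an `re_corpus`.
#' @param fractions length-3 numeric summing to 1 (train, validation,
#'   test).
#' @param seed integer seed.
#' @return named list of `re_corpus`: `train`, `validation`, `test`.
#' @export
split_corpus <- function(corpus, fractions = c(0.6, 0.1, 0.3), seed = 1L) {
  stopifnot(length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  n <- nrow(corpus$examples)
  largest_remainder <- function(total, frac) {
    raw <- total * frac
    base <- floor(raw)
    extra <- total - sum(base)
    if (extra > 0) {
      ord <- order(raw - base, decreasing = TRUE)
      base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
    }
    as.integer(base)
  }
  target <- largest_remainder(n, fractions)
  assign <- integer(n)
  withr::with_seed(seed, {
    for (lab in corpus$labels) {
      idx <- which(corpus$examples$label == lab)
      if (!length(idx)) next
      idx <- sample(idx)
      if (length(idx) < 3L)
        warning("label '", lab, "' has fewer examples (", length(idx),
                ") than splits; assigning round-robin", call. = FALSE)
      quota <- largest_remainder(length(idx), fractions)
      assign[idx] <- rep.int(1:3, quota)
    }
    # reconcile per-label rounding with the global targets
    sizes <- tabulate(assign, 3L)
    for (s in 1:3) {
      while (sizes[s] > target[s]) {
        d <- which(sizes < target)[1]
        pool <- which(assign == s)
        mv <- pool[sample.int(length(pool), 1L)]
        assign[mv] <- d
        sizes[s] <- sizes[s] - 1L; sizes[d] <- sizes[d] + 1L
      }
    }
  })
  list(train = subset_corpus(corpus, assign == 1L),
       validation = subset_corpus(corpus, assign == 2L),
       test = subset_corpus(corpus, assign == 3L))
}

#' Inverse-frequency class weights
#'
#' For label counts \eqn{n_c} over \eqn{N} training examples and \eqn{L}
#' labels, \eqn{w_c = N / (L \, n_c)}: rare labels are up-weighted and
#' the expected weight of a random training example is exactly 1
#' (\eqn{\sum_c n_c w_c = N}), normalizing the differing label
#' distributions of RE corpora.
#'
#' @param corpus an `re_corpus` (the training split) or a character
#'   vector of labels.
#' @param labels label set; required when `corpus` is a bare vector.
#' @return named numeric vector of weights, one per label.
#' @export
compute_class_weights <- function(corpus, labels = NULL) {
  if (inherits(corpus, "re_corpus")) {
    labels <- corpus$labels
    obs <- corpus$examples$label
  } else obs <- corpus
  stopifnot(!is.null(labels))
  counts <- vapply(labels, function(l) sum(obs == l), numeric(1))
  if (any(counts == 0))
    stop("label(s) absent from the training split: ",
         paste(labels[counts == 0], collapse = ", "), call. = FALSE)
  N <- length(obs); L <- length(labels)
  stats::setNames(N / (L * counts), labels)
}

#' Encode a corpus into model-ready flattened inputs
#'
#' Tokenizes each tagged sentence, expands it into a sentence tree under
#' the given injection mode, flattens, assigns soft positions, computes
#' the visible matrix and enforces `max_len` branch-first.
#'
#' @param corpus an `re_corpus`.
#' @param tables list of `lookup_table` (may be empty for
#'   `mode = "none"`).
#' @param mode `"targeted"`, `"contextual"` or `"none"` (no knowledge).
#' @param max_entities branch cap per anchor.
#' @param max_len maximum sequence length.
#' @param keep_markers retain entity-delimiter sentinel tokens in the
#'   trunk (see [tag_tokenize()]).
#' @return list of `flat_input`.
#' @export
encode_corpus <- function(corpus, tables = list(), mode = "none",
                          max_entities = 3, max_len = 64L,
                          keep_markers = FALSE) {
  lapply(seq_len(nrow(corpus$examples)), function(i) {
    s <- tag_tokenize(corpus$examples$text[i], corpus$examples$label[i],
                      keep_markers = keep_markers)
    tree <- build_sentence_tree(s, tables, mode = mode,
                                max_entities = max_entities)
    flat <- encode_tree(tree)
    if (nrow(flat$layout) > max_len)
      flat <- truncate_pad(flat, max_len, tree)
    flat
  })
}

#' Train the relation classifier
#'
#' Applies knowledge injection identically to the train, validation and
#' test splits, then runs a class-weighted training loop (Adam with
#' linear warmup and decay, batch size 32 by default) selecting the
#' epoch with the best validation weighted F-measure. Fully
#' deterministic under a fixed seed. With `epochs = 0` the freshly
#' initialized model is returned untouched.
#'
#' @param splits list with `train`, `validation`, `test` (`re_corpus`),
#'   as from [split_corpus()].
#' @param tables list of `lookup_table`.
#' @param mode injection mode: `"targeted"`, `"contextual"` or `"none"`.
#' @param max_entities knowledge entities injected per anchor (2-5
#'   typical).
#' @param config a `model_config`; `vocab_size` is overwritten with the
#'   size of the vocabulary built from the (injected) training split.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr peak learning rate.
#' @param seed seed for initialization, shuffling and dropout; defaults
#'   to `config$seed`.
#' @param precomputed optional list with `train`, `validation`, `test`
#'   elements of pre-encoded `flat_input` lists (as produced by
#'   [encode_corpus()] under the same injection settings), to avoid
#'   re-encoding when training several seeds on one corpus.
#' @param keep_markers retain entity-delimiter sentinels in the encoded
#'   trunk so the classifier can identify the candidate pair (default
#'   `FALSE`; ignored when `precomputed` is given).
#' @param ema_decay per-step exponential moving average of the weights
#'   (Polyak averaging); the averaged weights are what validation scores
#'   and the returned model use. Stabilizes the noisy end of short
#'   training runs. `0` disables.
#' @return object of class `re_model`: `params`, `config`, `vocab`,
#'   `labels`, `mode`, `max_entities`, `log` (per-epoch data.frame with
#'   train loss and validation weighted F), and `test` (the encoded test
#'   split, for convenience).
#' @export
train_model <- function(splits, tables = list(), mode = "none",
                        max_entities = 3, config, epochs = 20L,
                        batch_size = 32L, lr = 5e-4, seed = NULL,
                        precomputed = NULL, keep_markers = FALSE,
                        ema_decay = 0.995) {
  stopifnot(inherits(config, "model_config"))
  if (is.null(seed)) seed <- config$seed
  labels <- splits$train$labels
  enc <- if (!is.null(precomputed)) precomputed
  else lapply(splits[c("train", "validation", "test")], encode_corpus,
              tables = tables, mode = mode,
              max_entities = max_entities, max_len = config$max_len,
              keep_markers = keep_markers)
  vocab <- build_vocab(lapply(enc$train, function(f) f$layout$token))
  cfg <- config
  cfg$vocab_size <- length(vocab)
  cfg$seed <- as.integer(seed)
  n_tr <- length(enc$train)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_wf = numeric())
  model <- NULL
  withr::with_seed(cfg$seed, {
    params <- init_params(cfg)
    best <- list(params = params, wf = -Inf)
    if (epochs > 0L) {
      opt <- adam_init(params)
      ema <- if (ema_decay > 0) params else NULL
      total_steps <- epochs * ceiling(n_tr / batch_size)
      step <- 0L
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n_tr)
        losses <- numeric()
        for (b0 in seq(1L, n_tr, by = batch_size)) {
          take <- ord[b0:min(b0 + batch_size - 1L, n_tr)]
          bt <- prepare_batch(enc$train[take], vocab, labels)
          fwd <- encoder_forward(params, cfg, bt$ids, bt$soft, bt$masks,
                                 training = TRUE, keep_cache = TRUE)
          ls <- weighted_loss(fwd$logits, bt$gold, cfg$class_weights)
          grads <- encoder_backward(params, cfg, fwd, ls$dscores)
          step <- step + 1L
          upd <- adam_step(params, grads, opt,
                           lr_schedule(step, total_steps, lr))
          params <- upd$params; opt <- upd$state
          if (!is.null(ema))
            for (tn in names(params))
              ema[[tn]] <- ema_decay * ema[[tn]] +
                (1 - ema_decay) * params[[tn]]
          losses <- c(losses, ls$loss)
        }
        eval_params <- if (is.null(ema)) params else ema
        val_pred <- predict_flats(eval_params, cfg, vocab,
                                  enc$validation, batch_size)
        val_gold <- vapply(enc$validation, function(f) f$label,
                           character(1))
        wf <- evaluate(labels[val_pred], val_gold, labels)$weighted[["f1"]]
        log <- rbind(log, data.frame(epoch = ep,
                                     train_loss = mean(losses),
                                     val_wf = wf))
        if (wf > best$wf) best <- list(params = eval_params, wf = wf)
      }
    }
    model <- structure(
      list(params = best$params, config = cfg, vocab = vocab,
           labels = labels, mode = mode, max_entities = max_entities,
           log = log, test = enc$test),
      class = "re_model")
  })
  model
}

predict_flats <- function(params, config, vocab, flats, batch_size = 32L) {
  n <- length(flats)
  out <- integer(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    take <- b0:min(b0 + batch_size - 1L, n)
    logits <- forward_classify(flats[take], params, config, vocab)
    out[take] <- max.col(logits, ties.method = "first")
  }
  out
}

#' Predict relation labels
#'
#' @param object an `re_model`.
#' @param flats list of `flat_input` (e.g. `object$test`, or a corpus
#'   encoded with [encode_corpus()] under the model's injection mode).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.re_model <- function(object, flats = object$test, ...) {
  idx <- predict_flats(object$params, object$config, object$vocab, flats)
  object$labels[idx]
}

#' @export
print.re_model <- function(x, ...) {
  cat("<re_model> mode=", x$mode, ", ", x$config$layers, " layers, ",
      x$config$heads, " heads, hidden ", x$config$hidden,
      ", vocab ", length(x$vocab), ", labels {",
      paste(x$labels, collapse = ", "), "}\n", sep = "")
  if (nrow(x$log))
    cat("  best val weighted F: ", sprintf("%.4f", max(x$log$val_wf)),
        " (epoch ", x$log$epoch[which.max(x$log$val_wf)], ")\n", sep = "")
  invisible(x)
}

#' Weighted evaluation of relation predictions
#'
#' Per-label precision, recall, F-measure and support from the confusion
#' matrix, plus support-weighted averages (accounting for the label
#' imbalance typical of RE corpora) and accuracy. A label with no
#' predicted (or no gold) instances scores 0 for the undefined metric.
#'
#' @param predictions character vector of predicted labels.
#' @param gold character vector of gold labels (same length).
#' @param labels ordered label set.
#' @return object of class `eval_report`: list with `per_label`
#'   (data.frame), `weighted` (named numeric precision/recall/f1),
#'   `accuracy` and `support`.
#' @export
evaluate <- function(predictions, gold, labels) {
  stopifnot(length(predictions) == length(gold))
  if (!length(gold)) stop("nothing to evaluate", call. = FALSE)
  pred <- factor(predictions, levels = labels)
  gld <- factor(gold, levels = labels)
  cm <- table(gold = gld, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- as.numeric(rowSums(cm))
  wts <- support / sum(support)
  structure(list(
    per_label = data.frame(label = labels, precision = as.numeric(prec),
                           recall = as.numeric(rec), f1 = as.numeric(f1),
                           support = support, stringsAsFactors = FALSE),
    weighted = c(precision = sum(wts * prec), recall = sum(wts * rec),
                 f1 = sum(wts * f1)),
    accuracy = sum(tp) / sum(cm),
    support = sum(support)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n=", x$support, "\n", sep = "")
  print(x$per_label, row.names = FALSE, digits = 4)
  cat(sprintf("weighted: P %.4f  R %.4f  F %.4f   accuracy %.4f\n",
              x$weighted[["precision"]], x$weighted[["recall"]],
              x$weighted[["f1"]], x$accuracy))
  invisible(x)
}

#' One-tailed significance test between two sets of runs
#'
#' Welch's unequal-variance t-test of the hypothesis that the mean score
#' of `runs_b` exceeds that of `runs_a` (one-sided), comparing run-level
#' F-measures (or any score) across repeated seeded runs. Degenerate
#' inputs with zero variance on both sides return 0.5 for equal means
#' and 0 / 1 for a strictly higher / lower mean of `runs_b`.
#'
#' @param runs_a numeric scores of the reference system (>= 2 runs).
#' @param runs_b numeric scores of the compared system (>= 2 runs).
#' @return one-sided p-value for mean(b) > mean(a).
#' @export
significance <- function(runs_a, runs_b) {
  stopifnot(length(runs_a) >= 2L, length(runs_b) >= 2L)
  if (stats::sd(runs_a) < 1e-12 && stats::sd(runs_b) < 1e-12) {
    d <- mean(runs_b) - mean(runs_a)
    return(if (abs(d) < 1e-12) 0.5 else if (d > 0) 0 else 1)
  }
  stats::t.test(runs_b, runs_a, alternative = "greater",
                var.equal = FALSE)$p.value
}
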