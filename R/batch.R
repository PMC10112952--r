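#' Build a token vocabulary
#'
#' Special tokens `[PAD]`, `[UNK]`, `[CLS]` occupy the first three ids;
#' remaining tokens are ordered by descending frequency then
#' alphabetically. Unknown tokens map to `[UNK]` at encoding time.
#'
#' @param token_lists list of character vectors (one per example).
#' @param min_count drop tokens seen fewer times (default 1 = keep all).
#' @return character vector; position = token id.
#' @export
build_vocab <- function(token_lists, min_count = 1L) {
  tab <- table(unlist(token_lists, use.names = FALSE))
  tab <- tab[!(names(tab) %in% c(PAD_TOKEN, UNK_TOKEN, CLS_TOKEN))]
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  c(PAD_TOKEN, UNK_TOKEN, CLS_TOKEN, names(tab)[ord])
}

token_ids <- function(tokens, vocab) {
  id <- match(tokens, vocab)
  id[is.na(id)] <- match(UNK_TOKEN, vocab)
  id
}

# Pad a list of flat_input to a common length and assemble the matrices
# the encoder consumes. Padding positions are invisible both ways (their
# own diagonal stays visible so softmax is well defined).
prepare_batch <- function(flats, vocab, labels = NULL) {
  B <- length(flats)
  lens <- vapply(flats, function(f) nrow(f$layout), integer(1))
  L <- max(lens)
  ids <- matrix(match(PAD_TOKEN, vocab), B, L)
  soft <- matrix(0L, B, L)
  masks <- vector("list", B)
  for (e in seq_len(B)) {
    f <- flats[[e]]; n <- lens[e]
    ids[e, seq_len(n)] <- token_ids(f$layout$token, vocab)
    soft[e, seq_len(n)] <- f$soft
    M <- matrix(NEG_INF, L, L)
    vis <- f$visible
    if (is.null(vis)) stop("flat_input lacks a visible matrix",
                           call. = FALSE)
    Mn <- matrix(NEG_INF, n, n)
    Mn[vis] <- 0
    M[seq_len(n), seq_len(n)] <- Mn
    diag(M) <- 0
    masks[[e]] <- M
  }
  gold <- NULL
  if (!is.null(labels)) {
    gold <- match(vapply(flats, function(f) f$label, character(1)), labels)
    if (anyNA(gold))
      stop("example label not in the model label set", call. = FALSE)
  }
  list(ids = ids, soft = soft, masks = masks, gold = gold)
}

#' Classify a batch of flattened inputs
#'
#' Runs the full encoder - token + soft-position + segment embeddings,
#' `layers` blocks of mask-self-attention and feed-forward with residuals
#' and layer normalization - and reads per-label scores from the
#' classification position. Deterministic given fixed weights (dropout is
#' off outside training).
#'
#' @param flats list of `flat_input` (visible matrices computed; lengths
#'   at most `config$max_len`).
#' @param params parameter list from [init_params()] or training.
#' @param config the `model_config`.
#' @param vocab vocabulary from [build_vocab()].
#' @return numeric matrix of unnormalized per-label scores, one row per
#'   input.
#' @export
forward_classify <- function(flats, params, config, vocab) {
  lens <- vapply(flats, function(f) nrow(f$layout), integer(1))
  if (any(lens > config$max_len))
    stop("sequence longer than max_len; run truncate_pad() first",
         call. = FALSE)
  b <- prepare_batch(flats, vocab)
  encoder_forward(params, config, b$ids, b$soft, b$masks,
                  training = FALSE)$logits
}

#' Save encoder weights as a checkpoint
#'
#' Stores the named tensor list together with a shape manifest.
#'
#' @param params parameter list.
#' @param config the `model_config`.
#' @param path output file.
#' @export
save_checkpoint <- function(params, config, path) {
  manifest <- lapply(params, function(x)
    if (is.matrix(x)) dim(x) else length(x))
  saveRDS(list(params = params, manifest = manifest, config = config),
          path)
  invisible(path)
}

#' Load a checkpoint into a model configuration
#'
#' Tensors whose names and shapes match the target layout are loaded;
#' tensors absent from the checkpoint (e.g. a classification head saved
#' for a different label set) are freshly initialized from the
#' configuration seed, and both groups are reported. A present tensor
#' with a mismatched shape is an error naming the tensor.
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param config target `model_config`.
#' @return list with `params`, `loaded` (tensor names), `initialized`
#'   (tensor names) and `ignored` (checkpoint tensors with no target).
#' @export
load_checkpoint <- function(path, config) {
  ck <- readRDS(path)
  target <- init_params(config)
  shape <- function(x) if (is.matrix(x)) dim(x) else length(x)
  loaded <- character(); inited <- character()
  for (nm in names(target)) {
    if (nm %in% names(ck$params)) {
      if (!identical(shape(ck$params[[nm]]), shape(target[[nm]])))
        stop("shape mismatch for tensor '", nm, "': checkpoint ",
             paste(shape(ck$params[[nm]]), collapse = "x"),
             " vs target ", paste(shape(target[[nm]]), collapse = "x"),
             call. = FALSE)
      target[[nm]] <- ck$params[[nm]]
      loaded <- c(loaded, nm)
    } else {
      inited <- c(inited, nm)
    }
  }
  list(params = target, loaded = loaded, initialized = inited,
       ignored = setdiff(names(ck$params), names(target)))
}
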