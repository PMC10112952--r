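CLS_TOKEN <- "[CLS]"
PAD_TOKEN <- "[PAD]"
UNK_TOKEN <- "[UNK]"

#' Flatten a sentence tree into model input order
#'
#' Produces the token sequence fed to the encoder: a classification token
#' at hard position 0, then the trunk tokens in order, with each anchor's
#' branches inserted immediately after the anchor's last token (branches
#' in their kept order, each branch as relation token then tail tokens).
#' Hard positions are the 0-based indices of this flattened order; soft
#' positions are left unfilled (see [assign_soft_positions()]).
#'
#' @param tree a `sentence_tree`.
#' @param add_cls prepend the classification token (default `TRUE`).
#' @return object of class `flat_input`: list with `layout` (data.frame:
#'   `token`, `kind` in cls/trunk/branch/pad, `trunk_idx`, `anchor`,
#'   `branch`, `branch_pos`, `ic`), `soft` (`NULL` until assigned),
#'   `visible` (`NULL` until computed), `segment` (all `"A"`) and
#'   `label`.
#' @export
flatten_tree <- function(tree, add_cls = TRUE) {
  stopifnot(inherits(tree, "sentence_tree"))
  tok <- character(0); kind <- character(0)
  trunk_idx <- integer(0); anchor <- integer(0)
  branch <- integer(0); branch_pos <- integer(0); ic <- numeric(0)
  add <- function(t, k, ti = NA_integer_, a = NA_integer_,
                  b = NA_integer_, bp = NA_integer_, bic = NA_real_) {
    m <- length(t)
    tok <<- c(tok, t); kind <<- c(kind, rep(k, m))
    trunk_idx <<- c(trunk_idx, rep(ti, m))
    anchor <<- c(anchor, rep(a, m)); branch <<- c(branch, rep(b, m))
    branch_pos <<- c(branch_pos, if (is.na(bp)) seq_len(m) else bp)
    ic <<- c(ic, rep(bic, m))
  }
  if (add_cls) add(CLS_TOKEN, "cls", ti = 0L, bp = 0L)
  anchor_end <- vapply(tree$anchors, function(a) a$span[["end"]],
                       integer(1))
  for (i in seq_along(tree$trunk)) {
    add(tree$trunk[i], "trunk", ti = i, bp = 0L)
    for (a in which(anchor_end == i)) {
      br <- tree$anchors[[a]]$branches
      for (b in seq_along(br))
        add(br[[b]]$tokens, "branch", a = a, b = b, bic = br[[b]]$ic)
    }
  }
  layout <- data.frame(token = tok, kind = kind, trunk_idx = trunk_idx,
                       anchor = anchor, branch = branch,
                       branch_pos = branch_pos, ic = ic,
                       stringsAsFactors = FALSE)
  structure(list(layout = layout, soft = NULL, visible = NULL,
                 segment = rep("A", nrow(layout)),
                 label = tree$label, add_cls = add_cls,
                 n_trunk = length(tree$trunk)),
            class = "flat_input")
}

#' Assign soft (tree) positions to a flattened input
#'
#' Trunk tokens keep their sentence positions; each branch continues the
#' numbering from its anchor's last trunk token, incrementing along the
#' branch, and distinct branches of one anchor restart at the same
#' offset. Trunk tokens after an anchor keep their trunk positions, so a
#' soft position may legitimately appear both in the trunk and in a
#' branch. The classification token sits at soft position 0 and trunk
#' numbering starts at 1 (at 0 without it), so a branchless tree has
#' `soft == hard` everywhere.
#'
#' @param tree the originating `sentence_tree`.
#' @param flat the `flat_input` from [flatten_tree()].
#' @return `flat` with `soft` filled (0-based integer vector).
#' @export
assign_soft_positions <- function(tree, flat) {
  stopifnot(inherits(flat, "flat_input"))
  lay <- flat$layout
  off <- as.integer(isTRUE(flat$add_cls))
  trunk_soft <- function(ti) ti - 1L + off   # ti is 1-based trunk index
  soft <- integer(nrow(lay))
  anchor_end <- vapply(tree$anchors, function(a) a$span[["end"]],
                       integer(1))
  for (r in seq_len(nrow(lay))) {
    soft[r] <- switch(lay$kind[r],
      cls = 0L,
      trunk = trunk_soft(lay$trunk_idx[r]),
      branch = trunk_soft(anchor_end[lay$anchor[r]]) + lay$branch_pos[r],
      pad = 0L)
  }
  flat$soft <- soft
  flat
}

# pairwise visibility from layout columns alone
visibility_from_layout <- function(lay, anchors) {
  n <- nrow(lay)
  v <- matrix(FALSE, n, n)
  kind <- lay$kind
  core <- kind %in% c("cls", "trunk")    # the original sentence path
  v[core, core] <- TRUE
  if (any(kind == "branch")) {
    span_of <- function(a) anchors[[a]]$span
    for (i in which(kind == "branch")) {
      a <- lay$anchor[i]; b <- lay$branch[i]
      sp <- span_of(a)
      mates <- kind == "branch" & lay$anchor == a & lay$branch == b
      in_anchor <- kind == "trunk" &
        !is.na(lay$trunk_idx) & lay$trunk_idx >= sp[1] & lay$trunk_idx <= sp[2]
      vis <- mates | in_anchor
      v[i, ] <- vis
      v[, i] <- vis
    }
  }
  diag(v) <- TRUE
  if (any(kind == "pad")) {
    pad <- kind == "pad"
    v[pad, ] <- FALSE
    v[, pad] <- FALSE
    diag(v) <- TRUE
  }
  v
}

#' Compute the visible matrix of a flattened sentence tree
#'
#' The seeing layer: a square boolean matrix over hard positions that
#' prevents injected knowledge from altering the meaning of the rest of
#' the sentence. Trunk tokens all see each other; a branch token sees
#' only its own branch's tokens and the trunk tokens of its anchor span;
#' everything else is mutually invisible. Branches of the same anchor do
#' not see each other (each branch is a separate tree path), and the
#' classification token, being part of the sentence path, is invisible to
#' branch tokens. The matrix is symmetric with a true diagonal.
#'
#' @param tree the originating `sentence_tree`.
#' @param flat the `flat_input` from [flatten_tree()].
#' @return `flat` with `visible` filled (logical matrix).
#' @export
visible_matrix <- function(tree, flat) {
  stopifnot(inherits(flat, "flat_input"))
  flat$visible <- visibility_from_layout(flat$layout, tree$anchors)
  flat
}

#' Truncate or pad a flattened input to a fixed length
#'
#' Overlong sequences are cut branch-first: whole branches are dropped in
#' ascending order of tail information content (least informative first)
#' until the sequence fits, and only then is the trunk truncated from the
#' tail (the classification token is always kept). Short sequences are
#' padded with a PAD token that is invisible to and from every real
#' token. Soft positions and the visible matrix are re-derived
#' consistently.
#'
#' @param flat a `flat_input` with soft positions assigned.
#' @param max_len target length (>= 1).
#' @param tree the originating `sentence_tree` (for visibility
#'   recomputation).
#' @return a `flat_input` whose layout has exactly `max_len` rows.
#' @export
truncate_pad <- function(flat, max_len, tree) {
  stopifnot(inherits(flat, "flat_input"), max_len >= 1L)
  lay <- flat$layout
  soft <- flat$soft
  if (is.null(soft)) stop("assign_soft_positions() must run first",
                          call. = FALSE)
  # drop whole branches, least informative first
  while (nrow(lay) > max_len && any(lay$kind == "branch")) {
    br <- unique(lay[lay$kind == "branch",
                     c("anchor", "branch", "ic"), drop = FALSE])
    br <- br[order(br$ic, -br$anchor, -br$branch), , drop = FALSE]
    drop <- lay$kind == "branch" & lay$anchor == br$anchor[1] &
      lay$branch == br$branch[1]
    lay <- lay[!drop, , drop = FALSE]
    soft <- soft[!drop]
  }
  if (nrow(lay) > max_len) {           # truncate trunk tail
    keep <- seq_len(max_len)
    lay <- lay[keep, , drop = FALSE]
    soft <- soft[keep]
  }
  n_pad <- max_len - nrow(lay)
  if (n_pad > 0L) {
    pad <- data.frame(token = rep(PAD_TOKEN, n_pad), kind = "pad",
                      trunk_idx = NA_integer_, anchor = NA_integer_,
                      branch = NA_integer_, branch_pos = NA_integer_,
                      ic = NA_real_, stringsAsFactors = FALSE)
    lay <- rbind(lay, pad)
    soft <- c(soft, rep(0L, n_pad))
  }
  rownames(lay) <- NULL
  flat$layout <- lay
  flat$soft <- soft
  flat$segment <- rep("A", nrow(lay))
  flat$visible <- visibility_from_layout(lay, tree$anchors)
  flat
}

#' Encode a sentence tree end to end
#'
#' Convenience composition of [flatten_tree()], [assign_soft_positions()],
#' [visible_matrix()] and (optionally) [truncate_pad()].
#'
#' @param tree a `sentence_tree`.
#' @param max_len fixed length, or `NULL` to keep the natural length.
#' @param add_cls prepend the classification token.
#' @return a ready `flat_input`.
#' @export
encode_tree <- function(tree, max_len = NULL, add_cls = TRUE) {
  flat <- flatten_tree(tree, add_cls = add_cls)
  flat <- assign_soft_positions(tree, flat)
  flat <- visible_matrix(tree, flat)
  if (!is.null(max_len)) flat <- truncate_pad(flat, max_len, tree)
  flat
}

#' @export
print.flat_input <- function(x, ...) {
  cat("<flat_input> ", nrow(x$layout), " tokens, label=", x$label,
      "\n  ", paste(x$layout$token, collapse = " "), "\n", sep = "")
  if (!is.null(x$soft))
    cat("  soft: ", paste(x$soft, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Serialize flattened inputs to line-delimited records
#'
#' One JSON record per line: tokens, soft positions, segment tags, label
#' and a run-length encoding of the row-major visible matrix, decoupling
#' the injection stage from the model stage.
#'
#' @param flats list of `flat_input` (visible matrices computed).
#' @param path output file.
#' @export
write_flattened <- function(flats, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (f in flats) {
    r <- rle(as.logical(t(f$visible)))
    rec <- list(tokens = f$layout$token, soft = f$soft,
                segment = f$segment, label = f$label,
                vis_lengths = r$lengths, vis_values = r$values)
    writeLines(jsonlite::toJSON(rec, auto_unbox = FALSE), con)
  }
  invisible(path)
}

#' Read flattened inputs written by [write_flattened()]
#'
#' @param path input file.
#' @return list of records with `tokens`, `soft`, `segment`, `label`,
#'   `visible` (logical matrix).
#' @export
read_flattened <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    n <- length(rec$tokens)
    vis <- matrix(inverse.rle(list(lengths = rec$vis_lengths,
                                   values = rec$vis_values)),
                  n, n, byrow = TRUE)
    list(tokens = rec$tokens, soft = as.integer(rec$soft),
         segment = rec$segment,
         label = if (length(rec$label)) rec$label else NA_character_,
         visible = vis)
  })
}
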