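NEG_INF <- -1e9   # additive-mask realization of "invisible"

#' Model configuration for the mask-self-attention classifier
#'
#' @param vocab_size vocabulary size (including special tokens).
#' @param n_labels number of relation labels.
#' @param hidden hidden width; must be divisible by `heads`.
#' @param layers number of encoder layers.
#' @param heads number of attention heads.
#' @param max_len maximum sequence length (hard positions).
#' @param class_weights per-label positive weights for the loss
#'   (default uniform); see [compute_class_weights()].
#' @param dropout dropout rate applied to the embedding output and each
#'   sub-layer output during training.
#' @param ffn_mult feed-forward inner width as a multiple of `hidden`
#'   (2 by default at desk scale; the classic encoder uses 4).
#' @param seed seed controlling weight initialization and dropout.
#' @return object of class `model_config`.
#' @export
model_config <- function(vocab_size, n_labels, hidden = 64L, layers = 2L,
                         heads = 2L, max_len = 64L,
                         class_weights = rep(1, n_labels),
                         dropout = 0.1, ffn_mult = 2L, seed = 1L) {
  stopifnot(vocab_size >= 1, n_labels >= 2, hidden %% heads == 0,
            layers >= 1, heads >= 1, max_len >= 1,
            length(class_weights) == n_labels, all(class_weights > 0),
            dropout >= 0, dropout < 1)
  structure(list(vocab_size = as.integer(vocab_size),
                 n_labels = as.integer(n_labels),
                 hidden = as.integer(hidden), layers = as.integer(layers),
                 heads = as.integer(heads), max_len = as.integer(max_len),
                 class_weights = as.numeric(class_weights),
                 dropout = dropout, ffn_mult = as.integer(ffn_mult),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize encoder weights
#'
#' Draws all weight matrices from N(0, 0.02^2) and sets layer-norm gains
#' to 1 and every bias to 0, under the configuration seed. Tensor names
#' follow a flat `section.tensor` manifest (`emb.tok`, `emb.pos`,
#' `emb.seg`, `emb.ln.g/b`, `layer<l>.attn.Wq/Wk/Wv/Wo` and biases,
#' `layer<l>.ln1.g/b`, `layer<l>.ffn.W1/b1/W2/b2`, `layer<l>.ln2.g/b`,
#' `head.W`, `head.b`).
#'
#' @param config a `model_config`.
#' @return named list of parameter matrices/vectors.
#' @export
init_params <- function(config) {
  H <- config$hidden; FF <- H * config$ffn_mult
  withr::with_seed(config$seed, {
    rn <- function(r, c) matrix(stats::rnorm(r * c, 0, 0.02), r, c)
    p <- list(
      `emb.tok` = rn(config$vocab_size, H),
      `emb.pos` = rn(config$max_len + 8L, H),  # soft positions can exceed L
      `emb.seg` = rn(2L, H),
      `emb.ln.g` = rep(1, H), `emb.ln.b` = rep(0, H))
    for (l in seq_len(config$layers)) {
      nm <- function(s) paste0("layer", l, ".", s)
      # queries and keys start identical: QK^T opens as a Gram matrix,
      # biasing heads toward similarity matching (token-identity
      # attention) early in training; they untie freely from step one
      p[[nm("attn.Wk")]] <- rn(H, H); p[[nm("attn.bk")]] <- rep(0, H)
      p[[nm("attn.Wq")]] <- p[[nm("attn.Wk")]]
      p[[nm("attn.bq")]] <- rep(0, H)
      p[[nm("attn.Wv")]] <- rn(H, H); p[[nm("attn.bv")]] <- rep(0, H)
      p[[nm("attn.Wo")]] <- rn(H, H); p[[nm("attn.bo")]] <- rep(0, H)
      p[[nm("ln1.g")]] <- rep(1, H);  p[[nm("ln1.b")]] <- rep(0, H)
      p[[nm("ffn.W1")]] <- rn(H, FF); p[[nm("ffn.b1")]] <- rep(0, FF)
      p[[nm("ffn.W2")]] <- rn(FF, H); p[[nm("ffn.b2")]] <- rep(0, H)
      p[[nm("ln2.g")]] <- rep(1, H);  p[[nm("ln2.b")]] <- rep(0, H)
    }
    p[["head.W"]] <- rn(H, config$n_labels)
    p[["head.b"]] <- rep(0, config$n_labels)
    p
  })
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# layer norm and bias broadcast run in compiled code (src/)
ln_fwd <- function(X, g, b, eps = 1e-6) .ln_forward(X, g, b, eps)

ln_bwd <- function(dY, cache, g)
  .ln_backward(dY, cache$xhat, cache$invstd, g)

add_bias <- function(X, b) .add_bias(X, b)

#' Mask-self-attention for a single sequence
#'
#' Scaled dot-product attention with an additive visibility mask applied
#' before row normalization, so invisible positions receive (numerically)
#' zero weight and each output row is a convex combination of value rows
#' at visible positions only. A row left with no visible position at all
#' falls back to attending only to itself (reported via a message).
#'
#' @param Q,K,V numeric matrices, rows = positions.
#' @param mask either a logical visibility matrix or an additive mask
#'   (0 visible, large negative invisible).
#' @return list with `context` (attention output) and `weights` (the
#'   row-stochastic attention matrix).
#' @export
mask_self_attention <- function(Q, K, V, mask) {
  stopifnot(nrow(Q) == nrow(mask), nrow(K) == ncol(mask),
            nrow(K) == nrow(V))
  if (is.logical(mask)) mask <- ifelse(mask, 0, NEG_INF)
  dead <- apply(mask, 1L, function(r) all(r <= NEG_INF / 2))
  if (any(dead)) {
    message("mask_self_attention: ", sum(dead),
            " all-invisible row(s); falling back to self-attention only")
    for (i in which(dead)) mask[i, i] <- 0
  }
  S <- Q %*% t(K) / sqrt(ncol(Q)) + mask
  A <- softmax_rows(S)
  list(context = A %*% V, weights = A)
}

# masks: list of B additive L x L matrices; ids/soft: B x L matrices.
# Returns logits and, when keep_cache, everything backward needs.
encoder_forward <- function(params, config, ids, soft, masks,
                            training = FALSE, keep_cache = FALSE) {
  B <- nrow(ids); L <- ncol(ids)
  H <- config$hidden; nh <- config$heads; dh <- H %/% nh
  N <- B * L
  idx <- as.vector(t(ids))                 # example-major ordering
  pos <- pmin(as.vector(t(soft)) + 1L, nrow(params$`emb.pos`))
  E <- params$`emb.tok`[idx, , drop = FALSE] +
    params$`emb.pos`[pos, , drop = FALSE] +
    matrix(params$`emb.seg`[1L, ], N, H, byrow = TRUE)
  ln0 <- ln_fwd(E, params$`emb.ln.g`, params$`emb.ln.b`)
  X <- ln0$Y
  p <- config$dropout
  dmask <- function() {
    if (training && p > 0)
      matrix((stats::runif(N * H) >= p) / (1 - p), N, H)
    else NULL
  }
  m0 <- dmask(); if (!is.null(m0)) X <- X * m0
  caches <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    nm <- function(s) paste0("layer", l, ".", s)
    QKV <- add_bias(X %*% cbind(params[[nm("attn.Wq")]],
                                params[[nm("attn.Wk")]],
                                params[[nm("attn.Wv")]]),
                    c(params[[nm("attn.bq")]], params[[nm("attn.bk")]],
                      params[[nm("attn.bv")]]))
    Q <- QKV[, 1:H, drop = FALSE]
    K <- QKV[, H + 1:H, drop = FALSE]
    V <- QKV[, 2 * H + 1:H, drop = FALSE]
    af <- .attn_forward(Q, K, V, masks, B, L, nh, keep_cache)
    ctx <- af$ctx
    A_list <- if (keep_cache) af$A else NULL
    ao <- add_bias(ctx %*% params[[nm("attn.Wo")]], params[[nm("attn.bo")]])
    m1 <- dmask(); if (!is.null(m1)) ao <- ao * m1
    res1 <- X + ao
    ln1 <- ln_fwd(res1, params[[nm("ln1.g")]], params[[nm("ln1.b")]])
    H1 <- ln1$Y
    Hf <- pmax(add_bias(H1 %*% params[[nm("ffn.W1")]],
                        params[[nm("ffn.b1")]]), 0)
    F2 <- add_bias(Hf %*% params[[nm("ffn.W2")]], params[[nm("ffn.b2")]])
    m2 <- dmask(); if (!is.null(m2)) F2 <- F2 * m2
    res2 <- H1 + F2
    ln2 <- ln_fwd(res2, params[[nm("ln2.g")]], params[[nm("ln2.b")]])
    if (keep_cache)
      caches[[l]] <- list(X = X, Q = Q, K = K, V = V, A = A_list,
                          ctx = ctx, m1 = m1, ln1 = ln1, H1 = H1,
                          Hf = Hf, m2 = m2, ln2 = ln2)
    X <- ln2$Y
  }
  cls_rows <- seq.int(1L, by = L, length.out = B)
  cls_h <- X[cls_rows, , drop = FALSE]
  logits <- add_bias(cls_h %*% params$`head.W`, params$`head.b`)
  out <- list(logits = logits)
  if (keep_cache)
    out$cache <- list(idx = idx, pos = pos, ln0 = ln0, m0 = m0,
                      layers = caches, cls_h = cls_h, cls_rows = cls_rows,
                      B = B, L = L, masks = masks)
  out
}

encoder_backward <- function(params, config, fwd, dlogits) {
  cache <- fwd$cache
  B <- cache$B; L <- cache$L
  H <- config$hidden; nh <- config$heads; dh <- H %/% nh
  N <- B * L
  grads <- list()
  grads[["head.W"]] <- crossprod(cache$cls_h, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  dX <- matrix(0, N, H)
  dX[cache$cls_rows, ] <- tcrossprod(dlogits, params$`head.W`)
  for (l in rev(seq_len(config$layers))) {
    nm <- function(s) paste0("layer", l, ".", s)
    cl <- cache$layers[[l]]
    b2 <- ln_bwd(dX, cl$ln2, params[[nm("ln2.g")]])
    grads[[nm("ln2.g")]] <- b2$dg; grads[[nm("ln2.b")]] <- b2$db
    dres2 <- b2$dX
    dF2 <- if (is.null(cl$m2)) dres2 else dres2 * cl$m2
    grads[[nm("ffn.W2")]] <- crossprod(cl$Hf, dF2)
    grads[[nm("ffn.b2")]] <- colSums(dF2)
    dHf <- tcrossprod(dF2, params[[nm("ffn.W2")]])
    dpre <- dHf * (cl$Hf > 0)
    grads[[nm("ffn.W1")]] <- crossprod(cl$H1, dpre)
    grads[[nm("ffn.b1")]] <- colSums(dpre)
    dH1 <- dres2 + tcrossprod(dpre, params[[nm("ffn.W1")]])
    b1 <- ln_bwd(dH1, cl$ln1, params[[nm("ln1.g")]])
    grads[[nm("ln1.g")]] <- b1$dg; grads[[nm("ln1.b")]] <- b1$db
    dres1 <- b1$dX
    dao <- if (is.null(cl$m1)) dres1 else dres1 * cl$m1
    grads[[nm("attn.Wo")]] <- crossprod(cl$ctx, dao)
    grads[[nm("attn.bo")]] <- colSums(dao)
    dctx <- tcrossprod(dao, params[[nm("attn.Wo")]])
    ab <- .attn_backward(dctx, cl$Q, cl$K, cl$V, cl$A, B, L, nh)
    dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
    dQKV <- cbind(dQ, dK, dV)
    gW <- crossprod(cl$X, dQKV)
    grads[[nm("attn.Wq")]] <- gW[, 1:H, drop = FALSE]
    grads[[nm("attn.bq")]] <- colSums(dQ)
    grads[[nm("attn.Wk")]] <- gW[, H + 1:H, drop = FALSE]
    grads[[nm("attn.bk")]] <- colSums(dK)
    grads[[nm("attn.Wv")]] <- gW[, 2 * H + 1:H, drop = FALSE]
    grads[[nm("attn.bv")]] <- colSums(dV)
    dX <- dres1 + dQKV %*% rbind(t(params[[nm("attn.Wq")]]),
                                 t(params[[nm("attn.Wk")]]),
                                 t(params[[nm("attn.Wv")]]))
  }
  if (!is.null(cache$m0)) dX <- dX * cache$m0
  b0 <- ln_bwd(dX, cache$ln0, params$`emb.ln.g`)
  grads[["emb.ln.g"]] <- b0$dg; grads[["emb.ln.b"]] <- b0$db
  dE <- b0$dX
  gtok <- matrix(0, nrow(params$`emb.tok`), H)
  agg <- rowsum(dE, cache$idx)
  gtok[as.integer(rownames(agg)), ] <- agg
  grads[["emb.tok"]] <- gtok
  gpos <- matrix(0, nrow(params$`emb.pos`), H)
  aggp <- rowsum(dE, cache$pos)
  gpos[as.integer(rownames(aggp)), ] <- aggp
  grads[["emb.pos"]] <- gpos
  gseg <- matrix(0, 2L, H)
  gseg[1L, ] <- colSums(dE)
  grads[["emb.seg"]] <- gseg
  grads
}

#' Class-weighted cross-entropy loss
#'
#' Mean over the batch of per-example cross-entropy, each example scaled
#' by the weight of its gold class; uniform weights recover plain
#' cross-entropy. Also returns the gradient w.r.t. the scores.
#'
#' @param scores numeric matrix, one row per example, one column per
#'   label (unnormalized).
#' @param gold integer vector of 1-based gold label indices.
#' @param class_weights positive per-label weights.
#' @return list with `loss` (scalar) and `dscores` (gradient matrix).
#' @export
weighted_loss <- function(scores, gold, class_weights) {
  B <- nrow(scores)
  stopifnot(length(gold) == B,
            length(class_weights) == ncol(scores))
  if (any(gold < 1L | gold > ncol(scores)))
    stop("gold label index out of range", call. = FALSE)
  P <- softmax_rows(scores)
  w <- class_weights[gold]
  picked <- P[cbind(seq_len(B), gold)]
  loss <- sum(-w * log(pmax(picked, 1e-12))) / B
  dscores <- P
  dscores[cbind(seq_len(B), gold)] <-
    dscores[cbind(seq_len(B), gold)] - 1
  dscores <- dscores * (w / B)
  list(loss = loss, dscores = dscores)
}

adam_init <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# linear warmup then linear decay, classic fine-tuning schedule
lr_schedule <- function(step, total, base_lr, warmup_frac = 0.1) {
  warm <- max(1, floor(total * warmup_frac))
  if (step <= warm) return(base_lr * step / warm)
  base_lr * max(0, (total - step) / max(1, total - warm))
}
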