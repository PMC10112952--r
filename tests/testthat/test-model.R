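tiny_cfg <- function(...) {
  defaults <- list(vocab_size = 20L, n_labels = 2L, hidden = 8L,
                   layers = 1L, heads = 2L, max_len = 12L,
                   dropout = 0, seed = 4L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

test_that("configuration invariants are enforced", {
  expect_error(tiny_cfg(hidden = 9), "hidden")
  expect_error(tiny_cfg(class_weights = c(1, -1)))
  expect_s3_class(tiny_cfg(), "model_config")
})

test_that("an all-visible mask reduces to standard attention", {
  withr::with_seed(1, {
    Q <- matrix(rnorm(12), 4, 3); K <- matrix(rnorm(12), 4, 3)
    V <- matrix(rnorm(12), 4, 3)
  })
  out <- mask_self_attention(Q, K, V, matrix(0, 4, 4))
  # independent softmax computation
  S <- Q %*% t(K) / sqrt(3)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(out$weights, A, tolerance = 1e-12)
  expect_equal(out$context, A %*% V, tolerance = 1e-12)
  expect_equal(unname(rowSums(out$weights)), rep(1, 4))
})

test_that("masked positions receive numerically zero attention", {
  withr::with_seed(2, {
    Q <- matrix(rnorm(12), 4, 3); K <- matrix(rnorm(12), 4, 3)
    V <- matrix(rnorm(12), 4, 3)
  })
  vis <- matrix(TRUE, 4, 4); vis[1, 3] <- FALSE
  out <- mask_self_attention(Q, K, V, vis)
  expect_lt(out$weights[1, 3], 1e-6)
  # block-diagonal mask decomposes into independent attentions
  vis2 <- matrix(FALSE, 4, 4)
  vis2[1:2, 1:2] <- TRUE; vis2[3:4, 3:4] <- TRUE
  whole <- mask_self_attention(Q, K, V, vis2)
  b1 <- mask_self_attention(Q[1:2, ], K[1:2, ], V[1:2, ],
                            matrix(TRUE, 2, 2))
  b2 <- mask_self_attention(Q[3:4, ], K[3:4, ], V[3:4, ],
                            matrix(TRUE, 2, 2))
  expect_equal(whole$context[1:2, ], b1$context, tolerance = 1e-9)
  expect_equal(whole$context[3:4, ], b2$context, tolerance = 1e-9)
})

test_that("an all-invisible row falls back to self-attention with a note", {
  Q <- diag(3); K <- diag(3); V <- matrix(1:9, 3, 3)
  vis <- matrix(TRUE, 3, 3); vis[2, ] <- FALSE
  expect_message(out <- mask_self_attention(Q, K, V, vis),
                 "all-invisible")
  expect_equal(out$context[2, ], V[2, ])
})

test_that("forward_classify matches an independent plain encoder when all is visible", {
  cfg <- tiny_cfg(layers = 2L, hidden = 8L, heads = 2L)
  p <- init_params(cfg)
  withr::with_seed(7, {
    ids <- matrix(sample.int(20, 10), 2, 5)
    soft <- matrix(rep(0:4, 2), 2, 5, byrow = TRUE)
  })
  got <- kinject:::encoder_forward(p, cfg, ids, soft,
                                   all_visible_masks(2, 5))$logits
  want <- naive_encoder_logits(p, cfg, ids, soft)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("a single-layer toy forward matches hand matrix arithmetic", {
  cfg <- tiny_cfg(vocab_size = 6L, hidden = 4L, layers = 1L, heads = 1L)
  p <- init_params(cfg)
  ids <- matrix(c(2L, 3L, 5L), 1, 3)
  soft <- matrix(0:2, 1, 3)
  got <- kinject:::encoder_forward(p, cfg, ids, soft,
                                   all_visible_masks(1, 3))$logits
  # fully hand-rolled forward pass, scalar by scalar where possible
  X <- p$`emb.tok`[c(2, 3, 5), ] + p$`emb.pos`[1:3, ] +
    matrix(p$`emb.seg`[1, ], 3, 4, byrow = TRUE)
  ln <- function(x, g, b) {
    y <- x
    for (i in seq_len(nrow(x))) {
      m <- mean(x[i, ]); v <- mean((x[i, ] - m)^2)
      y[i, ] <- (x[i, ] - m) / sqrt(v + 1e-6) * g + b
    }
    y
  }
  X <- ln(X, p$`emb.ln.g`, p$`emb.ln.b`)
  Q <- X %*% p$`layer1.attn.Wq` + matrix(p$`layer1.attn.bq`, 3, 4, TRUE)
  K <- X %*% p$`layer1.attn.Wk` + matrix(p$`layer1.attn.bk`, 3, 4, TRUE)
  V <- X %*% p$`layer1.attn.Wv` + matrix(p$`layer1.attn.bv`, 3, 4, TRUE)
  S <- Q %*% t(K) / 2
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  ao <- (A %*% V) %*% p$`layer1.attn.Wo` +
    matrix(p$`layer1.attn.bo`, 3, 4, TRUE)
  H1 <- ln(X + ao, p$`layer1.ln1.g`, p$`layer1.ln1.b`)
  Hf <- pmax(H1 %*% p$`layer1.ffn.W1` +
               matrix(p$`layer1.ffn.b1`, 3, 8, TRUE), 0)
  F2 <- Hf %*% p$`layer1.ffn.W2` + matrix(p$`layer1.ffn.b2`, 3, 4, TRUE)
  X2 <- ln(H1 + F2, p$`layer1.ln2.g`, p$`layer1.ln2.b`)
  want <- X2[1, , drop = FALSE] %*% p$`head.W` +
    matrix(p$`head.b`, 1, 2)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- tiny_cfg(vocab_size = 15L, hidden = 8L, layers = 2L, heads = 2L)
  p <- init_params(cfg)
  withr::with_seed(3, ids <- matrix(sample.int(15, 8), 2, 4))
  soft <- matrix(rep(0:3, 2), 2, 4, byrow = TRUE)
  M <- matrix(0, 4, 4); M[2:3, 4] <- -1e9; M[4, 2:3] <- -1e9
  masks <- list(matrix(0, 4, 4), M)
  gold <- c(1L, 2L); w <- c(0.7, 1.6)
  fwd <- kinject:::encoder_forward(p, cfg, ids, soft, masks,
                                   keep_cache = TRUE)
  ls <- weighted_loss(fwd$logits, gold, w)
  gr <- kinject:::encoder_backward(p, cfg, fwd, ls$dscores)
  loss_at <- function(pp)
    weighted_loss(kinject:::encoder_forward(pp, cfg, ids, soft,
                                            masks)$logits, gold, w)$loss
  for (nm in c("emb.tok", "emb.pos", "layer1.attn.Wq", "layer1.attn.Wv",
               "layer2.ffn.W1", "layer2.ln2.g", "head.W", "head.b")) {
    i <- which(abs(gr[[nm]]) == max(abs(gr[[nm]])))[1]
    eps <- 1e-5
    pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps; up <- loss_at(pp)
    pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- loss_at(pp)
    numeric <- (up - dn) / (2 * eps)
    expect_equal(gr[[nm]][i], numeric, tolerance = 1e-4)
  }
})

test_that("visibility confines gradient flow as the mask dictates", {
  # position 4 invisible to everything (and vice versa) except itself:
  # its token embedding must not influence the [CLS]-position loss
  cfg <- tiny_cfg(vocab_size = 15L, hidden = 8L, layers = 2L, heads = 2L)
  p <- init_params(cfg)
  ids <- matrix(c(2L, 5L, 7L, 9L), 1, 4)
  soft <- matrix(0:3, 1, 4)
  M <- matrix(0, 4, 4); M[4, -4] <- -1e9; M[-4, 4] <- -1e9
  fwd <- kinject:::encoder_forward(p, cfg, ids, soft, list(M),
                                   keep_cache = TRUE)
  ls <- weighted_loss(fwd$logits, 1L, c(1, 1))
  gr <- kinject:::encoder_backward(p, cfg, fwd, ls$dscores)
  expect_equal(max(abs(gr$`emb.tok`[9, ])), 0)
  expect_gt(max(abs(gr$`emb.tok`[2, ])), 0)
})

test_that("weighted cross-entropy matches hand computation and scales linearly", {
  scores <- rbind(c(2, 0.5), c(-1, 1), c(0, 0))
  gold <- c(1L, 2L, 2L)
  sm <- function(r) exp(r) / sum(exp(r))
  hand <- -(log(sm(scores[1, ])[1]) + 2 * log(sm(scores[2, ])[2]) +
              2 * log(sm(scores[3, ])[2])) / 3
  expect_equal(weighted_loss(scores, gold, c(1, 2))$loss, hand)
  # uniform weights reduce to unweighted cross-entropy
  unw <- -(log(sm(scores[1, ])[1]) + log(sm(scores[2, ])[2]) +
             log(sm(scores[3, ])[2])) / 3
  expect_equal(weighted_loss(scores, gold, c(1, 1))$loss, unw)
  # doubling a class weight doubles its contribution
  base <- weighted_loss(scores, gold, c(1, 1))$loss
  l2 <- weighted_loss(scores, gold, c(2, 1))$loss
  per1 <- -log(sm(scores[1, ])[1]) / 3
  expect_equal(l2 - base, per1)
  expect_error(weighted_loss(scores, c(1L, 3L, 2L), c(1, 1)),
               "out of range")
})

test_that("batch order does not change per-example scores", {
  cfg <- tiny_cfg(vocab_size = 25L, hidden = 8L, layers = 2L,
                  heads = 2L, max_len = 48L)
  p <- init_params(cfg)
  vocab <- c("[PAD]", "[UNK]", "[CLS]", paste0("t", 1:22))
  flats <- lapply(c(31, 32, 33), function(s) encode_tree(random_tree(s)))
  s1 <- forward_classify(flats, p, cfg, vocab)
  s2 <- forward_classify(rev(flats), p, cfg, vocab)
  expect_equal(s1, s2[3:1, ], tolerance = 1e-10)
  # identical seeds and inputs -> identical scores
  expect_equal(s1, forward_classify(flats, p, cfg, vocab))
})

test_that("checkpoints round-trip and partial loads are reported", {
  cfg <- tiny_cfg()
  p <- init_params(cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(p, cfg, path)
  back <- load_checkpoint(path, cfg)
  expect_identical(back$params, p)
  expect_setequal(back$loaded, names(p))
  expect_length(back$initialized, 0)
  # body-only checkpoint: head re-initialized and both groups reported
  p_body <- p[setdiff(names(p), c("head.W", "head.b"))]
  save_checkpoint(p_body, cfg, path)
  partial <- load_checkpoint(path, cfg)
  expect_setequal(partial$initialized, c("head.W", "head.b"))
  expect_identical(partial$params$`emb.tok`, p$`emb.tok`)
  expect_equal(dim(partial$params$`head.W`), dim(p$`head.W`))
  # wrong hidden width is a named shape error
  cfg_wide <- tiny_cfg(hidden = 16L)
  expect_error(load_checkpoint(path, cfg_wide), "emb.tok")
})
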