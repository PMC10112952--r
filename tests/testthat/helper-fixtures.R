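# Shared in-code fixtures: tiny hand-written ontologies and random
# generators used across the suite. Everything is built at test time;
# nothing binary is stored.

# 4-concept chain/star used for closed-form IC checks:
#   root <- organ  <- heart   (heart is_a organ is_a root)
#   root <- tissue
toy_obo_lines <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: T:1", "name: root", "",
    "[Term]", "id: T:2", "name: organ", "is_a: T:1 ! root", "",
    "[Term]", "id: T:3", "name: heart",
    "synonym: \"cardiac organ\" EXACT []", "is_a: T:2 ! organ", "",
    "[Term]", "id: T:4", "name: tissue", "is_a: T:1 ! root", "")
}

write_toy_obo <- function(path = tempfile(fileext = ".obo"),
                          extra = character()) {
  writeLines(c(toy_obo_lines(), extra), path)
  path
}

toy_source <- function() {
  load_knowledge_source(write_toy_obo(), "obo", name = "toy")
}

# knowledge source built from an explicit triple data.frame of labels
source_from_triples <- function(triples, name = "mini") {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(triples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  load_knowledge_source(path, "tsv", name = name)
}

# a random seeded sentence tree (trunk of pseudo-tokens with random
# non-overlapping anchors carrying random 2-token branches)
random_tree <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(5:14, 1)
    trunk <- paste0("w", seq_len(n))
    n_anchor <- sample(0:3, 1)
    anchors <- list()
    used <- integer(0)
    for (a in seq_len(n_anchor)) {
      free <- which(!(seq_len(n) %in% used))
      if (!length(free)) break
      s <- sample(free, 1)
      e <- min(n, s + sample(0:1, 1))
      if (any(s:e %in% used)) e <- s
      used <- c(used, s:e)
      branches <- lapply(seq_len(sample(1:3, 1)), function(b)
        list(tokens = c("is_a", paste0("k", a, "_", b)),
             ic = stats::runif(1)))
      anchors[[length(anchors) + 1]] <- list(
        span = c(start = s, end = e), branches = branches)
    }
    structure(list(trunk = trunk, anchors = anchors,
                   entity_spans = rbind(c(1, 1), c(n, n)),
                   label = "x"),
              class = "sentence_tree")
  })
}

# brute-force visibility oracle: two flattened positions see each other
# iff they lie on a common root-to-leaf path of the sentence tree, i.e.
# both on the trunk (incl. [CLS]), or in the same branch, or one is a
# branch token and the other a trunk token of its anchor span
oracle_visible <- function(flat, tree) {
  lay <- flat$layout
  n <- nrow(lay)
  V <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- lay[i, ]; b <- lay[j, ]
    if (a$kind == "pad" || b$kind == "pad") { V[i, j] <- i == j; next }
    core_a <- a$kind %in% c("cls", "trunk")
    core_b <- b$kind %in% c("cls", "trunk")
    if (core_a && core_b) { V[i, j] <- TRUE; next }
    if (!core_a && !core_b) {
      V[i, j] <- a$anchor == b$anchor && a$branch == b$branch
      next
    }
    br <- if (core_a) b else a
    tk <- if (core_a) a else b
    sp <- tree$anchors[[br$anchor]]$span
    V[i, j] <- tk$kind == "trunk" &&
      tk$trunk_idx >= sp[1] && tk$trunk_idx <= sp[2]
  }
  V
}

# independent plain (unmasked) encoder used as the all-visible oracle:
# a from-first-principles reimplementation of the forward pass
naive_encoder_logits <- function(params, config, ids, soft) {
  H <- config$hidden; nh <- config$heads; dh <- H / nh
  lnorm <- function(x, g, b) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-6) * g + b
    }))
  }
  B <- nrow(ids); L <- ncol(ids)
  out <- matrix(0, B, config$n_labels)
  for (e in seq_len(B)) {
    X <- matrix(0, L, H)
    for (i in seq_len(L))
      X[i, ] <- params$`emb.tok`[ids[e, i], ] +
        params$`emb.pos`[soft[e, i] + 1, ] + params$`emb.seg`[1, ]
    X <- lnorm(X, params$`emb.ln.g`, params$`emb.ln.b`)
    for (l in seq_len(config$layers)) {
      nm <- function(s) paste0("layer", l, ".", s)
      Q <- X %*% params[[nm("attn.Wq")]] +
        matrix(params[[nm("attn.bq")]], L, H, byrow = TRUE)
      K <- X %*% params[[nm("attn.Wk")]] +
        matrix(params[[nm("attn.bk")]], L, H, byrow = TRUE)
      V <- X %*% params[[nm("attn.Wv")]] +
        matrix(params[[nm("attn.bv")]], L, H, byrow = TRUE)
      ctx <- matrix(0, L, H)
      for (h in seq_len(nh)) {
        cc <- ((h - 1) * dh + 1):(h * dh)
        S <- Q[, cc, drop = FALSE] %*% t(K[, cc, drop = FALSE]) / sqrt(dh)
        A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
        ctx[, cc] <- A %*% V[, cc, drop = FALSE]
      }
      ao <- ctx %*% params[[nm("attn.Wo")]] +
        matrix(params[[nm("attn.bo")]], L, H, byrow = TRUE)
      X1 <- lnorm(X + ao, params[[nm("ln1.g")]], params[[nm("ln1.b")]])
      Hf <- pmax(X1 %*% params[[nm("ffn.W1")]] +
                   matrix(params[[nm("ffn.b1")]], L,
                          ncol(params[[nm("ffn.W1")]]), byrow = TRUE), 0)
      F2 <- Hf %*% params[[nm("ffn.W2")]] +
        matrix(params[[nm("ffn.b2")]], L, H, byrow = TRUE)
      X <- lnorm(X1 + F2, params[[nm("ln2.g")]], params[[nm("ln2.b")]])
    }
    out[e, ] <- X[1, ] %*% params$`head.W` + params$`head.b`
  }
  out
}

all_visible_masks <- function(B, L) replicate(B, matrix(0, L, L),
                                              simplify = FALSE)
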