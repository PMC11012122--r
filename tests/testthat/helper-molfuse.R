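# Shared fixtures and independent brute-force oracles. The oracles are
# written in plain R from the defining formulas, deliberately separate from
# the package's tape-based implementation paths.

tiny_cfg <- function(...) {
  defaults <- list(d = 8L, lstm_hidden = 8L, n_heads = 2L, d_ff = 16L,
                   latent_dim = 4L, vae_hidden = 8L, head_hidden = 8L,
                   epochs = 2L, batch_size = 8L, seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(molfuse_config, args)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# gate-by-gate LSTM step from the defining equations
lstm_oracle <- function(x, h, c, p) {
  hx <- c(h, x)
  f <- sigmoid(hx %*% p$Wf + p$bf)
  i <- sigmoid(hx %*% p$Wi + p$bi)
  ct <- tanh(hx %*% p$Wc + p$bc)
  o <- sigmoid(hx %*% p$Wo + p$bo)
  c_new <- f * c + i * ct
  h_new <- o * tanh(c_new)
  list(hidden = as.numeric(h_new), cell = as.numeric(c_new))
}

# full single-direction LSTM over an embedded sequence
lstm_seq_oracle <- function(X, p, hdim) {
  h <- rep(0, hdim); cc <- rep(0, hdim)
  hs <- matrix(0, nrow(X), hdim)
  for (t in seq_len(nrow(X))) {
    st <- lstm_oracle(X[t, ], h, cc, p)
    h <- st$hidden; cc <- st$cell
    hs[t, ] <- h
  }
  list(final = h, steps = hs)
}

softmax_rows_oracle <- function(M) {
  t(apply(M, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
}

attention_oracle <- function(Q, K, V) {
  softmax_rows_oracle(Q %*% t(K) / sqrt(ncol(Q))) %*% V
}

layernorm_oracle <- function(X, gamma, beta, eps = 1e-5) {
  t(apply(X, 1, function(r) {
    mu <- mean(r); v <- mean((r - mu)^2)
    (r - mu) / sqrt(v + eps)
  })) * matrix(gamma, nrow(X), length(gamma), byrow = TRUE) +
    matrix(beta, nrow(X), length(beta), byrow = TRUE)
}

# end-to-end Transformer oracle, single molecule, single head
transformer_oracle <- function(ids, params, cfg) {
  emb <- params$emb[ids + 1L, , drop = FALSE]
  X <- emb
  if (cfg$positional_encoding) {
    X <- X + molfuse:::sinusoidal_pe(seq_len(nrow(X)), cfg$d)
  }
  for (l in seq_len(cfg$n_transformer_layers)) {
    p <- params$transformer[[paste0("layer", l)]]
    A <- attention_oracle(X %*% p$WQ, X %*% p$WK, X %*% p$WV) %*% p$WO
    Xh <- layernorm_oracle(X + A, p$ln_gamma, p$ln_beta)
    H <- pmax(sweep(Xh %*% p$W1, 2, p$b1, "+"), 0)
    X <- sweep(H %*% p$W2, 2, p$b2, "+")
  }
  pooled <- matrix(colMeans(X), 1)
  list(units = X,
       mol = pooled %*% params$transformer$pool$W + params$transformer$pool$b)
}

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

# dense GAT layer oracle with self-loops
gat_layer_oracle <- function(H, edges, p, slope = 0.2) {
  n <- nrow(H)
  HW <- H %*% p$W
  adj <- diag(1, n)
  if (nrow(edges) > 0) adj[edges] <- 1
  e_src <- as.numeric(HW %*% p$a_src)
  e_dst <- as.numeric(HW %*% p$a_dst)
  E <- outer(e_src, rep(1, n)) + outer(rep(1, n), e_dst)
  E <- ifelse(E > 0, E, slope * E)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    w <- exp(E[i, nb] - max(E[i, nb]))
    A[i, nb] <- w / sum(w)
  }
  elu(A %*% HW)
}

# pairwise-comparison ROC-AUC: P(score_pos > score_neg) + 0.5 P(tie)
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

central_diff_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

make_labeled_batch <- function(n = 6L, seed = 3L) {
  corp <- generate_corpus(n, seed = seed)
  vocab <- build_vocab(corp)
  list(corpus = corp, vocab = vocab,
       mols = molfuse:::featurize_molecules(corp, vocab))
}
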