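# Encoder correctness: gate-level LSTM behavior, attention arithmetic,
# graph-attention normalization, and equivalence with independent
# brute-force oracles on small instances.

make_lstm_params <- function(d_in, h, seed = 1, zero = FALSE) {
  set.seed(seed)
  p <- list(Wf = matrix(rnorm((d_in + h) * h, sd = 0.5), d_in + h, h),
            Wi = matrix(rnorm((d_in + h) * h, sd = 0.5), d_in + h, h),
            Wc = matrix(rnorm((d_in + h) * h, sd = 0.5), d_in + h, h),
            Wo = matrix(rnorm((d_in + h) * h, sd = 0.5), d_in + h, h),
            bf = matrix(rnorm(h), 1), bi = matrix(rnorm(h), 1),
            bc = matrix(rnorm(h), 1), bo = matrix(rnorm(h), 1))
  if (zero) p <- lapply(p, function(m) m * 0)
  p
}

test_that("lstm_cell_step with zero weights gives half-open gates and zero state", {
  p <- make_lstm_params(3, 3, zero = TRUE)
  st <- lstm_cell_step(c(1, -2, 3), list(hidden = rep(0, 3), cell = rep(0, 3)), p)
  expect_equal(as.numeric(st$f), rep(0.5, 3))
  expect_equal(as.numeric(st$i), rep(0.5, 3))
  expect_equal(as.numeric(st$o), rep(0.5, 3))
  expect_equal(as.numeric(st$cell), rep(0, 3))
  expect_equal(as.numeric(st$hidden), rep(0, 3))
})

test_that("saturated forget/input gates carry the previous cell state through", {
  p <- make_lstm_params(2, 2, zero = TRUE)
  p$bf <- matrix(50, 1, 2)   # forget gate -> 1
  p$bi <- matrix(-50, 1, 2)  # input gate -> 0
  prev <- list(hidden = c(0.3, -0.2), cell = c(1.5, -0.7))
  st <- lstm_cell_step(c(1, 1), prev, p)
  expect_equal(as.numeric(st$cell), prev$cell, tolerance = 1e-12)
})

test_that("lstm_cell_step matches the gate-by-gate oracle on random instances", {
  for (seed in 1:3) {
    p <- make_lstm_params(3, 3, seed = seed)
    set.seed(seed + 10)
    x <- rnorm(3); h0 <- rnorm(3); c0 <- rnorm(3)
    got <- lstm_cell_step(x, list(hidden = h0, cell = c0), p)
    want <- lstm_oracle(x, h0, c0, p)
    expect_equal(as.numeric(got$hidden), want$hidden, tolerance = 1e-6)
    expect_equal(as.numeric(got$cell), want$cell, tolerance = 1e-6)
  }
  expect_error(lstm_cell_step(c(1, 2), list(hidden = rep(0, 3), cell = rep(0, 3)),
                              make_lstm_params(3, 3)),
               "dimensions")
})

test_that("bilstm_encode agrees with two independent single-direction oracles", {
  cfg <- tiny_cfg()
  b <- make_labeled_batch(4)
  params <- init_params(b$vocab, cfg)
  ids <- b$mols[[1]]$enc$token_ids
  out <- bilstm_encode(ids, params, cfg)

  X <- params$emb[ids + 1L, , drop = FALSE]
  fw <- lstm_seq_oracle(X, params$bilstm$fw, cfg$lstm_hidden)
  bw <- lstm_seq_oracle(X[rev(seq_len(nrow(X))), , drop = FALSE],
                        params$bilstm$bw, cfg$lstm_hidden)
  mol <- matrix(c(fw$final, bw$final), 1) %*% params$bilstm$W_mol +
    params$bilstm$b_mol
  expect_equal(out$molecule_feature, mol, tolerance = 1e-6)
  L <- length(ids)
  units <- cbind(fw$steps, bw$steps[L:1, , drop = FALSE]) %*%
    params$bilstm$W_unit +
    matrix(params$bilstm$b_unit, L, cfg$d, byrow = TRUE)
  expect_equal(out$unit_features, units, tolerance = 1e-6)
})

test_that("bilstm forward and backward directions coincide on symmetric inputs", {
  cfg <- tiny_cfg()
  b <- make_labeled_batch(4)
  params <- init_params(b$vocab, cfg)
  params$bilstm$bw <- params$bilstm$fw  # direction-shared weights

  # length-1 sequence: the two directions perform the same single step
  one <- bilstm_encode(1L, params, cfg)
  X <- params$emb[2L, , drop = FALSE]
  fw <- lstm_seq_oracle(X, params$bilstm$fw, cfg$lstm_hidden)
  expect_equal(as.numeric(one$molecule_feature),
               as.numeric(matrix(c(fw$final, fw$final), 1) %*%
                            params$bilstm$W_mol + params$bilstm$b_mol),
               tolerance = 1e-6)

  # palindromic sequence with shared weights: final states equal
  ids <- c(2L, 3L, 2L)
  Xp <- params$emb[ids + 1L, , drop = FALSE]
  fwp <- lstm_seq_oracle(Xp, params$bilstm$fw, cfg$lstm_hidden)
  bwp <- lstm_seq_oracle(Xp[3:1, , drop = FALSE], params$bilstm$fw, cfg$lstm_hidden)
  expect_equal(fwp$final, bwp$final, tolerance = 1e-10)
})

test_that("scaled dot-product attention is row-stochastic and matches brute force", {
  # single token: output is the single V row
  one <- scaled_dot_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                              matrix(c(5, -3), 1))
  expect_equal(one$output, matrix(c(5, -3), 1))
  expect_equal(one$weights[1, 1], 1)

  # identical K rows: uniform weights 1/S
  set.seed(2)
  Q <- matrix(rnorm(8), 4, 2)
  K <- matrix(rep(c(0.3, -0.1), each = 4), 4, 2)
  V <- matrix(rnorm(12), 4, 3)
  res <- scaled_dot_attention(Q, K, V)
  expect_true(all(abs(res$weights - 0.25) < 1e-12))

  # 2-token brute force
  Q <- matrix(c(0.5, -1, 2, 0.3), 2, 2)
  K <- matrix(c(1, 0.2, -0.7, 0.9), 2, 2)
  V <- matrix(c(3, -2, 0.5, 1), 2, 2)
  res <- scaled_dot_attention(Q, K, V)
  expect_equal(res$output, attention_oracle(Q, K, V), tolerance = 1e-10)
  expect_true(all(abs(rowSums(res$weights) - 1) < 1e-6))

  expect_error(scaled_dot_attention(matrix(numeric(0), 1, 0),
                                    matrix(numeric(0), 1, 0), matrix(1)),
               "d_k")
})

test_that("transformer_encode follows the embed/PE/attention/LN/FFN pipeline", {
  cfg <- tiny_cfg(n_heads = 1L, n_transformer_layers = 2L)
  b <- make_labeled_batch(4)
  params <- init_params(b$vocab, cfg)
  ids <- b$mols[[2]]$enc$token_ids

  got <- transformer_encode(ids, params, cfg)
  want <- transformer_oracle(ids, params, cfg)
  expect_equal(got$unit_features, want$units, tolerance = 1e-5)
  expect_equal(got$molecule_feature, want$mol, tolerance = 1e-5)

  # FFN with W2 = 0 collapses every unit feature to the bias b2
  params0 <- params
  params0$transformer$layer2$W2 <- params0$transformer$layer2$W2 * 0
  set.seed(1)
  params0$transformer$layer2$b2 <- matrix(rnorm(cfg$d), 1)
  got0 <- transformer_encode(ids, params0, cfg)
  for (r in seq_len(nrow(got0$unit_features))) {
    expect_equal(got0$unit_features[r, ], as.numeric(params0$transformer$layer2$b2),
                 tolerance = 1e-10)
  }
})

test_that("without positional encoding the transformer is permutation-equivariant", {
  cfg <- tiny_cfg(positional_encoding = FALSE)
  b <- make_labeled_batch(4)
  params <- init_params(b$vocab, cfg)
  ids <- c(2L, 3L, 4L, 2L)
  perm <- c(3L, 1L, 4L, 2L)
  out1 <- transformer_encode(ids, params, cfg)$unit_features
  out2 <- transformer_encode(ids[perm], params, cfg)$unit_features
  expect_equal(out2, out1[perm, , drop = FALSE], tolerance = 1e-8)
})

test_that("graph-attention coefficients normalize over each neighborhood", {
  cfg <- tiny_cfg()
  set.seed(3)
  p <- list(W = matrix(rnorm(4 * 5, sd = 0.5), 4, 5),
            a_src = matrix(rnorm(5), 5, 1), a_dst = matrix(rnorm(5), 5, 1))

  # identical features -> equal logits -> uniform 1/k weights
  H <- matrix(rep(c(1, 0, -1, 0.5), 3), 3, 4, byrow = TRUE)
  edges <- cbind(c(1, 2, 2, 3, 1, 3), c(2, 1, 3, 2, 3, 1))  # triangle
  co <- gat_attention_coeffs(H, edges, p)
  expect_true(all(abs(co$weight - 1 / 3) < 1e-10))

  # random features: weights sum to 1 per source node
  set.seed(4)
  H <- matrix(rnorm(12), 3, 4)
  co <- gat_attention_coeffs(H, edges, p)
  sums <- tapply(co$weight, co$from, sum)
  expect_true(all(abs(sums - 1) < 1e-6))

  # 3-node path graph against the hand-computed LeakyReLU + softmax oracle
  path_edges <- cbind(c(1, 2, 2, 3), c(2, 1, 3, 2))
  HW <- H %*% p$W
  e_src <- as.numeric(HW %*% p$a_src); e_dst <- as.numeric(HW %*% p$a_dst)
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  # node 2 attends over {1, 2, 3}
  logits2 <- lrelu(e_src[2] + e_dst[c(1, 2, 3)])
  w2 <- exp(logits2 - max(logits2)); w2 <- w2 / sum(w2)
  co <- gat_attention_coeffs(H, path_edges, p)
  expect_equal(co$weight[co$from == 2], unname(w2), tolerance = 1e-6)
})

test_that("gat_layer matches dense brute-force aggregation", {
  set.seed(5)
  p <- list(W = matrix(rnorm(4 * 6, sd = 0.5), 4, 6),
            a_src = matrix(rnorm(6), 6, 1), a_dst = matrix(rnorm(6), 6, 1))

  # single node with self-loop: h' = ELU(W h)
  h1 <- matrix(rnorm(4), 1)
  out1 <- gat_layer(h1, matrix(integer(0), 0, 2), p)
  expect_equal(out1, elu(h1 %*% p$W), tolerance = 1e-10)

  # two identical, symmetrically connected nodes give identical rows
  H2 <- matrix(rep(rnorm(4), 2), 2, 4, byrow = TRUE)
  out2 <- gat_layer(H2, cbind(c(1, 2), c(2, 1)), p)
  expect_equal(out2[1, ], out2[2, ], tolerance = 1e-10)

  # 4-node instance vs brute force
  H4 <- matrix(rnorm(16), 4, 4)
  edges4 <- cbind(c(1, 2, 2, 3, 3, 4, 1, 4), c(2, 1, 3, 2, 4, 3, 4, 1))
  expect_equal(gat_layer(H4, edges4, p), gat_layer_oracle(H4, edges4, p),
               tolerance = 1e-5)
})

test_that("gat_encode max-pools over exactly two attention layers", {
  cfg <- tiny_cfg()
  b <- make_labeled_batch(4)
  params <- init_params(b$vocab, cfg)

  g <- smiles_to_graph("c1ccccc1C")
  out <- gat_encode(g, params, cfg)
  expect_equal(dim(out$unit_features), c(7L, cfg$d))
  # pooled vector dominates every node feature elementwise
  expect_true(all(outer(rep(1, 7), out$pooled_pre_mlp) >= out$unit_features - 1e-12))

  # two explicit layer applications reproduce the unit features
  H1 <- gat_layer(g$node_features, g$edges, params$gat$layer1)
  H2 <- gat_layer(H1, g$edges, params$gat$layer2)
  expect_equal(out$unit_features, H2, tolerance = 1e-6)

  # single atom: pooled (pre-MLP) equals its node feature
  g1 <- smiles_to_graph("C")
  out1 <- gat_encode(g1, params, cfg)
  expect_equal(out1$pooled_pre_mlp, as.numeric(out1$unit_features))
})

test_that("all encoders stay finite over a synthetic corpus and feed gradients to every parameter", {
  cfg <- tiny_cfg()
  corp <- generate_corpus(100, seed = 31)
  vocab <- build_vocab(corp)
  params <- init_params(vocab, cfg)
  mols <- molfuse:::featurize_molecules(corp, vocab)

  for (m in mols[1:20]) {
    bo <- bilstm_encode(m$enc$token_ids, params, cfg)
    to <- transformer_encode(m$enc$token_ids, params, cfg)
    go <- gat_encode(m$graph, params, cfg)
    expect_true(all(is.finite(c(bo$unit_features, bo$molecule_feature,
                                to$unit_features, to$molecule_feature,
                                go$unit_features, go$molecule_feature))))
  }

  # gradient-flow smoke: a batch loss touching units and molecule features
  # sends non-zero gradient into every encoder parameter
  ad <- asNamespace("molfuse")
  ad$ad_tape_reset()
  pn <- molfuse:::wrap_params(params[c("emb", "bilstm", "transformer", "gat")])
  sp <- molfuse:::prep_seq_batch(mols[1:16])
  gp <- molfuse:::prep_graph_batch(mols[1:16])
  bx <- molfuse:::bilstm_forward_ad(sp, pn, cfg, units = TRUE)
  tx <- molfuse:::transformer_forward_ad(sp, pn, cfg, units = TRUE)
  gx <- molfuse:::gat_forward_ad(gp, pn, cfg, units = TRUE)
  pieces <- list(bx$mol, bx$units, tx$mol, tx$units, gx$mol, gx$units)
  loss <- Reduce(function(a, b) ad$ad_add(a, b), lapply(pieces, ad$ad_sumsq))
  ad$ad_backward(loss)
  grads <- molfuse:::collect_grads(pn)
  flat <- rapply(grads, function(g) max(abs(g)), how = "unlist")
  expect_true(all(flat > 0), info = paste("zero-grad params:",
                                          paste(names(flat)[flat == 0], collapse = ", ")))
})
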