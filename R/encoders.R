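# The three molecular encoders.
#
# A bidirectional LSTM and a Transformer read the token sequence; a two-layer
# graph attention network reads the molecular graph. Each produces per-unit
# features (tokens or atoms) and a pooled molecule feature of shared
# dimension d, so the pairwise reconstruction objective and the fusion head
# can compare and combine them.
#
# Training runs batched on the autodiff tape: sequences are padded and
# masked for the BiLSTM, while the Transformer and GAT see the batch as one
# concatenated sequence/graph with a block-diagonal attention mask, which
# keeps attention strictly within each molecule.

# ---- featurization ----------------------------------------------------------

featurize_molecules <- function(smiles, vocab, max_len = 256L) {
  lapply(smiles, function(s) {
    enc <- encode_smiles(s, vocab, max_len)
    g <- smiles_to_graph(s)
    if (sum(enc$atom_mask) != g$n_atoms) {
      stop("internal: atom mask / graph mismatch for ", s)
    }
    list(enc = enc, graph = g, smiles = s)
  })
}

prep_seq_batch <- function(mols) {
  B <- length(mols)
  lens <- vapply(mols, function(m) m$enc$length, integer(1))
  if (any(lens == 0L)) stop("empty token sequence in batch")
  Lmax <- max(lens)
  ids <- matrix(0L, B, Lmax)
  ids_rev <- matrix(0L, B, Lmax)
  for (i in seq_len(B)) {
    ti <- mols[[i]]$enc$token_ids
    ids[i, seq_len(lens[i])] <- ti
    ids_rev[i, seq_len(lens[i])] <- rev(ti)
  }
  flat_ids <- unlist(lapply(mols, function(m) m$enc$token_ids), use.names = FALSE)
  tok_mol <- rep(seq_len(B), lens)
  tok_pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  attn_mask <- matrix(as.numeric(outer(tok_mol, tok_mol, "==")),
                      length(tok_mol), length(tok_mol))
  pool <- matrix(0, B, length(tok_mol))
  pool[cbind(tok_mol, seq_along(tok_mol))] <- 1 / lens[tok_mol]
  # unit-feature gather indices into the (Lmax*B) stacked per-time matrices
  idx_f <- (tok_pos - 1L) * B + tok_mol
  idx_b <- (lens[tok_mol] - tok_pos) * B + tok_mol
  atom_mask <- unlist(lapply(mols, function(m) m$enc$atom_mask), use.names = FALSE)
  list(B = B, lens = lens, Lmax = Lmax, ids = ids, ids_rev = ids_rev,
       flat_ids = flat_ids, tok_mol = tok_mol, attn_mask = attn_mask,
       pool = pool, idx_f = idx_f, idx_b = idx_b, atom_mask = atom_mask)
}

prep_graph_batch <- function(mols) {
  B <- length(mols)
  ns <- vapply(mols, function(m) m$graph$n_atoms, integer(1))
  offsets <- cumsum(c(0L, ns[-B]))
  feats <- do.call(rbind, lapply(mols, function(m) m$graph$node_features))
  N <- sum(ns)
  adj <- diag(1, N)  # self-loops keep every softmax neighborhood non-empty
  for (i in seq_len(B)) {
    e <- mols[[i]]$graph$edges
    if (nrow(e) > 0L) adj[cbind(e[, 1] + offsets[i], e[, 2] + offsets[i])] <- 1
  }
  node_mol <- rep(seq_len(B), ns)
  list(B = B, ns = ns, offsets = offsets, features = feats, adj = adj,
       node_mol = node_mol)
}

# ---- BiLSTM -----------------------------------------------------------------

lstm_step_ad <- function(x, h, c, p) {
  hx <- ad_cbind(h, x)
  f <- ad_sigmoid(ad_add(ad_mm(hx, p$Wf), p$bf))
  i <- ad_sigmoid(ad_add(ad_mm(hx, p$Wi), p$bi))
  c_tilde <- ad_tanh(ad_add(ad_mm(hx, p$Wc), p$bc))
  o <- ad_sigmoid(ad_add(ad_mm(hx, p$Wo), p$bo))
  c_new <- ad_add(ad_mul(f, c), ad_mul(i, c_tilde))
  h_new <- ad_mul(o, ad_tanh(c_new))
  list(h = h_new, c = c_new, f = f, i = i, o = o)
}

run_lstm_dir <- function(prep, ids, emb_node, p, hdim) {
  B <- prep$B
  h <- ad_leaf(matrix(0, B, hdim))
  cc <- ad_leaf(matrix(0, B, hdim))
  hs <- vector("list", prep$Lmax)
  for (t in seq_len(prep$Lmax)) {
    x_t <- ad_rows(emb_node, ids[, t] + 1L)
    st <- lstm_step_ad(x_t, h, cc, p)
    m <- matrix(as.numeric(prep$lens >= t), B, hdim)
    # freeze state once a sequence is exhausted
    h <- ad_add(ad_mulc(st$h, m), ad_mulc(h, 1 - m))
    cc <- ad_add(ad_mulc(st$c, m), ad_mulc(cc, 1 - m))
    hs[[t]] <- h
  }
  list(final = h, steps = hs)
}

bilstm_forward_ad <- function(prep, pn, cfg, units = FALSE) {
  p <- pn$bilstm
  fw <- run_lstm_dir(prep, prep$ids, pn$emb, p$fw, cfg$lstm_hidden)
  bw <- run_lstm_dir(prep, prep$ids_rev, pn$emb, p$bw, cfg$lstm_hidden)
  hcat <- ad_cbind(fw$final, bw$final)
  mol <- ad_add(ad_mm(hcat, p$W_mol), p$b_mol)
  out <- list(mol = mol)
  if (units) {
    fw_stack <- ad_rbind_list(fw$steps)
    bw_stack <- ad_rbind_list(bw$steps)
    u <- ad_cbind(ad_rows(fw_stack, prep$idx_f), ad_rows(bw_stack, prep$idx_b))
    out$units <- ad_add(ad_mm(u, p$W_unit), p$b_unit)
  }
  out
}

# ---- Transformer ------------------------------------------------------------

sinusoidal_pe <- function(positions, d) {
  pe <- matrix(0, length(positions), d)
  for (k in seq_len(d %/% 2L)) {
    freq <- 1 / 10000^(2 * (k - 1) / d)
    pe[, 2L * k - 1L] <- sin((positions - 1L) * freq)
    pe[, 2L * k] <- cos((positions - 1L) * freq)
  }
  pe
}

attention_ad <- function(X, p, n_heads, mask) {
  d <- ncol(ad_value(p$WQ))
  dk <- d %/% n_heads
  Q <- ad_mm(X, p$WQ); K <- ad_mm(X, p$WK); V <- ad_mm(X, p$WV)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- ad_cols(Q, cols); Kh <- ad_cols(K, cols); Vh <- ad_cols(V, cols)
    A <- ad_softmax_rows(ad_scale(ad_mm(Qh, ad_t(Kh)), 1 / sqrt(dk)), mask)
    heads[[h]] <- ad_mm(A, Vh)
  }
  out <- heads[[1]]
  if (n_heads > 1L) for (h in 2:n_heads) out <- ad_cbind(out, heads[[h]])
  ad_mm(out, p$WO)
}

layernorm_ad <- function(X, gamma, beta) {
  d <- ncol(ad_value(X))
  ones_col <- matrix(1, d, 1)
  ones_row <- matrix(1, 1, d)
  mu <- ad_scale(ad_mm(X, ad_leaf(ones_col)), 1 / d)
  center <- ad_sub(X, ad_mm(mu, ad_leaf(ones_row)))
  v <- ad_scale(ad_mm(ad_mul(center, center), ad_leaf(ones_col)), 1 / d)
  rsd <- ad_powc(v, -0.5, shift = 1e-5)
  normed <- ad_mul(center, ad_mm(rsd, ad_leaf(ones_row)))
  ad_add(ad_mul(normed, gamma), beta)
}

transformer_forward_ad <- function(prep, pn, cfg, units = FALSE) {
  p <- pn$transformer
  X <- ad_rows(pn$emb, prep$flat_ids + 1L)
  if (!identical(cfg$positional_encoding, FALSE)) {
    pos <- unlist(lapply(prep$lens, seq_len), use.names = FALSE)
    X <- ad_addc(X, sinusoidal_pe(pos, cfg$d))
  }
  for (l in seq_len(cfg$n_transformer_layers)) {
    pl <- p[[paste0("layer", l)]]
    attn <- attention_ad(X, pl, cfg$n_heads, prep$attn_mask)
    Xh <- layernorm_ad(ad_add(X, attn), pl$ln_gamma, pl$ln_beta)
    X <- ad_add(ad_mm(ad_relu(ad_add(ad_mm(Xh, pl$W1), pl$b1)), pl$W2), pl$b2)
  }
  pooled <- ad_mm(ad_leaf(prep$pool), X)
  out <- list(mol = ad_add(ad_mm(pooled, p$pool$W), p$pool$b))
  if (units) out$units <- X
  out
}

# ---- GAT --------------------------------------------------------------------

gat_attn_dense_ad <- function(H_in, pl, adj, slope) {
  HW <- ad_mm(H_in, pl$W)
  n <- nrow(ad_value(HW))
  ones_row <- ad_leaf(matrix(1, 1, n))
  e_src <- ad_mm(HW, pl$a_src)
  e_dst <- ad_mm(HW, pl$a_dst)
  logits <- ad_leaky_relu(ad_add(ad_mm(e_src, ones_row),
                                 ad_t(ad_mm(e_dst, ones_row))), slope)
  A <- ad_softmax_rows(logits, adj)
  list(A = A, HW = HW)
}

gat_layer_ad <- function(H_in, pl, adj, slope) {
  at <- gat_attn_dense_ad(H_in, pl, adj, slope)
  ad_elu(ad_mm(at$A, at$HW))
}

gat_forward_ad <- function(prep, pn, cfg, units = FALSE) {
  p <- pn$gat
  H0 <- ad_leaf(prep$features)
  H1 <- gat_layer_ad(H0, p$layer1, prep$adj, cfg$leaky_slope)
  H2 <- gat_layer_ad(H1, p$layer2, prep$adj, cfg$leaky_slope)
  pooled <- ad_rbind_list(lapply(seq_len(prep$B), function(i) {
    ad_colmax(ad_rows(H2, which(prep$node_mol == i)))
  }))
  mol <- mlp_ad(pooled, p$mlp)
  out <- list(mol = mol)
  if (units) out$units <- H2
  out
}

mlp_ad <- function(X, p) {
  ad_add(ad_mm(ad_relu(ad_add(ad_mm(X, p$W1), p$b1)), p$W2), p$b2)
}

# run all three encoders on a batch of featurized molecules
encode_batch_ad <- function(mols, pn, cfg, units = FALSE,
                            which_enc = c("B", "T", "G")) {
  out <- list()
  if (any(c("B", "T") %in% which_enc)) {
    sp <- prep_seq_batch(mols)
    if ("B" %in% which_enc) out$x <- bilstm_forward_ad(sp, pn, cfg, units)
    if ("T" %in% which_enc) out$y <- transformer_forward_ad(sp, pn, cfg, units)
    out$seq_prep <- sp
  }
  if ("G" %in% which_enc) {
    gp <- prep_graph_batch(mols)
    out$z <- gat_forward_ad(gp, pn, cfg, units)
    out$graph_prep <- gp
  }
  out
}

# ---- exported molecule-level operations ------------------------------------

#' One LSTM cell step
#'
#' Applies the forget/input/output-gate recurrence: `f, i, o` are sigmoid
#' gates over `[h_{t-1}, x_t]`, the cell updates as
#' `C_t = f * C_{t-1} + i * tanh(W_c [h,x] + b_c)` and the hidden state as
#' `h_t = o * tanh(C_t)`.
#'
#' @param x_t input vector.
#' @param prev list with `hidden` and `cell` vectors (equal length).
#' @param params list of `Wf, Wi, Wc, Wo` (`(d_in + h) x h`) and
#'   `bf, bi, bc, bo` (`1 x h`).
#' @return List with `hidden`, `cell`, and the gate activations `f`, `i`, `o`.
#' @export
lstm_cell_step <- function(x_t, prev, params) {
  x <- as_matrix(x_t); h <- as_matrix(prev$hidden); cc <- as_matrix(prev$cell)
  if (ncol(x) + ncol(h) != nrow(params$Wf)) {
    stop("lstm_cell_step: input/state dimensions do not match params")
  }
  ad_tape_reset()
  st <- lstm_step_ad(ad_leaf(x), ad_leaf(h), ad_leaf(cc), tree_map(params, ad_leaf))
  list(hidden = st$h$value, cell = st$c$value,
       f = st$f$value, i = st$i$value, o = st$o$value)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, each attention row a probability vector.
#'
#' @param Q,K,V numeric matrices; `Q` and `K` share column count `d_k`.
#' @return List with `output` (the attended values) and `weights` (the
#'   row-stochastic attention matrix).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  Q <- as_matrix(Q); K <- as_matrix(K); V <- as_matrix(V)
  if (ncol(Q) == 0L) stop("d_k = 0: attention undefined")
  if (ncol(Q) != ncol(K)) stop("Q and K must share column count d_k")
  ad_tape_reset()
  A <- ad_softmax_rows(ad_scale(ad_mm(ad_leaf(Q), ad_t(ad_leaf(K))),
                                1 / sqrt(ncol(Q))))
  out <- ad_mm(A, ad_leaf(V))
  list(output = out$value, weights = A$value)
}

single_mol_prep <- function(token_ids) {
  token_ids <- as.integer(token_ids)
  if (length(token_ids) == 0L) stop("empty token sequence")
  mols <- list(list(enc = list(token_ids = token_ids,
                               atom_mask = rep(TRUE, length(token_ids)),
                               length = length(token_ids))))
  prep_seq_batch(mols)
}

#' Encode a token sequence with the BiLSTM
#'
#' The molecule feature concatenates the two directions' final hidden states
#' and maps them linearly to the shared dimension d; unit features do the
#' same per position.
#'
#' @param token_ids integer vector of token ids (from [encode_tokens()]).
#' @param params full parameter tree (from [init_params()]).
#' @param config a `molfuse_config`.
#' @return List with `unit_features` (length x d) and `molecule_feature`
#'   (1 x d).
#' @export
bilstm_encode <- function(token_ids, params, config) {
  prep <- single_mol_prep(token_ids)
  ad_tape_reset()
  pn <- wrap_params(params[c("emb", "bilstm")])
  out <- bilstm_forward_ad(prep, pn, config, units = TRUE)
  list(unit_features = out$units$value, molecule_feature = out$mol$value)
}

#' Encode a token sequence with the Transformer
#'
#' Pipeline: embedding, additive sinusoidal position encoding, multi-head
#' scaled dot-product self-attention, residual connection with layer
#' normalization, then a two-linear feed-forward network with ReLU. The
#' molecule feature is the mean over positions mapped linearly to d.
#'
#' @inheritParams bilstm_encode
#' @return List with `unit_features` and `molecule_feature`.
#' @export
transformer_encode <- function(token_ids, params, config) {
  prep <- single_mol_prep(token_ids)
  if (prep$Lmax > config$max_len) stop("sequence longer than max_len")
  ad_tape_reset()
  pn <- wrap_params(params[c("emb", "transformer")])
  out <- transformer_forward_ad(prep, pn, config, units = TRUE)
  list(unit_features = out$units$value, molecule_feature = out$mol$value)
}

graph_adj_with_self_loops <- function(n_atoms, edges) {
  adj <- diag(1, n_atoms)
  if (nrow(edges) > 0L) adj[cbind(edges[, 1], edges[, 2])] <- 1
  adj
}

#' Graph-attention coefficients of one GAT layer
#'
#' Edge logits `e_ij = LeakyReLU(a^T [W h_i || W h_j])` are normalized with a
#' softmax over each node's neighborhood (self-loops included), so each
#' node's coefficients sum to one.
#'
#' @param node_features numeric matrix (n_atoms x input dim).
#' @param edges two-column integer matrix of directed edges.
#' @param params a GAT layer parameter list (`W`, `a_src`, `a_dst`).
#' @param slope LeakyReLU negative slope.
#' @return A tibble with columns `from`, `to`, `weight`; for every `from`
#'   node the weights sum to 1.
#' @export
gat_attention_coeffs <- function(node_features, edges, params, slope = 0.2) {
  node_features <- as_matrix(node_features)
  n <- nrow(node_features)
  if (n == 0L) stop("empty graph")
  adj <- graph_adj_with_self_loops(n, edges)
  ad_tape_reset()
  at <- gat_attn_dense_ad(ad_leaf(node_features), tree_map(params, ad_leaf),
                          adj, slope)
  idx <- which(adj > 0, arr.ind = TRUE)
  tibble::tibble(from = idx[, 1], to = idx[, 2],
                 weight = at$A$value[idx]) |>
    dplyr::arrange(.data$from, .data$to)
}

#' One graph-attention layer
#'
#' `h'_i = ELU(sum_j a_ij W h_j)` over the softmax-normalized neighborhood
#' (self-loops included).
#'
#' @inheritParams gat_attention_coeffs
#' @return Numeric matrix of updated node features.
#' @export
gat_layer <- function(node_features, edges, params, slope = 0.2) {
  node_features <- as_matrix(node_features)
  n <- nrow(node_features)
  if (n == 0L) stop("empty graph")
  adj <- graph_adj_with_self_loops(n, edges)
  ad_tape_reset()
  gat_layer_ad(ad_leaf(node_features), tree_map(params, ad_leaf),
               adj, slope)$value
}

#' Encode a molecular graph with the two-layer GAT
#'
#' Two graph-attention layers, then an elementwise max over atoms followed by
#' a two-layer MLP gives the molecule feature.
#'
#' @param graph a `mol_graph` from [smiles_to_graph()].
#' @param params full parameter tree.
#' @param config a `molfuse_config`.
#' @return List with `unit_features` (n_atoms x d), `molecule_feature`
#'   (1 x d), and `pooled_pre_mlp` (the max-pooled vector before the MLP).
#' @export
gat_encode <- function(graph, params, config) {
  stopifnot(inherits(graph, "mol_graph"))
  if (graph$n_atoms == 0L) stop("empty graph")
  prep <- list(B = 1L, ns = graph$n_atoms, offsets = 0L,
               features = graph$node_features,
               adj = graph_adj_with_self_loops(graph$n_atoms, graph$edges),
               node_mol = rep(1L, graph$n_atoms))
  ad_tape_reset()
  pn <- list(gat = wrap_params(params$gat))
  out <- gat_forward_ad(prep, pn, config, units = TRUE)
  list(unit_features = out$units$value,
       molecule_feature = out$mol$value,
       pooled_pre_mlp = apply(out$units$value, 2, max))
}
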