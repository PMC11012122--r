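# Hierarchical elem-feature fusion.
#
# Two feature matrices are stacked as a 2-channel image over (N, d), a 3x3
# convolution (padding 1) maps them to one channel, and a sigmoid turns that
# into an attention weight matrix W in (0,1). One branch is weighted by W,
# the other by its exact elementwise complement 1 - W; each branch adds a
# residual of its unweighted feature and passes through a linear + ReLU
# block, and the two branches are summed. Hierarchically, the two sequence
# features are fused first and the result is fused with the graph feature.

shift_mat <- function(n, k) {
  s <- matrix(0, n, n)
  if (k == 0) {
    diag(s) <- 1
  } else if (abs(k) < n) {
    idx <- seq_len(n - abs(k))
    if (k > 0) s[cbind(idx, idx + k)] <- 1 else s[cbind(idx + abs(k), idx)] <- 1
  }
  s
}

# 3x3 convolution, 2 channels -> 1, zero padding 1, expressed through shift
# matrices so the whole thing stays on the autodiff tape. Each molecule's
# stacked feature map is a 1 x d image (rows of the input matrix are
# independent molecules), so the kernel's vertical taps always fall on zero
# padding and only the centre row of the kernel is active; convolving along
# d never mixes molecules, keeping predictions batch-independent.
conv2d_two_channel_ad <- function(Xa, Xb, wa, wb, bias) {
  d <- ncol(ad_value(Xa))
  out <- NULL
  for (ch in 1:2) {
    X <- if (ch == 1) Xa else Xb
    Wn <- if (ch == 1) wa else wb
    for (dx in -1:1) {
      w_scalar <- ad_cols(ad_rows(Wn, 2L), dx + 2L)
      shifted <- ad_mm(X, ad_leaf(t(shift_mat(d, dx))))
      term <- ad_mul(shifted, w_scalar)
      out <- if (is.null(out)) term else ad_add(out, term)
    }
  }
  ad_add(out, bias)
}

fc_ad <- function(X, W, b) ad_relu(ad_add(ad_mm(X, W), b))

attention_fuse_ad <- function(ha, hb, p) {
  Wattn <- ad_sigmoid(conv2d_two_channel_ad(ha, hb, p$conv_wa, p$conv_wb,
                                            p$conv_b))
  Wcomp <- ad_addc(ad_scale(Wattn, -1), 1)
  branch_a <- fc_ad(ad_add(ad_mul(ha, Wattn), ha), p$fc_a_W, p$fc_a_b)
  branch_b <- fc_ad(ad_add(ad_mul(hb, Wcomp), hb), p$fc_b_W, p$fc_b_b)
  list(out = ad_add(branch_a, branch_b), Wattn = Wattn)
}

#' Attention-weighted fusion of two feature matrices
#'
#' Computes `W_attn = sigmoid(conv2d(stack(ha, hb)))` and returns
#' `FC(ha * W_attn + ha) + FC(hb * (1 - W_attn) + hb)`; the weight on `hb`
#' is exactly the elementwise complement of the weight on `ha`.
#'
#' @param ha,hb numeric matrices of identical shape (N x d).
#' @param block a fusion-block parameter list (as in
#'   `init_params()$fusion$seq_block`).
#' @return List with `output` (N x d) and `weights` (the attention matrix,
#'   entries strictly in (0, 1)).
#' @export
attention_fuse <- function(ha, hb, block) {
  ha <- as_matrix(ha); hb <- as_matrix(hb)
  if (!all(dim(ha) == dim(hb))) stop("ha and hb must have identical shapes")
  ad_tape_reset()
  res <- attention_fuse_ad(ad_leaf(ha), ad_leaf(hb), tree_map(block, ad_leaf))
  list(output = res$out$value, weights = res$Wattn$value)
}

hierarchical_fuse_ad <- function(hx, hy, hz, p) {
  seq_fused <- attention_fuse_ad(hx, hy, p$seq_block)$out
  attention_fuse_ad(seq_fused, hz, p$sg_block)$out
}

#' Hierarchical fusion of the three encoder features
#'
#' The two sequence features are fused first (BiLSTM with Transformer), then
#' the fused sequence feature is fused with the graph feature, using two
#' structurally identical but unshared fusion blocks.
#'
#' @param hx,hy,hz numeric matrices of identical shape (N x d).
#' @param block_seq,block_sg fusion-block parameter lists.
#' @return Fused N x d matrix.
#' @export
hierarchical_fuse <- function(hx, hy, hz, block_seq, block_sg) {
  hx <- as_matrix(hx); hy <- as_matrix(hy); hz <- as_matrix(hz)
  if (!all(dim(hx) == dim(hy)) || !all(dim(hx) == dim(hz))) {
    stop("hx, hy, hz must have identical shapes")
  }
  ad_tape_reset()
  hierarchical_fuse_ad(ad_leaf(hx), ad_leaf(hy), ad_leaf(hz),
                       list(seq_block = tree_map(block_seq, ad_leaf),
                            sg_block = tree_map(block_sg, ad_leaf)))$value
}

# concat-only fallback (ablation baseline): plain concatenation + linear+ReLU
concat_fuse_ad <- function(features, p) {
  X <- features[[1]]
  if (length(features) > 1L) {
    for (k in 2:length(features)) X <- ad_cbind(X, features[[k]])
  }
  fc_ad(X, p$W, p$b)
}
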