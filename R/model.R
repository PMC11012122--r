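# Model configuration, parameter initialization, the Adam optimizer, and
# checkpoint plumbing shared by pretraining and fine-tuning.

#' Model and training configuration
#'
#' All dimensions and optimization knobs in one validated list. The shared
#' feature dimension `d` is the size of each encoder's molecule feature
#' (h_x, h_y, h_z); the pairwise reconstruction objective compares features
#' across views, which forces this common space.
#'
#' @param d shared feature dimension of the three encoders (default 64).
#' @param lstm_hidden hidden size per BiLSTM direction.
#' @param n_heads attention heads in the Transformer (must divide `d`).
#' @param n_transformer_layers Transformer blocks (default 2).
#' @param d_ff Transformer feed-forward width.
#' @param latent_dim VAE latent dimension.
#' @param vae_hidden hidden width of the posterior/projector MLPs.
#' @param head_hidden hidden width of the prediction head.
#' @param beta weight of the KL terms in the pairwise loss (>= 0).
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param max_len maximum token-sequence length; longer inputs error.
#' @param leaky_slope negative slope of the graph-attention LeakyReLU.
#' @param positional_encoding add sinusoidal position encoding in the
#'   Transformer (disable only to probe permutation equivariance).
#' @param fusion `"attention"` (hierarchical elem-feature fusion) or
#'   `"concat"` (plain concatenation + linear, the ablation baseline).
#' @param encoder_set subset of encoders used downstream, e.g. `"BTG"`,
#'   `"BT"`, `"G"` (B = BiLSTM, T = Transformer, G = GAT).
#' @param seed integer RNG seed.
#' @return A list of class `molfuse_config`.
#' @export
molfuse_config <- function(d = 64L, lstm_hidden = d, n_heads = 4L,
                           n_transformer_layers = 2L, d_ff = 2L * d,
                           latent_dim = max(2L, d %/% 2L), vae_hidden = d,
                           head_hidden = d, beta = 0.1, lr = 1e-3,
                           epochs = 20L, batch_size = 32L, max_len = 256L,
                           leaky_slope = 0.2, positional_encoding = TRUE,
                           fusion = "attention",
                           encoder_set = "BTG", seed = 1L) {
  stopifnot(d >= 2L, d %% n_heads == 0L, latent_dim >= 1L, beta >= 0,
            lr > 0, epochs >= 1L, batch_size >= 1L, max_len >= 1L,
            fusion %in% c("attention", "concat"))
  if (!grepl("^[BTG]+$", encoder_set) || nchar(encoder_set) > 3L) {
    stop("encoder_set must be a non-empty combination of B, T, G")
  }
  structure(list(d = as.integer(d), lstm_hidden = as.integer(lstm_hidden),
                 n_heads = as.integer(n_heads),
                 n_transformer_layers = as.integer(n_transformer_layers),
                 d_ff = as.integer(d_ff), latent_dim = as.integer(latent_dim),
                 vae_hidden = as.integer(vae_hidden),
                 head_hidden = as.integer(head_hidden),
                 beta = beta, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 max_len = as.integer(max_len), leaky_slope = leaky_slope,
                 positional_encoding = isTRUE(positional_encoding),
                 fusion = fusion, encoder_set = encoder_set,
                 seed = as.integer(seed)),
            class = "molfuse_config")
}

# ---- parameter trees --------------------------------------------------------

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

zeros <- function(nr, nc) matrix(0, nr, nc)

init_lstm_dir <- function(d_in, h) {
  list(Wf = glorot(d_in + h, h), Wi = glorot(d_in + h, h),
       Wc = glorot(d_in + h, h), Wo = glorot(d_in + h, h),
       bf = zeros(1, h), bi = zeros(1, h), bc = zeros(1, h), bo = zeros(1, h))
}

init_transformer_layer <- function(d, d_ff) {
  list(WQ = glorot(d, d), WK = glorot(d, d), WV = glorot(d, d),
       WO = glorot(d, d),
       ln_gamma = matrix(1, 1, d), ln_beta = zeros(1, d),
       W1 = glorot(d, d_ff), b1 = zeros(1, d_ff),
       W2 = glorot(d_ff, d), b2 = zeros(1, d))
}

init_gat_layer <- function(d_in, d_out) {
  list(W = glorot(d_in, d_out), a_src = glorot(d_out, 1), a_dst = glorot(d_out, 1))
}

init_mlp <- function(d_in, d_hidden, d_out) {
  list(W1 = glorot(d_in, d_hidden), b1 = zeros(1, d_hidden),
       W2 = glorot(d_hidden, d_out), b2 = zeros(1, d_out))
}

init_vae_head <- function(d, hidden, latent) {
  list(post = list(W1 = glorot(d, hidden), b1 = zeros(1, hidden),
                   W_mu = glorot(hidden, latent), b_mu = zeros(1, latent),
                   W_lv = glorot(hidden, latent), b_lv = zeros(1, latent)),
       proj = init_mlp(latent, hidden, d))
}

init_fusion_block <- function(d) {
  list(conv_wa = glorot(3, 3), conv_wb = glorot(3, 3), conv_b = zeros(1, 1),
       fc_a_W = glorot(d, d), fc_a_b = zeros(1, d),
       fc_b_W = glorot(d, d), fc_b_b = zeros(1, d))
}

#' Initialize all model parameters
#'
#' @param vocab a `smiles_vocab`.
#' @param config a `molfuse_config`.
#' @param n_tasks number of prediction tasks (adds fusion + head parameters
#'   when not `NULL`).
#' @param seed RNG seed for initialization.
#' @return A nested named list of numeric matrices.
#' @keywords internal
#' @export
init_params <- function(vocab, config, n_tasks = NULL, seed = config$seed) {
  d <- config$d; h <- config$lstm_hidden
  withr::with_seed(seed, {
    p <- list(
      emb = glorot(length(vocab), d),
      bilstm = list(
        fw = init_lstm_dir(d, h), bw = init_lstm_dir(d, h),
        W_mol = glorot(2L * h, d), b_mol = zeros(1, d),
        W_unit = glorot(2L * h, d), b_unit = zeros(1, d)
      ),
      transformer = c(
        lapply(seq_len(config$n_transformer_layers), function(i)
          init_transformer_layer(d, config$d_ff)),
        list(pool = list(W = glorot(d, d), b = zeros(1, d)))
      ),
      gat = list(
        layer1 = init_gat_layer(atom_feature_dim(), d),
        layer2 = init_gat_layer(d, d),
        mlp = init_mlp(d, d, d)
      ),
      vae = list(x = init_vae_head(d, config$vae_hidden, config$latent_dim),
                 y = init_vae_head(d, config$vae_hidden, config$latent_dim),
                 z = init_vae_head(d, config$vae_hidden, config$latent_dim))
    )
    names(p$transformer) <- c(paste0("layer", seq_len(config$n_transformer_layers)), "pool")
    if (!is.null(n_tasks)) {
      n_enc <- nchar(config$encoder_set)
      p$fusion <- list(seq_block = init_fusion_block(d),
                       sg_block = init_fusion_block(d),
                       concat = list(W = glorot(n_enc * d, d), b = zeros(1, d)))
      p$head <- init_mlp(d, config$head_hidden, as.integer(n_tasks))
    }
    p
  })
}

# map f over the leaves (matrices) of a parameter tree
tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

# map f over aligned leaves of two parameter trees
tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (k in seq_along(x)) out[[k]] <- tree_map2(x[[k]], y[[k]], f)
    out
  } else {
    f(x, y)
  }
}

wrap_params <- function(params) tree_map(params, ad_leaf)

collect_grads <- function(nodes) {
  tree_map(nodes, function(n) if (is.null(n$grad)) n$value * 0 else n$grad)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  mhat_scale <- 1 / (1 - beta1^state$t)
  vhat_scale <- 1 / (1 - beta2^state$t)
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m * mhat_scale) / (sqrt(v * vhat_scale) + eps)
  })
  list(params = tree_map2(params, upd, function(p, u) p - u), state = state)
}

# ---- checkpoints ------------------------------------------------------------

#' Save a checkpoint (parameters + vocabulary + config)
#' @param object a `molfuse_pretrain` or `molfuse_model`.
#' @param path output `.rds` path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path `.rds` path.
#' @return The stored object.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
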