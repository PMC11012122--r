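# Generative self-supervised pretraining.
#
# Each encoder's pooled molecule feature gets a VAE head: a posterior MLP
# emitting (mu, logvar), a reparameterized latent draw, and a projector back
# into the shared d-dimensional representation space. Views are trained in
# pairs: the projection of view a's latent must reconstruct view b's feature
# (taken through a stop-gradient, so b is a fixed target for that term, and
# symmetrically), plus a beta-weighted KL pull of each posterior towards the
# standard-normal prior. The total objective is the mean of the three
# pairwise losses.

#' Reparameterization trick
#'
#' `z = mu + exp(0.5 * logvar) * eps` with `eps ~ N(0, I)`; `logvar` stores
#' the log-variance, the numerically stable parameterization.
#'
#' @param mu,logvar numeric vectors/matrices of equal shape.
#' @param eps the standard-normal draw, same shape.
#' @return The latent sample `z`.
#' @examples
#' reparameterize(1, log(4), 0.5)  # 1 + 2 * 0.5 = 2
#' @export
reparameterize <- function(mu, logvar, eps) {
  stopifnot(length(mu) == length(logvar), length(mu) == length(eps))
  mu + exp(0.5 * logvar) * eps
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form: `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`, always >= 0,
#' zero iff the posterior equals the prior.
#'
#' @param mu,logvar numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
kl_to_standard_normal <- function(mu, logvar) {
  if (!all(is.finite(mu)) || !all(is.finite(logvar))) {
    stop("non-finite posterior parameters")
  }
  stopifnot(length(mu) == length(logvar))
  0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)
}

#' Squared-error reconstruction term against a stop-gradient target
#'
#' `||projected - SG(target)||^2`. In training the target feature is routed
#' through the stop-gradient operator, so this term never backpropagates into
#' the encoder that produced the target.
#'
#' @param projected,target_feature numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
reconstruction_term <- function(projected, target_feature) {
  if (length(projected) != length(target_feature)) {
    stop("dimension mismatch between projected and target features")
  }
  sum((projected - target_feature)^2)
}

# ---- tape-side pieces -------------------------------------------------------

vae_posterior_ad <- function(h, p) {
  hid <- ad_relu(ad_add(ad_mm(h, p$post$W1), p$post$b1))
  list(mu = ad_add(ad_mm(hid, p$post$W_mu), p$post$b_mu),
       logvar = ad_add(ad_mm(hid, p$post$W_lv), p$post$b_lv))
}

reparameterize_ad <- function(mu, logvar, eps) {
  ad_add(mu, ad_mulc(ad_exp(ad_scale(logvar, 0.5)), eps))
}

# batch-mean KL to the standard normal
kl_ad <- function(mu, logvar) {
  B <- nrow(ad_value(mu))
  elem <- ad_sub(ad_add(ad_mul(mu, mu), ad_exp(logvar)), ad_addc(logvar, 1))
  ad_scale(ad_sum(elem), 0.5 / B)
}

# batch-mean squared reconstruction error against a stop-gradient target
recon_ad <- function(projected, target) {
  B <- nrow(ad_value(projected))
  ad_scale(ad_sumsq(ad_sub(projected, ad_stopgrad(target))), 1 / B)
}

# one view's VAE pass: posterior, one latent draw, projection
vae_view_ad <- function(h, p, eps) {
  post <- vae_posterior_ad(h, p)
  z <- reparameterize_ad(post$mu, post$logvar, eps)
  list(mu = post$mu, logvar = post$logvar, z = z, q = mlp_ad(z, p$proj))
}

pair_loss_ad <- function(view_a, view_b, h_a, h_b, beta) {
  recon <- ad_scale(ad_add(recon_ad(view_a$q, h_b), recon_ad(view_b$q, h_a)), 0.5)
  if (beta > 0) {
    kl <- ad_scale(ad_add(kl_ad(view_a$mu, view_a$logvar),
                          kl_ad(view_b$mu, view_b$logvar)), beta / 2)
    ad_add(recon, kl)
  } else {
    recon
  }
}

# full SSL loss over a featurized batch; pairs selects which of the three
# pairwise terms participate (the pretraining-pair ablation)
ssl_loss_ad <- function(mols, pn, cfg, eps, pairs = c("xy", "xz", "yz")) {
  need <- unique(unlist(strsplit(pairs, "")))
  which_enc <- c(x = "B", y = "T", z = "G")[need]
  enc <- encode_batch_ad(mols, pn, cfg, units = FALSE, which_enc = which_enc)
  views <- list()
  for (v in need) {
    views[[v]] <- vae_view_ad(enc[[v]]$mol, pn$vae[[v]], eps[[v]])
  }
  pair_nodes <- list()
  for (pr in pairs) {
    a <- substr(pr, 1, 1); b <- substr(pr, 2, 2)
    pair_nodes[[pr]] <- pair_loss_ad(views[[a]], views[[b]],
                                     enc[[a]]$mol, enc[[b]]$mol, cfg$beta)
  }
  total <- pair_nodes[[1]]
  if (length(pair_nodes) > 1L) {
    for (k in 2:length(pair_nodes)) total <- ad_add(total, pair_nodes[[k]])
  }
  total <- ad_scale(total, 1 / length(pair_nodes))
  list(total = total,
       pair_values = vapply(pair_nodes, function(n) n$value[1], numeric(1)))
}

#' Pairwise representation-reconstruction loss between two views
#'
#' `L_ab = 1/2 [recon(a -> b) + recon(b -> a)] + beta/2 [KL_a + KL_b]`:
#' each view's latent projection must reconstruct the other view's feature
#' (stop-gradient target), and each posterior is pulled towards the prior.
#' Symmetric in the two views and non-negative for `beta >= 0`.
#'
#' @param feature_a,feature_b molecule features (vectors of length d or
#'   `B x d` matrices).
#' @param heads list with elements `a` and `b`, each a VAE head parameter
#'   list (as in `init_params()$vae$x`).
#' @param eps_a,eps_b standard-normal draws of latent dimension.
#' @param beta KL weight (>= 0).
#' @return Scalar loss.
#' @export
pair_loss <- function(feature_a, feature_b, heads, eps_a, eps_b, beta = 0.1) {
  ha <- as_matrix(feature_a); hb <- as_matrix(feature_b)
  ad_tape_reset()
  han <- ad_leaf(ha); hbn <- ad_leaf(hb)
  pa <- tree_map(heads$a, ad_leaf); pb <- tree_map(heads$b, ad_leaf)
  va <- vae_view_ad(han, pa, as_matrix(eps_a))
  vb <- vae_view_ad(hbn, pb, as_matrix(eps_b))
  pair_loss_ad(va, vb, han, hbn, beta)$value[1]
}

#' Combine reconstruction and KL terms into one pairwise loss
#'
#' The scalar arithmetic of the pairwise objective:
#' `0.5 * (recon_ab + recon_ba) + beta / 2 * (kl_a + kl_b)`.
#'
#' @param recon_ab,recon_ba the two directed reconstruction terms.
#' @param kl_a,kl_b the two views' KL divergences.
#' @param beta KL weight.
#' @return Scalar loss.
#' @examples
#' combine_pair_loss(1, 3, 2, 4, beta = 1)  # 5
#' @export
combine_pair_loss <- function(recon_ab, recon_ba, kl_a, kl_b, beta = 0.1) {
  0.5 * (recon_ab + recon_ba) + beta / 2 * (kl_a + kl_b)
}

#' Total pretraining objective
#'
#' The arithmetic mean of the three pairwise losses.
#' @param Lxy,Lxz,Lyz finite scalars.
#' @return `mean(Lxy, Lxz, Lyz)`.
#' @export
total_pretrain_loss <- function(Lxy, Lxz, Lyz) {
  stopifnot(is.finite(Lxy), is.finite(Lxz), is.finite(Lyz))
  (Lxy + Lxz + Lyz) / 3
}

#' Pretrain the three encoders with the pairwise generative objective
#'
#' @param corpus character vector of SMILES (unlabeled); unparseable entries
#'   are dropped with a warning.
#' @param config a `molfuse_config`.
#' @param pairs which pairwise terms form the objective; default all three
#'   (`"xy"` = BiLSTM-Transformer, `"xz"` = BiLSTM-GAT, `"yz"` =
#'   Transformer-GAT). Subsets implement the pretraining-pair ablation.
#' @param verbose print per-epoch losses.
#' @return An object of class `molfuse_pretrain`: best-loss parameters
#'   (`params`), final-epoch parameters (`params_final`), `vocab`, `config`,
#'   the per-epoch loss `log` tibble, and `best_epoch`.
#' @export
pretrain <- function(corpus, config = molfuse_config(), pairs = c("xy", "xz", "yz"),
                     verbose = FALSE) {
  stopifnot(length(corpus) >= 1L, all(pairs %in% c("xy", "xz", "yz")),
            length(pairs) >= 1L)
  parsed <- vapply(corpus, function(s) {
    tryCatch({ smiles_to_graph(s); TRUE }, error = function(e) FALSE)
  }, logical(1))
  if (!any(parsed)) stop("no molecule in the corpus could be parsed")
  if (!all(parsed)) {
    warning(sum(!parsed), " unparseable molecule(s) dropped from the corpus")
    corpus <- corpus[parsed]
  }
  vocab <- build_vocab(corpus)
  params <- init_params(vocab, config, n_tasks = NULL, seed = config$seed)
  mols <- featurize_molecules(corpus, vocab, config$max_len)
  n <- length(mols)
  state <- adam_init(params)
  log_rows <- vector("list", config$epochs)
  best <- list(loss = Inf, epoch = NA_integer_, params = NULL)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      pair_sums <- stats::setNames(numeric(length(pairs)), pairs)
      total_sum <- 0
      for (bi in batches) {
        batch <- mols[bi]
        eps <- list()
        for (v in unique(unlist(strsplit(pairs, "")))) {
          eps[[v]] <- matrix(stats::rnorm(length(batch) * config$latent_dim),
                             length(batch), config$latent_dim)
        }
        ad_tape_reset()
        pn <- wrap_params(params)
        loss <- ssl_loss_ad(batch, pn, config, eps, pairs)
        ad_backward(loss$total)
        upd <- adam_step(params, collect_grads(pn), state, config$lr)
        params <- upd$params; state <- upd$state
        pair_sums <- pair_sums + loss$pair_values
        total_sum <- total_sum + loss$total$value[1]
      }
      nb <- length(batches)
      row <- tibble::tibble(epoch = epoch,
                            l_xy = NA_real_, l_xz = NA_real_, l_yz = NA_real_,
                            loss = total_sum / nb)
      for (pr in pairs) row[[paste0("l_", pr)]] <- pair_sums[[pr]] / nb
      log_rows[[epoch]] <- row
      if (row$loss < best$loss) {
        best <- list(loss = row$loss, epoch = epoch, params = params)
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f", epoch, row$loss))
      }
    }
  })
  ad_tape_reset()
  structure(list(params = best$params, params_final = params, vocab = vocab,
                 config = config, log = dplyr::bind_rows(log_rows),
                 best_epoch = best$epoch, pairs = pairs,
                 n_molecules = n),
            class = "molfuse_pretrain")
}

#' @export
print.molfuse_pretrain <- function(x, ...) {
  cat(sprintf("<molfuse_pretrain> %d molecules, %d epochs (best epoch %d, loss %.4f)\n",
              x$n_molecules, nrow(x$log), x$best_epoch,
              x$log$loss[x$best_epoch]))
  invisible(x)
}

#' Tidy the pretraining log
#' @param x a `molfuse_pretrain`.
#' @param ... ignored.
#' @return Tibble with per-epoch pair losses and the total.
#' @export
tidy.molfuse_pretrain <- function(x, ...) x$log

#' One-row summary of a pretraining run
#' @param x a `molfuse_pretrain`.
#' @param ... ignored.
#' @return A one-row tibble.
#' @export
glance.molfuse_pretrain <- function(x, ...) {
  tibble::tibble(n_molecules = x$n_molecules, epochs = nrow(x$log),
                 best_epoch = x$best_epoch,
                 best_loss = x$log$loss[x$best_epoch],
                 final_loss = x$log$loss[nrow(x$log)])
}

#' Plot the pretraining loss curves
#' @param object a `molfuse_pretrain`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.molfuse_pretrain <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "term",
                            values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Pairwise reconstruction pretraining") +
    ggplot2::theme_minimal()
}
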