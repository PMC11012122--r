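# The generative SSL objective: reparameterization, closed-form KL,
# stop-gradient reconstruction, pairwise losses, and the pretraining loop.

test_that("reparameterization is the exact location-scale transform", {
  expect_equal(reparameterize(c(1, 2), c(0, 0), c(0, 0)), c(1, 2))
  expect_equal(reparameterize(c(0, 0), c(0, 0), c(0.3, -1)), c(0.3, -1))
  expect_equal(reparameterize(1, log(4), 0.5), 2)
})

test_that("closed-form KL matches known values and a Monte-Carlo estimate", {
  expect_equal(kl_to_standard_normal(0, 0), 0)
  expect_equal(kl_to_standard_normal(1, 0), 0.5)
  expect_error(kl_to_standard_normal(NaN, 0), "non-finite")

  set.seed(42)
  mu <- rnorm(4, sd = 0.8)
  logvar <- rnorm(4, sd = 0.5)
  closed <- kl_to_standard_normal(mu, logvar)
  expect_gte(closed, 0)

  # Monte-Carlo oracle: E_q[log q(z) - log p(z)] over 10^6 draws
  n <- 1e6
  sd_q <- exp(0.5 * logvar)
  z <- matrix(rnorm(n * 4), n, 4) * matrix(sd_q, n, 4, byrow = TRUE) +
    matrix(mu, n, 4, byrow = TRUE)
  log_q <- sapply(1:4, function(j) dnorm(z[, j], mu[j], sd_q[j], log = TRUE))
  log_p <- sapply(1:4, function(j) dnorm(z[, j], 0, 1, log = TRUE))
  mc <- mean(rowSums(log_q - log_p))
  expect_lt(abs(closed - mc) / closed, 0.01)
})

test_that("reconstruction term is squared distance with a stop-gradient target", {
  expect_equal(reconstruction_term(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(reconstruction_term(rep(1, 5), rep(0, 5)), 5)
  expect_error(reconstruction_term(1:3, 1:4), "mismatch")
})

test_that("stop-gradient blocks all gradient into the target-producing encoder", {
  cfg <- tiny_cfg()
  b <- make_labeled_batch(6)
  params <- init_params(b$vocab, cfg)
  ad <- asNamespace("molfuse")
  ssl <- asNamespace("molfuse")

  # only the x -> y direction: project z_x and reconstruct SG(h_y)
  ad$ad_tape_reset()
  pn <- molfuse:::wrap_params(params)
  enc <- molfuse:::encode_batch_ad(b$mols, pn, cfg, which_enc = c("B", "T"))
  eps <- matrix(0.1, length(b$mols), cfg$latent_dim)
  vx <- ssl$vae_view_ad(enc$x$mol, pn$vae$x, eps)
  loss <- ssl$recon_ad(vx$q, enc$y$mol)
  ad$ad_backward(loss)
  grads <- molfuse:::collect_grads(pn)

  # every Transformer parameter (the target's encoder) gets exactly zero
  trans_flat <- rapply(grads$transformer, function(g) max(abs(g)), how = "unlist")
  expect_true(all(trans_flat == 0))
  # while the producing pathway (BiLSTM + its VAE head) is reached
  bilstm_max <- max(rapply(grads$bilstm, function(g) max(abs(g)), how = "unlist"))
  vae_x_max <- max(rapply(grads$vae$x, function(g) max(abs(g)), how = "unlist"))
  expect_gt(bilstm_max, 0)
  expect_gt(vae_x_max, 0)
})

test_that("pairwise loss arithmetic, symmetry and non-negativity hold", {
  expect_equal(combine_pair_loss(0, 0, 0, 0, beta = 1), 0)
  expect_equal(combine_pair_loss(1, 3, 2, 4, beta = 1), 5)

  cfg <- tiny_cfg()
  b <- make_labeled_batch(4)
  params <- init_params(b$vocab, cfg)
  set.seed(9)
  ha <- matrix(rnorm(cfg$d), 1)
  hb <- matrix(rnorm(cfg$d), 1)
  ea <- matrix(rnorm(cfg$latent_dim), 1)
  eb <- matrix(rnorm(cfg$latent_dim), 1)
  heads <- list(a = params$vae$x, b = params$vae$y)
  heads_rev <- list(a = params$vae$y, b = params$vae$x)
  l_ab <- pair_loss(ha, hb, heads, ea, eb, beta = 0.5)
  l_ba <- pair_loss(hb, ha, heads_rev, eb, ea, beta = 0.5)
  expect_equal(l_ab, l_ba, tolerance = 1e-10)
  expect_gte(l_ab, 0)
})

test_that("the total objective is the arithmetic mean of the three pair losses", {
  expect_equal(total_pretrain_loss(1, 2, 3), 2)
  expect_equal(total_pretrain_loss(0, 0, 0), 0)
  expect_equal(total_pretrain_loss(0.7, 0.7, 0.7), 0.7)
})

test_that("pretraining is reproducible and logs per-pair losses", {
  cfg <- tiny_cfg(epochs = 2L, batch_size = 8L, seed = 13L)
  corp <- generate_corpus(16, seed = 8)
  pt1 <- pretrain(corp, cfg)
  pt2 <- pretrain(corp, cfg)
  expect_equal(pt1$log, pt2$log)
  expect_equal(nrow(pt1$log), 2L)
  expect_true(all(c("l_xy", "l_xz", "l_yz", "loss") %in% names(pt1$log)))
  expect_true(all(pt1$log$loss >= 0))
  # the logged total is the mean of the logged pair losses
  expect_equal(pt1$log$loss,
               (pt1$log$l_xy + pt1$log$l_xz + pt1$log$l_yz) / 3,
               tolerance = 1e-10)
  expect_s3_class(tidy(pt1), "tbl_df")
  expect_equal(glance(pt1)$n_molecules, 16L)
})

test_that("beta = 0 drops the KL pull from the objective", {
  cfg0 <- tiny_cfg(epochs = 1L, beta = 0, seed = 5L)
  corp <- generate_corpus(8, seed = 9)
  b <- make_labeled_batch(4)
  params <- init_params(b$vocab, cfg0)

  # with beta = 0 the pair loss is the pure reconstruction average
  set.seed(1)
  ha <- matrix(rnorm(cfg0$d), 1); hb <- matrix(rnorm(cfg0$d), 1)
  ea <- matrix(0, 1, cfg0$latent_dim); eb <- matrix(0, 1, cfg0$latent_dim)
  heads <- list(a = params$vae$x, b = params$vae$y)
  l0 <- pair_loss(ha, hb, heads, ea, eb, beta = 0)
  l1 <- pair_loss(ha, hb, heads, ea, eb, beta = 1)
  expect_gt(l1, l0)  # the KL contribution is strictly positive here

  pt <- pretrain(corp, cfg0)
  expect_equal(pt$log$loss,
               (pt$log$l_xy + pt$log$l_xz + pt$log$l_yz) / 3,
               tolerance = 1e-10)
})

test_that("restricting to one pair logs only that pair", {
  cfg <- tiny_cfg(epochs = 1L, seed = 3L)
  corp <- generate_corpus(8, seed = 10)
  pt <- pretrain(corp, cfg, pairs = "xy")
  expect_false(anyNA(pt$log$l_xy))
  expect_true(all(is.na(pt$log$l_xz)))
  expect_true(all(is.na(pt$log$l_yz)))
  expect_equal(pt$log$loss, pt$log$l_xy)
})

test_that("an unparseable corpus errors; partial parse drops with a warning", {
  cfg <- tiny_cfg(epochs = 1L)
  expect_error(pretrain(c("not-smiles(", "also-bad("), cfg))
  expect_warning(pt <- pretrain(c("CCO", "CCN", "CCC", "C1CC"), cfg),
                 "dropped")
  expect_equal(pt$n_molecules, 3L)
})
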