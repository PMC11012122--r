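# Metrics, prediction contracts, and the fine-tuning loop's bookkeeping.

test_that("rmse follows its closed form", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(1)
  y <- rnorm(10)
  expect_equal(rmse(y + 0.7, y), 0.7, tolerance = 1e-12)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("multi-task ROC-AUC averages per-task rank AUCs and handles ties", {
  # perfectly ranked single task
  s <- matrix(c(0.9, 0.8, 0.2, 0.1), 4)
  l <- matrix(c(1, 1, 0, 0), 4)
  expect_equal(as.numeric(roc_auc_multitask(s, l)), 1)

  # per-task 0.5 and 1.0 average to 0.75
  s2 <- cbind(c(0.5, 0.5, 0.5, 0.5), c(0.9, 0.8, 0.2, 0.1))
  l2 <- cbind(c(1, 0, 1, 0), c(1, 1, 0, 0))
  res <- roc_auc_multitask(s2, l2)
  expect_equal(as.numeric(res), 0.75)
  expect_equal(unname(attr(res, "per_task")), c(0.5, 1.0))

  # 6-point instance with ties vs the brute-force pairwise oracle
  s3 <- c(0.3, 0.7, 0.7, 0.1, 0.9, 0.3)
  l3 <- c(0, 1, 0, 0, 1, 1)
  expect_equal(as.numeric(roc_auc_multitask(matrix(s3), matrix(l3))),
               auc_pairwise_oracle(s3, l3))

  # invariance under strictly monotone transforms of the scores
  expect_equal(as.numeric(roc_auc_multitask(matrix(exp(3 * s3)), matrix(l3))),
               auc_pairwise_oracle(s3, l3))

  # a one-class task is skipped with a warning
  s4 <- cbind(c(0.2, 0.8), c(0.4, 0.6))
  l4 <- cbind(c(1, 1), c(0, 1))
  expect_warning(res4 <- roc_auc_multitask(s4, l4), "one class")
  expect_equal(as.numeric(res4), 1)

  # missing labels are masked out
  s5 <- matrix(c(0.9, 0.5, 0.2, 0.6), 4)
  l5 <- matrix(c(1, NA, 0, NA), 4)
  expect_equal(as.numeric(roc_auc_multitask(s5, l5)), 1)
})

make_quick_model <- function(cfg = tiny_cfg(epochs = 2L), n = 20L,
                             kind = "regression") {
  corp <- generate_corpus(n, seed = 17)
  data <- if (kind == "regression") {
    make_regression_dataset(corp, c(0.5, 1), 0.2, seed = 3)
  } else {
    make_classification_dataset(corp, "has_ring")
  }
  model <- finetune(NULL, data, config = cfg)
  list(model = model, data = data)
}

test_that("prediction is deterministic, order-preserving, and batch-independent", {
  q <- make_quick_model()
  m <- q$model
  smiles <- q$data$smiles[1:8]

  p1 <- predict(m, smiles)
  p2 <- predict(m, smiles)
  expect_equal(p1, p2)

  # duplicates give identical predictions
  pd <- predict(m, c("CCO", "CCO"))
  expect_equal(pd$y[1], pd$y[2])

  # a molecule alone equals the same molecule inside a batch of 8
  alone <- predict(m, smiles[3])$y
  expect_equal(alone, p1$y[3], tolerance = 1e-5)

  # shuffled input gives correspondingly shuffled output
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  ps <- predict(m, smiles[perm])
  expect_equal(ps$y, p1$y[perm], tolerance = 1e-10)

  # invalid SMILES yields a per-record error while the batch continues
  px <- predict(m, c("CCO", "C1CC", "CCN"))
  expect_true(is.na(px$y[2]))
  expect_false(is.na(px$.error[2]))
  expect_false(anyNA(px$y[c(1, 3)]))
})

test_that("classification predictions are probabilities", {
  q <- make_quick_model(kind = "classification")
  p <- predict(q$model, q$data$smiles[1:6])
  expect_true(all(p$label > 0 & p$label < 1))
})

test_that("a fully missing task contributes nothing to the batch loss", {
  cfg <- tiny_cfg()
  b <- make_labeled_batch(4)
  params <- init_params(b$vocab, cfg, n_tasks = 2L)
  ad <- asNamespace("molfuse")

  labels2 <- cbind(c(1, 0, 1, NA), rep(NA_real_, 4))

  params2 <- init_params(b$vocab, cfg, n_tasks = 2L)
  ad$ad_tape_reset()
  pn <- molfuse:::wrap_params(params2)
  logits <- molfuse:::predict_forward_ad(b$mols, pn, cfg)
  l_masked <- molfuse:::supervised_loss_ad(logits, labels2, "classification")
  ad$ad_backward(l_masked)
  grads <- molfuse:::collect_grads(pn)
  # the head column for the all-NA task receives zero gradient
  expect_equal(max(abs(grads$head$W2[, 2])), 0)
  expect_gt(max(abs(grads$head$W2[, 1])), 0)
})

test_that("fine-tuning updates every parameter group after one step", {
  cfg <- tiny_cfg(epochs = 1L, batch_size = 4L, lr = 1e-2)
  corp <- generate_corpus(8, seed = 23)
  data <- make_regression_dataset(corp, c(0.5, 1), 0.1, seed = 4)
  sp <- random_split(nrow(data), c(0.5, 0.25, 0.25), seed = 1)
  pt <- pretrain(corp, tiny_cfg(epochs = 1L))
  model <- finetune(pt, data, split = sp, config = cfg)
  before <- init_params(pt$vocab, cfg, n_tasks = 1L, seed = cfg$seed)
  for (nm in c("emb", "bilstm", "transformer", "gat")) before[[nm]] <- pt$params[[nm]]
  before$vae <- NULL
  moved <- molfuse:::tree_map2(model$params_final, before,
                               function(a, b) max(abs(a - b)))
  flat <- rapply(moved, identity, how = "unlist")
  # parameters outside the downstream graph cannot move: the BiLSTM
  # unit-feature projection and, under attention fusion, the concat weights
  inert <- grepl("^bilstm\\.(W|b)_unit$|^fusion\\.concat\\.", names(flat))
  expect_true(all(flat[!inert] > 0),
              info = paste("unmoved:",
                           paste(names(flat)[!inert][flat[!inert] == 0],
                                 collapse = ", ")))
  expect_true(all(flat[inert] == 0))
})

test_that("fine-tuning bookkeeping: empty train errors, logs and summaries work", {
  cfg <- tiny_cfg(epochs = 2L)
  corp <- generate_corpus(12, seed = 29)
  data <- make_regression_dataset(corp, c(0.5, 1), 0.2, seed = 5)
  sp <- random_split(nrow(data), seed = 2)
  sp$train <- integer(0)
  expect_error(finetune(NULL, data, split = sp, config = cfg), "empty train")

  model <- finetune(NULL, data, config = cfg)
  expect_equal(nrow(tidy(model)), 2L)
  expect_s3_class(glance(model), "tbl_df")
  ev <- evaluate_model(model, data)
  expect_equal(ev$partition, c("train", "valid", "test"))
  expect_true(all(ev$value[ev$n > 0] >= 0))
})
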