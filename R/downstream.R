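# Downstream property prediction: fine-tuning, prediction, and the metrics
# the benchmarks report (RMSE for regression, mean ROC-AUC over tasks for
# classification, with missing labels masked out everywhere).

#' Task specification
#' @param kind `"regression"` or `"classification"`.
#' @param n_tasks number of label columns (>= 1).
#' @return A list of class `task_spec`.
#' @export
task_spec <- function(kind = c("regression", "classification"), n_tasks = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_tasks >= 1L)
  structure(list(kind = kind, n_tasks = as.integer(n_tasks)),
            class = "task_spec")
}

infer_task <- function(labels) {
  vals <- labels[is.finite(labels)]
  kind <- if (all(vals %in% c(0, 1))) "classification" else "regression"
  task_spec(kind, ncol(labels))
}

#' Root-mean-square error
#' @param pred,target numeric vectors of equal, non-zero length.
#' @return `sqrt(mean((pred - target)^2))`.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(pred, target) {
  if (length(pred) == 0L) stop("empty vectors")
  stopifnot(length(pred) == length(target))
  sqrt(mean((pred - target)^2))
}

# rank-statistic AUC with midrank tie handling; equals the probability that
# a random positive outranks a random negative (ties count 1/2)
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean ROC-AUC over tasks
#'
#' Computes a rank-statistic ROC-AUC per task over unmasked entries and
#' averages arithmetically over evaluable tasks (the multi-task convention
#' for panels such as Tox21/SIDER). Tasks with only one class after masking
#' are skipped with a warning.
#'
#' @param scores numeric matrix (molecules x tasks) of scores.
#' @param labels 0/1 matrix of the same shape; `NA` marks missing labels.
#' @param mask optional logical matrix; defaults to `!is.na(labels)`.
#' @return Scalar mean AUC with attribute `per_task` (named numeric, `NA`
#'   for skipped tasks).
#' @export
roc_auc_multitask <- function(scores, labels, mask = NULL) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)))
  if (is.null(mask)) mask <- !is.na(labels)
  per_task <- vapply(seq_len(ncol(scores)), function(j) {
    keep <- mask[, j] & !is.na(labels[, j])
    if (sum(keep) == 0L) return(NA_real_)
    auc_rank(scores[keep, j], labels[keep, j])
  }, numeric(1))
  names(per_task) <- colnames(scores) %||% paste0("task_", seq_along(per_task))
  if (anyNA(per_task)) {
    warning(sum(is.na(per_task)), " task(s) skipped: only one class present")
  }
  structure(mean(per_task, na.rm = TRUE), per_task = per_task)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- forward pass and losses ------------------------------------------------

downstream_encoders <- function(encoder_set) {
  strsplit(encoder_set, "")[[1]]
}

# fused molecule representation for a featurized batch -> logits (B x n_tasks)
predict_forward_ad <- function(mols, pn, cfg) {
  encs <- downstream_encoders(cfg$encoder_set)
  out <- encode_batch_ad(mols, pn, cfg, units = FALSE, which_enc = encs)
  feats <- list()
  if ("B" %in% encs) feats <- c(feats, list(out$x$mol))
  if ("T" %in% encs) feats <- c(feats, list(out$y$mol))
  if ("G" %in% encs) feats <- c(feats, list(out$z$mol))
  fused <- if (cfg$fusion == "concat") {
    concat_fuse_ad(feats, pn$fusion$concat)
  } else if (length(feats) == 1L) {
    feats[[1]]
  } else if (length(feats) == 2L) {
    attention_fuse_ad(feats[[1]], feats[[2]], pn$fusion$seq_block)$out
  } else {
    hierarchical_fuse_ad(feats[[1]], feats[[2]], feats[[3]], pn$fusion)
  }
  mlp_ad(fused, pn$head)
}

# masked losses; labels is a B x n_tasks matrix with NA for missing entries
supervised_loss_ad <- function(logits, labels, kind) {
  mask <- ifelse(is.na(labels), 0, 1)
  y <- ifelse(is.na(labels), 0, labels)
  n_obs <- max(sum(mask), 1)
  if (kind == "regression") {
    diff <- ad_mulc(ad_sub(logits, y), mask)
    ad_scale(ad_sumsq(diff), 1 / n_obs)
  } else {
    # stable BCE-with-logits: max(l,0) - l*y + log(1 + exp(-|l|))
    t1 <- ad_relu(logits)
    t2 <- ad_mulc(logits, y)
    t3 <- ad_log(ad_addc(ad_exp(ad_scale(ad_abs(logits), -1)), 1))
    elem <- ad_add(ad_sub(t1, t2), t3)
    ad_scale(ad_sum(ad_mulc(elem, mask)), 1 / n_obs)
  }
}

predict_batch_values <- function(mols, params, cfg, kind) {
  ad_tape_reset()
  pn <- wrap_params(params)
  logits <- predict_forward_ad(mols, pn, cfg)$value
  ad_tape_reset()
  if (kind == "classification") 1 / (1 + exp(-logits)) else logits
}

# ---- fine-tuning ------------------------------------------------------------

#' Fine-tune pretrained encoders with the fusion head on a labeled dataset
#'
#' All parameters — encoders, fusion blocks, prediction head — are updated
#' (full fine-tuning). The model with the best validation metric (lowest
#' RMSE / highest mean AUC) is retained. Missing labels contribute nothing
#' to the loss.
#'
#' @param pretrained a `molfuse_pretrain` checkpoint, or `NULL` for a
#'   randomly initialized run (the no-pretraining ablation arm).
#' @param data tibble with `smiles` plus numeric label columns (attribute
#'   `label_columns` respected; otherwise all non-smiles columns).
#' @param split a `dataset_split`; defaults to a seeded random 8:1:1 split.
#' @param task a `task_spec`; inferred from the labels when `NULL`.
#' @param config a `molfuse_config`; defaults to the pretraining config.
#' @param verbose print per-epoch progress.
#' @return An object of class `molfuse_model`.
#' @export
finetune <- function(pretrained, data, split = NULL, task = NULL,
                     config = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(data), "smiles" %in% names(data))
  labels <- label_matrix(data)
  if (is.null(task)) task <- infer_task(labels)
  stopifnot(inherits(task, "task_spec"), task$n_tasks == ncol(labels))
  if (is.null(config)) {
    config <- if (!is.null(pretrained)) pretrained$config else molfuse_config()
  }
  if (is.null(split)) split <- random_split(nrow(data), seed = config$seed)
  if (length(split$train) == 0L) stop("empty training partition")

  vocab <- if (!is.null(pretrained)) pretrained$vocab else build_vocab(data$smiles)
  params <- init_params(vocab, config, n_tasks = task$n_tasks,
                        seed = config$seed)
  if (!is.null(pretrained)) {
    if (!identical(pretrained$config$d, config$d)) {
      stop("checkpoint feature dimension does not match config")
    }
    for (nm in c("emb", "bilstm", "transformer", "gat")) {
      params[[nm]] <- pretrained$params[[nm]]
    }
  }
  params$vae <- NULL  # the VAE heads play no role downstream

  mols <- featurize_molecules(data$smiles, vocab, config$max_len)
  state <- adam_init(params)
  maximize <- task$kind == "classification"
  best <- list(metric = if (maximize) -Inf else Inf, params = params,
               epoch = 0L)
  log_rows <- vector("list", config$epochs)

  eval_metric <- function(params, idx) {
    if (length(idx) == 0L) return(NA_real_)
    preds <- predict_mols(mols[idx], params, config, task$kind)
    score_predictions(preds, labels[idx, , drop = FALSE], task$kind)
  }

  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(split$train)
      batches <- base::split(ord, ceiling(seq_along(ord) / config$batch_size))
      loss_sum <- 0
      for (bi in batches) {
        ad_tape_reset()
        pn <- wrap_params(params)
        logits <- predict_forward_ad(mols[bi], pn, config)
        loss <- supervised_loss_ad(logits, labels[bi, , drop = FALSE],
                                   task$kind)
        ad_backward(loss)
        upd <- adam_step(params, collect_grads(pn), state, config$lr)
        params <- upd$params; state <- upd$state
        loss_sum <- loss_sum + loss$value[1]
      }
      vm <- eval_metric(params, split$valid)
      improved <- !is.na(vm) &&
        ((maximize && vm > best$metric) || (!maximize && vm < best$metric))
      if (improved || (is.na(vm) && epoch == 1L)) {
        best <- list(metric = vm, params = params, epoch = epoch)
      }
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch,
                                          train_loss = loss_sum / length(batches),
                                          valid_metric = vm)
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f  valid %.4f",
                        epoch, loss_sum / length(batches), vm))
      }
    }
  })
  ad_tape_reset()
  structure(list(params = best$params, params_final = params, vocab = vocab,
                 config = config, task = task, split = split,
                 label_columns = colnames(labels), log = dplyr::bind_rows(log_rows),
                 best_epoch = best$epoch, best_valid_metric = best$metric),
            class = "molfuse_model")
}

predict_mols <- function(mols, params, config, kind) {
  chunks <- base::split(seq_along(mols), ceiling(seq_along(mols) / config$batch_size))
  res <- lapply(chunks, function(ix) {
    predict_batch_values(mols[ix], params, config, kind)
  })
  do.call(rbind, res)
}

score_predictions <- function(preds, labels, kind) {
  mask <- !is.na(labels)
  if (kind == "regression") {
    rmse(preds[mask], labels[mask])
  } else {
    as.numeric(suppressWarnings(roc_auc_multitask(preds, labels)))
  }
}

#' @export
print.molfuse_model <- function(x, ...) {
  cat(sprintf("<molfuse_model> %s, %d task(s), encoders %s, fusion %s (best epoch %d, valid %.4f)\n",
              x$task$kind, x$task$n_tasks, x$config$encoder_set,
              x$config$fusion, x$best_epoch, x$best_valid_metric))
  invisible(x)
}

#' Predict properties for new molecules
#'
#' Deterministic (no stochastic layers at evaluation) and order-preserving;
#' classification outputs are probabilities in (0, 1). Invalid SMILES yield
#' an error message in `.error` and `NA` predictions while the rest of the
#' batch proceeds.
#'
#' @param object a `molfuse_model`.
#' @param newdata character vector of SMILES, or a data frame with a
#'   `smiles` column.
#' @param ... ignored.
#' @return Tibble with `smiles`, one column per task, and `.error`.
#' @export
predict.molfuse_model <- function(object, newdata, ...) {
  smiles <- if (is.data.frame(newdata)) newdata$smiles else newdata
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  mols <- vector("list", length(smiles))
  errs <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    mols[[i]] <- tryCatch(
      featurize_molecules(smiles[i], object$vocab, object$config$max_len)[[1]],
      error = function(e) { errs[i] <<- conditionMessage(e); NULL })
  }
  ok <- which(!vapply(mols, is.null, logical(1)))
  preds <- matrix(NA_real_, length(smiles), object$task$n_tasks)
  if (length(ok) > 0L) {
    preds[ok, ] <- predict_mols(mols[ok], object$params, object$config,
                                object$task$kind)
  }
  colnames(preds) <- object$label_columns %||%
    paste0("task_", seq_len(object$task$n_tasks))
  out <- tibble::as_tibble(as.data.frame(preds))
  dplyr::bind_cols(tibble::tibble(smiles = smiles), out,
                   tibble::tibble(.error = errs))
}

#' Evaluate a fitted model on the partitions of its split
#'
#' @param model a `molfuse_model`.
#' @param data the dataset the model was fitted on (same row order).
#' @return Tibble with one row per partition: `partition`, `n`, `metric`,
#'   `value`.
#' @export
evaluate_model <- function(model, data) {
  labels <- label_matrix(data)
  mols <- featurize_molecules(data$smiles, model$vocab, model$config$max_len)
  metric_name <- if (model$task$kind == "regression") "rmse" else "mean_auc"
  parts <- list(train = model$split$train, valid = model$split$valid,
                test = model$split$test)
  rows <- lapply(names(parts), function(p) {
    idx <- parts[[p]]
    if (length(idx) == 0L) {
      return(tibble::tibble(partition = p, n = 0L, metric = metric_name,
                            value = NA_real_))
    }
    preds <- predict_mols(mols[idx], model$params, model$config,
                          model$task$kind)
    tibble::tibble(partition = p, n = length(idx), metric = metric_name,
                   value = score_predictions(preds, labels[idx, , drop = FALSE],
                                             model$task$kind))
  })
  dplyr::bind_rows(rows)
}

#' Tidy the fine-tuning log
#' @param x a `molfuse_model`.
#' @param ... ignored.
#' @return Tibble with per-epoch training loss and validation metric.
#' @export
tidy.molfuse_model <- function(x, ...) x$log

#' One-row summary of a fitted model
#' @param x a `molfuse_model`.
#' @param ... ignored.
#' @return A one-row tibble.
#' @export
glance.molfuse_model <- function(x, ...) {
  tibble::tibble(task = x$task$kind, n_tasks = x$task$n_tasks,
                 encoder_set = x$config$encoder_set, fusion = x$config$fusion,
                 epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_valid_metric = x$best_valid_metric)
}

#' Plot the fine-tuning trajectory
#' @param object a `molfuse_model`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.molfuse_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch", names_to = "series",
                            values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}
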