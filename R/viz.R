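# Atom-atom Pearson similarity matrices and heat maps.
#
# For a molecule, each encoder yields one feature vector per atom (sequence
# encoders contribute only atom-masked token positions). The Pearson
# correlation between atom feature vectors shows which atoms the model has
# learned to treat alike — clustered blocks correspond to chemically
# coherent fragments.

#' Pearson similarity between atom feature vectors
#'
#' @param unit_features numeric matrix (n_atoms x d), n_atoms >= 2, d >= 2.
#' @param labels optional atom labels (defaults to element + index).
#' @return An object of class `similarity_matrix`: an n_atoms x n_atoms
#'   correlation matrix, symmetric with unit diagonal; rows with zero
#'   variance get 0 off-diagonal entries with a warning.
#' @export
atom_feature_similarity <- function(unit_features, labels = NULL) {
  unit_features <- as.matrix(unit_features)
  if (ncol(unit_features) < 2L) {
    stop("feature dimension must be >= 2 for correlation")
  }
  if (nrow(unit_features) < 2L) stop("need at least 2 atoms")
  sds <- apply(unit_features, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance atom feature row(s); similarity set to 0")
  }
  sim <- suppressWarnings(stats::cor(t(unit_features)))
  sim[flat, ] <- 0
  sim[, flat] <- 0
  diag(sim) <- ifelse(flat, 0, 1)
  sim <- pmin(pmax(sim, -1), 1)
  if (is.null(labels)) labels <- paste0("a", seq_len(nrow(sim)))
  dimnames(sim) <- list(labels, labels)
  structure(sim, class = c("similarity_matrix", "matrix"))
}

#' Per-atom features of one molecule from a trained model
#'
#' @param object a `molfuse_pretrain` or `molfuse_model`.
#' @param smiles a single SMILES string.
#' @param encoder `"bilstm"`, `"transformer"`, `"gat"`, or `"mean"` (the
#'   elementwise mean of the three).
#' @return Matrix (n_atoms x d) of atom features, row names = element + index.
#' @export
atom_features <- function(object, smiles,
                          encoder = c("mean", "bilstm", "transformer", "gat")) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(object, c("molfuse_pretrain", "molfuse_model")))
  mol <- featurize_molecules(smiles, object$vocab, object$config$max_len)[[1]]
  ids <- mol$enc$token_ids
  amask <- mol$enc$atom_mask
  params <- object$params
  feats <- list()
  if (encoder %in% c("mean", "bilstm")) {
    u <- bilstm_encode(ids, params, object$config)$unit_features
    feats$bilstm <- u[amask, , drop = FALSE]
  }
  if (encoder %in% c("mean", "transformer")) {
    u <- transformer_encode(ids, params, object$config)$unit_features
    feats$transformer <- u[amask, , drop = FALSE]
  }
  if (encoder %in% c("mean", "gat")) {
    feats$gat <- gat_encode(mol$graph, params, object$config)$unit_features
  }
  out <- if (encoder == "mean") Reduce(`+`, feats) / length(feats) else feats[[encoder]]
  rownames(out) <- paste0(mol$graph$elements, seq_len(mol$graph$n_atoms))
  out
}

#' Atom-similarity matrix of one molecule
#'
#' Convenience wrapper: [atom_features()] then [atom_feature_similarity()].
#' @inheritParams atom_features
#' @return A `similarity_matrix`.
#' @export
molecule_similarity <- function(object, smiles,
                                encoder = c("mean", "bilstm", "transformer", "gat")) {
  f <- atom_features(object, smiles, encoder)
  atom_feature_similarity(f, labels = rownames(f))
}

sim_ramp <- function(v) {
  # blue (-1) -> white (0) -> red (+1)
  v <- pmin(pmax(v, -1), 1)
  r <- ifelse(v >= 0, 1, 1 + v)
  g <- 1 - abs(v)
  b <- ifelse(v <= 0, 1, 1 - v)
  list(r = r, g = g, b = b)
}

#' Render a similarity matrix as a PNG heat map
#'
#' Writes a raster image directly (deterministic bytes for identical input):
#' blue for -1 through white at 0 to red for +1, atoms in input order, each
#' cell a `cell_px` square.
#'
#' @param sim a `similarity_matrix` (or plain numeric matrix in [-1, 1]).
#' @param path output PNG path.
#' @param cell_px pixel size of each matrix cell.
#' @return Invisibly, `path`.
#' @export
render_heatmap <- function(sim, path, cell_px = 16L) {
  sim <- unclass(sim)
  n <- nrow(sim)
  cl <- sim_ramp(sim)
  up <- function(m) m[rep(seq_len(n), each = cell_px),
                      rep(seq_len(n), each = cell_px), drop = FALSE]
  img <- array(0, dim = c(n * cell_px, n * cell_px, 3))
  img[, , 1] <- up(matrix(cl$r, n, n))
  img[, , 2] <- up(matrix(cl$g, n, n))
  img[, , 3] <- up(matrix(cl$b, n, n))
  png::writePNG(img, target = path)
  invisible(path)
}

#' Write a similarity matrix as CSV
#' @param sim a `similarity_matrix`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_similarity_csv <- function(sim, path) {
  utils::write.csv(as.data.frame(unclass(sim)), path, row.names = TRUE)
  invisible(path)
}

#' Plot a similarity matrix as a ggplot tile map
#' @param object a `similarity_matrix`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(
    from = factor(rep(rownames(m), times = ncol(m)), levels = rownames(m)),
    to = factor(rep(colnames(m), each = nrow(m)), levels = rev(colnames(m))),
    similarity = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
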