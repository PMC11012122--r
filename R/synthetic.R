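# Synthetic SMILES corpora and labeled datasets with known structure.
#
# Molecules are built from a tiny grammar — an optional aromatic benzene
# fragment, an aliphatic chain over a small atom alphabet, and optional
# single-atom branches — so every emitted string is valid by construction
# and structural labels (atom counts, rings, heteroatoms) are exactly
# recoverable. This emulates the shape of real pretraining corpora and
# MoleculeNet-style datasets without any external chemistry data.

#' Generate a synthetic SMILES corpus
#'
#' @param n_molecules number of molecules.
#' @param max_heavy_atoms cap on heavy atoms per molecule (>= 2).
#' @param ring_probability probability a molecule carries an aromatic benzene
#'   ring (requires `max_heavy_atoms >= 7`).
#' @param branch_probability probability of a single-atom branch on the chain.
#' @param alphabet aliphatic atom alphabet; heteroatoms are drawn with lower
#'   weight than carbon.
#' @param seed integer RNG seed; the same seed reproduces the corpus.
#' @return Character vector of `n_molecules` valid SMILES strings.
#' @examples
#' generate_corpus(5, seed = 42)
#' @export
generate_corpus <- function(n_molecules, max_heavy_atoms = 12L,
                            ring_probability = 0.4,
                            branch_probability = 0.3,
                            alphabet = c("C", "N", "O"),
                            seed = 1L) {
  stopifnot(n_molecules >= 1L, max_heavy_atoms >= 2L,
            ring_probability >= 0, ring_probability <= 1,
            branch_probability >= 0, branch_probability <= 1)
  weights <- ifelse(alphabet == "C", 3, 1)
  withr::with_seed(seed, {
    vapply(seq_len(n_molecules), function(i) {
      ring <- ring_probability > 0 && max_heavy_atoms >= 7L &&
        stats::runif(1) < ring_probability
      budget <- max_heavy_atoms - if (ring) 6L else 0L
      chain_len <- sample(seq_len(max(1L, min(budget, max_heavy_atoms))), 1L)
      atoms <- sample(alphabet, chain_len, replace = TRUE, prob = weights)
      branch <- character(chain_len)
      if (branch_probability > 0 && chain_len >= 3L && budget - chain_len >= 1L &&
          stats::runif(1) < branch_probability) {
        at <- sample(2:(chain_len - 1L), 1L)
        branch[at] <- paste0("(", sample(alphabet, 1L, prob = weights), ")")
      }
      chain <- paste0(atoms, branch, collapse = "")
      if (ring) paste0("c1ccccc1", chain) else chain
    }, character(1))
  })
}

# ring count = cycle rank of the molecular graph (E/2 - V + components)
count_rings <- function(graph) {
  n <- graph$n_atoms
  if (nrow(graph$edges) == 0L) return(0L)
  comp <- seq_len(n)
  for (k in seq_len(nrow(graph$edges))) {
    a <- comp[graph$edges[k, 1]]; b <- comp[graph$edges[k, 2]]
    if (a != b) comp[comp == b] <- a
  }
  as.integer(nrow(graph$edges) / 2L - n + length(unique(comp)))
}

structure_descriptors <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    g <- smiles_to_graph(s)
    tibble::tibble(heavy_atoms = g$n_atoms,
                   rings = count_rings(g),
                   has_ring = count_rings(g) > 0L,
                   has_heteroatom = any(g$elements != "C"))
  })
  dplyr::bind_rows(rows)
}

#' Synthetic regression dataset from a corpus
#'
#' The label is a known linear function of structure plus Gaussian noise:
#' `y = c1 * heavy_atoms + c2 * rings + N(0, noise_sd^2)`, emulating
#' continuous properties such as solubility. The generating coefficients are
#' recorded as attributes so recovery can be checked.
#'
#' @param corpus character vector of SMILES.
#' @param coeffs length-2 numeric: weights on heavy-atom count and ring count.
#' @param noise_sd standard deviation of the label noise.
#' @param seed integer RNG seed for the noise draw.
#' @return A tibble with columns `smiles`, `y`; attributes `coeffs`,
#'   `noise_sd` and `label_columns`.
#' @export
make_regression_dataset <- function(corpus, coeffs = c(0.5, 1.0),
                                    noise_sd = 0.5, seed = 1L) {
  stopifnot(length(coeffs) == 2L, noise_sd >= 0)
  desc <- structure_descriptors(corpus)
  noise <- withr::with_seed(seed, stats::rnorm(length(corpus), 0, noise_sd))
  out <- tibble::tibble(
    smiles = corpus,
    y = coeffs[1] * desc$heavy_atoms + coeffs[2] * desc$rings + noise
  )
  attr(out, "coeffs") <- coeffs
  attr(out, "noise_sd") <- noise_sd
  attr(out, "label_columns") <- "y"
  out
}

#' Synthetic binary classification dataset from a corpus
#'
#' The label is a structural predicate: `has_ring` (any ring present) or
#' `has_heteroatom` (any non-carbon heavy atom), emulating binary endpoints
#' such as permeability or activity.
#'
#' @param corpus character vector of SMILES.
#' @param rule `"has_ring"` or `"has_heteroatom"`.
#' @param seed kept for interface symmetry; the rules are deterministic.
#' @return A tibble with columns `smiles`, `label` (0/1), attribute
#'   `label_columns`.
#' @export
make_classification_dataset <- function(corpus, rule = c("has_ring", "has_heteroatom"),
                                        seed = 1L) {
  rule <- match.arg(rule)
  desc <- structure_descriptors(corpus)
  out <- tibble::tibble(
    smiles = corpus,
    label = as.numeric(desc[[rule]])
  )
  attr(out, "label_columns") <- "label"
  out
}

#' Write a corpus as a one-SMILES-per-line text file
#' @param corpus character vector of SMILES.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(corpus, path)
  invisible(path)
}

#' Read a one-SMILES-per-line corpus file
#' @param path input path.
#' @return Character vector of SMILES (blank lines dropped).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  x <- readLines(path)
  x[nzchar(trimws(x))]
}
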