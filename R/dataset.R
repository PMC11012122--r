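# Labeled molecular datasets and train/validation/test splitting.

#' Read a MoleculeNet-style property CSV
#'
#' One row per molecule: a SMILES column plus one or more numeric label
#' columns. Empty cells become `NA` and mark missing labels (multi-task
#' datasets such as Tox21 leave many cells blank); downstream losses mask
#' them out.
#'
#' @param path path to a CSV file.
#' @param smiles_column name of the SMILES column (default `"smiles"`).
#' @param label_columns character vector of label column names; default: all
#'   columns except the SMILES column.
#' @return A tibble with columns `smiles` and the label columns (numeric),
#'   row order preserved, with attribute `label_columns`.
#' @export
read_property_csv <- function(path, smiles_column = "smiles",
                              label_columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!smiles_column %in% names(df)) {
    stop("missing SMILES column '", smiles_column, "' in ", path)
  }
  if (is.null(label_columns)) {
    label_columns <- setdiff(names(df), smiles_column)
  }
  missing_cols <- setdiff(label_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing label column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(label_columns) == 0L) stop("no label columns")
  out <- tibble::tibble(smiles = df[[smiles_column]])
  for (col in label_columns) {
    raw <- trimws(df[[col]])
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0L) {
      stop(sprintf("column '%s': cannot parse value '%s' as numeric at row %d",
                   col, raw[bad[1]], bad[1]))
    }
    out[[col]] <- val
  }
  attr(out, "label_columns") <- label_columns
  out
}

label_matrix <- function(data) {
  cols <- attr(data, "label_columns")
  if (is.null(cols)) cols <- setdiff(names(data), "smiles")
  as.matrix(data[, cols, drop = FALSE])
}

new_dataset_split <- function(train, valid, test, method, fractions, seed) {
  structure(list(train = as.integer(train), valid = as.integer(valid),
                 test = as.integer(test), method = method,
                 fractions = fractions, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %s split (seed %d): %d train / %d valid / %d test\n",
              x$method, x$seed, length(x$train), length(x$valid), length(x$test)))
  invisible(x)
}

#' Tidy a dataset split into a (index, partition) tibble
#' @param x a `dataset_split`.
#' @param ... ignored.
#' @return A tibble with columns `index` and `partition`.
#' @export
tidy.dataset_split <- function(x, ...) {
  tibble::tibble(
    index = c(x$train, x$valid, x$test),
    partition = rep(c("train", "valid", "test"),
                    c(length(x$train), length(x$valid), length(x$test)))
  ) |> dplyr::arrange(.data$index)
}

check_fractions <- function(fractions) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be three non-negative numbers summing to 1")
  }
}

#' Random train/validation/test split
#'
#' @param data a data frame of records (one molecule per row) or an integer
#'   count of records.
#' @param fractions train/valid/test fractions, summing to 1 (default 8:1:1).
#' @param seed integer RNG seed; the same seed reproduces the same split.
#' @return A `dataset_split`.
#' @export
random_split <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  check_fractions(fractions)
  n <- if (is.data.frame(data)) nrow(data) else as.integer(data)
  if (n < 1L) stop("no records to split")
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- round(fractions[1] * n)
  n_valid <- round(fractions[2] * n)
  n_valid <- min(n_valid, n - n_train)
  new_dataset_split(sort(perm[seq_len(n_train)]),
                    sort(perm[seq_len(n_valid) + n_train]),
                    sort(perm[setdiff(seq_len(n), seq_len(n_train + n_valid))]),
                    "random", fractions, as.integer(seed))
}

#' Scaffold-based train/validation/test split
#'
#' Groups molecules by Murcko scaffold key and assigns whole groups to
#' partitions so that no scaffold appears in more than one partition — the
#' generalization-stressing split used for classification benchmarks. Groups
#' are taken in order of decreasing size (ties broken by key) and fill train,
#' then validation, then test.
#'
#' @param data a data frame with a `smiles` column.
#' @param fractions train/valid/test fractions, summing to 1.
#' @param seed integer seed, recorded for provenance (assignment itself is
#'   deterministic).
#' @return A `dataset_split`; warns if a partition ends up empty (e.g. all
#'   molecules sharing one scaffold).
#' @export
scaffold_split <- function(data, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  check_fractions(fractions)
  stopifnot(is.data.frame(data), "smiles" %in% names(data))
  n <- nrow(data)
  keys <- murcko_scaffold(data$smiles)
  groups <- split(seq_len(n), keys)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  n_train <- fractions[1] * n
  n_valid <- fractions[2] * n
  train <- integer(0); valid <- integer(0); test <- integer(0)
  # fill train until it reaches its quota, then valid, then test; a group is
  # never divided, so an oversized group overflows its partition rather than
  # leaking scaffolds
  for (g in groups) {
    if (length(train) < n_train) {
      train <- c(train, g)
    } else if (length(valid) < n_valid) {
      valid <- c(valid, g)
    } else {
      test <- c(test, g)
    }
  }
  if (length(valid) == 0L || length(test) == 0L || length(train) == 0L) {
    warning("scaffold split left at least one partition empty ",
            "(large scaffold groups dominate)")
  }
  new_dataset_split(sort(train), sort(valid), sort(test),
                    "scaffold", fractions, as.integer(seed))
}

#' Write a split manifest as CSV
#' @param split a `dataset_split`.
#' @param path output CSV path.
#' @return Invisibly, the manifest tibble.
#' @export
write_split_csv <- function(split, path) {
  manifest <- tidy.dataset_split(split)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}
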