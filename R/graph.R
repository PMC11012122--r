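# Molecular graphs from SMILES: heavy atoms as nodes, bonds as directed edge
# pairs, with a fixed atom-feature encoding shared by the graph encoder.

.element_alphabet <- c("C", "N", "O", "S", "F", "Cl", "Br", "P", "I", "other")

parse_bracket_atom <- function(tok) {
  inner <- sub("^\\[", "", sub("\\]$", "", tok))
  m <- regexpr("[A-Za-z][a-z]?", inner)
  if (m == -1L) stop("bracket atom with no element symbol: ", tok)
  sym <- regmatches(inner, m)
  # lowercase first letter marks an aromatic atom (e.g. [nH])
  aromatic <- grepl("^[a-z]", sym)
  list(element = paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)),
       aromatic = aromatic)
}

atom_from_token <- function(tok) {
  if (grepl("^\\[", tok)) return(parse_bracket_atom(tok))
  aromatic <- tok %in% c("b", "c", "n", "o", "p", "s")
  list(element = toupper(tok), aromatic = aromatic)
}

#' Convert a SMILES string to a molecular graph
#'
#' Heavy atoms become nodes (hydrogens stay implicit) and every bond is stored
#' as two directed edges. Atom order matches the left-to-right atom order of
#' [smiles_tokenize()], so `sum(is_atom)` of the token table always equals
#' `n_atoms`. Node features are a fixed encoding: element one-hot over
#' `r paste(.element_alphabet, collapse = ", ")`, degree one-hot (0-5), and an
#' aromatic flag (17 dimensions).
#'
#' @param smiles a single SMILES string.
#' @return An object of class `mol_graph`: a list with `n_atoms`, `elements`,
#'   `aromatic`, `edges` (two-column integer matrix of directed edges,
#'   0 rows for a single atom), `bond_order` (numeric, per directed edge),
#'   and `node_features` (`n_atoms` x 17 matrix).
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' g$n_atoms      # 6
#' nrow(g$edges)  # 12 directed edges = 6 aromatic bonds
#' @export
smiles_to_graph <- function(smiles) {
  tk <- tokenize_one(smiles)
  tokens <- tk$tokens

  elements <- character(0)
  aromatic <- logical(0)
  edges_from <- integer(0)
  edges_to <- integer(0)
  orders <- numeric(0)

  prev <- NA_integer_      # atom awaiting a bond to the next atom
  stack <- integer(0)      # branch stack
  pending_bond <- NA_real_ # explicit bond order before next atom/ring closure
  ring_open <- list()      # ring label -> list(atom, order)

  add_bond <- function(i, j, order) {
    edges_from <<- c(edges_from, i, j)
    edges_to <<- c(edges_to, j, i)
    orders <<- c(orders, order, order)
  }

  bond_order_of <- function(sym) {
    switch(sym, "-" = 1, "=" = 2, "#" = 3, "$" = 4, ":" = 1.5,
           "/" = 1, "\\" = 1, stop("unknown bond symbol: ", sym))
  }

  for (pos in seq_along(tokens)) {
    tok <- tokens[[pos]]
    if (tk$atom_mask[[pos]]) {
      at <- atom_from_token(tok)
      elements <- c(elements, at$element)
      aromatic <- c(aromatic, at$aromatic)
      idx <- length(elements)
      if (!is.na(prev)) {
        ord <- if (!is.na(pending_bond)) pending_bond
               else if (aromatic[prev] && at$aromatic) 1.5 else 1
        add_bond(prev, idx, ord)
      }
      prev <- idx
      pending_bond <- NA_real_
    } else if (tok == "(") {
      if (is.na(prev)) stop("branch opened before any atom in '", smiles, "'")
      stack <- c(stack, prev)
    } else if (tok == ")") {
      if (length(stack) == 0L) stop("unmatched ')' in '", smiles, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tok == ".") {
      prev <- NA_integer_
      pending_bond <- NA_real_
    } else if (grepl("^%?[0-9]", tok)) {
      label <- sub("^%", "", tok)
      if (is.na(prev)) stop("ring closure before any atom in '", smiles, "'")
      if (!is.null(ring_open[[label]])) {
        op <- ring_open[[label]]
        ord <- if (!is.na(pending_bond)) pending_bond
               else if (!is.na(op$order)) op$order
               else if (aromatic[op$atom] && aromatic[prev]) 1.5 else 1
        add_bond(op$atom, prev, ord)
        ring_open[[label]] <- NULL
      } else {
        ring_open[[label]] <- list(atom = prev, order = pending_bond)
      }
      pending_bond <- NA_real_
    } else {
      pending_bond <- bond_order_of(tok)
    }
  }
  if (length(ring_open) > 0L) {
    stop("unclosed ring label(s) ", paste(names(ring_open), collapse = ", "),
         " in '", smiles, "'")
  }
  if (length(stack) > 0L) stop("unclosed branch in '", smiles, "'")
  if (length(elements) == 0L) stop("no atoms parsed from '", smiles, "'")

  n <- length(elements)
  edges <- cbind(from = edges_from, to = edges_to)
  degree <- tabulate(edges_from, nbins = n)

  elem_idx <- match(elements, .element_alphabet)
  elem_idx[is.na(elem_idx)] <- length(.element_alphabet)
  feat <- matrix(0, n, length(.element_alphabet) + 6L + 1L)
  feat[cbind(seq_len(n), elem_idx)] <- 1
  deg_capped <- pmin(degree, 5L)
  feat[cbind(seq_len(n), length(.element_alphabet) + deg_capped + 1L)] <- 1
  feat[, ncol(feat)] <- as.numeric(aromatic)

  structure(list(n_atoms = n, elements = elements, aromatic = aromatic,
                 edges = edges, bond_order = orders, node_features = feat),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$n_atoms, " atoms, ", nrow(x$edges),
      " directed edges\n", sep = "")
  invisible(x)
}

#' Dimension of the fixed atom-feature encoding
#' @return Integer, currently 17.
#' @export
atom_feature_dim <- function() length(.element_alphabet) + 6L + 1L

# ---- Murcko scaffolds -------------------------------------------------------

# Iteratively prune terminal (degree-1) atoms: what survives is the ring
# systems plus the linkers between them — the Murcko framework.
prune_to_scaffold <- function(graph) {
  keep <- rep(TRUE, graph$n_atoms)
  edges <- graph$edges
  repeat {
    deg <- tabulate(edges[keep[edges[, 1]] & keep[edges[, 2]], 1],
                    nbins = graph$n_atoms)
    terminal <- keep & deg <= 1L
    if (!any(terminal) || all(terminal == keep)) {
      # all remaining atoms terminal => acyclic remnant; empty scaffold
      if (all(terminal == keep)) keep[] <- FALSE
      break
    }
    keep[terminal] <- FALSE
  }
  keep
}

#' Murcko scaffold key of a molecule
#'
#' Computes the Bemis-Murcko framework (ring systems plus linkers, obtained by
#' iteratively pruning terminal atoms) and returns a canonical, structure-
#' invariant key for it via Weisfeiler-Lehman label refinement over element,
#' aromaticity and bond order. Molecules with the same framework get the same
#' key; acyclic molecules all map to the empty string.
#'
#' @param smiles character vector of SMILES strings.
#' @return Character vector of scaffold keys (`""` for acyclic molecules).
#' @examples
#' murcko_scaffold(c("CCO", "c1ccccc1CC", "c1ccccc1CCCC"))
#' @export
murcko_scaffold <- function(smiles) {
  vapply(smiles, function(s) {
    g <- smiles_to_graph(s)
    keep <- prune_to_scaffold(g)
    if (!any(keep)) return("")
    idx <- which(keep)
    remap <- match(seq_len(g$n_atoms), idx)
    sel <- keep[g$edges[, 1]] & keep[g$edges[, 2]]
    ef <- remap[g$edges[sel, 1]]
    et <- remap[g$edges[sel, 2]]
    ord <- g$bond_order[sel]
    labels <- paste0(g$elements[idx], ifelse(g$aromatic[idx], "a", ""))
    # WL refinement: three rounds is ample at molecular scaffold sizes
    for (it in 1:3) {
      nbr <- vapply(seq_along(idx), function(i) {
        k <- which(ef == i)
        paste(sort(paste0(ord[k], ":", labels[et[k]])), collapse = ",")
      }, character(1))
      labels <- paste0("(", labels, "|", nbr, ")")
    }
    paste(sort(labels), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}
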