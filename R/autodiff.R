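# Reverse-mode automatic differentiation over dense matrices.
#
# A global tape records every operation; ad_backward() walks it in reverse,
# accumulating gradients into leaf nodes (parameters). All values are plain
# numeric matrices; scalars are 1x1. The engine is deliberately small: only
# the primitives the encoders, VAE heads and fusion blocks need.

.ad <- new.env(parent = emptyenv())
.ad$nodes <- vector("list", 4096L)
.ad$n <- 0L

#' Reset the autodiff tape
#'
#' Clears all recorded operations. Called at the start of every forward pass;
#' exported mainly for tests and interactive exploration.
#' @return Invisibly, `NULL`.
#' @keywords internal
#' @export
ad_tape_reset <- function() {
  .ad$nodes <- vector("list", 4096L)
  .ad$n <- 0L
  invisible(NULL)
}

new_ad <- function(value, parents = NULL, backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  n <- .ad$n + 1L
  if (n > length(.ad$nodes)) length(.ad$nodes) <- 2L * n
  .ad$nodes[[n]] <- node
  .ad$n <- n
  node$id <- n
  node
}

is_ad <- function(x) is.environment(x)

as_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

#' Create a leaf node on the tape
#'
#' Leaves accumulate gradients but propagate nothing further; parameters and
#' constants are both leaves (gradients of constants are simply ignored).
#' @param x numeric vector or matrix.
#' @return An autodiff node.
#' @keywords internal
#' @export
ad_leaf <- function(x) new_ad(as_matrix(x))

ad_value <- function(x) if (is_ad(x)) x$value else as_matrix(x)

wrap <- function(x) if (is_ad(x)) x else ad_leaf(x)

# ---- binary ops -------------------------------------------------------------

ad_mm <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  av <- a$value; bv <- b$value
  new_ad(av %*% bv, list(a, b), function(g, nd) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

# addition with limited broadcasting: equal shape, 1xN row (bias), or 1x1
ad_add <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  av <- a$value; bv <- b$value
  if (all(dim(av) == dim(bv))) {
    new_ad(av + bv, list(a, b), function(g, nd) list(g, g))
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    new_ad(sweep(av, 2L, bv, "+"), list(a, b), function(g, nd) {
      list(g, matrix(colSums(g), 1L))
    })
  } else if (length(bv) == 1L) {
    new_ad(av + bv[1L], list(a, b), function(g, nd) {
      list(g, matrix(sum(g), 1L, 1L))
    })
  } else {
    stop("ad_add: incompatible shapes ", paste(dim(av), collapse = "x"),
         " and ", paste(dim(bv), collapse = "x"))
  }
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

# elementwise product: equal shape or b scalar (1x1, possibly a node)
ad_mul <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  av <- a$value; bv <- b$value
  if (all(dim(av) == dim(bv))) {
    new_ad(av * bv, list(a, b), function(g, nd) list(g * bv, g * av))
  } else if (length(bv) == 1L) {
    new_ad(av * bv[1L], list(a, b), function(g, nd) {
      list(g * bv[1L], matrix(sum(g * av), 1L, 1L))
    })
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    new_ad(sweep(av, 2L, bv, "*"), list(a, b), function(g, nd) {
      list(sweep(g, 2L, bv, "*"), matrix(colSums(g * av), 1L))
    })
  } else {
    stop("ad_mul: incompatible shapes")
  }
}

# multiply / add by a constant matrix or scalar without putting it on the tape
ad_mulc <- function(a, m) {
  av <- a$value
  new_ad(av * m, list(a), function(g, nd) list(g * m))
}

ad_addc <- function(a, m) {
  new_ad(a$value + m, list(a), function(g, nd) list(g))
}

ad_scale <- function(a, s) {
  a <- wrap(a)
  new_ad(a$value * s, list(a), function(g, nd) list(g * s))
}

# ---- unary ops --------------------------------------------------------------

ad_sigmoid <- function(a) {
  a <- wrap(a)
  s <- 1 / (1 + exp(-a$value))
  new_ad(s, list(a), function(g, nd) list(g * s * (1 - s)))
}

ad_tanh <- function(a) {
  a <- wrap(a)
  y <- tanh(a$value)
  new_ad(y, list(a), function(g, nd) list(g * (1 - y^2)))
}

ad_relu <- function(a) {
  a <- wrap(a)
  v <- a$value
  new_ad(pmax(v, 0), list(a), function(g, nd) list(g * (v > 0)))
}

ad_elu <- function(a) {
  a <- wrap(a)
  v <- a$value
  y <- ifelse(v > 0, v, exp(v) - 1)
  new_ad(y, list(a), function(g, nd) list(g * ifelse(v > 0, 1, y + 1)))
}

ad_leaky_relu <- function(a, slope = 0.2) {
  a <- wrap(a)
  v <- a$value
  new_ad(ifelse(v > 0, v, slope * v), list(a), function(g, nd) {
    list(g * ifelse(v > 0, 1, slope))
  })
}

ad_exp <- function(a) {
  a <- wrap(a)
  y <- exp(a$value)
  new_ad(y, list(a), function(g, nd) list(g * y))
}

ad_log <- function(a) {
  a <- wrap(a)
  v <- a$value
  new_ad(log(v), list(a), function(g, nd) list(g / v))
}

ad_abs <- function(a) {
  a <- wrap(a)
  v <- a$value
  new_ad(abs(v), list(a), function(g, nd) list(g * sign(v)))
}

# (v + shift)^p with constant p and shift; used for layer-norm 1/sqrt(var+eps)
ad_powc <- function(a, p, shift = 0) {
  a <- wrap(a)
  v <- a$value + shift
  new_ad(v^p, list(a), function(g, nd) list(g * p * v^(p - 1)))
}

ad_t <- function(a) {
  a <- wrap(a)
  new_ad(t(a$value), list(a), function(g, nd) list(t(g)))
}

ad_sum <- function(a) {
  a <- wrap(a)
  d <- dim(a$value)
  new_ad(matrix(sum(a$value), 1L, 1L), list(a), function(g, nd) {
    list(matrix(g[1L], d[1L], d[2L]))
  })
}

ad_mean <- function(a) {
  a <- wrap(a)
  d <- dim(a$value)
  n <- length(a$value)
  new_ad(matrix(mean(a$value), 1L, 1L), list(a), function(g, nd) {
    list(matrix(g[1L] / n, d[1L], d[2L]))
  })
}

ad_sumsq <- function(a) ad_sum(ad_mul(a, a))

# ---- structural ops ---------------------------------------------------------

ad_cbind <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  na <- ncol(a$value)
  new_ad(cbind(a$value, b$value), list(a, b), function(g, nd) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

ad_rbind_list <- function(xs) {
  xs <- lapply(xs, wrap)
  rows <- vapply(xs, function(x) nrow(x$value), integer(1))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  new_ad(do.call(rbind, lapply(xs, function(x) x$value)), xs, function(g, nd) {
    lapply(seq_along(xs), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

# row gather; duplicate indices accumulate in the backward pass (embedding)
ad_rows <- function(a, idx) {
  a <- wrap(a)
  av <- a$value
  idx <- as.integer(idx)
  new_ad(av[idx, , drop = FALSE], list(a), function(g, nd) {
    z <- matrix(0, nrow(av), ncol(av))
    acc <- rowsum(g, group = idx)
    z[as.integer(rownames(acc)), ] <- acc
    list(z)
  })
}

ad_cols <- function(a, idx) {
  a <- wrap(a)
  av <- a$value
  idx <- as.integer(idx)
  new_ad(av[, idx, drop = FALSE], list(a), function(g, nd) {
    z <- matrix(0, nrow(av), ncol(av))
    z[, idx] <- z[, idx] + g
    list(z)
  })
}

# row-wise softmax with an optional 0/1 constant mask; fully-masked rows
# yield all-zero rows rather than NaN
ad_softmax_rows <- function(a, mask = NULL) {
  a <- wrap(a)
  v <- a$value
  if (is.null(mask)) mask <- matrix(1, nrow(v), ncol(v))
  vm <- ifelse(mask > 0, v, -Inf)
  mx <- apply(vm, 1L, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(vm - mx) * mask
  e[mask == 0] <- 0
  rs <- rowSums(e)
  rs[rs == 0] <- 1
  s <- e / rs
  new_ad(s, list(a), function(g, nd) {
    list((g - rowSums(g * s)) * s)
  })
}

# column-wise max over rows -> 1 x d; gradient routed to the first argmax row
ad_colmax <- function(a) {
  a <- wrap(a)
  v <- a$value
  arg <- max.col(t(v), ties.method = "first")
  y <- matrix(v[cbind(arg, seq_len(ncol(v)))], 1L)
  new_ad(y, list(a), function(g, nd) {
    z <- matrix(0, nrow(v), ncol(v))
    z[cbind(arg, seq_len(ncol(v)))] <- g[1L, ]
    list(z)
  })
}

#' Stop-gradient operator
#'
#' Returns a node whose value equals the input's but which propagates no
#' gradient to the input's producers — the SG operator of the pairwise
#' representation-reconstruction objective.
#' @param a an autodiff node or matrix.
#' @return A leaf node carrying a copy of the value.
#' @keywords internal
#' @export
ad_stopgrad <- function(a) new_ad(ad_value(a))

# ---- backward ---------------------------------------------------------------

#' Backpropagate from a scalar root
#'
#' Seeds the root gradient with ones and walks the tape in reverse topological
#' order (creation order), accumulating into every reachable node's `$grad`.
#' @param root the output node (typically 1x1 loss).
#' @return Invisibly, the root.
#' @keywords internal
#' @export
ad_backward <- function(root) {
  force(root)  # the root expression may itself append nodes to the tape
  n <- .ad$n
  nodes <- .ad$nodes
  for (i in seq_len(n)) nodes[[i]]$grad <- NULL
  root$grad <- matrix(1, nrow(root$value), ncol(root$value))
  for (i in seq.int(root$id, 1L)) {
    nd <- nodes[[i]]
    g <- nd$grad
    if (is.null(g) || is.null(nd$backfn)) next
    pg <- nd$backfn(g, nd)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- ps[[k]]
      p$grad <- if (is.null(p$grad)) gk else p$grad + gk
    }
  }
  invisible(root)
}
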