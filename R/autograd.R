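# Reverse-mode automatic differentiation over dense numeric matrices.
#
# A tape records nodes in the order they are created during a forward pass;
# because every node is created after its parents, creation order is a valid
# topological order and the backward pass simply walks the tape in reverse.
# Nodes are environments so gradients can be accumulated in place.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_node <- function(tape, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$requires <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$requires, logical(1)))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

# Trainable leaf: gradient is collected after the backward pass.
ag_leaf <- function(tape, value) {
  nd <- ag_node(tape, value)
  nd$requires <- TRUE
  nd
}

# Constant leaf: no gradient tracked.
ag_const <- function(tape, value) {
  if (!is.matrix(value)) value <- as.matrix(value)
  ag_node(tape, value)
}

is_agnode <- function(x) is.environment(x) && !is.null(x$value)

as_node <- function(tape, x) {
  if (is_agnode(x)) x else ag_const(tape, x)
}

ag_accum <- function(p, g) {
  if (!p$requires) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar (1x1) node through the tape.
ag_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (nd$requires && !is.null(nd$grad) && !is.null(nd$backfn)) {
      nd$backfn(nd)
    }
  }
  invisible(NULL)
}

## ---- elementary operations -------------------------------------------------

ag_mm <- function(tape, a, b) {
  a <- as_node(tape, a); b <- as_node(tape, b)
  nd <- ag_node(tape, a$value %*% b$value, list(a, b), function(nd) {
    if (a$requires) ag_accum(a, tcrossprod(nd$grad, b$value))
    if (b$requires) ag_accum(b, crossprod(a$value, nd$grad))
  })
  nd
}

# Addition with row-vector (1 x n) and scalar (1 x 1) broadcasting on `b`.
ag_add <- function(tape, a, b) {
  a <- as_node(tape, a); b <- as_node(tape, b)
  av <- a$value; bv <- b$value
  v <- if (identical(dim(av), dim(bv))) {
    av + bv
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    sweep(av, 2L, as.numeric(bv), "+")
  } else if (length(bv) == 1L) {
    av + as.numeric(bv)
  } else stop("ag_add: incompatible shapes")
  ag_node(tape, v, list(a, b), function(nd) {
    ag_accum(a, nd$grad)
    if (identical(dim(av), dim(bv))) {
      ag_accum(b, nd$grad)
    } else if (length(bv) == 1L) {
      ag_accum(b, matrix(sum(nd$grad), 1L, 1L))
    } else {
      ag_accum(b, matrix(colSums(nd$grad), 1L))
    }
  })
}

ag_neg <- function(tape, a) {
  a <- as_node(tape, a)
  ag_node(tape, -a$value, list(a), function(nd) ag_accum(a, -nd$grad))
}

ag_sub <- function(tape, a, b) ag_add(tape, a, ag_neg(tape, as_node(tape, b)))

# Elementwise product; `b` may be a 1x1 scalar node.
ag_mul <- function(tape, a, b) {
  a <- as_node(tape, a); b <- as_node(tape, b)
  av <- a$value; bv <- b$value
  scalar_b <- length(bv) == 1L
  v <- if (scalar_b) av * as.numeric(bv) else av * bv
  if (!scalar_b && !identical(dim(av), dim(bv))) stop("ag_mul: incompatible shapes")
  ag_node(tape, v, list(a, b), function(nd) {
    if (scalar_b) {
      ag_accum(a, nd$grad * as.numeric(bv))
      ag_accum(b, matrix(sum(nd$grad * av), 1L, 1L))
    } else {
      ag_accum(a, nd$grad * bv)
      ag_accum(b, nd$grad * av)
    }
  })
}

ag_scale <- function(tape, a, s) {
  a <- as_node(tape, a)
  ag_node(tape, a$value * s, list(a), function(nd) ag_accum(a, nd$grad * s))
}

ag_relu <- function(tape, a) {
  a <- as_node(tape, a)
  m <- a$value > 0
  ag_node(tape, a$value * m, list(a), function(nd) ag_accum(a, nd$grad * m))
}

ag_sigmoid <- function(tape, a) {
  a <- as_node(tape, a)
  s <- 1 / (1 + exp(-a$value))
  ag_node(tape, s, list(a), function(nd) ag_accum(a, nd$grad * s * (1 - s)))
}

ag_tanh <- function(tape, a) {
  a <- as_node(tape, a)
  th <- tanh(a$value)
  ag_node(tape, th, list(a), function(nd) ag_accum(a, nd$grad * (1 - th^2)))
}

ag_exp <- function(tape, a) {
  a <- as_node(tape, a)
  e <- exp(a$value)
  ag_node(tape, e, list(a), function(nd) ag_accum(a, nd$grad * e))
}

ag_t <- function(tape, a) {
  a <- as_node(tape, a)
  ag_node(tape, t(a$value), list(a), function(nd) ag_accum(a, t(nd$grad)))
}

row_maxs <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

# Row-wise softmax (numerically stabilised) of `scale * a`. An optional
# logical `mask` (same shape, TRUE = position allowed) restricts each row's
# support; the mask carries no gradient.
ag_softmax_rows <- function(tape, a, mask = NULL, scale = 1) {
  a <- as_node(tape, a)
  x <- if (scale == 1) a$value else a$value * scale
  x <- x - row_maxs(x)
  e <- exp(x)
  if (!is.null(mask)) e[!mask] <- 0
  y <- e / rowSums(e)
  ag_node(tape, y, list(a), function(nd) {
    g <- nd$grad
    ag_accum(a, (y * (g - rowSums(g * y))) * scale)
  })
}

# Row-wise log-softmax.
ag_logsoftmax_rows <- function(tape, a) {
  a <- as_node(tape, a)
  x <- a$value
  m <- row_maxs(x)
  lse <- m + log(rowSums(exp(x - m)))
  v <- x - lse
  p <- exp(v)
  ag_node(tape, v, list(a), function(nd) {
    g <- nd$grad
    ag_accum(a, g - p * rowSums(g))
  })
}

# Per-row layer normalisation with gain/bias (1 x d nodes).
ag_layernorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  a <- as_node(tape, a); gamma <- as_node(tape, gamma); beta <- as_node(tape, beta)
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value); bv <- as.numeric(beta$value)
  v <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ag_node(tape, v, list(a, gamma, beta), function(nd) {
    g <- nd$grad
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    ag_accum(a, dx)
    ag_accum(gamma, matrix(colSums(g * xhat), 1L))
    ag_accum(beta, matrix(colSums(g), 1L))
  })
}

# Row selection / gather; `idx` may repeat (embedding lookup, TPE expansion).
ag_rows <- function(tape, a, idx) {
  a <- as_node(tape, a)
  idx <- as.integer(idx)
  ag_node(tape, a$value[idx, , drop = FALSE], list(a), function(nd) {
    gs <- rowsum(nd$grad, group = idx)
    full <- matrix(0, nrow(a$value), ncol(a$value))
    full[as.integer(rownames(gs)), ] <- gs
    ag_accum(a, full)
  })
}

# Fused affine map X %*% W + b (b a 1 x n row vector broadcast over rows).
ag_affine <- function(tape, x, w, b) {
  x <- as_node(tape, x); w <- as_node(tape, w); b <- as_node(tape, b)
  v <- x$value %*% w$value
  v <- sweep(v, 2L, as.numeric(b$value), "+")
  ag_node(tape, v, list(x, w, b), function(nd) {
    if (x$requires) ag_accum(x, tcrossprod(nd$grad, w$value))
    if (w$requires) ag_accum(w, crossprod(x$value, nd$grad))
    if (b$requires) ag_accum(b, matrix(colSums(nd$grad), 1L))
  })
}

# Column selection / gather.
ag_cols <- function(tape, a, idx) {
  a <- as_node(tape, a)
  idx <- as.integer(idx)
  ag_node(tape, a$value[, idx, drop = FALSE], list(a), function(nd) {
    gs <- rowsum(t(nd$grad), group = idx)
    full <- matrix(0, nrow(a$value), ncol(a$value))
    full[, as.integer(rownames(gs))] <- t(gs)
    ag_accum(a, full)
  })
}

ag_rbind <- function(tape, lst) {
  lst <- lapply(lst, as_node, tape = tape)
  rows <- vapply(lst, function(x) nrow(x$value), integer(1))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  ag_node(tape, do.call(rbind, lapply(lst, function(x) x$value)), lst, function(nd) {
    for (k in seq_along(lst)) {
      ag_accum(lst[[k]], nd$grad[starts[k]:ends[k], , drop = FALSE])
    }
  })
}

ag_cbind <- function(tape, lst) {
  lst <- lapply(lst, as_node, tape = tape)
  cols <- vapply(lst, function(x) ncol(x$value), integer(1))
  ends <- cumsum(cols)
  starts <- ends - cols + 1L
  ag_node(tape, do.call(cbind, lapply(lst, function(x) x$value)), lst, function(nd) {
    for (k in seq_along(lst)) {
      ag_accum(lst[[k]], nd$grad[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

# L2-normalise each row to the unit sphere.
ag_l2norm_rows <- function(tape, a, eps = 1e-12) {
  a <- as_node(tape, a)
  x <- a$value
  n <- sqrt(rowSums(x^2) + eps)
  v <- x / n
  ag_node(tape, v, list(a), function(nd) {
    g <- nd$grad
    ag_accum(a, g / n - x * (rowSums(g * x) / n^3))
  })
}

ag_sum <- function(tape, a) {
  a <- as_node(tape, a)
  ag_node(tape, matrix(sum(a$value), 1L, 1L), list(a), function(nd) {
    ag_accum(a, matrix(as.numeric(nd$grad), nrow(a$value), ncol(a$value)))
  })
}

ag_mean <- function(tape, a) {
  a <- as_node(tape, a)
  n <- length(a$value)
  ag_node(tape, matrix(mean(a$value), 1L, 1L), list(a), function(nd) {
    ag_accum(a, matrix(as.numeric(nd$grad) / n, nrow(a$value), ncol(a$value)))
  })
}

## ---- parameter store helpers ----------------------------------------------

# A per-forward cache wrapping named parameters as shared leaves, so a
# parameter used in several places accumulates a single gradient.
ag_param_cache <- function(tape, params) {
  cache <- new.env(parent = emptyenv())
  P <- function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    v <- params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    nd <- ag_leaf(tape, v)
    cache[[name]] <- nd
    nd
  }
  attr(P, "cache") <- cache
  P
}

ag_collect_grads <- function(P) {
  cache <- attr(P, "cache")
  out <- list()
  for (nm in ls(cache)) {
    g <- cache[[nm]]$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}
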