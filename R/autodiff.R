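# Minimal reverse-mode automatic differentiation on dense matrices.
# A tape records operation nodes in creation order; ad_backward walks it
# in reverse, accumulating vector-Jacobian products. All values are
# base-R numeric matrices so the heavy lifting (matmul, rowsum) stays in
# BLAS/C. This is the substrate for the equivariant network; only the
# operations that network needs are implemented.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

.ad_push <- function(tape, val, parents = NULL, vjp = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$vjp <- vjp
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes,
                                              vector("list", n))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

.ad_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

ad_const <- function(tape, val) .ad_push(tape, val)
ad_leaf <- ad_const  # leaves (inputs/parameters) just have no vjp

# Run reverse pass from `root` (seed gradient 1).
ad_backward <- function(tape, root, seed = matrix(1, 1, 1)) {
  root$grad <- seed
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$vjp)) nd$vjp(nd$grad, nd)
  }
  invisible(NULL)
}

ad_matmul <- function(tape, a, b, ta = FALSE, tb = FALSE) {
  av <- a$val; bv <- b$val
  v <- if (!ta && !tb) av %*% bv
       else if (ta && !tb) crossprod(av, bv)
       else if (!ta && tb) tcrossprod(av, bv)
       else t(bv %*% av)
  .ad_push(tape, v, list(a, b), function(g, nd) {
    if (!ta && !tb) { .ad_acc(a, tcrossprod(g, bv)); .ad_acc(b, crossprod(av, g)) }
    else if (ta && !tb) { .ad_acc(a, tcrossprod(bv, g)); .ad_acc(b, av %*% g) }
    else if (!ta && tb) { .ad_acc(a, g %*% bv); .ad_acc(b, crossprod(g, av)) }
    else { .ad_acc(a, tcrossprod(bv, t(g))); .ad_acc(b, crossprod(t(g), av)) }
  })
}

ad_add <- function(tape, a, b)
  .ad_push(tape, a$val + b$val, list(a, b), function(g, nd) {
    .ad_acc(a, g); .ad_acc(b, g)
  })

ad_sub <- function(tape, a, b)
  .ad_push(tape, a$val - b$val, list(a, b), function(g, nd) {
    .ad_acc(a, g); .ad_acc(b, -g)
  })

# bias: 1 x d row vector broadcast over rows of a (column-major
# recycling with rep(each = n) avoids sweep's aperm)
ad_add_bias <- function(tape, a, bias) {
  n <- nrow(a$val)
  .ad_push(tape, a$val + rep(as.numeric(bias$val), each = n),
           list(a, bias),
           function(g, nd) {
             .ad_acc(a, g)
             .ad_acc(bias, matrix(colSums(g), 1L))
           })
}

ad_mul <- function(tape, a, b) {
  av <- a$val; bv <- b$val
  .ad_push(tape, av * bv, list(a, b), function(g, nd) {
    .ad_acc(a, g * bv); .ad_acc(b, g * av)
  })
}

# elementwise multiply each row of a (n x d) by column vector v (n x 1)
ad_mul_colvec <- function(tape, a, v) {
  av <- a$val; vv <- as.numeric(v$val)
  .ad_push(tape, av * vv, list(a, v), function(g, nd) {
    .ad_acc(a, g * vv)
    .ad_acc(v, matrix(rowSums(g * av), ncol = 1L))
  })
}

ad_scale <- function(tape, a, s)  # s: plain scalar constant
  .ad_push(tape, a$val * s, list(a), function(g, nd) .ad_acc(a, g * s))

ad_gather <- function(tape, a, idx) {
  av <- a$val
  .ad_push(tape, av[idx, , drop = FALSE], list(a), function(g, nd) {
    acc <- rowsum(g, group = idx, reorder = FALSE)
    out <- matrix(0, nrow(av), ncol(av))
    out[as.integer(rownames(acc)), ] <- acc
    .ad_acc(a, out)
  })
}

# scatter-add rows of a (length(idx) x d) into an n-row matrix
ad_scatter <- function(tape, a, idx, n) {
  acc <- rowsum(a$val, group = idx, reorder = FALSE)
  v <- matrix(0, n, ncol(a$val))
  v[as.integer(rownames(acc)), ] <- acc
  .ad_push(tape, v, list(a), function(g, nd)
    .ad_acc(a, g[idx, , drop = FALSE]))
}

ad_silu <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  v <- a$val * s
  .ad_push(tape, v, list(a), function(g, nd)
    .ad_acc(a, g * (s * (1 + a$val * (1 - s)))))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  .ad_push(tape, s, list(a), function(g, nd) .ad_acc(a, g * s * (1 - s)))
}

ad_tanh <- function(tape, a) {
  v <- tanh(a$val)
  .ad_push(tape, v, list(a), function(g, nd) .ad_acc(a, g * (1 - v^2)))
}

ad_softplus <- function(tape, a) {
  x <- a$val
  v <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  .ad_push(tape, v, list(a), function(g, nd)
    .ad_acc(a, g / (1 + exp(-x))))
}

ad_rowsumsq <- function(tape, a) {  # n x d -> n x 1 of squared row norms
  av <- a$val
  .ad_push(tape, matrix(rowSums(av^2), ncol = 1L), list(a),
           function(g, nd) .ad_acc(a, 2 * av * as.numeric(g)))
}

ad_colmeans <- function(tape, a) {  # n x d -> 1 x d
  n <- nrow(a$val)
  .ad_push(tape, matrix(colMeans(a$val), 1L), list(a), function(g, nd)
    .ad_acc(a, matrix(rep(as.numeric(g) / n, each = n), n)))
}

ad_concat_cols <- function(tape, a, b) {
  na <- ncol(a$val)
  .ad_push(tape, cbind(a$val, b$val), list(a, b), function(g, nd) {
    .ad_acc(a, g[, seq_len(na), drop = FALSE])
    .ad_acc(b, g[, -seq_len(na), drop = FALSE])
  })
}

ad_cols <- function(tape, a, idx) {
  av <- a$val
  .ad_push(tape, av[, idx, drop = FALSE], list(a), function(g, nd) {
    out <- matrix(0, nrow(av), ncol(av))
    out[, idx] <- g
    .ad_acc(a, out)
  })
}

ad_softmax_rows <- function(tape, a) {
  x <- a$val
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  v <- e / rowSums(e)
  .ad_push(tape, v, list(a), function(g, nd)
    .ad_acc(a, (g - rowSums(g * v)) * v))
}

# Row-wise layer normalization with learned gain/bias (1 x d each).
ad_layernorm <- function(tape, a, gain, bias, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowSums(xc^2) / d
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  gv <- as.numeric(gain$val); bv <- as.numeric(bias$val)
  nr <- nrow(x)
  v <- xh * rep(gv, each = nr) + rep(bv, each = nr)
  .ad_push(tape, v, list(a, gain, bias), function(g, nd) {
    .ad_acc(gain, matrix(colSums(g * xh), 1L))
    .ad_acc(bias, matrix(colSums(g), 1L))
    gy <- sweep(g, 2L, gv, "*")
    gsum <- rowSums(gy)
    gxsum <- rowSums(gy * xh)
    .ad_acc(a, inv * (gy - gsum / d - xh * gxsum / d))
  })
}

# Clamp each row of a (n x d) to norm <= cmax (exact piecewise gradient).
ad_clamp_rows <- function(tape, a, cmax) {
  x <- a$val
  nr <- sqrt(rowSums(x^2))
  over <- nr > cmax
  s <- ifelse(over, cmax / pmax(nr, 1e-12), 1)
  v <- x * s
  .ad_push(tape, v, list(a), function(g, nd) {
    gx <- g * s
    if (any(over)) {
      io <- which(over)
      # d/dx [c * x / |x|] = c/|x| (I - xx^T/|x|^2)
      dot <- rowSums(g[io, , drop = FALSE] * x[io, , drop = FALSE])
      gx[io, ] <- gx[io, , drop = FALSE] -
        (cmax * dot / nr[io]^3) * x[io, , drop = FALSE]
    }
    .ad_acc(a, gx)
  })
}

ad_log <- function(tape, a)
  .ad_push(tape, log(a$val), list(a), function(g, nd)
    .ad_acc(a, g / a$val))

ad_sum <- function(tape, a)
  .ad_push(tape, matrix(sum(a$val), 1L, 1L), list(a), function(g, nd)
    .ad_acc(a, matrix(as.numeric(g), nrow(a$val), ncol(a$val))))
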