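# Network building blocks on top of the autodiff tape: parameter
# initialization, two-layer perceptrons, EGNN message-passing layers, and
# multi-head (cross/self) attention.

.init_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

.init_linear <- function(nin, nout, zero_out = FALSE) {
  list(W = if (zero_out) matrix(0, nin, nout) else .init_mat(nin, nout),
       b = matrix(0, 1L, nout))
}

.init_mlp2 <- function(nin, nhid, nout, small_out = FALSE) {
  l2 <- .init_linear(nhid, nout)
  if (small_out) l2$W <- l2$W * 0.1
  list(l1 = .init_linear(nin, nhid), l2 = l2)
}

.init_egnn <- function(d, dm = max(8L, d %/% 2L)) {
  # phi_e first layer split into per-node source/destination projections
  # plus a distance channel, so the expensive half runs at node rather
  # than edge granularity. Messages are dm-wide (bottlenecked edge MLP,
  # default half the node width).
  list(e_src = .init_mat(d, dm), e_dst = .init_mat(d, dm),
       e_dist = matrix(stats::rnorm(dm, sd = 0.1), 1L, dm),
       e_b = matrix(0, 1L, dm),
       e2 = .init_linear(dm, dm),
       x1 = .init_linear(dm, dm),
       x2 = list(W = matrix(stats::rnorm(dm, sd = 0.01), dm, 1L),
                 b = matrix(0, 1L, 1L)),
       h1 = .init_linear(d + dm, d), h2 = .init_linear(d, d))
}

.init_attention <- function(d) {
  list(Wq = .init_mat(d, d), Wk = .init_mat(d, d), Wv = .init_mat(d, d),
       Wo = .init_mat(d, d), ln_g = matrix(1, 1L, d),
       ln_b = matrix(0, 1L, d))
}

# Wrap a (possibly nested) list of parameter matrices as tape leaves.
.leafify <- function(tape, params) {
  rapply(params, function(m) ad_leaf(tape, m), classes = "matrix",
         how = "replace")
}

# Collect gradients from a leafified parameter tree (zeros where unused).
.collect_grads <- function(leaves) {
  rapply(leaves, function(nd) {
    if (is.null(nd$grad)) matrix(0, nrow(nd$val), ncol(nd$val)) else nd$grad
  }, classes = "environment", how = "replace")
}

.linear <- function(tape, x, p)
  ad_add_bias(tape, ad_matmul(tape, x, p$W), p$b)

.mlp2 <- function(tape, x, p)
  .linear(tape, ad_silu(tape, .linear(tape, x, p$l1)), p$l2)

# One EGNN layer. h: n x d node hiddens; x: n x 3 coordinates (tape
# nodes); edges: E x 2 (src -> dst). Messages m_ij = phi_e(h_i, h_j,
# |x_i - x_j|^2) are aggregated at the source node (each node attends to
# its own k nearest neighbours). Coordinates update only when
# update_coords, with a per-layer row-norm clamp; h gets a residual.
# The fused forward/backward runs in compiled code and is recorded on
# the tape as one operation.
egnn_layer <- function(tape, h, x, edges, p, update_coords = FALSE,
                       clamp = 5.0, dist_scale = 10.0) {
  n <- nrow(h$val)
  if (nrow(edges) == 0L) {
    # isolated nodes: h updated from the self term only, x unchanged
    dm <- nrow(p$h1$W$val) - ncol(h$val)
    zero <- ad_const(tape, matrix(0, n, dm))
    upd <- .mlp2(tape, ad_concat_cols(tape, h, zero),
                 list(l1 = p$h1, l2 = p$h2))
    return(list(h = ad_add(tape, h, upd), x = x))
  }
  src0 <- edges[, 1L] - 1L  # 0-based for the compiled kernel
  dst0 <- edges[, 2L] - 1L
  parm <- list(e_src = p$e_src$val, e_dst = p$e_dst$val,
               e_dist = p$e_dist$val, e_b = p$e_b$val,
               e2W = p$e2$W$val, e2b = p$e2$b$val,
               x1W = p$x1$W$val, x1b = p$x1$b$val,
               x2W = p$x2$W$val, x2b = p$x2$b$val,
               h1W = p$h1$W$val, h1b = p$h1$b$val,
               h2W = p$h2$W$val, h2b = p$h2$b$val)
  fw <- .egnn_forward_cpp(h$val, x$val, src0, dst0, parm, update_coords,
                          clamp, dist_scale)
  pnodes <- list(p$e_src, p$e_dst, p$e_dist, p$e_b, p$e2$W, p$e2$b,
                 p$x1$W, p$x1$b, p$x2$W, p$x2$b, p$h1$W, p$h1$b,
                 p$h2$W, p$h2$b)
  names(pnodes) <- c("e_src", "e_dst", "e_dist", "e_b", "e2W", "e2b",
                     "x1W", "x1b", "x2W", "x2b", "h1W", "h1b", "h2W",
                     "h2b")
  hv <- h$val; xv <- x$val
  # joint node carrying both outputs; grads for h' and x' accumulate on
  # the two child views below, then flow back through one fused vjp
  h_node <- .ad_push(tape, fw$h_out, c(list(h, x), pnodes), NULL)
  x_node <- .ad_push(tape, fw$x_out, list(h_node), NULL)
  h_node$vjp <- function(g, nd) {
    gx <- x_node$grad
    if (is.null(gx)) gx <- matrix(0, n, 3L)
    bw <- .egnn_backward_cpp(hv, xv, src0, dst0, parm, fw$cache, g, gx,
                             update_coords, clamp, dist_scale)
    .ad_acc(h, bw$g_h)
    .ad_acc(x, bw$g_x)
    for (nm in names(pnodes)) {
      gp <- bw$g_par[[nm]]
      if (!is.matrix(gp)) gp <- matrix(gp, nrow = 1L)
      .ad_acc(pnodes[[nm]], gp)
    }
  }
  # ensure h_node fires even when only x' is consumed downstream
  x_node$vjp <- function(g, nd) {
    if (is.null(h_node$grad))
      h_node$grad <- matrix(0, nrow(fw$h_out), ncol(fw$h_out))
  }
  list(h = h_node, x = x_node)
}

# Multi-head scaled dot-product attention block: queries from Hq, keys
# and values from Hkv, residual + layer norm on the query side. Returns
# the updated hiddens and the per-head attention matrices (rows sum to 1).
attention_block <- function(tape, hq, hkv, p, heads) {
  d <- ncol(hq$val)
  dh <- d %/% heads
  q <- ad_matmul(tape, hq, p$Wq)
  k <- ad_matmul(tape, hkv, p$Wk)
  v <- ad_matmul(tape, hkv, p$Wv)
  outs <- vector("list", heads)
  attn <- vector("list", heads)
  for (hd in seq_len(heads)) {
    idx <- ((hd - 1L) * dh + 1L):(hd * dh)
    qh <- ad_cols(tape, q, idx)
    kh <- ad_cols(tape, k, idx)
    vh <- ad_cols(tape, v, idx)
    scores <- ad_scale(tape, ad_matmul(tape, qh, kh, tb = TRUE),
                       1 / sqrt(dh))
    a <- ad_softmax_rows(tape, scores)
    attn[[hd]] <- a
    outs[[hd]] <- ad_matmul(tape, a, vh)
  }
  o <- outs[[1L]]
  if (heads > 1L) for (hd in 2L:heads) o <- ad_concat_cols(tape, o, outs[[hd]])
  o <- ad_matmul(tape, o, p$Wo)
  out <- ad_layernorm(tape, ad_add(tape, hq, o), p$ln_g, p$ln_b)
  list(out = out, attention = lapply(attn, function(a) a$val),
       attention_nodes = attn)
}
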