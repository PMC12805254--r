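# The two-stage network: EGNN layers, cross-attention, gating,
# propagation, and the full forward pass.

small_cfg <- function(...) model_config(hidden_dim = 16L,
                                        attention_heads = 2L,
                                        egnn_layers_encoder = 1L,
                                        egnn_layers_propagation = 1L,
                                        self_attention_layers = 1L, ...)

tiny_setup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gr <- fixture_graphs()
    cache <<- list(gp = gr$gp, g_bs = gr$g_bs,
                   gl_ago = build_ligand_graph("OCc1ccccc1"),
                   gl_ant = build_ligand_graph("Clc1ccccc1"),
                   model = init_model(small_cfg(seed = 11)))
    cache
  }
})

test_that("an EGNN layer is equivariant and symmetric-input consistent", {
  set.seed(2)
  d <- 8; n <- 6
  h <- matrix(rnorm(n * d), n)
  x <- matrix(rnorm(n * 3) * 4, n)
  edges <- cbind(rep(1:n, each = 2),
                 as.vector(vapply(1:n, function(i)
                   sample(setdiff(1:n, i), 2), integer(2))))
  p <- gpcrmoa:::.init_egnn(d)
  run <- function(xv) {
    tape <- ad_tape()
    pn <- gpcrmoa:::.leafify(tape, p)
    out <- gpcrmoa:::egnn_layer(tape, ad_const(tape, h),
                                ad_const(tape, xv), edges, pn,
                                update_coords = TRUE)
    list(h = out$h$val, x = out$x$val)
  }
  base <- run(x)
  rot <- random_rotation(); tr <- c(2, -1, 3)
  moved <- run(sweep(x %*% t(rot), 2, tr, "+"))
  expect_equal(moved$h, base$h, tolerance = 1e-10)
  expect_equal(moved$x, sweep(base$x %*% t(rot), 2, tr, "+"),
               tolerance = 1e-8)
})

test_that("mirror-symmetric node pairs receive equal hidden updates", {
  d <- 8
  h2 <- matrix(rep(rnorm(d), 2), 2, byrow = TRUE)
  x2 <- rbind(c(1, 0, 0), c(-1, 0, 0))
  edges <- rbind(c(1, 2), c(2, 1))
  set.seed(3)
  p <- gpcrmoa:::.init_egnn(d)
  tape <- ad_tape()
  out <- gpcrmoa:::egnn_layer(tape, ad_const(tape, h2),
                              ad_const(tape, x2), edges,
                              gpcrmoa:::.leafify(tape, p),
                              update_coords = TRUE)
  expect_equal(out$h$val[1, ], out$h$val[2, ], tolerance = 1e-12)
})

test_that("an isolated node keeps its coordinates and self-updates h", {
  d <- 8
  set.seed(4)
  p <- gpcrmoa:::.init_egnn(d)
  h <- matrix(rnorm(d), 1)
  x <- matrix(c(1, 2, 3), 1)
  tape <- ad_tape()
  out <- gpcrmoa:::egnn_layer(tape, ad_const(tape, h), ad_const(tape, x),
                              matrix(integer(0), 0, 2),
                              gpcrmoa:::.leafify(tape, p),
                              update_coords = TRUE)
  expect_equal(out$x$val, x)
  expect_false(isTRUE(all.equal(out$h$val, h)))
})

test_that("cross-attention rows are normalized, permutation-consistent, and
           degenerate for single keys", {
  set.seed(6)
  d <- 16; heads <- 2
  hp <- matrix(rnorm(5 * d), 5); hl <- matrix(rnorm(3 * d), 3)
  p <- gpcrmoa:::.init_attention(d)
  run <- function(hq, hkv) {
    tape <- ad_tape()
    gpcrmoa:::attention_block(tape, ad_const(tape, hq),
                              ad_const(tape, hkv),
                              gpcrmoa:::.leafify(tape, p), heads)
  }
  blk <- run(hp, hl)
  for (a in blk$attention) expect_equal(rowSums(a), rep(1, 5))
  # single ligand node -> every attention row is [1]
  one <- run(hp, hl[1, , drop = FALSE])
  for (a in one$attention) expect_equal(unname(a), matrix(1, 5, 1))
  # permuting keys permutes attention columns, leaves output unchanged
  perm <- c(3, 1, 2)
  blk_p <- run(hp, hl[perm, ])
  expect_equal(blk_p$out$val, blk$out$val, tolerance = 1e-12)
  for (hd in seq_len(heads))
    expect_equal(blk_p$attention[[hd]], blk$attention[[hd]][, perm],
                 tolerance = 1e-12)
})

test_that("zeroed queries yield uniform attention over keys", {
  set.seed(7)
  d <- 16
  p <- gpcrmoa:::.init_attention(d)
  hq <- matrix(0, 4, d)
  hkv <- matrix(rnorm(6 * d), 6)
  tape <- ad_tape()
  blk <- gpcrmoa:::attention_block(tape, ad_const(tape, hq),
                                   ad_const(tape, hkv),
                                   gpcrmoa:::.leafify(tape, p), 2)
  for (a in blk$attention)
    expect_equal(unname(a), matrix(1 / 6, 4, 6), tolerance = 1e-12)
})

test_that("the interaction module honours its shape contract and determinism", {
  ts <- tiny_setup()
  out <- interaction_module(ts$model, ts$g_bs, ts$gl_ago)
  expect_length(out$logit_bind, 1L)
  expect_equal(out$p_bind, plogis(out$logit_bind))
  expect_equal(nrow(out$interaction_signal), nrow(ts$g_bs$nodes))
  expect_equal(ncol(out$interaction_signal), ts$model$cfg$hidden_dim)
  for (a in out$cross_attention$protein_to_ligand)
    expect_equal(rowSums(a), rep(1, nrow(ts$g_bs$nodes)))
  out2 <- interaction_module(ts$model, ts$g_bs, ts$gl_ago)
  expect_identical(out$logit_bind, out2$logit_bind)
  # rigid transform of either graph leaves the logit unchanged
  rot <- random_rotation()
  out3 <- interaction_module(ts$model,
                             transform_graph(ts$g_bs, rot, c(1, 2, 3)),
                             ts$gl_ago)
  expect_equal(out3$logit_bind, out$logit_bind, tolerance = 1e-4)
})

test_that("gating scales the injected signal and leaves other nodes alone", {
  ts <- tiny_setup()
  n <- nrow(ts$gp$nodes); d <- ts$model$cfg$hidden_dim
  set.seed(8)
  h <- matrix(rnorm(n * d), n)
  sig <- matrix(rnorm(nrow(ts$g_bs$nodes) * d), nrow(ts$g_bs$nodes))
  parent <- ts$g_bs$parent_index
  aug1 <- gate_and_inject(h, sig, 1.0, parent)
  expect_equal(aug1[parent, ], h[parent, ] + sig)
  expect_identical(aug1[-parent, ], h[-parent, ])
  aug0 <- gate_and_inject(h, sig, 1e-9, parent)
  expect_lt(max(abs(aug0 - h)), 1e-9 * max(abs(sig)) * 1.01)
  expect_error(gate_and_inject(h, sig[-1, ], 0.5, parent), "mismatch")
})

test_that("the propagation module is equivariant with normalized attention", {
  ts <- tiny_setup()
  n <- nrow(ts$gp$nodes); d <- ts$model$cfg$hidden_dim
  set.seed(9)
  h <- matrix(rnorm(n * d), n)
  out <- propagation_module(ts$model, ts$gp, h)
  expect_length(out$global_repr, d)
  for (layer in out$self_attention)
    for (a in layer) expect_equal(rowSums(a), rep(1, n))
  rot <- random_rotation(); tr <- c(-2, 5, 1)
  out2 <- propagation_module(ts$model, transform_graph(ts$gp, rot, tr), h)
  expect_equal(out2$global_repr, out$global_repr, tolerance = 1e-4)
  expect_equal(out2$final_coords,
               sweep(out$final_coords %*% t(rot), 2, tr, "+"),
               tolerance = 1e-6)
})

test_that("with zero injected signal the ligand cannot influence Stage 2", {
  ts <- tiny_setup()
  d <- ts$model$cfg$hidden_dim
  base_h <- ts$gp$features %*% ts$model$params$p_embed$W +
    matrix(ts$model$params$p_embed$b, nrow(ts$gp$features), d,
           byrow = TRUE)
  run_zero <- function(gl) {
    sig <- interaction_module(ts$model, ts$g_bs, gl)$interaction_signal
    aug <- gate_and_inject(base_h, 0 * sig, 1e-12,
                           ts$g_bs$parent_index)
    propagation_module(ts$model, ts$gp, aug)$global_repr
  }
  expect_equal(run_zero(ts$gl_ago), run_zero(ts$gl_ant),
               tolerance = 1e-12)
})

test_that("the full forward pass keeps its shape and invariance contracts", {
  ts <- tiny_setup()
  out <- forward_pass(ts$model, ts$gp, ts$g_bs, ts$gl_ago)
  expect_length(out$activity_logits, 2L)
  expect_equal(sum(out$activity_softmax), 1, tolerance = 1e-12)
  expect_equal(dim(out$final_coords), dim(ts$gp$coords))
  expect_true(is.na(out$decision))
  rot <- random_rotation(); tr <- c(3, 3, 3)
  out2 <- forward_pass(ts$model,
                       transform_graph(ts$gp, rot, tr),
                       transform_graph(ts$g_bs, rot, tr),
                       transform_graph(ts$gl_ago, rot, tr))
  expect_equal(out2$logit_bind, out$logit_bind, tolerance = 1e-4)
  expect_equal(out2$activity_logits, out$activity_logits,
               tolerance = 1e-4)
})

test_that("activity loss gradients reach the ligand features through the gate", {
  ts <- tiny_setup()
  tape <- ad_tape()
  lig_feat <- ad_const(tape, ts$gl_ago$features)
  out <- forward_pass(ts$model, ts$gp, ts$g_bs, ts$gl_ago, tape = tape,
                      lig_feat_node = lig_feat)
  sm <- ad_softmax_rows(tape, out$nodes$act_logits)
  ce <- ad_scale(tape, ad_log(tape, ad_cols(tape, sm, 1L)), -1)
  ad_backward(tape, ce)
  expect_false(is.null(lig_feat$grad))
  expect_gt(max(abs(lig_feat$grad)), 0)
  # finite-difference spot check on one ligand feature entry
  idx <- which(abs(lig_feat$grad) == max(abs(lig_feat$grad)))[1]
  eps <- 1e-5
  ce_at <- function(delta) {
    gl <- ts$gl_ago
    gl$features[idx] <- gl$features[idx] + delta
    o <- forward_pass(ts$model, ts$gp, ts$g_bs, gl)
    -log(o$activity_softmax[1])
  }
  fd <- (ce_at(eps) - ce_at(-eps)) / (2 * eps)
  expect_equal(unname(fd), unname(lig_feat$grad[idx]), tolerance = 1e-4)
})

test_that("gate openness moves the global representation monotonically", {
  ts <- tiny_setup()
  sig <- interaction_module(ts$model, ts$g_bs,
                            ts$gl_ago)$interaction_signal
  base_h <- ts$gp$features %*% ts$model$params$p_embed$W +
    matrix(ts$model$params$p_embed$b, nrow(ts$gp$features),
           ts$model$cfg$hidden_dim, byrow = TRUE)
  g0 <- propagation_module(ts$model, ts$gp, base_h)$global_repr
  dists <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(a) {
    aug <- gate_and_inject(base_h, sig, max(a, 1e-12),
                           ts$g_bs$parent_index)
    sqrt(sum((propagation_module(ts$model, ts$gp, aug)$global_repr -
                g0)^2))
  }, numeric(1))
  expect_true(all(diff(dists) >= -1e-8))
})

test_that("architecture ablation switches change the decision pathway", {
  ts <- tiny_setup()
  for (arch in c("unified", "shared")) {
    m <- init_model(small_cfg(architecture = arch, seed = 11))
    out <- forward_pass(m, ts$gp, ts$g_bs, ts$gl_ago)
    expect_length(out$activity_logits, 2L)
    expect_true(out$p_bind > 0 && out$p_bind < 1)
  }
  m_direct <- init_model(small_cfg(transfer = "direct", seed = 11))
  m_gated <- init_model(small_cfg(transfer = "gated", seed = 11))
  o_d <- forward_pass(m_direct, ts$gp, ts$g_bs, ts$gl_ago)
  o_g <- forward_pass(m_gated, ts$gp, ts$g_bs, ts$gl_ago)
  # same weights, different transfer rule -> different stage-2 logits
  expect_false(isTRUE(all.equal(o_d$activity_logits,
                                o_g$activity_logits)))
  m_noattn <- init_model(small_cfg(use_self_attention = FALSE, seed = 11))
  o_na <- forward_pass(m_noattn, ts$gp, ts$g_bs, ts$gl_ago)
  expect_length(o_na$self_attention, 0L)
})

test_that("checkpoints round-trip through JSON", {
  ts <- tiny_setup()
  f <- tempfile(fileext = ".json")
  save_checkpoint(ts$model, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, ts$model$params, tolerance = 1e-12)
  o1 <- forward_pass(ts$model, ts$gp, ts$g_bs, ts$gl_ago)
  o2 <- forward_pass(back, ts$gp, ts$g_bs, ts$gl_ago)
  expect_equal(o1$logit_bind, o2$logit_bind, tolerance = 1e-10)
})
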