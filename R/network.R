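# The two-stage hierarchical model. Stage 1 (interaction module): EGNN
# encoders over the ligand graph and the binding-site subgraph,
# bidirectional cross-attention, mean pooling and a binding head giving a
# single logit; the cross-attention-updated binding-site hiddens are the
# interaction signal. Stage 2 (allosteric propagation): the signal,
# scaled by the predicted binding probability (gating), is added to the
# binding-site nodes of the full protein graph, propagated by
# coordinate-updating EGNN layers and global self-attention, pooled, and
# classified agonist vs antagonist by the activity head.

#' Model configuration
#'
#' @param hidden_dim Hidden width (divisible by `attention_heads`).
#' @param egnn_layers_encoder Stage-1 encoder depth (per graph).
#' @param egnn_layers_propagation Stage-2 EGNN depth (coordinate-updating).
#' @param self_attention_layers Stage-2 global attention depth.
#' @param attention_heads Heads for all attention blocks.
#' @param dropout Reserved (no dropout is applied in deterministic mode).
#' @param coordinate_update_clamp Max per-layer coordinate step (Angstrom).
#' @param architecture `"hierarchical"` (decoupled heads; default),
#'   `"shared"` (both heads on the propagated global representation), or
#'   `"unified"` (single 3-class head).
#' @param transfer `"gated"` (signal scaled by the Stage-1 binding
#'   probability; default) or `"direct"`.
#' @param use_self_attention Include the Stage-2 self-attention stack.
#' @param seed Initialization seed.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_dim = 128L, egnn_layers_encoder = 2L,
                         egnn_layers_propagation = 3L,
                         self_attention_layers = 2L, attention_heads = 4L,
                         dropout = 0.1, coordinate_update_clamp = 5.0,
                         architecture = c("hierarchical", "shared",
                                          "unified"),
                         transfer = c("gated", "direct"),
                         use_self_attention = TRUE, seed = 1L) {
  architecture <- match.arg(architecture)
  transfer <- match.arg(transfer)
  stopifnot(hidden_dim %% attention_heads == 0L,
            egnn_layers_encoder >= 1L, egnn_layers_propagation >= 1L,
            self_attention_layers >= 1L)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 egnn_layers_encoder = as.integer(egnn_layers_encoder),
                 egnn_layers_propagation =
                   as.integer(egnn_layers_propagation),
                 self_attention_layers = as.integer(self_attention_layers),
                 attention_heads = as.integer(attention_heads),
                 dropout = dropout,
                 coordinate_update_clamp = coordinate_update_clamp,
                 architecture = architecture, transfer = transfer,
                 use_self_attention = use_self_attention,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Initialize model parameters
#'
#' @param cfg A [model_config()].
#' @param p_feat,l_feat Protein/ligand feature widths (34 / 19).
#' @return A `gpcr_model`: list with `cfg` and `params` (named matrices).
#' @export
init_model <- function(cfg = model_config(), p_feat = 34L, l_feat = 19L) {
  set.seed(cfg$seed)
  d <- cfg$hidden_dim
  params <- list(
    p_embed = .init_linear(p_feat, d),
    l_embed = .init_linear(l_feat, d),
    enc_p = lapply(seq_len(cfg$egnn_layers_encoder),
                   function(i) .init_egnn(d)),
    enc_l = lapply(seq_len(cfg$egnn_layers_encoder),
                   function(i) .init_egnn(d)),
    cross_p = .init_attention(d),  # protein queries over ligand keys
    cross_l = .init_attention(d),  # ligand queries over protein keys
    bind_head = .init_mlp2(2L * d, d, 1L),
    prop = lapply(seq_len(cfg$egnn_layers_propagation),
                  function(i) .init_egnn(d)),
    self_attn = lapply(seq_len(cfg$self_attention_layers),
                       function(i) .init_attention(d)),
    act_head = .init_mlp2(d, d, 2L),
    unified_head = .init_mlp2(d, d, 3L),
    shared_bind_head = .init_mlp2(d, d, 1L))
  structure(list(cfg = cfg, params = params,
                 p_feat = as.integer(p_feat), l_feat = as.integer(l_feat)),
            class = "gpcr_model")
}

#' @export
print.gpcr_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, classes = "matrix", how = "unlist"))
  cat("gpcr_model: hidden ", x$cfg$hidden_dim, ", ",
      x$cfg$architecture, " architecture, ", x$cfg$transfer,
      " transfer, ", format(np, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# EGNN encoder stack (no coordinate updates in Stage 1: recognition, not
# motion).
.encode <- function(tape, feat, coords, edges, embed, stack) {
  h <- .linear(tape, feat, embed)
  x <- ad_const(tape, coords)
  for (p in stack) {
    out <- egnn_layer(tape, h, x, edges, p, update_coords = FALSE)
    h <- out$h
  }
  h
}

#' Stage-1 interaction module
#'
#' Encodes the binding-site subgraph and the ligand graph with separate
#' EGNN encoders, runs bidirectional cross-attention, mean-pools both
#' sides, and applies the binding head. The post-attention protein
#' hiddens are the interaction signal.
#'
#' @param model A `gpcr_model`.
#' @param g_bs Binding-site `protein_graph` (from [cbs_subgraph()]).
#' @param g_l A `ligand_graph`.
#' @param tape Optional shared tape (for end-to-end training).
#' @param lig_feat_node Optional tape node overriding the ligand feature
#'   leaf (used for gradient probes).
#' @return List: `logit_bind`, `p_bind`, `interaction_signal` (matrix),
#'   `cross_attention` (`protein_to_ligand`, `ligand_to_protein` per-head
#'   lists), plus tape nodes for training (`nodes`).
#' @export
interaction_module <- function(model, g_bs, g_l, tape = NULL,
                               lig_feat_node = NULL) {
  if (is.null(tape)) tape <- ad_tape()
  pl <- .leafify(tape, model$params)
  .interaction_forward(model$cfg, pl, tape, g_bs, g_l, lig_feat_node)
}

.interaction_forward <- function(cfg, pl, tape, g_bs, g_l,
                                 lig_feat_node = NULL) {
  if (!length(g_l$elements)) stop("empty ligand graph")
  hp <- .encode(tape, ad_const(tape, g_bs$features), g_bs$coords,
                g_bs$edges, pl$p_embed, pl$enc_p)
  lf <- if (is.null(lig_feat_node)) ad_const(tape, g_l$features)
        else lig_feat_node
  ledges <- if (nrow(g_l$edges))
    rbind(as.matrix(g_l$edges[, c("a1", "a2")]),
          as.matrix(g_l$edges[, c("a2", "a1")]))
  else matrix(integer(0), 0L, 2L)
  hl <- .encode(tape, lf, g_l$coords, ledges, pl$l_embed, pl$enc_l)

  cp <- attention_block(tape, hp, hl, pl$cross_p, cfg$attention_heads)
  cl <- attention_block(tape, hl, hp, pl$cross_l, cfg$attention_heads)

  pool <- ad_concat_cols(tape, ad_colmeans(tape, cp$out),
                         ad_colmeans(tape, cl$out))
  logit <- .mlp2(tape, pool, pl$bind_head)
  p_bind_node <- ad_sigmoid(tape, logit)
  list(logit_bind = as.numeric(logit$val),
       p_bind = as.numeric(p_bind_node$val),
       interaction_signal = cp$out$val,
       cross_attention = list(protein_to_ligand = cp$attention,
                              ligand_to_protein = cl$attention),
       nodes = list(tape = tape, params = pl, logit = logit,
                    p_bind = p_bind_node, signal = cp$out,
                    h_lig = cl$out))
}

#' Gate and inject the interaction signal into the full protein graph
#'
#' Adds `p_bind * signal` to the hiddens of the binding-site nodes
#' (index-aligned through the cBS subgraph's `parent_index`); other nodes
#' are untouched.
#'
#' @param h_full n x d matrix (or tape node) of full-graph hiddens.
#' @param signal cBS-node signal matrix (or tape node).
#' @param p_bind Scalar in (0, 1) (or a 1x1 tape node).
#' @param parent_index Row indices of cBS nodes within the full graph.
#' @return Augmented hiddens (same type as `h_full`).
#' @export
gate_and_inject <- function(h_full, signal, p_bind, parent_index) {
  if (is.matrix(h_full)) {
    if (length(parent_index) != nrow(signal))
      stop("signal / cBS node count mismatch")
    h_full[parent_index, ] <- h_full[parent_index, , drop = FALSE] +
      as.numeric(p_bind) * signal
    return(h_full)
  }
  stop("tape-node injection is internal; use .gate_inject_node")
}

.gate_inject_node <- function(tape, h_full, signal, p_bind_node,
                              parent_index, gated = TRUE) {
  if (nrow(signal$val) != length(parent_index))
    stop("signal / cBS node count mismatch")
  n <- nrow(h_full$val)
  sig <- if (gated) {
    ones <- ad_const(tape, matrix(1, nrow(signal$val), 1L))
    gate <- ad_matmul(tape, ones, p_bind_node)  # broadcast 1x1 scalar
    ad_mul_colvec(tape, signal, gate)
  } else signal
  ad_add(tape, h_full, ad_scatter(tape, sig, parent_index, n))
}

#' Stage-2 allosteric propagation module
#'
#' Runs the coordinate-updating EGNN stack and the global self-attention
#' stack over the full protein graph with injected signal, then
#' mean-pools into the global conformational-state representation.
#'
#' @param model A `gpcr_model`.
#' @param gp Full `protein_graph`.
#' @param h_augmented n x d matrix of augmented node hiddens.
#' @return List: `global_repr` (1 x d), `self_attention` (per-layer,
#'   per-head matrices), `final_coords` (n x 3).
#' @export
propagation_module <- function(model, gp, h_augmented) {
  tape <- ad_tape()
  pl <- .leafify(tape, model$params)
  out <- .propagation_forward(model$cfg, pl, tape, gp,
                              ad_const(tape, h_augmented))
  list(global_repr = out$global$val, self_attention = out$self_attention,
       final_coords = out$x$val)
}

.propagation_forward <- function(cfg, pl, tape, gp, h) {
  x <- ad_const(tape, gp$coords)
  for (p in pl$prop) {
    out <- egnn_layer(tape, h, x, gp$edges, p, update_coords = TRUE,
                      clamp = cfg$coordinate_update_clamp)
    h <- out$h; x <- out$x
  }
  attn <- list()
  if (cfg$use_self_attention) {
    for (p in pl$self_attn) {
      blk <- attention_block(tape, h, h, p, cfg$attention_heads)
      h <- blk$out
      attn[[length(attn) + 1L]] <- blk$attention
    }
  }
  list(global = ad_colmeans(tape, h), self_attention = attn, x = x, h = h)
}

#' Full two-stage forward pass
#'
#' Composes the interaction module, gated injection, propagation module
#' and the activity head. The 3-class decision is left to [decide()].
#'
#' @param model A `gpcr_model`.
#' @param gp Full `protein_graph` (with cBS/cAS masks).
#' @param g_bs cBS subgraph (from [cbs_subgraph()]; must carry
#'   `parent_index`).
#' @param g_l A `ligand_graph`.
#' @param tape Optional shared tape (training).
#' @param lig_feat_node Optional ligand-feature tape node.
#' @return A `prediction_output`: `logit_bind`, `p_bind`,
#'   `activity_logits` (length 2: agonist, antagonist),
#'   `activity_softmax`, `interaction` (Stage-1 output), `self_attention`,
#'   `final_coords`, `decision` (`NA`, filled by [decide()]), and `nodes`
#'   (tape handles for training).
#' @export
forward_pass <- function(model, gp, g_bs, g_l, tape = NULL,
                         lig_feat_node = NULL) {
  if (is.null(tape)) tape <- ad_tape()
  cfg <- model$cfg
  pl <- .leafify(tape, model$params)
  s1 <- .interaction_forward(cfg, pl, tape, g_bs, g_l, lig_feat_node)

  h_full <- .linear(tape, ad_const(tape, gp$features), pl$p_embed)
  parent <- g_bs$parent_index %||% which(gp$site_mask$in_cbs)
  h_aug <- .gate_inject_node(tape, h_full, s1$nodes$signal,
                             s1$nodes$p_bind, parent,
                             gated = cfg$transfer == "gated")
  s2 <- .propagation_forward(cfg, pl, tape, gp, h_aug)

  if (cfg$architecture == "unified") {
    logits3 <- .mlp2(tape, s2$global, pl$unified_head)
    act_logits <- ad_cols(tape, logits3, 2:3)
    bind_logit <- ad_cols(tape, logits3, 1L)  # binder-vs-not channel
    p_bind_node <- ad_sigmoid(tape, bind_logit)
  } else if (cfg$architecture == "shared") {
    act_logits <- .mlp2(tape, s2$global, pl$act_head)
    bind_logit <- .mlp2(tape, s2$global, pl$shared_bind_head)
    p_bind_node <- ad_sigmoid(tape, bind_logit)
  } else {
    act_logits <- .mlp2(tape, s2$global, pl$act_head)
    bind_logit <- s1$nodes$logit
    p_bind_node <- s1$nodes$p_bind
  }
  sm <- as.numeric(ad_softmax_rows(tape, act_logits)$val)

  structure(list(
    logit_bind = as.numeric(bind_logit$val),
    p_bind = as.numeric(p_bind_node$val),
    activity_logits = as.numeric(act_logits$val),
    activity_softmax = sm,
    interaction = s1[c("logit_bind", "p_bind", "interaction_signal",
                       "cross_attention")],
    self_attention = s2$self_attention,
    final_coords = s2$x$val,
    decision = NA_character_,
    nodes = list(tape = tape, params = pl, bind_logit = bind_logit,
                 p_bind = p_bind_node, act_logits = act_logits,
                 global = s2$global)),
    class = "prediction_output")
}

#' @export
print.prediction_output <- function(x, ...) {
  cat("prediction_output: p_bind = ", signif(x$p_bind, 4),
      ", softmax(agonist, antagonist) = (",
      paste(signif(x$activity_softmax, 4), collapse = ", "),
      "), decision = ", x$decision, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore model weights
#'
#' Writes parameters and configuration to a plain JSON checkpoint
#' (schema-versioned) and restores them.
#'
#' @param model A `gpcr_model`.
#' @param path Checkpoint path.
#' @return `path` / the restored `gpcr_model`.
#' @export
save_checkpoint <- function(model, path) {
  ser <- rapply(model$params, function(m) list(dim = dim(m),
                                               data = as.numeric(m)),
                classes = "matrix", how = "replace")
  jsonlite::write_json(list(schema = 1L, cfg = unclass(model$cfg),
                            p_feat = model$p_feat, l_feat = model$l_feat,
                            params = ser),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfg <- do.call(model_config, obj$cfg[setdiff(names(obj$cfg), NULL)])
  deser <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim")))
      matrix(x$data, x$dim[1L], x$dim[2L])
    else if (is.list(x)) lapply(x, deser)
    else x
  }
  structure(list(cfg = cfg, params = deser(obj$params),
                 p_feat = obj$p_feat, l_feat = obj$l_feat),
            class = "gpcr_model")
}
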