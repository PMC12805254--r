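# Classic modelling-idiom surface: one fitting function returning a
# classed object with print / summary / predict / plot methods, wrapping
# the graph construction, training loop and decision logic.

#' Fit the hierarchical activity model
#'
#' High-level fitting interface: takes training tuples (as produced by
#' [make_dataset()] or assembled from [build_protein_graph()] /
#' [build_ligand_graph()] outputs), trains with AdamW under the
#' hierarchical multitask loss, and returns a fitted model object.
#'
#' @param samples List of `list(gp, g_bs, g_l, label)` tuples.
#' @param val_samples Optional held-out tuples for checkpoint selection.
#' @param cfg A [model_config()].
#' @param decision_cfg A [decision_config()].
#' @param ... Passed to [train_loop()] (`epochs`, `batch_size`, `lr`,
#'   `weight_decay`, `lambda`, `w_fn`, `patience`, `seed`, `verbose`).
#' @return A `gpcrmoa_fit` object: `model`, `history`, `decision_cfg`,
#'   `call`.
#' @export
gpcrmoa_fit <- function(samples, val_samples = NULL, cfg = model_config(),
                        decision_cfg = decision_config(), ...) {
  tr <- train_loop(samples, cfg = cfg, val_samples = val_samples,
                   decision_cfg = decision_cfg, ...)
  structure(list(model = tr$model, final_model = tr$final_model,
                 history = tr$history, decision_cfg = decision_cfg,
                 cfg = cfg, call = match.call()),
            class = "gpcrmoa_fit")
}

#' @export
print.gpcrmoa_fit <- function(x, ...) {
  cat("Hierarchical GPCR activity model\n")
  print(x$model)
  h <- x$history
  if (!is.null(h) && nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("trained %d epoch(s); final loss %.4f; val BAcc %.3f\n",
                nrow(h), last$l_total,
                max(h$val_bacc, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.gpcrmoa_fit <- function(object, ...) {
  cat("Call: "); print(object$call)
  print(object)
  cat("\nDecision thresholds: tau_bind =", object$decision_cfg$tau_bind,
      ", rescue window [", paste(object$decision_cfg$rescue_window,
                                 collapse = ", "),
      "), tau_conf =", object$decision_cfg$tau_conf, "\n")
  if (!is.null(object$history)) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Predict decisions for new ligand tuples
#'
#' @param object A `gpcrmoa_fit`.
#' @param newdata List of `list(gp, g_bs, g_l, ...)` tuples.
#' @param ... Unused.
#' @return Data frame: `smiles` (when available), `p_bind`, `p_agonist`,
#'   `p_antagonist`, `decision`, `rescued`.
#' @export
predict.gpcrmoa_fit <- function(object, newdata, ...) {
  rows <- lapply(newdata, function(s) {
    o <- forward_pass(object$model, s$gp, s$g_bs, s$g_l)
    dec <- decide(o$p_bind, o$activity_softmax, object$decision_cfg)
    base_cfg <- object$decision_cfg
    base <- if (o$p_bind >= base_cfg$tau_bind) dec else "nonbinder"
    data.frame(smiles = s$smiles %||% NA_character_,
               p_bind = o$p_bind,
               p_agonist = o$activity_softmax[1L],
               p_antagonist = o$activity_softmax[2L],
               decision = dec, rescued = dec != base && dec != "nonbinder" &&
                 o$p_bind < base_cfg$tau_bind,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot training history
#' @param x A `gpcrmoa_fit`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gpcrmoa_fit <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history to plot")
  graphics::matplot(h$epoch, cbind(h$l_total, h$l_bind, h$l_act),
                    type = "l", lty = 1, xlab = "epoch", ylab = "loss",
                    ...)
  graphics::legend("topright", c("total", "binding", "activity"),
                   col = 1:3, lty = 1, bty = "n")
  invisible(x)
}
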