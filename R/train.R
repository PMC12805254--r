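# Hierarchical multitask training: composite loss (binding BCE on every
# sample, activity CE masked to ground-truth binders, with a w_FN = 1.5
# penalty on binding false negatives), AdamW optimization, and balanced
# accuracy metrics.

#' Construct an interaction label
#'
#' @param bind 0/1 binding label.
#' @param activity `"agonist"`, `"antagonist"`, or `"undefined"` (required
#'   iff nonbinder).
#' @param source_potency_um Optional potency in micromolar.
#' @return An `interaction_label` list.
#' @export
interaction_label <- function(bind, activity = "undefined",
                              source_potency_um = NULL) {
  bind <- as.integer(bind)
  stopifnot(bind %in% c(0L, 1L),
            activity %in% c("agonist", "antagonist", "undefined"))
  if ((bind == 1L) == (activity == "undefined"))
    stop("activity must be defined iff bind = 1")
  structure(list(bind = bind, activity = activity,
                 source_potency_um = source_potency_um),
            class = "interaction_label")
}

.bce_value <- function(logit, y) {
  # stable softplus(logit) - y * logit
  sp <- ifelse(logit > 30, logit, log1p(exp(pmin(logit, 30))))
  sp - y * logit
}

.ce_value <- function(logits2, activity) {
  m <- max(logits2)
  lse <- m + log(sum(exp(logits2 - m)))
  lse - logits2[if (activity == "agonist") 1L else 2L]
}

#' Composite hierarchical loss
#'
#' `l_bind` is the mean binary cross-entropy of the binding logit over
#' all samples. The activity term is computed only for ground-truth
#' binders (loss mask); each binder's cross-entropy is multiplied by
#' `w_fn` when the sample is a binding false negative at threshold 0.5
#' (`p_bind < 0.5` with `bind = 1`), and `l_act` is the mean over
#' binders (0 when the batch has none). `l_total = l_bind + lambda *
#' l_act`.
#'
#' @param outputs List of `prediction_output`.
#' @param labels List of [interaction_label()].
#' @param lambda Task-balance weight (default 1).
#' @param w_fn False-negative penalty weight (default 1.5).
#' @return A `loss_breakdown`: `l_bind`, `l_act`, `l_total`, `lambda`,
#'   `n_masked` (nonbinders), `n_fn_weighted`.
#' @export
composite_loss <- function(outputs, labels, lambda = 1.0, w_fn = 1.5) {
  stopifnot(length(outputs) == length(labels))
  if (!length(outputs)) stop("empty batch")
  bce <- mapply(function(o, l) .bce_value(o$logit_bind, l$bind),
                outputs, labels)
  binder <- vapply(labels, function(l) l$bind == 1L, logical(1L))
  act_terms <- numeric(0)
  n_fn <- 0L
  if (any(binder)) {
    act_terms <- mapply(function(o, l) {
      ce <- .ce_value(o$activity_logits, l$activity)
      if (o$p_bind < 0.5) { ce <- w_fn * ce }
      ce
    }, outputs[binder], labels[binder])
    n_fn <- sum(vapply(outputs[binder], function(o) o$p_bind < 0.5,
                       logical(1L)))
  }
  l_bind <- mean(bce)
  l_act <- if (length(act_terms)) mean(act_terms) else 0
  structure(list(l_bind = l_bind, l_act = l_act,
                 l_total = l_bind + lambda * l_act, lambda = lambda,
                 n_masked = sum(!binder), n_fn_weighted = as.integer(n_fn)),
            class = "loss_breakdown")
}

# ---- parameter flattening and AdamW ------------------------------------

.flatten_params <- function(p)
  unlist(rapply(p, as.numeric, classes = "matrix", how = "unlist"),
         use.names = FALSE)

.unflatten_params <- function(template, vec) {
  pos <- 0L
  fill <- function(x) {
    if (is.matrix(x)) {
      k <- length(x)
      m <- matrix(vec[(pos + 1L):(pos + k)], nrow(x), ncol(x))
      pos <<- pos + k
      m
    } else lapply(x, fill)
  }
  fill(template)
}

#' AdamW optimizer state and step
#'
#' Decoupled weight decay: `theta <- theta - lr * (m_hat / (sqrt(v_hat)
#' + eps) + weight_decay * theta)`.
#'
#' @param n Parameter-vector length.
#' @return Optimizer state list.
#' @export
adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

#' @rdname adamw_init
#' @param theta,grad Parameter and gradient vectors.
#' @param state State from [adamw_init()].
#' @param lr,weight_decay,beta1,beta2,eps AdamW hyperparameters.
#' @return List `theta`, `state`.
#' @export
adamw_step <- function(theta, grad, state, lr = 1e-4, weight_decay = 1e-5,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}

# Forward + loss-node construction for one sample on a fresh tape.
# Returns the loss node, tape, leafified params and the raw outputs.
.sample_loss_nodes <- function(model, sample, scale_bind, scale_act,
                               w_fn) {
  tape <- ad_tape()
  out <- forward_pass(model, sample$gp, sample$g_bs, sample$g_l,
                      tape = tape)
  nd <- out$nodes
  lab <- sample$label
  y <- lab$bind
  sp <- ad_softplus(tape, nd$bind_logit)
  bce <- ad_sub(tape, sp, ad_scale(tape, nd$bind_logit, y))
  loss <- ad_scale(tape, bce, scale_bind)
  if (y == 1L) {
    w <- if (out$p_bind < 0.5) w_fn else 1
    sm <- ad_softmax_rows(tape, nd$act_logits)
    onehot <- matrix(c(0, 0), 1L)
    onehot[1L, if (lab$activity == "agonist") 1L else 2L] <- 1
    p_true <- ad_matmul(tape, sm, ad_const(tape, t(onehot)))
    ce <- ad_scale(tape, ad_log(tape, p_true), -1)
    loss <- ad_add(tape, loss, ad_scale(tape, ce, scale_act * w))
  }
  list(loss = loss, tape = tape, params = nd$params, output = out)
}

#' Train the two-stage model
#'
#' Minimizes the composite loss with AdamW (defaults: learning rate 1e-4,
#' weight decay 1e-5). The false-negative weighting is dynamic (recomputed
#' from the current forward pass each step). The best checkpoint is
#' selected by validation 3-class balanced accuracy; optional early
#' stopping on the same criterion. All randomness derives from `seed`.
#'
#' @param samples List of `list(gp, g_bs, g_l, label)` training tuples.
#' @param model A `gpcr_model` (or `NULL` to initialize from `cfg`).
#' @param cfg [model_config()] used when `model` is `NULL`.
#' @param val_samples Held-out tuples for checkpoint selection (optional).
#' @param epochs,batch_size,lr,weight_decay,lambda,w_fn Training
#'   hyperparameters.
#' @param patience Early-stopping patience in epochs (Inf to disable).
#' @param stop_at_val_bacc Optional convergence bar: training stops once
#'   the validation balanced accuracy reaches this value.
#' @param seed RNG seed for shuffling.
#' @param decision_cfg [decision_config()] used for validation decisions.
#' @param verbose Print per-epoch summaries to stderr.
#' @return List: `model` (best checkpoint), `final_model`, `history`
#'   (data frame).
#' @export
train_loop <- function(samples, model = NULL, cfg = model_config(),
                       val_samples = NULL, epochs = 10L, batch_size = 32L,
                       lr = 1e-4, weight_decay = 1e-5, lambda = 1.0,
                       w_fn = 1.5, patience = 10L, seed = 1L,
                       stop_at_val_bacc = NULL,
                       decision_cfg = decision_config(),
                       verbose = FALSE) {
  if (!length(samples)) stop("empty dataset")
  if (is.null(model)) model <- init_model(cfg)
  set.seed(seed)
  theta <- .flatten_params(model$params)
  opt <- adamw_init(length(theta))
  hist <- list()
  best <- list(bacc = -Inf, theta = theta)
  stall <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample(length(samples))
    ep_out <- vector("list", length(samples))
    ep_lab <- vector("list", length(samples))
    for (start in seq(1L, length(ord), by = batch_size)) {
      bidx <- ord[start:min(start + batch_size - 1L, length(ord))]
      n_b <- length(bidx)
      n_binders <- sum(vapply(samples[bidx],
                              function(s) s$label$bind == 1L, logical(1L)))
      gacc <- numeric(length(theta))
      for (i in bidx) {
        sl <- .sample_loss_nodes(model, samples[[i]], 1 / n_b,
                                 if (n_binders) lambda / n_binders else 0,
                                 w_fn)
        ad_backward(sl$tape, sl$loss)
        gacc <- gacc + .flatten_params(.collect_grads(sl$params))
        ep_out[[i]] <- .slim_output(sl$output)
        ep_lab[[i]] <- samples[[i]]$label
      }
      st <- adamw_step(theta, gacc, opt, lr = lr,
                       weight_decay = weight_decay)
      theta <- st$theta; opt <- st$state
      model$params <- .unflatten_params(model$params, theta)
    }
    lb <- composite_loss(ep_out, ep_lab, lambda = lambda, w_fn = w_fn)
    tr_dec <- vapply(ep_out, function(o)
      decide(o$p_bind, o$activity_softmax, decision_cfg), character(1L))
    tr_true <- vapply(ep_lab, .label_class, character(1L))
    tr_bacc <- suppressWarnings(balanced_accuracy(tr_true, tr_dec))
    val_bacc <- NA_real_
    if (!is.null(val_samples) && length(val_samples)) {
      vp <- lapply(val_samples, function(s)
        .slim_output(forward_pass(model, s$gp, s$g_bs, s$g_l)))
      vd <- vapply(vp, function(o)
        decide(o$p_bind, o$activity_softmax, decision_cfg), character(1L))
      vt <- vapply(val_samples, function(s) .label_class(s$label),
                   character(1L))
      val_bacc <- suppressWarnings(balanced_accuracy(vt, vd))
      if (val_bacc >= best$bacc) {  # ties favour the longer-trained model
        stall <- if (val_bacc > best$bacc) 0L else stall + 1L
        best <- list(bacc = val_bacc, theta = theta)
      } else stall <- stall + 1L
    }
    hist[[ep]] <- data.frame(epoch = ep, l_bind = lb$l_bind,
                             l_act = lb$l_act, l_total = lb$l_total,
                             train_bacc = tr_bacc, val_bacc = val_bacc)
    if (verbose)
      message(sprintf("epoch %d: l_total %.4f (bind %.4f act %.4f) train BAcc %.3f val BAcc %.3f",
                      ep, lb$l_total, lb$l_bind, lb$l_act, tr_bacc,
                      val_bacc))
    if (stall >= patience) break
    if (!is.null(stop_at_val_bacc) && is.finite(val_bacc) &&
        val_bacc >= stop_at_val_bacc) break
  }
  final_model <- model
  best_model <- model
  if (is.finite(best$bacc))
    best_model$params <- .unflatten_params(model$params, best$theta)
  list(model = best_model, final_model = final_model,
       history = do.call(rbind, hist))
}

.slim_output <- function(o)
  list(logit_bind = o$logit_bind, p_bind = o$p_bind,
       activity_logits = o$activity_logits,
       activity_softmax = o$activity_softmax)

.label_class <- function(label)
  if (label$bind == 0L) "nonbinder" else label$activity

#' Balanced accuracy (mean per-class recall)
#'
#' Classes absent from `y_true` are excluded with a warning. For binary
#' binder/nonbinder tasks, use [binary_metrics()].
#'
#' @param y_true,y_pred Character vectors of class labels.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  classes <- unique(y_true)
  recalls <- vapply(classes, function(cl)
    mean(y_pred[y_true == cl] == cl), numeric(1L))
  all_classes <- union(unique(y_true), unique(y_pred))
  if (length(setdiff(all_classes, classes)))
    warning("class(es) absent from y_true excluded: ",
            paste(setdiff(all_classes, classes), collapse = ", "))
  mean(recalls)
}

#' Binary binding metrics (binder = positive class)
#'
#' @param y_true,y_pred Logical or 0/1 vectors (TRUE/1 = binder).
#' @return List: `precision`, `recall`, `f1`, `specificity`,
#'   `balanced_accuracy`.
#' @export
binary_metrics <- function(y_true, y_pred) {
  y_true <- as.logical(y_true); y_pred <- as.logical(y_pred)
  tp <- sum(y_true & y_pred); fp <- sum(!y_true & y_pred)
  fn <- sum(y_true & !y_pred); tn <- sum(!y_true & !y_pred)
  prec <- if (tp + fp) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp) tn / (tn + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(precision = prec, recall = rec, f1 = f1, specificity = spec,
       balanced_accuracy = mean(c(rec, spec)))
}
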