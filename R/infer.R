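# Hierarchical three-class decision logic with confidence-based rescue,
# threshold calibration by grid search, and reliability (calibration)
# curves.

#' Decision thresholds
#'
#' @param tau_bind Primary binding threshold (default 0.5).
#' @param rescue_window `c(low, high)` uncertainty range (default
#'   `c(0.4, 0.5)`); closed on the left, open on the right.
#' @param tau_conf Activity-confidence threshold for rescue (default
#'   0.95, strict `>`).
#' @return A `decision_config` list.
#' @export
decision_config <- function(tau_bind = 0.5, rescue_window = c(0.4, 0.5),
                            tau_conf = 0.95) {
  stopifnot(rescue_window[1L] <= rescue_window[2L],
            rescue_window[2L] <= tau_bind, tau_bind <= 1,
            rescue_window[1L] > 0, tau_conf > 0.5, tau_conf < 1)
  structure(list(tau_bind = tau_bind, rescue_window = rescue_window,
                 tau_conf = tau_conf), class = "decision_config")
}

#' Three-class decision with confidence-based rescue
#'
#' If `p_bind >= tau_bind`, the argmax of the activity softmax decides
#' (exact ties go to antagonist). Otherwise the compound is a nonbinder
#' unless rescued: `low <= p_bind < tau_bind` and
#' `max(activity_softmax) > tau_conf` override the nonbinder call with
#' the argmax class.
#'
#' @param p_bind Binding probability.
#' @param activity_softmax Length-2 vector (agonist, antagonist) summing
#'   to 1.
#' @param cfg A [decision_config()].
#' @return `"nonbinder"`, `"agonist"`, or `"antagonist"`.
#' @export
decide <- function(p_bind, activity_softmax, cfg = decision_config()) {
  if (abs(sum(activity_softmax) - 1) > 1e-6)
    stop("activity softmax must sum to 1")
  act <- if (activity_softmax[1L] > activity_softmax[2L]) "agonist"
         else "antagonist"
  if (p_bind >= cfg$tau_bind) return(act)
  if (p_bind >= cfg$rescue_window[1L] && p_bind < cfg$tau_bind &&
      max(activity_softmax) > cfg$tau_conf)
    return(act)
  "nonbinder"
}

#' Calibrate rescue thresholds by grid search
#'
#' Exhaustively evaluates (window lower bound, confidence threshold)
#' pairs on a validation set, selecting the configuration maximizing
#' 3-class balanced accuracy. Ties prefer the wider window, then the
#' higher confidence threshold.
#'
#' @param validation Data frame or list with `p_bind` (numeric),
#'   `activity_softmax` (n x 2 matrix or list), `label` (true classes).
#' @param window_grid Candidate window lower bounds.
#' @param conf_grid Candidate confidence thresholds.
#' @param tau_bind Fixed primary threshold.
#' @return List: `config` (best [decision_config()]), `score`
#'   (its balanced accuracy), `baseline_score` (no-rescue), `table`
#'   (full grid scores).
#' @export
calibrate_thresholds <- function(validation,
                                 window_grid = seq(0.3, 0.5, by = 0.05),
                                 conf_grid = seq(0.8, 0.99, by = 0.01),
                                 tau_bind = 0.5) {
  if (!length(window_grid) || !length(conf_grid)) stop("empty grid")
  p_bind <- validation$p_bind
  sm <- validation$activity_softmax
  if (is.list(sm) && !is.matrix(sm)) sm <- do.call(rbind, sm)
  labels <- validation$label
  if (length(unique(labels)) < 2L)
    stop("validation must contain multiple true classes")
  score_cfg <- function(cfg) {
    dec <- vapply(seq_along(p_bind), function(i)
      decide(p_bind[i], sm[i, ], cfg), character(1L))
    suppressWarnings(balanced_accuracy(labels, dec))
  }
  baseline <- score_cfg(decision_config(tau_bind = tau_bind,
                                        rescue_window = c(tau_bind,
                                                          tau_bind),
                                        tau_conf = 0.9999999))
  rows <- expand.grid(low = window_grid, tau_conf = conf_grid)
  rows <- rows[rows$low <= tau_bind, , drop = FALSE]
  rows$score <- vapply(seq_len(nrow(rows)), function(r)
    score_cfg(decision_config(tau_bind = tau_bind,
                              rescue_window = c(rows$low[r], tau_bind),
                              tau_conf = rows$tau_conf[r])),
    numeric(1L))
  # wider window = smaller low; ties then prefer higher tau_conf
  o <- order(-rows$score, rows$low, -rows$tau_conf)
  bestrow <- rows[o[1L], ]
  best_cfg <- decision_config(tau_bind = tau_bind,
                              rescue_window = c(bestrow$low, tau_bind),
                              tau_conf = bestrow$tau_conf)
  list(config = best_cfg, score = bestrow$score,
       baseline_score = baseline, table = rows)
}

#' Reliability curve and expected calibration error
#'
#' Bins predictions by confidence (equal-width bins on the max softmax
#' probability) and reports per-bin mean confidence, accuracy and count;
#' `ECE = sum_b (n_b / n) * |acc_b - conf_b|`.
#'
#' @param probs Numeric vector of confidences in `[0, 1]` (max softmax),
#'   or an n x k softmax matrix (the row max is used).
#' @param labels Logical/0-1 vector: was the prediction correct? (Or, with
#'   a matrix `probs`, the true class index per row.)
#' @param n_bins Number of bins (default 10).
#' @return List: `bins` (data frame `confidence`, `accuracy`, `count`),
#'   `ece`.
#' @export
reliability_curve <- function(probs, labels, n_bins = 10L) {
  if (is.matrix(probs)) {
    conf <- apply(probs, 1L, max)
    correct <- max.col(probs) == labels
  } else {
    conf <- probs
    correct <- as.logical(labels)
  }
  if (!length(conf)) stop("empty input")
  stopifnot(all(conf >= 0 & conf <= 1))
  bin <- pmin(pmax(ceiling(conf * n_bins), 1L), n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    i <- bin == b
    data.frame(bin = b, confidence = if (any(i)) mean(conf[i]) else NA,
               accuracy = if (any(i)) mean(correct[i]) else NA,
               count = sum(i))
  })
  bins <- do.call(rbind, rows)
  used <- bins$count > 0
  ece <- sum(bins$count[used] / length(conf) *
               abs(bins$accuracy[used] - bins$confidence[used]))
  list(bins = bins, ece = ece)
}
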