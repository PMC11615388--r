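# Per-horizon evaluation: AUROC (midrank statistic), AUPRC (average
# precision), confusion metrics at a threshold, macro averages, plus the
# O(n^2) brute-force oracles used to validate them.

#' Area under the ROC curve (rank statistic with tie midranks)
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: only one class present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral over descending unique score thresholds:
#' `sum (R_i - R_{i-1}) * P_i`. No interpolation.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L || n1 == length(labels))
    stop("AUPRC undefined: only one class present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate only at the last index of each tied score block
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))
  P <- tp[last] / (tp[last] + fp[last])
  R <- tp[last] / n1
  sum(diff(c(0, R)) * P)
}

# O(n^2) pair-counting oracle for AUROC (tests only, exported for reuse in
# scripts): P(score_pos > score_neg) + 0.5 P(tie)
#' Brute-force metric oracles
#'
#' Independent recomputations used to validate [auroc()] and [auprc()]:
#' `auroc_oracle` counts all positive/negative score pairs directly
#' (O(n^2)); `auprc_oracle` sweeps every unique threshold and accumulates
#' the precision-recall step integral with explicit loops.
#'
#' @inheritParams auroc
#' @return The metric value.
#' @export
auroc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

#' @rdname auroc_oracle
#' @export
auprc_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  ap <- 0; r_prev <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / n1
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# per-horizon AUROC/AUPRC + macros; horizons with one class are excluded
horizon_metrics <- function(probs, labels) {
  nh <- ncol(labels)
  au <- ap <- rep(NA_real_, nh)
  for (h in seq_len(nh)) {
    y <- labels[, h]
    if (length(unique(y)) < 2L) next
    au[h] <- auroc(probs[, h], y)
    ap[h] <- auprc(probs[, h], y)
  }
  list(auroc = au, auprc = ap,
       macro_auroc = mean(au, na.rm = TRUE),
       macro_auprc = mean(ap, na.rm = TRUE))
}

#' Evaluate a model on labeled prediction windows
#'
#' Computes, for every horizon, the confusion metrics (sensitivity,
#' specificity, precision, F1) at the configured probability threshold plus
#' AUROC and AUPRC, and the unweighted macro averages over horizons. A
#' horizon whose labels contain a single class is flagged undefined and
#' excluded from the macros with a warning.
#'
#' @param model A fitted `"edfuse"`, an `"ed_lr_suite"`, or any function
#'   mapping a window list to an `n x 12` probability matrix.
#' @param windows A `window_set` or list of labeled prediction windows.
#' @param threshold Probability cutoff for the confusion metrics.
#' @param probs Optional precomputed probability matrix (skips prediction).
#' @return Object of class `"metrics_report"`: `per_horizon` data.frame,
#'   `macro_auroc`, `macro_auprc`, `selection_sum`, `n_pos`, `n_neg`.
#' @export
evaluate_windows <- function(model, windows, threshold = 0.5, probs = NULL) {
  wl <- if (inherits(windows, "window_set")) windows$windows else windows
  labels <- do.call(rbind, lapply(wl, `[[`, "labels"))
  if (is.null(probs)) {
    probs <- if (is.function(model)) model(wl) else predict(model, wl)
  }
  stopifnot(nrow(probs) == nrow(labels), ncol(probs) == ncol(labels))
  nh <- ncol(labels)
  per <- data.frame(horizon = seq_len(nh), n_pos = colSums(labels),
                    n_neg = colSums(1 - labels),
                    sensitivity = NA_real_, specificity = NA_real_,
                    precision = NA_real_, f1 = NA_real_,
                    auroc = NA_real_, auprc = NA_real_)
  for (h in seq_len(nh)) {
    y <- labels[, h]; p <- probs[, h]
    if (length(unique(y)) < 2L) {
      warning("horizon ", h, " has a single class; excluded from macros",
              call. = FALSE)
      next
    }
    yhat <- as.integer(p >= threshold)
    tp <- sum(yhat == 1 & y == 1); fn <- sum(yhat == 0 & y == 1)
    fp <- sum(yhat == 1 & y == 0); tn <- sum(yhat == 0 & y == 0)
    per$sensitivity[h] <- tp / (tp + fn)
    per$specificity[h] <- tn / (tn + fp)
    per$precision[h] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    per$f1[h] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    per$auroc[h] <- auroc(p, y)
    per$auprc[h] <- auprc(p, y)
  }
  macro_auroc <- mean(per$auroc, na.rm = TRUE)
  macro_auprc <- mean(per$auprc, na.rm = TRUE)
  structure(list(per_horizon = per, macro_auroc = macro_auroc,
                 macro_auprc = macro_auprc,
                 selection_sum = macro_auroc + macro_auprc,
                 threshold = threshold,
                 n_pos = per$n_pos, n_neg = per$n_neg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-horizon evaluation (threshold ", x$threshold, "):\n", sep = "")
  print(x$per_horizon, row.names = FALSE, digits = 3)
  cat(sprintf("macro-AUROC %.4f  macro-AUPRC %.4f  (sum %.4f)\n",
              x$macro_auroc, x$macro_auprc, x$selection_sum))
  invisible(x)
}

#' @export
plot.metrics_report <- function(x, ...) {
  ph <- x$per_horizon
  graphics::barplot(rbind(ph$auroc, ph$auprc), beside = TRUE,
                    names.arg = ph$horizon, xlab = "horizon (h)",
                    ylab = "score", ylim = c(0, 1),
                    legend.text = c("AUROC", "AUPRC"),
                    args.legend = list(x = "bottomright", bty = "n"), ...)
  invisible(x)
}
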