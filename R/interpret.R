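# Post hoc interpretation: feature-ablation importance (token deletion),
# input-sequence-length analysis, and the dense-vitals time-resolution
# experiment.

#' Feature-ablation importance
#'
#' For each feature (or whole modality), tokens of that feature are deleted
#' from every test window — under the set-embedding structure ablation is
#' token deletion, never zero-filling, since zero is a legitimate observed
#' value — and the model is re-evaluated on the subset of windows from cases
#' in which the feature was observed at least once. Importance is the drop
#' `full - ablated` in macro-AUROC and macro-AUPRC on that subset.
#'
#' @param model A fitted `"edfuse"` model.
#' @param windows Test `window_set` or window list.
#' @param features Character vector of sparse feature ids to ablate.
#' @param modalities Optional modalities (e.g. `"text"`, `"image"`) ablated
#'   wholesale.
#' @return `data.frame` (class `"importance_table"`) with columns `feature`,
#'   `delta_auroc`, `delta_auprc`, `n_eval`, `rank` (by `delta_auroc`);
#'   features never observed are skipped with a warning.
#' @export
ablation_importance <- function(model, windows, features = NULL,
                                modalities = NULL) {
  wl <- if (inherits(windows, "window_set")) windows$windows else windows
  ids <- vapply(wl, `[[`, character(1), "admission_id")
  feat_of <- function(w, fset = NULL, mset = NULL)
    any(vapply(w$events, function(e)
      (!is.null(fset) && e$feature_id %in% fset) ||
      (!is.null(mset) && e$modality %in% mset), logical(1)))
  rows <- list()
  eval_one <- function(label, fset, mset) {
    has <- vapply(wl, feat_of, logical(1), fset = fset, mset = mset)
    case_has <- unique(ids[has])
    sel <- ids %in% case_has
    if (!any(sel)) {
      warning("feature ", label, " never observed; skipped", call. = FALSE)
      return(NULL)
    }
    sub <- wl[sel]
    labs <- do.call(rbind, lapply(sub, `[[`, "labels"))
    if (length(unique(as.vector(labs))) < 2L) {
      warning("ablation subset for ", label, " single-class; skipped",
              call. = FALSE)
      return(NULL)
    }
    full <- horizon_metrics(predict(model, sub), labs)
    abl <- horizon_metrics(predict(model, sub, drop_feature = fset,
                                   drop_modality = mset), labs)
    data.frame(feature = label,
               delta_auroc = full$macro_auroc - abl$macro_auroc,
               delta_auprc = full$macro_auprc - abl$macro_auprc,
               n_eval = length(case_has), stringsAsFactors = FALSE)
  }
  for (f in features) rows[[length(rows) + 1L]] <- eval_one(f, f, NULL)
  for (m in modalities)
    rows[[length(rows) + 1L]] <- eval_one(paste0("modality:", m), NULL, m)
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$rank <- rank(-out$delta_auroc, ties.method = "first")
  class(out) <- c("importance_table", "data.frame")
  out[order(out$rank), ]
}

window_token_count <- function(w, model) {
  tk <- window_tokens(w, model$vocab, model$norm_stats, model$cfg)
  n <- length(tk$sparse$feature) + length(tk$text) +
    (!is.null(tk$image$feat))
  for (d in tk$dense) n <- n + max(0L, conv_out_len(nrow(d$x), 3L, 2L) - 2L)
  n
}

#' Predictive power by input-sequence length
#'
#' Windows are stratified into `n_bins` quantile bins of their token count N
#' and the model is scored per bin — the longer the accumulated event
#' sequence, the more information the model has.
#'
#' @param model A fitted `"edfuse"`.
#' @param windows Test windows.
#' @param n_bins Number of length strata.
#' @return `data.frame`: `bin`, `n_min`, `n_max`, `n_windows`,
#'   `macro_auroc`, `macro_auprc` (NA for single-class bins, flagged with a
#'   warning).
#' @export
sequence_length_curve <- function(model, windows, n_bins = 4L) {
  wl <- if (inherits(windows, "window_set")) windows$windows else windows
  len <- vapply(wl, window_token_count, numeric(1), model = model)
  qs <- unique(stats::quantile(len, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(len, breaks = qs, include.lowest = TRUE, labels = FALSE)
  probs <- predict(model, wl)
  labs <- do.call(rbind, lapply(wl, `[[`, "labels"))
  out <- data.frame()
  for (b in sort(unique(bins))) {
    sel <- bins == b
    m <- if (length(unique(as.vector(labs[sel, , drop = FALSE]))) < 2L) {
      warning("length bin ", b, " is single-class; metrics undefined",
              call. = FALSE)
      list(macro_auroc = NA_real_, macro_auprc = NA_real_)
    } else horizon_metrics(probs[sel, , drop = FALSE],
                           labs[sel, , drop = FALSE])
    out <- rbind(out, data.frame(bin = b, n_min = min(len[sel]),
                                 n_max = max(len[sel]), n_windows = sum(sel),
                                 macro_auroc = m$macro_auroc,
                                 macro_auprc = m$macro_auprc))
  }
  out
}

#' Dense-vitals time-resolution experiment
#'
#' Trains and evaluates the circulatory-shock model once per discretization
#' interval, downsampling every dense monitor block (1-minute base grid) to
#' that interval before windowing/embedding, and tabulates macro-AUROC /
#' macro-AUPRC against the interval.
#'
#' @param records Cohort containing dense monitor blocks on a 1-minute grid.
#' @param intervals_min Discretization intervals in minutes (each `>= 1`).
#' @param cfg Base [run_config()]; `dense_resample_min` is overridden per
#'   interval.
#' @param verbose Print progress?
#' @return `data.frame`: `interval_min`, `macro_auroc`, `macro_auprc`.
#' @export
time_resolution_experiment <- function(records, intervals_min, cfg,
                                       verbose = FALSE) {
  if (any(intervals_min < 1))
    stop("interval below the 1-minute base grid", call. = FALSE)
  out <- data.frame()
  for (iv in intervals_min) {
    cfg_i <- cfg
    cfg_i$dense_resample_min <- iv
    sp <- split_cohort(records, cfg$split_ratio, cfg$seed,
                       stratify_outcome = cfg_i$outcome_task)
    fit <- fit_fusion(sp$train, cfg_i, verbose = verbose)
    test_w <- cohort_windows(sp$test, cfg_i$outcome_task, cfg_i)
    rep <- evaluate_windows(fit, test_w, threshold = cfg_i$threshold)
    out <- rbind(out, data.frame(interval_min = iv,
                                 macro_auroc = rep$macro_auroc,
                                 macro_auprc = rep$macro_auprc))
    if (verbose)
      message(sprintf("interval %d min: AUROC %.3f AUPRC %.3f", iv,
                      rep$macro_auroc, rep$macro_auprc))
  }
  out
}

#' Downsample a dense block to a coarser grid
#'
#' Keeps every `interval`-th row of a 1-minute-grid matrix (rows at minutes
#' 0, interval, 2*interval, ...): the resulting length is
#' `ceiling(t_dense / interval)`.
#'
#' @param block `t_dense x 5` matrix on the 1-minute grid.
#' @param interval Minutes between retained rows (`>= 1`).
#' @return The downsampled matrix.
#' @export
downsample_dense <- function(block, interval) {
  if (interval < 1) stop("interval below base grid", call. = FALSE)
  block[(seq_len(nrow(block)) - 1) %% interval == 0, , drop = FALSE]
}
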