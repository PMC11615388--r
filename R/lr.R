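# Logistic-regression comparison suite: 12 per-horizon binary models with
# carry-forward + train-mean imputation and follow-up-minus-initial vital
# deltas (step 2). Free text is excluded; DBP is dropped in step 1 because of
# its correlation with SBP.

LR_VITALS <- c("SBP", "DBP", "HR", "RR", "BT", "SpO2")
LR_TRIAGE <- c("age", "sex_male", "KTAS", "mental_status", "visit_method")
LR_LABS <- c("lactate", "wbc", "hb", "platelet", "creatinine", "crp",
             "procalcitonin")

lr_feature_names <- function(step) {
  if (step == "step1_triage")
    c(LR_TRIAGE, setdiff(LR_VITALS, "DBP"))
  else
    c(LR_TRIAGE, LR_VITALS, LR_LABS,
      paste0("delta_", setdiff(LR_VITALS, "BT")))
}

#' Build the fixed-width logistic-regression feature row of one window
#'
#' Carry-forward within the window (the latest observation of each feature at
#' or before the reference time), then train-mean fill for features never
#' observed. Step 1 uses triage variables and initial vitals without DBP;
#' step 2 adds latest follow-up vitals, mental status and labs, plus
#' follow-up-minus-initial vital deltas. Text and image events are excluded.
#'
#' @param window A prediction window.
#' @param step `"step1_triage"` or `"step2_posttriage"`.
#' @param train_stats Named per-feature training means (see
#'   [lr_train_means()]); features never observed in a window are filled
#'   from it (0 when absent there too).
#' @return Named numeric vector with no missing entries; fixed feature order.
#' @export
build_lr_features <- function(window, step = c("step2_posttriage",
                                                "step1_triage"),
                              train_stats = list()) {
  step <- match.arg(step)
  feats <- lr_feature_names(step)
  sp <- Filter(function(e) e$modality == "sparse_tabular", window$events)
  fid <- vapply(sp, function(e) e$feature_id, character(1))
  val <- if (length(sp)) vapply(sp, function(e) e$value, numeric(1)) else numeric(0)
  tt <- if (length(sp)) vapply(sp, function(e) e$time_min, numeric(1)) else numeric(0)
  latest <- function(f) {
    i <- which(fid == f)
    if (!length(i)) return(NA_real_)
    val[i[which.max(tt[i])]]
  }
  initial <- function(f) {
    i <- which(fid == f & tt == 0)
    if (!length(i)) return(NA_real_)
    val[i[1]]
  }
  out <- stats::setNames(numeric(length(feats)), feats)
  for (f in feats) {
    v <- if (startsWith(f, "delta_")) {
      base <- sub("delta_", "", f)
      lv <- latest(base); iv <- initial(base)
      if (is.na(lv) || is.na(iv)) 0 else lv - iv
    } else latest(f)
    if (is.na(v)) {
      m <- train_stats[[f]]
      v <- if (is.null(m)) 0 else m
    }
    out[f] <- v
  }
  out
}

#' Per-feature training means for LR mean-fill
#'
#' @param windows Training `window_set` or window list.
#' @param step Model step (fixes the feature list).
#' @return Named list of means of the observed (carried-forward) values.
#' @export
lr_train_means <- function(windows, step = "step2_posttriage") {
  wl <- if (inherits(windows, "window_set")) windows$windows else windows
  feats <- lr_feature_names(step)
  acc <- stats::setNames(vector("list", length(feats)), feats)
  for (w in wl) {
    row <- build_lr_features(w, step, train_stats = list())
    sp <- Filter(function(e) e$modality == "sparse_tabular", w$events)
    seen <- unique(vapply(sp, function(e) e$feature_id, character(1)))
    for (f in feats) {
      obs <- if (startsWith(f, "delta_")) sub("delta_", "", f) %in% seen
             else f %in% seen
      if (obs) acc[[f]] <- c(acc[[f]], row[[f]])
    }
  }
  lapply(acc, function(v) if (length(v)) mean(v) else 0)
}

#' Fit the 12-model logistic-regression suite
#'
#' One binomial GLM per horizon (label = that horizon's element of the window
#' label vector), fitted by IRLS with the iteration cap raised to 1000. A
#' horizon whose training labels hold a single class is marked degenerate and
#' excluded from macro averages downstream.
#'
#' @param windows Training `window_set` or window list.
#' @param step `"step1_triage"` or `"step2_posttriage"`.
#' @param cfg A [run_config()] (supplies the horizon count).
#' @return Object of class `"ed_lr_suite"`: fitted models, feature order,
#'   training means, step.
#' @export
fit_lr_suite <- function(windows, step = c("step2_posttriage", "step1_triage"),
                         cfg = run_config()) {
  step <- match.arg(step)
  wl <- if (inherits(windows, "window_set")) windows$windows else windows
  means <- lr_train_means(wl, step)
  X <- do.call(rbind, lapply(wl, build_lr_features, step = step,
                             train_stats = means))
  labels <- do.call(rbind, lapply(wl, `[[`, "labels"))
  nh <- ncol(labels)
  models <- vector("list", nh)
  degenerate <- logical(nh)
  df <- as.data.frame(X)
  for (h in seq_len(nh)) {
    y <- labels[, h]
    if (length(unique(y)) < 2L) {
      degenerate[h] <- TRUE
      warning("horizon ", h, ": single-class training labels; model marked ",
              "degenerate", call. = FALSE)
      next
    }
    dat <- cbind(df, .y = y)
    models[[h]] <- suppressWarnings(
      stats::glm(.y ~ ., family = stats::binomial(), data = dat,
                 control = stats::glm.control(maxit = 1000)))
  }
  structure(list(models = models, degenerate = degenerate,
                 feature_names = colnames(X), train_means = means,
                 step = step),
            class = "ed_lr_suite")
}

#' @export
print.ed_lr_suite <- function(x, ...) {
  cat("Logistic-regression baseline suite (", x$step, "): ",
      sum(!x$degenerate), "/", length(x$models), " horizon models fitted\n",
      sep = "")
  invisible(x)
}

#' Predict with the LR suite
#'
#' Per-horizon probabilities for each window (or prebuilt feature matrix).
#' Unlike the fusion model, monotonicity of the probabilities across horizons
#' is not guaranteed. Degenerate horizons yield `NA`.
#'
#' @param object An `"ed_lr_suite"`.
#' @param newdata Window list / `window_set`, or numeric feature matrix with
#'   the suite's feature order.
#' @param ... Unused.
#' @return `n x 12` probability matrix.
#' @export
predict.ed_lr_suite <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) {
    if (!identical(colnames(newdata), object$feature_names))
      stop("feature order mismatch with training", call. = FALSE)
    newdata
  } else {
    wl <- if (inherits(newdata, "window_set")) newdata$windows else newdata
    do.call(rbind, lapply(wl, build_lr_features, step = object$step,
                          train_stats = object$train_means))
  }
  df <- as.data.frame(X)
  out <- matrix(NA_real_, nrow(X), length(object$models))
  for (h in seq_along(object$models)) {
    if (object$degenerate[h]) next
    out[, h] <- stats::predict(object$models[[h]], newdata = df,
                               type = "response")
  }
  out
}

#' Coefficient table of the LR suite
#'
#' @param object An `"ed_lr_suite"`.
#' @param ... Unused.
#' @return Matrix: one column per horizon model, rows = intercept + features.
#' @export
coef.ed_lr_suite <- function(object, ...) {
  sapply(seq_along(object$models), function(h) {
    if (object$degenerate[h])
      return(rep(NA_real_, length(object$feature_names) + 1L))
    stats::coef(object$models[[h]])
  })
}
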