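# Multimodal transformer fusion model: batched forward/backward over token
# sets, Adam training with the configured imbalance sampler, per-epoch
# validation, and checkpoint selection on macro-AUPRC.

# ---- batched forward/backward ---------------------------------------------

# Assemble the flat token arrays of a batch of precomputed descriptors.
# Token order: all sparse tokens, then dense conv steps, then image, then
# text. Order is irrelevant downstream (no positional encoding, masked mean
# pooling); attention and pooling group rows by win_id.
batch_forward <- function(desc, params, cfg, training, bn_state,
                          want_cache = FALSE) {
  B <- length(desc)
  acc <- function() list()
  sp_val_l <- acc(); sp_win_l <- acc(); sp_row_l <- acc(); sp_dt_l <- acc()
  dn_fw <- acc(); dn_win_l <- acc(); dn_dt_l <- acc(); dn_len_l <- acc()
  im_feat_l <- acc(); im_win_l <- acc(); im_dt_l <- acc()
  tx_feat_l <- acc(); tx_win_l <- acc(); tx_dt_l <- acc()
  vocab <- attr(desc, "vocab")
  for (b in seq_len(B)) {
    tk <- desc[[b]]
    ns <- length(tk$sparse$feature)
    if (ns) {
      sp_val_l[[b]] <- tk$sparse$value
      sp_dt_l[[b]] <- tk$sparse$dt
      sp_win_l[[b]] <- rep.int(b, ns)
      sp_row_l[[b]] <- vapply(tk$sparse$feature, function(f)
        vocab_row(vocab, f), integer(1))
    }
    for (dblk in tk$dense) {
      fw <- dense_conv_forward(dblk$x, params)
      L2 <- nrow(fw$H2)
      last_row <- 2 * (seq_len(L2) + 2) + 1
      i <- length(dn_fw) + 1L
      dn_fw[[i]] <- fw
      dn_win_l[[i]] <- rep.int(b, L2)
      dn_dt_l[[i]] <- tk$t_ref - dblk$row_times[last_row]
      dn_len_l[[i]] <- L2
    }
    if (!is.null(tk$image$feat)) {
      i <- length(im_win_l) + 1L
      im_feat_l[[i]] <- tk$image$feat
      im_win_l[[i]] <- b; im_dt_l[[i]] <- tk$image$dt
    }
    for (fld in names(tk$text)) {
      i <- length(tx_win_l) + 1L
      tx_feat_l[[i]] <- tk$text[[fld]]$feat
      tx_win_l[[i]] <- b; tx_dt_l[[i]] <- tk$text[[fld]]$dt
    }
  }
  sp_val <- unlist(sp_val_l); sp_dt <- unlist(sp_dt_l)
  sp_win <- unlist(sp_win_l); sp_row <- unlist(sp_row_l)
  dn_win <- unlist(dn_win_l); dn_dt <- unlist(dn_dt_l)
  dn_len <- unlist(dn_len_l)
  im_win <- unlist(im_win_l); im_dt <- unlist(im_dt_l)
  tx_win <- unlist(tx_win_l); tx_dt <- unlist(tx_dt_l)
  if (is.null(sp_val)) sp_val <- numeric(0)
  if (is.null(dn_len)) dn_len <- integer(0)
  im_feat <- if (length(im_win_l)) do.call(rbind, im_feat_l)
  tx_feat <- if (length(tx_win_l)) do.call(rbind, tx_feat_l)
  im_win <- if (is.null(im_win)) integer(0) else im_win
  tx_win <- if (is.null(tx_win)) integer(0) else tx_win
  d <- ncol(params$sW2)
  n_sp <- length(sp_val); n_dn <- sum(dn_len)
  n_im <- length(im_win); n_tx <- length(tx_win)

  sp_mlp <- if (n_sp) mlp2_forward(sp_val, params$sW1, params$sb1,
                                   params$sW2, params$sb2) else NULL
  im_lin <- if (n_im) linear_forward(im_feat, params$iW, params$ib) else NULL
  tx_lin <- if (n_tx) linear_forward(tx_feat, params$xW, params$xb) else NULL

  Ev <- rbind(if (n_sp) sp_mlp$Y,
              if (n_dn) do.call(rbind, lapply(dn_fw, `[[`, "H2")),
              if (n_im) im_lin$Y,
              if (n_tx) tx_lin$Y)
  win_id <- c(sp_win, dn_win, im_win, tx_win)
  dt_all <- c(sp_dt, dn_dt, im_dt, tx_dt)
  rows_all <- c(sp_row,
                rep.int(vocab_row(vocab, "MOD:dense_vitals"), n_dn),
                rep.int(vocab_row(vocab, "MOD:image"), n_im),
                rep.int(vocab_row(vocab, "MOD:text"), n_tx))
  t_mlp <- mlp2_forward(dt_all / cfg$time_scale_min, params$tW1, params$tb1,
                        params$tW2, params$tb2)
  X <- Ev + t_mlp$Y + params$E[rows_all, , drop = FALSE]

  layer_caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    lf <- encoder_layer_forward(X, win_id, layer_params(params, l), cfg$heads)
    X <- lf$Y
    layer_caches[[l]] <- lf$cache
  }
  pl <- pool_forward(X, win_id, B)
  h1 <- linear_forward(pl$Y, params$hW1, params$hb1)
  bn <- bn_forward(h1$Y, params$bn_g, params$bn_b, bn_state,
                   training = training)
  H <- pmax(bn$Y, 0)
  h2 <- linear_forward(H, params$hW2, params$hb2)
  probs <- 1 / (1 + exp(-h2$Y))
  out <- list(probs = probs, bn_state = bn$state)
  if (want_cache)
    out$cache <- list(sp = list(n = n_sp, mlp = sp_mlp$cache),
                      dn = list(n = n_dn, fw = dn_fw, len = dn_len),
                      im = list(n = n_im, lin = im_lin$cache),
                      tx = list(n = n_tx, lin = tx_lin$cache),
                      t_mlp = t_mlp$cache, rows_all = rows_all, win_id = win_id,
                      layers = layer_caches, pool = pl$cache,
                      h1 = h1$cache, bn = bn$cache, H = H, h2 = h2$cache,
                      probs = probs, B = B, d = d, n_rows_E = nrow(params$E))
  out
}

batch_backward <- function(cache, labels, params, cfg) {
  B <- cache$B; nh <- ncol(cache$probs)
  g <- list()
  dlogit <- (cache$probs - labels) / (B * nh)
  hb2 <- linear_backward(dlogit, cache$h2)
  g$hW2 <- hb2$dW; g$hb2 <- hb2$db
  dH <- hb2$dX * (cache$H > 0)
  bnb <- bn_backward(dH, cache$bn)
  g$bn_g <- bnb$dg; g$bn_b <- bnb$db
  hb1 <- linear_backward(bnb$dX, cache$h1)
  g$hW1 <- hb1$dW; g$hb1 <- hb1$db
  dX <- pool_backward(hb1$dX, cache$pool)
  for (l in rev(seq_len(cfg$layers))) {
    lb <- encoder_layer_backward(dX, cache$layers[[l]])
    dX <- lb$dX
    names(lb$grads) <- paste0("L", l, ".", names(lb$grads))
    g <- c(g, lb$grads)
  }
  # time embedder: every token
  tb <- mlp2_backward(dX, cache$t_mlp)
  g$tW1 <- tb$dW1; g$tb1 <- tb$db1; g$tW2 <- tb$dW2; g$tb2 <- tb$db2
  # feature/modality lookup rows
  dE <- rowsum(dX, group = cache$rows_all, reorder = FALSE)
  g$E <- matrix(0, cache$n_rows_E, cache$d)
  g$E[as.integer(rownames(dE)), ] <- dE
  # split dX by token kind (same stacking order as the forward pass)
  ofs <- 0L
  if (cache$sp$n) {
    dsp <- dX[ofs + seq_len(cache$sp$n), , drop = FALSE]
    sb <- mlp2_backward(dsp, cache$sp$mlp)
    g$sW1 <- sb$dW1; g$sb1 <- sb$db1; g$sW2 <- sb$dW2; g$sb2 <- sb$db2
    ofs <- ofs + cache$sp$n
  }
  if (cache$dn$n) {
    pos <- ofs
    for (k in seq_along(cache$dn$fw)) {
      L2 <- cache$dn$len[k]
      dh2 <- dX[pos + seq_len(L2), , drop = FALSE]
      db <- dense_conv_backward(dh2, cache$dn$fw[[k]], params)
      for (nm in names(db))
        g[[nm]] <- if (is.null(g[[nm]])) db[[nm]] else g[[nm]] + db[[nm]]
      pos <- pos + L2
    }
    ofs <- ofs + cache$dn$n
  }
  if (cache$im$n) {
    dim_ <- dX[ofs + seq_len(cache$im$n), , drop = FALSE]
    ib <- linear_backward(dim_, cache$im$lin)
    g$iW <- ib$dW; g$ib <- ib$db
    ofs <- ofs + cache$im$n
  }
  if (cache$tx$n) {
    dtx <- dX[ofs + seq_len(cache$tx$n), , drop = FALSE]
    xb <- linear_backward(dtx, cache$tx$lin)
    g$xW <- xb$dW; g$xb <- xb$db
  }
  g
}

prepare_descriptors <- function(windows, vocab, norm_stats, cfg) {
  desc <- lapply(windows, window_tokens, vocab = vocab,
                 norm_stats = norm_stats, cfg = cfg)
  attr(desc, "vocab") <- vocab
  desc
}

# prediction over arbitrarily many windows, chunked to bound memory
predict_descriptors <- function(desc, params, cfg, bn_state, chunk = 128L) {
  n <- length(desc)
  out <- matrix(NA_real_, n, length(cfg$horizons_min))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    sub <- desc[i:j]
    attr(sub, "vocab") <- attr(desc, "vocab")
    out[i:j, ] <- batch_forward(sub, params, cfg, training = FALSE,
                                bn_state = bn_state)$probs
    i <- j + 1L
  }
  out
}

# ---- fitting ---------------------------------------------------------------

#' Fit the multimodal fusion model
#'
#' The central fitting function: converts admissions to prediction windows,
#' embeds every observation as a UMSE token, fuses each window's token set
#' with a transformer encoder (no positional encoding; masked mean pooling)
#' and trains the 12-horizon sigmoid classifier head with binary
#' cross-entropy and Adam, using the configured class-imbalance sampler.
#' After every epoch the model is scored on the validation windows
#' (per-horizon AUROC/AUPRC, macro averages and their sum); the checkpoint
#' with the highest validation macro-AUPRC is retained as the fitted model.
#'
#' @param records Training cohort (list of [admission_record()]), or a
#'   pre-built `window_set` via `windows =`.
#' @param cfg A [run_config()]; `cfg$outcome_task`, `cfg$step`,
#'   `cfg$modality_set` and the training hyperparameters all live here.
#' @param val_records Optional held-out validation cohort; when omitted,
#'   `records` is split case-wise by `cfg$split_ratio` (stratified on the
#'   outcome task).
#' @param windows,val_windows Optional pre-extracted `window_set`s
#'   (overriding `records`/`val_records`).
#' @param verbose Print per-epoch progress?
#' @return Object of class `"edfuse"` with the selected parameters, feature
#'   vocabulary, normalization statistics, configuration and training
#'   `history` (one row per epoch).
#' @export
fit_fusion <- function(records = NULL, cfg = run_config(), val_records = NULL,
                       windows = NULL, val_windows = NULL, verbose = FALSE) {
  if (is.null(windows)) {
    stopifnot(!is.null(records))
    if (is.null(val_records)) {
      sp <- split_cohort(records, cfg$split_ratio, cfg$seed,
                         stratify_outcome = cfg$outcome_task)
      records <- sp$train; val_records <- sp$test
    }
    windows <- cohort_windows(records, cfg$outcome_task, cfg)
    val_windows <- cohort_windows(val_records, cfg$outcome_task, cfg)
    vocab <- build_vocabulary(records)
  } else {
    stopifnot(!is.null(val_windows))
    vocab <- build_vocabulary(sparse_features = sort(unique(unlist(
      lapply(windows$windows, function(w)
        vapply(Filter(function(e) e$modality == "sparse_tabular", w$events),
               function(e) e$feature_id, character(1))))), method = "radix"))
  }
  if (!inherits(windows, "window_set")) windows <- window_set(windows)
  if (!inherits(val_windows, "window_set")) val_windows <- window_set(val_windows)
  norm_stats <- compute_norm_stats(windows)

  pos <- vapply(windows$windows, function(w) any(w$labels == 1L), logical(1))
  if (!any(pos) || all(pos))
    stop("training windows must contain both classes", call. = FALSE)

  # index-level samplers (operate on positions, so descriptors are reused)
  make_batches <- function(epoch_seed) {
    set.seed(epoch_seed)
    n <- length(windows$windows)
    if (cfg$sampling == "windowwise_oversample") {
      n_pos <- sum(pos); n_neg <- n - n_pos
      idx <- seq_len(n)
      if (n_pos / n_neg < cfg$oversample_ratio) {
        need <- ceiling(cfg$oversample_ratio * n_neg) - n_pos
        idx <- c(idx, sample(which(pos), need, replace = TRUE))
      }
      idx <- sample(idx)
      split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    } else if (cfg$sampling == "casewise_balance") {
      balance_casewise(windows, batch_size = cfg$batch_size,
                       cap = cfg$case_cap,
                       n_batches = max(1L, ceiling(length(windows$windows) /
                                                     cfg$batch_size)),
                       seed = epoch_seed)
    } else {
      idx <- sample(n)
      split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    }
  }

  desc <- prepare_descriptors(windows$windows, vocab, norm_stats, cfg)
  vdesc <- prepare_descriptors(val_windows$windows, vocab, norm_stats, cfg)
  labmat <- do.call(rbind, lapply(windows$windows, `[[`, "labels"))
  vlab <- do.call(rbind, lapply(val_windows$windows, `[[`, "labels"))

  init <- init_fusion_params(vocab, cfg, seed = cfg$seed)
  params <- init$params; bn_state <- init$bn_state
  opt <- adam_init(params)
  history <- data.frame()
  best <- list(auprc = -Inf)

  for (epoch in seq_len(cfg$epochs)) {
    batches <- make_batches(cfg$seed * 1000L + epoch)
    ep_loss <- 0; nb <- 0L
    for (bi in batches) {
      sub <- desc[bi]
      attr(sub, "vocab") <- vocab
      fw <- batch_forward(sub, params, cfg, training = TRUE,
                          bn_state = bn_state, want_cache = TRUE)
      bn_state <- fw$bn_state
      loss <- bce_multihorizon_loss(fw$probs, labmat[bi, , drop = FALSE])
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      grads <- batch_backward(fw$cache, labmat[bi, , drop = FALSE], params, cfg)
      st <- adam_step(params, grads, opt, lr = cfg$lr)
      params <- st$params; opt <- st$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    vp <- predict_descriptors(vdesc, params, cfg, bn_state)
    vm <- horizon_metrics(vp, vlab)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / nb,
      val_macro_auroc = vm$macro_auroc, val_macro_auprc = vm$macro_auprc,
      val_selection_sum = vm$macro_auroc + vm$macro_auprc))
    if (verbose)
      message(sprintf("epoch %d loss %.4f val AUROC %.3f AUPRC %.3f",
                      epoch, ep_loss / nb, vm$macro_auroc, vm$macro_auprc))
    if (is.finite(vm$macro_auprc) && vm$macro_auprc > best$auprc)
      best <- list(auprc = vm$macro_auprc, params = params,
                   bn_state = bn_state, epoch = epoch)
  }
  if (is.null(best$params))
    best <- list(auprc = NA_real_, params = params, bn_state = bn_state,
                 epoch = cfg$epochs)
  structure(list(params = best$params, bn_state = best$bn_state,
                 vocab = vocab, norm_stats = norm_stats, cfg = cfg,
                 history = history, best_epoch = best$epoch,
                 task = cfg$outcome_task),
            class = "edfuse")
}

#' @export
print.edfuse <- function(x, ...) {
  cat("Multimodal fusion deterioration model (task: ", x$task, ")\n",
      "  d_model = ", x$cfg$d_model, ", layers = ", x$cfg$layers,
      ", heads = ", x$cfg$heads, ", horizons = ",
      length(x$cfg$horizons_min), "\n", sep = "")
  if (nrow(x$history)) {
    b <- x$history[x$best_epoch, ]
    cat(sprintf("  best epoch %d: val macro-AUROC %.3f, macro-AUPRC %.3f\n",
                x$best_epoch, b$val_macro_auroc, b$val_macro_auprc))
  }
  invisible(x)
}

#' @export
summary.edfuse <- function(object, ...) {
  cat("Training history (", nrow(object$history), " epochs):\n", sep = "")
  print(object$history, row.names = FALSE, digits = 4)
  cat("Selected checkpoint: epoch ", object$best_epoch,
      " (highest validation macro-AUPRC)\n", sep = "")
  invisible(object$history)
}

#' Predict multi-horizon deterioration probabilities
#'
#' @param object A fitted `"edfuse"` model.
#' @param newdata A list of prediction windows, a `window_set`, or a list of
#'   admission records (windows are then extracted with the model's config).
#' @param drop_feature,drop_modality Optional ablation: tokens of this
#'   feature id / modality are deleted from every window before prediction
#'   (the UMSE structure makes ablation token deletion, not zero-filling).
#' @param ... Unused.
#' @return `n x 12` matrix of probabilities in (0, 1), one row per window.
#' @export
predict.edfuse <- function(object, newdata, drop_feature = NULL,
                           drop_modality = NULL, ...) {
  windows <- as_window_list(newdata, object$cfg)
  if (!is.null(drop_feature) || !is.null(drop_modality))
    windows <- lapply(windows, ablate_window, feature = drop_feature,
                      modality = drop_modality)
  desc <- prepare_descriptors(windows, object$vocab, object$norm_stats,
                              object$cfg)
  predict_descriptors(desc, object$params, object$cfg, object$bn_state)
}

as_window_list <- function(newdata, cfg) {
  if (inherits(newdata, "window_set")) return(newdata$windows)
  if (inherits(newdata, "prediction_window")) return(list(newdata))
  if (inherits(newdata, "admission_record"))
    return(extract_windows(newdata, cfg$outcome_task, cfg))
  stopifnot(is.list(newdata))
  if (length(newdata) && inherits(newdata[[1]], "admission_record"))
    return(unlist(lapply(newdata, extract_windows, task = cfg$outcome_task,
                         cfg = cfg), recursive = FALSE))
  newdata
}

ablate_window <- function(w, feature = NULL, modality = NULL) {
  w$events <- Filter(function(e) {
    if (!is.null(feature) && e$feature_id %in% feature) return(FALSE)
    if (!is.null(modality) && e$modality %in% modality) return(FALSE)
    TRUE
  }, w$events)
  w
}

#' Per-update prediction stream for one admission
#'
#' The real-time surface of the model: one 12-horizon prediction at every
#' data-update time, equivalent to predicting each extracted window
#' independently (predictions at an update depend only on data acquired at
#' or before it).
#'
#' @param model A fitted `"edfuse"`.
#' @param record An [admission_record()].
#' @param cfg Optional config override (defaults to the model's).
#' @return `data.frame` with `reference_time_min` and one `p_<h>h` column per
#'   horizon.
#' @export
predict_stream <- function(model, record, cfg = model$cfg) {
  windows <- extract_windows(record, cfg$outcome_task, cfg)
  if (!length(windows)) return(data.frame())
  probs <- predict.edfuse(model, windows)
  out <- data.frame(reference_time_min =
                      vapply(windows, `[[`, numeric(1), "reference_time_min"))
  colnames(probs) <- paste0("p_", seq_len(ncol(probs)), "h")
  cbind(out, as.data.frame(probs))
}

#' Fuse one token set into a single representation
#'
#' Applies the model's transformer encoder (no positional encoding) to a
#' token set and mean-pools over the real tokens. Exposed for diagnostics
#' and invariance testing; [predict.edfuse()] is the end-to-end surface.
#'
#' @param tokens A `token_set` from [compose_tokens()], or a plain numeric
#'   `N x d` matrix of token vectors.
#' @param params Parameter list from [init_fusion_params()]`$params`.
#' @param cfg A [run_config()].
#' @return d_model vector.
#' @export
fuse <- function(tokens, params, cfg) {
  E <- if (inherits(tokens, "token_set")) tokens$E else as.matrix(tokens)
  if (!nrow(E)) stop("empty token set", call. = FALSE)
  X <- E
  win_id <- rep.int(1L, nrow(E))
  for (l in seq_len(cfg$layers))
    X <- encoder_layer_forward(X, win_id, layer_params(params, l), cfg$heads)$Y
  colMeans(X)
}

#' Classifier head on a fused representation
#'
#' `Linear -> BatchNorm -> ReLU -> Linear -> sigmoid`; inference uses the
#' running batch-norm statistics, so a single window's prediction does not
#' depend on batch composition.
#'
#' @param fused d_model vector or `n x d` matrix.
#' @param params Parameter list (classifier entries `hW1`, `bn_*`, `hW2`...).
#' @param bn_state Running mean/var list.
#' @return Vector (or matrix) of probabilities in (0, 1), width 12.
#' @export
predict_horizons <- function(fused, params, bn_state) {
  X <- if (is.matrix(fused)) fused else matrix(fused, nrow = 1)
  h1 <- linear_forward(X, params$hW1, params$hb1)
  bn <- bn_forward(h1$Y, params$bn_g, params$bn_b, bn_state, training = FALSE)
  H <- pmax(bn$Y, 0)
  probs <- 1 / (1 + exp(-(linear_forward(H, params$hW2, params$hb2)$Y)))
  if (is.matrix(fused)) probs else as.numeric(probs)
}

#' @export
plot.edfuse <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$val_macro_auroc, type = "b", pch = 19,
                 ylim = range(c(h$val_macro_auroc, h$val_macro_auprc),
                              na.rm = TRUE),
                 xlab = "epoch", ylab = "validation score",
                 main = paste("Validation metrics -", x$task), ...)
  graphics::lines(h$epoch, h$val_macro_auprc, type = "b", pch = 1, lty = 2)
  graphics::legend("bottomright", c("macro-AUROC", "macro-AUPRC"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
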