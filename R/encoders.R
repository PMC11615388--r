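# UMSE: modality-specific embedders, time embedding, and token composition.
# Every observation becomes one token e = e_time + e_value + e_feature/modality;
# unobserved features contribute no tokens (no imputation anywhere).

TEXT_FIELDS <- c("chief_complaint", "patient_info", "ekg_report")
BACKBONE_WIDTH <- 16L  # feature width of the stand-in image/text backbones

#' Feature/modality vocabulary
#'
#' Maps each sparse feature id to its own embedding row and each of the
#' dense/image/text modalities to a single per-modality row (sparse features
#' are heterogeneous; the other modalities are internally typed by their
#' encoders). Unknown feature ids at embedding time are routed to a reserved
#' `UNK` row with a warning.
#'
#' @param records Optional cohort; sparse feature ids are collected from it.
#' @param sparse_features Explicit character vector of sparse feature ids
#'   (used instead of `records` when given).
#' @return Object of class `"feature_vocabulary"`: named integer index map.
#' @export
build_vocabulary <- function(records = NULL, sparse_features = NULL) {
  if (is.null(sparse_features)) {
    stopifnot(!is.null(records))
    # radix: locale-independent ordering, so vocabulary rows are stable
    sparse_features <- sort(unique(unlist(lapply(records, function(r)
      vapply(Filter(function(e) e$modality == "sparse_tabular", r$events),
             function(e) e$feature_id, character(1))))), method = "radix")
  }
  keys <- c(sparse_features, "MOD:dense_vitals", "MOD:image", "MOD:text", "UNK")
  idx <- stats::setNames(seq_along(keys), keys)
  structure(list(index = idx, sparse_features = sparse_features),
            class = "feature_vocabulary")
}

vocab_row <- function(vocab, key) {
  i <- unname(vocab$index[key])
  if (is.na(i)) {
    warning("unknown feature id '", key, "' routed to UNK row", call. = FALSE)
    i <- unname(vocab$index["UNK"])
  }
  i
}

#' Per-feature standardization statistics
#'
#' Mean and standard deviation of every sparse feature over the supplied
#' (training) windows or records; used to normalize scalar values before the
#' value embedder. Computed on the training split only to avoid leakage.
#'
#' @param x A list of prediction windows, a `window_set`, or a list of
#'   admission records.
#' @return Named list `feature_id -> c(mean, sd)` (sd floored at 1e-6).
#' @export
compute_norm_stats <- function(x) {
  if (inherits(x, "window_set")) x <- x$windows
  evs <- unlist(lapply(x, function(w) w$events), recursive = FALSE)
  evs <- Filter(function(e) e$modality == "sparse_tabular", evs)
  fid <- vapply(evs, function(e) e$feature_id, character(1))
  val <- vapply(evs, function(e) e$value, numeric(1))
  out <- list()
  for (f in unique(fid)) {
    v <- val[fid == f]
    out[[f]] <- c(mean = mean(v), sd = max(stats::sd(v), 1e-6))
    if (length(v) == 1L) out[[f]]["sd"] <- 1
  }
  out
}

norm_value <- function(stats_map, fid, v) {
  s <- stats_map[[fid]]
  if (is.null(s)) return(v)
  (v - s[["mean"]]) / s[["sd"]]
}

#' Stand-in image backbone: grid-pooled intensity features
#'
#' Deterministic contract-compatible replacement for a large pretrained
#' vision backbone: the grayscale array is partitioned into a 4x4 grid and
#' each cell's mean intensity becomes one feature, giving a fixed-length
#' 16-vector regardless of image size.
#'
#' @param img Numeric H x W matrix.
#' @return Numeric feature vector of length 16.
#' @export
image_backbone_standin <- function(img) {
  img <- as.matrix(img)
  H <- nrow(img); W <- ncol(img)
  rb <- floor(seq(0, H, length.out = 5L))
  cb <- floor(seq(0, W, length.out = 5L))
  out <- numeric(16L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    out[k] <- mean(img[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]])
  }
  out
}

#' Tokenizer and stand-in text encoder
#'
#' `text_vocabulary()` builds the token-id map from the simulator's template
#' vocabulary plus an UNK id. `tokenize_text()` lower-cases and splits on
#' whitespace. `text_backbone_standin()` is a deterministic bag-of-words
#' encoder honoring the contract of a transformer text encoder: per-position
#' vectors from a fixed (seeded) word-embedding table with a designated
#' summary position — here the mean over positions, which is invariant to
#' permutations of the non-summary positions.
#'
#' @return `text_vocabulary()`: named integer map; `tokenize_text()`: integer
#'   id vector; `text_backbone_standin()`: numeric feature vector (length 16).
#' @export
text_vocabulary <- function() {
  tpl <- unlist(text_templates(), use.names = FALSE)
  extra <- c("male", "female", "elderly", "adult", "hypertension", "diabetes",
             "no", "history")
  words <- sort(unique(c(unlist(strsplit(tolower(tpl), "\\s+")), extra)),
                method = "radix")
  stats::setNames(seq_along(words), words)
}

#' @rdname text_vocabulary
#' @param text Character string.
#' @param vocab Token-id map from `text_vocabulary()`.
#' @export
tokenize_text <- function(text, vocab = text_vocabulary()) {
  words <- strsplit(tolower(trimws(text)), "\\s+")[[1]]
  words <- words[nzchar(words)]
  ids <- vocab[words]
  ids[is.na(ids)] <- length(vocab) + 1L  # UNK id
  as.integer(ids)
}

#' @rdname text_vocabulary
#' @param token_ids Integer token-id sequence.
#' @export
text_backbone_standin <- function(token_ids, vocab = text_vocabulary()) {
  if (!length(token_ids)) stop("empty token sequence", call. = FALSE)
  V <- length(vocab) + 1L
  emb <- local({
    old <- .Random.seed_exists()
    set.seed(424242L)
    e <- matrix(stats::rnorm(V * BACKBONE_WIDTH), V, BACKBONE_WIDTH)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    e
  })
  colMeans(emb[token_ids, , drop = FALSE])
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}

#' Initialize fusion-model parameters
#'
#' Allocates and randomly initializes every trainable array of the model:
#' the sparse-value and time MLP embedders, the two-layer 1-D convolution for
#' dense vitals (kernel 3, strides 2 then 1, channels 5 -> 16 -> d_model),
#' the image and text projections, the feature/modality lookup table, the
#' transformer encoder layers, and the two-layer classifier head with batch
#' normalization (output width = number of horizons).
#'
#' @param vocab A [build_vocabulary()] object.
#' @param cfg A [run_config()].
#' @param seed Integer seed for the initialization draws.
#' @return List with elements `params` (named list of arrays), `bn_state`
#'   (running batch-norm statistics) and layout metadata.
#' @export
init_fusion_params <- function(vocab, cfg, seed = cfg$seed) {
  set.seed(seed)
  d <- cfg$d_model; dc <- cfg$d_classifier; nh <- length(cfg$horizons_min)
  c1 <- 16L
  p <- list(
    sW1 = rand_mat(1, d, 0.5), sb1 = numeric(d),
    sW2 = rand_mat(d, d), sb2 = numeric(d),
    tW1 = rand_mat(1, d, 0.5), tb1 = numeric(d),
    tW2 = rand_mat(d, d), tb2 = numeric(d),
    cW1 = rand_mat(15, c1), cb1 = numeric(c1),
    cW2 = rand_mat(3 * c1, d), cb2 = numeric(d),
    iW = rand_mat(BACKBONE_WIDTH, d), ib = numeric(d),
    xW = rand_mat(BACKBONE_WIDTH, d), xb = numeric(d),
    E = rand_mat(length(vocab$index), d, 0.1),
    hW1 = rand_mat(d, dc), hb1 = numeric(dc),
    bn_g = rep(1, dc), bn_b = numeric(dc),
    hW2 = rand_mat(dc, nh), hb2 = numeric(nh))
  for (l in seq_len(cfg$layers)) {
    lp <- list(Wq = rand_mat(d, d), bq = numeric(d),
               Wk = rand_mat(d, d), bk = numeric(d),
               Wv = rand_mat(d, d), bv = numeric(d),
               Wo = rand_mat(d, d), bo = numeric(d),
               ln1_g = rep(1, d), ln1_b = numeric(d),
               ffW1 = rand_mat(d, d * cfg$ff_mult), ffb1 = numeric(d * cfg$ff_mult),
               ffW2 = rand_mat(d * cfg$ff_mult, d), ffb2 = numeric(d),
               ln2_g = rep(1, d), ln2_b = numeric(d))
    names(lp) <- paste0("L", l, ".", names(lp))
    p <- c(p, lp)
  }
  list(params = p, bn_state = list(mean = numeric(dc), var = rep(1, dc)),
       c1 = c1, d = d)
}

layer_params <- function(params, l) {
  pref <- paste0("L", l, ".")
  nms <- names(params)[startsWith(names(params), pref)]
  stats::setNames(params[nms], sub(pref, "", nms, fixed = TRUE))
}

#' Embed a sparse scalar observation (value embedder)
#'
#' Two linear layers with a tanh between: `Linear(tanh(Linear(x)))`.
#'
#' @param x Finite scalar (or vector of scalars), already normalized.
#' @param p Parameter list with `W1` (1 x d), `b1`, `W2` (d x d), `b2`.
#' @return `length(x) x d` matrix of value embeddings.
#' @export
embed_sparse <- function(x, p) {
  if (any(!is.finite(x)))
    stop("embed_sparse received a non-finite value; missing features must ",
         "produce no token", call. = FALSE)
  mlp2_forward(x, p$W1, p$b1, p$W2, p$b2)$Y
}

#' Embed a time difference (time embedder)
#'
#' Same MLP form as the sparse value embedder, applied to the normalized
#' difference between acquisition time and the current prediction time.
#'
#' @param delta_t Non-negative minutes (vector allowed).
#' @param p Parameter list with `W1`, `b1`, `W2`, `b2`.
#' @param scale Normalization scale in minutes (default 720).
#' @return `length(delta_t) x d` matrix.
#' @export
embed_time <- function(delta_t, p, scale = 720) {
  if (any(delta_t < 0))
    stop("negative time difference: acquisition after prediction time",
         call. = FALSE)
  mlp2_forward(delta_t / scale, p$W1, p$b1, p$W2, p$b2)$Y
}

conv_out_len <- function(t, kernel, stride) floor((t - kernel) / stride) + 1L

#' Embed a dense vitals block (two-layer 1-D CNN)
#'
#' `ReLU(Conv(ReLU(Conv(x))))` over the time axis: kernel 3 / stride 2, then
#' kernel 3 / stride 1 (channels 5 -> 16 -> d). Each output step is assigned
#' the acquisition time of the last input sample in its receptive field.
#'
#' @param x `t_dense x 5` matrix (channel order [ed_dense_channels()]).
#' @param p Parameter list with `cW1` (15 x 16), `cb1`, `cW2` (48 x d), `cb2`.
#' @param row_times Optional acquisition times of the input rows (minutes);
#'   defaults to `0, step, 2*step, ...` with `step = 1`.
#' @param step_min Grid step used when `row_times` is absent.
#' @return List: `E` (`t'_dense x d`, non-negative), `times` (length
#'   `t'_dense`).
#' @export
embed_dense <- function(x, p, row_times = NULL, step_min = 1) {
  t_in <- nrow(x)
  if (t_in < 7L)
    stop("dense block too short: need at least 7 samples for the ",
         "two-layer convolution", call. = FALSE)
  if (is.null(row_times)) row_times <- (seq_len(t_in) - 1) * step_min
  fw <- dense_conv_forward(x, p)
  last_row <- 2 * (seq_len(nrow(fw$H2)) + 2) + 1  # last input sample per step
  list(E = fw$H2, times = row_times[last_row])
}

dense_conv_forward <- function(x, p) {
  t_in <- nrow(x)
  L1 <- conv_out_len(t_in, 3L, 2L)
  idx1 <- t(vapply(seq_len(L1), function(j) (2 * (j - 1) + 1):(2 * (j - 1) + 3),
                   integer(3)))
  X1 <- do.call(rbind, lapply(seq_len(L1), function(j) as.numeric(t(x[idx1[j, ], ]))))
  Z1 <- X1 %*% p$cW1 + matrix(p$cb1, L1, length(p$cb1), byrow = TRUE)
  H1 <- pmax(Z1, 0)
  L2 <- L1 - 2L
  X2 <- do.call(rbind, lapply(seq_len(L2), function(j) as.numeric(t(H1[j:(j + 2), ]))))
  Z2 <- X2 %*% p$cW2 + matrix(p$cb2, L2, ncol(p$cW2), byrow = TRUE)
  H2 <- pmax(Z2, 0)
  list(H2 = H2, cache = list(X1 = X1, Z1 = Z1, H1 = H1, X2 = X2, Z2 = Z2,
                             L1 = L1, L2 = L2, idx1 = idx1))
}

dense_conv_backward <- function(dH2, fw, p) {
  cc <- fw$cache
  dZ2 <- dH2 * (cc$Z2 > 0)
  dW2 <- crossprod(cc$X2, dZ2); db2 <- colSums(dZ2)
  dX2 <- dZ2 %*% t(p$cW2)
  c1 <- ncol(cc$H1)
  dH1 <- matrix(0, cc$L1, c1)
  for (j in seq_len(cc$L2)) {
    seg <- matrix(dX2[j, ], nrow = 3, byrow = TRUE)
    dH1[j:(j + 2), ] <- dH1[j:(j + 2), ] + seg
  }
  dZ1 <- dH1 * (cc$Z1 > 0)
  dW1 <- crossprod(cc$X1, dZ1); db1 <- colSums(dZ1)
  list(cW1 = dW1, cb1 = db1, cW2 = dW2, cb2 = db2)
}

#' Embed the latest chest image of a window
#'
#' Backbone output (fixed-length feature vector) passed through one linear
#' projection to d_model.
#'
#' @param x H x W numeric matrix.
#' @param p Parameter list with `iW`, `ib`.
#' @param backbone Function `matrix -> feature vector`.
#' @return d_model vector.
#' @export
embed_image <- function(x, p, backbone = image_backbone_standin) {
  as.numeric(backbone(x) %*% p$iW + p$ib)
}

#' Embed one text field
#'
#' The backbone's summary vector is linearly projected to d_model.
#'
#' @param token_ids Integer token-id sequence (non-empty).
#' @param p Parameter list with `xW`, `xb`.
#' @param backbone Function `token ids -> summary feature vector`.
#' @return d_model vector.
#' @export
embed_text <- function(token_ids, p, backbone = text_backbone_standin) {
  as.numeric(backbone(token_ids) %*% p$xW + p$xb)
}

# ---- token descriptors -----------------------------------------------------
# Flat, embedder-agnostic description of one window's observations: what the
# forward/backward passes consume. Also the ablation surface: dropping a
# feature = dropping its descriptor rows.
window_tokens <- function(window, vocab, norm_stats, cfg) {
  t_ref <- window$reference_time_min
  sp_feat <- character(0); sp_val <- numeric(0); sp_dt <- numeric(0)
  dense <- list()
  img_feat <- NULL; img_dt <- NULL; img_time <- -Inf
  txt <- list()
  for (e in window$events) {
    if (!(e$modality %in% cfg$modality_set)) next
    if (e$modality == "sparse_tabular") {
      sp_feat <- c(sp_feat, e$feature_id)
      sp_val <- c(sp_val, norm_value(norm_stats, e$feature_id, e$value))
      sp_dt <- c(sp_dt, t_ref - e$time_min)
    } else if (e$modality == "dense_vitals") {
      step <- attr(e$value, "step_min"); if (is.null(step)) step <- 1
      if (nrow(e$value) >= 7L)
        dense[[length(dense) + 1L]] <- list(
          x = scale_dense_block(e$value),
          row_times = e$time_min + (seq_len(nrow(e$value)) - 1) * step)
    } else if (e$modality == "image") {
      if (e$time_min >= img_time) {   # latest image only
        img_time <- e$time_min
        img_feat <- image_backbone_standin(e$value)
        img_dt <- t_ref - e$time_min
      }
    } else if (e$modality == "text") {
      # one token per text field: keep the latest entry of each field
      txt[[e$feature_id]] <- list(
        feat = text_backbone_standin(tokenize_text(e$value)),
        dt = t_ref - e$time_min)
    }
  }
  list(sparse = list(feature = sp_feat, value = sp_val, dt = sp_dt),
       dense = dense, image = list(feat = img_feat, dt = img_dt),
       text = txt, t_ref = t_ref)
}

# crude within-block standardization so conv inputs are O(1)
scale_dense_block <- function(v) {
  ctr <- c(RR = 18, SBP = 120, HR = 85, DBP = 75, SpO2 = 96)
  scl <- c(RR = 5, SBP = 25, HR = 20, DBP = 15, SpO2 = 3)
  sweep(sweep(v, 2, ctr[ed_dense_channels()]), 2, scl[ed_dense_channels()], `/`)
}

#' Compose the UMSE token set of one prediction window
#'
#' Builds one token per observation: each sparse observation, each dense
#' convolution output step, at most one (latest) image, and one per text
#' field; every token is the sum `e_time + e_value + e_feature/modality`.
#' Absent features simply contribute no tokens.
#'
#' @param window A prediction window from [extract_windows()].
#' @param vocab A [build_vocabulary()] object.
#' @param params Parameter list from [init_fusion_params()]`$params`.
#' @param norm_stats Output of [compute_norm_stats()] on the training split.
#' @param cfg A [run_config()].
#' @return Object of class `"token_set"`: `E` (N x d matrix), `feature_id`,
#'   `time_min` and `modality` vectors (length N).
#' @export
compose_tokens <- function(window, vocab, params, norm_stats = list(),
                           cfg = run_config()) {
  tok <- window_tokens(window, vocab, norm_stats, cfg)
  d <- ncol(params$sW2)
  E <- matrix(0, 0, d); fid <- character(0); tmin <- numeric(0); mod <- character(0)
  sp <- tok$sparse
  if (length(sp$feature)) {
    ev <- embed_sparse(sp$value, list(W1 = params$sW1, b1 = params$sb1,
                                      W2 = params$sW2, b2 = params$sb2))
    et <- embed_time(sp$dt, list(W1 = params$tW1, b1 = params$tb1,
                                 W2 = params$tW2, b2 = params$tb2),
                     scale = cfg$time_scale_min)
    rows <- vapply(sp$feature, function(f) vocab_row(vocab, f), integer(1))
    E <- rbind(E, ev + et + params$E[rows, , drop = FALSE])
    fid <- c(fid, sp$feature); tmin <- c(tmin, tok$t_ref - sp$dt)
    mod <- c(mod, rep("sparse_tabular", length(sp$feature)))
  }
  for (dblk in tok$dense) {
    de <- embed_dense(dblk$x, params, row_times = dblk$row_times)
    dt <- tok$t_ref - de$times
    et <- embed_time(dt, list(W1 = params$tW1, b1 = params$tb1,
                              W2 = params$tW2, b2 = params$tb2),
                     scale = cfg$time_scale_min)
    r <- vocab_row(vocab, "MOD:dense_vitals")
    E <- rbind(E, de$E + et +
                 matrix(params$E[r, ], nrow(de$E), d, byrow = TRUE))
    fid <- c(fid, rep("dense_vitals_block", nrow(de$E)))
    tmin <- c(tmin, de$times)
    mod <- c(mod, rep("dense_vitals", nrow(de$E)))
  }
  if (!is.null(tok$image$feat)) {
    ev <- as.numeric(tok$image$feat %*% params$iW + params$ib)
    et <- embed_time(tok$image$dt, list(W1 = params$tW1, b1 = params$tb1,
                                        W2 = params$tW2, b2 = params$tb2),
                     scale = cfg$time_scale_min)
    E <- rbind(E, ev + as.numeric(et) + params$E[vocab_row(vocab, "MOD:image"), ])
    fid <- c(fid, "chest_image"); tmin <- c(tmin, tok$t_ref - tok$image$dt)
    mod <- c(mod, "image")
  }
  for (fld in names(tok$text)) {
    tx <- tok$text[[fld]]
    ev <- as.numeric(tx$feat %*% params$xW + params$xb)
    et <- embed_time(tx$dt, list(W1 = params$tW1, b1 = params$tb1,
                                 W2 = params$tW2, b2 = params$tb2),
                     scale = cfg$time_scale_min)
    E <- rbind(E, ev + as.numeric(et) + params$E[vocab_row(vocab, "MOD:text"), ])
    fid <- c(fid, fld); tmin <- c(tmin, tok$t_ref - tx$dt)
    mod <- c(mod, "text")
  }
  if (!nrow(E)) stop("window produced no tokens (triage data expected)",
                     call. = FALSE)
  structure(list(E = E, feature_id = fid, time_min = tmin, modality = mod),
            class = "token_set")
}

#' @export
print.token_set <- function(x, ...) {
  cat("<token_set> N =", nrow(x$E), "tokens, d =", ncol(x$E), "\n")
  invisible(x)
}
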