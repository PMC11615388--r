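# Fusion network: gradient correctness, permutation/padding invariance,
# classifier head contract, loss, prediction stream causality.

mini_cfg <- run_config(d_model = 8, d_classifier = 4, layers = 1, heads = 2,
                       epochs = 1, batch_size = 4, seed = 3)

mini_setup <- function(n = 6, seed = 1, with_modalities = TRUE) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    extra <- list()
    if (with_modalities && i %% 2 == 0)
      extra <- list(
        clinical_event("chest_image", "image", 10, matrix(rnorm(64), 8, 8)),
        clinical_event("chief_complaint", "text", 0, "chest pain radiating"),
        clinical_event("dense_vitals_block", "dense_vitals", 0,
                       matrix(rnorm(60, 100, 10), 12, 5)))
    toy_record(paste0("m", i), update_times = sort(runif(2, 10, 300)),
               outcome_at = if (i <= n / 2) 350 else NA, discharge = 500,
               extra_events = extra)
  })
  cfgd <- mini_cfg; cfgd$dense_resample_min <- 1
  ws <- cohort_windows(recs, "circulatory_shock", cfgd)
  vocab <- build_vocabulary(recs)
  norm <- compute_norm_stats(ws)
  desc <- edfuse:::prepare_descriptors(ws$windows, vocab, norm, cfgd)
  init <- init_fusion_params(vocab, cfgd, seed = seed)
  labs <- do.call(rbind, lapply(ws$windows, `[[`, "labels"))
  list(desc = desc, init = init, labs = labs, cfg = cfgd, ws = ws,
       vocab = vocab, norm = norm)
}

test_that("analytic gradients match finite differences for every parameter block", {
  s <- mini_setup(n = 4, seed = 2)
  params <- s$init$params; bn0 <- s$init$bn_state
  sub <- s$desc; attr(sub, "vocab") <- s$vocab  # all modalities represented
  labs <- s$labs
  loss_fn <- function(p) {
    fw <- edfuse:::batch_forward(sub, p, s$cfg, training = TRUE,
                                 bn_state = list(mean = bn0$mean, var = bn0$var))
    bce_multihorizon_loss(fw$probs, labs)
  }
  fw <- edfuse:::batch_forward(sub, params, s$cfg, training = TRUE,
                               bn_state = bn0, want_cache = TRUE)
  grads <- edfuse:::batch_backward(fw$cache, labs, params, s$cfg)
  # BCE backward assumes mean reduction; grads computed on dlogit scale
  eps <- 1e-5
  set.seed(99)
  for (nm in c("sW1", "sb2", "tW2", "cW1", "cW2", "iW", "xb", "E",
               "L1.Wq", "L1.Wo", "L1.ln1_g", "L1.ffW1", "L1.ln2_b",
               "hW1", "bn_g", "bn_b", "hW2", "hb2")) {
    g <- grads[[nm]]
    expect_false(is.null(g), label = paste("gradient exists for", nm))
    # probe a few random coordinates of each block
    for (k in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(unname(g[k]), num, tolerance = 1e-4,
                   label = paste0("d", nm, "[", k, "]"))
    }
  }
})

test_that("fused representation is invariant to token order and to padding", {
  s <- mini_setup(n = 6, seed = 4)
  params <- s$init$params
  set.seed(7)
  for (i in 1:100) {
    w <- s$ws$windows[[sample(length(s$ws$windows), 1)]]
    ts <- compose_tokens(w, s$vocab, params, s$norm, s$cfg)
    f1 <- fuse(ts, params, s$cfg)
    perm <- sample(nrow(ts$E))
    f2 <- fuse(ts$E[perm, , drop = FALSE], params, s$cfg)
    expect_equal(f1, f2, tolerance = 1e-5)
  }
})

test_that("batched forward equals window-at-a-time forward (masking contract)", {
  s <- mini_setup(n = 6, seed = 5)
  params <- s$init$params; bn <- s$init$bn_state
  all_probs <- edfuse:::predict_descriptors(s$desc, params, s$cfg, bn)
  # one window at a time (batch of 1 = no padding/other-window interference)
  for (i in seq_along(s$desc)) {
    one <- s$desc[i]; attr(one, "vocab") <- s$vocab
    p1 <- edfuse:::batch_forward(one, params, s$cfg, training = FALSE,
                                 bn_state = bn)$probs
    expect_equal(as.numeric(p1), as.numeric(all_probs[i, ]), tolerance = 1e-10)
  }
})

test_that("classifier head emits exactly 12 probabilities strictly inside (0,1)", {
  s <- mini_setup(n = 4, seed = 6)
  params <- s$init$params
  fused <- rnorm(8)
  pr <- predict_horizons(fused, params, s$init$bn_state)
  expect_length(pr, 12)
  expect_true(all(pr > 0 & pr < 1))
  # zero final-layer weights and bias -> sigmoid(0) = 0.5 everywhere
  pz <- params; pz$hW2[] <- 0; pz$hb2[] <- 0
  expect_equal(predict_horizons(fused, pz, s$init$bn_state), rep(0.5, 12))
  # inference must not depend on batch composition (running statistics)
  two <- predict_horizons(rbind(fused, rnorm(8) * 10), params, s$init$bn_state)
  expect_equal(as.numeric(two[1, ]), as.numeric(pr), tolerance = 1e-12)
})

test_that("multi-horizon BCE matches its closed forms and a scalar oracle", {
  expect_equal(bce_multihorizon_loss(rep(0.5, 12), rep(1, 12)), log(2),
               tolerance = 1e-9)
  y <- c(1, 0, 1, 0)
  expect_lt(bce_multihorizon_loss(y, y), 1e-6)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(12, 0.01, 0.99); y <- rbinom(12, 1, 0.5)
    oracle <- 0
    for (h in 1:12) oracle <- oracle - (y[h] * log(p[h]) +
                                          (1 - y[h]) * log(1 - p[h]))
    expect_equal(bce_multihorizon_loss(p, y), oracle / 12, tolerance = 1e-9)
  }
})

test_that("prediction stream is causal and one-per-update", {
  tm <- fit_toy_model(n_cases = 40, seed = 9, epochs = 1)
  r <- toy_record("S", update_times = c(30, 90, 200))
  ps <- predict_stream(tm$fit, r)
  expect_equal(nrow(ps), 4)   # the four-window worked example
  expect_equal(ncol(ps), 13)  # reference time + 12 horizons
  # prefix-equivalence: prediction at update k equals prediction on the
  # record truncated after update k
  r_trunc <- toy_record("S", update_times = c(30), discharge = 500)
  ps_tr <- predict_stream(tm$fit, r_trunc)
  expect_equal(as.numeric(ps[2, -1]), as.numeric(ps_tr[2, -1]),
               tolerance = 1e-10)
  # adding a future event leaves earlier predictions unchanged
  r_more <- toy_record("S", update_times = c(30, 90, 200, 400))
  ps_more <- predict_stream(tm$fit, r_more)
  expect_equal(as.matrix(ps_more[1:4, ]), as.matrix(ps[1:4, ]),
               tolerance = 1e-10)
})

test_that("models trained trimodally predict windows lacking image/text", {
  tm <- fit_toy_model(n_cases = 40, seed = 10, epochs = 1)
  r <- toy_record("plain", update_times = c(50))  # sparse-only record
  p <- predict(tm$fit, list(r))
  expect_equal(dim(p), c(2L, 12L))
  expect_true(all(p > 0 & p < 1))
})

test_that("best checkpoint carries the highest logged validation macro-AUPRC", {
  tm <- fit_toy_model(n_cases = 50, seed = 11, epochs = 3)
  h <- tm$fit$history
  expect_equal(tm$fit$best_epoch, h$epoch[which.max(h$val_macro_auprc)])
  expect_gte(h$val_macro_auprc[tm$fit$best_epoch], max(h$val_macro_auprc))
})
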