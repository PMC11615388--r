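# Modality embedders, time embedding, and UMSE token composition.

cfg8 <- run_config(d_model = 8, d_classifier = 4, layers = 1, heads = 2)

test_that("sparse value embedder computes Linear-tanh-Linear exactly", {
  # 1-unit toy: weights [[2]], bias 0, then tanh, then [[3]], bias 1 on x=0.5
  p <- list(W1 = matrix(2), b1 = 0, W2 = matrix(3), b2 = 1)
  expect_equal(as.numeric(embed_sparse(0.5, p)), 3 * tanh(1) + 1,
               tolerance = 1e-12)
  # zero weights and biases give the zero vector
  pz <- list(W1 = matrix(0, 1, 4), b1 = numeric(4), W2 = matrix(0, 4, 4),
             b2 = numeric(4))
  expect_equal(as.numeric(embed_sparse(1.7, pz)), numeric(4))
  # output width is d_model for any input
  vocab <- build_vocabulary(sparse_features = c("SBP"))
  pr <- init_fusion_params(vocab, cfg8)$params
  expect_equal(ncol(embed_sparse(c(-2, 0, 3.3), list(W1 = pr$sW1, b1 = pr$sb1,
                                                     W2 = pr$sW2, b2 = pr$sb2))), 8)
  expect_error(embed_sparse(NaN, p), "non-finite")
})

test_that("time embedder is injective on toy weights and rejects negatives", {
  p <- list(W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0)
  e1 <- embed_time(30, p); e2 <- embed_time(90, p)
  expect_false(isTRUE(all.equal(e1, e2)))
  expect_equal(as.numeric(embed_time(0, p)), tanh(0))
  expect_error(embed_time(-5, p), "negative")
  # intermediate tanh activations bounded
  expect_lte(abs(tanh(720 / 720)), 1)
})

test_that("dense conv arithmetic, time mapping, and activation properties hold", {
  vocab <- build_vocabulary(sparse_features = "SBP")
  pr <- init_fusion_params(vocab, cfg8)$params
  # conv output-length oracle: floor((t - k)/s) + 1 per layer
  expect_equal(edfuse:::conv_out_len(7, 3, 2), 3)
  expect_equal(edfuse:::conv_out_len(21, 3, 2), 10)
  x <- matrix(rnorm(7 * 5), 7, 5)
  out <- embed_dense(x, pr)
  expect_equal(nrow(out$E), 1)            # (floor((7-3)/2)+1) - 2
  expect_equal(ncol(out$E), 8)
  expect_true(all(out$E >= 0))            # final ReLU
  # each output step timed at the last input sample of its receptive field
  x21 <- matrix(rnorm(21 * 5), 21, 5)
  out21 <- embed_dense(x21, pr, row_times = (0:20) * 10)
  expect_equal(nrow(out21$E), 8)
  expect_equal(out21$times, (2 * (1:8 + 2) + 1 - 1) * 10)
  # all-zero input with zero biases stays zero
  pz <- pr; pz$cb1 <- pz$cb1 * 0; pz$cb2 <- pz$cb2 * 0
  expect_equal(max(abs(embed_dense(matrix(0, 9, 5), pz)$E)), 0)
  expect_error(embed_dense(matrix(0, 5, 5), pr), "at least 7")
})

test_that("image embedder projects the backbone features; latest image wins", {
  vocab <- build_vocabulary(sparse_features = "SBP")
  pr <- init_fusion_params(vocab, cfg8)$params
  # stand-in backbone returning zeros -> projection bias vector
  zero_bb <- function(img) numeric(16)
  pr2 <- pr; pr2$ib <- seq(0.1, 0.8, by = 0.1)
  expect_equal(embed_image(matrix(1, 4, 4), pr2, backbone = zero_bb), pr2$ib)
  # output width = d_model regardless of backbone width
  wide_bb <- function(img) numeric(16) + 1
  expect_length(embed_image(matrix(0, 6, 6), pr, backbone = wide_bb), 8)
  # two images in a window: exactly one token, from the later time
  w <- extract_windows(toy_record("I", update_times = 100,
    extra_events = list(
      clinical_event("chest_image", "image", 20, matrix(0, 8, 8)),
      clinical_event("chest_image", "image", 80, matrix(5, 8, 8)))),
    "circulatory_shock", cfg8)
  ts <- compose_tokens(w[[length(w)]], vocab2 <- build_vocabulary(
    sparse_features = c("age", "SBP", "HR")), pr, list(), cfg8)
  img_tok <- which(ts$modality == "image")
  expect_length(img_tok, 1)
  expect_equal(ts$time_min[img_tok], 80)
})

test_that("text embedder uses the summary vector and ignores word order", {
  vocab <- build_vocabulary(sparse_features = "SBP")
  pr <- init_fusion_params(vocab, cfg8)$params
  fixed_bb <- function(ids) rep(2, 16)
  ids <- tokenize_text("chest pain radiating")
  expect_equal(embed_text(ids, pr, backbone = fixed_bb),
               as.numeric(rep(2, 16) %*% pr$xW + pr$xb))
  # bag-of-words stand-in: permuting positions leaves the summary unchanged
  ids2 <- sample(ids)
  expect_equal(text_backbone_standin(ids), text_backbone_standin(ids2))
  expect_equal(embed_text(ids, pr), embed_text(rev(ids), pr))
})

test_that("token composition counts follow the additive formula; no imputation", {
  vocab <- build_vocabulary(sparse_features = c("age", "SBP", "HR", "lactate"))
  pr <- init_fusion_params(vocab, cfg8)$params
  # 6 sparse observations, nothing else -> N = 6
  r <- toy_record("C", update_times = 100)  # 3 triage sparse + 2 update sparse
  w <- extract_windows(r, "circulatory_shock", cfg8)[[2]]
  ts <- compose_tokens(w, vocab, pr, list(), cfg8)
  expect_equal(nrow(ts$E), 5)
  # sparse + dense(3 steps) + image + 2 texts
  dense <- matrix(rnorm(11 * 5), 11, 5)  # L1 = 5, L2 = 3
  r2 <- toy_record("C2", update_times = 100, extra_events = list(
    clinical_event("dense_vitals_block", "dense_vitals", 0, dense),
    clinical_event("chest_image", "image", 10, matrix(0, 8, 8)),
    clinical_event("chief_complaint", "text", 0, "dyspnea severe"),
    clinical_event("ekg_report", "text", 30, "normal sinus rhythm")))
  cfg_d <- run_config(d_model = 8, d_classifier = 4, layers = 1, heads = 2,
                      dense_resample_min = 1)
  w2 <- extract_windows(r2, "circulatory_shock", cfg_d)
  ts2 <- compose_tokens(w2[[length(w2)]], vocab, pr, list(), cfg_d)
  expect_equal(nrow(ts2$E), 5 + 3 + 1 + 2)
  # deleting one observation removes exactly that one token
  w_del <- w2[[length(w2)]]
  drop_idx <- which(vapply(w_del$events, function(e)
    e$feature_id == "SBP" & e$time_min == 100, logical(1)))
  w_del$events <- w_del$events[-drop_idx]
  ts_del <- compose_tokens(w_del, vocab, pr, list(), cfg_d)
  expect_equal(nrow(ts_del$E), nrow(ts2$E) - 1)
  keep <- !(ts2$feature_id == "SBP" & ts2$time_min == 100)
  expect_equal(ts_del$E, ts2$E[keep, , drop = FALSE])
})

test_that("tokens decompose additively into time, value and feature parts", {
  vocab <- build_vocabulary(sparse_features = c("age", "SBP", "HR"))
  pr <- init_fusion_params(vocab, cfg8)$params
  w <- extract_windows(toy_record("A", update_times = numeric(0)),
                       "circulatory_shock", cfg8)[[1]]
  full <- compose_tokens(w, vocab, pr, list(), cfg8)
  # parameter surgery: zero the value and lookup parts -> time embedding alone
  pz <- pr
  pz$sW1[] <- 0; pz$sb1[] <- 0; pz$sW2[] <- 0; pz$sb2[] <- 0; pz$E[] <- 0
  t_only <- compose_tokens(w, vocab, pz, list(), cfg8)
  tp <- list(W1 = pr$tW1, b1 = pr$tb1, W2 = pr$tW2, b2 = pr$tb2)
  expect_equal(t_only$E[1, ],
               as.numeric(embed_time(0, tp, scale = cfg8$time_scale_min)),
               tolerance = 1e-12)
  # and the cyclic complement: zero the time part -> value + lookup
  pt <- pr; pt$tW1[] <- 0; pt$tb1[] <- 0; pt$tW2[] <- 0; pt$tb2[] <- 0
  v_only <- compose_tokens(w, vocab, pt, list(), cfg8)
  expect_equal(full$E, t_only$E + v_only$E - 0, tolerance = 1e-9)
})

test_that("unknown feature ids are routed to the UNK row with a warning", {
  vocab <- build_vocabulary(sparse_features = c("SBP"))
  pr <- init_fusion_params(vocab, cfg8)$params
  w <- extract_windows(toy_record("U", update_times = numeric(0)),
                       "circulatory_shock", cfg8)[[1]]  # contains age, HR
  msgs <- capture_warnings(ts <- compose_tokens(w, vocab, pr, list(), cfg8))
  expect_true(all(grepl("UNK", msgs)))
  expect_length(msgs, 2)  # age and HR are both unknown to this vocabulary
  expect_equal(nrow(ts$E), 3)
})
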