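# Window extraction, 12-horizon labeling, oracle equivalence, samplers.

cfg <- run_config(d_model = 8, heads = 2)

test_that("a record with triage data and three later updates yields 4 windows", {
  r <- toy_record(update_times = c(30, 90, 200))
  w <- extract_windows(r, "circulatory_shock", cfg)
  expect_length(w, 4)
  expect_equal(vapply(w, `[[`, numeric(1), "reference_time_min"),
               c(0, 30, 90, 200))
  # first window holds only admission data
  expect_true(all(vapply(w[[1]]$events, function(e) e$time_min, numeric(1)) == 0))
  # later windows accumulate all earlier events
  expect_length(w[[4]]$events, length(r$events))
})

test_that("triage-only records give one window; empty records none", {
  r <- toy_record(update_times = numeric(0))
  expect_length(extract_windows(r, "circulatory_shock", cfg), 1)
  r0 <- admission_record("empty", 40, "M", list(), list(), 100)
  expect_warning(w <- extract_windows(r0, "circulatory_shock", cfg), "no events")
  expect_length(w, 0)
})

test_that("windows stop strictly before outcome onset", {
  r <- toy_record(update_times = c(30, 90, 200), outcome_at = 150)
  w <- extract_windows(r, "circulatory_shock", cfg)
  expect_equal(vapply(w, `[[`, numeric(1), "reference_time_min"), c(0, 30, 90))
  expect_true(all(vapply(w, `[[`, logical(1), "is_from_positive_case")))
})

test_that("step1 restricts to the t = 0 window", {
  cfg1 <- run_config(d_model = 8, heads = 2, step = "step1_triage")
  r <- toy_record(update_times = c(30, 90))
  expect_length(extract_windows(r, "circulatory_shock", cfg1), 1)
})

test_that("label_window implements the half-open (t_ref, t_ref + h] rule", {
  h <- seq(60, 720, by = 60)
  expect_equal(label_window(100, 130, h), rep(1L, 12))
  expect_equal(label_window(100, NA, h), rep(0L, 12))
  # onset at 300 min from ref 0: boundary at the 5th horizon counts positive
  lab <- label_window(0, 300, h)
  oracle <- vapply(h, function(hh) as.integer(300 > 0 && 300 <= hh), integer(1))
  expect_equal(lab, oracle)
  expect_equal(lab, c(0L, 0L, 0L, 0L, rep(1L, 8)))
  expect_error(label_window(100, 100, h), "strictly after")
  # monotone non-decreasing always
  expect_true(all(diff(label_window(10, 400, h)) >= 0))
})

test_that("extract_windows agrees with the brute-force label oracle", {
  set.seed(42)
  for (i in 1:400) {
    r <- random_record(paste0("r", i))
    w <- extract_windows(r, "circulatory_shock", cfg)
    orc <- label_oracle(r, "circulatory_shock", cfg)
    expect_equal(length(w), length(orc))
    for (k in seq_along(w)) {
      expect_identical(w[[k]]$labels, orc[[k]])
      expect_true(all(diff(w[[k]]$labels) >= 0))
      expect_true(all(vapply(w[[k]]$events, function(e) e$time_min, numeric(1))
                      <= w[[k]]$reference_time_min))
    }
  }
})

test_that("horizon-boundary onsets agree between implementation and oracle", {
  for (b in seq(60, 720, by = 60)) {
    r <- toy_record(update_times = c(10), outcome_at = b + 10, discharge = 2000)
    w <- extract_windows(r, "circulatory_shock", cfg)
    orc <- label_oracle(r, "circulatory_shock", cfg)
    for (k in seq_along(w)) expect_identical(w[[k]]$labels, orc[[k]])
    # window at t=10: onset exactly b later -> horizon b/60 positive
    expect_equal(w[[2]]$labels[b / 60], 1L)
    if (b > 60) expect_equal(w[[2]]$labels[b / 60 - 1], 0L)
  }
})

test_that("negative windows arise from positive cases with long stays", {
  r <- toy_record(update_times = c(30), outcome_at = 60 * 13 + 35,
                  discharge = 60 * 15)
  w <- extract_windows(r, "circulatory_shock", cfg)
  expect_true(w[[1]]$is_from_positive_case)
  expect_equal(sum(w[[1]]$labels), 0)  # onset beyond the 12 h range
})

test_that("events sharing one timestamp form a single update", {
  r <- toy_record(update_times = c(50, 50, 50))
  w <- extract_windows(r, "circulatory_shock", cfg)
  expect_length(w, 2)
})

test_that("window-wise oversampling reaches the target ratio and keeps originals", {
  mk_ws <- function(npos, nneg) {
    pos <- lapply(seq_len(npos), function(i) {
      w <- extract_windows(toy_record(paste0("p", i), update_times = numeric(0),
                                      outcome_at = 50, discharge = 100),
                           "circulatory_shock", cfg)[[1]]
      w
    })
    neg <- lapply(seq_len(nneg), function(i)
      extract_windows(toy_record(paste0("n", i), update_times = numeric(0)),
                      "circulatory_shock", cfg)[[1]])
    edfuse:::window_set(c(pos, neg))
  }
  ws <- mk_ws(1, 99)
  os <- oversample_windowwise(ws, 1.0, seed = 3)
  expect_equal(unname(os$class_counts["pos"]), 99)
  expect_equal(unname(os$class_counts["neg"]), 99)
  # already balanced: no-op
  wsb <- mk_ws(5, 5)
  expect_equal(length(oversample_windowwise(wsb, 1.0, seed = 1)$windows), 10)
  # property: achieved ratio within one window of target, originals retained
  set.seed(9)
  for (i in 1:20) {
    npos <- sample(1:30, 1); nneg <- sample(1:60, 1)
    tr <- runif(1, 0.3, 1.5)
    ws <- mk_ws(npos, nneg)
    os <- oversample_windowwise(ws, tr, seed = i)
    cc <- os$class_counts
    expect_gte((cc["pos"] + 1) / cc["neg"], tr)
    expect_gte(cc["pos"], npos)
    expect_equal(unname(cc["neg"]), nneg)
    ids <- vapply(os$windows, `[[`, character(1), "admission_id")
    expect_true(all(paste0("p", seq_len(npos)) %in% ids))
  }
  # single-class input errors, naming the absent class
  expect_error(oversample_windowwise(mk_ws(0 + 1, 0), 1, 1), "negative")
})

test_that("case-wise batches balance sources and respect the per-record cap", {
  pos <- lapply(1:5, function(i)
    extract_windows(toy_record(paste0("p", i), update_times = c(30, 60, 90),
                               outcome_at = 500, discharge = 600),
                    "circulatory_shock", cfg))
  neg <- lapply(1:5, function(i)
    extract_windows(toy_record(paste0("n", i), update_times = c(30, 60, 90)),
                    "circulatory_shock", cfg))
  ws <- edfuse:::window_set(unlist(c(pos, neg), recursive = FALSE))
  batches <- balance_casewise(ws, batch_size = 8, cap = 2, n_batches = 100,
                              seed = 1)
  expect_length(batches, 100)
  for (b in batches) {
    ids <- vapply(ws$windows[b], `[[`, character(1), "admission_id")
    posrc <- vapply(ws$windows[b], `[[`, logical(1), "is_from_positive_case")
    expect_gte(length(unique(ids[posrc])), 2)
    expect_gte(length(unique(ids[!posrc])), 2)
    expect_lte(max(table(ids)), 2)  # cap enforcement
  }
  # determinism
  expect_identical(batches,
                   balance_casewise(ws, batch_size = 8, cap = 2,
                                    n_batches = 100, seed = 1))
  # one long-stay record cannot dominate: cap applies even with 500 windows
  long <- extract_windows(toy_record("L", update_times = seq(1, 500),
                                     outcome_at = 590, discharge = 600),
                          "circulatory_shock", cfg)
  ws2 <- edfuse:::window_set(c(long, unlist(neg, recursive = FALSE)))
  b2 <- balance_casewise(ws2, batch_size = 8, cap = 4, n_batches = 20, seed = 2)
  for (b in b2) {
    ids <- vapply(ws2$windows[b], `[[`, character(1), "admission_id")
    expect_lte(sum(ids == "L"), 4)
  }
  # single-class cohort errors
  expect_error(balance_casewise(edfuse:::window_set(
    unlist(neg, recursive = FALSE)), 8, 2, 10, 1), "positive")
})
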