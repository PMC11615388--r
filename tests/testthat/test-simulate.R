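# Synthetic cohort generator: determinism, calibrated prevalence vs the
# closed-form exponential survival probability, coverage fractions, planted
# signal, independence under a null hazard.

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_cases = 150, seed = 17)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_equal(c1, c2)
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_cohort(c1, p1); write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("with zero coefficients a fixed baseline reproduces the closed-form prevalence", {
  # independent oracle: P(outcome < discharge) = E[1 - exp(-lambda * L_hours)]
  # under a constant hazard; choose lambda for 3% from a lognormal LOS sample
  los_meanlog <- log(240); los_sdlog <- 0.95
  set.seed(1000)
  L <- pmin(pmax(rlnorm(200000, los_meanlog, los_sdlog), 45), 4320) / 60
  lam <- uniroot(function(l) mean(1 - exp(-l * L)) - 0.03, c(1e-6, 1))$root
  cfg <- generator_config(
    n_cases = 4000, seed = 18,
    hazard = hazard_params(strength = "none", baseline_rate = lam),
    outcome_prevalence = c(IHCA = 0, circulatory_shock = 0.03,
                           advanced_airway = 0, ICU_admission = 0),
    los_meanlog = los_meanlog, los_sdlog = los_sdlog)
  co <- generate_cohort(cfg)
  prev <- mean(vapply(co, function(r)
    !is.na(outcome_time(r, "circulatory_shock")), logical(1)))
  expect_lt(abs(prev - 0.03), 0.01)
})

test_that("a hazard too weak for the target triggers the achieved-prevalence warning", {
  cfg <- generator_config(
    n_cases = 300, seed = 19,
    hazard = hazard_params(strength = "none", baseline_rate = 1e-5),
    outcome_prevalence = c(IHCA = 0, circulatory_shock = 0.2,
                           advanced_airway = 0, ICU_admission = 0))
  expect_warning(generate_cohort(cfg), "achieved prevalence")
})

test_that("modality coverage matches the configured probabilities", {
  cfg <- generator_config(n_cases = 4000, seed = 20, image_prob = 0.66)
  co <- generate_cohort(cfg)
  s <- summarize_cohort(co)
  img_frac <- s$n[s$variable == "chest_xray"] / length(co)
  expect_lt(abs(img_frac - 0.66), 0.02)
  lab_frac <- s$n[s$variable == "laboratory_test"] / length(co)
  expect_lt(abs(lab_frac - 0.72), 0.03)
  ekg_frac <- s$n[s$variable == "ekg_report"] / length(co)
  expect_lt(abs(ekg_frac - 0.44), 0.03)
  # LOS bands partition the cohort
  bands <- s$n[s$variable %in% c("los_0_12h", "los_12_24h", "los_over_24h")]
  expect_equal(sum(bands), length(co))
})

test_that("calibrated prevalences land on the reference targets", {
  cfg <- generator_config(n_cases = 4000, seed = 22)
  co <- generate_cohort(cfg)
  s <- summarize_cohort(co)
  for (chk in list(c("circulatory_shock", 0.026), c("ICU_admission", 0.035))) {
    prev <- s$n[s$variable == chk[1]] / length(co)
    expect_lt(abs(prev - as.numeric(chk[2])), 0.012)
  }
})

test_that("summary arithmetic is exact on a hand-built cohort", {
  co <- c(lapply(1:2, function(i)
    toy_record(paste0("p", i), update_times = numeric(0), outcome_at = 50,
               discharge = 100,
               extra_events = list(ev_sparse("wbc", 10, 9)))),
    lapply(1:98, function(i)
      toy_record(paste0("n", i), update_times = numeric(0), discharge = 100,
                 extra_events = list(ev_sparse("wbc", 10, 9)))))
  s <- summarize_cohort(co)
  expect_equal(s$n[s$variable == "circulatory_shock"], 2)
  expect_equal(s$pct[s$variable == "circulatory_shock"], 2.0)
  expect_equal(s$pct[s$variable == "laboratory_test"], 100)
})

test_that("planted signal raises outcome rate in the top lactate quartile", {
  cfg <- generator_config(n_cases = 4000, seed = 23,
                          outcome_prevalence = c(IHCA = 0,
                                                 circulatory_shock = 0.08,
                                                 advanced_airway = 0,
                                                 ICU_admission = 0))
  co <- planted_signal_cohort(cfg, "lactate", beta = 1.5)
  lac <- vapply(co, function(r) {
    v <- Filter(function(e) e$feature_id == "lactate", r$events)
    if (length(v)) v[[1]]$value else NA_real_
  }, numeric(1))
  pos <- vapply(co, function(r)
    !is.na(outcome_time(r, "circulatory_shock")), logical(1))
  q <- quantile(lac, c(0.25, 0.75), na.rm = TRUE)
  rate_hi <- mean(pos[lac >= q[2]]); rate_lo <- mean(pos[lac <= q[1]])
  expect_gt(rate_hi, 3 * rate_lo)
  # null case: zero coefficient equalizes the rates within sampling error
  co0 <- planted_signal_cohort(cfg, "lactate", beta = 0)
  lac0 <- vapply(co0, function(r) {
    v <- Filter(function(e) e$feature_id == "lactate", r$events)
    if (length(v)) v[[1]]$value else NA_real_
  }, numeric(1))
  pos0 <- vapply(co0, function(r)
    !is.na(outcome_time(r, "circulatory_shock")), logical(1))
  q0 <- quantile(lac0, c(0.25, 0.75), na.rm = TRUE)
  diff0 <- abs(mean(pos0[lac0 >= q0[2]]) - mean(pos0[lac0 <= q0[1]]))
  expect_lt(diff0, 3 * sqrt(2 * 0.08 * 0.92 / 1000))
})

test_that("achieved prevalence grows monotonically with the signal coefficient", {
  prevs <- vapply(c(0, 1, 2.5), function(b) {
    cfg <- generator_config(n_cases = 2500, seed = 24,
      hazard = hazard_params(strength = "none", baseline_rate = 0.004),
      outcome_prevalence = c(IHCA = 0, circulatory_shock = 0.05,
                             advanced_airway = 0, ICU_admission = 0))
    co <- planted_signal_cohort(cfg, "lactate", beta = b)
    mean(vapply(co, function(r)
      !is.na(outcome_time(r, "circulatory_shock")), logical(1)))
  }, numeric(1))
  expect_true(all(diff(prevs) > 0))
})

test_that("with zero hazard coefficients outcomes are independent of features", {
  # chi-square independence across several seeds; at most one failure at
  # alpha = 0.01 (sizes chosen to keep the default run short)
  fails <- 0L
  for (sd in 1:6) {
    cfg <- generator_config(n_cases = 1500, seed = 100 + sd,
      hazard = hazard_params(strength = "none"),
      outcome_prevalence = c(IHCA = 0, circulatory_shock = 0.1,
                             advanced_airway = 0, ICU_admission = 0))
    co <- generate_cohort(cfg)
    pos <- vapply(co, function(r)
      !is.na(outcome_time(r, "circulatory_shock")), logical(1))
    has_img <- vapply(co, function(r)
      any(vapply(r$events, function(e) e$modality == "image", logical(1))),
      logical(1))
    pv <- suppressWarnings(chisq.test(table(pos, has_img))$p.value)
    if (pv < 0.01) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("event timelines respect the admission-record invariants", {
  co <- generate_cohort(generator_config(n_cases = 200, seed = 25,
                                         dense_monitor_prob = 0.5))
  for (r in co) {
    tt <- vapply(r$events, function(e) e$time_min, numeric(1))
    expect_true(!is.unsorted(tt))
    expect_lte(max(tt), r$discharge_time_min)
    for (o in r$outcomes) expect_lte(o$time_min, r$discharge_time_min)
    expect_gte(length(triage_events(r)), 5)
  }
})
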