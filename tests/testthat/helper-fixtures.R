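# Shared fixture builders: tiny hand-assembled admissions and windows.

ev_sparse <- function(fid, t, v) clinical_event(fid, "sparse_tabular", t, v)

# a minimal admission: triage vitals at t=0, optional later updates and outcome
toy_record <- function(id = "A1", update_times = c(30, 90, 200),
                       outcome_at = NA, discharge = 600,
                       extra_events = list()) {
  ev <- list(ev_sparse("age", 0, 60), ev_sparse("SBP", 0, 120),
             ev_sparse("HR", 0, 80))
  for (t in update_times) {
    ev <- c(ev, list(ev_sparse("SBP", t, 115), ev_sparse("HR", t, 88)))
  }
  ev <- c(ev, extra_events)
  ev <- ev[order(vapply(ev, function(e) e$time_min, numeric(1)))]
  oo <- if (is.na(outcome_at)) list() else
    list(outcome_event("circulatory_shock", outcome_at))
  admission_record(id, 60, "F", ev, oo, discharge)
}

# random record generator for property-style tests (sparse-only, fast)
random_record <- function(id, max_updates = 6, p_outcome = 0.4,
                          discharge_max = 1500) {
  dis <- runif(1, 60, discharge_max)
  nt <- sample(0:max_updates, 1)
  ut <- sort(runif(nt, 1, dis))
  ev <- list(ev_sparse("age", 0, runif(1, 20, 90)),
             ev_sparse("SBP", 0, runif(1, 80, 180)))
  for (t in ut) ev <- c(ev, list(ev_sparse("SBP", t, runif(1, 70, 180))))
  oo <- list()
  if (runif(1) < p_outcome) {
    t_on <- runif(1, 1, dis)
    oo <- list(outcome_event("circulatory_shock", t_on))
  }
  admission_record(id, 50, "M", ev, oo, dis)
}

toy_cfg <- function(...) run_config(d_model = 8, d_classifier = 4, layers = 1,
                                    heads = 2, epochs = 1, batch_size = 8,
                                    seed = 11, ...)

# tiny trained-model fixture shared by prediction-surface tests
fit_toy_model <- function(n_cases = 60, seed = 5, epochs = 2, ...) {
  cfg <- generator_config(n_cases = n_cases, seed = seed,
                          hazard = hazard_params(strength = "strong"),
                          outcome_prevalence = c(IHCA = 0,
                                                 circulatory_shock = 0.2,
                                                 advanced_airway = 0,
                                                 ICU_admission = 0))
  co <- generate_cohort(cfg)
  rc <- run_config(d_model = 16, d_classifier = 8, layers = 1, heads = 2,
                   epochs = epochs, batch_size = 32, lr = 2e-3, seed = seed, ...)
  list(fit = fit_fusion(co, rc), cohort = co, cfg = rc)
}
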