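# Synthetic ED cohort simulator: irregular multimodal events, block
# missingness, and outcome times drawn from a planted log-linear hazard
# evaluated on the simulated vital-sign trajectory.

#' Planted-hazard parameters
#'
#' The simulator's outcome process is an inhomogeneous Poisson first-event
#' time with piecewise-constant intensity
#' `lambda(t) = lambda0 * exp(sum(coefficients * z(t)))`, where `z(t)` are
#' risk features read off the current simulated trajectory: systolic
#' hypotension depth (`sbp_dev`), tachypnea level (`rr_level`), heart-rate
#' trend slope (`hr_trend`), latest lactate elevation (`lactate`) and the
#' mental-status code (`mental_status`). `lambda0` is calibrated per outcome
#' so the achieved prevalence matches the configured target; pass
#' `baseline_rate` (events/hour) to skip calibration and use a fixed baseline
#' (achieved prevalence is then reported with a warning when far from target).
#'
#' @param coefficients Named numeric weights on the risk features.
#' @param baseline_rate Optional fixed baseline intensity, events per hour.
#' @param strength Convenience preset: `"none"` zeroes all coefficients,
#'   `"moderate"`/`"strong"` scale the default weights.
#' @return Object of class `"hazard_params"`.
#' @export
hazard_params <- function(coefficients = NULL, baseline_rate = NULL,
                          strength = c("moderate", "strong", "none")) {
  strength <- match.arg(strength)
  base <- c(sbp_dev = 0.35, rr_level = 0.30, hr_trend = 0.20,
            lactate = 0.40, mental_status = 0.30)
  if (is.null(coefficients))
    coefficients <- switch(strength, none = base * 0, moderate = base,
                           strong = base * 2.5)
  if (!is.null(baseline_rate) && baseline_rate <= 0)
    stop("baseline_rate must be > 0")
  structure(list(coefficients = coefficients, baseline_rate = baseline_rate,
                 link = "log-linear"),
            class = "hazard_params")
}

#' Generator configuration for the synthetic ED cohort
#'
#' Defaults emulate the reference cohort's coverage structure: laboratory
#' testing in ~72% of cases, chest radiography in ~66%, EKG report text in
#' ~44%, outcome prevalences of 0.2% (IHCA), 0.9% (advanced airway), 2.6%
#' (circulatory shock) and 3.5% (ICU admission), and a length-of-stay
#' distribution with ~85% of stays under 12 h. Dense monitor blocks are off
#' by default (they model the prospectively collected waveform sub-cohort);
#' set `dense_monitor_prob = 1` for time-resolution experiments.
#'
#' @param n_cases Number of admissions.
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @param vitals_interarrival_min Mean exponential gap between repeated
#'   vital-sign measurements, minutes.
#' @param lab_prob Probability a case gets laboratory testing at all.
#' @param lab_panel_prob Named per-feature inclusion probabilities within a
#'   drawn panel.
#' @param image_prob Probability of a chest-image event.
#' @param text_prob Named probabilities for the text fields
#'   (`chief_complaint`, `patient_info`, `ekg_report`).
#' @param dense_monitor_prob Probability a case carries a dense monitor block
#'   (1-minute base grid).
#' @param dense_span_min Length of the dense block in minutes (truncated at
#'   discharge).
#' @param outcome_prevalence Named target fractions per outcome task.
#' @param hazard A [hazard_params()] object.
#' @param los_meanlog,los_sdlog Lognormal length-of-stay parameters (minutes).
#' @param image_dim Side length of the procedural grayscale images.
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(n_cases = 1000L, seed = 1L,
                             vitals_interarrival_min = 60,
                             lab_prob = 0.72,
                             lab_panel_prob = c(lactate = 0.7, wbc = 0.9,
                                                hb = 0.9, platelet = 0.9,
                                                creatinine = 0.8, crp = 0.6,
                                                procalcitonin = 0.3),
                             image_prob = 0.66,
                             text_prob = c(chief_complaint = 1.0,
                                           patient_info = 1.0,
                                           ekg_report = 0.44),
                             dense_monitor_prob = 0,
                             dense_span_min = 180,
                             outcome_prevalence = c(IHCA = 0.002,
                                                    circulatory_shock = 0.026,
                                                    advanced_airway = 0.009,
                                                    ICU_admission = 0.035),
                             hazard = hazard_params(),
                             los_meanlog = log(240), los_sdlog = 0.95,
                             image_dim = 16L) {
  stopifnot(n_cases >= 1)
  probs <- c(lab_prob, lab_panel_prob, image_prob, text_prob,
             dense_monitor_prob, outcome_prevalence)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 vitals_interarrival_min = vitals_interarrival_min,
                 lab_prob = lab_prob, lab_panel_prob = lab_panel_prob,
                 image_prob = image_prob, text_prob = text_prob,
                 dense_monitor_prob = dense_monitor_prob,
                 dense_span_min = dense_span_min,
                 outcome_prevalence = outcome_prevalence,
                 hazard = hazard,
                 los_meanlog = los_meanlog, los_sdlog = los_sdlog,
                 image_dim = as.integer(image_dim)),
            class = "generator_config")
}

# vocabulary the template texts are built from (also used by the text encoder)
text_templates <- function() {
  list(
    benign = c("abdominal pain mild", "sore throat", "minor laceration hand",
               "dizziness transient", "back pain chronic", "rash itching",
               "headache mild", "sprained ankle"),
    severe = c("chest pain radiating", "dyspnea severe", "altered mentality",
               "hypotension collapse", "hemoptysis massive",
               "syncope recurrent", "sepsis suspected fever rigors"),
    ekg_benign = c("normal sinus rhythm", "sinus rhythm no acute change"),
    ekg_severe = c("sinus tachycardia st depression",
                   "atrial fibrillation rapid ventricular response",
                   "st elevation anterior leads"))
}

# per-case latent trajectory: baseline vitals plus severity-driven drift.
# Returns closures evaluated at arbitrary times (minutes).
sim_trajectory <- function(sev) {
  base <- c(SBP = rnorm(1, 134, 20), DBP = rnorm(1, 80, 12),
            HR = rnorm(1, 89, 15), RR = rnorm(1, 17.5, 2.2),
            BT = rnorm(1, 36.8, 0.5), SpO2 = min(100, rnorm(1, 97, 2)))
  ramp <- function(t) pmin(t, 480) / 480
  list(
    SBP  = function(t) base["SBP"] - 45 * sev * ramp(t),
    DBP  = function(t) base["DBP"] - 25 * sev * ramp(t),
    HR   = function(t) base["HR"] + 35 * sev * ramp(t),
    RR   = function(t) base["RR"] + 11 * sev * ramp(t),
    BT   = function(t) rep(base["BT"], length(t)),
    SpO2 = function(t) pmin(100, base["SpO2"] - 9 * sev * ramp(t)))
}

# risk features are clamped so the log-linear multiplier stays bounded even
# when two observations fall arbitrarily close in time (slope blow-up)
risk_features <- function(sbp, rr, hr_slope, lactate, mental) {
  c(sbp_dev = min(6, max(0, (110 - sbp) / 10)),
    rr_level = min(5, max(0, (rr - 20) / 4)),
    hr_trend = min(4, max(0, hr_slope / 10)),
    lactate = if (is.na(lactate)) 0 else min(6, max(0, (lactate - 2) / 2)),
    mental_status = mental)
}

# piecewise-constant unit-rate cumulative hazard for one case:
# knots tk (sorted, starting at 0), multipliers mk on [tk, t_{k+1}), end = LOS
unit_cumhaz <- function(tk, mk, los) {
  widths <- diff(c(tk, los)) / 60  # hours
  cum <- cumsum(mk * widths)
  list(tk = tk, mk = mk, cum = cum, total = cum[length(cum)])
}

# invert: first-event time for exponential deviate E under lambda0 * unit hazard
invert_hazard <- function(uh, lambda0, E, los) {
  target <- E / lambda0
  k <- which(c(0, uh$cum[-length(uh$cum)]) < target & uh$cum >= target)
  if (!length(k)) return(NA_real_)
  k <- k[1]
  prev <- if (k == 1) 0 else uh$cum[k - 1]
  t_star <- uh$tk[k] + (target - prev) / uh$mk[k] * 60
  if (t_star >= los) NA_real_ else t_star
}

#' Generate a synthetic ED cohort
#'
#' Simulates `cfg$n_cases` admissions: triage observations at t = 0 (KTAS,
#' initial vitals, mental status, demographics, chief-complaint text),
#' repeated vitals at exponential inter-arrival gaps, a random laboratory
#' panel at 1-2 draw times, text fields and a procedural chest image with the
#' configured coverage probabilities, an optional 1-minute dense monitor
#' block, and outcome onset times sampled by inversion from the planted
#' log-linear hazard evaluated on the trajectory. The baseline intensity of
#' each outcome is calibrated on the simulated trajectories so the achieved
#' prevalence hits the configured target (unless `hazard$baseline_rate` is
#' fixed, in which case a warning reports the achieved prevalence when it
#' misses the target by more than half the target).
#'
#' @param cfg A [generator_config()].
#' @return List of [admission_record()] objects.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cases
  tpl <- text_templates()
  coefs <- cfg$hazard$coefficients

  cases <- vector("list", n)
  uhs <- vector("list", n)
  for (i in seq_len(n)) {
    sev <- stats::rbeta(1, 0.7, 4)            # mostly mild, a thin severe tail
    los <- min(max(stats::rlnorm(1, cfg$los_meanlog, cfg$los_sdlog), 45), 4320)
    age <- min(max(stats::rnorm(1, 53, 20), 18), 100)
    sex <- if (stats::runif(1) < 0.468) "M" else "F"
    ktas <- sample(1:5, 1, prob = c(0.012, 0.089, 0.281, 0.491, 0.127))
    if (sev > 0.5) ktas <- min(ktas, sample(1:3, 1, prob = c(0.2, 0.5, 0.3)))
    mental <- if (sev > 0.6) sample(0:4, 1, prob = c(0.3, 0.3, 0.2, 0.1, 0.1)) else
      sample(0:1, 1, prob = c(0.985, 0.015))
    traj <- sim_trajectory(sev)

    # vital-sign update times: exponential gaps, capped
    gaps <- stats::rexp(40, rate = 1 / cfg$vitals_interarrival_min)
    vt <- cumsum(gaps); vt <- vt[vt < los]
    obs_t <- c(0, vt)
    meas <- function(fid, t) traj[[fid]](t) + stats::rnorm(length(t), 0,
      c(SBP = 4, DBP = 3, HR = 3, RR = 1, BT = 0.15, SpO2 = 1)[fid])
    vit_names <- c("SBP", "DBP", "HR", "RR", "BT", "SpO2")
    vit_vals <- sapply(vit_names, function(f) meas(f, obs_t))
    vit_vals <- matrix(vit_vals, nrow = length(obs_t))
    colnames(vit_vals) <- vit_names

    ev <- list()
    add_sparse <- function(fid, t, v)
      ev[[length(ev) + 1L]] <<- clinical_event(fid, "sparse_tabular", t, v)
    add_sparse("age", 0, age)
    add_sparse("sex_male", 0, as.numeric(sex == "M"))
    add_sparse("KTAS", 0, ktas)
    add_sparse("mental_status", 0, mental)
    add_sparse("visit_method", 0, sample(1:3, 1, prob = c(0.6, 0.3, 0.1)))
    for (k in seq_along(obs_t))
      for (f in vit_names) add_sparse(f, obs_t[k], vit_vals[k, f])
    # mental status re-assessed at later updates for sicker cases
    if (sev > 0.6 && length(obs_t) > 1)
      for (t in obs_t[-1]) add_sparse("mental_status", t,
        min(4, mental + stats::rbinom(1, 1, 0.5)))

    # labs: 1-2 draw times, random panel subset
    lab_vals <- list(); lab_t <- numeric(0)
    if (stats::runif(1) < cfg$lab_prob) {
      nlab <- sample(1:2, 1, prob = c(0.7, 0.3))
      lab_t <- sort(stats::runif(nlab, 10, max(20, min(los - 1, 300))))
      for (t in lab_t) {
        panel <- names(cfg$lab_panel_prob)[
          stats::runif(length(cfg$lab_panel_prob)) < cfg$lab_panel_prob]
        for (f in panel) {
          v <- switch(f,
            lactate = max(0.3, 1.1 + 7 * sev + stats::rnorm(1, 0, 0.5)),
            wbc = max(1, stats::rnorm(1, 9 + 6 * sev, 3)),
            hb = max(4, stats::rnorm(1, 13.5 - 2 * sev, 1.8)),
            platelet = max(10, stats::rnorm(1, 250 - 80 * sev, 70)),
            creatinine = max(0.3, stats::rnorm(1, 1 + 1.5 * sev, 0.4)),
            crp = max(0.1, stats::rnorm(1, 20 + 120 * sev, 25)),
            procalcitonin = max(0.01, stats::rnorm(1, 0.2 + 4 * sev, 0.8)))
          add_sparse(f, t, v)
          lab_vals[[f]] <- v
        }
      }
    }

    # text fields
    sev_text <- sev > 0.45
    if (stats::runif(1) < cfg$text_prob[["chief_complaint"]])
      ev[[length(ev) + 1L]] <- clinical_event("chief_complaint", "text", 0,
        sample(if (sev_text) tpl$severe else tpl$benign, 1))
    if (stats::runif(1) < cfg$text_prob[["patient_info"]])
      ev[[length(ev) + 1L]] <- clinical_event("patient_info", "text", 0,
        paste(if (sex == "M") "male" else "female",
              if (age >= 65) "elderly" else "adult",
              sample(c("hypertension", "diabetes", "no history"), 1)))
    if (stats::runif(1) < cfg$text_prob[["ekg_report"]])
      ev[[length(ev) + 1L]] <- clinical_event("ekg_report", "text",
        stats::runif(1, 5, max(10, min(los - 1, 120))),
        sample(if (sev_text) tpl$ekg_severe else tpl$ekg_benign, 1))

    # procedural chest image: noise background + central blob ~ severity
    if (stats::runif(1) < cfg$image_prob) {
      D <- cfg$image_dim
      g <- outer(seq_len(D), seq_len(D), function(r, c)
        exp(-((r - D / 2)^2 + (c - D / 2)^2) / (2 * (D / 5)^2)))
      img <- matrix(stats::rnorm(D * D, 0, 0.3), D, D) + (0.3 + 2.2 * sev) * g
      ev[[length(ev) + 1L]] <- clinical_event("chest_image", "image",
        stats::runif(1, 5, max(10, min(los - 1, 240))), img)
    }

    # dense monitor block on a 1-minute base grid (fast AR component makes
    # recency informative for the time-resolution experiment)
    dense <- NULL
    if (stats::runif(1) < cfg$dense_monitor_prob) {
      span <- min(cfg$dense_span_min, floor(los) - 1)
      if (span >= 10) {
        tg <- 0:span
        ar <- stats::filter(stats::rnorm(length(tg), 0, 3 + 8 * sev), 0.9,
                            method = "recursive")
        dense <- cbind(RR = traj$RR(tg), SBP = traj$SBP(tg) + as.numeric(ar),
                       HR = traj$HR(tg), DBP = traj$DBP(tg),
                       SpO2 = traj$SpO2(tg))
        dense <- dense + matrix(stats::rnorm(length(tg) * 5, 0, 0.8),
                                ncol = 5)
        ev[[length(ev) + 1L]] <- clinical_event("dense_vitals_block",
                                                "dense_vitals", 0, dense)
      }
    }

    # hazard knots: vitals updates + lab draws (+ 5-min dense knots)
    kt <- sort(unique(c(obs_t, lab_t)))
    if (!is.null(dense)) kt <- sort(unique(c(kt, seq(0, nrow(dense) - 1, by = 5))))
    latest_lac <- function(t) {
      if (is.null(lab_vals$lactate) || !length(lab_t) || min(lab_t) > t)
        NA_real_ else lab_vals$lactate
    }
    mk <- numeric(length(kt))
    for (k in seq_along(kt)) {
      t <- kt[k]
      if (!is.null(dense) && t <= nrow(dense) - 1) {
        sbp <- dense[floor(t) + 1, "SBP"]; rr <- dense[floor(t) + 1, "RR"]
      } else {
        j <- max(which(obs_t <= t))
        sbp <- vit_vals[j, "SBP"]; rr <- vit_vals[j, "RR"]
      }
      j <- max(which(obs_t <= t))
      hr_slope <- if (j >= 2)
        (vit_vals[j, "HR"] - vit_vals[j - 1, "HR"]) /
          (obs_t[j] - obs_t[j - 1]) * 60 else 0
      z <- risk_features(sbp, rr, hr_slope, latest_lac(t), mental)
      mk[k] <- min(exp(sum(coefs * z[names(coefs)])), 1e6)
    }
    uhs[[i]] <- unit_cumhaz(kt, mk, los)
    cases[[i]] <- list(id = sprintf("case%05d", i), age = age, sex = sex,
                       los = los, events = ev)
  }

  # calibrate baseline intensity per outcome, then invert
  totals <- vapply(uhs, function(u) u$total, numeric(1))
  E_draws <- lapply(ed_outcomes(), function(o) stats::rexp(n))
  names(E_draws) <- ed_outcomes()
  records <- vector("list", n)
  onset <- matrix(NA_real_, n, length(ed_outcomes()),
                  dimnames = list(NULL, ed_outcomes()))
  for (oc in names(cfg$outcome_prevalence)) {
    target <- cfg$outcome_prevalence[[oc]]
    if (target <= 0) next
    if (!is.null(cfg$hazard$baseline_rate)) {
      lam0 <- cfg$hazard$baseline_rate
    } else {
      f <- function(loglam) mean(1 - exp(-exp(loglam) * totals)) - target
      lam0 <- exp(stats::uniroot(f, c(-25, 10))$root)
    }
    for (i in seq_len(n))
      onset[i, oc] <- invert_hazard(uhs[[i]], lam0, E_draws[[oc]][i],
                                    cases[[i]]$los)
    achieved <- mean(!is.na(onset[, oc]))
    if (!is.null(cfg$hazard$baseline_rate) &&
        abs(achieved - target) > 0.5 * target)
      warning(sprintf(
        "outcome %s: achieved prevalence %.4f vs target %.4f (fixed baseline)",
        oc, achieved, target), call. = FALSE)
  }

  for (i in seq_len(n)) {
    oo <- list()
    for (oc in ed_outcomes())
      if (!is.na(onset[i, oc]))
        oo[[length(oo) + 1L]] <- outcome_event(oc, onset[i, oc])
    ci <- cases[[i]]
    ev <- ci$events[order(vapply(ci$events, function(e) e$time_min, numeric(1)))]
    records[[i]] <- admission_record(ci$id, ci$age, ci$sex, ev, oo, ci$los)
  }
  records
}

#' Cohort with signal planted in a single sparse feature
#'
#' A fixture for ablation-recovery experiments: the outcome hazard depends
#' only on `signal_feature` (observed for every case), and every other
#' feature is independent noise. The hazard multiplier is
#' `exp(beta * value_z)` once the feature has been observed, with `beta`
#' taken from `cfg$hazard$coefficients[["signal"]]` (default 1.5).
#'
#' With `carrier = "repeated"` the latent risk level is instead expressed
#' through every repeated measurement of `signal_feature` (each observation
#' is the latent level plus independent noise) and the hazard multiplier is
#' constant from admission. A window with more observations then permits a
#' better estimate of the latent level, so discriminability provably grows
#' with the number of accumulated observations — the fixture for
#' input-sequence-length analyses.
#'
#' @param cfg A [generator_config()]; `outcome_prevalence` supplies the
#'   calibration target for `task`.
#' @param signal_feature Sparse feature id carrying the signal (default
#'   `"lactate"`; use a vital such as `"SBP"` with `carrier = "repeated"`).
#' @param task Outcome the hazard drives.
#' @param beta Signal strength on the standardized latent value.
#' @param carrier `"single"` (one draw of the feature at triage) or
#'   `"repeated"` (noisy repeated measurements of the feature).
#' @param obs_noise_sd Measurement noise, in latent-scale units, for
#'   `carrier = "repeated"`.
#' @return List of [admission_record()] objects.
#' @export
planted_signal_cohort <- function(cfg, signal_feature = "lactate",
                                  task = "circulatory_shock", beta = 1.5,
                                  carrier = c("single", "repeated"),
                                  obs_noise_sd = 1.5) {
  carrier <- match.arg(carrier)
  if (carrier == "repeated" &&
      !signal_feature %in% c("SBP", "DBP", "HR", "RR", "BT", "SpO2"))
    stop("carrier = \"repeated\" requires a repeatedly measured vital sign ",
         "as signal_feature", call. = FALSE)
  stopifnot(inherits(cfg, "generator_config"))
  task <- match.arg(task, ed_outcomes())
  set.seed(cfg$seed)
  n <- cfg$n_cases
  tpl <- text_templates()
  target <- cfg$outcome_prevalence[[task]]
  if (is.null(target) || target <= 0) target <- 0.05

  cases <- vector("list", n); uhs <- vector("list", n)
  for (i in seq_len(n)) {
    los <- min(max(stats::rlnorm(1, cfg$los_meanlog, cfg$los_sdlog), 45), 4320)
    traj <- sim_trajectory(0)           # pure-noise physiology
    gaps <- stats::rexp(40, 1 / cfg$vitals_interarrival_min)
    vt <- cumsum(gaps); vt <- vt[vt < los]
    obs_t <- c(0, vt)
    ev <- list()
    add <- function(fid, t, v)
      ev[[length(ev) + 1L]] <<- clinical_event(fid, "sparse_tabular", t, v)
    add("age", 0, min(max(stats::rnorm(1, 53, 20), 18), 100))
    add("sex_male", 0, stats::rbinom(1, 1, 0.468))
    add("KTAS", 0, sample(1:5, 1, prob = c(0.012, 0.089, 0.281, 0.491, 0.127)))
    add("mental_status", 0, sample(0:1, 1, prob = c(0.98, 0.02)))
    zval <- stats::rnorm(1)                 # the case's latent risk level
    for (k in seq_along(obs_t))
      for (f in c("SBP", "DBP", "HR", "RR", "BT", "SpO2")) {
        v <- traj[[f]](obs_t[k]) + stats::rnorm(1, 0, 2)
        if (carrier == "repeated" && f == signal_feature)
          v <- traj[[f]](0) - 12 * (zval + stats::rnorm(1, 0, obs_noise_sd))
        add(f, obs_t[k], v)
      }
    # noise labs
    for (f in c("wbc", "hb", "creatinine"))
      if (stats::runif(1) < 0.8) add(f, stats::runif(1, 10, max(20, min(los - 1, 200))),
                                     stats::rnorm(1, 10, 3))
    if (carrier == "single") {
      # one draw at triage for every case so each window can see it;
      # standardized N(0,1) value on the hazard scale
      add(signal_feature, 0, 2 + 1.5 * zval)
    }
    ev[[length(ev) + 1L]] <- clinical_event("chief_complaint", "text", 0,
      sample(c(tpl$benign, tpl$severe), 1))

    kt <- c(0)
    mk <- c(exp(beta * zval))
    uhs[[i]] <- unit_cumhaz(kt, mk, los)
    cases[[i]] <- list(id = sprintf("sig%05d", i),
                       age = ev[[1]]$value, sex = if (ev[[2]]$value > 0) "M" else "F",
                       los = los, events = ev)
  }
  totals <- vapply(uhs, function(u) u$total, numeric(1))
  if (!is.null(cfg$hazard$baseline_rate)) {
    lam0 <- cfg$hazard$baseline_rate
  } else {
    f <- function(loglam) mean(1 - exp(-exp(loglam) * totals)) - target
    lam0 <- exp(stats::uniroot(f, c(-25, 10))$root)
  }
  E <- stats::rexp(n)
  lapply(seq_len(n), function(i) {
    ci <- cases[[i]]
    t_on <- invert_hazard(uhs[[i]], lam0, E[i], ci$los)
    oo <- if (is.na(t_on)) list() else list(outcome_event(task, t_on))
    ev <- ci$events[order(vapply(ci$events, function(e) e$time_min, numeric(1)))]
    admission_record(ci$id, ci$age, ci$sex, ev, oo, ci$los)
  })
}

#' Cohort summary table
#'
#' Per-modality observation coverage, outcome counts and percentages, and
#' length-of-stay bands (0-12 h, 12-24 h, >24 h).
#'
#' @param records List of admission records.
#' @return `data.frame` with columns `variable`, `n`, `pct`.
#' @export
summarize_cohort <- function(records) {
  stopifnot(length(records) >= 1)
  n <- length(records)
  has_feat <- function(pred) sum(vapply(records, function(r)
    any(vapply(r$events, pred, logical(1))), logical(1)))
  lab_feats <- c("lactate", "wbc", "hb", "platelet", "creatinine", "crp",
                 "procalcitonin")
  rows <- list(
    c("n_cases", n, 100),
    c("laboratory_test", has_feat(function(e) e$feature_id %in% lab_feats), NA),
    c("chest_xray", has_feat(function(e) e$modality == "image"), NA),
    c("ekg_report", has_feat(function(e) e$feature_id == "ekg_report"), NA),
    c("dense_monitor", has_feat(function(e) e$modality == "dense_vitals"), NA))
  los <- vapply(records, function(r) r$discharge_time_min, numeric(1))
  rows <- c(rows, list(
    c("los_0_12h", sum(los <= 720), NA),
    c("los_12_24h", sum(los > 720 & los <= 1440), NA),
    c("los_over_24h", sum(los > 1440), NA)))
  for (oc in ed_outcomes()) {
    cnt <- sum(vapply(records, function(r) !is.na(outcome_time(r, oc)),
                      logical(1)))
    rows <- c(rows, list(c(oc, cnt, NA)))
  }
  df <- data.frame(variable = vapply(rows, `[`, character(1), 1),
                   n = as.numeric(vapply(rows, `[`, character(1), 2)),
                   stringsAsFactors = FALSE)
  df$pct <- round(100 * df$n / n, 1)
  df
}
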