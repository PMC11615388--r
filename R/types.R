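# Domain types: clinical events, outcome events, admission records, run config.

#' Modality, outcome and dense-channel constants
#'
#' `ed_modalities()` returns the four supported input modalities,
#' `ed_outcomes()` the four deterioration outcome tasks, and
#' `ed_dense_channels()` the fixed channel order of dense monitor blocks
#' (respiratory rate, systolic blood pressure, heart rate, diastolic blood
#' pressure, arterial oxygen saturation).
#'
#' @return Character vector.
#' @export
ed_modalities <- function() c("sparse_tabular", "dense_vitals", "image", "text")

#' @rdname ed_modalities
#' @export
ed_outcomes <- function() c("IHCA", "circulatory_shock", "advanced_airway", "ICU_admission")

#' @rdname ed_modalities
#' @export
ed_dense_channels <- function() c("RR", "SBP", "HR", "DBP", "SpO2")

#' Construct a single timed clinical observation
#'
#' A `clinical_event` is one observation in an admission's event stream:
#' a feature identifier, its modality, the acquisition time in minutes since
#' ED admission, and a value payload whose shape depends on the modality:
#' a finite scalar for `sparse_tabular`, a `t_dense x 5` numeric matrix for
#' `dense_vitals` (channels in the order of [ed_dense_channels()]), an
#' `H x W` numeric matrix for `image`, and a character string for `text`.
#'
#' @param feature_id Character feature key, e.g. `"SBP"`, `"lactate"`,
#'   `"chief_complaint"`, `"chest_image"`, `"dense_vitals_block"`.
#' @param modality One of [ed_modalities()].
#' @param time_min Acquisition time, minutes since admission (`>= 0`).
#' @param value Payload matching the modality (see Details).
#' @return An object of class `"clinical_event"`.
#' @export
clinical_event <- function(feature_id, modality, time_min, value) {
  modality <- match.arg(modality, ed_modalities())
  if (!is.character(feature_id) || length(feature_id) != 1L || !nzchar(feature_id))
    stop("feature_id must be a non-empty string", call. = FALSE)
  if (!is.numeric(time_min) || length(time_min) != 1L || is.na(time_min) || time_min < 0)
    stop("time_min must be a single non-negative number", call. = FALSE)
  value <- switch(modality,
    sparse_tabular = {
      if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
        stop("sparse_tabular value must be a finite scalar for feature ",
             feature_id, call. = FALSE)
      as.numeric(value)
    },
    dense_vitals = {
      value <- as.matrix(value)
      if (ncol(value) != 5L)
        stop("dense_vitals value must have 5 channels (",
             paste(ed_dense_channels(), collapse = ", "), ")", call. = FALSE)
      storage.mode(value) <- "double"
      value
    },
    image = {
      value <- as.matrix(value)
      storage.mode(value) <- "double"
      value
    },
    text = {
      if (!is.character(value) || length(value) != 1L)
        stop("text value must be a single character string", call. = FALSE)
      value
    })
  structure(list(feature_id = feature_id, modality = modality,
                 time_min = as.numeric(time_min), value = value),
            class = "clinical_event")
}

#' Construct an outcome event
#'
#' @param outcome_id One of [ed_outcomes()].
#' @param time_min Onset time in minutes since admission (`> 0`).
#' @return An object of class `"outcome_event"`.
#' @export
outcome_event <- function(outcome_id, time_min) {
  outcome_id <- match.arg(outcome_id, ed_outcomes())
  if (!is.numeric(time_min) || length(time_min) != 1L || is.na(time_min) || time_min <= 0)
    stop("outcome time_min must be a single positive number", call. = FALSE)
  structure(list(outcome_id = outcome_id, time_min = as.numeric(time_min)),
            class = "outcome_event")
}

#' Construct one ED admission record
#'
#' Bundles the admission's timed events (triage observations sit at
#' `time_min = 0`), its outcome events (only the first occurrence per outcome
#' is retained) and the discharge time. Events are sorted by time; unsorted
#' input is auto-sorted with a warning. Invariants enforced: all event times
#' `<= discharge_time_min`, all outcome times in `(0, discharge_time_min]`.
#'
#' @param admission_id Character id.
#' @param age_years,sex Demographics; `sex` is `"M"` or `"F"`.
#' @param events List of [clinical_event()] objects.
#' @param outcomes List of [outcome_event()] objects (possibly empty).
#' @param discharge_time_min Discharge time, minutes since admission.
#' @return Object of class `"admission_record"`.
#' @export
admission_record <- function(admission_id, age_years, sex, events, outcomes,
                             discharge_time_min) {
  stopifnot(is.character(admission_id), length(admission_id) == 1L)
  sex <- match.arg(sex, c("M", "F"))
  if (!is.list(events)) stop("events must be a list of clinical_event")
  times <- vapply(events, function(e) e$time_min, numeric(1))
  if (is.unsorted(times)) {
    warning("events for admission ", admission_id,
            " not sorted by time; auto-sorting", call. = FALSE)
    events <- events[order(times)]
    times <- sort(times)
  }
  if (length(times) && max(times) > discharge_time_min)
    stop("event time exceeds discharge_time_min in admission ", admission_id,
         call. = FALSE)
  # first occurrence only, per outcome id
  if (length(outcomes)) {
    oid <- vapply(outcomes, function(o) o$outcome_id, character(1))
    ot  <- vapply(outcomes, function(o) o$time_min, numeric(1))
    keep <- !duplicated(oid[order(ot)])
    outcomes <- outcomes[order(ot)][keep]
    ot <- vapply(outcomes, function(o) o$time_min, numeric(1))
    if (any(ot > discharge_time_min))
      stop("outcome time after discharge in admission ", admission_id, call. = FALSE)
  }
  structure(list(admission_id = admission_id,
                 age_years = as.numeric(age_years), sex = sex,
                 events = events, outcomes = outcomes,
                 discharge_time_min = as.numeric(discharge_time_min)),
            class = "admission_record")
}

#' @export
print.admission_record <- function(x, ...) {
  cat("<admission_record ", x$admission_id, "> ", length(x$events), " events, ",
      length(x$outcomes), " outcome(s), discharge at ",
      round(x$discharge_time_min, 1), " min\n", sep = "")
  invisible(x)
}

#' Triage events of an admission
#'
#' Events acquired at ED arrival (`time_min == 0`).
#' @param record An [admission_record()].
#' @return List of clinical events at time zero.
#' @export
triage_events <- function(record) {
  Filter(function(e) e$time_min == 0, record$events)
}

#' First onset time of an outcome task
#'
#' @param record An [admission_record()].
#' @param task One of [ed_outcomes()].
#' @return Onset time in minutes, or `NA_real_` if the outcome never occurs.
#' @export
outcome_time <- function(record, task) {
  task <- match.arg(task, ed_outcomes())
  for (o in record$outcomes) if (o$outcome_id == task) return(o$time_min)
  NA_real_
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [run_config()]
#' (unknown keys are rejected); `physiological_limits` may be given as a
#' map of two-element lists.
#'
#' @param path YAML file path.
#' @return A validated [run_config()] object.
#' @export
run_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$physiological_limits))
    y$physiological_limits <- lapply(y$physiological_limits, unlist)
  do.call(run_config, y)
}

#' Default physiological plausibility limits
#'
#' Per-feature (lower, upper) clamping bounds used to tame transcription
#' outliers in vital signs and laboratory values. The bounds are editorial
#' defaults spanning the physiologically survivable range of each variable;
#' they are a configuration table, not a fixed constant — pass your own map
#' to [run_config()] to override.
#'
#' @return Named list of `c(lower, upper)` numeric pairs.
#' @export
default_physiological_limits <- function() {
  list(
    SBP = c(40, 300), DBP = c(20, 200), HR = c(20, 300), RR = c(4, 60),
    BT = c(30, 43), SpO2 = c(50, 100),
    lactate = c(0, 30), wbc = c(0, 500), hb = c(1, 25), platelet = c(1, 2000),
    creatinine = c(0, 30), crp = c(0, 600), procalcitonin = c(0, 200),
    age = c(18, 110), KTAS = c(1, 5), mental_status = c(0, 4)
  )
}

#' Run configuration for windowing, embedding, fusion and training
#'
#' Collects every tunable of the pipeline. Defaults follow the reference
#' design: 12 hourly horizons (60..720 min), hidden width 256, an 8:2
#' train/test split, and 10-minute discretization of dense monitor data.
#' Desk-scale experiments typically pass a smaller `d_model`.
#'
#' @param d_model Token/hidden width shared by all modality embedders.
#' @param horizons_min Strictly increasing look-ahead horizons in minutes.
#' @param step `"step1_triage"` (triage-only window) or `"step2_posttriage"`.
#' @param modality_set Subset of [ed_modalities()] admitted into token sets.
#' @param outcome_task One of [ed_outcomes()].
#' @param split_ratio Train fraction in (0, 1).
#' @param seed Integer seed governing all randomized stages.
#' @param physiological_limits Named list of `c(lower, upper)` bounds.
#' @param dense_resample_min Discretization interval (minutes) for dense
#'   monitor blocks; the generator's base grid is 1 minute.
#' @param dense_updates Should dense-grid points count as data updates
#'   (spawn prediction windows) in step 2?
#' @param time_scale_min Normalization scale for the time-difference input of
#'   the time embedder.
#' @param layers,heads,ff_mult Transformer encoder depth, attention heads and
#'   feed-forward width multiplier.
#' @param d_classifier Hidden width of the two-layer classifier head.
#' @param lr,epochs,batch_size Adam learning rate, training epochs, minibatch
#'   size.
#' @param sampling `"windowwise_oversample"`, `"casewise_balance"` or `"none"`.
#' @param oversample_ratio Target positive:negative ratio for window-wise
#'   oversampling.
#' @param case_cap Per-record per-batch window cap for case-wise balancing.
#' @param threshold Probability threshold for confusion-matrix metrics.
#' @return Object of class `"run_config"` (a validated list).
#' @export
run_config <- function(d_model = 256L,
                       horizons_min = seq(60, 720, by = 60),
                       step = c("step2_posttriage", "step1_triage"),
                       modality_set = ed_modalities(),
                       outcome_task = "circulatory_shock",
                       split_ratio = 0.8,
                       seed = 1L,
                       physiological_limits = default_physiological_limits(),
                       dense_resample_min = 10,
                       dense_updates = TRUE,
                       time_scale_min = 720,
                       layers = 2L, heads = 4L, ff_mult = 2L,
                       d_classifier = 64L,
                       lr = 1e-3, epochs = 6L, batch_size = 64L,
                       sampling = c("windowwise_oversample", "casewise_balance", "none"),
                       oversample_ratio = 1.0,
                       case_cap = 4L,
                       threshold = 0.5) {
  step <- match.arg(step)
  sampling <- match.arg(sampling)
  outcome_task <- match.arg(outcome_task, ed_outcomes())
  modality_set <- match.arg(modality_set, ed_modalities(), several.ok = TRUE)
  if (any(diff(horizons_min) <= 0)) stop("horizons_min must be strictly increasing")
  if (split_ratio <= 0 || split_ratio >= 1) stop("split_ratio must be in (0, 1)")
  for (nm in names(physiological_limits)) {
    b <- physiological_limits[[nm]]
    if (length(b) != 2L || b[1] >= b[2])
      stop("physiological limit for ", nm, " must satisfy lower < upper")
  }
  if (d_model %% heads != 0) stop("d_model must be divisible by heads")
  structure(list(d_model = as.integer(d_model),
                 horizons_min = as.numeric(horizons_min),
                 step = step, modality_set = modality_set,
                 outcome_task = outcome_task,
                 split_ratio = split_ratio, seed = as.integer(seed),
                 physiological_limits = physiological_limits,
                 dense_resample_min = dense_resample_min,
                 dense_updates = isTRUE(dense_updates),
                 time_scale_min = time_scale_min,
                 layers = as.integer(layers), heads = as.integer(heads),
                 ff_mult = as.integer(ff_mult),
                 d_classifier = as.integer(d_classifier),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 sampling = sampling, oversample_ratio = oversample_ratio,
                 case_cap = as.integer(case_cap), threshold = threshold),
            class = "run_config")
}
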