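# Per-event prediction windows with 12-horizon binary labels.

#' Label one prediction window across look-ahead horizons
#'
#' Element `h` is 1 iff the outcome occurs within `(t_ref, t_ref + horizons[h]]`
#' — the half-open convention: an onset exactly at a horizon boundary counts
#' as positive; an onset at (or before) the reference time violates the
#' windows-precede-onset contract and raises an error. The returned vector is
#' monotone non-decreasing across horizons by construction.
#'
#' @param reference_time_min Window reference time (latest data update).
#' @param outcome_time_min Onset time, or `NA`/`NULL` if no outcome.
#' @param horizons_min Ascending horizons in minutes (default hourly 60..720).
#' @return Integer 0/1 vector, one element per horizon.
#' @export
label_window <- function(reference_time_min, outcome_time_min,
                         horizons_min = seq(60, 720, by = 60)) {
  if (any(diff(horizons_min) <= 0)) stop("horizons must be strictly increasing")
  if (is.null(outcome_time_min) || is.na(outcome_time_min))
    return(integer(length(horizons_min)))
  dt <- outcome_time_min - reference_time_min
  if (dt <= 0)
    stop("outcome_time_min must be strictly after reference_time_min ",
         "(windows exist only before onset)", call. = FALSE)
  as.integer(dt <= horizons_min)
}

# distinct data-update times of a record, in [0, endpoint)
update_times <- function(record, endpoint, cfg) {
  tt <- vapply(record$events, function(e) e$time_min, numeric(1))
  mod <- vapply(record$events, function(e) e$modality, character(1))
  keep <- mod != "dense_vitals"
  tt <- tt[keep]
  if (cfg$dense_updates && cfg$step == "step2_posttriage") {
    for (e in record$events) if (e$modality == "dense_vitals") {
      step <- cfg$dense_resample_min
      grid <- seq(0, nrow(e$value) - 1) # base 1-min grid
      grid <- grid[grid %% step == 0]
      tt <- c(tt, e$time_min + grid)
    }
  }
  tt <- sort(unique(c(0, tt)))
  tt[tt < endpoint]
}

# truncate a record's events to those acquired at or before t_ref;
# dense blocks are row-truncated to grid points <= t_ref and resampled
truncate_events <- function(events, t_ref, cfg) {
  out <- list()
  for (e in events) {
    if (e$modality == "dense_vitals") {
      if (e$time_min > t_ref) next
      avail <- floor(t_ref - e$time_min) + 1     # rows on the 1-min base grid
      avail <- min(avail, nrow(e$value))
      if (avail < 1) next
      v <- e$value[seq_len(avail), , drop = FALSE]
      step <- cfg$dense_resample_min
      if (step > 1) {
        keep <- which((seq_len(avail) - 1) %% step == 0)
        v <- v[keep, , drop = FALSE]
      }
      e$value <- v
      attr(e$value, "step_min") <- max(1, cfg$dense_resample_min)
      out[[length(out) + 1L]] <- e
    } else if (e$time_min <= t_ref) {
      out[[length(out) + 1L]] <- e
    }
  }
  out
}

#' Extract per-event prediction windows from one admission
#'
#' One window per distinct data-update time in `[0, endpoint)`, where the
#' endpoint is the onset of the task outcome when present and discharge
#' otherwise. The first window holds only the admission (triage) data; each
#' later window holds the union of all events acquired at or before its
#' reference time. `step1_triage` restricts output to the t = 0 window.
#' Events sharing one timestamp form a single update. With
#' `cfg$dense_updates`, dense monitor grid points (at the configured
#' resampling interval) also count as updates in step 2.
#'
#' @param record An [admission_record()].
#' @param task Outcome task from [ed_outcomes()].
#' @param cfg A [run_config()].
#' @return List of `prediction_window` objects: fields `admission_id`,
#'   `reference_time_min`, `events`, `labels`, `is_from_positive_case`.
#' @export
extract_windows <- function(record, task = cfg$outcome_task, cfg = run_config()) {
  task <- match.arg(task, ed_outcomes())
  if (!length(record$events)) {
    warning("record ", record$admission_id, " has no events; no windows",
            call. = FALSE)
    return(list())
  }
  t_out <- outcome_time(record, task)
  endpoint <- if (is.na(t_out)) record$discharge_time_min else t_out
  ut <- update_times(record, endpoint, cfg)
  if (cfg$step == "step1_triage") ut <- ut[ut == 0]
  lapply(ut, function(tr) {
    structure(list(
      admission_id = record$admission_id,
      reference_time_min = tr,
      events = truncate_events(record$events, tr, cfg),
      labels = label_window(tr, t_out, cfg$horizons_min),
      is_from_positive_case = !is.na(t_out)),
      class = "prediction_window")
  })
}

#' @export
print.prediction_window <- function(x, ...) {
  cat("<prediction_window ", x$admission_id, " @ ",
      round(x$reference_time_min, 1), " min> ", length(x$events),
      " events, labels ", paste(x$labels, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Brute-force label oracle
#'
#' Independent recomputation of the window labels of one admission: for every
#' distinct update time before the endpoint and every horizon, the outcome
#' list is scanned directly. O(windows x horizons); intended for testing
#' [extract_windows()] / [label_window()].
#'
#' @inheritParams extract_windows
#' @return List of integer label vectors, one per window.
#' @export
label_oracle <- function(record, task = cfg$outcome_task, cfg = run_config()) {
  task <- match.arg(task, ed_outcomes())
  t_out <- NA_real_
  for (o in record$outcomes) if (o$outcome_id == task) t_out <- o$time_min
  endpoint <- if (is.na(t_out)) record$discharge_time_min else t_out
  ut <- update_times(record, endpoint, cfg)
  if (cfg$step == "step1_triage") ut <- ut[ut == 0]
  lapply(ut, function(tr) {
    lab <- integer(length(cfg$horizons_min))
    for (h in seq_along(cfg$horizons_min)) {
      hit <- 0L
      for (o in record$outcomes) {
        if (o$outcome_id != task) next
        if (o$time_min > tr && o$time_min <= tr + cfg$horizons_min[h]) hit <- 1L
      }
      lab[h] <- hit
    }
    lab
  })
}

#' Extract windows for a whole cohort
#'
#' @param records List of admission records.
#' @inheritParams extract_windows
#' @return A `window_set`: list with `windows`, `sampling_mode`, and
#'   `class_counts` (a window is positive when any horizon label is 1).
#' @export
cohort_windows <- function(records, task = cfg$outcome_task, cfg = run_config()) {
  ws <- unlist(lapply(records, extract_windows, task = task, cfg = cfg),
               recursive = FALSE)
  window_set(ws, sampling_mode = "none")
}

window_set <- function(windows, sampling_mode = "none") {
  pos <- vapply(windows, function(w) any(w$labels == 1L), logical(1))
  structure(list(windows = windows, sampling_mode = sampling_mode,
                 class_counts = c(pos = sum(pos), neg = sum(!pos))),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> ", length(x$windows), " windows (",
      x$class_counts["pos"], " pos / ", x$class_counts["neg"],
      " neg), sampling: ", x$sampling_mode, "\n", sep = "")
  invisible(x)
}

#' Window-wise minority oversampling
#'
#' Duplicates minority-class windows (sampling with replacement,
#' deterministic given `seed`) until the positive:negative ratio reaches at
#' least `target_ratio`. All original windows are retained; the multiset of
#' distinct windows is unchanged.
#'
#' @param ws A `window_set` with at least one window of each class.
#' @param target_ratio Target positive:negative ratio (default 1.0).
#' @param seed Integer seed.
#' @return A `window_set` with `sampling_mode = "windowwise_oversample"`.
#' @export
oversample_windowwise <- function(ws, target_ratio = 1.0, seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  pos <- vapply(ws$windows, function(w) any(w$labels == 1L), logical(1))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L) stop("no positive windows to oversample", call. = FALSE)
  if (n_neg == 0L) stop("no negative windows present", call. = FALSE)
  out <- ws$windows
  set.seed(seed)
  if (n_pos / n_neg < target_ratio) {
    need <- ceiling(target_ratio * n_neg) - n_pos
    extra <- sample(which(pos), need, replace = TRUE)
    out <- c(out, ws$windows[extra])
  }
  window_set(out, sampling_mode = "windowwise_oversample")
}

#' Case-wise balanced mini-batches
#'
#' The alternative imbalance regime for small cohorts: each mini-batch draws
#' windows from several positive-source and several negative-source cases
#' (equal expected numbers of each), with a per-record per-batch cap so no
#' single long-stay admission dominates a batch. Deterministic given `seed`.
#'
#' @param ws A `window_set` whose windows come from >= 1 positive and >= 1
#'   negative case.
#' @param batch_size Windows per batch.
#' @param cap Maximum windows contributed by one admission per batch.
#' @param n_batches Number of batches to emit.
#' @param seed Integer seed.
#' @return List of integer index vectors into `ws$windows`.
#' @export
balance_casewise <- function(ws, batch_size = 32L, cap = 4L, n_batches = 50L,
                             seed = 1L) {
  stopifnot(inherits(ws, "window_set"))
  ids <- vapply(ws$windows, function(w) w$admission_id, character(1))
  posc <- vapply(ws$windows, function(w) w$is_from_positive_case, logical(1))
  pos_cases <- unique(ids[posc]); neg_cases <- unique(ids[!posc])
  if (!length(pos_cases)) stop("no positive-outcome cases", call. = FALSE)
  if (!length(neg_cases)) stop("no negative-outcome cases", call. = FALSE)
  by_case <- split(seq_along(ids), ids)
  set.seed(seed)
  half <- batch_size %/% 2L
  per_case <- max(1L, min(cap, half))
  lapply(seq_len(n_batches), function(b) {
    pick_side <- function(case_pool, n_slots) {
      need_cases <- ceiling(n_slots / per_case)
      cs <- sample(case_pool, min(need_cases, length(case_pool)),
                   replace = length(case_pool) < need_cases)
      idx <- integer(0)
      for (cid in cs) {
        avail <- by_case[[cid]]
        k <- min(per_case, length(avail), n_slots - length(idx))
        if (k <= 0) break
        idx <- c(idx, sample(avail, k, replace = FALSE))
      }
      idx
    }
    c(pick_side(pos_cases, half), pick_side(neg_cases, batch_size - half))
  })
}
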