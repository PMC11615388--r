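# Cohort serialization (JSONL dialect), outlier clipping, cohort splitting.

event_to_list <- function(e) {
  val <- if (e$modality %in% c("dense_vitals", "image")) {
    # nested row-major arrays; shape restored on read
    unname(apply(e$value, 1L, function(r) as.numeric(r), simplify = FALSE))
  } else e$value
  list(feature_id = e$feature_id, modality = e$modality,
       time_min = e$time_min, value = val)
}

list_to_event <- function(x, line) {
  for (f in c("feature_id", "modality", "time_min", "value"))
    if (is.null(x[[f]])) stop("schema error at line ", line,
                              ": event missing field '", f, "'", call. = FALSE)
  val <- x$value
  if (x$modality %in% c("dense_vitals", "image")) {
    if (is.list(val)) val <- do.call(rbind, lapply(val, as.numeric))
    val <- as.matrix(val)
  }
  clinical_event(x$feature_id, x$modality, x$time_min, val)
}

#' Write a cohort to newline-delimited JSON
#'
#' One admission per line with keys `admission_id`, `age`, `sex`,
#' `discharge_time_min`, `events` and `outcomes`. Matrix payloads
#' (dense vitals, images) are inlined as nested arrays; full double precision
#' is kept so that write/read round-trips are exact.
#'
#' @param records List of [admission_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    obj <- list(admission_id = r$admission_id, age = r$age_years, sex = r$sex,
                discharge_time_min = r$discharge_time_min,
                events = lapply(r$events, event_to_list),
                outcomes = lapply(r$outcomes, function(o)
                  list(outcome_id = o$outcome_id, time_min = o$time_min)))
    # 17 significant digits: doubles survive the decimal round-trip bitwise
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                null = "null"), con)
  }
  invisible(path)
}

#' Read a cohort from disk
#'
#' Reads the JSONL dialect written by [write_cohort()] (`schema = "jsonl"`),
#' or a directory of per-modality CSVs (`schema = "csv_dir"`) holding
#' `admissions.csv` (admission_id, age, sex, discharge_time_min),
#' `sparse.csv` (admission_id, feature_id, time_min, value),
#' optional `text.csv` (admission_id, feature_id, time_min, value) and
#' `outcomes.csv` (admission_id, outcome_id, time_min).
#'
#' Records are validated on construction: events are auto-sorted by time with
#' a warning if needed; missing required fields raise a schema error naming
#' the field and line.
#'
#' @param path File (jsonl) or directory (csv_dir).
#' @param schema `"jsonl"` (default) or `"csv_dir"`.
#' @return List of [admission_record()] objects.
#' @examples
#' path <- system.file("extdata", "synthetic_cohort_example.jsonl",
#'                     package = "edfuse")
#' cohort <- read_cohort(path)
#' summarize_cohort(cohort)
#' @export
read_cohort <- function(path, schema = c("jsonl", "csv_dir")) {
  schema <- match.arg(schema)
  if (schema == "csv_dir") return(read_cohort_csv_dir(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    for (f in c("admission_id", "age", "sex", "discharge_time_min"))
      if (is.null(x[[f]])) stop("schema error at line ", i,
                                ": missing field '", f, "'", call. = FALSE)
    events <- lapply(x$events, list_to_event, line = i)
    outcomes <- lapply(x$outcomes, function(o) {
      if (is.null(o$outcome_id) || is.null(o$time_min))
        stop("schema error at line ", i, ": malformed outcome", call. = FALSE)
      outcome_event(o$outcome_id, o$time_min)
    })
    out[[i]] <- tryCatch(
      admission_record(x$admission_id, x$age, x$sex, events, outcomes,
                       x$discharge_time_min),
      error = function(e) stop("invalid record '", x$admission_id,
                               "' at line ", i, ": ", conditionMessage(e),
                               call. = FALSE))
  }
  out
}

read_cohort_csv_dir <- function(dir) {
  adm <- utils::read.csv(file.path(dir, "admissions.csv"),
                         stringsAsFactors = FALSE)
  sp  <- utils::read.csv(file.path(dir, "sparse.csv"), stringsAsFactors = FALSE)
  txp <- file.path(dir, "text.csv")
  txt <- if (file.exists(txp))
    utils::read.csv(txp, stringsAsFactors = FALSE) else NULL
  ocp <- file.path(dir, "outcomes.csv")
  oc  <- if (file.exists(ocp))
    utils::read.csv(ocp, stringsAsFactors = FALSE) else NULL
  lapply(seq_len(nrow(adm)), function(i) {
    id <- adm$admission_id[i]
    ev <- lapply(which(sp$admission_id == id), function(j)
      clinical_event(sp$feature_id[j], "sparse_tabular", sp$time_min[j],
                     sp$value[j]))
    if (!is.null(txt))
      ev <- c(ev, lapply(which(txt$admission_id == id), function(j)
        clinical_event(txt$feature_id[j], "text", txt$time_min[j],
                       txt$value[j])))
    oo <- if (is.null(oc)) list() else
      lapply(which(oc$admission_id == id), function(j)
        outcome_event(oc$outcome_id[j], oc$time_min[j]))
    ev <- ev[order(vapply(ev, function(e) e$time_min, numeric(1)))]
    admission_record(id, adm$age[i], adm$sex[i], ev, oo,
                     adm$discharge_time_min[i])
  })
}

#' Clamp a clinical event into physiological range
#'
#' Scalar (`sparse_tabular`) values and dense-vitals channels are clamped
#' elementwise into their `(lower, upper)` bounds; image and text events pass
#' through unchanged, as does any feature absent from `limits`. Clipping is
#' idempotent.
#'
#' @param event A [clinical_event()].
#' @param limits Named list of `c(lower, upper)` pairs, e.g.
#'   [default_physiological_limits()]. Dense channels are looked up under the
#'   names in [ed_dense_channels()].
#' @return The (possibly clamped) event.
#' @export
clip_physiological <- function(event, limits = default_physiological_limits()) {
  if (event$modality == "sparse_tabular") {
    b <- limits[[event$feature_id]]
    if (!is.null(b)) event$value <- min(max(event$value, b[1]), b[2])
  } else if (event$modality == "dense_vitals") {
    ch <- ed_dense_channels()
    for (k in seq_along(ch)) {
      b <- limits[[ch[k]]]
      if (!is.null(b)) event$value[, k] <- pmin(pmax(event$value[, k], b[1]), b[2])
    }
  }
  event
}

#' Apply physiological clipping to every event of a cohort
#'
#' @param records List of admission records.
#' @param limits See [clip_physiological()].
#' @return The cohort with clamped numeric payloads.
#' @export
clip_cohort <- function(records, limits = default_physiological_limits()) {
  lapply(records, function(r) {
    r$events <- lapply(r$events, clip_physiological, limits = limits)
    r
  })
}

#' Split a cohort into train and test sets at the case level
#'
#' Random, deterministic given `seed`; no admission appears in both sets and
#' the train size is `round(ratio * N)`. With `stratify_outcome` set, positive
#' and negative cases for that outcome are split separately so prevalence is
#' preserved within one case.
#'
#' @param records List of admission records (`>= 2`).
#' @param ratio Train fraction in (0, 1).
#' @param seed Integer seed.
#' @param stratify_outcome Optional outcome id from [ed_outcomes()].
#' @return List with elements `train` and `test`.
#' @export
split_cohort <- function(records, ratio = 0.8, seed = 1L,
                         stratify_outcome = NULL) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)", call. = FALSE)
  if (length(records) < 2L) stop("need at least 2 records to split", call. = FALSE)
  n <- length(records)
  rng <- local({ set.seed(seed); runif(n) })
  if (is.null(stratify_outcome)) {
    idx <- order(rng)
    n_train <- round(ratio * n)
    train_idx <- idx[seq_len(n_train)]
  } else {
    pos <- vapply(records, function(r) !is.na(outcome_time(r, stratify_outcome)),
                  logical(1))
    train_idx <- integer(0)
    for (grp in list(which(pos), which(!pos))) {
      if (!length(grp)) next
      idx <- grp[order(rng[grp])]
      train_idx <- c(train_idx, idx[seq_len(round(ratio * length(grp)))])
    }
  }
  list(train = records[sort(train_idx)],
       test = records[sort(setdiff(seq_len(n), train_idx))])
}
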