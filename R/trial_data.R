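#' Canonical baseline covariates
#'
#' Short names accepted in aggregate-target configurations, mapped to the
#' columns of the subject table. `male` and `white` are 0/1 indicators; the
#' remaining covariates are continuous baseline measurements.
#'
#' @keywords internal
COVARIATE_COLUMNS <- c(
  age       = "age",
  male      = "male",
  white     = "white",
  egfr      = "egfr_baseline",
  upcr      = "upcr_baseline",
  uacr      = "uacr_baseline",
  uprot24h  = "uprot24h_baseline"
)

ARM_LEVELS <- c("control", "active")
EVENT_TYPES <- c("egfr40_confirmed", "eskd", "death", "censored")

#' Construct a validated IPD object
#'
#' Bundles one trial's individual patient data as two tables: a subject table
#' (one row per subject: arm, baseline covariates, optional terminal event)
#' and a visit table (one row per subject-visit: post-baseline eGFR, UPCR and
#' UACR measurements, possibly missing).
#'
#' @param subjects data.frame with columns `subject_id`, `trial_id`, `arm`
#'   (`"active"`/`"control"`), `age`, `male`, `white`, `egfr_baseline`,
#'   `upcr_baseline`, `uacr_baseline`, `uprot24h_baseline`, and optionally
#'   `event_time` (months) and `event_type`.
#' @param visits data.frame with columns `subject_id`, `timepoint` (months)
#'   and at least one of `egfr`, `upcr`, `uacr`.
#' @return An object of class `maic_ipd`.
#' @export
maic_ipd <- function(subjects, visits) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  visits <- as.data.frame(visits, stringsAsFactors = FALSE)

  need <- c("subject_id", "trial_id", "arm", unname(COVARIATE_COLUMNS))
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0)
    stop_maic("subject table is missing column(s): ", paste(miss, collapse = ", "))
  if (!"event_time" %in% names(subjects)) subjects$event_time <- NA_real_
  if (!"event_type" %in% names(subjects)) subjects$event_type <- NA_character_
  subjects$event_type <- as.character(subjects$event_type)
  subjects$trial_id <- as.character(subjects$trial_id)

  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$arm <- as.character(subjects$arm)
  if (anyDuplicated(subjects$subject_id))
    stop_maic("duplicate subject_id in subject table")
  if (!all(subjects$arm %in% ARM_LEVELS))
    stop_maic("arm must be one of: ", paste(ARM_LEVELS, collapse = ", "))
  bad_ev <- !is.na(subjects$event_type) & !subjects$event_type %in% EVENT_TYPES
  if (any(bad_ev))
    stop_maic("unknown event_type: ", paste(unique(subjects$event_type[bad_ev]), collapse = ", "))

  for (col in c("age", "egfr_baseline", "upcr_baseline", "uacr_baseline",
                "uprot24h_baseline", "event_time")) {
    v <- subjects[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad) > 0)
        stop_maic("non-numeric value in '", col, "' at subject row ", bad[1])
      subjects[[col]] <- as.numeric(v)
    }
  }
  subjects$male <- as.integer(subjects$male)
  subjects$white <- as.integer(subjects$white)
  if (any(subjects$age <= 0, na.rm = TRUE)) stop_maic("age must be positive")
  if (any(subjects$egfr_baseline <= 0, na.rm = TRUE))
    stop_maic("egfr_baseline must be positive")
  for (col in c("upcr_baseline", "uacr_baseline", "uprot24h_baseline"))
    if (any(subjects[[col]] < 0, na.rm = TRUE))
      stop_maic(col, " must be non-negative")
  if (any(subjects$event_time < 0, na.rm = TRUE))
    stop_maic("event_time must be non-negative")
  if (!all(subjects$male %in% c(0L, 1L, NA)) || !all(subjects$white %in% c(0L, 1L, NA)))
    stop_maic("male/white must be 0/1 indicators")

  need_v <- c("subject_id", "timepoint")
  miss <- setdiff(need_v, names(visits))
  if (length(miss) > 0)
    stop_maic("visit table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("egfr", "upcr", "uacr"))
    if (!col %in% names(visits)) visits[[col]] <- NA_real_
  visits$subject_id <- as.character(visits$subject_id)
  visits$timepoint <- as.numeric(visits$timepoint)
  for (col in c("egfr", "upcr", "uacr")) visits[[col]] <- as.numeric(visits[[col]])

  orphan <- setdiff(visits$subject_id, subjects$subject_id)
  if (length(orphan) > 0)
    stop_maic("visit rows reference unknown subject(s): ",
              paste(utils::head(orphan, 3), collapse = ", "))
  key <- paste(visits$subject_id, visits$timepoint)
  if (anyDuplicated(key))
    stop_maic("duplicate (subject, timepoint) pair: ", key[duplicated(key)][1])
  all_missing <- is.na(visits$egfr) & is.na(visits$upcr) & is.na(visits$uacr)
  if (any(all_missing))
    stop_maic("visit row with all outcomes missing (subject ",
              visits$subject_id[all_missing][1], ")")
  for (col in c("egfr", "upcr", "uacr"))
    if (any(visits[[col]] < 0, na.rm = TRUE))
      stop_maic("visit ", col, " must be non-negative")

  visits <- visits[order(visits$subject_id, visits$timepoint),
                   c("subject_id", "timepoint", "egfr", "upcr", "uacr")]
  rownames(subjects) <- rownames(visits) <- NULL
  structure(list(subjects = subjects, visits = visits), class = "maic_ipd")
}

#' @export
print.maic_ipd <- function(x, ...) {
  cat("<maic_ipd> ", nrow(x$subjects), " subjects (",
      sum(x$subjects$arm == "active"), " active / ",
      sum(x$subjects$arm == "control"), " control), ",
      nrow(x$visits), " visit records, trial '",
      x$subjects$trial_id[1], "'\n", sep = "")
  invisible(x)
}

#' Number of subjects in an IPD object
#' @param ipd A `maic_ipd` object.
#' @return Integer count.
#' @export
n_subjects <- function(ipd) nrow(ipd$subjects)

#' Timepoint pairing between the index and comparator trials
#'
#' The index trial reports visits in months, the comparator in weeks; the
#' published comparison pairs month 9 with week 36, month 12 with week 48 and
#' month 24 with week 106 (the closest reported week). The pairing is a
#' bijection; values are never interpolated.
#'
#' @return data.frame with columns `index_month` and `comparator_week`.
#' @export
timepoint_map <- function() {
  data.frame(index_month = c(9, 12, 24), comparator_week = c(36, 48, 106))
}

#' Map timepoint labels across trials
#'
#' @param x Numeric vector of timepoint labels.
#' @param from `"month"` to map index months to comparator weeks,
#'   `"week"` for the inverse.
#' @return Numeric vector of mapped labels.
#' @export
map_timepoint <- function(x, from = c("month", "week")) {
  from <- match.arg(from)
  tm <- timepoint_map()
  if (from == "month") {
    idx <- match(x, tm$index_month)
    if (anyNA(idx)) stop_maic("unknown index-trial month: ", x[is.na(idx)][1])
    tm$comparator_week[idx]
  } else {
    idx <- match(x, tm$comparator_week)
    if (anyNA(idx)) stop_maic("unknown comparator-trial week: ", x[is.na(idx)][1])
    tm$index_month[idx]
  }
}

# Default column mapping for IPD CSV files: canonical name -> file column.
default_ipd_schema <- function() {
  cols <- c("subject_id", "trial_id", "arm", unname(COVARIATE_COLUMNS),
            "event_time", "event_type", "timepoint", "egfr", "upcr", "uacr")
  stats::setNames(as.list(cols), cols)
}

#' Read individual patient data from CSV
#'
#' Reads a long-format CSV (one row per subject-visit, baseline columns
#' repeated on every row) into a validated [maic_ipd] object. Column names in
#' the file may be remapped through `schema`; missing outcome cells are kept
#' missing, never zero-filled.
#'
#' @param path CSV file path.
#' @param schema Named list mapping canonical column names to file column
#'   names; defaults to identity.
#' @return A [maic_ipd] object.
#' @export
read_ipd <- function(path, schema = NULL) {
  sch <- default_ipd_schema()
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), names(sch))
    if (length(unknown) > 0)
      stop_maic("schema names unknown: ", paste(unknown, collapse = ", "))
    sch[names(schema)] <- schema
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "trial_id", "arm", unname(COVARIATE_COLUMNS),
                "timepoint")
  for (canon in required) {
    if (!sch[[canon]] %in% names(raw))
      stop_maic("input file lacks required column '", sch[[canon]], "'")
  }
  get_col <- function(canon, default = NULL) {
    col <- sch[[canon]]
    if (col %in% names(raw)) raw[[col]] else default
  }
  subj_cols <- c("subject_id", "trial_id", "arm", unname(COVARIATE_COLUMNS))
  subj_all <- data.frame(lapply(stats::setNames(subj_cols, subj_cols), get_col),
                         stringsAsFactors = FALSE)
  subj_all$event_time <- get_col("event_time", NA_real_)
  subj_all$event_type <- get_col("event_type", NA_character_)
  if (is.character(subj_all$event_type))
    subj_all$event_type[!nzchar(subj_all$event_type)] <- NA_character_

  # baseline fields must be constant within subject
  first_idx <- !duplicated(subj_all$subject_id)
  for (col in setdiff(names(subj_all), "subject_id")) {
    ref <- subj_all[[col]][first_idx][match(subj_all$subject_id,
                                            subj_all$subject_id[first_idx])]
    differs <- !(is.na(ref) & is.na(subj_all[[col]])) &
      (is.na(ref) != is.na(subj_all[[col]]) | ref != subj_all[[col]])
    if (any(differs, na.rm = TRUE))
      stop_maic("baseline column '", col, "' varies within subject ",
                subj_all$subject_id[which(differs)[1]])
  }
  subjects <- subj_all[first_idx, , drop = FALSE]

  visits <- data.frame(
    subject_id = subj_all$subject_id,
    timepoint = get_col("timepoint"),
    egfr = get_col("egfr", NA_real_),
    upcr = get_col("upcr", NA_real_),
    uacr = get_col("uacr", NA_real_),
    stringsAsFactors = FALSE
  )
  maic_ipd(subjects, visits)
}

#' Write individual patient data to CSV
#'
#' Long format, inverse of [read_ipd]: one row per subject-visit with the
#' baseline columns repeated. `read_ipd(write_ipd(x, f))` reproduces `x`.
#'
#' @param ipd A [maic_ipd] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(ipd, path) {
  stopifnot(inherits(ipd, "maic_ipd"))
  merged <- merge(ipd$visits, ipd$subjects, by = "subject_id", sort = FALSE)
  merged <- merged[order(merged$subject_id, merged$timepoint), ]
  cols <- c("subject_id", "trial_id", "arm", unname(COVARIATE_COLUMNS),
            "event_time", "event_type", "timepoint", "egfr", "upcr", "uacr")
  num <- vapply(merged[cols], is.numeric, logical(1))
  out <- merged[cols]
  out[num] <- lapply(out[num], function(v) {
    s <- sprintf("%.17g", v)
    s[is.na(v)] <- NA_character_
    s
  })
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

TARGET_KINDS <- c("mean", "proportion", "threshold_proportion")

#' Construct an aggregate-target set
#'
#' Target moments for the comparator population: plain means, proportions of
#' binary covariates, and proportions above (or below) a threshold of a
#' continuous covariate. Proportions may be entered on the 0-100 percentage
#' scale; they are stored as fractions with the original value retained in
#' `value_raw` for reporting.
#'
#' @param name Covariate short names (see `maickit:::COVARIATE_COLUMNS`).
#' @param kind One of `"mean"`, `"proportion"`, `"threshold_proportion"`.
#' @param value Target value (covariate units for means; fraction or
#'   percentage for proportions).
#' @param threshold Threshold in covariate units (threshold_proportion only).
#' @param direction `"greater"` or `"less"` (threshold_proportion only);
#'   comparisons are strict.
#' @param source Free-text citation label per target.
#' @return data.frame of class `aggregate_targets`.
#' @export
aggregate_targets <- function(name, kind, value, threshold = NA_real_,
                              direction = NA_character_, source = NA_character_) {
  n <- max(length(name), length(kind), length(value), length(threshold))
  if (n == 0 || length(name) == 0) stop_maic("no targets")
  tg <- data.frame(
    name = rep_len(as.character(name), n),
    kind = rep_len(as.character(kind), n),
    value_raw = rep_len(as.numeric(value), n),
    threshold = rep_len(as.numeric(threshold), n),
    direction = rep_len(as.character(direction), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  if (!all(tg$kind %in% TARGET_KINDS))
    stop_maic("unknown target kind: ",
              paste(setdiff(tg$kind, TARGET_KINDS), collapse = ", "))
  if (!all(tg$name %in% names(COVARIATE_COLUMNS)))
    stop_maic("unknown covariate name: ",
              paste(setdiff(tg$name, names(COVARIATE_COLUMNS)), collapse = ", "))
  prop <- tg$kind != "mean"
  tg$value <- tg$value_raw
  if (any(prop)) {
    v <- tg$value_raw[prop]
    if (any(v < 0 | v > 100))
      stop_maic("proportion target outside [0, 100]: ", v[v < 0 | v > 100][1])
    # values above 1 are read as percentages
    tg$value[prop] <- ifelse(v > 1, v / 100, v)
  }
  need_thr <- tg$kind == "threshold_proportion"
  if (any(need_thr & is.na(tg$threshold)))
    stop_maic("threshold_proportion target without threshold: ",
              tg$name[need_thr & is.na(tg$threshold)][1])
  tg$direction[need_thr & is.na(tg$direction)] <- "greater"
  if (any(need_thr & !tg$direction %in% c("greater", "less")))
    stop_maic("direction must be 'greater' or 'less'")
  key <- paste(tg$name, tg$kind, tg$threshold)
  if (anyDuplicated(key))
    stop_maic("duplicate target: ", key[duplicated(key)][1])
  class(tg) <- c("aggregate_targets", "data.frame")
  tg
}

#' Labels for reporting target moments
#' @param targets An `aggregate_targets` object.
#' @return Character vector, one label per target.
#' @export
target_labels <- function(targets) {
  ifelse(targets$kind == "mean", paste0("mean ", targets$name),
    ifelse(targets$kind == "proportion", paste0(targets$name, " (%)"),
      paste0(targets$name, " ",
             ifelse(targets$direction == "less", "<", ">"),
             targets$threshold, " (%)")))
}

#' Construct a comparator-summary table
#'
#' Published effect summaries for the comparator trial: either within-trial
#' relative effects (active vs control; used by the anchored comparison) or
#' arm-level effects (used by the unanchored comparison), each as a point
#' estimate with a 95% interval on the reporting scale.
#'
#' @param endpoint `"egfr"`, `"upcr"`, `"uacr"` or `"composite"`.
#' @param timepoint Comparator-trial week label, or `NA` for the composite.
#' @param scale `"mean_difference"`, `"log_gmr"` or `"log_hr"`. Estimates for
#'   ratio scales may be supplied on the natural (GMR/HR) scale via
#'   `natural_scale = TRUE`, in which case they are log-transformed.
#' @param estimate,lower,upper Point estimate and 95% interval bounds.
#' @param arm Arm label (`"active"`/`"control"`) for arm-level rows, `NA` for
#'   relative effects.
#' @param interval_type `"confidence"` or `"credible"`.
#' @param natural_scale Logical; log-transform ratio-scale rows on input.
#' @return data.frame of class `comparator_summary`.
#' @export
comparator_summary <- function(endpoint, timepoint, scale, estimate, lower,
                               upper, arm = NA_character_,
                               interval_type = "confidence",
                               natural_scale = FALSE) {
  cs <- data.frame(
    endpoint = as.character(endpoint),
    timepoint = as.numeric(timepoint),
    scale = as.character(scale),
    arm = rep_len(as.character(arm), length(endpoint)),
    estimate = as.numeric(estimate),
    lower = as.numeric(lower),
    upper = as.numeric(upper),
    interval_type = rep_len(as.character(interval_type), length(endpoint)),
    stringsAsFactors = FALSE
  )
  if (!all(cs$scale %in% c("mean_difference", "log_gmr", "log_hr")))
    stop_maic("unknown scale in comparator summary")
  ratio <- cs$scale %in% c("log_gmr", "log_hr")
  if (natural_scale && any(ratio)) {
    if (any(cs$estimate[ratio] <= 0 | cs$lower[ratio] <= 0 | cs$upper[ratio] <= 0))
      stop_maic("ratio-scale summaries must be strictly positive")
    cs$estimate[ratio] <- log(cs$estimate[ratio])
    cs$lower[ratio] <- log(cs$lower[ratio])
    cs$upper[ratio] <- log(cs$upper[ratio])
  }
  bad <- !(cs$lower <= cs$estimate & cs$estimate <= cs$upper)
  if (any(bad)) stop_maic("interval must satisfy lower <= estimate <= upper")
  class(cs) <- c("comparator_summary", "data.frame")
  cs
}

#' Read aggregate targets and comparator summaries from JSON or YAML
#'
#' The document holds a `targets` list (entries: `name`, `kind`, `value`,
#' optional `threshold`, `direction`, `source`) and an optional
#' `comparator_summaries` list (entries: `endpoint`, `timepoint`, `scale`,
#' `estimate`, `lower`, `upper`, optional `arm`, `interval_type`,
#' `natural_scale`).
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return List with elements `targets` ([aggregate_targets]) and `summaries`
#'   ([comparator_summary] or `NULL`).
#' @export
read_targets <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else stop_maic("targets file must be .json, .yaml or .yml")
  tl <- doc$targets
  if (is.null(tl) || length(tl) == 0) stop_maic("no targets")
  pick <- function(field, default) {
    vapply(tl, function(e) {
      v <- e[[field]]
      if (is.null(v)) default else
        if (is.numeric(default)) as.numeric(v) else as.character(v)
    }, default)
  }
  targets <- aggregate_targets(
    name = pick("name", NA_character_),
    kind = pick("kind", NA_character_),
    value = pick("value", NA_real_),
    threshold = pick("threshold", NA_real_),
    direction = pick("direction", NA_character_),
    source = pick("source", NA_character_)
  )
  summaries <- NULL
  sl <- doc$comparator_summaries
  if (!is.null(sl) && length(sl) > 0) {
    pick_s <- function(field, default) {
      vapply(sl, function(e) {
        v <- e[[field]]
        if (is.null(v)) default else
          if (is.numeric(default)) as.numeric(v) else
          if (is.logical(default)) as.logical(v) else as.character(v)
      }, default)
    }
    nat <- pick_s("natural_scale", FALSE)
    if (length(unique(nat)) > 1)
      stop_maic("natural_scale must be uniform across comparator summaries")
    summaries <- comparator_summary(
      endpoint = pick_s("endpoint", NA_character_),
      timepoint = pick_s("timepoint", NA_real_),
      scale = pick_s("scale", NA_character_),
      estimate = pick_s("estimate", NA_real_),
      lower = pick_s("lower", NA_real_),
      upper = pick_s("upper", NA_real_),
      arm = pick_s("arm", NA_character_),
      interval_type = pick_s("interval_type", "confidence"),
      natural_scale = nat[1]
    )
  }
  list(targets = targets, summaries = summaries)
}

#' Build the covariate matrix for a target set
#'
#' One numeric column per target moment, in target order: the raw covariate
#' for `mean` targets, the 0/1 covariate itself for `proportion` targets, and
#' a strict-inequality 0/1 indicator for `threshold_proportion` targets
#' (boundary values score 0, matching published row labels such as
#' ">1.8 g/day").
#'
#' @param ipd A [maic_ipd] object.
#' @param targets An [aggregate_targets] object.
#' @param na_action `"fail"` (default) errors listing subjects with a missing
#'   matching covariate; `"exclude"` drops them (complete-case) and records
#'   them in the `"excluded_subjects"` attribute.
#' @return Numeric matrix (subjects x targets) with `target_labels()` column
#'   names and subject ids as row names.
#' @export
derive_threshold_indicators <- function(ipd, targets,
                                        na_action = c("fail", "exclude")) {
  stopifnot(inherits(ipd, "maic_ipd"), inherits(targets, "aggregate_targets"))
  na_action <- match.arg(na_action)
  subj <- ipd$subjects
  cols <- lapply(seq_len(nrow(targets)), function(j) {
    x <- as.numeric(subj[[COVARIATE_COLUMNS[[targets$name[j]]]]])
    switch(targets$kind[j],
      mean = x,
      proportion = {
        if (!all(x %in% c(0, 1, NA)))
          stop_maic("proportion target '", targets$name[j],
                    "' requires a 0/1 covariate")
        x
      },
      threshold_proportion = {
        ind <- if (targets$direction[j] == "greater")
          as.numeric(x > targets$threshold[j])
        else as.numeric(x < targets$threshold[j])
        ind[is.na(x)] <- NA
        ind
      })
  })
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(subj$subject_id, target_labels(targets))
  incomplete <- rowSums(is.na(mat)) > 0
  excluded <- character(0)
  if (any(incomplete)) {
    if (na_action == "fail")
      stop_maic("missing matching covariate for subject(s): ",
                paste(utils::head(subj$subject_id[incomplete], 5), collapse = ", "))
    excluded <- subj$subject_id[incomplete]
    message(length(excluded), " subject(s) excluded from matching (complete-case)")
    mat <- mat[!incomplete, , drop = FALSE]
  }
  attr(mat, "excluded_subjects") <- excluded
  mat
}
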