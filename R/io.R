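## Cohort table I/O and reporting. The on-disk cohort format is a plain
## UTF-8 comma-delimited table, one row per wound, empty string = absent.

COHORT_COLUMNS <- c(
  "wound_id", "patient_id", "skin_type",
  "surf1", "epi1", "dermal1", "vasc1",
  "surf2", "epi2", "dermal2", "vasc2",
  "clinical_judgment", "outcome", "days_to_graft"
)

SCORE_COLUMNS <- c("score", "depth_class", "management")

## Validate one cohort row; returns NULL if valid, else a message.
validate_cohort_row <- function(row) {
  msg <- function(fmt, ...) sprintf(fmt, ...)
  if (is.na(row$wound_id) || !nzchar(row$wound_id)) {
    return(msg("missing wound_id"))
  }
  if (!(row$skin_type %in% SKIN_TYPES)) {
    return(msg("skin_type '%s' not one of %s", row$skin_type,
               paste(SKIN_TYPES, collapse = "|")))
  }
  g1 <- list(surface_irregularity = row$surf1, epidermal_loss = row$epi1,
             dermal_pattern = row$dermal1, vascular_network = row$vasc1)
  ok <- tryCatch({
    validate_grades(g1, row$skin_type)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(paste("observer 1:", ok))
  obs2 <- c(row$surf2, row$epi2, row$dermal2, row$vasc2)
  if (any(!is.na(obs2))) {
    if (anyNA(obs2)) return(msg("observer 2 grades are incomplete"))
    g2 <- list(surface_irregularity = row$surf2, epidermal_loss = row$epi2,
               dermal_pattern = row$dermal2, vascular_network = row$vasc2)
    ok <- tryCatch({
      validate_grades(g2, row$skin_type)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(paste("observer 2:", ok))
  }
  if (!is.na(row$clinical_judgment) &&
      !(row$clinical_judgment %in% c("superficial", "deep"))) {
    return(msg("clinical_judgment '%s' not superficial|deep",
               row$clinical_judgment))
  }
  if (!(row$outcome %in% OUTCOME_LEVELS)) {
    return(msg("outcome '%s' not one of %s", row$outcome,
               paste(OUTCOME_LEVELS, collapse = "|")))
  }
  if (row$outcome == "grafted") {
    if (is.na(row$days_to_graft) || row$days_to_graft < 0) {
      return(msg("grafted wound needs a nonnegative days_to_graft"))
    }
  } else if (!is.na(row$days_to_graft)) {
    return(msg("days_to_graft given but outcome is '%s'", row$outcome))
  }
  NULL
}

#' Read a cohort table from CSV
#'
#' The schema has one row per wound: `wound_id`, `patient_id`,
#' `skin_type` (`glabrous|hair_bearing`), observer-1 grade columns
#' `surf1,epi1,dermal1,vasc1`, optional observer-2 columns
#' `surf2,epi2,dermal2,vasc2`, `clinical_judgment` (`superficial|deep`,
#' may be empty), `outcome`
#' (`healed_spontaneously|grafted|deep_refused_graft`) and
#' `days_to_graft` (empty unless grafted). Grades are validated through
#' the same rules as [validate_grades()].
#'
#' In `"strict"` mode (default) the first invalid row aborts the read with
#' a row-numbered message; `"permissive"` mode skips invalid rows and
#' reports them in attributes `n_rejected` / `rejected_messages`,
#' mirroring exclusion of unusable scans rather than silent repair.
#'
#' @param path CSV file path.
#' @param mode `"strict"` or `"permissive"`.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stopf("missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  to_int <- function(x) {
    x[!nzchar(x)] <- NA_character_
    bad <- !is.na(x) & is.na(suppressWarnings(as.integer(x)))
    out <- suppressWarnings(as.integer(x))
    if (any(bad)) out[bad] <- NA_integer_
    attr(out, "malformed") <- bad
    out
  }
  cohort <- data.frame(
    wound_id = raw$wound_id, patient_id = raw$patient_id,
    skin_type = raw$skin_type, stringsAsFactors = FALSE
  )
  malformed <- rep(FALSE, nrow(raw))
  for (cl in c("surf1", "epi1", "dermal1", "vasc1",
               "surf2", "epi2", "dermal2", "vasc2", "days_to_graft")) {
    v <- to_int(raw[[cl]])
    malformed <- malformed | attr(v, "malformed")
    attr(v, "malformed") <- NULL
    cohort[[cl]] <- v
  }
  cj <- raw$clinical_judgment
  cj[!nzchar(cj)] <- NA_character_
  cohort$clinical_judgment <- cj
  cohort$outcome <- raw$outcome
  cohort <- cohort[, COHORT_COLUMNS]
  dup <- duplicated(cohort$wound_id)
  msgs <- character(0)
  bad_rows <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    m <- if (malformed[i]) {
      "non-integer value in a grade or day column"
    } else if (dup[i]) {
      sprintf("duplicate wound_id '%s'", cohort$wound_id[i])
    } else {
      validate_cohort_row(cohort[i, , drop = FALSE])
    }
    if (!is.null(m)) {
      bad_rows[i] <- TRUE
      msgs <- c(msgs, sprintf("row %d: %s", i, m))
    }
  }
  if (length(msgs) && mode == "strict") {
    stopf("invalid cohort rows:\n%s", paste(msgs, collapse = "\n"))
  }
  out <- cohort[!bad_rows, , drop = FALSE]
  rownames(out) <- NULL
  if (mode == "permissive") {
    attr(out, "n_rejected") <- sum(bad_rows)
    attr(out, "rejected_messages") <- msgs
  }
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: absent values become empty strings; a
#' written table reads back field-for-field identical.
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(c(COHORT_COLUMNS, SCORE_COLUMNS), names(cohort))
  out <- cohort[, cols, drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Append score, depth class and management columns to a cohort
#'
#' Scores each wound from one observer's grades and appends `score`,
#' `depth_class` and `management` columns. Idempotent: re-scoring a scored
#' table reproduces the same columns.
#'
#' @param cohort cohort data.frame.
#' @param threshold management threshold passed to [predict_management()].
#' @param observer `"obs1"` (default) or `"obs2"`.
#' @return The cohort with three added (or overwritten) columns.
#' @export
score_cohort <- function(cohort, threshold = 4L, observer = "obs1") {
  if (is.null(cohort) || nrow(cohort) == 0L) {
    stop("empty cohort: at least one wound record is required", call. = FALSE)
  }
  sc <- cohort_scores(cohort, observer)
  if (!all(sc$keep)) stopf("cohort has rows without %s grades", observer)
  cohort$score <- sc$score
  cohort$depth_class <- classify_depth(sc$score)
  cohort$management <- predict_management(sc$score, threshold)
  cohort
}

#' Evaluate a cohort at a score threshold
#'
#' Builds the confusion table and diagnostic statistics and returns a flat
#' key-value report (counts, point estimates, confidence bounds, rounded
#' percentages with their rounding mode made explicit).
#'
#' @inheritParams build_confusion
#' @param ci_method `"wilson"` or `"exact"`.
#' @param percent_digits decimal places for reported percentages (0 or 1).
#' @return Named list of class `cohort_report`.
#' @export
evaluate_cohort <- function(cohort, threshold = 4L,
                            ci_method = c("wilson", "exact"),
                            deep_rule = DEEP_RULES,
                            observer = "obs1",
                            percent_digits = 0L) {
  ci_method <- match.arg(ci_method)
  deep_rule <- match.arg(deep_rule)
  tab <- build_confusion(cohort, threshold, deep_rule, observer)
  st <- diagnostic_stats(tab, ci_method)
  rep <- list(
    n_records = nrow(cohort),
    threshold = as.integer(threshold),
    deep_rule = deep_rule,
    observer = observer,
    ci_method = ci_method,
    percent_rounding = sprintf("half-up, %d decimal(s)", percent_digits),
    a_pred_deep_actual_deep = tab$a,
    b_pred_deep_healed = tab$b,
    c_pred_superficial_actual_deep = tab$c,
    d_pred_superficial_healed = tab$d
  )
  for (i in seq_len(nrow(st))) {
    m <- st$metric[i]
    rep[[m]] <- st$estimate[i]
    rep[[paste0(m, "_lower")]] <- st$lower[i]
    rep[[paste0(m, "_upper")]] <- st$upper[i]
    rep[[paste0(m, "_percent")]] <-
      if (is.na(st$estimate[i])) NA_real_
      else percent_round(st$estimate[i], percent_digits)
  }
  class(rep) <- "cohort_report"
  rep
}

#' @export
print.cohort_report <- function(x, ...) {
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("%s\t%s\n", k,
                if (is.numeric(v)) format(v, digits = 10) else as.character(v)))
  }
  invisible(x)
}

#' Write a flat key-value report
#'
#' @param report named list (e.g. a `cohort_report`).
#' @param path output path; tab-separated `key<TAB>value` lines.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  lines <- vapply(names(report), function(k) {
    v <- report[[k]]
    sprintf("%s\t%s", k,
            if (is.numeric(v)) format(v, digits = 15) else as.character(v))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Default run configuration
#'
#' One nestable key-value object holding every tunable of the pipeline:
#' the management threshold, CI method, percent rounding, automated-grader
#' thresholds, the phantom benchmark grid and the seed.
#'
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    threshold = 4L,
    ci_method = "wilson",
    deep_rule = "graft_or_refused",
    observer = "obs1",
    percent_digits = 0L,
    seed = 1L,
    grader_thresholds = grader_thresholds(),
    phantom_grid = "default"
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; unknown keys are
#' rejected rather than ignored, so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file; may be `NULL` for all defaults.
#' @return `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (k == "grader_thresholds") {
      bad <- setdiff(names(user[[k]]), names(cfg$grader_thresholds))
      if (length(bad)) {
        stopf("unknown grader_thresholds keys: %s", paste(bad, collapse = ", "))
      }
      cfg$grader_thresholds[names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}
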