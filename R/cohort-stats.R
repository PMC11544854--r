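## Cohort-level diagnostic evaluation: confusion tables at a score
## threshold, predictive values with confidence intervals, threshold
## sweeps, summaries and inter-observer agreement.

DEEP_RULES <- c("graft_or_refused", "grafted_only")

#' Scores for each cohort row from one observer's grade columns
#'
#' @param cohort cohort data.frame.
#' @param observer `"obs1"`, `"obs2"`, or `"consensus"` (keep only wounds
#'   where the two observers agree on every item; rows without observer-2
#'   grades are dropped there).
#' @return List with `score` (integer vector, `NA` where ungradeable) and
#'   `keep` (logical vector of usable rows).
#' @export
cohort_scores <- function(cohort, observer = c("obs1", "obs2", "consensus")) {
  observer <- match.arg(observer)
  s1 <- score_from_items(cohort$surf1, cohort$epi1, cohort$dermal1, cohort$vasc1)
  if (observer == "obs1") return(list(score = s1, keep = rep(TRUE, nrow(cohort))))
  has2 <- !is.na(cohort$surf2)
  s2 <- rep(NA_integer_, nrow(cohort))
  s2[has2] <- score_from_items(cohort$surf2[has2], cohort$epi2[has2],
                               cohort$dermal2[has2], cohort$vasc2[has2])
  if (observer == "obs2") return(list(score = s2, keep = has2))
  agree <- has2 &
    cohort$surf1 == cohort$surf2 & cohort$epi1 == cohort$epi2 &
    cohort$dermal1 == cohort$dermal2 & cohort$vasc1 == cohort$vasc2
  agree[is.na(agree)] <- FALSE
  list(score = s1, keep = agree)
}

is_deep_outcome <- function(outcome, deep_rule = DEEP_RULES) {
  deep_rule <- match.arg(deep_rule)
  if (deep_rule == "grafted_only") {
    outcome == "grafted"
  } else {
    outcome %in% c("grafted", "deep_refused_graft")
  }
}

#' Build a 2x2 confusion table from a scored cohort
#'
#' Wounds scoring above `threshold` are predicted deep (graft candidates);
#' the reference standard is the healing course. By default a wound is
#' "actually deep" when it was grafted or when grafting was indicated but
#' refused; `deep_rule = "grafted_only"` restricts the reference to surgery
#' actually performed.
#'
#' @param cohort cohort data.frame (see [read_cohort()] for the schema).
#' @param threshold integer score threshold, default 4 (scores >= 5 predict
#'   grafting).
#' @param deep_rule `"graft_or_refused"` (default) or `"grafted_only"`.
#' @param observer which observer's grades feed the score: `"obs1"`
#'   (default), `"obs2"`, or `"consensus"` (only wounds where both
#'   observers agree on every item).
#' @return An object of class `confusion_table`: counts `a` (predicted
#'   deep, actually deep), `b` (predicted deep, healed), `c` (predicted
#'   superficial, actually deep), `d` (predicted superficial, healed).
#' @export
build_confusion <- function(cohort, threshold = 4L,
                            deep_rule = DEEP_RULES,
                            observer = "obs1") {
  if (is.null(cohort) || nrow(cohort) == 0L) {
    stop("empty cohort: at least one wound record is required", call. = FALSE)
  }
  deep_rule <- match.arg(deep_rule)
  sc <- cohort_scores(cohort, observer)
  keep <- sc$keep
  if (!any(keep)) stop("empty cohort: no scoreable records", call. = FALSE)
  score <- sc$score[keep]
  check_score(score)
  pred_deep <- predict_management(score, threshold) == "graft_candidate"
  act_deep <- is_deep_outcome(cohort$outcome[keep], deep_rule)
  confusion_table(
    a = sum(pred_deep & act_deep),
    b = sum(pred_deep & !act_deep),
    c = sum(!pred_deep & act_deep),
    d = sum(!pred_deep & !act_deep)
  )
}

#' Construct a confusion table from counts
#'
#' @param a,b,c,d nonnegative counts: rows are predicted deep/superficial,
#'   columns actual deep (grafting course) / healed.
#' @return `confusion_table` object.
#' @export
confusion_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != as.integer(counts))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  counts <- stats::setNames(as.integer(counts), c("a", "b", "c", "d"))
  structure(as.list(counts), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(predicted = c("deep", "superficial"),
                              actual = c("deep", "healed")))
  print(m)
  invisible(x)
}

#' Binomial proportion confidence interval
#'
#' Wilson score interval (default) or exact Clopper-Pearson interval via
#' beta quantiles.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param method `"wilson"` or `"exact"`.
#' @param conf confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
binom_ci <- function(x, n, method = c("wilson", "exact"), conf = 0.95) {
  method <- match.arg(method)
  if (n < 1L || x < 0L || x > n) stop("need 0 <= x <= n, n >= 1", call. = FALSE)
  alpha <- 1 - conf
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  } else {
    lo <- if (x == 0L) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  }
  c(lower = lo, upper = hi)
}

#' Diagnostic accuracy statistics from a confusion table
#'
#' Point estimates and two-sided 95% confidence intervals for positive and
#' negative predictive value, sensitivity, specificity and raw agreement
#' `(a + d) / n`. A metric whose denominator is zero is reported as `NA`
#' (absent), never as zero.
#'
#' @param table a `confusion_table`.
#' @param ci_method `"wilson"` (default) or `"exact"` (Clopper-Pearson).
#' @param conf confidence level.
#' @return data.frame with columns `metric`, `estimate`, `lower`, `upper`,
#'   `x` (numerator), `n` (denominator).
#' @export
diagnostic_stats <- function(table, ci_method = c("wilson", "exact"),
                             conf = 0.95) {
  stopifnot(inherits(table, "confusion_table"))
  ci_method <- match.arg(ci_method)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  if (n == 0L) stop("all-zero confusion table", call. = FALSE)
  cells <- list(
    ppv         = c(a, a + b),
    npv         = c(d, c + d),
    sensitivity = c(a, a + c),
    specificity = c(d, b + d),
    agreement   = c(a + d, n)
  )
  rows <- lapply(names(cells), function(m) {
    x <- cells[[m]][1L]; den <- cells[[m]][2L]
    if (den == 0L) {
      data.frame(metric = m, estimate = NA_real_, lower = NA_real_,
                 upper = NA_real_, x = x, n = den)
    } else {
      ci <- binom_ci(x, den, ci_method, conf)
      data.frame(metric = m, estimate = x / den, lower = ci[["lower"]],
                 upper = ci[["upper"]], x = x, n = den)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diagnostic statistics across all score thresholds
#'
#' Runs [build_confusion()] and [diagnostic_stats()] at every threshold
#' 0-6, giving the operating characteristics of each possible cut point.
#'
#' @inheritParams build_confusion
#' @param ci_method passed to [diagnostic_stats()].
#' @return data.frame, one row per threshold, with confusion counts and
#'   `<metric>`, `<metric>_lower`, `<metric>_upper` columns.
#' @export
threshold_sweep <- function(cohort, deep_rule = DEEP_RULES,
                            observer = "obs1",
                            ci_method = c("wilson", "exact")) {
  deep_rule <- match.arg(deep_rule)
  ci_method <- match.arg(ci_method)
  rows <- lapply(0:6, function(th) {
    tab <- build_confusion(cohort, th, deep_rule, observer)
    st <- diagnostic_stats(tab, ci_method)
    wide <- data.frame(threshold = th, a = tab$a, b = tab$b,
                       c = tab$c, d = tab$d)
    for (i in seq_len(nrow(st))) {
      m <- st$metric[i]
      wide[[m]] <- st$estimate[i]
      wide[[paste0(m, "_lower")]] <- st$lower[i]
      wide[[paste0(m, "_upper")]] <- st$upper[i]
    }
    wide
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a cohort of scored wounds
#'
#' Tallies wounds per score value, depth class and outcome, and (when the
#' total number of admissions is supplied) the percentage of admitted
#' patients with hand injuries, at one-decimal precision.
#'
#' @param cohort cohort data.frame.
#' @param admissions_total optional count of all admissions against which
#'   the number of distinct patients is expressed.
#' @return A list of class `cohort_summary` with `n_wounds`, `n_patients`,
#'   `score_counts` (named over 0-6), `depth_class_counts`,
#'   `outcome_counts`, `median_days_to_graft` and, when available,
#'   `hand_injury_percent`.
#' @export
cohort_summary <- function(cohort, admissions_total = NULL) {
  if (is.null(cohort) || nrow(cohort) == 0L) {
    stop("empty cohort: at least one wound record is required", call. = FALSE)
  }
  score <- cohort_scores(cohort, "obs1")$score
  check_score(score)
  n_patients <- length(unique(cohort$patient_id))
  out <- list(
    n_wounds  = nrow(cohort),
    n_patients = n_patients,
    score_counts = table(factor(score, levels = 0:6)),
    depth_class_counts = table(factor(classify_depth(score),
                                      levels = DEPTH_CLASSES)),
    outcome_counts = table(factor(cohort$outcome, levels = OUTCOME_LEVELS)),
    median_days_to_graft =
      if (any(!is.na(cohort$days_to_graft))) {
        stats::median(cohort$days_to_graft, na.rm = TRUE)
      } else {
        NA_real_
      }
  )
  if (!is.null(admissions_total)) {
    if (admissions_total < n_patients) {
      stop("admissions_total is smaller than the number of patients",
           call. = FALSE)
    }
    out$hand_injury_percent <- percent_round(n_patients / admissions_total, 1L)
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d wounds in %d patients\n", x$n_wounds, x$n_patients))
  cat("Scores 0-6:", paste(as.integer(x$score_counts), collapse = " "), "\n")
  cat("Outcomes:",
      paste(names(x$outcome_counts), as.integer(x$outcome_counts),
            sep = "=", collapse = "  "), "\n")
  if (!is.null(x$hand_injury_percent)) {
    cat(sprintf("Hand injuries among admissions: %.1f%%\n",
                x$hand_injury_percent))
  }
  invisible(x)
}

## Cohen's kappa from two equally long grade vectors. Returns NA when the
## chance agreement is 1 (both raters constant on the same level).
cohen_kappa <- function(x, y, levels) {
  stopifnot(length(x) == length(y), length(x) > 0L)
  tab <- table(factor(x, levels = levels), factor(y, levels = levels))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e >= 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(p_o = p_o, p_e = p_e, kappa = kappa, n = n)
}

#' Inter-observer agreement between the two graders
#'
#' For each of the four score items, the observed percent agreement and
#' Cohen's kappa between observers 1 and 2, plus agreement on the total
#' score. Wounds without a second observer's grades are excluded and
#' counted.
#'
#' @param cohort cohort data.frame.
#' @return A list of class `interobserver_agreement` with `items` (a
#'   data.frame: `item`, `p_o`, `p_e`, `kappa`, `n`), `total_score` (same
#'   fields for the summed score) and `n_excluded`.
#' @export
interobserver_agreement <- function(cohort) {
  has2 <- !is.na(cohort$surf2) & !is.na(cohort$epi2) &
    !is.na(cohort$dermal2) & !is.na(cohort$vasc2)
  n_excluded <- sum(!has2)
  dual <- cohort[has2, , drop = FALSE]
  if (nrow(dual) < 2L) {
    stop("no dual-graded records: need >= 2 wounds graded by both observers",
         call. = FALSE)
  }
  cols <- list(
    surface_irregularity = c("surf1", "surf2"),
    epidermal_loss       = c("epi1", "epi2"),
    dermal_pattern       = c("dermal1", "dermal2"),
    vascular_network     = c("vasc1", "vasc2")
  )
  items <- do.call(rbind, lapply(names(cols), function(item) {
    lv <- 0:GRADE_MAX[[item]]
    k <- cohen_kappa(dual[[cols[[item]][1L]]], dual[[cols[[item]][2L]]], lv)
    data.frame(item = item, p_o = k$p_o, p_e = k$p_e, kappa = k$kappa,
               n = k$n)
  }))
  rownames(items) <- NULL
  s1 <- score_from_items(dual$surf1, dual$epi1, dual$dermal1, dual$vasc1)
  s2 <- score_from_items(dual$surf2, dual$epi2, dual$dermal2, dual$vasc2)
  total <- cohen_kappa(s1, s2, 0:6)
  structure(list(items = items, total_score = total,
                 n_excluded = n_excluded),
            class = "interobserver_agreement")
}

#' @export
print.interobserver_agreement <- function(x, ...) {
  cat(sprintf("Inter-observer agreement on %d dual-graded wounds (%d excluded)\n",
              x$items$n[1L], x$n_excluded))
  print(x$items, row.names = FALSE)
  cat(sprintf("Total score: agreement %.3f, kappa %s\n",
              x$total_score$p_o,
              if (is.na(x$total_score$kappa)) "NA"
              else sprintf("%.3f", x$total_score$kappa)))
  invisible(x)
}
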