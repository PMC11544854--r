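#' @keywords internal
"_PACKAGE"

## Item grade ceilings: surface and epidermal loss are binary, the dermal
## pattern (skin lines on glabrous skin / papillary spots on hair-bearing
## skin) and the microvascular network run 0-2.
GRADE_MAX <- c(
  surface_irregularity = 1L,
  epidermal_loss       = 1L,
  dermal_pattern       = 2L,
  vascular_network     = 2L
)

GRADE_ITEMS <- names(GRADE_MAX)

SKIN_TYPES <- c("glabrous", "hair_bearing")

DEPTH_CLASSES <- c("healthy_or_epidermal", "partial_spontaneous", "deep_graft")

MANAGEMENT_LEVELS <- c("spontaneous_healing", "graft_candidate")

OUTCOME_LEVELS <- c("healed_spontaneously", "grafted", "deep_refused_graft")

#' Validate a skin type
#'
#' Exactly two sites are distinguished: `"glabrous"` (palms and soles, skin
#' lines visible) and `"hair_bearing"` (hand dorsum, papillary spot pattern).
#' There is no mixed type.
#'
#' @param skin_type character scalar.
#' @return The validated skin type string.
#' @export
validate_skin_type <- function(skin_type) {
  if (!is.character(skin_type) || length(skin_type) != 1L ||
      !(skin_type %in% SKIN_TYPES)) {
    stop("skin_type must be one of ", paste(SKIN_TYPES, collapse = ", "),
         call. = FALSE)
  }
  skin_type
}

is_whole_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

#' Construct a validated set of feature grades
#'
#' Bundles the four item grades of the OCT burn score with the skin type.
#' The dermal pattern item is read as "skin lines" on glabrous skin and as
#' "papillary pattern" on hair-bearing skin; a record carries exactly one of
#' the two, so a single `dermal_pattern` grade plus `skin_type` encodes it.
#'
#' Grades are discrete integers; fractional values (e.g. two observers
#' averaged) are rejected rather than rounded.
#'
#' @param surface_irregularity integer 0 (smooth linear surface) or 1
#'   (irregular surface).
#' @param epidermal_loss integer 0 (dark epidermal band present) or 1 (band
#'   absent).
#' @param dermal_pattern integer 0 (normal), 1 (partially visible), 2
#'   (absent / completely disrupted).
#' @param vascular_network integer 0 (normal arborized network), 1 (minor
#'   damage), 2 (disrupted network, truncated vessels).
#' @param skin_type `"glabrous"` or `"hair_bearing"`.
#' @return An object of class `feature_grades`: a list with the four integer
#'   grades and the skin type.
#' @seealso [validate_grades()], [compute_score()]
#' @examples
#' g <- feature_grades(1, 1, 2, 2, "hair_bearing")
#' compute_score(g)
#' @export
feature_grades <- function(surface_irregularity, epidermal_loss,
                           dermal_pattern, vascular_network, skin_type) {
  raw <- list(
    surface_irregularity = surface_irregularity,
    epidermal_loss       = epidermal_loss,
    dermal_pattern       = dermal_pattern,
    vascular_network     = vascular_network
  )
  validate_grades(raw, skin_type)
}

#' Validate raw item grades
#'
#' Checks that all four score items are present, integer-valued and within
#' their allowed ranges. Values are never clamped or rounded: a grade of 2
#' on a binary item, or 1.5 anywhere, is an error.
#'
#' @param raw named list or vector with entries `surface_irregularity`,
#'   `epidermal_loss`, `dermal_pattern`, `vascular_network`.
#' @param skin_type `"glabrous"` or `"hair_bearing"`.
#' @return A `feature_grades` object.
#' @export
validate_grades <- function(raw, skin_type) {
  skin_type <- validate_skin_type(skin_type)
  raw <- as.list(raw)
  g <- integer(4L)
  names(g) <- GRADE_ITEMS
  for (item in GRADE_ITEMS) {
    if (is.null(raw[[item]]) || (length(raw[[item]]) == 1L && is.na(raw[[item]]))) {
      stop(sprintf("incomplete grading: missing item '%s'", item),
           call. = FALSE)
    }
    v <- raw[[item]]
    if (!is_whole_number(v) || v < 0L || v > GRADE_MAX[[item]]) {
      stop(sprintf(
        "grade out of range: %s = %s (allowed integers 0-%d)",
        item, format(v), GRADE_MAX[[item]]
      ), call. = FALSE)
    }
    g[[item]] <- as.integer(v)
  }
  structure(
    c(as.list(g), list(skin_type = skin_type)),
    class = "feature_grades"
  )
}

#' @export
print.feature_grades <- function(x, ...) {
  cat(sprintf(
    "OCT feature grades (%s skin): surface=%d epidermis=%d dermal=%d vascular=%d -> score %d\n",
    x$skin_type, x$surface_irregularity, x$epidermal_loss,
    x$dermal_pattern, x$vascular_network, compute_score(x)
  ))
  invisible(x)
}

#' Compute the additive OCT burn score
#'
#' The score is the plain sum of the four item grades; 0 marks healthy skin
#' and 6 a deep burn with destroyed dermal structure and absent papillary
#' plexus.
#'
#' @param grades a `feature_grades` object.
#' @return Integer score in 0-6.
#' @examples
#' compute_score(feature_grades(0, 0, 0, 0, "glabrous"))  # healthy: 0
#' compute_score(feature_grades(1, 1, 2, 2, "glabrous"))  # deep burn: 6
#' @export
compute_score <- function(grades) {
  if (!inherits(grades, "feature_grades")) {
    stop("grades must be a feature_grades object", call. = FALSE)
  }
  grades$surface_irregularity + grades$epidermal_loss +
    grades$dermal_pattern + grades$vascular_network
}

## Vectorized score over raw integer columns (used by the cohort layer,
## where each column has already been range-checked row by row).
score_from_items <- function(surf, epi, dermal, vasc) {
  as.integer(surf + epi + dermal + vasc)
}

#' Map scores to burn depth classes
#'
#' Scores 0-2 indicate healthy skin or a purely epidermal injury, 3-4 a
#' partial-thickness burn expected to heal spontaneously, and 5-6 a
#' full-thickness burn needing grafting. The bands are exhaustive and
#' disjoint over 0-6.
#'
#' @param score integer vector of scores in 0-6.
#' @return Character vector with values among
#'   `"healthy_or_epidermal"`, `"partial_spontaneous"`, `"deep_graft"`.
#' @export
classify_depth <- function(score) {
  check_score(score)
  ifelse(score <= 2L, DEPTH_CLASSES[1L],
         ifelse(score <= 4L, DEPTH_CLASSES[2L], DEPTH_CLASSES[3L]))
}

check_score <- function(score) {
  if (length(score) == 0L || anyNA(score) ||
      !all(score == as.integer(score)) ||
      any(score < 0L) || any(score > 6L)) {
    stop("invalid score: scores must be integers in 0-6", call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict management from the score
#'
#' Wounds scoring at or below the threshold are predicted to heal
#' spontaneously under dressing; above it they are graft candidates. The
#' default threshold of 4 is inclusive on the healing side.
#'
#' @param score integer vector of scores in 0-6.
#' @param threshold integer in 0-6; scores `<= threshold` predict
#'   spontaneous healing.
#' @return Character vector with values `"spontaneous_healing"` or
#'   `"graft_candidate"`.
#' @export
predict_management <- function(score, threshold = 4L) {
  check_score(score)
  if (!is_whole_number(threshold) || threshold < 0L || threshold > 6L) {
    stop("invalid threshold: must be an integer in 0-6", call. = FALSE)
  }
  ifelse(score <= threshold, MANAGEMENT_LEVELS[1L], MANAGEMENT_LEVELS[2L])
}

#' Enumerate all valid grade combinations
#'
#' All 2 x 2 x 3 x 3 = 36 item-grade tuples, optionally restricted to a
#' target total score. Used by the synthetic cohort sampler and handy for
#' exhaustive checks.
#'
#' @param total optional integer; keep only tuples summing to `total`.
#' @return A data.frame with columns `surface_irregularity`,
#'   `epidermal_loss`, `dermal_pattern`, `vascular_network`, `score`.
#' @export
grade_combinations <- function(total = NULL) {
  g <- expand.grid(
    surface_irregularity = 0:1,
    epidermal_loss       = 0:1,
    dermal_pattern       = 0:2,
    vascular_network     = 0:2,
    KEEP.OUT.ATTRS = FALSE
  )
  g$score <- with(g, surface_irregularity + epidermal_loss +
                    dermal_pattern + vascular_network)
  if (!is.null(total)) {
    check_score(total)
    g <- g[g$score == total, , drop = FALSE]
    rownames(g) <- NULL
  }
  g
}
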