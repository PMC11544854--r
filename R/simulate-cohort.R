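## Synthetic cohorts with the statistical structure of the validation
## study: the printed per-score frequencies, score-conditional deep/healed
## outcomes, a glabrous/hair-bearing mixture, and a second observer whose
## grades deviate from the first by single-step flips.

#' Configuration for a synthetic wound cohort
#'
#' Defaults reproduce the structure of the validation cohort: 63 scored
#' wounds with score frequencies proportional to 2/15/29/12/5 over scores
#' 2-6 (scores 0-1 were never assigned to a debrided wound). The
#' score-conditional probabilities of a truly deep wound are calibration
#' choices, not observed per-score rates (only band-level outcomes are
#' reported clinically): essentially zero below the threshold, rising
#' steeply above it.
#'
#' @param n_wounds number of wounds to simulate.
#' @param score_weights nonnegative sampling weights for scores 0-6.
#' @param p_deep_given_score probability that a wound with each score 0-6
#'   is actually deep (will not heal spontaneously).
#' @param p_graft_given_deep probability that a deep wound is grafted; the
#'   remainder are labelled `deep_refused_graft`.
#' @param skin_type_mix probability a wound is on glabrous skin.
#' @param observer_flip_prob per-item probability that observer 2's grade
#'   deviates from observer 1's by one level (clipped to the item range).
#' @param p_obs2_present probability a wound has second-observer grades.
#' @param p_clinical_deep_given_deep,p_clinical_deep_given_superficial
#'   probabilities that the initial clinical judgment calls the wound deep,
#'   conditioned on its true depth; the default over-calls superficial
#'   wounds, mirroring clinicians' tendency to rate wounds too deep.
#' @param median_days_to_graft centre of the Poisson draw for time from
#'   injury to grafting, in days.
#' @param seed integer seed making the cohort reproducible.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_wounds = 63L,
                          score_weights = c(0, 0, 2, 15, 29, 12, 5),
                          p_deep_given_score = c(0, 0, 0, 0, 0.03, 0.5, 0.9),
                          p_graft_given_deep = 0.9,
                          skin_type_mix = 0.5,
                          observer_flip_prob = 0.1,
                          p_obs2_present = 1,
                          p_clinical_deep_given_deep = 0.9,
                          p_clinical_deep_given_superficial = 0.18,
                          median_days_to_graft = 9,
                          seed = 1L) {
  cfg <- list(
    n_wounds = n_wounds, score_weights = score_weights,
    p_deep_given_score = p_deep_given_score,
    p_graft_given_deep = p_graft_given_deep,
    skin_type_mix = skin_type_mix,
    observer_flip_prob = observer_flip_prob,
    p_obs2_present = p_obs2_present,
    p_clinical_deep_given_deep = p_clinical_deep_given_deep,
    p_clinical_deep_given_superficial = p_clinical_deep_given_superficial,
    median_days_to_graft = median_days_to_graft,
    seed = seed
  )
  if (!is_whole_number(n_wounds) || n_wounds < 1L) {
    stopf("invalid config: n_wounds must be a positive integer")
  }
  if (length(score_weights) != 7L || any(score_weights < 0) ||
      sum(score_weights) <= 0) {
    stopf("invalid config: score_weights must be 7 nonnegative weights with positive sum")
  }
  if (length(p_deep_given_score) != 7L) {
    stopf("invalid config: p_deep_given_score must have 7 entries (scores 0-6)")
  }
  probs <- c(p_deep_given_score, p_graft_given_deep, skin_type_mix,
             observer_flip_prob, p_obs2_present,
             p_clinical_deep_given_deep, p_clinical_deep_given_superficial)
  if (anyNA(probs) || any(probs < 0) || any(probs > 1)) {
    stopf("invalid config: all probabilities must lie in [0, 1]")
  }
  if (!is_whole_number(seed)) stopf("invalid config: seed must be an integer")
  class(cfg) <- "cohort_config"
  cfg
}

#' Draw item grades consistent with a target score
#'
#' Samples uniformly among all valid grade tuples whose items sum to the
#' target score (the inverse of [compute_score()]). Scores 0 and 6 have a
#' single admissible tuple each.
#'
#' @param target_score integer 0-6.
#' @param skin_type `"glabrous"` or `"hair_bearing"`.
#' @return A `feature_grades` object with `compute_score()` equal to
#'   `target_score`. Uses the current RNG stream.
#' @export
sample_grades_for_score <- function(target_score, skin_type) {
  combos <- grade_combinations(target_score)
  i <- if (nrow(combos) == 1L) 1L else sample.int(nrow(combos), 1L)
  feature_grades(combos$surface_irregularity[i], combos$epidermal_loss[i],
                 combos$dermal_pattern[i], combos$vascular_network[i],
                 skin_type)
}

## One-step grade perturbation, clipped to [0, max]; at interior levels the
## step direction is symmetric.
flip_grade <- function(g, max_level, flip_prob) {
  if (stats::runif(1L) >= flip_prob) return(g)
  step <- if (g == 0L) 1L else if (g == max_level) -1L
          else sample(c(-1L, 1L), 1L)
  g + step
}

#' Generate a synthetic cohort of wound records
#'
#' Draws `n_wounds` records in a fixed per-record order (score, grades,
#' observer-2 flips, depth, outcome, clinical judgment), so the same
#' config and seed reproduce the cohort exactly. Wounds are grouped into
#' patients, a minority of whom have bilateral injuries.
#'
#' @param config a [cohort_config()].
#' @return A cohort data.frame in the standard schema (see
#'   [read_cohort()]), with attribute `"config"`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_wounds = 20, seed = 7))
#' table(cohort_scores(coh, "obs1")$score)
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stopf("invalid config: expected a cohort_config object")
  }
  n <- config$n_wounds
  combos_by_score <- lapply(0:6, grade_combinations)
  with_seed(config$seed, {
    ## patient grouping first: ~40% of patients have a bilateral injury
    pid <- integer(n); p <- 0L; i <- 1L
    while (i <= n) {
      p <- p + 1L
      k <- if (stats::runif(1L) < 0.4 && i < n) 2L else 1L
      pid[i:(i + k - 1L)] <- p
      i <- i + k
    }
    rows <- vector("list", n)
    for (w in seq_len(n)) {
      score <- sample(0:6, 1L, prob = config$score_weights)
      skin <- if (stats::runif(1L) < config$skin_type_mix) "glabrous"
              else "hair_bearing"
      cm <- combos_by_score[[score + 1L]]
      ci <- if (nrow(cm) == 1L) 1L else sample.int(nrow(cm), 1L)
      g1 <- c(cm$surface_irregularity[ci], cm$epidermal_loss[ci],
              cm$dermal_pattern[ci], cm$vascular_network[ci])
      has2 <- stats::runif(1L) < config$p_obs2_present
      g2 <- rep(NA_integer_, 4L)
      if (has2) {
        maxes <- unname(GRADE_MAX)
        g2 <- vapply(1:4, function(j) {
          flip_grade(g1[j], maxes[j], config$observer_flip_prob)
        }, integer(1L))
      }
      deep <- stats::runif(1L) < config$p_deep_given_score[score + 1L]
      if (deep) {
        grafted <- stats::runif(1L) < config$p_graft_given_deep
        outcome <- if (grafted) "grafted" else "deep_refused_graft"
        days <- if (grafted) {
          max(1L, stats::rpois(1L, config$median_days_to_graft))
        } else {
          NA_integer_
        }
      } else {
        outcome <- "healed_spontaneously"
        days <- NA_integer_
      }
      p_cd <- if (deep) config$p_clinical_deep_given_deep
              else config$p_clinical_deep_given_superficial
      judgment <- if (stats::runif(1L) < p_cd) "deep" else "superficial"
      rows[[w]] <- data.frame(
        wound_id = sprintf("w%03d", w),
        patient_id = sprintf("p%03d", pid[w]),
        skin_type = skin,
        surf1 = g1[1L], epi1 = g1[2L], dermal1 = g1[3L], vasc1 = g1[4L],
        surf2 = g2[1L], epi2 = g2[2L], dermal2 = g2[3L], vasc2 = g2[4L],
        clinical_judgment = judgment,
        outcome = outcome,
        days_to_graft = days,
        stringsAsFactors = FALSE
      )
    }
    cohort <- do.call(rbind, rows)
    attr(cohort, "config") <- config
    cohort
  })
}
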