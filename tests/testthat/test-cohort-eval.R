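test_that("confusion counts match brute-force enumeration and partition the cohort", {
  coh <- ten_wound_cohort()
  for (th in 0:6) {
    for (rule in c("graft_or_refused", "grafted_only")) {
      tab <- build_confusion(coh, th, rule)
      orc <- oracle_confusion(coh, th, rule)
      expect_identical(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d), orc)
      expect_identical(tab$a + tab$b + tab$c + tab$d, nrow(coh))
    }
  }
  expect_error(build_confusion(coh[0, ]), "empty cohort")
})

test_that("deep-outcome rule and observer selection change the table as intended", {
  coh <- ten_wound_cohort()
  tab_both <- build_confusion(coh, deep_rule = "graft_or_refused")
  tab_graft <- build_confusion(coh, deep_rule = "grafted_only")
  expect_identical(tab_both$a - tab_graft$a, 1L)  # the refused-graft wound
  ## consensus mode keeps only wounds where the observers agree everywhere
  coh$surf2[1] <- 1
  tab_cons <- build_confusion(coh, observer = "consensus")
  expect_identical(tab_cons$a + tab_cons$b + tab_cons$c + tab_cons$d, 9L)
})

test_that("diagnostic statistics reproduce hand-computed proportions", {
  ## 17 predicted-deep wounds of which 9 grafted
  tab <- confusion_table(a = 9, b = 8, c = 0, d = 0)
  st <- diagnostic_stats(tab)
  ppv <- st$estimate[st$metric == "ppv"]
  expect_equal(ppv, 9 / 17)
  expect_equal(percent_round(ppv), 53)
  ## zero-denominator metrics are absent, not zero
  expect_true(is.na(st$estimate[st$metric == "npv"]))
  ## perfect table
  st2 <- diagnostic_stats(confusion_table(5, 0, 0, 5))
  expect_true(all(st2$estimate == 1))
  expect_true(all(st2$lower <= st2$estimate & st2$estimate <= st2$upper))
  expect_error(diagnostic_stats(confusion_table(0, 0, 0, 0)), "all-zero")
})

test_that("swapping both class labels swaps ppv<->npv and sensitivity<->specificity", {
  tab <- confusion_table(a = 7, b = 3, c = 2, d = 11)
  swapped <- confusion_table(a = 11, b = 2, c = 3, d = 7)
  st <- diagnostic_stats(tab)
  sw <- diagnostic_stats(swapped)
  get <- function(s, m) s$estimate[s$metric == m]
  expect_equal(get(st, "ppv"), get(sw, "npv"))
  expect_equal(get(st, "sensitivity"), get(sw, "specificity"))
  expect_equal(get(st, "agreement"), get(sw, "agreement"))
})

test_that("agreement is 1 exactly when both off-diagonal cells are empty", {
  get_agree <- function(tab) {
    st <- diagnostic_stats(tab)
    st$estimate[st$metric == "agreement"]
  }
  expect_equal(get_agree(confusion_table(3, 0, 0, 9)), 1)
  expect_lt(get_agree(confusion_table(3, 1, 0, 9)), 1)
  expect_lt(get_agree(confusion_table(3, 0, 2, 9)), 1)
})

test_that("exact CI endpoints match the grid tail-inversion oracle to 1e-4", {
  cases <- list(c(9, 17), c(0, 10), c(10, 10), c(1, 41), c(40, 41))
  for (cs in cases) {
    got <- binom_ci(cs[1], cs[2], "exact")
    want <- oracle_exact_ci(cs[1], cs[2])
    expect_equal(unname(got), unname(want), tolerance = 1e-4)
  }
})

test_that("Wilson interval covers the true proportion at about 95%", {
  set.seed(42)
  n <- 40; p <- 0.3; reps <- 10000
  x <- rbinom(reps, n, p)
  z <- qnorm(0.975)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  covered <- mean(centre - half <= p & p <= centre + half)
  expect_gt(covered, 0.93)
  expect_lt(covered, 0.97)
  ## spot-check the vectorized arithmetic against the package function
  expect_equal(unname(binom_ci(x[1], n, "wilson")),
               c(centre[1] - half[1], centre[1] + half[1]))
})

test_that("threshold sweep rows equal direct computation at each threshold", {
  coh <- generate_cohort(cohort_config(n_wounds = 80, seed = 11))
  sweep <- threshold_sweep(coh)
  expect_equal(nrow(sweep), 7L)
  for (th in c(0L, 4L, 6L)) {
    tab <- build_confusion(coh, th)
    st <- diagnostic_stats(tab)
    row <- sweep[sweep$threshold == th, ]
    expect_identical(c(row$a, row$b, row$c, row$d),
                     c(tab$a, tab$b, tab$c, tab$d))
    expect_equal(row$ppv, st$estimate[st$metric == "ppv"])
  }
  ## all-healed cohort scores <= 4: perfect agreement at threshold 4
  healed <- ten_wound_cohort()[1:6, ]
  row4 <- threshold_sweep(healed)[5, ]
  expect_equal(row4$agreement, 1)
  ## single grafted score-6 wound: threshold 5 row has a=1, sensitivity 1
  single <- make_row("w1", g1 = c(1, 1, 2, 2), outcome = "grafted", days = 9L)
  row5 <- threshold_sweep(single)[6, ]
  expect_identical(row5$a, 1L)
  expect_equal(row5$sensitivity, 1)
})

test_that("cohort summary tallies scores, classes and outcomes correctly", {
  coh <- ten_wound_cohort()
  s <- cohort_summary(coh)
  expect_equal(as.integer(s$score_counts),
               c(1L, 0L, 1L, 2L, 2L, 2L, 2L))  # direct tally of the fixture
  expect_equal(as.integer(s$depth_class_counts), c(2L, 4L, 4L))
  expect_equal(unname(s$outcome_counts[["grafted"]]), 2L)
  expect_equal(s$median_days_to_graft, 10)
  one <- cohort_summary(coh[3, ])
  expect_equal(one$n_wounds, 1L)
  expect_equal(sum(one$score_counts), 1L)
  expect_error(cohort_summary(coh, admissions_total = 3), "smaller")
})

test_that("kappa matches direct formula evaluation on a fixed 2x2 table", {
  ## item table [[20,5],[10,15]]: p_o=0.7, p_e=0.5, kappa=0.4
  x <- rep(c(0, 0, 1, 1), c(20, 5, 10, 15))
  y <- rep(c(0, 1, 0, 1), c(20, 5, 10, 15))
  rows <- lapply(seq_along(x), function(i) {
    make_row(sprintf("w%02d", i), g1 = c(x[i], 0, 0, 0),
             g2 = c(y[i], 0, 0, 0))
  })
  coh <- do.call(rbind, rows)
  res <- interobserver_agreement(coh)
  surf <- res$items[res$items$item == "surface_irregularity", ]
  expect_equal(surf$p_o, 0.7)
  expect_equal(surf$p_e, 0.5)
  expect_equal(surf$kappa, 0.4)
  ## constant items have p_e = 1: kappa reported absent
  derm <- res$items[res$items$item == "dermal_pattern", ]
  expect_equal(derm$p_o, 1)
  expect_true(is.na(derm$kappa))
})

test_that("identical gradings give kappa 1; independent gradings concentrate near 0", {
  coh <- generate_cohort(cohort_config(n_wounds = 40, observer_flip_prob = 0,
                                       seed = 3))
  res <- interobserver_agreement(coh)
  expect_true(all(res$items$p_o == 1))
  expect_true(all(res$items$kappa[!is.na(res$items$kappa)] == 1))
  expect_equal(res$total_score$kappa, 1)
  ## independent observer 2: shuffle observer-2 columns across wounds
  set.seed(99)
  big <- generate_cohort(cohort_config(n_wounds = 4000, seed = 5))
  perm <- sample.int(nrow(big))
  for (cl in c("surf2", "epi2", "dermal2", "vasc2")) {
    big[[cl]] <- big[[cl]][perm]
  }
  res2 <- interobserver_agreement(big)
  expect_true(all(abs(res2$items$kappa) < 0.08))
})

test_that("dual-grading prerequisites are enforced and exclusions counted", {
  coh <- ten_wound_cohort()
  coh$surf2[1:3] <- NA_integer_
  res <- interobserver_agreement(coh)
  expect_equal(res$n_excluded, 3L)
  expect_equal(res$items$n[1], 7L)
  none <- ten_wound_cohort()
  none[, c("surf2", "epi2", "dermal2", "vasc2")] <- NA_integer_
  expect_error(interobserver_agreement(none), "no dual-graded records")
})
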