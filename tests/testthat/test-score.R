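test_that("grade validation enforces item presence, integrality and range", {
  full <- list(surface_irregularity = 1, epidermal_loss = 1,
               dermal_pattern = 2, vascular_network = 2)
  g <- validate_grades(full, "hair_bearing")
  expect_s3_class(g, "feature_grades")
  expect_equal(compute_score(g), 6)

  zero <- list(surface_irregularity = 0, epidermal_loss = 0,
               dermal_pattern = 0, vascular_network = 0)
  expect_equal(compute_score(validate_grades(zero, "glabrous")), 0)

  missing_item <- full[-2]
  expect_error(validate_grades(missing_item, "glabrous"),
               "incomplete grading.*epidermal_loss")
  over <- full; over$surface_irregularity <- 2
  expect_error(validate_grades(over, "glabrous"),
               "grade out of range.*surface_irregularity")
  frac <- full; frac$dermal_pattern <- 1.5
  expect_error(validate_grades(frac, "glabrous"), "grade out of range")
  neg <- full; neg$vascular_network <- -1
  expect_error(validate_grades(neg, "glabrous"), "grade out of range")
  expect_error(validate_grades(full, "mixed"), "skin_type")
})

test_that("score is additive, bounded and monotone over all 36 combinations", {
  combos <- grade_combinations()
  expect_equal(nrow(combos), 36L)
  for (i in seq_len(nrow(combos))) {
    g <- feature_grades(combos$surface_irregularity[i],
                        combos$epidermal_loss[i],
                        combos$dermal_pattern[i],
                        combos$vascular_network[i],
                        "hair_bearing")
    s <- compute_score(g)
    expect_identical(s, combos$score[i])
    expect_true(s >= 0 && s <= 6)
  }
  ## bumping any single item never decreases the score
  items <- c("surface_irregularity", "epidermal_loss",
             "dermal_pattern", "vascular_network")
  maxes <- c(1, 1, 2, 2)
  for (i in seq_len(nrow(combos))) {
    for (j in seq_along(items)) {
      if (combos[i, items[j]] < maxes[j]) {
        bumped <- combos[i, items, drop = TRUE]
        bumped[[j]] <- bumped[[j]] + 1
        g2 <- do.call(feature_grades, c(unname(bumped), list("glabrous")))
        expect_gte(compute_score(g2), combos$score[i])
      }
    }
  }
})

test_that("depth bands are exhaustive, disjoint and match the threshold rule", {
  expect_equal(classify_depth(0:6),
               c(rep("healthy_or_epidermal", 3),
                 rep("partial_spontaneous", 2),
                 rep("deep_graft", 2)))
  expect_error(classify_depth(7), "invalid score")
  expect_error(classify_depth(-1), "invalid score")
  ## deep_graft band coincides with graft_candidate at the default threshold
  for (s in 0:6) {
    expect_identical(classify_depth(s) == "deep_graft",
                     predict_management(s, 4L) == "graft_candidate")
  }
})

test_that("management prediction is threshold-inclusive on the healing side", {
  expect_equal(predict_management(4L), "spontaneous_healing")
  expect_equal(predict_management(5L), "graft_candidate")
  expect_equal(predict_management(0L), "spontaneous_healing")
  expect_equal(predict_management(3L, threshold = 2L), "graft_candidate")
  expect_error(predict_management(3L, threshold = 7L), "invalid threshold")
  expect_error(predict_management(3L, threshold = 2.5), "invalid threshold")
})
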