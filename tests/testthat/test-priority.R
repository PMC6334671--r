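test_that("axis scores follow the shipped tables and strict ordinal ordering", {
  m <- as_risk_matrix(shipped())
  expect_identical(score_condition("good", m), 1L)
  expect_identical(score_condition("very_poor", m), 4L)
  expect_identical(score_disturbance("unlikely", m), 1L)
  expect_identical(score_disturbance("highly_likely", m), 4L)
  expect_gt(score_condition("poor", m), score_condition("fair", m))
  expect_gt(score_disturbance("likely", m), score_disturbance("somewhat_likely", m))
  expect_error(score_condition("immaculate", m), class = "acm_value_error")
})

test_that("summed scores map through the bands to the four priority levels", {
  m <- as_risk_matrix(shipped())
  expect_identical(assess_priority("good", "unlikely", m), "very_low")
  expect_identical(assess_priority("very_poor", "highly_likely", m), "high")
  expect_identical(assess_priority("fair", "likely", m), "low")  # 2 + 3 = 5

  cells <- expand_risk_matrix(m)
  expect_identical(nrow(cells), 16L)
  expect_setequal(unique(cells$priority),
                  c("very_low", "low", "medium", "high"))
  # additivity is symmetric: swapping which axis contributes which addend
  # leaves the priority unchanged whenever the two scores exist on both axes
  for (i in seq_len(nrow(cells))) {
    ci <- cells$condition_score[i]; di <- cells$disturbance_score[i]
    swapped <- cells[cells$condition_score == di & cells$disturbance_score == ci, ]
    expect_identical(unique(swapped$priority), cells$priority[i])
  }
})

test_that("all 16 cells are monotone in each axis with anchored endpoints", {
  cells <- expand_risk_matrix(as_risk_matrix(shipped()))
  lv <- function(p) match(p, c("very_low", "low", "medium", "high"))
  tab <- matrix(lv(cells$priority), nrow = 4, byrow = TRUE)
  expect_true(all(apply(tab, 1, function(x) all(diff(x) >= 0))))
  expect_true(all(apply(tab, 2, function(x) all(diff(x) >= 0))))
  expect_identical(cells$priority[1], "very_low")    # good + unlikely
  expect_identical(cells$priority[16], "high")       # very_poor + highly_likely
})

test_that("malformed risk matrices are rejected at construction", {
  ok <- default_risk_matrix()
  expect_s3_class(ok, "risk_matrix")

  expect_error(risk_matrix(c(good = 1, fair = 2, poor = 3),
                           ok$disturbance_scores, ok$sum_to_priority),
               class = "acm_matrix_error")
  expect_error(risk_matrix(c(good = 2, fair = 2, poor = 3, very_poor = 4),
                           ok$disturbance_scores, ok$sum_to_priority),
               class = "acm_matrix_error")
  # a sum band left uncovered
  expect_error(risk_matrix(ok$condition_scores, ok$disturbance_scores,
                           list(list(min = 2L, max = 3L, priority = "very_low"),
                                list(min = 6L, max = 8L, priority = "high"))),
               class = "acm_matrix_error")
  # endpoints not anchored
  expect_error(risk_matrix(ok$condition_scores, ok$disturbance_scores,
                           list(list(min = 2L, max = 8L, priority = "medium"))),
               class = "acm_matrix_error")
  # priority decreasing with the sum
  expect_error(risk_matrix(ok$condition_scores, ok$disturbance_scores,
                           list(list(min = 2L, max = 2L, priority = "very_low"),
                                list(min = 3L, max = 4L, priority = "medium"),
                                list(min = 5L, max = 7L, priority = "low"),
                                list(min = 8L, max = 8L, priority = "high"))),
               class = "acm_matrix_error")
})

test_that("the quantitative 1-10 rating is recorded but never changes the priority", {
  plan_for <- function(rating) list(
    eaves = list(visual = "cement_sheet_joiner_strips", install = "unknown",
                 condition = "poor", rating = rating, disturbance = "likely"))
  reports <- lapply(c(1L, 5L, 10L), function(r) {
    generate_report(scripted_session(plan = plan_for(r)),
                    report_id = "fixed", timestamp = "2026-01-01T00:00:00Z")
  })
  priorities <- vapply(reports, function(r) r$results$eaves$priority, "")
  expect_identical(unique(priorities), "medium")  # 3 + 3 = 6
  ratings <- vapply(reports, function(r) r$results$eaves$condition$quantitative, 1L)
  expect_identical(ratings, c(1L, 5L, 10L))
})

test_that("each priority level carries its verbatim recommendation", {
  inst <- shipped()
  expect_identical(recommendation_for("very_low", inst)$text,
                   "Monitor and no immediate action necessary")
  expect_identical(recommendation_for("low", inst)$text,
                   "Monitor and minor maintenance and repair")
  expect_identical(recommendation_for("medium", inst)$text,
                   paste("Removal and replacement should be a priority.",
                         "Major repair activity should be considered as a",
                         "secondary and temporary action"))
  expect_identical(recommendation_for("high", inst)$text,
                   "Consult an asbestos professional for removal, disposal and replacement of the ACM.")
  expect_identical(sort(names(inst$recommendations)),
                   sort(c("very_low", "low", "medium", "high")))
  expect_error(recommendation_for("extreme", inst), class = "acm_value_error")
})
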