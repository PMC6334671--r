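test_that("a fresh session starts at the first household question with no answers", {
  inst <- shipped()
  s1 <- start_session(inst)
  s2 <- start_session(inst)
  expect_identical(s1$cursor, "state")
  expect_length(s1$answers, 0)
  expect_false(is_complete(s1))
  expect_identical(s1, s2)
})

test_that("sessions cannot start on an instrument that fails validation", {
  expect_error(start_session(toy_cycle_instrument()),
               class = "acm_invalid_instrument")
})

test_that("answers are validated for order, options and scale bounds", {
  s <- start_session(shipped())
  expect_error(submit_answer(s, "dwelling_type", "separate_house"),
               class = "acm_order_error")
  expect_error(submit_answer(s, "state", "mars"), class = "acm_answer_error")
  s <- submit_answer(s, "state", "wa")
  s <- submit_answer(s, "user_description", "householder")
  expect_error(submit_answer(s, "post_code", 11L), class = "acm_answer_error")
  expect_error(submit_answer(s, "post_code", 6000.5), class = "acm_answer_error")
  s <- submit_answer(s, "post_code", 6000L)
  expect_identical(s$cursor, "construction_period")
})

test_that("the 1990 cutoff governs the full/abbreviated pathway split", {
  abbreviated <- scripted_session(period = "post_1990")
  full <- scripted_session(period = "pre_1985")
  unknown <- scripted_session(period = "unknown")
  inside_qs <- inside_question_ids()

  expect_false(any(pathway_trace(abbreviated) %in% inside_qs))
  expect_true(any(pathway_trace(full) %in% inside_qs))
  expect_true(any(pathway_trace(unknown) %in% inside_qs))

  # outside screening still happens on the abbreviated pathway
  expect_true("fencing_present" %in% pathway_trace(abbreviated))
})

test_that("select_pathway maps bands through the 1990 cutoff and matches the module gate", {
  expect_identical(select_pathway("post_1990"), "abbreviated")
  expect_identical(select_pathway("pre_1985"), "full")
  expect_identical(select_pathway("y1985_to_1990"), "full")
  expect_identical(select_pathway("unknown"), "full")
  expect_error(select_pathway("victorian_era"), class = "acm_value_error")

  # the declarative inside-module gate encodes exactly the full-pathway bands
  inst <- shipped()
  gate <- NULL
  for (m in inst$modules) if (identical(m$scope, "inside")) gate <- m$presented_when
  full_bands <- Filter(function(b) select_pathway(b) == "full",
                       c("pre_1985", "y1985_to_1990", "post_1990", "unknown"))
  expect_setequal(unlist(gate$values), full_bands)
})

test_that("absent materials skip their install, visual and assessment questions", {
  s <- scripted_session(period = "pre_1985", plan = list(
    outbuildings = NULL,
    eaves = list(visual = "metal_or_timber_lining")))
  tr <- pathway_trace(s)
  expect_true("outbuildings_present" %in% tr)
  expect_false(any(c("outbuildings_install", "outbuildings_visual",
                     "outbuildings_condition", "outbuildings_disturbance") %in% tr))
  # unlikely designation (non-ACM eaves lining) also skips the assessment
  expect_true("eaves_visual" %in% tr)
  expect_false("eaves_condition" %in% tr)
})

test_that("identical answer sequences produce identical traces", {
  plan <- list(eaves = list(visual = "cement_sheet_joiner_strips",
                            condition = "poor", disturbance = "likely"))
  s1 <- scripted_session(plan = plan)
  s2 <- scripted_session(plan = plan)
  expect_identical(pathway_trace(s1), pathway_trace(s2))
  expect_identical(s1$answers, s2$answers)
  expect_identical(length(pathway_trace(s1)), length(s1$answers))
  expect_false(anyDuplicated(pathway_trace(s1)) > 0)
})

test_that("every answer sequence on toy instruments terminates within |questions| steps and matches the enumerator", {
  toys <- list(toy_branch_instrument(),
               toy_instrument(list(toy_q("A"), toy_q("B"), toy_q("C"))),
               toy_instrument(list(
                 toy_q("A", list(list(predicate = "equals", value = "no",
                                      target = "end"))),
                 toy_q("B", list(list(predicate = "equals", value = "yes",
                                      target = "end"),
                                 list(predicate = "equals", value = "no",
                                      target = "end"))),
                 toy_q("C"))))
  for (inst in toys) {
    qids <- vapply(inst$modules[[1]]$questions, function(q) q$id, "")
    for (assignment in all_assignments(qids)) {
      answer_of <- function(q) assignment[[q]]
      s <- start_session(inst)
      steps <- 0
      while (!is_complete(s)) {
        s <- submit_answer(s, s$cursor, answer_of(s$cursor))
        steps <- steps + 1
        expect_lte(steps, length(qids))
      }
      expect_identical(pathway_trace(s), oracle_trace(inst, answer_of))
    }
  }
})

test_that("revising an earlier answer truncates the trace and re-routes", {
  inst <- toy_branch_instrument()
  s <- start_session(inst)
  s <- submit_answer(s, "A", "no")   # falls through to B
  s <- submit_answer(s, "B", "yes")
  expect_identical(s$cursor, "C")
  s <- submit_answer(s, "A", "yes")  # revision: now skips straight to C
  expect_identical(pathway_trace(s), "A")
  expect_identical(s$cursor, "C")
  expect_identical(names(s$answers), "A")
  s <- submit_answer(s, "C", "no")
  expect_true(is_complete(s))
  expect_identical(pathway_trace(s), c("A", "C"))
})

test_that("sessions round-trip through their JSON persistence file", {
  inst <- shipped()
  s <- scripted_session(plan = list(
    fencing = list(visual = "corrugated_cement_fence",
                   install = "original_pre_1990",
                   condition = "poor", disturbance = "highly_likely")))
  p <- tempfile(fileext = ".json")
  write_session(s, p)
  again <- read_session(p, inst)
  expect_identical(again$answers, s$answers)
  expect_identical(pathway_trace(again), pathway_trace(s))
  expect_identical(again$status, s$status)

  writeLines(substr(paste(readLines(p), collapse = "\n"), 1, 40), p)
  expect_error(read_session(p, inst), class = "acm_corrupt_file")
  unlink(p)
})
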