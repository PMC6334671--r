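test_that("reports require a complete session", {
  s <- start_session(shipped())
  s <- submit_answer(s, "state", "wa")
  expect_error(generate_report(s), class = "acm_incomplete_session")
})

test_that("an abbreviated post-1990 house reports outside materials only, with no priorities", {
  s <- scripted_session(period = "post_1990")
  r <- generate_report(s, timestamp = "2026-01-01T00:00:00Z")
  outside_ids <- vapply(list_materials(shipped(), "outside"), function(m) m$id, "")
  expect_setequal(names(r$results), outside_ids)
  cats <- vapply(r$results, function(z) z$category, "")
  expect_true(all(cats %in% c("not_applicable", "unlikely_acm")))
  expect_true(all(vapply(r$results, function(z) is.null(z$priority), TRUE)))
})

test_that("report generation is deterministic apart from the timestamp", {
  plan <- list(ceilings = list(visual = "cement_sheet_joiner_strips",
                               install = "original_pre_1990",
                               condition = "fair", disturbance = "somewhat_likely"))
  r1 <- generate_report(scripted_session(plan = plan), timestamp = "T")
  r2 <- generate_report(scripted_session(plan = plan), timestamp = "T")
  expect_identical(r1, r2)  # includes the content-derived report id
})

test_that("a likely ACM in very poor condition and highly likely disturbance reaches high priority", {
  plan <- list(fencing = list(visual = "corrugated_cement_fence",
                              install = "original_pre_1990",
                              condition = "very_poor", rating = 1L,
                              disturbance = "highly_likely"))
  r <- generate_report(scripted_session(plan = plan))
  z <- r$results$fencing
  expect_identical(z$category, "likely_acm")
  expect_identical(z$priority, "high")
  expect_identical(z$recommendation$text,
                   "Consult an asbestos professional for removal, disposal and replacement of the ACM.")
})

test_that("renderers list every result once and tag priorities with the colour code", {
  plan <- list(flooring = list(visual = "vinyl_with_fibrous_backing",
                               install = "unknown",
                               condition = "very_poor", disturbance = "highly_likely"))
  r <- generate_report(scripted_session(plan = plan),
                       timestamp = "2026-01-01T00:00:00Z")
  txt <- render_report(r, "text")
  for (z in r$results) {
    expect_identical(sum(gregexpr(z$display_name, txt, fixed = TRUE)[[1]] > 0) >= 1,
                     TRUE)
  }
  expect_match(txt, "high \\[red\\]")

  html <- render_report(r, "html")
  expect_match(html, "Consult an asbestos professional for removal, disposal and replacement of the ACM.",
               fixed = TRUE)
  expect_match(html, 'class="priority-high"', fixed = TRUE)
  expect_error(render_report(r, "pdf"))

  empty <- structure(list(report_id = "r0", instrument_id = "acm_check",
                          instrument_version = "1.0.0",
                          timestamp = "2026-01-01T00:00:00Z",
                          household = list(), results = list()),
                     class = "acm_report")
  expect_match(render_report(empty, "text"), "0 materials assessed")
  expect_silent(render_report(empty, "html"))
})

test_that("a report covers exactly the materials on the session pathway, with priorities iff triggered", {
  st <- simulate_survey(housing_stock_model(seed = 11), 25)
  for (r in st$reports) {
    for (z in r$results) {
      triggered <- z$category %in% c("possible_acm", "likely_acm")
      expect_identical(!is.null(z$priority), triggered)
      expect_identical(!is.null(z$recommendation), triggered)
      expect_identical(!is.null(z$condition), triggered)
    }
  }
  # completeness against the pathway on a scripted session
  s <- scripted_session(period = "post_1990")
  r <- generate_report(s)
  presented <- vapply(list_materials(shipped()), function(m) {
    m$presence_question %in% pathway_trace(s)
  }, TRUE)
  expect_setequal(names(r$results),
                  vapply(list_materials(shipped()), function(m) m$id, "")[presented])
})

test_that("report stores round-trip exactly and list newest first", {
  r1 <- generate_report(scripted_session(period = "post_1990"),
                        report_id = "a", timestamp = "2026-01-01T10:00:00Z")
  r2 <- generate_report(
    scripted_session(plan = list(
      eaves = list(visual = "cement_sheet_joiner_strips",
                   condition = "fair", disturbance = "likely"))),
    report_id = "b", timestamp = "2026-01-02T10:00:00Z")
  store <- add_report(add_report(report_store(), r1), r2)
  expect_error(add_report(store, r1), class = "acm_value_error")

  p <- tempfile(fileext = ".json")
  write_report_store(store, p)
  again <- read_report_store(p)
  expect_identical(again, store)

  listing <- list_reports(store)
  expect_identical(nrow(listing), 2L)
  expect_identical(listing$report_id, c("b", "a"))

  writeLines(substr(paste(readLines(p), collapse = ""), 1, 50), p)
  expect_error(read_report_store(p), class = "acm_corrupt_file")
  writeLines('{"something": "else"}', p)
  expect_error(read_report_store(p), class = "acm_corrupt_file")
  unlink(p)
})

test_that("aggregation matches a hand tally on a two-house store", {
  r1 <- generate_report(
    scripted_session(plan = list(
      eaves = list(visual = "cement_sheet_joiner_strips", install = "unknown",
                   condition = "fair", disturbance = "likely"),
      fencing = list(visual = "corrugated_cement_fence",
                     install = "original_pre_1990",
                     condition = "very_poor", disturbance = "highly_likely"))),
    report_id = "h1", timestamp = "2026-01-01T00:00:00Z")
  r2 <- generate_report(scripted_session(period = "post_1990"),
                        report_id = "h2", timestamp = "2026-01-02T00:00:00Z")
  agg <- aggregate_survey(add_report(add_report(report_store(), r1), r2))

  # hand tally: h1 assessed 13 materials (eaves possible, fencing likely,
  # 11 not applicable); h2 assessed the 8 outside materials, all not
  # applicable.
  expect_identical(agg$n_houses, 2L)
  mc <- agg$material_categories
  n_of <- function(mat, cat) mc$n[mc$material == mat & mc$category == cat]
  expect_identical(n_of("eaves", "possible_acm"), 1L)
  expect_identical(n_of("eaves", "not_applicable"), 1L)
  expect_identical(n_of("fencing", "likely_acm"), 1L)
  expect_identical(n_of("heater_flues", "not_applicable"), 1L)  # h1 only
  expect_identical(unname(agg$priority_counts),
                   c(0L, 1L, 0L, 1L))  # eaves fair+likely -> low; fencing -> high
  expect_identical(unname(agg$condition_counts["fair"]), 1L)
  expect_identical(unname(agg$condition_counts["very_poor"]), 1L)

  empty <- aggregate_survey(report_store())
  expect_identical(empty$n_houses, 0L)
  expect_identical(sum(empty$priority_counts), 0L)
  expect_identical(nrow(empty$material_categories), 0L)
})

test_that("the flat export carries one row per report-material pair with household descriptors", {
  st <- simulate_survey(housing_stock_model(seed = 5), 10)
  tab <- export_survey_table(st)
  n_expected <- sum(vapply(st$reports, function(r) length(r$results), 0L))
  expect_identical(nrow(tab), n_expected)
  expect_true(all(c("report_id", "post_code", "construction_period",
                    "material", "category", "condition_rating", "priority") %in%
                    names(tab)))
  p <- tempfile(fileext = ".csv")
  export_survey_table(st, p)
  expect_identical(nrow(utils::read.csv(p)), n_expected)
  unlink(p)
})

test_that("rule export exposes every decision-table row and the 16-cell matrix", {
  rules <- export_rules(shipped())
  expect_identical(nrow(rules$matrix), 16L)
  expect_true(nrow(rules$tables) >= 8)
  expect_true(all(rules$tables$category %in%
                    c("not_applicable", "unlikely_acm", "possible_acm", "likely_acm")))
  # the final rule of each table is the unconditional default
  last <- rules$tables[!duplicated(rules$tables$table, fromLast = TRUE), ]
  expect_true(all(last$present == "*" & last$house_age == "*" &
                    last$install == "*" & last$visual == "*"))
})
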