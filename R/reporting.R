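#' Generate a per-house summary report
#'
#' Runs classification and, where triggered, priority scoring over every
#' material assessed on the session's pathway and assembles the summary
#' report: household information, then one result per inspected material
#' with its probability designation and -- for possible or likely ACMs
#' only -- the condition assessment, likelihood of disturbance, priority
#' level and recommendation. Materials skipped by the branching (e.g. the
#' whole inside module on an abbreviated pathway) yield no result row.
#'
#' @param session A *complete* `acm_session`.
#' @param report_id Optional identifier; defaults to a deterministic
#'   content hash of the instrument identity and the answers, so the same
#'   session always yields the same id.
#' @param timestamp Optional ISO-8601 UTC string; defaults to the current
#'   time. Timestamps are the only non-deterministic report field.
#' @return An `acm_report` object.
#' @export
#' @examples
#' # see the package vignette for a fully worked session
generate_report <- function(session, report_id = NULL, timestamp = NULL) {
  stopifnot(inherits(session, "acm_session"))
  if (!is_complete(session)) {
    stop_acm("cannot report on an incomplete session (cursor at '%s')",
             session$cursor, class = "acm_incomplete_session")
  }
  inst <- session$instrument
  matrix <- as_risk_matrix(inst)
  results <- list()
  for (mat in inst$materials %||% list()) {
    if (!mat$presence_question %in% session$trace) next  # material skipped
    factors <- session_factors(session, mat$id)
    category <- classify_material(inst, mat$id, factors)
    res <- list(material = mat$id,
                display_name = mat$display_name %||% mat$id,
                setting = mat$setting,
                category = category,
                condition = NULL, disturbance = NULL,
                priority = NULL, recommendation = NULL)
    if (requires_priority_assessment(category)) {
      qual <- session$answers[[mat$condition_question %||% ""]]
      quant <- session$answers[[mat$condition_rating_question %||% ""]]
      dist <- session$answers[[mat$disturbance_question %||% ""]]
      if (is.null(qual) || is.null(dist)) {
        stop_acm("material '%s' is %s but its priority assessment is unanswered",
                 mat$id, category, class = "acm_incomplete_session")
      }
      res$condition <- c(list(qualitative = qual),
                         if (!is.null(quant)) list(quantitative = as.integer(quant)))
      res$disturbance <- list(level = dist)
      res$priority <- assess_priority(qual, dist, matrix)
      res$recommendation <- recommendation_for(res$priority, inst)
    }
    # absent assessments are omitted, not stored as nulls, so that the
    # JSON round trip is exact
    results[[mat$id]] <- res[!vapply(res, is.null, TRUE)]
  }
  household <- household_info(session)
  if (is.null(report_id)) {
    payload <- jsonlite::toJSON(list(inst$identifier, inst$version, session$answers),
                                auto_unbox = TRUE, digits = NA)
    report_id <- paste0("r", content_hash(as.character(payload)))
  }
  structure(list(report_id = report_id,
                 instrument_id = inst$identifier,
                 instrument_version = inst$version,
                 timestamp = timestamp %||% iso_utc_now(),
                 household = household,
                 results = results),
            class = "acm_report")
}

iso_utc_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# Answers of the household-information module, keyed by question id, with
# choice answers kept as option identifiers (labels live in the
# instrument and renderers can look them up).
household_info <- function(session) {
  inst <- session$instrument
  out <- list()
  for (m in inst$modules) {
    if (!identical(m$scope %||% "", "household_info")) next
    for (q in m$questions %||% list()) {
      if (q$id %in% names(session$answers)) out[[q$id]] <- session$answers[[q$id]]
    }
  }
  out
}

# ---- rendering --------------------------------------------------------------

#' Render a summary report
#'
#' Produces a plain-text or HTML document listing every material result
#' exactly once -- probability designation, condition, likelihood of
#' disturbance and priority level -- with priority rows tagged by the
#' documented colour code ([priority_colors()]) and each triggered
#' result's recommendation, description and resource links.
#'
#' @param report An `acm_report`.
#' @param format `"text"` or `"html"`.
#' @return A single string containing the rendered document.
#' @export
render_report <- function(report, format = c("text", "html")) {
  stopifnot(inherits(report, "acm_report"))
  format <- match.arg(format)
  if (format == "text") render_report_text(report) else render_report_html(report)
}

result_rows <- function(report) {
  rows <- lapply(report$results, function(r) {
    data.frame(
      material = r$material,
      display_name = r$display_name,
      setting = r$setting,
      category = r$category,
      condition = if (is.null(r$condition)) NA_character_ else r$condition$qualitative,
      condition_rating = if (is.null(r$condition$quantitative)) NA_integer_
                         else r$condition$quantitative,
      disturbance = if (is.null(r$disturbance)) NA_character_ else r$disturbance$level,
      priority = r$priority %||% NA_character_,
      recommendation = if (is.null(r$recommendation)) NA_character_
                       else r$recommendation$text
    )
  })
  if (length(rows) == 0) {
    return(data.frame(material = character(), display_name = character(),
                      setting = character(), category = character(),
                      condition = character(), condition_rating = integer(),
                      disturbance = character(), priority = character(),
                      recommendation = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

render_report_text <- function(report) {
  rows <- result_rows(report)
  colors <- priority_colors()
  lines <- c(
    sprintf("ACM screening summary report %s", report$report_id),
    sprintf("Instrument: %s v%s   Generated: %s",
            report$instrument_id, report$instrument_version, report$timestamp),
    "",
    "Household",
    vapply(names(report$household), function(k) {
      sprintf("  %-22s %s", k, as.character(report$household[[k]]))
    }, ""),
    "",
    sprintf("Results (%d material%s assessed)", nrow(rows),
            if (nrow(rows) == 1) "" else "s")
  )
  if (nrow(rows) > 0) {
    header <- sprintf("  %-28s %-14s %-10s %-14s %-18s", "Material", "Designation",
                      "Condition", "Disturbance", "Priority")
    body <- vapply(seq_len(nrow(rows)), function(i) {
      pr <- rows$priority[[i]]
      pr_txt <- if (is.na(pr)) "-" else sprintf("%s [%s]", pr, colors[[pr]])
      sprintf("  %-28s %-14s %-10s %-14s %-18s",
              rows$display_name[[i]], rows$category[[i]],
              ifelse(is.na(rows$condition[[i]]), "-", rows$condition[[i]]),
              ifelse(is.na(rows$disturbance[[i]]), "-", rows$disturbance[[i]]),
              pr_txt)
    }, "")
    lines <- c(lines, header, body)
  }
  recs <- Filter(function(r) !is.null(r$recommendation), report$results)
  if (length(recs) > 0) {
    lines <- c(lines, "", "Recommendations")
    for (r in recs) {
      rec <- r$recommendation
      lines <- c(lines,
                 sprintf("  %s (%s priority): %s", r$display_name, r$priority, rec$text))
      if (nzchar(rec$description %||% "")) {
        lines <- c(lines, sprintf("    %s", rec$description))
      }
      for (l in rec$links) lines <- c(lines, sprintf("    see: %s", l))
    }
  }
  paste(lines, collapse = "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_report_html <- function(report) {
  rows <- result_rows(report)
  colors <- priority_colors()
  td <- function(x) sprintf("<td>%s</td>", html_escape(as.character(x)))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    pr <- rows$priority[[i]]
    pr_cell <- if (is.na(pr)) "<td>-</td>" else {
      sprintf('<td class="priority-%s" style="background:%s">%s</td>',
              pr, colors[[pr]], pr)
    }
    paste0("<tr>", td(rows$display_name[[i]]), td(rows$category[[i]]),
           td(ifelse(is.na(rows$condition[[i]]), "-", rows$condition[[i]])),
           td(ifelse(is.na(rows$disturbance[[i]]), "-", rows$disturbance[[i]])),
           pr_cell, "</tr>")
  }, "")
  recs <- Filter(function(r) !is.null(r$recommendation), report$results)
  rec_html <- vapply(recs, function(r) {
    rec <- r$recommendation
    links <- paste(vapply(rec$links, function(l) {
      sprintf('<a href="%s">%s</a>', html_escape(l), html_escape(l))
    }, ""), collapse = " ")
    sprintf("<li><strong>%s</strong> (%s priority): %s<br/><em>%s</em> %s</li>",
            html_escape(r$display_name), r$priority, html_escape(rec$text),
            html_escape(rec$description %||% ""), links)
  }, "")
  hh <- vapply(names(report$household), function(k) {
    sprintf("<tr><th>%s</th><td>%s</td></tr>", html_escape(k),
            html_escape(as.character(report$household[[k]])))
  }, "")
  paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>ACM screening report %s</title></head><body>", report$report_id),
    sprintf("<h1>ACM screening summary report</h1><p>Report %s &mdash; instrument %s v%s &mdash; %s</p>",
            report$report_id, report$instrument_id, report$instrument_version,
            report$timestamp),
    "<h2>Household</h2><table>", paste(hh, collapse = ""), "</table>",
    "<h2>Results</h2><table><tr><th>Material</th><th>Designation</th>",
    "<th>Condition</th><th>Disturbance</th><th>Priority</th></tr>",
    paste(body, collapse = ""), "</table>",
    if (length(rec_html) > 0) {
      paste0("<h2>Recommendations</h2><ul>", paste(rec_html, collapse = ""), "</ul>")
    } else "",
    "</body></html>"
  )
}

#' @export
print.acm_report <- function(x, ...) {
  cat(render_report_text(x), "\n")
  invisible(x)
}

# ---- report store -----------------------------------------------------------

#' An on-disk collection of house reports
#'
#' A report store holds the summary reports of many dwellings -- useful
#' for owners of multiple properties and for survey aggregation -- as a
#' single portable JSON document. `add_report()` enforces unique report
#' ids; `read_report_store()` raises an explicit corruption error on a
#' truncated or malformed file and otherwise round-trips exactly.
#'
#' @param reports Optional list of `acm_report` objects to seed the store.
#' @return `report_store()` and `add_report()` return the
#'   `acm_report_store`; `write_report_store()` its path, invisibly.
#' @export
#' @examples
#' st <- report_store()
#' length(st$reports)
report_store <- function(reports = list()) {
  store <- structure(list(reports = list()), class = "acm_report_store")
  for (r in reports) store <- add_report(store, r)
  store
}

#' @rdname report_store
#' @param store An `acm_report_store`.
#' @param report An `acm_report`.
#' @export
add_report <- function(store, report) {
  stopifnot(inherits(store, "acm_report_store"), inherits(report, "acm_report"))
  if (report$report_id %in% names(store$reports)) {
    stop_acm("report id '%s' already present in store", report$report_id,
             class = "acm_value_error")
  }
  store$reports[[report$report_id]] <- report
  store
}

#' @rdname report_store
#' @param path File path of the JSON store.
#' @export
write_report_store <- function(store, path) {
  stopifnot(inherits(store, "acm_report_store"))
  x <- list(store_format = 1L,
            reports = lapply(unname(store$reports), unclass))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname report_store
#' @export
read_report_store <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) {
                  stop_acm("corrupt report store %s: %s", path,
                           conditionMessage(e), class = "acm_corrupt_file")
                })
  if (!is.list(x) || !is_integerish(x$store_format %||% NA) || !is.list(x$reports)) {
    stop_acm("corrupt report store %s: not a report-store document", path,
             class = "acm_corrupt_file")
  }
  store <- report_store()
  for (r in x$reports) {
    r$results <- lapply(r$results, rebuild_result)
    names(r$results) <- vapply(r$results, function(z) z$material, "")
    r$household <- lapply(r$household, rebuild_scalar)
    store <- add_report(store, structure(r, class = "acm_report"))
  }
  store
}

rebuild_scalar <- function(x) if (is_integerish(x)) as.integer(x) else x

rebuild_result <- function(r) {
  if (!is.null(r$condition$quantitative)) {
    r$condition$quantitative <- as.integer(r$condition$quantitative)
  }
  if (!is.null(r$recommendation)) {
    r$recommendation$links <- as.character(unlist(r$recommendation$links %||% list()))
  }
  r
}

#' List stored reports, newest first
#'
#' @param store An `acm_report_store`.
#' @return Data frame with `report_id`, `timestamp`, `n_results`,
#'   `n_priority` (results carrying a priority), ordered newest first.
#' @export
list_reports <- function(store) {
  stopifnot(inherits(store, "acm_report_store"))
  rs <- store$reports
  if (length(rs) == 0) {
    return(data.frame(report_id = character(), timestamp = character(),
                      n_results = integer(), n_priority = integer()))
  }
  out <- data.frame(
    report_id = vapply(rs, function(r) r$report_id, ""),
    timestamp = vapply(rs, function(r) r$timestamp, ""),
    n_results = vapply(rs, function(r) length(r$results), 0L),
    n_priority = vapply(rs, function(r) {
      sum(vapply(r$results, function(z) !is.null(z$priority), TRUE))
    }, 0L)
  )
  rownames(out) <- NULL
  out[order(out$timestamp, seq_len(nrow(out)), decreasing = TRUE), , drop = FALSE]
}

# ---- aggregation ------------------------------------------------------------

#' Aggregate a store into a survey summary
#'
#' Cross-house epidemiologic aggregates: the number of houses assessed,
#' per-material counts over the four probability designations, the
#' priority-level distribution over all triggered assessments, and the
#' qualitative-condition distribution among possible/likely ACMs. Counts
#' obey conservation: each material's category counts sum to the number
#' of houses in which that material was assessed, and priority counts sum
#' to the number of possible/likely results.
#'
#' @param store An `acm_report_store`.
#' @return An `acm_survey_summary` list with elements `n_houses`,
#'   `material_categories` (long data frame material x category x n),
#'   `priority_counts`, `condition_counts`.
#' @export
aggregate_survey <- function(store) {
  stopifnot(inherits(store, "acm_report_store"))
  cats <- probability_categories()
  mc <- list()
  priority <- stats::setNames(rep(0L, 4), priority_levels())
  condition <- stats::setNames(rep(0L, 4), condition_levels())
  for (r in store$reports) {
    for (z in r$results) {
      key <- z$material
      if (is.null(mc[[key]])) mc[[key]] <- stats::setNames(rep(0L, 4), cats)
      mc[[key]][[z$category]] <- mc[[key]][[z$category]] + 1L
      if (!is.null(z$priority)) {
        priority[[z$priority]] <- priority[[z$priority]] + 1L
        condition[[z$condition$qualitative]] <- condition[[z$condition$qualitative]] + 1L
      }
    }
  }
  material_categories <- if (length(mc) == 0) {
    data.frame(material = character(), category = character(), n = integer())
  } else {
    do.call(rbind, lapply(names(mc), function(m) {
      data.frame(material = m, category = cats, n = unname(mc[[m]]))
    }))
  }
  structure(list(n_houses = length(store$reports),
                 material_categories = material_categories,
                 priority_counts = priority,
                 condition_counts = condition),
            class = "acm_survey_summary")
}

#' @export
print.acm_survey_summary <- function(x, ...) {
  cat(sprintf("<acm_survey_summary> %d house%s\n", x$n_houses,
              if (x$n_houses == 1) "" else "s"))
  if (nrow(x$material_categories) > 0) {
    wide <- stats::xtabs(n ~ material + category, data = x$material_categories)
    print(wide)
  }
  cat("priority levels among possible/likely ACMs:\n")
  print(x$priority_counts)
  invisible(x)
}

#' Export a store as a flat delimited table
#'
#' One row per (report, material) pair, carrying household descriptors
#' (including post code, for downstream mapping tools), the probability
#' designation, the condition assessment including the unscored 1-10
#' rating, the disturbance level, the priority and the recommendation
#' text. Suitable for CSV export and downstream epidemiologic analysis.
#'
#' @param store An `acm_report_store`.
#' @param path Optional path; when given the table is also written as CSV.
#' @return The data frame, invisibly when `path` is given.
#' @export
export_survey_table <- function(store, path = NULL) {
  stopifnot(inherits(store, "acm_report_store"))
  rows <- list()
  for (r in store$reports) {
    hh <- r$household
    rr <- result_rows(r)
    if (nrow(rr) == 0) next
    rr$report_id <- r$report_id
    rr$timestamp <- r$timestamp
    rr$state <- as.character(hh$state %||% NA_character_)
    rr$post_code <- as.character(hh$post_code %||% NA_character_)
    rr$construction_period <- as.character(hh$construction_period %||% NA_character_)
    rr$dwelling_type <- as.character(hh$dwelling_type %||% NA_character_)
    rows[[length(rows) + 1]] <- rr
  }
  out <- if (length(rows) == 0) {
    cbind(data.frame(report_id = character(), timestamp = character(),
                     state = character(), post_code = character(),
                     construction_period = character(),
                     dwelling_type = character()),
          result_rows(structure(list(results = list()), class = "acm_report")))
  } else {
    do.call(rbind, rows)
  }
  front <- c("report_id", "timestamp", "state", "post_code",
             "construction_period", "dwelling_type")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, na = "")
    return(invisible(out))
  }
  out
}

#' Export an instrument's decision rules for review
#'
#' @param instrument An `acm_instrument`.
#' @return List of two data frames: `tables` (every decision-table rule,
#'   one row per rule with its factor pattern and category) and `matrix`
#'   (the 16-cell expanded risk matrix).
#' @export
export_rules <- function(instrument) {
  stopifnot(inherits(instrument, "acm_instrument"))
  rows <- list()
  for (tbl in instrument$tables %||% list()) {
    for (i in seq_along(tbl$rules)) {
      w <- tbl$rules[[i]]$when %||% list()
      fmt <- function(v) if (is.null(v)) "*" else paste(unlist(v), collapse = "|")
      rows[[length(rows) + 1]] <- data.frame(
        table = tbl$id, rule = i,
        present = if (is.null(w$present)) "*" else tolower(as.character(w$present)),
        house_age = fmt(w$house_age), install = fmt(w$install),
        visual = fmt(w$visual), category = tbl$rules[[i]]$category)
    }
  }
  tables <- if (length(rows) == 0) {
    data.frame(table = character(), rule = integer(), present = character(),
               house_age = character(), install = character(),
               visual = character(), category = character())
  } else {
    do.call(rbind, rows)
  }
  list(tables = tables, matrix = expand_risk_matrix(as_risk_matrix(instrument)))
}
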