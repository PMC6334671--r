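#' Start a questionnaire session
#'
#' Creates a fresh session positioned at the first question of the
#' household-information module (or, for instruments without one, the
#' first question overall). The instrument must validate cleanly; a
#' defective instrument is rejected with its first finding.
#'
#' @param instrument An `acm_instrument` that passes
#'   [validate_instrument()] with no findings.
#' @return An `acm_session` object with an empty answer set.
#' @export
#' @examples
#' s <- start_session(acm_check_instrument())
#' s$cursor
start_session <- function(instrument) {
  stopifnot(inherits(instrument, "acm_instrument"))
  findings <- validate_instrument(instrument)
  if (nrow(findings) > 0) {
    stop_acm("instrument fails validation (%d finding%s); first: [%s] %s",
             nrow(findings), if (nrow(findings) == 1) "" else "s",
             findings$location[[1]], findings$message[[1]],
             class = "acm_invalid_instrument")
  }
  first <- first_question(instrument)
  structure(
    list(instrument = instrument,
         answers = list(),
         trace = character(),
         cursor = first,
         status = if (identical(first, terminal_marker())) "complete" else "in_progress"),
    class = "acm_session"
  )
}

first_question <- function(inst) {
  mods <- inst$modules
  scopes <- vapply(mods, function(m) m$scope %||% "", "")
  start <- which(scopes == "household_info")
  order <- if (length(start) == 1) c(start, setdiff(seq_along(mods), start)) else seq_along(mods)
  for (i in order) {
    qs <- mods[[i]]$questions %||% list()
    if (length(qs) > 0) return(qs[[1]]$id)
  }
  terminal_marker()
}

#' Record an answer and advance the session
#'
#' The question must be the session's current cursor; answering an
#' *earlier* question instead revises it -- the trace is truncated after
#' that question, later answers are discarded, and routing restarts from
#' there. After recording, the cursor advances to the target of the first
#' matching branch rule, or falls through to the next question in module
#' order (skipping modules whose gate is closed), or terminates.
#'
#' @param session An `acm_session`.
#' @param question Question identifier; must equal `session$cursor` or an
#'   already-answered question.
#' @param answer An option identifier (choice questions) or integer
#'   within the scale bounds (numeric scales).
#' @return The updated `acm_session`.
#' @export
submit_answer <- function(session, question, answer) {
  stopifnot(inherits(session, "acm_session"))
  inst <- session$instrument
  if (identical(session$status, "complete") && !question %in% session$trace) {
    stop_acm("session is complete; no further questions", class = "acm_order_error")
  }
  if (!identical(question, session$cursor)) {
    pos <- match(question, session$trace)
    if (is.na(pos)) {
      stop_acm("out-of-order answer: expected question '%s', got '%s'",
               session$cursor, question, class = "acm_order_error")
    }
    # revision: rewind to the revised question and re-route from there
    keep <- session$trace[seq_len(pos - 1)]
    session$trace <- keep
    session$answers <- session$answers[keep]
    session$cursor <- question
    session$status <- "in_progress"
  }
  q <- get_question(inst, question)
  if (is.null(q)) {
    stop_acm("unknown question: %s", question, class = "acm_value_error")
  }
  answer <- check_answer(q, answer)
  session$answers[[question]] <- answer
  session$trace <- c(session$trace, question)
  session$cursor <- next_cursor(inst, q, session$answers)
  if (identical(session$cursor, terminal_marker())) session$status <- "complete"
  session
}

check_answer <- function(q, answer) {
  kind <- q$kind %||% ""
  if (kind == "numeric_scale") {
    if (!is_integerish(answer)) {
      stop_acm("question '%s' expects an integer answer", q$id,
               class = "acm_answer_error")
    }
    if (answer < q$scale_min || answer > q$scale_max) {
      stop_acm("answer %s to question '%s' is outside [%d, %d]",
               format(answer), q$id, q$scale_min, q$scale_max,
               class = "acm_answer_error")
    }
    return(as.integer(answer))
  }
  if (!is_scalar_chr(answer) || !answer %in% option_ids(q)) {
    stop_acm("'%s' is not an option of question '%s'",
             as.character(answer %||% "<missing>"), q$id,
             class = "acm_answer_error")
  }
  answer
}

# ---- routing ----------------------------------------------------------------

next_cursor <- function(inst, q, answers) {
  for (r in q$rules %||% list()) {
    if (rule_matches(inst, q, r, answers)) {
      return(resolve_target(inst, r$target, answers))
    }
  }
  lexical_next(inst, q$id, answers)
}

rule_matches <- function(inst, q, rule, answers) {
  pred <- rule$predicate
  ans <- answers[[q$id]]
  switch(pred,
    equals = identical(ans, rule$value),
    in_set = is_scalar_chr(ans) && ans %in% unlist(rule$values),
    band_before = band_compare(q, ans, rule$year, before = TRUE),
    band_after = band_compare(q, ans, rule$year, before = FALSE),
    category_in = {
      cat <- classify_session_material_answers(inst, rule$material, answers)
      cat %in% unlist(rule$values)
    },
    stop_acm("unknown predicate '%s' on question '%s'", pred, q$id,
             class = "acm_value_error")
  )
}

# An option matches band_before Y when its band ends before Y, and
# band_after Y when its band starts after Y; options without band years
# (e.g. "unknown") match neither.
band_compare <- function(q, ans, year, before) {
  if (!is_scalar_chr(ans)) return(FALSE)
  opt <- NULL
  for (o in q$options %||% list()) if (identical(o$id, ans)) opt <- o
  if (is.null(opt)) return(FALSE)
  if (before) {
    !is.null(opt$band_end) && opt$band_end < year
  } else {
    !is.null(opt$band_start) && opt$band_start > year
  }
}

resolve_target <- function(inst, target, answers) {
  if (identical(target, terminal_marker())) return(terminal_marker())
  if (is_module_target(target)) {
    mid <- sub("^module:", "", target)
    pos <- match(mid, inst_index(inst)$module_ids)
    return(module_entry(inst, pos, answers))
  }
  target
}

# First question of the first presented module at or after position `pos`.
module_entry <- function(inst, pos, answers) {
  mods <- inst$modules
  while (pos <= length(mods)) {
    m <- mods[[pos]]
    if (module_presented(inst, m, answers)) {
      qs <- m$questions %||% list()
      if (length(qs) > 0) return(qs[[1]]$id)
    }
    pos <- pos + 1
  }
  terminal_marker()
}

lexical_next <- function(inst, qid, answers) {
  idx <- inst_index(inst)
  mid <- idx$question_module[[qid]]
  pos <- match(mid, idx$module_ids)
  qs <- inst$modules[[pos]]$questions
  at <- which(vapply(qs, function(q) identical(q$id, qid), TRUE))[1]
  if (at < length(qs)) return(qs[[at + 1]]$id)
  module_entry(inst, pos + 1, answers)
}

# A module gate evaluates against the answer to its subject question; an
# unanswered gate leaves the module presented (the conservative, full
# pathway).
module_presented <- function(inst, m, answers) {
  gate <- m$presented_when
  if (is.null(gate)) return(TRUE)
  ans <- answers[[gate$question]]
  if (is.null(ans)) return(TRUE)
  gq <- get_question(inst, gate$question)
  rule_matches(inst, gq, c(gate, list(target = terminal_marker())),
               answers)
}

# ---- pathway selection ------------------------------------------------------

#' Full or abbreviated pathway for a construction-period band
#'
#' Houses built after 1990 -- the cutoff after which asbestos-containing
#' materials ceased to be installed in new housing -- receive the
#' abbreviated, outside-only questionnaire; every other band, including an
#' unknown construction period, receives the full questionnaire (the
#' conservative choice).
#'
#' @param period_band One of `"pre_1985"`, `"y1985_to_1990"`,
#'   `"post_1990"`, `"unknown"`.
#' @return `"abbreviated"` or `"full"`.
#' @export
#' @examples
#' select_pathway("post_1990")   # abbreviated
#' select_pathway("unknown")     # full
select_pathway <- function(period_band) {
  if (!is_scalar_chr(period_band) || !period_band %in% house_age_bands()) {
    stop_acm("undefined construction-period band: %s",
             as.character(period_band), class = "acm_value_error")
  }
  if (period_band == "post_1990") "abbreviated" else "full"
}

#' Session status and pathway trace
#'
#' `is_complete()` reports whether the session has reached the terminal
#' marker; `pathway_trace()` returns the ordered identifiers of every
#' question answered so far (the custom pathway through the instrument).
#'
#' @param session An `acm_session`.
#' @return A logical scalar / character vector.
#' @export
is_complete <- function(session) {
  stopifnot(inherits(session, "acm_session"))
  identical(session$status, "complete")
}

#' @rdname is_complete
#' @export
pathway_trace <- function(session) {
  stopifnot(inherits(session, "acm_session"))
  session$trace
}

#' Replay a recorded answer set through the engine
#'
#' Starts a fresh session and submits answers in pathway order until the
#' session completes or an answer is missing. Every submission passes the
#' full answer validation, so a replayed set is guaranteed
#' branching-consistent.
#'
#' @param instrument An `acm_instrument`.
#' @param answers Named list or vector mapping question identifiers to
#'   answers.
#' @return The resulting `acm_session` (complete iff every presented
#'   question had an answer).
#' @export
replay_answers <- function(instrument, answers) {
  session <- start_session(instrument)
  while (!is_complete(session)) {
    q <- session$cursor
    if (!q %in% names(answers)) break
    session <- submit_answer(session, q, answers[[q]])
  }
  session
}

# ---- persistence ------------------------------------------------------------

#' Save and restore sessions
#'
#' Sessions persist as JSON carrying the instrument identifier/version,
#' the answers in pathway order, the trace, and the status. Loading
#' replays the answers through the engine against the supplied
#' instrument, so a stored file can never smuggle in a
#' branching-inconsistent state; a mismatch with the recorded trace is an
#' error.
#'
#' @param session An `acm_session`.
#' @param path File path.
#' @param instrument The instrument to replay against (must match the
#'   stored identifier and version).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   the reconstructed `acm_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "acm_session"))
  x <- list(
    instrument_id = session$instrument$identifier,
    instrument_version = session$instrument$version,
    answers = session$answers,
    trace = as.list(session$trace),
    status = session$status
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, instrument) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) {
                  stop_acm("corrupt session file %s: %s", path,
                           conditionMessage(e), class = "acm_corrupt_file")
                })
  if (!identical(x$instrument_id, instrument$identifier) ||
      !identical(x$instrument_version, instrument$version)) {
    stop_acm("session file %s was recorded against instrument %s v%s",
             path, x$instrument_id %||% "?", x$instrument_version %||% "?",
             class = "acm_value_error")
  }
  session <- replay_answers(instrument, x$answers)
  if (!identical(session$trace, as.character(unlist(x$trace)))) {
    stop_acm("session file %s is inconsistent with the instrument's branching",
             path, class = "acm_corrupt_file")
  }
  session
}

#' @export
print.acm_session <- function(x, ...) {
  cat(sprintf("<acm_session> %s v%s: %s\n", x$instrument$identifier,
              x$instrument$version, x$status))
  cat(sprintf("  answered: %d question%s; cursor: %s\n", length(x$trace),
              if (length(x$trace) == 1) "" else "s", x$cursor))
  invisible(x)
}
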