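# Toy instruments and independent oracles used across the suite.

# Minimal yes/no question with optional branch rules.
toy_q <- function(id, rules = NULL) {
  q <- list(id = id, kind = "single_choice", prompt = id,
            options = list(list(id = "yes", label = "Yes"),
                           list(id = "no", label = "No")))
  if (!is.null(rules)) q$rules <- rules
  q
}

# Single-module instrument from a list of questions (no materials/scoring).
toy_instrument <- function(questions, id = "toy") {
  instrument_from_list(list(
    schema_version = 1L, identifier = id, version = "0",
    modules = list(list(id = "m1", title = "Toy", scope = "household_info",
                        questions = questions))))
}

# A -> B -> C -> A cycle through explicit rules.
toy_cycle_instrument <- function() {
  toy_instrument(list(
    toy_q("A", list(list(predicate = "equals", value = "yes", target = "B"))),
    toy_q("B", list(list(predicate = "equals", value = "yes", target = "C"))),
    toy_q("C", list(list(predicate = "equals", value = "yes", target = "A")))))
}

# Branching toy: A yes -> C (skipping B), C no -> end.
toy_branch_instrument <- function() {
  toy_instrument(list(
    toy_q("A", list(list(predicate = "equals", value = "yes", target = "C"))),
    toy_q("B"),
    toy_q("C", list(list(predicate = "equals", value = "no", target = "end")))))
}

# ---- independent oracles ----------------------------------------------------

# Brute-force cycle detector: enumerate every walk along the transition
# edges (rule targets + lexical successor); a cycle exists iff some walk
# revisits a question. Only for instruments with <= 20 questions.
toy_edges <- function(inst) {
  qids <- unlist(lapply(inst$modules, function(m) {
    vapply(m$questions, function(q) q$id, "")
  }))
  stopifnot(length(qids) <= 20)
  succ <- list()
  for (i in seq_along(qids)) {
    q <- NULL
    for (m in inst$modules) for (cand in m$questions) {
      if (identical(cand$id, qids[[i]])) q <- cand
    }
    targets <- character()
    for (r in q$rules %||% list()) {
      if (!identical(r$target, "end") && !startsWith(r$target, "module:")) {
        targets <- c(targets, r$target)
      }
    }
    if (i < length(qids)) targets <- c(targets, qids[[i + 1]])
    succ[[qids[[i]]]] <- unique(targets)
  }
  succ
}

brute_force_has_cycle <- function(inst) {
  succ <- toy_edges(inst)
  qids <- names(succ)
  found <- FALSE
  walk <- function(path) {
    if (found) return()
    tip <- path[[length(path)]]
    for (s in succ[[tip]]) {
      if (s %in% path) { found <<- TRUE; return() }
      walk(c(path, s))
    }
  }
  for (q in qids) walk(q)
  found
}

# Independent path enumerator for toy instruments whose rules use only
# the `equals` predicate: follows the declared first-match-else-lexical
# routing without touching the engine, returning the presented trace for
# one answer function.
oracle_trace <- function(inst, answer_of) {
  qids <- unlist(lapply(inst$modules, function(m) {
    vapply(m$questions, function(q) q$id, "")
  }))
  get_q <- function(id) {
    for (m in inst$modules) for (q in m$questions) if (identical(q$id, id)) return(q)
    NULL
  }
  cur <- qids[[1]]
  trace <- character()
  while (!identical(cur, "end")) {
    trace <- c(trace, cur)
    stopifnot(length(trace) <= length(qids) + 1)  # oracle-level termination guard
    q <- get_q(cur)
    a <- answer_of(cur)
    nxt <- NULL
    for (r in q$rules %||% list()) {
      stopifnot(identical(r$predicate, "equals"))
      if (identical(a, r$value)) { nxt <- r$target; break }
    }
    if (is.null(nxt)) {
      at <- match(cur, qids)
      nxt <- if (at < length(qids)) qids[[at + 1]] else "end"
    }
    cur <- nxt
  }
  trace
}

# All yes/no answer assignments over a set of question ids.
all_assignments <- function(qids) {
  grids <- do.call(expand.grid, c(stats::setNames(
    rep(list(c("yes", "no")), length(qids)), qids),
    stringsAsFactors = FALSE))
  lapply(seq_len(nrow(grids)), function(i) as.list(grids[i, , drop = FALSE]))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- shipped-instrument helpers ---------------------------------------------

shipped <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- acm_check_instrument()
    cache
  }
})

household_answers <- function(period = "pre_1985") {
  list(state = "wa", user_description = "householder", post_code = 6000L,
       construction_period = period, dwelling_type = "separate_house",
       occupants_count = 3L, occupants_age = "adults_only")
}

# Complete a session by answering the household block, then material
# questions from a per-material answer plan; unplanned materials are
# marked not present.
scripted_session <- function(period = "pre_1985", plan = list()) {
  inst <- shipped()
  s <- start_session(inst)
  hh <- household_answers(period)
  for (q in names(hh)) s <- submit_answer(s, q, hh[[q]])
  while (!is_complete(s)) {
    q <- s$cursor
    mat <- sub("_(present|install|visual|condition_rating|condition|disturbance)$", "", q)
    step <- sub(sprintf("^%s_", mat), "", q)
    p <- plan[[mat]]
    a <- if (is.null(p)) {
      "not_present"
    } else {
      switch(step,
             present = "present",
             install = p$install %||% "unknown",
             visual = p$visual,
             condition = p$condition %||% "fair",
             condition_rating = p$rating %||% 5L,
             disturbance = p$disturbance %||% "unlikely")
    }
    s <- submit_answer(s, q, a)
  }
  s
}

inside_question_ids <- function(inst = shipped()) {
  for (m in inst$modules) if (identical(m$scope, "inside")) {
    return(vapply(m$questions, function(q) q$id, ""))
  }
  character()
}

# Enumerate the full screening-factor space for a material.
factor_grid <- function(inst, material) {
  mat <- NULL
  for (m in inst$materials) if (identical(m$id, material)) mat <- m
  expand.grid(present = c(TRUE, FALSE),
              house_age_band = c("pre_1985", "y1985_to_1990", "post_1990", "unknown"),
              install_history = c("original_pre_1990", "replaced_post_1990",
                                  "installed_post_1990", "unknown"),
              visual_class = c("non_acm", "ambiguous", "suggestive"),
              stringsAsFactors = FALSE)
}
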