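#' Load a screening instrument definition
#'
#' Reads a declarative questionnaire instrument from a structured-text file
#' (YAML is canonical; JSON is also accepted), resolves all
#' cross-references, and returns an `acm_instrument` object. Structural
#' defects that make the definition unusable -- an unknown schema version,
#' or a branch rule, module gate or material specification that references
#' a question, module, option or decision table that does not exist -- are
#' errors at load time and name the offending identifier. Semantic
#' invariants (acyclicity of the question graph, option-count rules,
#' risk-matrix shape and so on) are audited separately by
#' [validate_instrument()], which returns findings rather than throwing,
#' so that a defective instrument can still be inspected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` instrument definition.
#' @param format File dialect; `"auto"` (default) infers it from the file
#'   extension, falling back to YAML.
#' @return An `acm_instrument` object.
#' @seealso [acm_check_instrument()] for the shipped instrument,
#'   [validate_instrument()], [write_instrument()].
#' @export
#' @examples
#' inst <- acm_check_instrument()
#' length(inst$modules)
load_instrument <- function(path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  if (!is_scalar_chr(path) || !file.exists(path)) {
    stop_acm("instrument file not found: %s", path, class = "acm_parse_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "yaml"
  }
  raw <- tryCatch(
    if (format == "json") {
      jsonlite::fromJSON(path, simplifyVector = FALSE)
    } else {
      # keep sequences as lists so YAML and JSON load to identical structures
      yaml::read_yaml(path, handlers = list(seq = function(x) as.list(x)))
    },
    error = function(e) {
      stop_acm("cannot parse instrument file %s: %s", path, conditionMessage(e),
               class = "acm_parse_error")
    }
  )
  instrument_from_list(raw)
}

#' Build an instrument from a parsed definition list
#'
#' Lower-level constructor behind [load_instrument()]; useful for
#' assembling small instruments programmatically (e.g. in tests).
#'
#' @param x A list with the fields of the instrument schema
#'   (`schema_version`, `identifier`, `version`, `modules`, and optionally
#'   `materials`, `tables`, `scoring`, `recommendations`, `metadata`,
#'   `house_age_question`).
#' @return An `acm_instrument` object.
#' @export
instrument_from_list <- function(x) {
  if (!is.list(x) || length(x) == 0) {
    stop_acm("empty or non-list instrument definition", class = "acm_parse_error")
  }
  ver <- x$schema_version
  if (is.null(ver)) {
    stop_acm("instrument definition lacks a schema_version field",
             class = "acm_parse_error")
  }
  if (!is_integerish(ver) || ver != 1) {
    stop_acm("unknown instrument schema version: %s", format(ver),
             class = "acm_schema_error")
  }
  for (field in c("identifier", "version")) {
    if (!is_scalar_chr(x[[field]] %||% NULL)) {
      stop_acm("instrument definition lacks a scalar '%s' field", field,
               class = "acm_parse_error")
    }
  }
  if (!is.list(x$modules) || length(x$modules) == 0) {
    stop_acm("instrument definition has no modules", class = "acm_parse_error")
  }
  inst <- structure(x, class = "acm_instrument")
  inst <- build_index(inst)
  check_references(inst)
  inst
}

# ---- internal index ---------------------------------------------------------

# Flatten modules into global question order and id-keyed lookups. The
# index is recomputed at load and never serialised.
build_index <- function(inst) {
  qids <- character()
  qmod <- character()
  questions <- list()
  for (m in inst$modules) {
    mid <- m$id %||% stop_acm("module without id", class = "acm_parse_error")
    for (q in m$questions %||% list()) {
      qid <- q$id %||% stop_acm("question without id in module '%s'", mid,
                                class = "acm_parse_error")
      q$module_id <- mid
      qids <- c(qids, qid)
      qmod <- c(qmod, mid)
      # first definition wins; duplicates are reported by the validator
      if (is.null(questions[[qid]])) questions[[qid]] <- q
    }
  }
  index <- list(
    question_ids = qids,
    question_module = stats::setNames(qmod, qids),
    questions = questions,
    module_ids = vapply(inst$modules, function(m) m$id %||% "", ""),
    materials = name_by_id(inst$materials %||% list()),
    tables = name_by_id(inst$tables %||% list())
  )
  attr(inst, "index") <- index
  inst
}

name_by_id <- function(items) {
  out <- list()
  for (it in items) if (!is.null(it$id) && is.null(out[[it$id]])) out[[it$id]] <- it
  out
}

inst_index <- function(inst) attr(inst, "index")

get_question <- function(inst, qid) inst_index(inst)$questions[[qid]]

get_material <- function(inst, mid) inst_index(inst)$materials[[mid]]

get_table <- function(inst, tid) inst_index(inst)$tables[[tid]]

option_ids <- function(q) vapply(q$options %||% list(), function(o) o$id %||% "", "")

is_module_target <- function(target) {
  is_scalar_chr(target) && startsWith(target, "module:")
}

# ---- load-time reference resolution ----------------------------------------

# Dangling references abort the load; everything else is left to
# validate_instrument() so partially broken instruments remain inspectable.
check_references <- function(inst) {
  idx <- inst_index(inst)
  known_q <- idx$question_ids
  known_m <- idx$module_ids
  assert_target <- function(target, where) {
    if (identical(target, terminal_marker())) return(invisible())
    if (is_module_target(target)) {
      mid <- sub("^module:", "", target)
      if (!mid %in% known_m) {
        stop_acm("%s: branch target references unknown module '%s'", where, mid,
                 class = "acm_reference_error")
      }
      return(invisible())
    }
    if (!is_scalar_chr(target) || !target %in% known_q) {
      stop_acm("%s: branch target references unknown question '%s'", where,
               as.character(target %||% "<missing>"),
               class = "acm_reference_error")
    }
  }
  for (m in inst$modules) {
    gate <- m$presented_when
    if (!is.null(gate) && !(gate$question %||% "") %in% known_q) {
      stop_acm("module '%s': presented_when references unknown question '%s'",
               m$id, gate$question %||% "<missing>",
               class = "acm_reference_error")
    }
    for (q in m$questions %||% list()) {
      for (r in q$rules %||% list()) {
        assert_target(r$target %||% NULL,
                      sprintf("question '%s'", q$id %||% "<missing>"))
        if (identical(r$predicate, "category_in") &&
            !(r$material %||% "") %in% names(idx$materials)) {
          stop_acm("question '%s': rule references unknown material '%s'",
                   q$id, r$material %||% "<missing>",
                   class = "acm_reference_error")
        }
      }
    }
  }
  for (mat in inst$materials %||% list()) {
    refs <- c(mat$presence_question, mat$install_question,
              unlist(mat$visual_questions), mat$condition_question,
              mat$condition_rating_question, mat$disturbance_question)
    bad <- setdiff(refs, known_q)
    if (length(bad) > 0) {
      stop_acm("material '%s' references unknown question '%s'",
               mat$id %||% "<missing>", bad[[1]],
               class = "acm_reference_error")
    }
    if (!is.null(mat$classification_table) &&
        !mat$classification_table %in% names(idx$tables)) {
      stop_acm("material '%s' references unknown decision table '%s'",
               mat$id, mat$classification_table, class = "acm_reference_error")
    }
  }
  haq <- inst$house_age_question
  if (!is.null(haq) && !haq %in% known_q) {
    stop_acm("house_age_question references unknown question '%s'", haq,
             class = "acm_reference_error")
  }
  invisible(inst)
}

# ---- validation -------------------------------------------------------------

#' Audit an instrument against its invariants
#'
#' Checks identifier uniqueness, question shape (choice questions need at
#' least two options, numeric scales need `scale_min < scale_max`, the
#' quantitative condition rating must run 1 to 10), branch-rule operand
#' validity, acyclicity of the question-transition graph, material
#' specifications (referenced questions must sit in the module matching
#' the material's setting), decision-table totality vocabulary, the
#' condition-by-disturbance risk matrix, and the recommendation map.
#' Findings are returned, never thrown: an empty result means every
#' invariant holds.
#'
#' @param instrument An `acm_instrument`.
#' @return A data frame with columns `check`, `location`, `message`; zero
#'   rows iff the instrument is valid.
#' @export
#' @examples
#' nrow(validate_instrument(acm_check_instrument()))  # 0
validate_instrument <- function(instrument) {
  stopifnot(inherits(instrument, "acm_instrument"))
  idx <- inst_index(instrument)
  f <- list()
  add <- function(check, location, message) {
    f[[length(f) + 1]] <<- data.frame(check = check, location = location,
                                      message = message)
  }

  ## uniqueness
  mids <- idx$module_ids
  for (d in unique(mids[duplicated(mids)])) {
    add("uniqueness", d, sprintf("duplicate module identifier '%s'", d))
  }
  scopes <- vapply(instrument$modules, function(m) m$scope %||% "", "")
  for (d in unique(scopes[duplicated(scopes) & nzchar(scopes)])) {
    add("uniqueness", d, sprintf("more than one module with scope '%s'", d))
  }
  bad_scope <- setdiff(scopes[nzchar(scopes)], module_scopes())
  for (s in bad_scope) add("schema", s, sprintf("unknown module scope '%s'", s))
  qids <- idx$question_ids
  for (d in unique(qids[duplicated(qids)])) {
    add("uniqueness", d, sprintf("duplicate question identifier '%s'", d))
  }

  ## question shape + rule operands
  for (m in instrument$modules) {
    for (q in m$questions %||% list()) {
      loc <- q$id %||% "<missing>"
      kind <- q$kind %||% ""
      if (!kind %in% c("single_choice", "numeric_scale", "year_band")) {
        add("schema", loc, sprintf("unknown question kind '%s'", kind))
        next
      }
      if (kind %in% c("single_choice", "year_band")) {
        oids <- option_ids(q)
        if (length(oids) < 2) {
          add("question", loc, "choice question has fewer than 2 options")
        }
        for (d in unique(oids[duplicated(oids)])) {
          add("uniqueness", loc, sprintf("duplicate option identifier '%s'", d))
        }
      }
      if (kind == "numeric_scale") {
        lo <- q$scale_min; hi <- q$scale_max
        if (!is_integerish(lo %||% NA) || !is_integerish(hi %||% NA) || lo >= hi) {
          add("question", loc, "numeric_scale requires integer scale_min < scale_max")
        }
      }
      for (r in q$rules %||% list()) {
        pred <- r$predicate %||% ""
        if (!pred %in% c("equals", "in_set", "band_before", "band_after",
                         "category_in")) {
          add("rule", loc, sprintf("unknown predicate '%s'", pred))
          next
        }
        if (pred == "equals" && !(r$value %||% "") %in% option_ids(q)) {
          add("rule", loc, sprintf("equals operand '%s' is not an option of '%s'",
                                   r$value %||% "<missing>", loc))
        }
        if (pred == "in_set") {
          bad <- setdiff(unlist(r$values), option_ids(q))
          if (length(bad) > 0) {
            add("rule", loc, sprintf("in_set operand '%s' is not an option of '%s'",
                                     bad[[1]], loc))
          }
        }
        if (pred %in% c("band_before", "band_after")) {
          if (kind != "year_band") {
            add("rule", loc, sprintf("%s predicate on non-year_band question", pred))
          }
          if (!is_integerish(r$year %||% NA)) {
            add("rule", loc, sprintf("%s predicate needs an integer year", pred))
          }
        }
        if (pred == "category_in") {
          bad <- setdiff(unlist(r$values), probability_categories())
          if (length(bad) > 0) {
            add("rule", loc, sprintf("category_in operand '%s' is not a probability category",
                                     bad[[1]]))
          }
        }
      }
    }
    gate <- m$presented_when
    if (!is.null(gate)) {
      gq <- get_question(instrument, gate$question %||% "")
      if (is.null(gq)) {
        add("reference", m$id, "presented_when gate question missing")
      } else if (identical(gate$predicate, "in_set")) {
        bad <- setdiff(unlist(gate$values), option_ids(gq))
        if (length(bad) > 0) {
          add("rule", m$id, sprintf("presented_when operand '%s' is not an option of '%s'",
                                    bad[[1]], gq$id))
        }
      }
    }
  }

  ## acyclicity of the question-transition graph
  cyc <- find_cycle(instrument)
  if (!is.null(cyc)) {
    add("acyclic", cyc[[1]],
        sprintf("question-transition graph has a cycle: %s",
                paste(cyc, collapse = " -> ")))
  }

  ## materials
  for (mat in instrument$materials %||% list()) {
    loc <- mat$id %||% "<missing>"
    setting <- mat$setting %||% ""
    if (!setting %in% c("outside", "inside")) {
      add("schema", loc, sprintf("unknown material setting '%s'", setting))
    }
    screen_refs <- c(mat$presence_question, mat$install_question,
                     unlist(mat$visual_questions))
    for (ref in screen_refs) {
      mod_scope <- scope_of_question(instrument, ref)
      if (!is.null(mod_scope) && nzchar(setting) && !identical(mod_scope, setting)) {
        add("material", loc,
            sprintf("question '%s' sits in a '%s' module but material is '%s'",
                    ref, mod_scope, setting))
      }
    }
    pq <- get_question(instrument, mat$presence_question %||% "")
    if (!is.null(pq) && !all(c("present", "not_present") %in% option_ids(pq))) {
      add("material", loc, "presence question must offer 'present' and 'not_present'")
    }
    iq <- get_question(instrument, mat$install_question %||% "")
    if (!is.null(iq)) {
      bad <- setdiff(option_ids(iq), install_history_levels())
      if (length(bad) > 0) {
        add("material", loc,
            sprintf("install question option '%s' is not an install-history level", bad[[1]]))
      }
    }
    for (vq_id in unlist(mat$visual_questions)) {
      vq <- get_question(instrument, vq_id)
      if (is.null(vq)) next
      cls <- vapply(vq$options %||% list(),
                    function(o) o$visual_class %||% "", "")
      bad <- setdiff(cls, visual_classes())
      if (length(bad) > 0 || any(!nzchar(cls))) {
        add("material", loc,
            sprintf("visual question '%s' has options without a valid visual_class", vq_id))
      }
    }
    cq <- get_question(instrument, mat$condition_question %||% "")
    if (!is.null(cq) && !identical(sort(option_ids(cq)), sort(condition_levels()))) {
      add("material", loc,
          sprintf("condition question '%s' must offer exactly the 4 qualitative levels",
                  mat$condition_question))
    }
    rq <- get_question(instrument, mat$condition_rating_question %||% "")
    if (!is.null(rq) && !(is_integerish(rq$scale_min %||% NA) &&
                          is_integerish(rq$scale_max %||% NA) &&
                          rq$scale_min == 1 && rq$scale_max == 10)) {
      add("material", loc,
          sprintf("quantitative condition rating '%s' must run 1 to 10",
                  mat$condition_rating_question))
    }
    dq <- get_question(instrument, mat$disturbance_question %||% "")
    if (!is.null(dq) && !identical(sort(option_ids(dq)), sort(disturbance_levels()))) {
      add("material", loc,
          sprintf("disturbance question '%s' must offer exactly the 4 likelihood levels",
                  mat$disturbance_question))
    }
    tbl <- get_table(instrument, mat$classification_table %||% "")
    if (!is.null(tbl)) {
      for (finding in validate_decision_table(tbl)) add("table", loc, finding)
    }
  }

  ## scoring + recommendations
  if (!is.null(instrument$scoring)) {
    mt <- tryCatch(as_risk_matrix(instrument), error = function(e) e)
    if (inherits(mt, "error")) {
      add("scoring", "scoring", conditionMessage(mt))
    }
    recs <- instrument$recommendations %||% list()
    missing <- setdiff(priority_levels(), names(recs))
    extra <- setdiff(names(recs), priority_levels())
    if (length(missing) > 0) {
      add("recommendation", "recommendations",
          sprintf("no recommendation for priority '%s'", missing[[1]]))
    }
    if (length(extra) > 0) {
      add("recommendation", "recommendations",
          sprintf("recommendation for unknown priority '%s'", extra[[1]]))
    }
  }

  haq <- instrument$house_age_question
  if (!is.null(haq)) {
    hq <- get_question(instrument, haq)
    if (!is.null(hq) && !identical(hq$kind, "year_band")) {
      add("schema", haq, "house_age_question must be a year_band question")
    }
  }

  if (length(f) == 0) {
    data.frame(check = character(), location = character(), message = character())
  } else {
    do.call(rbind, f)
  }
}

scope_of_question <- function(inst, qid) {
  mid <- inst_index(inst)$question_module[[qid]]
  if (is.null(mid) || is.na(mid)) return(NULL)
  for (m in inst$modules) if (identical(m$id, mid)) return(m$scope %||% NULL)
  NULL
}

validate_decision_table <- function(tbl) {
  findings <- character()
  rules <- tbl$rules %||% list()
  if (length(rules) == 0) {
    return(sprintf("decision table '%s' has no rules", tbl$id %||% "<missing>"))
  }
  for (r in rules) {
    if (!(r$category %||% "") %in% probability_categories()) {
      findings <- c(findings,
                    sprintf("decision table '%s': rule category '%s' is not a probability category",
                            tbl$id, r$category %||% "<missing>"))
    }
    w <- r$when %||% list()
    bad_keys <- setdiff(names(w), c("present", "house_age", "install", "visual"))
    if (length(bad_keys) > 0) {
      findings <- c(findings,
                    sprintf("decision table '%s': unknown factor '%s'", tbl$id, bad_keys[[1]]))
    }
    checks <- list(house_age = house_age_bands(), install = install_history_levels(),
                   visual = visual_classes())
    for (k in names(checks)) {
      bad <- setdiff(unlist(w[[k]]), checks[[k]])
      if (length(bad) > 0) {
        findings <- c(findings,
                      sprintf("decision table '%s': '%s' is not a legal %s value",
                              tbl$id, bad[[1]], k))
      }
    }
  }
  last <- rules[[length(rules)]]$when %||% list()
  if (length(last) != 0) {
    # require an unconditional final rule so the table is total by construction
    findings <- c(findings,
                  sprintf("decision table '%s' lacks an unconditional final rule", tbl$id))
  }
  findings
}

# Cycle detection over the question-transition graph (rule targets plus
# lexical fall-through), by depth-first search with colouring.
find_cycle <- function(inst) {
  idx <- inst_index(inst)
  qids <- unique(idx$question_ids)
  succ <- transition_edges(inst)
  color <- stats::setNames(rep(0L, length(qids)), qids)  # 0 new, 1 active, 2 done
  path <- character()
  cycle <- NULL
  visit <- function(q) {
    if (!is.null(cycle)) return()
    color[[q]] <<- 1L
    path <<- c(path, q)
    for (s in succ[[q]] %||% character()) {
      if (!s %in% qids) next
      if (color[[s]] == 1L) {
        cycle <<- c(path[which(path == s)[1]:length(path)], s)
        return()
      }
      if (color[[s]] == 0L) visit(s)
      if (!is.null(cycle)) return()
    }
    color[[q]] <<- 2L
    path <<- path[-length(path)]
  }
  for (q in qids) if (color[[q]] == 0L) visit(q)
  cycle
}

# Successor sets for every question: explicit rule targets (modules resolve
# to their first question) plus the lexical next question.
transition_edges <- function(inst) {
  idx <- inst_index(inst)
  qids <- idx$question_ids
  succ <- list()
  module_first <- list()
  for (m in inst$modules) {
    qs <- m$questions %||% list()
    if (length(qs) > 0) module_first[[m$id]] <- qs[[1]]$id
  }
  for (i in seq_along(qids)) {
    q <- get_question(inst, qids[[i]])
    targets <- character()
    for (r in q$rules %||% list()) {
      t <- r$target %||% NULL
      if (is.null(t) || identical(t, terminal_marker())) next
      if (is_module_target(t)) {
        mf <- module_first[[sub("^module:", "", t)]]
        if (!is.null(mf)) targets <- c(targets, mf)
      } else {
        targets <- c(targets, t)
      }
    }
    if (i < length(qids)) targets <- c(targets, qids[[i + 1]])
    succ[[qids[[i]]]] <- unique(targets)
  }
  succ
}

# ---- material listing -------------------------------------------------------

#' List the materials an instrument inspects
#'
#' @param instrument An `acm_instrument`.
#' @param setting Optional filter, `"outside"` or `"inside"`.
#' @return A list of material specifications in instrument order.
#' @export
#' @examples
#' length(list_materials(acm_check_instrument(), "outside"))  # 8
list_materials <- function(instrument, setting = NULL) {
  stopifnot(inherits(instrument, "acm_instrument"))
  mats <- instrument$materials %||% list()
  if (is.null(setting)) return(mats)
  if (!is_scalar_chr(setting) || !setting %in% c("outside", "inside")) {
    stop_acm("unknown material setting: %s", as.character(setting),
             class = "acm_value_error")
  }
  Filter(function(m) identical(m$setting, setting), mats)
}

# ---- serialization ----------------------------------------------------------

#' Write an instrument definition back to disk
#'
#' Serialises the definition (not the internal index) so that
#' `load_instrument(write_instrument(x, p))` reproduces `x`.
#'
#' @param instrument An `acm_instrument`.
#' @param path Output path; `.json` selects JSON, anything else YAML.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "acm_instrument"))
  x <- unclass(instrument)
  attr(x, "index") <- NULL
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, handlers = list(logical = yaml::verbatim_logical))
  }
  invisible(path)
}

#' Path to, and loader for, the shipped screening instrument
#'
#' The shipped instrument reconstructs a residential asbestos screening
#' questionnaire: three modules (household information, outside, inside),
#' eight outside locations (exterior walls and gable ends, eaves or soffit
#' linings, roofing, gutters, downpipes, electrical meter box, fencing,
#' outbuildings) and five inside locations (interior walls, cupboards and
#' backsplashes, ceilings, flooring, heater flues), with per-material
#' decision tables and the additive condition-by-disturbance risk matrix.
#' Question wording and decision-table cells are reconstructions (flagged
#' `reconstructed_tables` in the metadata); the 1985/1990 jurisdiction
#' cutoff years are instrument metadata.
#'
#' @return `acm_check_path()` returns the file path; `acm_check_instrument()`
#'   the loaded `acm_instrument`.
#' @export
#' @examples
#' inst <- acm_check_instrument()
#' vapply(inst$modules, function(m) m$scope, "")
acm_check_instrument <- function() {
  load_instrument(acm_check_path())
}

#' @rdname acm_check_instrument
#' @export
acm_check_path <- function() {
  system.file("extdata", "acm_check.yaml", package = "acmscreen", mustWork = TRUE)
}

#' @export
print.acm_instrument <- function(x, ...) {
  cat(sprintf("<acm_instrument> %s v%s\n", x$identifier, x$version))
  cat(sprintf("  modules:   %d (%s)\n", length(x$modules),
              paste(vapply(x$modules, function(m) m$id, ""), collapse = ", ")))
  cat(sprintf("  questions: %d\n", length(inst_index(x)$question_ids)))
  cat(sprintf("  materials: %d outside, %d inside\n",
              length(list_materials(x, "outside")),
              length(list_materials(x, "inside"))))
  invisible(x)
}
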