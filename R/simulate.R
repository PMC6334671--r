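#' Generative model of a synthetic housing stock
#'
#' Parameterises the distribution of synthetic dwellings used for
#' end-to-end testing and survey-scale simulation: the construction-period
#' mix, per-material presence probabilities conditional on the period
#' (pre/post the 1990 cutoff), install-history and visual-feature
#' distributions, and condition/disturbance distributions. The defaults
#' sketch an older, detached-house-heavy stock in which most structural
#' locations exist in every house while fences, outbuildings and fixed
#' heaters are optional; they are illustrative, not calibrated to any
#' real housing census. All probability vectors must sum to 1 (tolerance
#' 1e-9). Generation is driven by a single integer master seed with
#' per-household streams derived by counter-based splitting, so the same
#' `(model, index)` always reproduces the same dwelling.
#'
#' @param period_probs Probabilities over the four construction-period
#'   bands.
#' @param presence_probs Named list of per-material presence
#'   probabilities, each a vector `c(pre_1990 =, post_1990 =)`; the
#'   `default` entry covers materials without their own entry.
#' @param install_probs List with `pre_1990` and `post_1990` probability
#'   vectors over the four install-history options, selected by the
#'   house's period band (unknown periods draw from `pre_1990`, the
#'   conservative older-stock assumption).
#' @param visual_class_probs Probabilities over the three visual-feature
#'   classes; the drawn class picks uniformly among the material's
#'   options of that class (renormalising when a class is absent).
#' @param condition_probs Probabilities over the four qualitative
#'   condition levels. The correlated 1-10 rating is drawn around a
#'   per-level centre (good 9, fair 7, poor 4, very poor 2) with unit
#'   jitter, clamped to the scale.
#' @param disturbance_probs Probabilities over the four disturbance
#'   levels.
#' @param question_probs Optional named list of per-question probability
#'   vectors (keyed by option id) for questions without a screening role,
#'   e.g. household descriptors; unlisted questions draw uniformly.
#' @param seed Integer master seed.
#' @return A `housing_stock_model` object.
#' @export
#' @examples
#' m <- housing_stock_model(seed = 7)
#' ans <- synthesize_household(m, 1)
#' head(names(ans))
housing_stock_model <- function(
    period_probs = c(pre_1985 = 0.45, y1985_to_1990 = 0.15,
                     post_1990 = 0.30, unknown = 0.10),
    presence_probs = list(
      default = c(pre_1990 = 0.95, post_1990 = 0.95),
      fencing = c(pre_1990 = 0.60, post_1990 = 0.35),
      outbuildings = c(pre_1990 = 0.40, post_1990 = 0.25),
      heater_flues = c(pre_1990 = 0.30, post_1990 = 0.10)
    ),
    install_probs = list(
      pre_1990 = c(original_pre_1990 = 0.55, replaced_post_1990 = 0.15,
                   installed_post_1990 = 0.05, unknown = 0.25),
      post_1990 = c(original_pre_1990 = 0.00, replaced_post_1990 = 0.10,
                    installed_post_1990 = 0.70, unknown = 0.20)
    ),
    visual_class_probs = c(non_acm = 0.40, ambiguous = 0.35, suggestive = 0.25),
    condition_probs = c(good = 0.40, fair = 0.30, poor = 0.20, very_poor = 0.10),
    disturbance_probs = c(unlikely = 0.40, somewhat_likely = 0.30,
                          likely = 0.20, highly_likely = 0.10),
    question_probs = list(),
    seed = 1L) {
  model <- structure(
    list(period_probs = period_probs,
         presence_probs = presence_probs,
         install_probs = install_probs,
         visual_class_probs = visual_class_probs,
         condition_probs = condition_probs,
         disturbance_probs = disturbance_probs,
         question_probs = question_probs,
         seed = as.integer(seed)),
    class = "housing_stock_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  check_probs <- function(p, expected_names, where) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0)) {
      stop_acm("%s: probabilities must be non-negative numbers", where,
               class = "acm_model_error")
    }
    if (!is.null(expected_names) && !setequal(names(p), expected_names)) {
      stop_acm("%s: probabilities must be named over {%s}", where,
               paste(expected_names, collapse = ", "), class = "acm_model_error")
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop_acm("%s: probabilities sum to %.12f, not 1", where, sum(p),
               class = "acm_model_error")
    }
  }
  check_probs(model$period_probs, house_age_bands(), "period_probs")
  check_probs(model$visual_class_probs, visual_classes(), "visual_class_probs")
  check_probs(model$condition_probs, condition_levels(), "condition_probs")
  check_probs(model$disturbance_probs, disturbance_levels(), "disturbance_probs")
  for (k in names(model$install_probs)) {
    check_probs(model$install_probs[[k]], install_history_levels(),
                sprintf("install_probs$%s", k))
  }
  if (!all(c("pre_1990", "post_1990") %in% names(model$install_probs))) {
    stop_acm("install_probs needs pre_1990 and post_1990 entries",
             class = "acm_model_error")
  }
  for (k in names(model$presence_probs)) {
    p <- model$presence_probs[[k]]
    if (!is.numeric(p) || !setequal(names(p), c("pre_1990", "post_1990")) ||
        any(p < 0) || any(p > 1)) {
      stop_acm("presence_probs$%s must be c(pre_1990 =, post_1990 =) in [0, 1]",
               k, class = "acm_model_error")
    }
  }
  if (is.null(model$presence_probs$default)) {
    stop_acm("presence_probs needs a 'default' entry", class = "acm_model_error")
  }
  for (k in names(model$question_probs)) {
    check_probs(model$question_probs[[k]], NULL, sprintf("question_probs$%s", k))
  }
  if (!is_integerish(model$seed)) {
    stop_acm("seed must be an integer", class = "acm_model_error")
  }
  invisible(model)
}

# Counter-based seed splitting: one independent stream per household,
# reproducible and order-independent. Kept below 2^31 - 1.
derive_seed <- function(master, index) {
  as.integer(((as.numeric(master) %% 65521) * 31397 +
                as.numeric(index) * 2654435 + 97) %% 2147483587)
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Synthesise one dwelling's answer set
#'
#' Generates a complete, branching-consistent answer set by replaying the
#' engine question by question and sampling each answer as it is
#' presented -- answers are never drawn as an unconditional table, so
#' only questions on the generated pathway are answered and every answer
#' passes [submit_answer()] validation by construction.
#'
#' @param model A [housing_stock_model()].
#' @param index Household counter (1-based); with the model's seed it
#'   fully determines the dwelling.
#' @param instrument Instrument to run; the shipped one by default.
#' @return Named list mapping question identifiers to answers, in
#'   pathway order. Replay with [replay_answers()].
#' @export
synthesize_household <- function(model, index,
                                 instrument = acm_check_instrument()) {
  stopifnot(inherits(model, "housing_stock_model"))
  validate_model(model)
  if (!is_integerish(index) || index < 0) {
    stop_acm("index must be a non-negative integer", class = "acm_value_error")
  }
  with_preserved_rng({
    set.seed(derive_seed(model$seed, index))
    session <- start_session(instrument)
    while (!is_complete(session)) {
      q <- get_question(instrument, session$cursor)
      session <- submit_answer(session, q$id,
                               draw_answer(model, instrument, q, session$answers))
    }
    session$answers
  })
}

sample1 <- function(probs) {
  sample(names(probs), 1L, prob = unname(probs))
}

draw_answer <- function(model, inst, q, answers) {
  role <- question_role(inst, q$id)
  band <- if (!is.null(inst$house_age_question)) {
    answers[[inst$house_age_question]] %||% "unknown"
  } else "unknown"
  period_key <- if (identical(band, "post_1990")) "post_1990" else "pre_1990"
  switch(role$kind,
    period = sample1(model$period_probs),
    presence = {
      p <- (model$presence_probs[[role$material]] %||% model$presence_probs$default)[[period_key]]
      if (stats::runif(1) < p) "present" else "not_present"
    },
    install = sample1(model$install_probs[[period_key]]),
    visual = draw_visual(model, q),
    condition = sample1(model$condition_probs),
    rating = {
      mat <- get_material(inst, role$material)
      draw_rating(model, answers[[mat$condition_question %||% ""]])
    },
    disturbance = sample1(model$disturbance_probs),
    generic = draw_generic(model, q)
  )
}

draw_visual <- function(model, q) {
  opts <- q$options
  cls <- vapply(opts, function(o) o$visual_class %||% "ambiguous", "")
  avail <- intersect(names(model$visual_class_probs), unique(cls))
  p <- model$visual_class_probs[avail]
  p <- p / sum(p)
  chosen <- sample1(p)
  ids <- vapply(opts[cls == chosen], function(o) o$id, "")
  if (length(ids) == 1) ids else sample(ids, 1L)
}

rating_centers <- c(good = 9L, fair = 7L, poor = 4L, very_poor = 2L)

draw_rating <- function(model, qualitative) {
  center <- rating_centers[[qualitative %||% "fair"]]
  max(1L, min(10L, center + sample(-1:1, 1L)))
}

draw_generic <- function(model, q) {
  if (identical(q$kind, "numeric_scale")) {
    return(sample(seq(q$scale_min, q$scale_max), 1L))
  }
  ids <- option_ids(q)
  p <- model$question_probs[[q$id]]
  if (!is.null(p)) {
    p <- p[ids]
    if (anyNA(p)) {
      stop_acm("question_probs$%s does not cover all options", q$id,
               class = "acm_model_error")
    }
    sample1(p)
  } else if (length(ids) == 1) ids else sample(ids, 1L)
}

# Role of a question in the screening flow, resolved against the
# material specifications. The role drives which model distribution the
# generator samples from; `answers`-dependent context (period band, the
# already-drawn qualitative condition) rides along.
question_role <- function(inst, qid) {
  role <- question_role_static(inst, qid)
  role
}

question_role_static <- function(inst, qid) {
  cache <- attr(inst, "role_cache")
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    for (mat in inst$materials %||% list()) {
      assign(mat$presence_question, list(kind = "presence", material = mat$id),
             envir = cache)
      if (!is.null(mat$install_question)) {
        assign(mat$install_question, list(kind = "install", material = mat$id),
               envir = cache)
      }
      for (vq in unlist(mat$visual_questions)) {
        assign(vq, list(kind = "visual", material = mat$id), envir = cache)
      }
      if (!is.null(mat$condition_question)) {
        assign(mat$condition_question, list(kind = "condition", material = mat$id),
               envir = cache)
      }
      if (!is.null(mat$condition_rating_question)) {
        assign(mat$condition_rating_question,
               list(kind = "rating", material = mat$id), envir = cache)
      }
      if (!is.null(mat$disturbance_question)) {
        assign(mat$disturbance_question,
               list(kind = "disturbance", material = mat$id), envir = cache)
      }
    }
    if (!is.null(inst$house_age_question)) {
      assign(inst$house_age_question, list(kind = "period"), envir = cache)
    }
  }
  if (exists(qid, envir = cache, inherits = FALSE)) {
    get(qid, envir = cache, inherits = FALSE)
  } else {
    list(kind = "generic")
  }
}

#' Simulate a housing survey
#'
#' Generates `n` synthetic dwellings, runs each through the full
#' screening pipeline (branching engine, classification, priority
#' scoring, report generation) and collects the reports into a store.
#' Reports receive sequential house identifiers and deterministic
#' timestamps derived from the house index, so a fixed `(model, n)` run
#' is exactly reproducible, byte for byte.
#'
#' @param model A [housing_stock_model()].
#' @param n Number of houses (>= 0).
#' @param instrument Instrument to administer; the shipped one by default.
#' @return An `acm_report_store` with `n` reports.
#' @export
#' @examples
#' st <- simulate_survey(housing_stock_model(seed = 42), n = 5)
#' aggregate_survey(st)$n_houses
simulate_survey <- function(model, n, instrument = acm_check_instrument()) {
  stopifnot(inherits(model, "housing_stock_model"))
  if (!is_integerish(n) || n < 0) {
    stop_acm("n must be a non-negative integer", class = "acm_value_error")
  }
  store <- report_store()
  if (n == 0) return(store)
  base_time <- as.POSIXct("2026-01-01 00:00:00", tz = "UTC")
  for (i in seq_len(n)) {
    answers <- synthesize_household(model, i, instrument)
    session <- replay_answers(instrument, answers)
    report <- generate_report(
      session,
      report_id = sprintf("house-%06d", i),
      timestamp = format(base_time + (i - 1) * 60, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    )
    store <- add_report(store, report)
  }
  store
}

#' @export
print.housing_stock_model <- function(x, ...) {
  cat("<housing_stock_model>\n")
  cat("  period mix:", paste(sprintf("%s=%.2f", names(x$period_probs),
                                     x$period_probs), collapse = " "), "\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
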