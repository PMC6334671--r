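#' House-age probability category
#'
#' Maps a construction-period band to one of the three house-level
#' categories for the probability that the house contains asbestos.
#' Houses built before 1985 are highly likely to contain
#' asbestos-containing material; houses built after 1990 (when ACMs
#' ceased to be installed in new housing) are unlikely to; the 1985-1990
#' band, and an unknown construction period, sit in the middle category.
#'
#' @param band One of `"pre_1985"`, `"y1985_to_1990"`, `"post_1990"`,
#'   `"unknown"`.
#' @return `"likely"`, `"possible"` or `"unlikely"`.
#' @export
#' @examples
#' classify_house_age("pre_1985")   # likely
#' classify_house_age("post_1990")  # unlikely
classify_house_age <- function(band) {
  if (!is_scalar_chr(band) || !band %in% house_age_bands()) {
    stop_acm("undefined construction-period band: %s", as.character(band),
             class = "acm_value_error")
  }
  switch(band,
         pre_1985 = "likely",
         y1985_to_1990 = "possible",
         post_1990 = "unlikely",
         unknown = "possible")
}

#' The three house-age categories
#' @return Ordered character vector, least to most probable.
#' @export
house_age_categories <- function() c("unlikely", "possible", "likely")

#' Screening factors for one material
#'
#' Assembles the four screening factors used to designate a material --
#' house age, install/renovation history, presence of the
#' material/location, and its visual features -- either directly or from
#' a session's answers. When several visual questions are answered, the
#' most suggestive class wins (`suggestive` > `ambiguous` > `non_acm`);
#' with no visual answer the features count as `ambiguous` (unknown).
#'
#' @param present Logical; is the material/location present at the
#'   property?
#' @param house_age_band Construction-period band (see
#'   [classify_house_age()]).
#' @param install_history One of `"original_pre_1990"`,
#'   `"replaced_post_1990"`, `"installed_post_1990"`, `"unknown"`.
#' @param visual_class One of `"non_acm"`, `"ambiguous"`, `"suggestive"`.
#' @param visual_answers Optional named mapping question id -> option id,
#'   recorded for audit.
#' @return A `screening_factors` list.
#' @export
#' @examples
#' screening_factors(TRUE, "unknown", "unknown", "suggestive")
screening_factors <- function(present,
                              house_age_band = "unknown",
                              install_history = "unknown",
                              visual_class = "ambiguous",
                              visual_answers = NULL) {
  stopifnot(is.logical(present), length(present) == 1L, !is.na(present))
  if (!house_age_band %in% house_age_bands()) {
    stop_acm("undefined construction-period band: %s", house_age_band,
             class = "acm_value_error")
  }
  if (!install_history %in% install_history_levels()) {
    stop_acm("undefined install history: %s", install_history,
             class = "acm_value_error")
  }
  if (!visual_class %in% visual_classes()) {
    stop_acm("undefined visual class: %s", visual_class,
             class = "acm_value_error")
  }
  structure(list(present = present,
                 house_age_band = house_age_band,
                 install_history = install_history,
                 visual_class = visual_class,
                 visual_answers = visual_answers),
            class = "screening_factors")
}

#' @rdname screening_factors
#' @param session A (possibly in-progress) `acm_session`.
#' @param material Material identifier.
#' @export
session_factors <- function(session, material) {
  stopifnot(inherits(session, "acm_session"))
  factors_from_answers(session$instrument, material, session$answers)
}

factors_from_answers <- function(inst, material, answers) {
  mat <- get_material(inst, material)
  if (is.null(mat)) {
    stop_acm("unknown material: %s", material, class = "acm_value_error")
  }
  present <- identical(answers[[mat$presence_question]], "present")
  haq <- inst$house_age_question
  band <- if (!is.null(haq)) answers[[haq]] %||% "unknown" else "unknown"
  install <- answers[[mat$install_question %||% ""]] %||% "unknown"
  vqs <- unlist(mat$visual_questions)
  vans <- list()
  cls <- character()
  for (vq_id in vqs) {
    a <- answers[[vq_id]]
    if (is.null(a)) next
    vans[[vq_id]] <- a
    vq <- get_question(inst, vq_id)
    for (o in vq$options %||% list()) {
      if (identical(o$id, a)) cls <- c(cls, o$visual_class %||% "ambiguous")
    }
  }
  vc <- if ("suggestive" %in% cls) "suggestive"
        else if ("ambiguous" %in% cls) "ambiguous"
        else if (length(cls) > 0) "non_acm"
        else "ambiguous"
  screening_factors(present, band, install, vc,
                    visual_answers = if (length(vans)) vans else NULL)
}

#' Designate a material's probability of containing asbestos
#'
#' Evaluates the material's declarative decision table, first match wins,
#' over the four screening factors, returning one of the four probability
#' designations: `not_applicable` (reserved for materials not present),
#' `unlikely_acm`, `possible_acm` or `likely_acm`. Tables end in an
#' unconditional rule, so classification is total over the factor space.
#'
#' @param instrument An `acm_instrument`.
#' @param material Material identifier.
#' @param factors A [screening_factors()] object.
#' @return A probability category string.
#' @export
#' @examples
#' inst <- acm_check_instrument()
#' classify_material(inst, "eaves",
#'   screening_factors(TRUE, "unknown", "unknown", "suggestive"))
classify_material <- function(instrument, material, factors) {
  stopifnot(inherits(instrument, "acm_instrument"),
            inherits(factors, "screening_factors"))
  mat <- get_material(instrument, material)
  if (is.null(mat)) {
    stop_acm("unknown material: %s", material, class = "acm_value_error")
  }
  tbl <- get_table(instrument, mat$classification_table %||% "")
  if (is.null(tbl)) {
    stop_acm("material '%s' has no decision table", material,
             class = "acm_value_error")
  }
  for (r in tbl$rules) {
    if (decision_rule_matches(r$when %||% list(), factors)) return(r$category)
  }
  stop_acm("decision table '%s' is not total: no rule matched", tbl$id,
           class = "acm_table_error")
}

decision_rule_matches <- function(when, factors) {
  if (!is.null(when$present) && !identical(as.logical(when$present), factors$present)) {
    return(FALSE)
  }
  if (!is.null(when$house_age) && !factors$house_age_band %in% unlist(when$house_age)) {
    return(FALSE)
  }
  if (!is.null(when$install) && !factors$install_history %in% unlist(when$install)) {
    return(FALSE)
  }
  if (!is.null(when$visual) && !factors$visual_class %in% unlist(when$visual)) {
    return(FALSE)
  }
  TRUE
}

# Classification from a raw answer map (used by the branching engine's
# category_in predicate mid-session).
classify_session_material_answers <- function(inst, material, answers) {
  classify_material(inst, material, factors_from_answers(inst, material, answers))
}

#' Does a probability category trigger the priority assessment?
#'
#' The condition and likelihood-of-disturbance assessment is triggered
#' for each material designated a possible or likely ACM; materials
#' designated not applicable or unlikely are not assessed further.
#'
#' @param category A probability category string.
#' @return Logical scalar.
#' @export
#' @examples
#' requires_priority_assessment("possible_acm")  # TRUE
requires_priority_assessment <- function(category) {
  if (!is_scalar_chr(category) || !category %in% probability_categories()) {
    stop_acm("unknown probability category: %s", as.character(category),
             class = "acm_value_error")
  }
  category %in% c("possible_acm", "likely_acm")
}
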