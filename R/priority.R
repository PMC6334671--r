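#' Construct and validate a condition-by-disturbance risk matrix
#'
#' The priority of a possible or likely asbestos-containing material is
#' the sum of a numeric score for its qualitative condition and a numeric
#' score for its likelihood of disturbance, mapped through contiguous sum
#' bands to one of four ordered priority levels. Construction enforces
#' the matrix invariants and rejects a malformed matrix outright: scores
#' must be integers strictly increasing along each ordinal axis, every
#' one of the 16 condition-by-disturbance pairs must map to a priority,
#' priority must be non-decreasing in each axis, and the endpoints are
#' anchored (best condition + least disturbance gives `very_low`; worst
#' condition + most disturbance gives `high`).
#'
#' @param condition_scores Named integer vector over `good`, `fair`,
#'   `poor`, `very_poor`.
#' @param disturbance_scores Named integer vector over `unlikely`,
#'   `somewhat_likely`, `likely`, `highly_likely`.
#' @param sum_to_priority List of bands, each
#'   `list(min =, max =, priority =)`, jointly covering every achievable
#'   score sum.
#' @return A `risk_matrix` object.
#' @export
#' @examples
#' m <- default_risk_matrix()
#' assess_priority("fair", "likely", m)
risk_matrix <- function(condition_scores, disturbance_scores, sum_to_priority) {
  cs <- unlist(condition_scores)[condition_levels()]
  ds <- unlist(disturbance_scores)[disturbance_levels()]
  if (anyNA(cs) || anyNA(ds)) {
    stop_acm("risk matrix must score all 4 condition and all 4 disturbance levels",
             class = "acm_matrix_error")
  }
  if (!all(vapply(c(cs, ds), is_integerish, TRUE))) {
    stop_acm("risk-matrix scores must be integers", class = "acm_matrix_error")
  }
  if (any(diff(cs) <= 0) || any(diff(ds) <= 0)) {
    stop_acm("risk-matrix scores must strictly increase with worsening condition and rising disturbance",
             class = "acm_matrix_error")
  }
  bands <- lapply(sum_to_priority, function(b) {
    if (!is_integerish(b$min %||% NA) || !is_integerish(b$max %||% NA) ||
        b$min > b$max || !(b$priority %||% "") %in% priority_levels()) {
      stop_acm("malformed sum-to-priority band", class = "acm_matrix_error")
    }
    b
  })
  m <- structure(list(condition_scores = cs, disturbance_scores = ds,
                      sum_to_priority = bands),
                 class = "risk_matrix")
  cells <- expand_risk_matrix(m)  # errors if any sum is uncovered/ambiguous
  pr <- array(match(cells$priority, priority_levels()), dim = c(4, 4))
  if (any(apply(pr, 1, function(r) any(diff(r) < 0))) ||
      any(apply(pr, 2, function(c) any(diff(c) < 0)))) {
    stop_acm("risk matrix priority must be non-decreasing in each axis",
             class = "acm_matrix_error")
  }
  if (!identical(cells$priority[[1]], "very_low")) {
    stop_acm("best condition with least disturbance must map to very_low priority",
             class = "acm_matrix_error")
  }
  if (!identical(cells$priority[[nrow(cells)]], "high")) {
    stop_acm("worst condition with most disturbance must map to high priority",
             class = "acm_matrix_error")
  }
  m
}

#' Default risk matrix
#'
#' Scores 1/2/3/4 along each ordinal axis, with sums 2-3, 4-5, 6-7 and 8
#' mapping to very low, low, medium and high priority. The values are
#' instrument configuration (under `scoring:`) and can be overridden per
#' instrument; these defaults satisfy every structural constraint of the
#' additive scheme.
#'
#' @return A `risk_matrix` object.
#' @export
default_risk_matrix <- function() {
  risk_matrix(
    condition_scores = c(good = 1L, fair = 2L, poor = 3L, very_poor = 4L),
    disturbance_scores = c(unlikely = 1L, somewhat_likely = 2L,
                           likely = 3L, highly_likely = 4L),
    sum_to_priority = list(
      list(min = 2L, max = 3L, priority = "very_low"),
      list(min = 4L, max = 5L, priority = "low"),
      list(min = 6L, max = 7L, priority = "medium"),
      list(min = 8L, max = 8L, priority = "high")
    )
  )
}

#' Risk matrix carried by an instrument
#'
#' @param instrument An `acm_instrument` whose `scoring` block defines
#'   the score tables and sum bands.
#' @return A validated `risk_matrix`.
#' @export
as_risk_matrix <- function(instrument) {
  sc <- instrument$scoring
  if (is.null(sc)) {
    stop_acm("instrument carries no scoring block", class = "acm_matrix_error")
  }
  risk_matrix(sc$condition_scores, sc$disturbance_scores, sc$sum_to_priority)
}

#' Numeric scores of the two priority-assessment axes
#'
#' @param qualitative Condition level: `good`, `fair`, `poor`,
#'   `very_poor`.
#' @param level Disturbance level: `unlikely`, `somewhat_likely`,
#'   `likely`, `highly_likely`.
#' @param matrix A `risk_matrix`.
#' @return Integer score.
#' @export
#' @examples
#' score_condition("very_poor", default_risk_matrix())  # 4
score_condition <- function(qualitative, matrix = default_risk_matrix()) {
  stopifnot(inherits(matrix, "risk_matrix"))
  if (!is_scalar_chr(qualitative) || !qualitative %in% condition_levels()) {
    stop_acm("unknown condition level: %s", as.character(qualitative),
             class = "acm_value_error")
  }
  unname(matrix$condition_scores[[qualitative]])
}

#' @rdname score_condition
#' @export
score_disturbance <- function(level, matrix = default_risk_matrix()) {
  stopifnot(inherits(matrix, "risk_matrix"))
  if (!is_scalar_chr(level) || !level %in% disturbance_levels()) {
    stop_acm("unknown disturbance level: %s", as.character(level),
             class = "acm_value_error")
  }
  unname(matrix$disturbance_scores[[level]])
}

#' Priority level from condition and disturbance
#'
#' Sums the two axis scores and maps the sum through the matrix's bands.
#' The quantitative 1-10 condition rating is recorded for reporting but
#' never enters the score.
#'
#' @param condition Condition level string, or a list with a
#'   `$qualitative` element (e.g. a report's condition assessment).
#' @param disturbance Disturbance level string, or a list with `$level`.
#' @param matrix A `risk_matrix`.
#' @return One of `"very_low"`, `"low"`, `"medium"`, `"high"`.
#' @export
#' @examples
#' assess_priority("very_poor", "highly_likely")  # high
assess_priority <- function(condition, disturbance,
                            matrix = default_risk_matrix()) {
  if (is.list(condition)) condition <- condition$qualitative
  if (is.list(disturbance)) disturbance <- disturbance$level
  s <- score_condition(condition, matrix) + score_disturbance(disturbance, matrix)
  priority_for_sum(s, matrix)
}

priority_for_sum <- function(s, matrix) {
  for (b in matrix$sum_to_priority) {
    if (s >= b$min && s <= b$max) return(b$priority)
  }
  stop_acm("score sum %d is outside the risk matrix's bands (malformed matrix)",
           s, class = "acm_matrix_error")
}

#' Expand a risk matrix to its 16 cells
#'
#' @param matrix A `risk_matrix`.
#' @return Data frame with one row per (condition, disturbance) pair:
#'   the axis scores, their sum and the resulting priority, ordered by
#'   condition then disturbance.
#' @export
expand_risk_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "risk_matrix"))
  grid <- expand.grid(disturbance = disturbance_levels(),
                      condition = condition_levels(),
                      stringsAsFactors = FALSE)[, c("condition", "disturbance")]
  grid$condition_score <- unname(matrix$condition_scores[grid$condition])
  grid$disturbance_score <- unname(matrix$disturbance_scores[grid$disturbance])
  grid$sum <- grid$condition_score + grid$disturbance_score
  grid$priority <- vapply(grid$sum, priority_for_sum, "", matrix = matrix)
  grid
}

#' Recommendation for a priority level
#'
#' Returns the instrument's general recommendation for a priority level:
#' the verbatim recommendation text plus an explanatory description and
#' links to further resources. Recommendations rise in severity from
#' monitoring only, for very low priority, to consulting an asbestos
#' professional for removal, at high priority.
#'
#' @param priority One of the four priority levels.
#' @param instrument Instrument carrying the recommendation map; the
#'   shipped instrument by default.
#' @return List with `priority`, `text`, `description`, `links`.
#' @export
#' @examples
#' recommendation_for("very_low")$text
recommendation_for <- function(priority, instrument = acm_check_instrument()) {
  if (!is_scalar_chr(priority) || !priority %in% priority_levels()) {
    stop_acm("unknown priority level: %s", as.character(priority),
             class = "acm_value_error")
  }
  rec <- instrument$recommendations[[priority]]
  if (is.null(rec)) {
    stop_acm("instrument carries no recommendation for priority '%s'", priority,
             class = "acm_value_error")
  }
  list(priority = priority,
       text = rec$text,
       description = rec$description %||% "",
       links = as.character(unlist(rec$links %||% list())))
}

#' @export
print.risk_matrix <- function(x, ...) {
  cat("<risk_matrix> priority = band(condition score + disturbance score)\n")
  cells <- expand_risk_matrix(x)
  tab <- matrix(cells$priority, nrow = 4, byrow = TRUE,
                dimnames = list(condition = condition_levels(),
                                disturbance = disturbance_levels()))
  print(tab, quote = FALSE)
  invisible(x)
}
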