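# Expert calibration: score each expert's derived intervals against
# known-answer ("truth") intervals, and average the per-question overlap
# proportions into a single calibration weight per expert.

#' Validate a table of correct-answer intervals
#'
#' @param truths Data frame with columns `question_id`, `low`, `high`, all
#'   values on the \[0, 1\] scale, `low <= high`. A point-valued correct
#'   answer is encoded as a zero-width interval (`low == high`).
#' @return The validated data frame (ids coerced to character).
#' @export
validate_truth <- function(truths) {
  required <- c("question_id", "low", "high")
  if (!is.data.frame(truths)) stop("`truths` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(required, names(truths))
  if (length(missing_cols) > 0L) {
    stop("truth table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  truths$question_id <- as.character(truths$question_id)
  if (anyDuplicated(truths$question_id)) {
    stop("duplicate question_id in truth table", call. = FALSE)
  }
  for (col in c("low", "high")) {
    if (!is.numeric(truths[[col]]) || anyNA(truths[[col]])) {
      stop("column `", col, "` must be numeric without missing values",
           call. = FALSE)
    }
  }
  .check_fraction_units(truths$low, "low")
  .check_fraction_units(truths$high, "high")
  if (any(truths$low > truths$high)) {
    i <- which(truths$low > truths$high)[1L]
    stop(sprintf("truth interval reversed for question '%s'",
                 truths$question_id[i]), call. = FALSE)
  }
  truths
}

#' Overlap proportion of a derived interval with a correct-answer interval
#'
#' The proportion of the expert's derived confidence interval that overlaps
#' the pre-determined correct-answer interval:
#' `|ci intersect truth| / |ci|`. The score is 1 exactly when the expert's
#' interval sits entirely inside the truth interval, and 0 when they are
#' disjoint. Degenerate cases are scored by closed-set membership: a
#' zero-width expert interval scores 1 if its point lies inside the truth
#' interval; a zero-width (point) truth scores 1 if that point lies inside
#' the expert's interval.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param ci_low,ci_high Endpoints of the expert's derived interval(s).
#' @param truth_low,truth_high Endpoints of the correct-answer interval(s).
#' @return Numeric vector of overlap proportions in \[0, 1\].
#' @examples
#' question_score(0.2, 0.6, 0.3, 0.5)  # 0.5
#' @export
question_score <- function(ci_low, ci_high, truth_low, truth_high) {
  n <- max(length(ci_low), length(ci_high), length(truth_low), length(truth_high))
  ci_low <- rep_len(ci_low, n); ci_high <- rep_len(ci_high, n)
  truth_low <- rep_len(truth_low, n); truth_high <- rep_len(truth_high, n)
  if (any(ci_low > ci_high) || any(truth_low > truth_high)) {
    stop("interval endpoints must satisfy low <= high", call. = FALSE)
  }
  width <- ci_high - ci_low
  overlap <- pmax(0, pmin(ci_high, truth_high) - pmax(ci_low, truth_low))
  score <- ifelse(width > 0, overlap / width, NA_real_)
  # zero-width truth against a positive-width ci: membership of the point
  point_truth <- truth_high == truth_low & width > 0
  score[point_truth] <- as.numeric(
    truth_low[point_truth] >= ci_low[point_truth] &
    truth_low[point_truth] <= ci_high[point_truth])
  # zero-width ci: membership of the point in the truth interval (closed)
  point_ci <- width == 0
  score[point_ci] <- as.numeric(
    ci_low[point_ci] >= truth_low[point_ci] &
    ci_low[point_ci] <= truth_high[point_ci])
  score
}

#' Average per-question overlap scores into a calibration weight
#'
#' @param scores Numeric vector of per-question overlap proportions in
#'   \[0, 1\]; at least one.
#' @return The arithmetic mean, a weight in \[0, 1\]. A perfectly calibrated
#'   expert (every derived interval inside the corresponding truth interval)
#'   has weight 1.
#' @examples
#' calibrate_expert(c(0.5, 0.3, 0.4, 0.8, 0.0))  # 0.40
#' @export
calibrate_expert <- function(scores) {
  if (length(scores) == 0L) stop("no scores to average", call. = FALSE)
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  mean(scores)
}

#' Calibrate a panel of experts against a set of known-answer questions
#'
#' Derives each expert's standardized confidence intervals from their
#' calibration-question responses ([derive_ci()]), scores every
#' expert-question pair by overlap with the correct-answer interval
#' ([question_score()]), and averages each expert's scores into a
#' calibration weight ([calibrate_expert()]). Weights are absolute, not
#' re-normalized across the panel: a perfectly calibrated expert contributes
#' 1 in the later aggregation, a poorly calibrated one less than 1.
#'
#' @param records Elicitation records for the calibration questions
#'   (`item_id` matching the truth table's `question_id`).
#' @param truths Correct-answer intervals, see [validate_truth()].
#' @param target_level Nominal coverage for the derived intervals
#'   (default 0.80).
#' @param missing Policy when an expert did not answer some calibration
#'   question: `"error"` (default) stops; `"omit"` averages that expert over
#'   the questions they did answer.
#' @return An object of class `calibration` with components `scores` (data
#'   frame `expert_id`, `question_id`, `score`), `weights` (data frame
#'   `expert_id`, `weight`, sorted by expert), and `target_level`.
#' @export
calibrate_panel <- function(records, truths, target_level = 0.8,
                            missing = c("error", "omit")) {
  missing <- match.arg(missing)
  truths <- validate_truth(truths)
  ci <- derive_ci(records, target_level = target_level)
  unknown <- setdiff(unique(ci$item_id), truths$question_id)
  if (length(unknown) > 0L) {
    stop("records reference calibration question(s) with no truth interval: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ci[c("expert_id", "item_id")])) {
    stop("duplicate expert x question response", call. = FALSE)
  }
  experts <- sort(unique(ci$expert_id))
  missing_cells <- setdiff(
    paste(rep(experts, each = nrow(truths)), truths$question_id, sep = "\r"),
    paste(ci$expert_id, ci$item_id, sep = "\r"))
  if (length(missing_cells) > 0L && missing == "error") {
    cell <- strsplit(missing_cells[1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf(
      "expert '%s' has no response for calibration question '%s' (and %d other missing cell(s)); use missing = \"omit\" to average over answered questions",
      cell[1L], cell[2L], length(missing_cells) - 1L), call. = FALSE)
  }
  idx <- match(ci$item_id, truths$question_id)
  scores <- data.frame(
    expert_id = ci$expert_id,
    question_id = ci$item_id,
    score = question_score(ci$low, ci$high, truths$low[idx], truths$high[idx]),
    stringsAsFactors = FALSE
  )
  scores <- scores[order(scores$expert_id, scores$question_id), , drop = FALSE]
  rownames(scores) <- NULL
  weights <- data.frame(
    expert_id = experts,
    weight = vapply(experts, function(e) {
      calibrate_expert(scores$score[scores$expert_id == e])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(weights) <- NULL
  structure(
    list(scores = scores, weights = weights, target_level = target_level),
    class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("Expert calibration (", nrow(x$weights), " experts, ",
      length(unique(x$scores$question_id)), " questions, target level ",
      format(x$target_level), ")\n", sep = "")
  cat("Weights: mean = ", format(round(mean(x$weights$weight), 3)),
      ", range = ", format(round(min(x$weights$weight), 3)), " to ",
      format(round(max(x$weights$weight), 3)), "\n", sep = "")
  print(x$weights, ...)
  invisible(x)
}

# Accept either a calibration object or a bare expert_id/weight data frame.
.calibration_weights <- function(profiles) {
  if (inherits(profiles, "calibration")) return(profiles$weights)
  if (is.data.frame(profiles) && all(c("expert_id", "weight") %in% names(profiles))) {
    profiles$expert_id <- as.character(profiles$expert_id)
    return(profiles)
  }
  stop("`profiles` must be a calibration object or a data frame with columns expert_id, weight",
       call. = FALSE)
}
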