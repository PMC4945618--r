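# Interval-valued elicitation records and their standardization to derived
# confidence intervals.
#
# An elicitation record is one expert's answer to one item: an interval
# [low, high] on the 0-1 likelihood scale (the ends of the ellipse drawn on
# the questionnaire), a best estimate inside it, and the expert's stated
# confidence (0.5-1.0) that the truth lies within the interval.

#' Validate a table of interval-valued elicitation records
#'
#' Checks the structural invariants of elicitation records: columns
#' `expert_id`, `item_id`, `low`, `best`, `high`, `confidence`; ordering
#' `0 <= low <= best <= high <= 1`; and confidence on the half-to-full scale
#' `[0.5, 1]` used on the questionnaire. Zero-width responses
#' (`low == best == high`) are legal.
#'
#' @param records A data frame with columns `expert_id`, `item_id`, `low`,
#'   `best`, `high`, `confidence`. Values are decimal fractions, not
#'   percentages.
#' @return The validated data frame, invisibly unchanged (ids coerced to
#'   character).
#' @examples
#' rec <- data.frame(expert_id = "e1", item_id = "q1",
#'                   low = 0.2, best = 0.4, high = 0.6, confidence = 0.8)
#' validate_elicitation(rec)
#' @export
validate_elicitation <- function(records) {
  required <- c("expert_id", "item_id", "low", "best", "high", "confidence")
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("elicitation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records$expert_id <- as.character(records$expert_id)
  records$item_id <- as.character(records$item_id)
  for (col in c("low", "best", "high", "confidence")) {
    if (!is.numeric(records[[col]])) {
      stop("column `", col, "` must be numeric", call. = FALSE)
    }
    if (anyNA(records[[col]])) {
      stop("column `", col, "` contains missing values", call. = FALSE)
    }
  }
  .check_fraction_units(records$low, "low")
  .check_fraction_units(records$high, "high")
  .check_fraction_units(records$best, "best")

  bad_order <- records$low > records$best | records$best > records$high
  if (any(bad_order)) {
    i <- which(bad_order)[1L]
    stop(sprintf(
      "ordering violation (expected low <= best <= high) for expert '%s', item '%s': (%g, %g, %g)",
      records$expert_id[i], records$item_id[i],
      records$low[i], records$best[i], records$high[i]), call. = FALSE)
  }
  bad_range <- records$low < 0 | records$high > 1
  if (any(bad_range)) {
    i <- which(bad_range)[1L]
    stop(sprintf(
      "estimates outside [0, 1] for expert '%s', item '%s'",
      records$expert_id[i], records$item_id[i]), call. = FALSE)
  }
  bad_conf <- records$confidence < 0.5 | records$confidence > 1
  if (any(bad_conf)) {
    i <- which(bad_conf)[1L]
    stop(sprintf(
      "confidence out of range [0.5, 1] for expert '%s', item '%s': %g",
      records$expert_id[i], records$item_id[i], records$confidence[i]),
      call. = FALSE)
  }
  records
}

# Guard against percentage-style inputs (e.g. 80 where 0.8 was meant).
.check_fraction_units <- function(x, name) {
  if (any(x > 1 | x < 0)) {
    hint <- if (any(x > 1.5)) {
      " (values look like percentages; divide by 100)"
    } else {
      ""
    }
    stop("column `", name, "` must lie in [0, 1]", hint, call. = FALSE)
  }
  invisible(x)
}

#' Derive standardized confidence intervals by linear extrapolation
#'
#' Rescales each elicited interval about its best estimate so that every
#' expert's interval carries the same nominal coverage (`target_level`,
#' 0.80 by default). Each side of the interval is scaled by the factor
#' `target_level / confidence`:
#' \deqn{low' = best - (best - low) \cdot t/c, \quad
#'       high' = best + (high - best) \cdot t/c}
#' and the result is clipped to the physically bounded likelihood scale
#' \[0, 1\]. An expert who stated exactly `target_level` confidence keeps
#' their interval unchanged; a more confident expert's interval is widened,
#' a less confident expert's narrowed. The derived interval always contains
#' the best estimate.
#'
#' @param records Elicitation records; validated via
#'   [validate_elicitation()].
#' @param target_level Nominal coverage of the derived interval, in (0, 1].
#'   The default 0.80 gives derived 80\% confidence intervals; any level
#'   appropriate to the study can be used.
#' @return A data frame with columns `expert_id`, `item_id`, `low`, `high`,
#'   `best`, `target_level` and a logical `clipped` flagging intervals that
#'   ran past \[0, 1\] before clipping.
#' @examples
#' rec <- data.frame(expert_id = "e1", item_id = "q1",
#'                   low = 0.2, best = 0.4, high = 0.6, confidence = 1.0)
#' derive_ci(rec, target_level = 0.8)  # (0.24, 0.56)
#' @export
derive_ci <- function(records, target_level = 0.8) {
  records <- validate_elicitation(records)
  if (!is.numeric(target_level) || length(target_level) != 1L ||
      is.na(target_level) || target_level <= 0 || target_level > 1) {
    stop("`target_level` must be a single value in (0, 1]", call. = FALSE)
  }
  scale <- target_level / records$confidence
  low_raw <- records$best - (records$best - records$low) * scale
  high_raw <- records$best + (records$high - records$best) * scale
  clipped <- low_raw < 0 | high_raw > 1
  out <- data.frame(
    expert_id = records$expert_id,
    item_id = records$item_id,
    low = pmax(0, low_raw),
    high = pmin(1, high_raw),
    best = records$best,
    target_level = target_level,
    clipped = clipped,
    stringsAsFactors = FALSE
  )
  attr(out, "n_clipped") <- sum(clipped)
  out
}
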