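# The interval agreement approach: sum (weighted) indicator functions of
# experts' closed intervals into a piecewise-constant agreement function on
# [0, 1]. Where more experts' intervals overlap, the function is higher;
# with ten unit-weight experts in complete agreement, the maximum is 10.
#
# The canonical representation is exact: breakpoints are the union of all
# interval endpoints, each open piece between consecutive breakpoints
# carries a constant level, and each breakpoint carries its own point level
# (closed-endpoint convention, so levels at shared endpoints sum). No grid
# discretization is involved; grids appear only in test oracles and plots.

#' Aggregate weighted expert intervals into an agreement function
#'
#' Builds the agreement function of the interval agreement approach: at
#' every likelihood `x`, the level equals the sum of the weights of the
#' expert intervals (treated as closed) containing `x`. Unit weights give a
#' plain count of agreeing experts; calibration weights scale each expert's
#' contribution down from 1.
#'
#' @param intervals A data frame with columns `low`, `high` (in \[0, 1\],
#'   `low <= high`), optionally `weight` (default 1, in \[0, 1\]) and
#'   `expert_id`.
#' @return An object of class `agreement_function`: a list with
#'   `breakpoints` (strictly increasing positions), `piece_levels` (constant
#'   level on each open piece between consecutive breakpoints),
#'   `point_levels` (level at each breakpoint), `total_weight`
#'   (sum of weights) and `n_intervals`.
#' @examples
#' af <- aggregate_intervals(data.frame(low = c(0, 0.2), high = c(0.4, 0.6)))
#' evaluate_agreement(af, c(0.1, 0.3, 0.5))  # 1 2 1
#' @export
aggregate_intervals <- function(intervals) {
  if (!is.data.frame(intervals) || !all(c("low", "high") %in% names(intervals))) {
    stop("`intervals` must be a data frame with columns low, high", call. = FALSE)
  }
  if (nrow(intervals) == 0L) {
    stop("cannot aggregate an empty set of intervals", call. = FALSE)
  }
  low <- intervals$low
  high <- intervals$high
  weight <- if ("weight" %in% names(intervals)) intervals$weight else rep(1, nrow(intervals))
  if (anyNA(low) || anyNA(high) || anyNA(weight)) {
    stop("intervals contain missing values", call. = FALSE)
  }
  if (any(low > high)) stop("interval endpoints must satisfy low <= high", call. = FALSE)
  if (any(low < 0 | high > 1)) stop("intervals must lie within [0, 1]", call. = FALSE)
  if (any(weight < 0 | weight > 1)) stop("weights must lie in [0, 1]", call. = FALSE)

  bp <- sort(unique(c(low, high)))
  k <- length(bp)
  point_levels <- vapply(bp, function(b) sum(weight[low <= b & high >= b]),
                         numeric(1))
  piece_levels <- if (k > 1L) {
    vapply(seq_len(k - 1L), function(j) {
      sum(weight[low <= bp[j] & high >= bp[j + 1L]])
    }, numeric(1))
  } else {
    numeric(0)
  }
  structure(
    list(breakpoints = bp,
         piece_levels = piece_levels,
         point_levels = point_levels,
         total_weight = sum(weight),
         n_intervals = nrow(intervals)),
    class = "agreement_function")
}

#' Evaluate an agreement function at given likelihoods
#'
#' @param af An `agreement_function` from [aggregate_intervals()].
#' @param x Numeric vector of likelihoods in \[0, 1\].
#' @return The agreement level at each `x` under the closed-endpoint
#'   convention: at a breakpoint the point level, inside a piece the piece
#'   level, and 0 outside the union of all intervals.
#' @export
evaluate_agreement <- function(af, x) {
  stopifnot(inherits(af, "agreement_function"))
  if (any(is.na(x)) || any(x < 0 | x > 1)) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  bp <- af$breakpoints
  k <- length(bp)
  vapply(x, function(xi) {
    hit <- which(bp == xi)
    if (length(hit) == 1L) return(af$point_levels[hit])
    if (xi < bp[1L] || xi > bp[k]) return(0)
    j <- findInterval(xi, bp)
    af$piece_levels[j]
  }, numeric(1))
}

#' Aggregate a panel's responses to one item under a named variant
#'
#' The three aggregation variants used in the elicitation workflow:
#' `"raw"` aggregates the intervals exactly as elicited, all with unit
#' weight; `"ci"` first standardizes every interval to the derived
#' confidence interval at `target_level` ([derive_ci()]), still with unit
#' weight; `"calibrated"` uses the derived intervals weighted by each
#' expert's calibration weight, so a perfectly calibrated expert contributes
#' 1 and others less. Comparing the three shows how standardization and
#' calibration move the agreement structure.
#'
#' @param records Elicitation records for a single item (all rows must share
#'   one `item_id`).
#' @param profiles Calibration profiles ([calibrate_panel()] output or a
#'   data frame `expert_id`, `weight`); required for the calibrated variant.
#' @param variant One of `"raw"`, `"ci"`, `"calibrated"`.
#' @param target_level Nominal coverage for derived intervals (default 0.80).
#' @return An `agreement_function`.
#' @export
aggregate_variant <- function(records, profiles = NULL,
                              variant = c("calibrated", "ci", "raw"),
                              target_level = 0.8) {
  variant <- match.arg(variant)
  records <- validate_elicitation(records)
  if (length(unique(records$item_id)) > 1L) {
    stop("records span more than one item; aggregate one item at a time",
         call. = FALSE)
  }
  if (variant == "raw") {
    iv <- data.frame(expert_id = records$expert_id,
                     low = records$low, high = records$high, weight = 1,
                     stringsAsFactors = FALSE)
  } else {
    ci <- derive_ci(records, target_level = target_level)
    iv <- data.frame(expert_id = ci$expert_id,
                     low = ci$low, high = ci$high, weight = 1,
                     stringsAsFactors = FALSE)
    if (variant == "calibrated") {
      if (is.null(profiles)) {
        stop("the calibrated variant requires calibration profiles", call. = FALSE)
      }
      w <- .calibration_weights(profiles)
      idx <- match(iv$expert_id, w$expert_id)
      if (anyNA(idx)) {
        stop("no calibration weight for expert(s): ",
             paste(unique(iv$expert_id[is.na(idx)]), collapse = ", "),
             call. = FALSE)
      }
      iv$weight <- w$weight[idx]
    }
  }
  aggregate_intervals(iv)
}

#' @export
print.agreement_function <- function(x, ...) {
  cat("Agreement function over", x$n_intervals, "interval(s), total weight",
      format(x$total_weight), "\n")
  pos <- x$point_levels > 0
  if (!any(pos)) {
    cat("Identically zero (all contributions have zero weight)\n")
  } else {
    support <- range(x$breakpoints[pos])
    cat("Support [", format(support[1L]), ", ", format(support[2L]), "], ",
        length(x$breakpoints), " breakpoints, peak level ",
        format(max(x$point_levels)), "\n", sep = "")
  }
  invisible(x)
}

# Total area under the agreement function (point levels have measure zero).
.af_area <- function(af) {
  if (length(af$breakpoints) < 2L) return(0)
  sum(af$piece_levels * diff(af$breakpoints))
}
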