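# CSV schemas and configuration. All likelihoods and confidences are stored
# as decimal fractions; loaders reject percentage-style values with a units
# hint. Every writer has a reader that reproduces the records exactly.

.read_schema <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(df), required)
  if (length(unknown) > 0L) {
    stop(path, ": unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df
}

# Per-row numeric checks with file/line (header is line 1) in the message.
.check_rows <- function(df, path, cols, ordered = NULL) {
  for (col in cols) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      stop(path, ": column `", col, "` is not numeric", call. = FALSE)
    }
    bad <- which(is.na(x) | x < 0 | x > 1)
    if (length(bad) > 0L) {
      hint <- if (any(x[bad] > 1.5, na.rm = TRUE)) {
        " (values look like percentages; use decimal fractions)"
      } else {
        ""
      }
      stop(path, " line ", bad[1L] + 1L, ": `", col,
           "` outside [0, 1]", hint, call. = FALSE)
    }
  }
  if (!is.null(ordered)) {
    for (j in seq_len(length(ordered) - 1L)) {
      bad <- which(df[[ordered[j]]] > df[[ordered[j + 1L]]])
      if (length(bad) > 0L) {
        stop(path, " line ", bad[1L] + 1L, ": expected ",
             paste(ordered, collapse = " <= "), call. = FALSE)
      }
    }
  }
  invisible(df)
}

#' Read an elicitation table
#'
#' Expects columns `expert_id,item_id,low,best,high,confidence` with all
#' numeric values as decimal fractions. Malformed rows are reported with
#' their line number.
#'
#' @param path Path to a CSV file.
#' @return A validated elicitation data frame.
#' @export
read_elicitation <- function(path) {
  df <- .read_schema(path, c("expert_id", "item_id", "low", "best", "high",
                             "confidence"))
  .check_rows(df, path, c("low", "best", "high"),
              ordered = c("low", "best", "high"))
  bad <- which(is.na(df$confidence) | df$confidence < 0.5 | df$confidence > 1)
  if (length(bad) > 0L) {
    hint <- if (any(df$confidence[bad] > 1.5, na.rm = TRUE)) {
      " (values look like percentages; use decimal fractions)"
    } else {
      ""
    }
    stop(path, " line ", bad[1L] + 1L, ": `confidence` outside [0.5, 1]",
         hint, call. = FALSE)
  }
  validate_elicitation(df)
}

#' Write an elicitation table
#' @param records Elicitation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_elicitation <- function(records, path) {
  records <- validate_elicitation(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a correct-answer interval table
#'
#' Expects columns `question_id,low,high`.
#' @param path Path to a CSV file.
#' @return A validated truth data frame.
#' @export
read_truth <- function(path) {
  df <- .read_schema(path, c("question_id", "low", "high"))
  .check_rows(df, path, c("low", "high"), ordered = c("low", "high"))
  validate_truth(df)
}

#' Write a correct-answer interval table
#' @param truths Truth data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truths, path) {
  truths <- validate_truth(truths)
  utils::write.csv(truths, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a risk-item registry
#'
#' Expects columns `factor,element`; one row per risk-factor x element
#' combination in the study design.
#' @param path Path to a CSV file.
#' @return Data frame with character `factor` and `element`.
#' @export
read_items <- function(path) {
  df <- .read_schema(path, c("factor", "element"))
  df$factor <- as.character(df$factor)
  df$element <- as.character(df$element)
  if (anyDuplicated(df[c("factor", "element")])) {
    stop(path, ": duplicate factor x element row", call. = FALSE)
  }
  df
}

#' Read a screening table
#'
#' Expects columns `factor,element,retained` with `retained` coded as
#' TRUE/FALSE or 1/0; rows with `retained = FALSE` form the screening mask.
#' @param path Path to a CSV file.
#' @return Data frame with `factor`, `element`, logical `retained`.
#' @export
read_screening <- function(path) {
  df <- .read_schema(path, c("factor", "element", "retained"))
  df$factor <- as.character(df$factor)
  df$element <- as.character(df$element)
  ret <- df$retained
  if (is.character(ret)) ret <- toupper(trimws(ret)) %in% c("TRUE", "T", "1", "YES")
  ret <- as.logical(ret)
  if (anyNA(ret)) stop(path, ": `retained` must be logical", call. = FALSE)
  df$retained <- ret
  df
}

#' Serialize an agreement function to CSV
#'
#' One row per breakpoint with the level of the piece to its left
#' (`NA` for the first breakpoint) and the point level at the breakpoint.
#' [read_agreement()] reconstructs the function exactly.
#'
#' @param af An `agreement_function`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_agreement <- function(af, path) {
  stopifnot(inherits(af, "agreement_function"))
  k <- length(af$breakpoints)
  df <- data.frame(
    breakpoint = af$breakpoints,
    level_left_piece = c(NA_real_, af$piece_levels),
    point_level = af$point_levels
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a serialized agreement function
#' @param path CSV written by [write_agreement()].
#' @return An `agreement_function` (with `total_weight` and `n_intervals`
#'   unknown, set to `NA`).
#' @export
read_agreement <- function(path) {
  df <- .read_schema(path, c("breakpoint", "level_left_piece", "point_level"))
  structure(
    list(breakpoints = df$breakpoint,
         piece_levels = df$level_left_piece[-1L],
         point_levels = df$point_level,
         total_weight = NA_real_,
         n_intervals = NA_integer_),
    class = "agreement_function")
}

#' Write per-item summary statistics
#' @param summaries Data frame of [summarize_agreement()] rows (optionally
#'   with `factor`/`element`/`variant` columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write calibration scores and weights
#' @param cal A `calibration` object.
#' @param scores_path,weights_path Output CSV paths.
#' @return A character vector of the two paths, invisibly.
#' @export
write_calibration <- function(cal, scores_path, weights_path) {
  stopifnot(inherits(cal, "calibration"))
  utils::write.csv(cal$scores, scores_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cal$weights, weights_path, row.names = FALSE, quote = FALSE)
  invisible(c(scores_path, weights_path))
}

#' Read calibration weights
#' @param path CSV with columns `expert_id,weight`.
#' @return Data frame usable as `profiles` in [aggregate_variant()].
#' @export
read_calibration <- function(path) {
  df <- .read_schema(path, c("expert_id", "weight"))
  .check_rows(df, path, "weight")
  df$expert_id <- as.character(df$expert_id)
  df
}

#' Write a risk report
#' @param report A `risk_report`.
#' @param report_path,ranking_path Output CSV paths for the per-item table
#'   and the factor ranking.
#' @return A character vector of the two paths, invisibly.
#' @export
write_report <- function(report, report_path, ranking_path) {
  stopifnot(inherits(report, "risk_report"))
  per_item <- report$per_item
  per_item$variant <- report$variant
  utils::write.csv(per_item, report_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(rank_factors(report), ranking_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(report_path, ranking_path))
}

#' Write an agreement graph to an image file
#'
#' Renders [plot.agreement_function()] into a PNG file.
#' @param af An `agreement_function` (must be non-empty).
#' @param path Output PNG path.
#' @param width,height,res Device geometry.
#' @param ... Passed to [plot.agreement_function()].
#' @return `path`, invisibly.
#' @export
plot_agreement <- function(af, path, width = 800, height = 500, res = 120,
                           ...) {
  stopifnot(inherits(af, "agreement_function"))
  if (max(af$point_levels) <= 0) {
    stop("empty agreement: nothing to plot", call. = FALSE)
  }
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  plot(af, ...)
  invisible(path)
}

#' Assemble a validated run configuration
#'
#' Bundles the tunable settings of a pipeline run. All values are decimal
#' fractions.
#'
#' @param target_level Nominal coverage of derived intervals, in (0, 1\]
#'   (default 0.80).
#' @param variant Aggregation variant: `"calibrated"`, `"ci"` or `"raw"`.
#' @param headline_statistic `"min_max"`, `"max_max"` or `"centroid"`.
#' @param headline_threshold Affected-combination threshold in \[0, 1\]
#'   (default 0.05).
#' @param seed Integer seed for any randomness in the run.
#' @param output_dir Output directory.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(target_level = 0.8,
                       variant = c("calibrated", "ci", "raw"),
                       headline_statistic = c("min_max", "max_max", "centroid"),
                       headline_threshold = 0.05,
                       seed = 1L,
                       output_dir = ".") {
  variant <- match.arg(variant)
  headline_statistic <- match.arg(headline_statistic)
  if (!is.numeric(target_level) || target_level <= 0 || target_level > 1) {
    stop("`target_level` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(headline_threshold) || headline_threshold < 0 ||
      headline_threshold > 1) {
    stop("`headline_threshold` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(target_level = target_level, variant = variant,
         headline_statistic = headline_statistic,
         headline_threshold = headline_threshold,
         seed = as.integer(seed), output_dir = output_dir),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; unknown keys are
#' rejected.
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(path, ": unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}
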