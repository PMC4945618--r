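# Orchestration over the risk-factor x biological-element matrix:
# enumerate all combinations, apply the group screening (combinations judged
# to carry a 5% or smaller chance of causing management target failure are
# set aside), aggregate the panel's intervals for every retained
# combination, and rank risk factors by the number of elements they affect.

#' Item identifier for a risk-factor x element combination
#'
#' @param factor,element Character identifiers.
#' @return The `item_id` used in elicitation tables for that combination.
#' @export
risk_item_id <- function(factor, element) {
  paste(factor, element, sep = "::")
}

#' Build the full risk-factor x element matrix
#'
#' Enumerates the cross-product of risk factors and biological elements;
#' every combination starts retained (screening is applied separately with
#' [apply_screening()]).
#'
#' @param factors Character vector of risk-factor identifiers,
#'   duplicate-free.
#' @param elements Character vector of biological-element identifiers,
#'   duplicate-free.
#' @return An object of class `risk_matrix`: list with `factors`,
#'   `elements` and `pairs` (data frame `factor`, `element`, `item_id`,
#'   `retained`).
#' @examples
#' m <- risk_matrix(paste0("f", 1:3), paste0("el", 1:2))
#' nrow(m$pairs)  # 6
#' @export
risk_matrix <- function(factors, elements) {
  factors <- as.character(factors)
  elements <- as.character(elements)
  if (length(factors) == 0L || length(elements) == 0L) {
    stop("factors and elements must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(factors)) stop("duplicate risk factors", call. = FALSE)
  if (anyDuplicated(elements)) stop("duplicate elements", call. = FALSE)
  pairs <- expand.grid(element = elements, factor = factors,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[, c("factor", "element")]
  pairs$item_id <- risk_item_id(pairs$factor, pairs$element)
  pairs$retained <- TRUE
  rownames(pairs) <- NULL
  structure(list(factors = factors, elements = elements, pairs = pairs),
            class = "risk_matrix")
}

#' Apply a screening mask to a risk matrix
#'
#' Moves the masked combinations to the screened-out set. The mask encodes
#' the panel's preliminary group judgement that those combinations present a
#' small (at most the screening level, 5% in the reference workflow) chance
#' of causing management target failure; the screening itself is a group
#' decision supplied as input, not a computation.
#'
#' @param matrix A `risk_matrix`.
#' @param mask Data frame with columns `factor` and `element` listing the
#'   combinations to screen out; every row must exist in the matrix.
#' @return The updated `risk_matrix`.
#' @export
apply_screening <- function(matrix, mask) {
  stopifnot(inherits(matrix, "risk_matrix"))
  if (!is.data.frame(mask) || !all(c("factor", "element") %in% names(mask))) {
    stop("`mask` must be a data frame with columns factor, element", call. = FALSE)
  }
  if (nrow(mask) == 0L) return(matrix)
  key <- risk_item_id(as.character(mask$factor), as.character(mask$element))
  unknown <- setdiff(key, matrix$pairs$item_id)
  if (length(unknown) > 0L) {
    stop("screening mask references unknown combination(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  matrix$pairs$retained[matrix$pairs$item_id %in% key] <- FALSE
  matrix
}

#' @export
print.risk_matrix <- function(x, ...) {
  n <- nrow(x$pairs)
  r <- sum(x$pairs$retained)
  cat("Risk matrix: ", length(x$factors), " risk factors x ",
      length(x$elements), " elements = ", n, " combinations (",
      r, " retained, ", n - r, " screened out)\n", sep = "")
  invisible(x)
}

#' Run the full risk analysis over the retained combinations
#'
#' For every retained risk-factor x element combination, aggregates the
#' panel's elicited intervals under the chosen variant
#' ([aggregate_variant()]) and extracts the crisp summaries
#' ([summarize_agreement()]). A combination counts as "affected" for its
#' risk factor when the headline likelihood strictly exceeds
#' `headline_threshold`; the default threshold 0.05 matches the screening
#' level, so screened-out combinations and sub-threshold results are
#' treated alike.
#'
#' @param matrix A `risk_matrix`, typically after [apply_screening()].
#' @param records Elicitation records whose `item_id` follows
#'   [risk_item_id()]; every retained combination needs at least one record.
#' @param profiles Calibration profiles (required for the calibrated
#'   variant).
#' @param variant Aggregation variant, see [aggregate_variant()].
#' @param target_level Nominal coverage for derived intervals.
#' @param headline Statistic used as the headline likelihood
#'   (default min-max).
#' @param headline_threshold Likelihood above which a combination counts as
#'   affected (default 0.05).
#' @return An object of class `risk_report`: list with `per_item` (one
#'   [summarize_agreement()] row per retained combination plus `factor` and
#'   `element` columns), `per_factor` (data frame `factor`,
#'   `n_affected`, `max_headline`, `elements`), and the configuration
#'   fields `variant`, `headline`, `headline_threshold`, `target_level`.
#' @export
run_analysis <- function(matrix, records, profiles = NULL,
                         variant = c("calibrated", "ci", "raw"),
                         target_level = 0.8,
                         headline = c("min_max", "max_max", "centroid"),
                         headline_threshold = 0.05) {
  stopifnot(inherits(matrix, "risk_matrix"))
  variant <- match.arg(variant)
  headline <- match.arg(headline)
  if (headline_threshold < 0 || headline_threshold > 1) {
    stop("`headline_threshold` must lie in [0, 1]", call. = FALSE)
  }
  retained <- matrix$pairs[matrix$pairs$retained, , drop = FALSE]
  per_item <- NULL
  if (nrow(retained) > 0L) {
    records <- validate_elicitation(records)
    missing_items <- setdiff(retained$item_id, unique(records$item_id))
    if (length(missing_items) > 0L) {
      stop("no elicitation records for retained combination(s): ",
           paste(missing_items, collapse = ", "), call. = FALSE)
    }
    rows <- lapply(seq_len(nrow(retained)), function(i) {
      id <- retained$item_id[i]
      af <- aggregate_variant(records[records$item_id == id, , drop = FALSE],
                              profiles = profiles, variant = variant,
                              target_level = target_level)
      s <- summarize_agreement(af, item_id = id, headline = headline)
      cbind(data.frame(factor = retained$factor[i],
                       element = retained$element[i],
                       stringsAsFactors = FALSE), s)
    })
    per_item <- do.call(rbind, rows)
    rownames(per_item) <- NULL
  } else {
    per_item <- data.frame(factor = character(0), element = character(0),
                           item_id = character(0), min_max = numeric(0),
                           max_max = numeric(0), centroid = numeric(0),
                           headline = numeric(0), peak_agreement = numeric(0),
                           support_low = numeric(0), support_high = numeric(0),
                           n_experts = integer(0), stringsAsFactors = FALSE)
  }
  per_factor <- do.call(rbind, lapply(matrix$factors, function(f) {
    rows <- per_item[per_item$factor == f & per_item$headline > headline_threshold, ,
                     drop = FALSE]
    data.frame(
      factor = f,
      n_affected = nrow(rows),
      max_headline = if (nrow(rows) > 0L) max(rows$headline) else NA_real_,
      elements = paste(sort(rows$element), collapse = "; "),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_factor) <- NULL
  structure(
    list(per_item = per_item, per_factor = per_factor, variant = variant,
         headline = headline, headline_threshold = headline_threshold,
         target_level = target_level),
    class = "risk_report")
}

#' Rank risk factors by the number of affected elements
#'
#' Sorts risk factors by affected-element count (descending). Ties are
#' broken by the maximum headline likelihood across the factor's affected
#' combinations (descending), then alphabetically by factor name; the sort
#' is stable.
#'
#' @param report A `risk_report`.
#' @return The `per_factor` table of the report, sorted, with a `rank`
#'   column.
#' @export
rank_factors <- function(report) {
  stopifnot(inherits(report, "risk_report"))
  pf <- report$per_factor
  if (nrow(pf) == 0L) stop("report contains no risk factors", call. = FALSE)
  ml <- ifelse(is.na(pf$max_headline), -Inf, pf$max_headline)
  ord <- order(-pf$n_affected, -ml, pf$factor)
  out <- pf[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.risk_report <- function(x, ...) {
  cat("Risk report (", x$variant, " variant, headline = ", x$headline,
      " > ", format(x$headline_threshold), ")\n", sep = "")
  cat(nrow(x$per_item), "retained combination(s) analysed\n")
  affected <- x$per_factor[x$per_factor$n_affected > 0L, , drop = FALSE]
  if (nrow(affected) == 0L) {
    cat("No risk factor exceeds the headline threshold\n")
  } else {
    ord <- order(-affected$n_affected, affected$factor)
    print(affected[ord, c("factor", "n_affected", "max_headline")],
          row.names = FALSE, ...)
  }
  invisible(x)
}

#' Plot a risk report as a bipartite factor-element network
#'
#' Draws risk factors on one side, biological elements on the other, with an
#' edge for every affected combination; edge width is proportional to the
#' headline likelihood, so thicker lines flag the combinations most likely
#' to cause management target failure. Combinations at or below the
#' headline threshold are not drawn.
#'
#' @param x A `risk_report`.
#' @param max_lwd Line width of a likelihood-1 edge.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return The igraph object, invisibly.
#' @export
plot.risk_report <- function(x, max_lwd = 8, ...) {
  edges <- x$per_item[x$per_item$headline > x$headline_threshold, , drop = FALSE]
  if (nrow(edges) == 0L) {
    stop("no combination exceeds the headline threshold: nothing to plot",
         call. = FALSE)
  }
  factors <- sort(unique(edges$factor))
  elements <- sort(unique(edges$element))
  g <- igraph::graph_from_data_frame(
    edges[, c("factor", "element")],
    directed = FALSE,
    vertices = data.frame(name = c(factors, elements),
                          type = rep(c(FALSE, TRUE),
                                     c(length(factors), length(elements)))))
  lay <- igraph::layout_as_bipartite(g)
  igraph::plot.igraph(
    g, layout = lay,
    edge.width = pmax(0.5, edges$headline * max_lwd),
    vertex.shape = "rectangle",
    vertex.size = 36, vertex.size2 = 14,
    vertex.color = ifelse(igraph::V(g)$type, "white", "grey85"),
    vertex.label.cex = 0.7, vertex.label.color = "black", ...)
  invisible(g)
}
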