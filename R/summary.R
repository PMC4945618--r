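# Crisp likelihood summaries extracted from an agreement function:
# min-max and max-max (smallest / largest likelihood attaining the global
# maximum level of agreement) and the centroid (centre of gravity of the
# area under the curve). The elicitation workflow's default headline
# statistic is min-max, the most conservative of the three; the centroid or
# max-max can be chosen instead.

# Breakpoints attaining the global maximum level. Because intervals are
# closed, the point level at a piece's left breakpoint is always >= the
# piece level, so the global maximum is attained at breakpoints; a relative
# tolerance of 1e-9 absorbs floating-point noise in summed weights.
.af_peak <- function(af) {
  m <- max(af$point_levels, if (length(af$piece_levels)) max(af$piece_levels) else -Inf)
  if (m <= 0) stop("empty agreement: the function is identically zero", call. = FALSE)
  tol <- 1e-9 * max(1, abs(m))
  list(level = m, at = af$breakpoints[af$point_levels >= m - tol])
}

#' Smallest likelihood attaining the highest level of agreement
#'
#' @param af An `agreement_function`.
#' @return The minimum position on the likelihood axis where the agreement
#'   function reaches its global maximum (the start of the highest plateau).
#' @examples
#' af <- aggregate_intervals(data.frame(low = c(0, 0.2), high = c(0.4, 0.6)))
#' min_max(af)  # 0.2
#' @export
min_max <- function(af) {
  stopifnot(inherits(af, "agreement_function"))
  min(.af_peak(af)$at)
}

#' Largest likelihood attaining the highest level of agreement
#'
#' @param af An `agreement_function`.
#' @return The maximum position on the likelihood axis where the agreement
#'   function reaches its global maximum (the end of the highest plateau).
#' @export
max_max <- function(af) {
  stopifnot(inherits(af, "agreement_function"))
  max(.af_peak(af)$at)
}

#' Centroid of the area under an agreement function
#'
#' The centre of gravity of the area under the piecewise-constant curve,
#' computed exactly piece by piece:
#' \deqn{c = \int_0^1 x\,a(x)\,dx \Big/ \int_0^1 a(x)\,dx.}
#'
#' @param af An `agreement_function` with positive total area.
#' @return The centroid likelihood.
#' @export
centroid <- function(af) {
  stopifnot(inherits(af, "agreement_function"))
  area <- .af_area(af)
  if (area <= 0) {
    stop("empty agreement: zero area under the function", call. = FALSE)
  }
  bp <- af$breakpoints
  k <- length(bp)
  moment <- sum(af$piece_levels * (bp[-1L]^2 - bp[-k]^2) / 2)
  moment / area
}

#' Bundle the crisp summaries of one item's agreement function
#'
#' @param af An `agreement_function` for one risk item.
#' @param item_id Identifier recorded in the output row.
#' @param headline Which statistic is designated the headline likelihood
#'   (default `"min_max"`, the conservative choice; `"max_max"` or
#'   `"centroid"` may suit other settings).
#' @return A one-row data frame with columns `item_id`, `min_max`,
#'   `max_max`, `centroid`, `headline` (the value of the chosen statistic),
#'   `peak_agreement`, `support_low`, `support_high`, `n_experts`. For a
#'   zero-area function (all intervals degenerate points) the centroid is
#'   `NA` and the headline falls back as documented in [centroid()].
#' @export
summarize_agreement <- function(af, item_id = NA_character_,
                                headline = c("min_max", "max_max", "centroid")) {
  stopifnot(inherits(af, "agreement_function"))
  headline <- match.arg(headline)
  peak <- .af_peak(af)
  pos <- af$point_levels > 0
  support <- range(af$breakpoints[pos])
  cen <- if (.af_area(af) > 0) centroid(af) else NA_real_
  stats <- c(min_max = min(peak$at), max_max = max(peak$at), centroid = cen)
  data.frame(
    item_id = as.character(item_id),
    min_max = stats[["min_max"]],
    max_max = stats[["max_max"]],
    centroid = stats[["centroid"]],
    headline = stats[[headline]],
    peak_agreement = peak$level,
    support_low = support[1L],
    support_high = support[2L],
    n_experts = af$n_intervals,
    stringsAsFactors = FALSE
  )
}

#' @export
summary.agreement_function <- function(object, ...) {
  summarize_agreement(object, ...)
}

#' Plot an agreement function as a step graph
#'
#' Draws the aggregation graph for one item: agreement level against
#' likelihood, with the min-max, centroid and max-max positions marked.
#'
#' @param x An `agreement_function`.
#' @param markers Draw the min-max / centroid / max-max markers
#'   (default `TRUE`; the centroid marker is skipped for zero-area
#'   functions).
#' @param main,xlab,ylab,... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.agreement_function <- function(x, markers = TRUE,
                                    main = "Agreement function",
                                    xlab = "Likelihood",
                                    ylab = "Agreement level", ...) {
  bp <- x$breakpoints
  k <- length(bp)
  if (max(x$point_levels) <= 0) {
    stop("empty agreement: nothing to plot", call. = FALSE)
  }
  # step outline: level 0 outside the support
  xs <- c(0, rep(bp, each = 2L), 1)
  lv <- c(0, 0, if (k > 1L) rep(x$piece_levels, each = 2L) else NULL, 0, 0)
  ymax <- max(x$point_levels)
  graphics::plot(xs, lv, type = "l", xlim = c(0, 1), ylim = c(0, ymax * 1.08),
                 main = main, xlab = xlab, ylab = ylab, ...)
  graphics::points(bp, x$point_levels, pch = 16, cex = 0.6)
  if (markers) {
    mm <- min_max(x); xm <- max_max(x)
    graphics::abline(v = mm, lty = 2, col = "grey40")
    graphics::abline(v = xm, lty = 3, col = "grey40")
    lab <- c("min-max", "max-max"); at <- c(mm, xm)
    if (.af_area(x) > 0) {
      cen <- centroid(x)
      graphics::abline(v = cen, lty = 4, col = "grey60")
      lab <- c(lab, "centroid"); at <- c(at, cen)
    }
    graphics::mtext(lab, side = 3, at = at, cex = 0.7, line = 0.1)
  }
  invisible(x)
}
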