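# Seeded synthetic expert panels and calibration truth sets. The generator
# emulates the elicitation protocol — estimates on [0, 1], stated
# confidences between 50% and 100%, ten-expert panels — so every stage of
# the pipeline is testable without a workshop dataset. The distributional
# conventions are fixture choices, not claims about real experts.

#' Specify a synthetic expert panel
#'
#' Each synthetic expert holds a bell-shaped subjective belief about the
#' item's true likelihood: the best estimate is drawn from a normal
#' distribution centred at `true_value + bias` with standard deviation
#' `spread`, truncated to \[0, 1\] by clipping. The expert states a
#' confidence drawn uniformly from \[0.5, 1\] and reports the central
#' interval of their belief at a coverage governed by
#' `confidence_behaviour`: an `honest` expert's interval has nominal
#' coverage equal to the stated confidence; an `overconfident` expert
#' states the same confidence but draws a much narrower interval (actual
#' coverage `0.5 + 0.3 (c - 0.5)`); an `underconfident` expert a wider one
#' (actual coverage `c + 0.7 (1 - c)`).
#'
#' @param n_experts Number of experts (default 10, the reference panel
#'   size).
#' @param true_value True likelihood in \[0, 1\] the panel is asked about.
#' @param bias Systematic offset of expert beliefs; scalar or one value per
#'   expert.
#' @param spread Standard deviation of the best-estimate error and scale of
#'   interval half-widths; scalar or per expert.
#' @param confidence_behaviour `"honest"`, `"overconfident"` or
#'   `"underconfident"`.
#' @param seed Integer seed fixing all draws.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_experts = 10, true_value = 0.5, bias = 0,
                       spread = 0.1,
                       confidence_behaviour = c("honest", "overconfident",
                                                "underconfident"),
                       seed = 1L) {
  confidence_behaviour <- match.arg(confidence_behaviour)
  stopifnot(n_experts >= 1, true_value >= 0, true_value <= 1,
            all(spread >= 0), length(seed) == 1L)
  structure(
    list(n_experts = as.integer(n_experts), true_value = true_value,
         bias = rep_len(bias, n_experts), spread = rep_len(spread, n_experts),
         confidence_behaviour = confidence_behaviour,
         seed = as.integer(seed)),
    class = "panel_spec")
}

.clip01 <- function(x) pmin(1, pmax(0, x))

#' Generate one item's elicitation records from a panel specification
#'
#' @param spec A [panel_spec()].
#' @param item_id Item identifier written into the records.
#' @return A validated elicitation data frame (`expert_id`, `item_id`,
#'   `low`, `best`, `high`, `confidence`), one row per expert, reproducible
#'   from `spec$seed`.
#' @export
generate_panel <- function(spec, item_id = "item1") {
  stopifnot(inherits(spec, "panel_spec"))
  n <- spec$n_experts
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(spec$seed)
  best <- .clip01(stats::rnorm(n, spec$true_value + spec$bias, spec$spread))
  stated <- stats::runif(n, 0.5, 1)
  coverage <- switch(spec$confidence_behaviour,
    honest = stated,
    overconfident = 0.5 + 0.3 * (stated - 0.5),
    underconfident = stated + 0.7 * (1 - stated))
  coverage <- pmin(coverage, 0.999)
  half <- stats::qnorm((1 + coverage) / 2) * spec$spread
  out <- data.frame(
    expert_id = sprintf("e%02d", seq_len(n)),
    item_id = item_id,
    low = .clip01(best - half),
    best = best,
    high = .clip01(best + half),
    confidence = stated,
    stringsAsFactors = FALSE
  )
  validate_elicitation(out)
}

#' Generate a calibration truth set with prescribed overlap proportions
#'
#' Builds `n_questions` correct-answer intervals (each `centre +/-
#' difficulty` with centres drawn uniformly in \[0.25, 0.75\]) together with
#' panel responses constructed so that each expert's derived interval has a
#' known overlap proportion with the truth. Responses are stated at
#' confidence equal to `target_level`, so derivation is the identity and
#' the overlap proportions — hence the recovered calibration weights — are
#' exact by construction. This gives a closed-form oracle for
#' weight-recovery tests.
#'
#' @param n_questions Number of calibration questions.
#' @param n_experts Number of experts (default 10).
#' @param difficulty Half-width of each truth interval (default 0.05);
#'   expert intervals have width `difficulty`.
#' @param seed Integer seed.
#' @param overlaps Optional `n_experts` x `n_questions` matrix of prescribed
#'   overlap proportions in \[0, 1\]; by default drawn from the grid
#'   `0, 0.1, ..., 1` under `seed`.
#' @param target_level Stated confidence of the constructed responses
#'   (default 0.80).
#' @return A list with `truths` (truth-interval table), `records`
#'   (elicitation table), `overlaps` (the matrix used) and
#'   `expected_weights` (data frame `expert_id`, `weight`; the row means of
#'   `overlaps`).
#' @export
generate_truth_set <- function(n_questions, n_experts = 10, difficulty = 0.05,
                               seed = 1L, overlaps = NULL,
                               target_level = 0.8) {
  stopifnot(n_questions >= 1, n_experts >= 1,
            difficulty > 0, difficulty <= 0.1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  centre <- stats::runif(n_questions, 0.25, 0.75)
  truths <- data.frame(
    question_id = sprintf("q%02d", seq_len(n_questions)),
    low = centre - difficulty,
    high = centre + difficulty,
    stringsAsFactors = FALSE
  )
  if (is.null(overlaps)) {
    overlaps <- matrix(sample(seq(0, 1, by = 0.1), n_experts * n_questions,
                              replace = TRUE),
                       nrow = n_experts, ncol = n_questions)
  }
  overlaps <- as.matrix(overlaps)
  stopifnot(nrow(overlaps) == n_experts, ncol(overlaps) == n_questions,
            all(overlaps >= 0 & overlaps <= 1))
  w <- difficulty  # expert interval width; <= truth width 2*difficulty
  rows <- vector("list", n_experts * n_questions)
  k <- 0L
  for (e in seq_len(n_experts)) {
    for (q in seq_len(n_questions)) {
      p <- overlaps[e, q]
      th <- truths$high[q]; tl <- truths$low[q]
      if (p > 0) {
        # overlap segment [th - p*w, th] lies inside the truth interval
        lo <- th - p * w
        hi <- lo + w
      } else {
        # disjoint, placed just above the truth interval
        lo <- th + 0.05
        hi <- lo + w
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        expert_id = sprintf("e%02d", e),
        item_id = truths$question_id[q],
        low = lo, best = (lo + hi) / 2, high = hi,
        confidence = target_level,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- validate_elicitation(do.call(rbind, rows))
  list(
    truths = truths,
    records = records,
    overlaps = overlaps,
    expected_weights = data.frame(
      expert_id = sprintf("e%02d", seq_len(n_experts)),
      weight = rowMeans(overlaps),
      stringsAsFactors = FALSE
    )
  )
}

# Preserve the caller's RNG state around seeded generation.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
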