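point_truths <- function(n_questions, seed) {
  set.seed(seed)
  centres <- runif(n_questions, 0.25, 0.75)
  data.frame(question_id = sprintf("q%02d", seq_len(n_questions)),
             low = centres, high = centres, stringsAsFactors = FALSE)
}

panel_for_truths <- function(truths, behaviour, seed, spread = 0.15) {
  do.call(rbind, lapply(seq_len(nrow(truths)), function(q) {
    generate_panel(
      panel_spec(n_experts = 10,
                 true_value = (truths$low[q] + truths$high[q]) / 2,
                 spread = spread, confidence_behaviour = behaviour,
                 seed = seed * 1000L + q),
      item_id = truths$question_id[q])
  }))
}

test_that("panel generation is deterministic in the seed", {
  spec <- panel_spec(n_experts = 10, true_value = 0.4, spread = 0.1, seed = 99)
  expect_identical(generate_panel(spec, "it"), generate_panel(spec, "it"))
  other <- panel_spec(n_experts = 10, true_value = 0.4, spread = 0.1, seed = 100)
  expect_false(identical(generate_panel(spec, "it"),
                         generate_panel(other, "it")))
  ts1 <- generate_truth_set(4, seed = 5)
  ts2 <- generate_truth_set(4, seed = 5)
  expect_identical(ts1, ts2)
})

test_that("zero spread collapses every interval onto the true value", {
  rec <- generate_panel(panel_spec(n_experts = 8, true_value = 0.37,
                                   spread = 0, seed = 3), "it")
  expect_equal(rec$low, rep(0.37, 8))
  expect_equal(rec$best, rep(0.37, 8))
  expect_equal(rec$high, rep(0.37, 8))
  expect_true(all(rec$confidence >= 0.5 & rec$confidence <= 1))
})

test_that("generated records always satisfy the elicitation invariants", {
  for (seed in 1:10) {
    for (beh in c("honest", "overconfident", "underconfident")) {
      rec <- generate_panel(panel_spec(n_experts = 10,
                                       true_value = runif(1),
                                       spread = runif(1, 0, 0.3),
                                       confidence_behaviour = beh,
                                       seed = seed), "it")
      expect_silent(validate_elicitation(rec))
    }
  }
})

test_that("the constructed truth set recovers prescribed weights exactly", {
  ts <- generate_truth_set(n_questions = 6, n_experts = 10, seed = 42)
  cal <- calibrate_panel(ts$records, ts$truths)
  expect_equal(cal$weights$weight, ts$expected_weights$weight,
               tolerance = 1e-12)

  # the classic hand-computable case: mean of (0.5, 0.3, 0.4, 0.8, 0.0)
  ts1 <- generate_truth_set(n_questions = 5, n_experts = 1, seed = 8,
                            overlaps = matrix(c(0.5, 0.3, 0.4, 0.8, 0.0),
                                              nrow = 1))
  cal1 <- calibrate_panel(ts1$records, ts1$truths)
  expect_equal(cal1$weights$weight, 0.40, tolerance = 1e-12)

  # an expert whose every derived interval sits inside truth weighs 1
  ts2 <- generate_truth_set(n_questions = 4, n_experts = 1, seed = 9,
                            overlaps = matrix(1, nrow = 1, ncol = 4))
  expect_equal(calibrate_panel(ts2$records, ts2$truths)$weights$weight, 1.0)
})

test_that("honest consensus panels recover the true value by centroid", {
  errs <- vapply(1:200, function(s) {
    rec <- generate_panel(panel_spec(n_experts = 10, true_value = 0.45,
                                     spread = 0.05, seed = s), "it")
    abs(centroid(aggregate_variant(rec, variant = "ci")) - 0.45)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("estimator bias shrinks as the panel spread shrinks", {
  mean_err <- function(spread) {
    mean(vapply(1:30, function(s) {
      tr <- point_truths(5, seed = s)
      cal <- calibrate_panel(panel_for_truths(tr, "honest", s,
                                              spread = spread),
                             tr)
      rec <- generate_panel(panel_spec(n_experts = 10, true_value = 0.45,
                                       spread = spread, seed = 5000L + s),
                            "it")
      af <- aggregate_variant(rec, profiles = cal, variant = "calibrated")
      abs(centroid(af) - 0.45)
    }, numeric(1)))
  }
  errs <- vapply(c(0.02, 0.08, 0.2), mean_err, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("overconfident panels earn lower calibration weights than honest ones", {
  mean_weight <- function(behaviour, s) {
    tr <- point_truths(5, seed = s)
    mean(calibrate_panel(panel_for_truths(tr, behaviour, s), tr)$weights$weight)
  }
  hw <- vapply(1:100, function(s) mean_weight("honest", s), numeric(1))
  ow <- vapply(1:100, function(s) mean_weight("overconfident", s), numeric(1))
  expect_lt(mean(ow), mean(hw))
  expect_gt(mean(hw > ow), 0.9)  # and seed by seed, almost always
})
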