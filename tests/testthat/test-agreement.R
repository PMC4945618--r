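test_that("a single unit interval aggregates to its indicator function", {
  af <- aggregate_intervals(data.frame(low = 0.2, high = 0.6))
  expect_s3_class(af, "agreement_function")
  expect_equal(evaluate_agreement(af, c(0.1, 0.2, 0.4, 0.6, 0.7)),
               c(0, 1, 1, 1, 0))
})

test_that("levels count the weighted covering intervals on each piece", {
  af <- aggregate_intervals(data.frame(low = c(0.0, 0.2), high = c(0.4, 0.6)))
  expect_equal(af$breakpoints, c(0, 0.2, 0.4, 0.6))
  expect_equal(af$piece_levels, c(1, 2, 1))
  expect_equal(af$point_levels, c(1, 2, 2, 1))
  expect_equal(evaluate_agreement(af, 0.4), 2)   # closed endpoints both count
  expect_equal(evaluate_agreement(af, 0.1), 1)
})

test_that("complete agreement of ten unit-weight experts scores ten", {
  af <- aggregate_intervals(data.frame(low = rep(0.3, 10), high = rep(0.5, 10)))
  expect_identical(max(af$point_levels), 10)
  expect_identical(evaluate_agreement(af, 0.4), 10)
  expect_identical(evaluate_agreement(af, 0.9), 0)
})

test_that("degenerate and invalid inputs are handled", {
  expect_error(aggregate_intervals(data.frame(low = numeric(0),
                                              high = numeric(0))),
               "empty")
  expect_error(aggregate_intervals(data.frame(low = 0.5, high = 0.2)),
               "low <= high")
  expect_error(aggregate_intervals(data.frame(low = 0.5, high = 1.2)),
               "\\[0, 1\\]")
  # a zero-width interval contributes a point mass
  af <- aggregate_intervals(data.frame(low = 0.4, high = 0.4))
  expect_equal(evaluate_agreement(af, 0.4), 1)
  expect_equal(evaluate_agreement(af, 0.41), 0)
  expect_error(evaluate_agreement(af, 1.5), "\\[0, 1\\]")
})

test_that("exact representation matches a brute-force oracle on a grid", {
  grid <- seq(0, 1, by = 1e-3)
  for (seed in 1:12) {
    iv <- random_intervals(n = sample(1:12, 1), seed = seed)
    af <- aggregate_intervals(iv)
    expect_equal(evaluate_agreement(af, grid), brute_force_level(iv, grid),
                 tolerance = 1e-12, info = paste("seed", seed))
  }
})

test_that("area under the function conserves total weighted interval length", {
  for (seed in 13:24) {
    iv <- random_intervals(n = sample(1:12, 1), seed = seed)
    af <- aggregate_intervals(iv)
    area <- sum(af$piece_levels * diff(af$breakpoints))
    expect_equal(area, sum(iv$weight * (iv$high - iv$low)),
                 tolerance = 1e-12)
  }
})

test_that("enlarging one interval never lowers the agreement anywhere", {
  grid <- seq(0, 1, by = 5e-3)
  set.seed(31)
  for (i in 1:10) {
    iv <- random_intervals(n = 8, seed = 100 + i)
    before <- evaluate_agreement(aggregate_intervals(iv), grid)
    j <- sample(8, 1)
    iv$low[j] <- max(0, iv$low[j] - runif(1, 0, 0.2))
    iv$high[j] <- min(1, iv$high[j] + runif(1, 0, 0.2))
    after <- evaluate_agreement(aggregate_intervals(iv), grid)
    expect_true(all(after - before >= -1e-12))
  }
})

test_that("the ceiling is reached exactly when all intervals share a point", {
  for (seed in 41:60) {
    iv <- random_intervals(n = sample(2:10, 1), seed = seed)
    af <- aggregate_intervals(iv)
    shares_point <- max(iv$low) <= min(iv$high)
    expect_identical(
      isTRUE(all.equal(max(af$point_levels), sum(iv$weight), tolerance = 1e-12)),
      shares_point, info = paste("seed", seed))
  }
})

test_that("aggregation variants weight and standardize as named", {
  # confidence equal to the target: raw and ci variants coincide
  rec <- make_record(0.2, 0.4, 0.6, 0.8, item_id = "it")
  expect_equal(aggregate_variant(rec, variant = "raw"),
               aggregate_variant(rec, variant = "ci"))

  # a single half-calibrated expert caps the function at their weight
  prof <- data.frame(expert_id = "e1", weight = 0.5)
  af <- aggregate_variant(rec, profiles = prof, variant = "calibrated")
  expect_equal(max(af$point_levels), 0.5)

  # ten perfectly calibrated experts in full agreement reach ten
  panel <- identical_panel(10, 0.3, 0.5)
  prof10 <- data.frame(expert_id = sprintf("e%02d", 1:10), weight = 1)
  af10 <- aggregate_variant(panel, profiles = prof10, variant = "calibrated")
  expect_equal(max(af10$point_levels), 10)

  # the ci variant uses derived endpoints: full confidence narrows
  rec1 <- make_record(0.2, 0.4, 0.6, 1.0, item_id = "it")
  af_ci <- aggregate_variant(rec1, variant = "ci")
  expect_equal(af_ci$breakpoints, c(0.24, 0.56))

  expect_error(aggregate_variant(rec, variant = "calibrated"),
               "requires calibration")
  expect_error(aggregate_variant(rec, profiles = data.frame(
    expert_id = "someone-else", weight = 1), variant = "calibrated"),
    "no calibration weight")
  expect_error(aggregate_variant(rbind(rec, make_record(0.1, 0.2, 0.3, 0.8,
                                                        item_id = "other")),
                                 variant = "raw"),
               "one item")
})
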