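test_that("the matrix enumerates the full factor x element cross-product", {
  m <- risk_matrix(sprintf("f%02d", 1:23), sprintf("el%02d", 1:14))
  expect_equal(nrow(m$pairs), 322)
  expect_true(all(m$pairs$retained))
  expect_equal(nrow(risk_matrix("f", "e")$pairs), 1)
  expect_equal(nrow(risk_matrix(c("a", "b", "c"), c("x", "y"))$pairs), 6)
  expect_error(risk_matrix(c("a", "a"), "x"), "duplicate")
  expect_error(risk_matrix(character(0), "x"), "non-empty")
})

test_that("screening moves masked combinations out and keeps the books", {
  m <- risk_matrix(sprintf("f%02d", 1:23), sprintf("el%02d", 1:14))
  set.seed(91)
  mask <- m$pairs[sample(322, 269), c("factor", "element")]
  m2 <- apply_screening(m, mask)
  expect_equal(sum(m2$pairs$retained), 53)
  expect_equal(sum(!m2$pairs$retained) + sum(m2$pairs$retained), 322)

  expect_equal(apply_screening(m, m$pairs[0, c("factor", "element")]), m)
  small <- apply_screening(risk_matrix(c("a", "b", "c"), c("x", "y")),
                           data.frame(factor = c("a", "a", "b", "c"),
                                      element = c("x", "y", "x", "y")))
  expect_equal(sum(small$pairs$retained), 2)
  expect_error(
    apply_screening(m, data.frame(factor = "nope", element = "el01")),
    "unknown combination")
})

test_that("the analysis counts affected elements per risk factor", {
  fx <- toy_risk_fixture()
  report <- run_analysis(fx$matrix, fx$records, variant = "ci")
  expect_s3_class(report, "risk_report")
  counts <- setNames(report$per_factor$n_affected, report$per_factor$factor)
  expect_equal(counts, fx$expected_counts)
  expect_equal(report$per_factor$elements[report$per_factor$factor == "A"],
               "x")
  expect_equal(nrow(report$per_item), 4)
})

test_that("an all-screened matrix yields an empty report", {
  m <- apply_screening(risk_matrix("a", "x"),
                       data.frame(factor = "a", element = "x"))
  report <- run_analysis(m, make_record(0.1, 0.2, 0.3, 0.8), variant = "ci")
  expect_equal(nrow(report$per_item), 0)
  expect_equal(report$per_factor$n_affected, 0L)
})

test_that("a retained combination without records is an error naming it", {
  m <- risk_matrix(c("a", "b"), "x")
  rec <- make_record(0.1, 0.2, 0.3, 0.8, item_id = risk_item_id("a", "x"))
  expect_error(run_analysis(m, rec, variant = "ci"), "b::x")
})

test_that("the report is invariant to record and expert order", {
  fx <- toy_risk_fixture()
  shuffled <- fx$records[rev(seq_len(nrow(fx$records))), ]
  r1 <- run_analysis(fx$matrix, fx$records, variant = "ci")
  r2 <- run_analysis(fx$matrix, shuffled, variant = "ci")
  expect_equal(r1$per_item, r2$per_item)
  expect_equal(r1$per_factor, r2$per_factor)
})

test_that("raising the headline threshold never increases affected counts", {
  fx <- toy_risk_fixture()
  thresholds <- c(0, 0.05, 0.3, 0.5, 0.9)
  counts <- vapply(thresholds, function(th) {
    sum(run_analysis(fx$matrix, fx$records, variant = "ci",
                     headline_threshold = th)$per_factor$n_affected)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("factors rank by affected count, then peak likelihood, then name", {
  fake_report <- function(per_factor) {
    structure(list(per_factor = per_factor), class = "risk_report")
  }
  r <- rank_factors(fake_report(data.frame(
    factor = c("B", "A"), n_affected = c(1L, 3L),
    max_headline = c(0.2, 0.4), elements = "", stringsAsFactors = FALSE)))
  expect_equal(r$factor, c("A", "B"))

  r <- rank_factors(fake_report(data.frame(
    factor = c("B", "A"), n_affected = c(2L, 2L),
    max_headline = c(0.9, 0.4), elements = "", stringsAsFactors = FALSE)))
  expect_equal(r$factor, c("B", "A"))  # likelihood breaks the count tie

  r <- rank_factors(fake_report(data.frame(
    factor = c("B", "A"), n_affected = c(2L, 2L),
    max_headline = c(0.4, 0.4), elements = "", stringsAsFactors = FALSE)))
  expect_equal(r$factor, c("A", "B"))  # name breaks the full tie

  r <- rank_factors(fake_report(data.frame(
    factor = "solo", n_affected = 0L, max_headline = NA_real_,
    elements = "", stringsAsFactors = FALSE)))
  expect_equal(r$factor, "solo")
  expect_equal(r$rank, 1L)
})
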