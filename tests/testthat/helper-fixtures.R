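# Shared fixture builders. All randomness is seeded inside the helpers.

make_record <- function(low, best, high, confidence,
                        expert_id = "e1", item_id = "q1") {
  data.frame(expert_id = expert_id, item_id = item_id,
             low = low, best = best, high = high, confidence = confidence,
             stringsAsFactors = FALSE)
}

# n random weighted intervals in [0, 1]
random_intervals <- function(n, seed, weighted = TRUE) {
  set.seed(seed)
  a <- runif(n)
  b <- runif(n)
  data.frame(
    expert_id = sprintf("e%02d", seq_len(n)),
    low = pmin(a, b),
    high = pmax(a, b),
    weight = if (weighted) runif(n) else rep(1, n),
    stringsAsFactors = FALSE
  )
}

# Independent oracle: weighted covering count of closed intervals at x.
brute_force_level <- function(intervals, x) {
  vapply(x, function(xi) {
    sum(intervals$weight[intervals$low <= xi & intervals$high >= xi])
  }, numeric(1))
}

# Panel where every expert supplies the same interval.
identical_panel <- function(n, low, high, confidence = 0.8,
                            item_id = "item") {
  best <- (low + high) / 2
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_record(low, best, high, confidence,
                expert_id = sprintf("e%02d", i), item_id = item_id)
  }))
}

# A 2x2 risk fixture: exactly one combination (A, x) built to exceed the
# 5% headline threshold; the three others sit at likelihood ~0.
toy_risk_fixture <- function(n_experts = 5) {
  m <- risk_matrix(c("A", "B"), c("x", "y"))
  high_pair <- identical_panel(n_experts, 0.5, 0.7,
                               item_id = risk_item_id("A", "x"))
  low_pairs <- do.call(rbind, lapply(
    list(c("A", "y"), c("B", "x"), c("B", "y")),
    function(p) {
      rec <- identical_panel(n_experts, 0, 0.02,
                             item_id = risk_item_id(p[1], p[2]))
      rec$best <- 0.01
      rec
    }))
  list(matrix = m, records = rbind(high_pair, low_pairs),
       expected_counts = c(A = 1L, B = 0L))
}
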