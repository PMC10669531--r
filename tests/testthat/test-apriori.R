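test_that("the ten-transaction worked example mines exactly as counted by hand", {
  tx <- fix10()
  f <- apriori_frequent_itemsets(tx, 0.4)
  expect_identical(nrow(f), 6L)
  got <- setNames(f$support, vapply(f$items, paste, character(1),
                                    collapse = ","))
  expect_equal(got[c("A", "B", "Y", "A,B", "A,Y", "B,Y")],
               c(A = 0.6, B = 0.6, Y = 0.6, `A,B` = 0.4, `A,Y` = 0.4,
                 `B,Y` = 0.4))
  expect_identical(nrow(apriori_frequent_itemsets(tx, 0.7)), 0L)

  b <- brute_force_frequent_itemsets(tx, 0.3)
  abY <- which(vapply(b$items, function(x) identical(x, c("A", "B", "Y")),
                      logical(1)))
  expect_length(abY, 1L)
  expect_equal(b$support[abY], 0.3)

  r <- mine_rules(tx, rhs = "Y", min_sup = 0.3, min_conf = 0.7)
  expect_identical(nrow(r), 1L)
  expect_identical(sort(r$lhs[[1]]), c("A", "B"))
  expect_equal(r$support, 0.3)
  expect_equal(r$confidence, 0.75)
  expect_equal(r$lift, 1.25)
  expect_false(rule_has_lhs(r, "A"))   # conf 4/6 < 0.7: correctly absent

  m <- evaluate_rule(c("A", "B"), "Y", transaction_set(tx))
  expect_equal(m$support, 0.3)
  expect_equal(m$confidence, 0.75)
  expect_equal(m$lift, 1.25)
  expect_identical(m$n_both, 3L)
})

test_that("degenerate mining inputs behave per contract", {
  expect_error(apriori_frequent_itemsets(list(), 0.1), "empty")
  expect_error(brute_force_frequent_itemsets(list(), 0.1), "empty")
  one <- brute_force_frequent_itemsets(list("A"), 1.0)
  expect_identical(nrow(one), 1L)
  expect_equal(one$support, 1.0)
  # empty catalog (all-empty transactions)
  expect_identical(nrow(brute_force_frequent_itemsets(
    list(character(0), character(0)), 0.5)), 0L)
  big <- transaction_set(list(letters[1:21]))
  expect_error(brute_force_frequent_itemsets(big, 0.5), "guard")
  # consequent absent from every transaction
  r <- rules_for_consequent(apriori_frequent_itemsets(fix10(), 0.3), "B",
                            transaction_set(fix10()),
                            mining_params(0.3, 0.99))
  expect_identical(nrow(r), 0L)
  expect_error(mine_rules(fix10(), "Z", 0.3, 0.7), "catalog")
  expect_error(evaluate_rule(character(0), "Y", transaction_set(fix10())),
               "non-empty")
  no_a <- transaction_set(list("B", "B"),
                          catalog = data.frame(label = c("A", "B"),
                                               polarity = NA,
                                               source_variable = NA))
  expect_error(evaluate_rule("A", "B", no_a), "never occurs")
})

test_that("Apriori agrees with exhaustive enumeration on randomized instances", {
  for (seed in 1:30) {
    ts <- random_instance(seed, max_items = 10L, max_tx = 200L)
    min_sup <- stats::runif(1, 0.05, 0.5)
    a <- apriori_frequent_itemsets(ts, min_sup)
    b <- brute_force_frequent_itemsets(ts, min_sup)
    expect_identical(freq_key(a), freq_key(b))
  }
})

test_that("anti-monotonicity and the metric identities hold on mined output", {
  ts <- random_instance(99L, max_items = 9L, max_tx = 150L)
  f <- apriori_frequent_itemsets(ts, 0.08)
  key <- setNames(f$support_count,
                  vapply(f$items, paste, character(1), collapse = "|"))
  for (i in which(f$size > 1L)) {
    it <- f$items[[i]]
    for (d in seq_along(it)) {
      sub <- paste(it[-d], collapse = "|")
      expect_true(sub %in% names(key))
      expect_gte(key[[sub]], f$support_count[i])
    }
  }
  # lift = confidence / base rate, exactly, on integer counts
  rules <- rules_for_consequent(f, ts$catalog$label[1], ts,
                                mining_params(0.08, 0.01, min_lift = 0))
  if (nrow(rules)) {
    expect_equal(rules$lift,
                 rules$confidence / (rules$n_rhs / rules$n_total),
                 tolerance = 1e-12)
    expect_equal(rules$support, rules$n_both / rules$n_total,
                 tolerance = 1e-12)
    # lift > 1 iff confidence above the consequent's empirical base rate
    expect_identical(rules$lift > 1,
                     rules$confidence > rules$n_rhs / rules$n_total)
  }
  expect_true(all(rules$support <= rules$confidence))
})

test_that("independent items yield lift near 1", {
  set.seed(31)
  n <- 4000L
  x <- runif(n) < 0.4
  y <- runif(n) < 0.5
  tx <- lapply(seq_len(n), function(i)
    c(if (x[i]) "X", if (y[i]) "Y", "pad"))
  m <- evaluate_rule("X", "Y", transaction_set(tx))
  se_conf <- sqrt(m$confidence * (1 - m$confidence) / m$n_lhs)
  expect_lt(abs(m$lift - 1), 3 * se_conf / (m$n_rhs / m$n_total))
})

test_that("rule ordering is deterministic, tie-broken, and idempotent", {
  mk <- function(lhs, conf, sup) list(lhs = lhs, conf = conf, sup = sup)
  rows <- list(mk("b", 0.75, 0.08), mk("a", 0.80, 0.05),
               mk("c", 0.75, 0.08), mk("d", 0.75, 0.05))
  rs <- data.frame(rhs = "Y",
                   support = vapply(rows, `[[`, numeric(1), "sup"),
                   confidence = vapply(rows, `[[`, numeric(1), "conf"),
                   lift = 1.2, n_total = 100L, n_lhs = 10L, n_rhs = 50L,
                   n_both = 8L, itemset_size = 2L)
  rs$lhs <- lapply(rows, `[[`, "lhs")
  class(rs) <- c("rule_set", "data.frame")
  sorted <- filter_sort_rules(rs)
  expect_identical(unlist(sorted$lhs), c("a", "b", "c", "d"))
  expect_identical(filter_sort_rules(sorted), sorted)

  # transaction order is irrelevant to the mined result
  ts <- random_instance(7L)
  shuf <- transaction_set(rev(ts$transactions), catalog = ts$catalog)
  r1 <- mine_rules(ts, ts$catalog$label[1], 0.1, 0.2, min_lift = 0)
  r2 <- mine_rules(shuf, ts$catalog$label[1], 0.1, 0.2, min_lift = 0)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})
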