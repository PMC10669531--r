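test_that("nearest-rank quartiles match hand evaluation", {
  s <- make_scored(data.frame(cohesion_total = 1:100))
  ct <- compute_cutoffs(s, "cohesion")
  expect_identical(ct$p25, 25L)
  expect_identical(ct$p75, 75L)

  s2 <- make_scored(data.frame(cohesion_total = c(3, 1, 2, 2, 5, 4, 4, 4)))
  ct2 <- compute_cutoffs(s2, "cohesion")
  expect_equal(ct2$p25, 2)   # position ceiling(0.25 * 8) = 2 of sorted
  expect_equal(ct2$p75, 4)   # position 6

  s3 <- make_scored(data.frame(cohesion_total = rep(7L, 5)))
  ct3 <- compute_cutoffs(s3, "cohesion")
  expect_identical(ct3$p25, ct3$p75)

  expect_error(compute_cutoffs(s[0, ]), "empty")
})

test_that("outcome labelling applies the inclusive threshold", {
  expect_identical(label_outcome(15L), "depression")
  expect_identical(label_outcome(14L), "nondepression")
  expect_identical(label_outcome(0L), "nondepression")
  expect_identical(label_outcome(16L, outcome_rule(15, inclusive = FALSE)),
                   "depression")
  expect_identical(label_outcome(15L, outcome_rule(15, inclusive = FALSE)),
                   "nondepression")
  expect_error(label_outcome(37L), "range")
  expect_error(outcome_rule(40), "\\[0, 36\\]")
})

test_that("item assignment follows the criteria grid, boundaries inclusive", {
  ct <- stub_cutoffs()
  at_p25 <- make_scored(data.frame(cohesion_total = 40L))   # == P25
  items <- assign_items(at_p25, ct, "risk")[[1]]
  expect_true("low family cohesion" %in% items)

  at_p75 <- make_scored(data.frame(teacher_total = 21L))    # == P75
  expect_true("high teacher support" %in%
                assign_items(at_p75, ct, "protective")[[1]])

  mid <- make_scored(data.frame(cohesion_total = 50L))
  expect_false(any(grepl("cohesion", assign_items(mid, ct, "risk")[[1]])))
  expect_false(any(grepl("cohesion",
                         assign_items(mid, ct, "protective")[[1]])))

  # binary flags map to their risk / protective labels
  flagged <- make_scored(data.frame(left_behind = 1L,
                                    family_structure_intact = 0L,
                                    school_counselors = 0L))
  ri <- assign_items(flagged, ct, "risk")[[1]]
  expect_true(all(c("separation from parents", "family structure risk",
                    "absence of counselors in the school") %in% ri))
  pi <- assign_items(flagged, ct, "protective")[[1]]
  expect_true(all(c("presence of psychological courses",
                    "presence of counseling rooms in the school",
                    "parental education junior high or above") %in% pi))
  expect_false("non-left-behind children" %in% pi)
})

test_that("transactions carry one outcome item and honour exclusions", {
  ct <- stub_cutoffs()
  two <- make_scored(data.frame(
    gender = c("male", "female"),
    academic_ranking = c("average", "top10"),
    cohesion_total = c(40L, 50L),
    depression_score = c(20L, 5L)))
  ts <- build_transactions(two, ct, mode = "risk")
  expect_identical(
    ts$transactions[[1]],
    sort(c("low family cohesion", "male", "primary school students",
           "average academic ranking", "depression"), method = "radix"))
  expect_identical(
    ts$transactions[[2]],
    sort(c("female", "primary school students", "top-10 academic ranking",
           "nondepression"), method = "radix"))

  # stratifier exclusion removes the variable's items everywhere
  ts2 <- build_transactions(two, ct, mode = "risk",
                            exclude_variables = "gender")
  expect_false(any(c("female", "male") %in% unlist(ts2$transactions)))
  expect_false(any(c("female", "male") %in% ts2$catalog$label))

  # degenerate scale contributes nothing, in either mode
  deg <- make_scored(data.frame(cohesion_total = c(40L, 40L)))
  ctd <- compute_cutoffs(deg)
  expect_message(
    tsd <- build_transactions(deg, ctd, mode = "risk"), "degenerate")
  expect_false(any(grepl("cohesion", unlist(tsd$transactions))))

  # exactly one outcome item per transaction
  outc <- vapply(ts$transactions, function(t)
    sum(t %in% c("depression", "nondepression")), integer(1))
  expect_true(all(outc == 1L))
})

test_that("risk and protective quartile items are mutually exclusive and cover >= 25%", {
  s <- small_cohort(seed = 6L, n = 600L)
  ct <- compute_cutoffs(s)
  risk <- assign_items(s, ct, "risk")
  prot <- assign_items(s, ct, "protective")
  pairs <- list(c("low family cohesion", "high family cohesion"),
                c("high family conflict", "low family conflict"),
                c("low peer support", "high peer support"))
  for (pr in pairs) {
    both <- mapply(function(r, p) (pr[1] %in% r) && (pr[2] %in% p),
                   risk, prot)
    expect_false(any(both))
  }
  n <- nrow(s)
  for (lab in c("low family cohesion", "high family conflict",
                "low peer support", "low teacher support")) {
    frac <- mean(vapply(risk, function(x) lab %in% x, logical(1)))
    expect_gte(frac, floor(0.25 * n) / n)
  }
})

test_that("basket and one-hot exports round-trip", {
  ts <- transaction_set(fix10())
  path <- withr::local_tempfile(fileext = ".basket")
  write_basket(ts, path)
  ts2 <- read_basket(path)
  expect_identical(ts2$transactions, ts$transactions)
  oh <- as_onehot(ts)
  expect_identical(unname(rowSums(oh)), as.numeric(lengths(ts$transactions)))
  expect_identical(colnames(oh), c("A", "B", "Y"))
})
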