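test_that("default configuration carries the study's marginals and calibrations", {
  cfg <- default_config()
  expect_identical(cfg$n, 2445L)
  expect_equal(cfg$marginals$p_female, 0.528)
  expect_equal(cfg$marginals$p_middle_school, 1281 / 2445)
  expect_equal(cfg$marginals$p_left_behind, 0.356)
  # Spearman-Brown-type inversion of the reliability targets
  expect_equal(unname(cfg$scale_rho[["cohesion"]]),
               0.82 / (16 - 15 * 0.82), tolerance = 1e-12)
  expect_equal(unname(cfg$scale_rho[["cohesion"]]), 0.2216, tolerance = 1e-4)
  expect_equal(unname(cfg$scale_rho[["conflict"]]), 0.63 / (9 - 8 * 0.63))
})

test_that("generation is deterministic in the seed and respects ranges", {
  cfg <- default_config(n = 120L)
  a <- generate_participants(cfg, seed = 4L)
  b <- generate_participants(cfg, seed = 4L)
  expect_identical(a, b)
  c <- generate_participants(cfg, seed = 5L)
  expect_false(identical(a, c))
  expect_identical(nrow(generate_participants(default_config(n = 0L))), 0L)

  df <- as.data.frame(a)
  for (sc in cfg$codebook$scales) {
    cols <- sprintf("%s_%02d", sc$prefix, seq_len(sc$item_count))
    vals <- unlist(df[cols])
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= sc$response_min & vals <= sc$response_max))
  }
  expect_true(all(df$grade %in% 5:9))
})

test_that("sampled demographics sit within binomial bounds of the configured marginals", {
  cfg <- default_config(n = 10000L)
  cfg$missingness_rate <- 0
  df <- as.data.frame(generate_participants(cfg, seed = 21L))
  se <- function(p) sqrt(p * (1 - p) / nrow(df))
  expect_lt(abs(mean(df$gender == "female") - 0.528), 3 * se(0.528))
  expect_lt(abs(mean(df$left_behind) - 0.356), 3 * se(0.356))
  expect_lt(abs(mean(df$grade >= 7) - 1281 / 2445), 3 * se(1281 / 2445))
})

test_that("invalid configurations are rejected", {
  cfg <- default_config()
  cfg$cross_scale_cor["cohesion", "conflict"] <- -2
  cfg$cross_scale_cor["conflict", "cohesion"] <- -2
  expect_error(generate_participants(cfg), "positive semi-definite")
  cfg2 <- default_config()
  cfg2$marginals$p_female <- 1.4
  expect_error(generate_participants(cfg2), "\\[0, 1\\]")
  cfg3 <- default_config()
  names(cfg3$outcome_model$main)[1] <- "no such factor"
  expect_error(generate_participants(cfg3), "unknown outcome-model")
})

test_that("depression prevalence rises monotonically with the outcome intercept", {
  prev <- vapply(c(-3, -1.7, -0.5), function(b0) {
    cfg <- default_config(n = 1500L)
    cfg$outcome_model$intercept <- b0
    s <- score_scales(suppressMessages(filter_complete_cases(
      generate_participants(cfg, seed = 8L))))
    mean(s$depression_score >= 15)
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("single-cohort reliabilities track the calibration targets", {
  cfg <- default_config()
  p <- suppressMessages(filter_complete_cases(
    generate_participants(cfg, seed = 13L)))
  df <- as.data.frame(p)
  for (sc in cfg$codebook$scales) {
    a <- cronbach_alpha(df[sprintf("%s_%02d", sc$prefix,
                                   seq_len(sc$item_count))])
    expect_lt(abs(a - sc$alpha_target), 0.05)
  }
})

test_that("the Monte-Carlo rule oracle behaves at its analytic limits", {
  cfg <- default_config(n = 800L)
  cfg$missingness_rate <- 0
  # null model: every lift is 1 in expectation
  null <- cfg
  null$outcome_model$main[] <- 0
  null$outcome_model$interactions <- list()
  o <- planted_rule_oracle(null, c("low family cohesion"), reps = 12L,
                           seed = 2L)
  expect_lt(abs(o$lift - 1), 3 * o$se[["lift"]] + 0.02)
  # intercept -> -inf: confidence collapses to 0
  degen <- cfg
  degen$outcome_model$intercept <- -12
  o2 <- planted_rule_oracle(degen, c("high family conflict"), reps = 4L,
                            seed = 2L)
  expect_lt(o2$confidence, 0.05)
  expect_error(planted_rule_oracle(cfg, "no such item", reps = 2L),
               "unknown item")
})

test_that("generator configs round-trip through YAML", {
  cfg <- default_config(n = 99L, seed = 17L)
  path <- withr::local_tempfile(fileext = ".yml")
  write_generator_config(cfg, path)
  cfg2 <- read_generator_config(path)
  expect_equal(cfg2$n, cfg$n)
  expect_equal(cfg2$marginals, cfg$marginals)
  expect_equal(cfg2$cross_scale_cor, cfg$cross_scale_cor)
  expect_equal(cfg2$outcome_model, cfg$outcome_model)
  expect_identical(generate_participants(cfg2, seed = 3L),
                   generate_participants(cfg, seed = 3L))
})
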