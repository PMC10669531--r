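# Shared fixtures, built in code.

# Ten-transaction worked example used throughout the mining tests.
fix10 <- function() {
  list(c("A", "B", "Y"), c("A", "B", "Y"), c("A", "Y"), c("B", "Y"),
       c("A", "B"), "A", "B", "Y", character(0), c("A", "B", "Y"))
}

# Random market-basket instance for oracle-equivalence checks.
random_instance <- function(seed, max_items = 10L, max_tx = 200L) {
  set.seed(seed)
  p <- sample(2:max_items, 1)
  n <- sample(10:max_tx, 1)
  labs <- LETTERS[seq_len(p)]
  prob <- stats::runif(p, 0.1, 0.7)
  tx <- lapply(seq_len(n), function(i) labs[stats::runif(p) < prob])
  transaction_set(tx, catalog = data.frame(label = labs,
                                           polarity = NA, source_variable = NA))
}

freq_key <- function(f) {
  paste(vapply(f$items, paste, character(1), collapse = "|"),
        f$support_count, sep = "#")
}

# Minimal scored_df with every column the discretization stage reads.
make_scored <- function(df) {
  defaults <- list(
    gender = "male", grade = 5L, left_behind = 0L,
    family_structure_intact = 1L, parental_education_low = 0L,
    school_psych_courses = 1L, school_counselors = 1L,
    school_counseling_rooms = 1L, academic_ranking = "average",
    cohesion_total = 50L, conflict_total = 3L, financial_total = 10L,
    teacher_total = 18L, peer_total = 30L, autonomy_total = 12L,
    depression_score = 5L)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  if (is.null(df$participant_id))
    df$participant_id <- sprintf("P%02d", seq_len(nrow(df)))
  df$school_stage <- ifelse(df$grade <= 6L, "primary", "middle")
  class(df) <- c("scored_df", "data.frame")
  df
}

# Cutoff table with every scale strictly non-degenerate.
stub_cutoffs <- function() {
  out <- data.frame(
    scale = c("cohesion", "conflict", "financial", "teacher", "peer",
              "autonomy"),
    p25 = c(40, 2, 8, 14, 26, 10),
    p75 = c(60, 5, 14, 21, 39, 15))
  class(out) <- c("cutoff_table", "data.frame")
  out
}

# Small complete scored cohort for pipeline tests.
small_cohort <- function(seed = 42L, n = 400L) {
  cfg <- default_config(n = n, seed = seed)
  score_scales(suppressMessages(filter_complete_cases(
    generate_participants(cfg))))
}

rule_has_lhs <- function(rules, lhs) {
  target <- sort(lhs)
  any(vapply(rules$lhs, function(x) identical(sort(x), target), logical(1)))
}
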