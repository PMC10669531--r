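# Stratified risk/protective analyses and reporting.

STRATIFIERS <- list(
  gender = list(variable = "gender",
                levels = c("female", "male")),
  age_group = list(variable = "school_stage",
                   levels = c("primary", "middle")),
  left_behind_status = list(variable = "left_behind",
                            levels = c("left-behind", "non-left-behind"))
)

#' Analysis configuration
#'
#' Thresholds per stratifier and mode. Defaults: risk mode uses minimum
#' support 5% with minimum confidence 70% for the gender and age-group
#' analyses and 80% for the left-behind analysis; protective mode uses 20%
#' and 80% throughout; lift must exceed 1 everywhere.
#'
#' @param mode `"risk"` or `"protective"`.
#' @param params Named list of [mining_params()] keyed by stratifier
#'   (`gender`, `age_group`, `left_behind_status`); defaults as above.
#' @param rule The [outcome_rule()] used to label depression.
#' @param cutoff_scope `"pooled"` (quartiles on the full analytic sample,
#'   default) or `"stratum"` (recomputed within each stratum).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(mode = c("risk", "protective"), params = NULL,
                            rule = outcome_rule(),
                            cutoff_scope = c("pooled", "stratum")) {
  mode <- match.arg(mode)
  cutoff_scope <- match.arg(cutoff_scope)
  if (is.null(params)) {
    params <- if (mode == "risk") {
      list(gender = mining_params(0.05, 0.70),
           age_group = mining_params(0.05, 0.70),
           left_behind_status = mining_params(0.05, 0.80))
    } else {
      list(gender = mining_params(0.20, 0.80),
           age_group = mining_params(0.20, 0.80),
           left_behind_status = mining_params(0.20, 0.80))
    }
  }
  stopifnot(all(names(STRATIFIERS) %in% names(params)))
  structure(list(mode = mode, params = params, rule = rule,
                 cutoff_scope = cutoff_scope),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("Analysis config: %s mode, %s cutoffs, outcome threshold %d\n",
              x$mode, x$cutoff_scope, x$rule$threshold))
  for (nm in names(x$params)) {
    p <- x$params[[nm]]
    cat(sprintf("  %-18s min_sup %.2f, min_conf %.2f, lift > %.2f\n",
                nm, p$min_sup, p$min_conf, p$min_lift))
  }
  invisible(x)
}

stratum_membership <- function(scored, stratifier, level) {
  switch(stratifier,
    gender = scored$gender == level,
    age_group = scored$school_stage == level,
    left_behind_status =
      scored$left_behind == (if (level == "left-behind") 1L else 0L),
    stop("unknown stratifier: ", stratifier, call. = FALSE))
}

#' Run the stratified rule-mining analyses
#'
#' For each stratifier (gender, age group, left-behind status) and each of
#' its levels: subset the scored records, build transactions in the given
#' mode with the stratifying variable excluded from the item universe, and
#' mine rules whose consequent is `"depression"` (risk mode) or
#' `"nondepression"` (protective mode) at that stratifier's thresholds.
#' Per-stage record/transaction/rule counts go to `message()`.
#'
#' @param scored A complete `scored_df` from [score_scales()].
#' @param config An [analysis_config()].
#' @param stratifiers Which stratifiers to run (default all three).
#' @return An object of class `stratified_rules`: a list of `rule_table`
#'   objects (one per stratifier level), each holding the stratum spec, the
#'   stratum size and the sorted `rule_set`.
#' @export
run_stratified_analysis <- function(scored, config = analysis_config("risk"),
                                    stratifiers = names(STRATIFIERS)) {
  rhs <- if (config$mode == "risk") "depression" else "nondepression"
  pooled_cutoffs <- compute_cutoffs(scored)
  tables <- list()
  for (st in stratifiers) {
    spec <- STRATIFIERS[[st]]
    for (lev in spec$levels) {
      keep <- stratum_membership(scored, st, lev)
      sub <- scored[keep, , drop = FALSE]
      class(sub) <- class(scored)
      key <- paste(config$mode, st, lev, sep = ".")
      if (nrow(sub) == 0L) {
        warning("empty stratum: ", st, " = ", lev, call. = FALSE)
        rules <- empty_rule_set(0L, rhs, config$params[[st]])
      } else {
        cutoffs <- if (config$cutoff_scope == "pooled") pooled_cutoffs
                   else compute_cutoffs(sub)
        ts <- build_transactions(sub, cutoffs, mode = config$mode,
                                 rule = config$rule,
                                 exclude_variables = spec$variable)
        rules <- mine_rules(ts, rhs = rhs,
                            min_sup = config$params[[st]]$min_sup,
                            min_conf = config$params[[st]]$min_conf,
                            min_lift = config$params[[st]]$min_lift)
        message(sprintf("%s: %d records -> %d transactions -> %d rule(s)",
                        key, nrow(sub), length(ts), nrow(rules)))
      }
      tables[[key]] <- structure(
        list(stratifier = st, level = lev, mode = config$mode,
             n_stratum = nrow(sub), rules = rules),
        class = "rule_table")
    }
  }
  structure(list(tables = tables, mode = config$mode, config = config),
            class = "stratified_rules")
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("Rule table [%s mode] %s = %s (n = %d)\n",
              x$mode, x$stratifier, x$level, x$n_stratum))
  print(x$rules, ...)
  invisible(x)
}

#' @export
print.stratified_rules <- function(x, ...) {
  cat(sprintf("Stratified %s-factor analysis: %d rule tables\n",
              x$mode, length(x$tables)))
  for (tab in x$tables)
    cat(sprintf("  %-20s %-15s n = %5d   %3d rule(s)\n",
                tab$stratifier, tab$level, tab$n_stratum, nrow(tab$rules)))
  invisible(x)
}

# Extract percent-scale metric vectors and itemset sizes from a rule_set,
# rule_table or fixture table.
rule_vectors <- function(x, part = NULL) {
  if (inherits(x, "rule_table")) x <- x$rules
  if (inherits(x, "fixture_rules")) {
    if (!is.null(part)) x <- x[x$part == part, , drop = FALSE]
    list(support = x$support, confidence = x$confidence, lift = x$lift,
         size = lengths(x$lhs) + 1L)
  } else if (inherits(x, "rule_set")) {
    list(support = 100 * x$support, confidence = 100 * x$confidence,
         lift = x$lift, size = x$itemset_size)
  } else stop("cannot summarize object of class ",
              paste(class(x), collapse = "/"), call. = FALSE)
}

#' Summarize a rule table
#'
#' Counts the rules, decomposes them by itemset size (k = number of LHS
#' items + 1 for the consequent), reports the min/max of support,
#' confidence (percent) and lift, and the implied-base-rate diagnostic
#' (confidence / lift per rule, with mean and coefficient of variation).
#'
#' @param x A `rule_set`, `rule_table`, or packaged fixture table.
#' @param part For fixture tables: restrict to one Part (stratum level).
#' @return An object of class `rule_table_summary`.
#' @export
summarize_rule_table <- function(x, part = NULL) {
  v <- rule_vectors(x, part)
  n <- length(v$lift)
  size_counts <- if (n) table(factor(v$size, levels = sort(unique(v$size))))
                 else table(integer(0))
  rng <- function(z) if (n) c(min = min(z), max = max(z))
                     else c(min = NA_real_, max = NA_real_)
  base <- if (n && all(v$lift > 0)) implied_base_rates(v$confidence, v$lift)
          else list(per_rule = numeric(0), mean = NA_real_, cv = NA_real_)
  structure(list(rule_count = n, size_counts = size_counts,
                 support_range = rng(v$support),
                 confidence_range = rng(v$confidence),
                 lift_range = rng(v$lift), base_rate = base),
            class = "rule_table_summary")
}

#' @export
print.rule_table_summary <- function(x, ...) {
  cat(sprintf("Rules: %d", x$rule_count))
  if (x$rule_count) {
    cat("  (",
        paste(sprintf("%s-item: %d", names(x$size_counts), x$size_counts),
              collapse = ", "), ")", sep = "")
    cat(sprintf("\n  support %.2f%%-%.2f%%  confidence %.2f%%-%.2f%%  lift %.2f-%.2f\n",
                x$support_range[1], x$support_range[2],
                x$confidence_range[1], x$confidence_range[2],
                x$lift_range[1], x$lift_range[2]))
    cat(sprintf("  implied base rate: mean %.2f%%, CV %.3f%%\n",
                x$base_rate$mean, 100 * x$base_rate$cv))
  } else cat("\n")
  invisible(x)
}

implied_base_rates <- function(confidence, lift) {
  per <- confidence / lift
  m <- mean(per)
  cv <- if (length(per) > 1L) stats::sd(per) / m else 0
  list(per_rule = per, mean = m, cv = cv)
}

#' Implied-base-rate consistency diagnostic
#'
#' Within one stratum every rule shares the consequent, so confidence
#' divided by lift estimates the consequent's prevalence and must be nearly
#' constant across rows; a large coefficient of variation flags an
#' inconsistent (e.g. mistranscribed) table. On tables produced by this
#' package the identity holds exactly up to rounding.
#'
#' @inheritParams summarize_rule_table
#' @return A list with `per_rule` (percent), `mean` and `cv`.
#' @export
implied_base_rate_check <- function(x, part = NULL) {
  v <- rule_vectors(x, part)
  if (!length(v$lift)) stop("rule table is empty", call. = FALSE)
  if (any(v$lift <= 0)) stop("lift must be positive", call. = FALSE)
  implied_base_rates(v$confidence, v$lift)
}

# Half-up rounding to `digits` decimals (the convention of the printed
# tables; R's round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Write analysis reports
#'
#' Writes, into `destination`: one tab-delimited full-precision rule table
#' per stratum (`rules_<mode>_<stratifier>_<level>.tsv`) and a
#' human-readable `report.txt` with support/confidence as percentages and
#' lift rounded half-up to 2 decimals, in the layout of the published
#' tables. Output bytes are deterministic for fixed input.
#'
#' @param result A `stratified_rules` object.
#' @param destination Directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, destination) {
  dir.create(destination, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  report <- c(sprintf("Association rules report (%s mode)", result$mode), "")
  for (key in names(result$tables)) {
    tab <- result$tables[[key]]
    fname <- paste0("rules_", gsub("[^a-z0-9]+", "_", key), ".tsv")
    fpath <- file.path(destination, fname)
    utils::write.table(as.data.frame(tab$rules), fpath, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, fpath)
    report <- c(report,
                sprintf("%s = %s (n = %d): %d rule(s)",
                        tab$stratifier, tab$level, tab$n_stratum,
                        nrow(tab$rules)))
    if (nrow(tab$rules)) {
      df <- tab$rules
      report <- c(report, sprintf(
        "  %s => %s  %.2f  %.2f  %.2f",
        format_lhs(df$lhs), df$rhs,
        round_half_up(100 * df$support), round_half_up(100 * df$confidence),
        round_half_up(df$lift)))
    }
    report <- c(report, "")
  }
  rpath <- file.path(destination, "report.txt")
  writeLines(report, rpath)
  invisible(c(paths, rpath))
}
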