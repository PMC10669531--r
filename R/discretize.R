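# Discretization of scored records into risk-mode or protective-mode
# transactions: quartile criteria on scale totals, fixed criteria on the
# binary family/school variables, demographic level items, and the
# depression / nondepression outcome item.

QUARTILE_SCALES <- c("cohesion", "conflict", "financial",
                     "teacher", "peer", "autonomy")

#' Outcome labelling rule
#'
#' Depression classification from the DSRSC total: scores at or above the
#' threshold (default 15, inclusive) are labelled `"depression"`, all others
#' `"nondepression"`.
#'
#' @param threshold Integer cutoff in `[0, 36]`.
#' @param inclusive Logical; if `TRUE` (default) a score equal to the
#'   threshold counts as depression.
#' @return An object of class `outcome_rule`.
#' @export
outcome_rule <- function(threshold = 15L, inclusive = TRUE) {
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 0L || threshold > 36L)
    stop("threshold must lie in [0, 36]", call. = FALSE)
  structure(list(threshold = threshold, inclusive = isTRUE(inclusive)),
            class = "outcome_rule")
}

#' Label the depression outcome
#'
#' @param score Integer DSRSC total(s) in `[0, 36]`.
#' @param rule An [outcome_rule()].
#' @return Character vector: `"depression"` or `"nondepression"`.
#' @export
label_outcome <- function(score, rule = outcome_rule()) {
  if (any(is.na(score)) || any(score < 0L) || any(score > 36L))
    stop("depression score out of range [0, 36]", call. = FALSE)
  hit <- if (rule$inclusive) score >= rule$threshold else score > rule$threshold
  ifelse(hit, "depression", "nondepression")
}

#' Quartile cutoffs for the scale totals
#'
#' Nearest-rank percentiles on the analytic sample: the q-th percentile is
#' the value at position `ceiling(q * n)` of the sorted totals. Computed on
#' the full sample passed in (pooled scope by default; pass a stratum's
#' records for stratum scope).
#'
#' @param scored A `scored_df` from [score_scales()].
#' @param scales Character vector of scale names to cut (defaults to the six
#'   quartile-discretized scales).
#' @return A `data.frame` of class `cutoff_table` with columns `scale`,
#'   `p25`, `p75`.
#' @export
compute_cutoffs <- function(scored, scales = QUARTILE_SCALES) {
  if (nrow(scored) == 0L)
    stop("cannot compute cutoffs on an empty record set", call. = FALSE)
  rows <- lapply(scales, function(sn) {
    tot <- scored[[paste0(sn, "_total")]]
    if (is.null(tot)) stop("no totals for scale '", sn, "'", call. = FALSE)
    data.frame(scale = sn, p25 = nearest_rank(tot, 0.25),
               p75 = nearest_rank(tot, 0.75))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat("Quartile cutoffs (nearest-rank):\n")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

# Full item catalog: label, polarity, source variable, mode availability.
item_catalog <- function(mode = c("risk", "protective")) {
  mode <- match.arg(mode)
  scale_src <- c(cohesion = "cohesion", conflict = "conflict",
                 financial = "financial", teacher = "teacher",
                 peer = "peer", autonomy = "autonomy")
  if (mode == "risk") {
    factor_items <- data.frame(
      label = c("low family cohesion", "high family conflict",
                "family economic strain", "low teacher support",
                "low peer support", "low autonomy support",
                "family structure risk", "separation from parents",
                "low parental education level",
                "absence of psychological courses",
                "absence of counselors in the school",
                "absence of counseling rooms in the school"),
      polarity = "risk",
      source_variable = c(unname(scale_src), "family_structure",
                          "left_behind", "parental_education",
                          "psych_courses", "counselors", "counseling_rooms")
    )
  } else {
    factor_items <- data.frame(
      label = c("high family cohesion", "low family conflict",
                "no family economic strain", "high teacher support",
                "high peer support", "high autonomy support",
                "no family structure risk", "non-left-behind children",
                "parental education junior high or above",
                "presence of psychological courses",
                "presence of counselors in the school",
                "presence of counseling rooms in the school"),
      polarity = "protective",
      source_variable = c(unname(scale_src), "family_structure",
                          "left_behind", "parental_education",
                          "psych_courses", "counselors", "counseling_rooms")
    )
  }
  demo_items <- data.frame(
    label = c("female", "male", "primary school students",
              "middle school students", "top-10 academic ranking",
              "average academic ranking", "last-10 academic ranking"),
    polarity = c("demographic", "demographic", "demographic", "demographic",
                 "ranking", "ranking", "ranking"),
    source_variable = c("gender", "gender", "school_stage", "school_stage",
                        "academic_ranking", "academic_ranking",
                        "academic_ranking")
  )
  outcome_items <- data.frame(
    label = c("depression", "nondepression"),
    polarity = "outcome", source_variable = "outcome"
  )
  rbind(factor_items, demo_items, outcome_items)
}

#' Map scored records to discrete items
#'
#' Applies the risk or protective criteria grid. In risk mode the quartile
#' criteria are: scale total at or below P25 for cohesion and the three
#' support scales; at or above P75 for conflict and financial strain; plus
#' the binary risk flags (non-intact family structure, separation from
#' parents/left-behind, low parental education, absence of each school
#' mental-health resource). Protective mode emits the mirrored criteria
#' (>= P75 cohesion/support, <= P25 conflict/strain, intact family,
#' non-left-behind, parental education junior high or above, presence of
#' resources). Both modes always add the respondent's gender, school-stage
#' and academic-ranking level items. Scales listed in `suppress_scales`
#' (degenerate P25 = P75) contribute no quartile item.
#'
#' @param scored A `scored_df` (complete records).
#' @param cutoffs A [compute_cutoffs()] table.
#' @param mode `"risk"` or `"protective"`.
#' @param suppress_scales Character vector of scale names to silence.
#' @return A list (one element per record) of character item-label vectors;
#'   outcome items are not included (see [build_transactions()]).
#' @export
assign_items <- function(scored, cutoffs, mode = c("risk", "protective"),
                         suppress_scales = character()) {
  mode <- match.arg(mode)
  cut_of <- function(sn, col) cutoffs[cutoffs$scale == sn, col][1]
  n <- nrow(scored)
  member <- list()
  for (sn in intersect(QUARTILE_SCALES, cutoffs$scale)) {
    if (sn %in% suppress_scales) next
    tot <- scored[[paste0(sn, "_total")]]
    lo <- tot <= cut_of(sn, "p25")
    hi <- tot >= cut_of(sn, "p75")
    if (mode == "risk") {
      member[[risk_label(sn)]] <- if (sn %in% c("conflict", "financial")) hi else lo
    } else {
      member[[protective_label(sn)]] <-
        if (sn %in% c("conflict", "financial")) lo else hi
    }
  }
  if (mode == "risk") {
    member[["family structure risk"]] <- scored$family_structure_intact == 0L
    member[["separation from parents"]] <- scored$left_behind == 1L
    member[["low parental education level"]] <-
      scored$parental_education_low == 1L
    member[["absence of psychological courses"]] <-
      scored$school_psych_courses == 0L
    member[["absence of counselors in the school"]] <-
      scored$school_counselors == 0L
    member[["absence of counseling rooms in the school"]] <-
      scored$school_counseling_rooms == 0L
  } else {
    member[["no family structure risk"]] <- scored$family_structure_intact == 1L
    member[["non-left-behind children"]] <- scored$left_behind == 0L
    member[["parental education junior high or above"]] <-
      scored$parental_education_low == 0L
    member[["presence of psychological courses"]] <-
      scored$school_psych_courses == 1L
    member[["presence of counselors in the school"]] <-
      scored$school_counselors == 1L
    member[["presence of counseling rooms in the school"]] <-
      scored$school_counseling_rooms == 1L
  }
  member[["female"]] <- scored$gender == "female"
  member[["male"]] <- scored$gender == "male"
  member[["primary school students"]] <- scored$school_stage == "primary"
  member[["middle school students"]] <- scored$school_stage == "middle"
  member[["top-10 academic ranking"]] <- scored$academic_ranking == "top10"
  member[["average academic ranking"]] <- scored$academic_ranking == "average"
  member[["last-10 academic ranking"]] <- scored$academic_ranking == "last10"
  mm <- do.call(cbind, member)
  labs <- colnames(mm)
  lapply(seq_len(n), function(i) labs[mm[i, ]])
}

risk_label <- function(scale) {
  c(cohesion = "low family cohesion", conflict = "high family conflict",
    financial = "family economic strain", teacher = "low teacher support",
    peer = "low peer support", autonomy = "low autonomy support")[[scale]]
}

protective_label <- function(scale) {
  c(cohesion = "high family cohesion", conflict = "low family conflict",
    financial = "no family economic strain",
    teacher = "high teacher support", peer = "high peer support",
    autonomy = "high autonomy support")[[scale]]
}

#' Transaction set
#'
#' Container for the per-respondent item sets fed to the miner. Usually
#' produced by [build_transactions()]; the constructor also accepts any list
#' of character item vectors (for generic market-basket input).
#'
#' @param transactions List of character vectors.
#' @param ids Optional respondent ids (defaults to `T1..Tn`).
#' @param catalog Optional item-catalog `data.frame` (`label`, `polarity`,
#'   `source_variable`); derived from the transactions when omitted.
#' @param mode `"risk"`, `"protective"` or `NA` for generic input.
#' @return An object of class `transaction_set`.
#' @export
transaction_set <- function(transactions, ids = NULL, catalog = NULL,
                            mode = NA_character_) {
  stopifnot(is.list(transactions))
  transactions <- lapply(transactions, as.character)
  if (is.null(ids)) ids <- paste0("T", seq_along(transactions))
  if (is.null(catalog)) {
    labs <- sort_c(as.character(unique(unlist(transactions))))
    catalog <- data.frame(label = labs,
                          polarity = rep(NA_character_, length(labs)),
                          source_variable = rep(NA_character_, length(labs)))
  }
  unknown <- setdiff(unique(unlist(transactions)), catalog$label)
  if (length(unknown))
    stop("transaction item(s) missing from catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(transactions = transactions, ids = ids,
                 catalog = catalog, mode = mode),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat(sprintf("Transaction set: %d transactions over %d catalog items (mode: %s)\n",
              length(x$transactions), nrow(x$catalog),
              ifelse(is.na(x$mode), "generic", x$mode)))
  sizes <- lengths(x$transactions)
  if (length(sizes))
    cat(sprintf("  items per transaction: median %.0f, range %d-%d\n",
                stats::median(sizes), min(sizes), max(sizes)))
  invisible(x)
}

#' @export
length.transaction_set <- function(x) length(x$transactions)

# Locale-independent lexicographic sort (C collation) for deterministic
# item ordering.
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

#' Build transactions from scored records
#'
#' One transaction per respondent: the [assign_items()] item set plus
#' exactly one outcome item from [label_outcome()]. Items whose source
#' variable is in `exclude_variables` (normally the stratifying variable)
#' are dropped from the catalog and from every transaction. Scales whose
#' P25 equals P75 are degenerate and contribute no quartile items (reported
#' via `message()`).
#'
#' @param scored A complete `scored_df`.
#' @param cutoffs A [compute_cutoffs()] table (computed on `scored` when
#'   omitted).
#' @param mode `"risk"` or `"protective"`.
#' @param rule An [outcome_rule()].
#' @param exclude_variables Character vector of source-variable names to
#'   drop (e.g. `"gender"`, `"school_stage"`, `"left_behind"`).
#' @return A [transaction_set()].
#' @export
build_transactions <- function(scored, cutoffs = NULL,
                               mode = c("risk", "protective"),
                               rule = outcome_rule(),
                               exclude_variables = character()) {
  mode <- match.arg(mode)
  if (is.null(cutoffs)) cutoffs <- compute_cutoffs(scored)
  degenerate <- cutoffs$scale[cutoffs$p25 == cutoffs$p75]
  if (length(degenerate))
    message("degenerate scale(s) suppressed (P25 = P75): ",
            paste(degenerate, collapse = ", "))
  catalog <- item_catalog(mode)
  drop_labels <- catalog$label[catalog$source_variable %in% exclude_variables]
  sup_scales <- unique(c(degenerate,
                         intersect(exclude_variables, QUARTILE_SCALES)))
  item_lists <- assign_items(scored, cutoffs, mode,
                             suppress_scales = sup_scales)
  outcome <- label_outcome(scored$depression_score, rule)
  tx <- mapply(function(items, y) {
    sort_c(c(setdiff(items, drop_labels), y))
  }, item_lists, outcome, SIMPLIFY = FALSE)
  catalog <- catalog[!(catalog$label %in% drop_labels) &
                       !(catalog$source_variable %in% degenerate), ,
                     drop = FALSE]
  rownames(catalog) <- NULL
  transaction_set(tx, ids = scored$participant_id, catalog = catalog,
                  mode = mode)
}

#' Export transactions
#'
#' `write_basket()` writes one transaction per line as comma-separated item
#' labels. `as_onehot()` returns a logical indicator matrix (transactions in
#' rows, catalog items in columns), the interchange format of external
#' rule-mining tools.
#'
#' @param ts A [transaction_set()].
#' @param path Output file path.
#' @return `write_basket`: `path` invisibly; `as_onehot`: a logical matrix.
#' @export
write_basket <- function(ts, path) {
  writeLines(vapply(ts$transactions, paste, character(1), collapse = ","),
             path)
  invisible(path)
}

#' @rdname write_basket
#' @export
as_onehot <- function(ts) {
  labs <- ts$catalog$label
  m <- matrix(FALSE, length(ts$transactions), length(labs),
              dimnames = list(ts$ids, labs))
  for (i in seq_along(ts$transactions))
    m[i, ts$transactions[[i]]] <- TRUE
  m
}

#' Read a basket-format file
#'
#' @param path Path to a text file with one transaction per line,
#'   comma-separated item labels (blank line = empty transaction).
#' @return A [transaction_set()].
#' @export
read_basket <- function(path) {
  lines <- readLines(path)
  tx <- lapply(strsplit(lines, ","), function(x) trimws(x[nzchar(trimws(x))]))
  transaction_set(tx)
}
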