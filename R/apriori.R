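# Levelwise Apriori frequent-itemset mining and fixed-consequent rule
# generation, written from scratch on exact integer counts, plus an
# exhaustive enumeration oracle used to cross-check it.

#' Mining thresholds
#'
#' @param min_sup Minimum support, a fraction in (0, 1]; applied to the
#'   support of the whole itemset X union Y (inclusive comparison).
#' @param min_conf Minimum confidence in (0, 1] (inclusive).
#' @param min_lift Lift bound (exclusive: rules must have lift strictly
#'   greater). Default 1.
#' @param max_itemset_size Optional cap on itemset size (LHS + RHS);
#'   `NULL` = unbounded.
#' @return An object of class `mining_params`.
#' @export
mining_params <- function(min_sup, min_conf, min_lift = 1,
                          max_itemset_size = NULL) {
  if (!(min_sup > 0 && min_sup <= 1))
    stop("min_sup must lie in (0, 1]", call. = FALSE)
  if (!(min_conf > 0 && min_conf <= 1))
    stop("min_conf must lie in (0, 1]", call. = FALSE)
  structure(list(min_sup = min_sup, min_conf = min_conf,
                 min_lift = min_lift,
                 max_itemset_size =
                   if (is.null(max_itemset_size)) NULL
                   else as.integer(max_itemset_size)),
            class = "mining_params")
}

#' @export
print.mining_params <- function(x, ...) {
  cat(sprintf("Mining thresholds: support >= %.3f, confidence >= %.3f, lift > %.2f%s\n",
              x$min_sup, x$min_conf, x$min_lift,
              if (is.null(x$max_itemset_size)) ""
              else sprintf(", itemset size <= %d", x$max_itemset_size)))
  invisible(x)
}

as_transaction_set <- function(x) {
  if (inherits(x, "transaction_set")) x else transaction_set(x)
}

# One-hot matrix over the catalog in fixed C-lexicographic item order.
onehot_ordered <- function(ts) {
  labs <- sort_c(ts$catalog$label)
  m <- matrix(FALSE, length(ts$transactions), length(labs),
              dimnames = list(NULL, labs))
  for (i in seq_along(ts$transactions))
    m[i, ts$transactions[[i]]] <- TRUE
  m
}

itemset_key <- function(idx) paste(idx, collapse = "\r")

freq_result <- function(sets, counts, labs, n_total) {
  items <- lapply(sets, function(ix) labs[ix])
  out <- data.frame(size = lengths(sets),
                    support_count = as.integer(counts))
  out$items <- items
  out$support <- out$support_count / n_total
  out <- out[order(out$size,
                   vapply(items, paste, character(1), collapse = "\r"),
                   method = "radix"), c("items", "size", "support_count",
                                        "support")]
  rownames(out) <- NULL
  attr(out, "n_total") <- n_total
  class(out) <- c("freq_itemsets", "data.frame")
  out
}

#' @export
print.freq_itemsets <- function(x, n = 10L, ...) {
  cat(sprintf("Frequent itemsets: %d (over %d transactions)\n",
              nrow(x), attr(x, "n_total")))
  if (nrow(x)) {
    shown <- utils::head(x, n)
    cat(sprintf("  {%s}  count %d  support %.4f\n",
                vapply(shown$items, paste, character(1), collapse = ", "),
                shown$support_count, shown$support), sep = "")
    if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  }
  invisible(x)
}

#' Apriori frequent-itemset mining
#'
#' Levelwise search: frequent 1-itemsets first; candidate k-itemsets by
#' joining frequent (k-1)-itemsets that share a (k-2)-prefix under a fixed
#' lexicographic item order; candidates with any infrequent (k-1)-subset are
#' pruned before counting; supports counted in one pass per level. Returns
#' exactly the itemsets with support at or above `min_sup`, with exact
#' counts, ordered by size then lexicographically.
#'
#' @param ts A [transaction_set()] (or a plain list of character vectors).
#' @param min_sup Minimum support fraction, > 0.
#' @param max_size Optional maximum itemset size.
#' @return A `data.frame` of class `freq_itemsets` with list-column `items`
#'   and columns `size`, `support_count`, `support`.
#' @export
apriori_frequent_itemsets <- function(ts, min_sup, max_size = NULL) {
  ts <- as_transaction_set(ts)
  n <- length(ts$transactions)
  if (n == 0L) stop("empty transaction set", call. = FALSE)
  if (!(min_sup > 0)) stop("min_sup must be positive", call. = FALSE)
  m <- onehot_ordered(ts)
  labs <- colnames(m)
  min_count <- ceiling(min_sup * n - 1e-9)

  counts1 <- colSums(m)
  frequent_idx <- which(counts1 >= min_count)
  sets <- lapply(frequent_idx, identity)
  counts <- counts1[frequent_idx]
  level <- lapply(frequent_idx, identity)   # each an integer vector
  k <- 1L
  while (length(level) >= 2L &&
         (is.null(max_size) || k < max_size)) {
    k <- k + 1L
    prev_keys <- vapply(level, itemset_key, character(1))
    # join step: pairs sharing the (k-2)-prefix, under ascending index order
    prefixes <- vapply(level, function(ix)
      itemset_key(ix[-length(ix)]), character(1))
    lasts <- vapply(level, function(ix) ix[length(ix)], integer(1))
    cand <- list()
    for (grp in split(seq_along(level), prefixes)) {
      if (length(grp) < 2L) next
      grp <- grp[order(lasts[grp])]
      for (a in seq_len(length(grp) - 1L)) {
        for (b in seq((a + 1L), length(grp))) {
          cand[[length(cand) + 1L]] <-
            c(level[[grp[a]]], lasts[grp[b]])
        }
      }
    }
    if (!length(cand)) break
    # prune step: all (k-1)-subsets must be frequent
    keep <- vapply(cand, function(ix) {
      for (drop in seq_along(ix)) {
        if (!(itemset_key(ix[-drop]) %in% prev_keys)) return(FALSE)
      }
      TRUE
    }, logical(1))
    cand <- cand[keep]
    if (!length(cand)) break
    # count step: one pass over the indicator matrix per level
    ccount <- vapply(cand, function(ix)
      sum(rowSums(m[, ix, drop = FALSE]) == length(ix)), numeric(1))
    ok <- ccount >= min_count
    level <- cand[ok]
    if (!length(level)) break
    sets <- c(sets, level)
    counts <- c(counts, ccount[ok])
  }
  freq_result(sets, counts, labs, n)
}

#' Exhaustive frequent-itemset oracle
#'
#' Enumerates every non-empty subset of the item catalog and counts its
#' support directly. Exponential in the catalog size; guarded at 20 items.
#' Used as the independent reference for [apriori_frequent_itemsets()].
#'
#' @inheritParams apriori_frequent_itemsets
#' @return A `freq_itemsets` data.frame identical in layout to the Apriori
#'   output.
#' @export
brute_force_frequent_itemsets <- function(ts, min_sup) {
  ts <- as_transaction_set(ts)
  n <- length(ts$transactions)
  if (n == 0L) stop("empty transaction set", call. = FALSE)
  p <- nrow(ts$catalog)
  if (p > 20L)
    stop("brute-force oracle is guarded at 20 catalog items (got ", p, ")",
         call. = FALSE)
  min_count <- ceiling(min_sup * n - 1e-9)
  if (p == 0L) return(freq_result(list(), integer(0), character(0), n))
  m <- onehot_ordered(ts)
  labs <- colnames(m)
  sets <- list()
  counts <- numeric(0)
  for (k in seq_len(p)) {
    combos <- utils::combn(p, k)
    for (j in seq_len(ncol(combos))) {
      ix <- combos[, j]
      cnt <- sum(rowSums(m[, ix, drop = FALSE]) == k)
      if (cnt >= min_count) {
        sets[[length(sets) + 1L]] <- ix
        counts <- c(counts, cnt)
      }
    }
  }
  freq_result(sets, counts, labs, n)
}

#' Evaluate one association rule on a transaction set
#'
#' Exact counts and the three rule metrics: support = n(X and Y)/n,
#' confidence = n(X and Y)/n(X), lift = confidence / (n(Y)/n).
#'
#' @param lhs Non-empty character vector of antecedent item labels.
#' @param rhs Single consequent item label.
#' @param ts A [transaction_set()].
#' @return A list of class `rule_metrics`: `support`, `confidence`, `lift`,
#'   and counts `n_total`, `n_lhs`, `n_rhs`, `n_both`.
#' @export
evaluate_rule <- function(lhs, rhs, ts) {
  ts <- as_transaction_set(ts)
  if (length(lhs) == 0L) stop("lhs must be non-empty", call. = FALSE)
  stopifnot(length(rhs) == 1L)
  unknown <- setdiff(c(lhs, rhs), ts$catalog$label)
  if (length(unknown))
    stop("unknown item label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  has_lhs <- vapply(ts$transactions, function(t) all(lhs %in% t), logical(1))
  has_rhs <- vapply(ts$transactions, function(t) rhs %in% t, logical(1))
  n_total <- length(ts$transactions)
  n_lhs <- sum(has_lhs)
  n_rhs <- sum(has_rhs)
  n_both <- sum(has_lhs & has_rhs)
  if (n_lhs == 0L)
    stop("antecedent never occurs: confidence undefined", call. = FALSE)
  structure(list(support = n_both / n_total,
                 confidence = n_both / n_lhs,
                 lift = (n_both / n_lhs) / (n_rhs / n_total),
                 n_total = n_total, n_lhs = n_lhs, n_rhs = n_rhs,
                 n_both = n_both),
            class = "rule_metrics")
}

#' @export
print.rule_metrics <- function(x, ...) {
  cat(sprintf("support %.4f  confidence %.4f  lift %.3f  (n=%d, lhs=%d, rhs=%d, both=%d)\n",
              x$support, x$confidence, x$lift, x$n_total, x$n_lhs,
              x$n_rhs, x$n_both))
  invisible(x)
}

empty_rule_set <- function(n_total, rhs, params = NULL) {
  out <- data.frame(rhs = character(0), support = numeric(0),
                    confidence = numeric(0), lift = numeric(0),
                    n_total = integer(0), n_lhs = integer(0),
                    n_rhs = integer(0), n_both = integer(0),
                    itemset_size = integer(0))
  out$lhs <- list()
  out <- out[c("lhs", "rhs", "support", "confidence", "lift", "n_total",
               "n_lhs", "n_rhs", "n_both", "itemset_size")]
  attr(out, "params") <- params
  attr(out, "consequent") <- rhs
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Generate rules with a fixed consequent
#'
#' For every frequent itemset S that contains `rhs` and has at least two
#' items, forms the rule (S minus rhs) => rhs with exact metrics, and keeps
#' rules meeting the thresholds: support >= `min_sup` (the itemset's own
#' support), confidence >= `min_conf`, lift > `min_lift`.
#'
#' @param frequent A `freq_itemsets` result computed at `params$min_sup` on
#'   the same transactions.
#' @param rhs Single consequent item label.
#' @param ts The [transaction_set()] the itemsets were mined from.
#' @param params A [mining_params()].
#' @return An object of class `rule_set` (a `data.frame` with list-column
#'   `lhs`), sorted by [filter_sort_rules()].
#' @export
rules_for_consequent <- function(frequent, rhs, ts, params) {
  ts <- as_transaction_set(ts)
  if (!(rhs %in% ts$catalog$label))
    stop("consequent '", rhs, "' is not in the item catalog", call. = FALSE)
  n_total <- length(ts$transactions)
  keys <- vapply(frequent$items, function(it) itemset_key(sort_c(it)),
                 character(1))
  count_of <- stats::setNames(frequent$support_count, keys)
  if (!(itemset_key(rhs) %in% names(count_of))) {
    # rhs itself below min_sup: no itemset containing it can qualify
    return(empty_rule_set(n_total, rhs, params))
  }
  rhs_count <- count_of[[itemset_key(rhs)]]
  rows <- list()
  for (i in seq_len(nrow(frequent))) {
    it <- frequent$items[[i]]
    if (length(it) < 2L || !(rhs %in% it)) next
    lhs <- setdiff(it, rhs)
    n_both <- frequent$support_count[i]
    n_lhs <- count_of[[itemset_key(sort_c(lhs))]]
    support <- n_both / n_total
    confidence <- n_both / n_lhs
    lift <- confidence / (rhs_count / n_total)
    if (support >= params$min_sup - 1e-12 &&
        confidence >= params$min_conf - 1e-12 &&
        lift > params$min_lift) {
      rows[[length(rows) + 1L]] <- list(
        lhs = lhs, support = support, confidence = confidence, lift = lift,
        n_lhs = as.integer(n_lhs), n_both = as.integer(n_both),
        itemset_size = length(it))
    }
  }
  if (!length(rows)) return(empty_rule_set(n_total, rhs, params))
  out <- data.frame(
    rhs = rhs,
    support = vapply(rows, `[[`, numeric(1), "support"),
    confidence = vapply(rows, `[[`, numeric(1), "confidence"),
    lift = vapply(rows, `[[`, numeric(1), "lift"),
    n_total = n_total,
    n_lhs = vapply(rows, `[[`, integer(1), "n_lhs"),
    n_rhs = as.integer(rhs_count),
    n_both = vapply(rows, `[[`, integer(1), "n_both"),
    itemset_size = vapply(rows, `[[`, integer(1), "itemset_size"))
  out$lhs <- lapply(rows, `[[`, "lhs")
  out <- out[c("lhs", "rhs", "support", "confidence", "lift", "n_total",
               "n_lhs", "n_rhs", "n_both", "itemset_size")]
  attr(out, "params") <- params
  attr(out, "consequent") <- rhs
  class(out) <- c("rule_set", "data.frame")
  filter_sort_rules(out)
}

#' Order a rule set for reporting
#'
#' Stable sort by confidence (descending), ties broken by support
#' (descending), then by the lexicographic order of the antecedent labels.
#' Idempotent and deterministic.
#'
#' @param rules A `rule_set`.
#' @return The same `rule_set`, reordered.
#' @export
filter_sort_rules <- function(rules) {
  if (!nrow(rules)) return(rules)
  lhs_key <- vapply(rules$lhs, function(x) paste(sort_c(x), collapse = "\r"),
                    character(1))
  ord <- order(-rules$confidence, -rules$support, lhs_key, method = "radix")
  out <- rules[ord, ]
  rownames(out) <- NULL
  attributes(out)[c("params", "consequent")] <-
    attributes(rules)[c("params", "consequent")]
  class(out) <- class(rules)
  out
}

#' Mine association rules with a fixed consequent
#'
#' The package's main fitting entry point: runs the levelwise Apriori search
#' at `min_sup`, generates rules whose right-hand side is `rhs`, applies the
#' confidence and lift thresholds, and returns the rules in reporting order.
#'
#' @param ts A [transaction_set()] (e.g. from [build_transactions()]) or a
#'   plain list of character vectors.
#' @param rhs Consequent item label (e.g. `"depression"`).
#' @param min_sup,min_conf,min_lift,max_itemset_size See [mining_params()].
#' @return A `rule_set` object; see [print.rule_set()],
#'   [summary.rule_set()], [as.data.frame.rule_set()].
#' @examples
#' tx <- list(c("A", "B", "Y"), c("A", "B", "Y"), c("A", "Y"), c("B", "Y"),
#'            c("A", "B"), "A", "B", "Y", character(0), c("A", "B", "Y"))
#' mine_rules(tx, rhs = "Y", min_sup = 0.3, min_conf = 0.7)
#' @export
mine_rules <- function(ts, rhs, min_sup, min_conf, min_lift = 1,
                       max_itemset_size = NULL) {
  params <- mining_params(min_sup, min_conf, min_lift, max_itemset_size)
  ts <- as_transaction_set(ts)
  frequent <- apriori_frequent_itemsets(ts, params$min_sup,
                                        max_size = params$max_itemset_size)
  rules_for_consequent(frequent, rhs, ts, params)
}

format_lhs <- function(lhs) {
  vapply(lhs, paste, character(1), collapse = ", ")
}

#' @export
print.rule_set <- function(x, digits = 2, ...) {
  params <- attr(x, "params")
  cat(sprintf("Association rules: %d rule(s), consequent '%s'\n",
              nrow(x), attr(x, "consequent") %||% "?"))
  if (!is.null(params))
    cat(sprintf("  thresholds: support >= %s, confidence >= %s, lift > %s\n",
                format(params$min_sup), format(params$min_conf),
                format(params$min_lift)))
  if (nrow(x)) {
    tab <- data.frame(
      LHS = format_lhs(x$lhs),
      support = sprintf(paste0("%.", digits, "f%%"), 100 * x$support),
      confidence = sprintf(paste0("%.", digits, "f%%"), 100 * x$confidence),
      lift = sprintf(paste0("%.", digits, "f"), x$lift))
    print.data.frame(tab, row.names = TRUE, right = FALSE)
  }
  invisible(x)
}

#' @export
summary.rule_set <- function(object, ...) {
  summarize_rule_table(object)
}

#' Flatten a rule set to a plain data.frame
#'
#' @param x A `rule_set`.
#' @param sep Separator used to join antecedent labels (semicolon, the
#'   delimited-export convention).
#' @param ... Unused.
#' @return A plain `data.frame` with `lhs` as a joined string and the
#'   full-precision metric and count columns.
#' @export
as.data.frame.rule_set <- function(x, sep = ";", ...) {
  data.frame(
    lhs = vapply(x$lhs, paste, character(1), collapse = sep),
    rhs = x$rhs, support = x$support, confidence = x$confidence,
    lift = x$lift, n_total = x$n_total, n_lhs = x$n_lhs, n_rhs = x$n_rhs,
    n_both = x$n_both, itemset_size = x$itemset_size,
    stringsAsFactors = FALSE)
}
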