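#' Read a participant table
#'
#' Reads a delimited text file (UTF-8, header row, comma-separated by
#' default) with one row per respondent: an id column, demographic and
#' school-resource columns, and one column per scale item. Empty cells are
#' missing; item responses outside their scale's response range are also
#' flagged missing (with a warning), so downstream complete-case filtering
#' treats out-of-range entries like blanks.
#'
#' @param path Path to the table.
#' @param cb A [codebook()] describing the expected schema.
#' @param sep Field separator (default comma).
#'
#' @return A `data.frame` of participants, one row per respondent, row order
#'   preserved; class `c("participant_df", "data.frame")` with the codebook
#'   attached as attribute `"codebook"`.
#' @export
load_participants <- function(path, cb = default_codebook(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  wanted <- participant_cols(cb)
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols))
    stop("participant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[wanted]
  as_participant_df(df, cb, source = path)
}

# Validate/coerce a character-or-mixed data.frame into a participant_df.
as_participant_df <- function(df, cb, source = "<data>") {
  num_cols <- c("grade", flag_cols(),
                unlist(lapply(cb$scales, scale_item_cols), use.names = FALSE))
  for (col in num_cols) {
    raw <- df[[col]]
    x <- suppressWarnings(as.integer(raw))
    bad <- !is.na(raw) & is.na(x) & !(is.character(raw) & !nzchar(raw))
    if (any(bad))
      stop(sprintf("unparseable value '%s' at row %d, column '%s' of %s",
                   raw[which(bad)[1]], which(bad)[1], col, source),
           call. = FALSE)
    df[[col]] <- x
  }
  df$participant_id <- as.character(df$participant_id)
  for (v in names(cb$categories)) {
    lev <- cb$categories[[v]]
    bad <- !is.na(df[[v]]) & !(df[[v]] %in% lev)
    if (any(bad))
      stop(sprintf("unknown level '%s' at row %d, column '%s' of %s",
                   df[[v]][which(bad)[1]], which(bad)[1], v, source),
           call. = FALSE)
    df[[v]] <- as.character(df[[v]])
  }
  bad_grade <- !is.na(df$grade) & (df$grade < 5L | df$grade > 9L)
  if (any(bad_grade))
    stop(sprintf("grade out of range 5-9 at row %d of %s",
                 which(bad_grade)[1], source), call. = FALSE)
  for (fc in flag_cols()) {
    bad <- !is.na(df[[fc]]) & !(df[[fc]] %in% c(0L, 1L))
    if (any(bad))
      stop(sprintf("flag column '%s' must be 0/1 (row %d of %s)",
                   fc, which(bad)[1], source), call. = FALSE)
  }
  n_oor <- 0L
  for (s in cb$scales) {
    for (col in scale_item_cols(s)) {
      oor <- !is.na(df[[col]]) &
        (df[[col]] < s$response_min | df[[col]] > s$response_max)
      n_oor <- n_oor + sum(oor)
      df[[col]][oor] <- NA_integer_
    }
  }
  if (n_oor > 0L)
    warning(sprintf("%d out-of-range item response(s) flagged missing", n_oor),
            call. = FALSE)
  attr(df, "codebook") <- cb
  class(df) <- c("participant_df", "data.frame")
  df
}

#' @export
print.participant_df <- function(x, ...) {
  cb <- attr(x, "codebook")
  cat(sprintf("Participant table: %d respondents, %d scales, %d columns\n",
              nrow(x), length(cb$scales), ncol(x)))
  cat(sprintf("  complete cases: %d (%.1f%%)\n", sum(stats::complete.cases(x)),
              if (nrow(x)) 100 * mean(stats::complete.cases(x)) else 100))
  invisible(x)
}

#' Write a participant table
#'
#' Inverse of [load_participants()]: missing values become empty cells, so a
#' write/load round trip reproduces the records exactly.
#'
#' @param participants A participant `data.frame`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path, sep = ",") {
  utils::write.table(participants, path, sep = sep, na = "",
                     row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep only complete cases
#'
#' Complete-case filtering over every analysed column (demographics, flags
#' and all scale items): any missing value drops the respondent. Counts in
#' and out are reported via `message()`.
#'
#' @param participants A participant `data.frame`.
#' @return The subset of rows with no missing values, same class/attributes.
#' @export
filter_complete_cases <- function(participants) {
  keep <- stats::complete.cases(as.data.frame(participants))
  out <- participants[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("complete-case filter: %d of %d record(s) retained (%d dropped)",
                  nrow(out), nrow(participants), sum(!keep)))
  attr(out, "codebook") <- attr(participants, "codebook")
  class(out) <- class(participants)
  out
}

#' Score the survey scales
#'
#' Computes each scale's total as the plain sum of its item responses (no
#' reverse keying) and carries the categorical attributes forward. The DSRSC
#' total is exposed as `depression_score` (range 0-36). School stage is
#' derived from grade (5-6 primary, 7-9 middle), never stored independently.
#'
#' @param participants A complete participant `data.frame` (run
#'   [filter_complete_cases()] first; any missing item is an error).
#' @param cb The [codebook()] (defaults to the one attached to
#'   `participants`).
#' @return A `data.frame` of class `c("scored_df", "data.frame")` with one
#'   row per respondent: id, categorical attributes, `school_stage`, one
#'   `<scale>_total` column per non-outcome scale, and `depression_score`.
#' @export
score_scales <- function(participants, cb = attr(participants, "codebook")) {
  if (is.null(cb)) cb <- default_codebook()
  df <- as.data.frame(participants)
  if (anyNA(df))
    stop("missing values present; apply filter_complete_cases() before scoring",
         call. = FALSE)
  out <- df[c("participant_id", "gender", "grade", flag_cols(),
              "academic_ranking")]
  out$school_stage <- school_stage(df$grade)
  for (s in cb$scales) {
    tot <- as.integer(rowSums(df[scale_item_cols(s)]))
    if (s$name == "dsrsc") out$depression_score <- tot
    else out[[paste0(s$name, "_total")]] <- tot
  }
  rownames(out) <- NULL
  attr(out, "codebook") <- cb
  class(out) <- c("scored_df", "data.frame")
  out
}

#' @export
print.scored_df <- function(x, ...) {
  cat(sprintf("Scored survey records: %d respondents\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  depression_score: median %.0f, range %d-%d\n",
                stats::median(x$depression_score),
                min(x$depression_score), max(x$depression_score)))
  }
  invisible(x)
}

school_stage <- function(grade) {
  ifelse(grade <= 6L, "primary", "middle")
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a k-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(total score))`,
#' with sample variances (denominator n-1). Alpha can be negative for
#' incoherent item sets; a respondent set with zero total-score variance has
#' undefined reliability and raises an error.
#'
#' @param item_matrix Numeric matrix or data.frame, respondents in rows
#'   (n >= 2), items in columns (k >= 2), no missing values.
#' @return The alpha coefficient (scalar).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 respondents and 2 items", call. = FALSE)
  if (anyNA(m)) stop("item matrix contains missing values", call. = FALSE)
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0)
    stop("total-score variance is zero: reliability undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
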