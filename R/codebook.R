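#' Define a psychometric scale
#'
#' A scale is a block of Likert-type items scored by plain summation. The
#' total-score range is `item_count * response_min` to
#' `item_count * response_max`.
#'
#' @param name Scale identifier (single string), e.g. `"cohesion"`.
#' @param item_count Number of items (positive integer).
#' @param response_min,response_max Integer response bounds; all items share
#'   one response format and `response_min < response_max`.
#' @param prefix Column-name prefix used in participant tables; items are
#'   named `<prefix>_01 .. <prefix>_<item_count>` (zero-padded to 2 digits).
#' @param alpha_target Optional Cronbach's alpha the synthetic generator
#'   should reproduce for this scale (`NA` to leave uncalibrated).
#'
#' @return An object of class `scale_definition`.
#' @seealso [default_codebook()]
#' @export
scale_definition <- function(name, item_count, response_min, response_max,
                             prefix = name, alpha_target = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  item_count <- as.integer(item_count)
  response_min <- as.integer(response_min)
  response_max <- as.integer(response_max)
  if (is.na(item_count) || item_count < 1L)
    stop("item_count must be a positive integer", call. = FALSE)
  if (response_min >= response_max)
    stop("response_min must be strictly below response_max", call. = FALSE)
  structure(
    list(name = name, item_count = item_count,
         response_min = response_min, response_max = response_max,
         prefix = prefix, alpha_target = as.numeric(alpha_target)),
    class = "scale_definition"
  )
}

#' @export
print.scale_definition <- function(x, ...) {
  cat(sprintf("Scale '%s': %d items scored %d-%d (columns %s_01..%s_%02d)\n",
              x$name, x$item_count, x$response_min, x$response_max,
              x$prefix, x$prefix, x$item_count))
  if (!is.na(x$alpha_target))
    cat(sprintf("  generator reliability target: alpha = %.2f\n",
                x$alpha_target))
  invisible(x)
}

scale_item_cols <- function(scale) {
  sprintf("%s_%02d", scale$prefix, seq_len(scale$item_count))
}

#' Survey codebook
#'
#' Bundles the scale definitions and the dictionaries of categorical
#' variables that together define the participant-table schema.
#'
#' @param scales List of [scale_definition()] objects; names must be unique.
#' @param categories Named list; each element is a character vector of the
#'   admissible levels of one categorical column.
#'
#' @return An object of class `codebook`.
#' @export
codebook <- function(scales, categories) {
  nm <- vapply(scales, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("scale names must be unique", call. = FALSE)
  names(scales) <- nm
  structure(list(scales = scales, categories = categories),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("Survey codebook:", length(x$scales), "scales,",
      length(x$categories), "categorical variables\n")
  for (s in x$scales) print(s)
  cat("Categorical variables:\n")
  for (v in names(x$categories))
    cat(sprintf("  %s: %s\n", v, paste(x$categories[[v]], collapse = ", ")))
  invisible(x)
}

#' Default codebook for the adolescent family/school survey
#'
#' Six psychometric scales plus a financial-strain block:
#' family cohesion (16 items, 1-5), family conflict (9 dichotomous items,
#' 0-1), teacher support (7 items, 1-4), peer support (13 items, 1-4),
#' autonomy support (5 items, 1-4), financial strain (5 items, 1-4) and the
#' 18-item children's depression self-rating scale (DSRSC, 0-2, total range
#' 0-36). Reliability targets are the internal consistencies the generator
#' is calibrated against. The financial-strain block length is a codebook
#' convention (only its quartiles are used downstream).
#'
#' @return A [codebook()].
#' @export
default_codebook <- function() {
  codebook(
    scales = list(
      scale_definition("cohesion",  16L, 1L, 5L, "coh",   alpha_target = 0.82),
      scale_definition("conflict",   9L, 0L, 1L, "con",   alpha_target = 0.63),
      scale_definition("teacher",    7L, 1L, 4L, "tea",   alpha_target = 0.80),
      scale_definition("peer",      13L, 1L, 4L, "peer",  alpha_target = 0.81),
      scale_definition("autonomy",   5L, 1L, 4L, "auto",  alpha_target = 0.76),
      scale_definition("financial",  5L, 1L, 4L, "fin",   alpha_target = 0.80),
      scale_definition("dsrsc",     18L, 0L, 2L, "dsrsc", alpha_target = 0.84)
    ),
    categories = list(
      gender = c("female", "male"),
      academic_ranking = c("top10", "average", "last10")
    )
  )
}

# Binary 0/1 flag columns of the participant table (besides grade and the
# categorical columns above).
flag_cols <- function() {
  c("left_behind", "family_structure_intact", "parental_education_low",
    "school_psych_courses", "school_counselors", "school_counseling_rooms")
}

participant_cols <- function(cb) {
  c("participant_id", "gender", "grade", flag_cols(), "academic_ranking",
    unlist(lapply(cb$scales, scale_item_cols), use.names = FALSE))
}

#' Write / read a codebook as a YAML file
#'
#' The on-disk form is a human-editable key-value document listing each
#' scale's item count, response range, column prefix and reliability target,
#' plus the categorical level dictionaries.
#'
#' @param cb A [codebook()].
#' @param path File path.
#' @return `read_codebook` returns a [codebook()]; `write_codebook` returns
#'   `path` invisibly.
#' @export
write_codebook <- function(cb, path) {
  doc <- list(
    scales = lapply(unname(cb$scales), function(s)
      list(name = s$name, item_count = s$item_count,
           response_min = s$response_min, response_max = s$response_max,
           prefix = s$prefix, alpha_target = s$alpha_target)),
    categories = cb$categories
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  doc <- yaml::read_yaml(path)
  codebook(
    scales = lapply(doc$scales, function(s)
      scale_definition(s$name, s$item_count, s$response_min, s$response_max,
                       s$prefix, s$alpha_target %||% NA_real_)),
    categories = lapply(doc$categories, as.character)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
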