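# Synthetic survey-cohort generator.
#
# Respondent-level construct scores are multivariate-normal latents; item
# responses arise by thresholding compound-symmetric item latents around the
# respondent's construct level. Depression status is drawn from a logistic
# model on the Table-1-style discretized risk indicators of the synthetic
# cohort itself (so the planted dependence is expressed on exactly the
# variables the miner sees), and the 18-item depression scale is generated
# consistently with that status.

RISK_INDICATORS <- c(
  "low family cohesion", "high family conflict", "family economic strain",
  "low teacher support", "low peer support", "low autonomy support",
  "family structure risk", "separation from parents",
  "low parental education level", "absence of psychological courses",
  "absence of counselors in the school",
  "absence of counseling rooms in the school"
)

#' Default generator configuration
#'
#' Study-scale defaults: n = 2445 respondents; 52.8% female; 1281/2445 in
#' middle school with the observed grade split within stage; 35.6%
#' left-behind. Per-scale inter-item correlations are set by inverting the
#' Spearman-Brown-type identity `rho = alpha / (k - (k-1) alpha)` at each
#' scale's reliability target (e.g. cohesion: 0.82/(16 - 15*0.82) = 0.2216);
#' the generator additionally corrects these Pearson-scale targets for
#' discretization attenuation before use (see the methods vignette).
#' The planted outcome model assigns log-odds 0.9 to low family cohesion and
#' high family conflict, 0.6 to their interaction, and 0.5 to low peer and
#' low teacher support; the intercept (-1.72) puts overall depression
#' prevalence near 0.30, and the cross-scale latent correlations place the
#' lift of the planted family-adversity combination near the published
#' 2.4-3.0 range.
#'
#' @param n Cohort size before missingness (default 2445).
#' @param seed Default random seed carried in the config.
#' @param cb Codebook defining the scales.
#' @return An object of class `generator_config`.
#' @export
default_config <- function(n = 2445L, seed = 1L, cb = default_codebook()) {
  scale_names <- setdiff(names(cb$scales), "dsrsc")
  rho <- vapply(cb$scales, function(s) {
    a <- s$alpha_target
    k <- s$item_count
    a / (k - (k - 1) * a)
  }, numeric(1))
  item_probs <- list(
    cohesion  = rep(0.2, 5),
    conflict  = c(0.65, 0.35),
    teacher   = rep(0.25, 4),
    peer      = rep(0.25, 4),
    autonomy  = rep(0.25, 4),
    financial = rep(0.25, 4),
    dsrsc     = c(0.55, 0.30, 0.15)
  )
  cs <- diag(1, 6)
  dimnames(cs) <- list(scale_names, scale_names)
  set_cor <- function(m, a, b, v) { m[a, b] <- v; m[b, a] <- v; m }
  cs <- set_cor(cs, "cohesion", "conflict",  -0.45)
  cs <- set_cor(cs, "cohesion", "financial", -0.15)
  cs <- set_cor(cs, "cohesion", "teacher",    0.40)
  cs <- set_cor(cs, "cohesion", "peer",       0.45)
  cs <- set_cor(cs, "cohesion", "autonomy",   0.25)
  cs <- set_cor(cs, "conflict", "financial",  0.15)
  cs <- set_cor(cs, "conflict", "teacher",   -0.30)
  cs <- set_cor(cs, "conflict", "peer",      -0.35)
  cs <- set_cor(cs, "conflict", "autonomy",  -0.15)
  cs <- set_cor(cs, "financial", "teacher",  -0.05)
  cs <- set_cor(cs, "financial", "peer",     -0.10)
  cs <- set_cor(cs, "financial", "autonomy", -0.05)
  cs <- set_cor(cs, "teacher", "peer",        0.45)
  cs <- set_cor(cs, "teacher", "autonomy",    0.40)
  cs <- set_cor(cs, "peer", "autonomy",       0.35)

  main <- c(0.9, 0.9, 0.5, 0.5)
  names(main) <- c("low family cohesion", "high family conflict",
                   "low peer support", "low teacher support")
  cfg <- structure(list(
    n = as.integer(n),
    seed = as.integer(seed),
    codebook = cb,
    marginals = list(
      p_female = 0.528,
      p_middle_school = 1281 / 2445,
      grade_primary = c(`5` = 590, `6` = 574) / 1164,
      grade_middle  = c(`7` = 414, `8` = 418, `9` = 449) / 1281,
      p_left_behind = 0.356,
      p_intact_family = 0.85,
      p_parental_education_low = 0.35,
      academic_ranking = c(top10 = 0.25, average = 0.55, last10 = 0.20),
      p_psych_courses = 0.60,
      p_counselors = 0.50,
      p_counseling_rooms = 0.55
    ),
    scale_rho = rho,
    item_probs = item_probs,
    cross_scale_cor = cs,
    outcome_model = list(
      intercept = -1.72,
      main = main,
      interactions = list(
        list(items = c("low family cohesion", "high family conflict"),
             beta = 0.6)
      )
    ),
    dsrsc = list(threshold = 15L, status_shift = 3.0,
                 target_prevalence = 0.30),
    missingness_rate = 355 / 2800
  ), class = "generator_config")
  validate_config(cfg)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic survey generator config: n = %d, seed = %d\n",
              x$n, x$seed))
  cat(sprintf("  female %.1f%%, middle school %.1f%%, left-behind %.1f%%, row missingness %.1f%%\n",
              100 * x$marginals$p_female, 100 * x$marginals$p_middle_school,
              100 * x$marginals$p_left_behind, 100 * x$missingness_rate))
  cat(sprintf("  planted outcome model: intercept %.2f; %d main effect(s), %d interaction(s)\n",
              x$outcome_model$intercept, length(x$outcome_model$main),
              length(x$outcome_model$interactions)))
  invisible(x)
}

validate_config <- function(cfg) {
  m <- cfg$marginals
  probs <- c(m$p_female, m$p_middle_school, m$p_left_behind,
             m$p_intact_family, m$p_parental_education_low,
             m$p_psych_courses, m$p_counselors, m$p_counseling_rooms,
             cfg$missingness_rate)
  if (any(probs < 0 | probs > 1))
    stop("config probabilities must lie in [0, 1]", call. = FALSE)
  for (d in list(m$grade_primary, m$grade_middle, m$academic_ranking))
    if (abs(sum(d) - 1) > 1e-8)
      stop("config probability distributions must sum to 1", call. = FALSE)
  if (cfg$n < 0L) stop("config n must be non-negative", call. = FALSE)
  cs <- cfg$cross_scale_cor
  if (!isSymmetric(unname(cs)) || any(abs(diag(cs) - 1) > 1e-8))
    stop("cross-scale correlation matrix must be symmetric with unit diagonal",
         call. = FALSE)
  ev <- eigen(cs, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("cross-scale correlation matrix is not positive semi-definite",
         call. = FALSE)
  labs <- c(names(cfg$outcome_model$main),
            unlist(lapply(cfg$outcome_model$interactions, `[[`, "items")))
  unknown <- setdiff(labs, RISK_INDICATORS)
  if (length(unknown))
    stop("unknown outcome-model indicator label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

# Deterministic per-stage substream seed so adding a generation stage never
# perturbs the draws of earlier stages.
substream_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

# Attenuation of the Pearson correlation induced by thresholding a standard
# normal into ordered categories with marginal probabilities p: lambda is
# the correlation between the latent and its discretized score, so
# discretized-item correlation ~ lambda^2 * latent correlation.
threshold_lambda <- function(p, scores) {
  cuts <- stats::qnorm(cumsum(p))          # last = Inf
  lo <- c(-Inf, cuts[-length(cuts)])
  hi <- cuts
  cov_xs <- sum(scores * (stats::dnorm(lo) - stats::dnorm(hi)))
  mu <- sum(scores * p)
  v <- sum(scores^2 * p) - mu^2
  cov_xs / sqrt(v)
}

# Latent compound-symmetry correlation needed so that, after thresholding
# (attenuation lambda^2) and, for the depression scale, the extra
# between-status variance v_b of the construct level, the realized
# inter-item Pearson correlation matches the alpha-derived target.
latent_rho <- function(r_target, lambda2, v_b = 0) {
  r_lat <- min(r_target / lambda2, 0.99)
  r_lat / (1 + v_b * (1 - r_lat))
}

# Threshold a latent matrix (rows = respondents) into integer responses.
cut_items <- function(x, p, response_min) {
  cuts <- stats::qnorm(cumsum(p)[-length(p)])
  resp <- matrix(response_min + findInterval(x, cuts),
                 nrow = nrow(x), ncol = ncol(x))
  resp
}

# Compound-symmetric item block around construct level w (any variance);
# standardized before thresholding so the configured marginals hold.
draw_item_block <- function(w, k, rho_lat, p, response_min, var_w = 1) {
  n <- length(w)
  x <- sqrt(rho_lat) * matrix(w, n, k) +
    sqrt(1 - rho_lat) * matrix(stats::rnorm(n * k), n, k)
  x <- x / sqrt(rho_lat * var_w + (1 - rho_lat))
  cut_items(x, p, response_min)
}

nearest_rank <- function(x, q) {
  s <- sort(x)
  s[ceiling(q * length(s))]
}

# Table-1-style risk indicator matrix from raw totals (pre-outcome, used to
# plant the dependence). Columns follow RISK_INDICATORS.
indicator_matrix <- function(totals, flags) {
  qlo <- function(x) x <= nearest_rank(x, 0.25)
  qhi <- function(x) x >= nearest_rank(x, 0.75)
  m <- cbind(
    qlo(totals$cohesion), qhi(totals$conflict), qhi(totals$financial),
    qlo(totals$teacher), qlo(totals$peer), qlo(totals$autonomy),
    !flags$family_structure_intact, flags$left_behind == 1L,
    flags$parental_education_low == 1L,
    flags$school_psych_courses == 0L, flags$school_counselors == 0L,
    flags$school_counseling_rooms == 0L
  )
  colnames(m) <- RISK_INDICATORS
  m * 1L
}

outcome_linpred <- function(model, ind) {
  lp <- rep(model$intercept, nrow(ind))
  for (lab in names(model$main)) lp <- lp + model$main[[lab]] * ind[, lab]
  for (ia in model$interactions)
    lp <- lp + ia$beta * apply(ind[, ia$items, drop = FALSE], 1, prod)
  lp
}

#' Generate a synthetic survey cohort
#'
#' Deterministic given the seed. Stages, each on its own derived random
#' substream: (1) demographics from the configured marginals, drawn
#' independently; (2) respondent-level construct scores from the cross-scale
#' latent correlation matrix; (3) item responses by thresholding
#' compound-symmetric item latents (inter-item correlation calibrated to the
#' scale's reliability target, with discretization-attenuation correction);
#' (4) provisional risk indicators by the quartile/criterion grid on this
#' cohort; (5) depression status from the planted logistic model on those
#' indicators; (6) depression-scale items from a status-shifted latent,
#' minimally adjusted so the total is >= 15 exactly for the depressed;
#' (7) completely-at-random row-level missingness.
#'
#' @param config A [default_config()]-style `generator_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A participant `data.frame` (see [load_participants()]).
#' @export
generate_participants <- function(config, seed = config$seed) {
  validate_config(config)
  cb <- config$codebook
  n <- config$n
  m <- config$marginals
  cols <- participant_cols(cb)
  if (n == 0L) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                               dimnames = list(NULL, cols)))
    return(as_participant_df(df, cb, source = "<generated>"))
  }

  # (1) demographics
  set.seed(substream_seed(seed, "demographics"))
  gender <- ifelse(stats::runif(n) < m$p_female, "female", "male")
  middle <- stats::runif(n) < m$p_middle_school
  grade <- integer(n)
  grade[!middle] <- sample(c(5L, 6L), sum(!middle), TRUE, m$grade_primary)
  grade[middle] <- sample(c(7L, 8L, 9L), sum(middle), TRUE, m$grade_middle)
  flags <- data.frame(
    left_behind = as.integer(stats::runif(n) < m$p_left_behind),
    family_structure_intact = as.integer(stats::runif(n) < m$p_intact_family),
    parental_education_low =
      as.integer(stats::runif(n) < m$p_parental_education_low),
    school_psych_courses = as.integer(stats::runif(n) < m$p_psych_courses),
    school_counselors = as.integer(stats::runif(n) < m$p_counselors),
    school_counseling_rooms =
      as.integer(stats::runif(n) < m$p_counseling_rooms)
  )
  ranking <- sample(names(m$academic_ranking), n, TRUE, m$academic_ranking)

  # (2) construct levels
  set.seed(substream_seed(seed, "scale-latents"))
  cs <- config$cross_scale_cor
  z <- matrix(stats::rnorm(n * ncol(cs)), n, ncol(cs)) %*% chol(cs)
  colnames(z) <- colnames(cs)

  # (3) predictor-scale items
  set.seed(substream_seed(seed, "items"))
  items <- list()
  for (sn in colnames(cs)) {
    s <- cb$scales[[sn]]
    p <- config$item_probs[[sn]]
    lam2 <- threshold_lambda(p, s$response_min:s$response_max)^2
    rho_lat <- latent_rho(config$scale_rho[[sn]], lam2)
    blk <- draw_item_block(z[, sn], s$item_count, rho_lat, p, s$response_min)
    colnames(blk) <- scale_item_cols(s)
    items[[sn]] <- blk
  }

  # (4) provisional risk indicators on this cohort
  totals <- lapply(items, rowSums)
  ind <- indicator_matrix(totals, flags)

  # (5) depression status
  set.seed(substream_seed(seed, "outcome"))
  pdep <- stats::plogis(outcome_linpred(config$outcome_model, ind))
  depressed <- stats::runif(n) < pdep

  # (6) depression-scale items consistent with status
  set.seed(substream_seed(seed, "dsrsc"))
  sd_def <- cb$scales$dsrsc
  pd <- config$item_probs$dsrsc
  lam2 <- threshold_lambda(pd, sd_def$response_min:sd_def$response_max)^2
  prev <- config$dsrsc$target_prevalence
  delta <- config$dsrsc$status_shift
  v_b <- delta^2 * prev * (1 - prev)
  rho_lat <- latent_rho(config$scale_rho[["dsrsc"]], lam2, v_b)
  mu <- ifelse(depressed, delta * (1 - prev), -delta * prev)
  w <- mu + stats::rnorm(n)
  dsr <- draw_item_block(w, sd_def$item_count, rho_lat, pd,
                         sd_def$response_min, var_w = 1 + v_b)
  dsr <- enforce_outcome_side(dsr, depressed, config$dsrsc$threshold,
                              sd_def$response_max)
  colnames(dsr) <- scale_item_cols(sd_def)
  items$dsrsc <- dsr

  df <- data.frame(
    participant_id = sprintf("S%04d", seq_len(n)),
    gender = gender, grade = grade, flags,
    academic_ranking = ranking,
    do.call(cbind, unname(items)),
    stringsAsFactors = FALSE, check.names = FALSE
  )

  # (7) row-level missingness
  set.seed(substream_seed(seed, "missingness"))
  if (config$missingness_rate > 0) {
    item_cols <- unlist(lapply(cb$scales, scale_item_cols), use.names = FALSE)
    hit <- which(stats::runif(n) < config$missingness_rate)
    for (i in hit) {
      k <- 1L + stats::rpois(1, 1)
      df[i, sample(item_cols, min(k, length(item_cols)))] <- NA_integer_
    }
  }
  as_participant_df(df, cb, source = "<generated>")
}

# Minimal adjustment so total >= threshold exactly for the depressed:
# bump randomly chosen items up (or down) one step at a time.
enforce_outcome_side <- function(items, depressed, threshold, resp_max) {
  tot <- rowSums(items)
  up <- which(depressed & tot < threshold)
  for (i in up) {
    need <- threshold - tot[i]
    while (need > 0) {
      j <- sample(which(items[i, ] < resp_max), 1L)
      items[i, j] <- items[i, j] + 1L
      need <- need - 1L
    }
  }
  down <- which(!depressed & tot >= threshold)
  for (i in down) {
    need <- tot[i] - (threshold - 1L)
    while (need > 0) {
      j <- sample(which(items[i, ] > 0L), 1L)
      items[i, j] <- items[i, j] - 1L
      need <- need - 1L
    }
  }
  items
}

#' Monte-Carlo oracle for a planted rule
#'
#' Estimates the support, confidence and lift of `lhs_items` implying
#' depression under the generative model by direct simulation, bypassing the
#' transaction-building and mining code entirely: indicators are recomputed
#' inline from raw totals and compared by plain proportions. Intended as an
#' independent cross-check of the mining pipeline.
#'
#' @param config A `generator_config`.
#' @param lhs_items Character vector of risk-indicator and/or demographic
#'   labels (e.g. `c("low family cohesion", "high family conflict")`).
#' @param reps Number of simulated cohorts (>= 1).
#' @param seed Integer seed.
#' @return List of class `rule_oracle` with elements `support`,
#'   `confidence`, `lift` (Monte-Carlo means) and `se` (their standard
#'   errors), plus `reps`.
#' @export
planted_rule_oracle <- function(config, lhs_items, reps = 20L,
                                seed = config$seed) {
  stopifnot(reps >= 1L)
  demo_labels <- c("female", "male", "primary school students",
                   "middle school students")
  unknown <- setdiff(lhs_items, c(RISK_INDICATORS, demo_labels))
  if (length(unknown))
    stop("unknown item label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sup <- conf <- lift <- numeric(reps)
  for (r in seq_len(reps)) {
    cohort <- generate_participants(config,
                                    seed = substream_seed(seed, paste0("oracle", r)))
    cohort <- as.data.frame(cohort)
    cohort <- cohort[stats::complete.cases(cohort), , drop = FALSE]
    cb <- config$codebook
    totals <- lapply(cb$scales, function(s)
      rowSums(cohort[scale_item_cols(s)]))
    ind <- indicator_matrix(totals, cohort)
    demo <- cbind(
      "female" = cohort$gender == "female",
      "male" = cohort$gender == "male",
      "primary school students" = cohort$grade <= 6L,
      "middle school students" = cohort$grade >= 7L
    ) * 1L
    all_ind <- cbind(ind, demo)
    dep <- totals$dsrsc >= config$dsrsc$threshold
    in_lhs <- rowSums(all_ind[, lhs_items, drop = FALSE]) == length(lhs_items)
    sup[r] <- mean(in_lhs & dep)
    conf[r] <- if (any(in_lhs)) mean(dep[in_lhs]) else NA_real_
    lift[r] <- conf[r] / mean(dep)
  }
  se <- function(x) stats::sd(x) / sqrt(sum(!is.na(x)))
  structure(list(
    support = mean(sup, na.rm = TRUE), confidence = mean(conf, na.rm = TRUE),
    lift = mean(lift, na.rm = TRUE),
    se = c(support = se(sup), confidence = se(conf), lift = se(lift)),
    reps = reps, lhs = lhs_items
  ), class = "rule_oracle")
}

#' @export
print.rule_oracle <- function(x, ...) {
  cat(sprintf("Monte-Carlo rule oracle (%d cohorts): {%s} => depression\n",
              x$reps, paste(x$lhs, collapse = ", ")))
  cat(sprintf("  support    %.4f (se %.4f)\n", x$support, x$se["support"]))
  cat(sprintf("  confidence %.4f (se %.4f)\n", x$confidence,
              x$se["confidence"]))
  cat(sprintf("  lift       %.3f (se %.4f)\n", x$lift, x$se["lift"]))
  invisible(x)
}

#' Write / read a generator configuration as YAML
#'
#' @param config A `generator_config`.
#' @param path File path.
#' @return `read_generator_config` returns a `generator_config`;
#'   `write_generator_config` returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  doc <- list(
    n = config$n, seed = config$seed,
    marginals = lapply(config$marginals, function(x)
      if (is.null(names(x))) x else as.list(x)),
    scale_rho = as.list(config$scale_rho),
    item_probs = config$item_probs,
    cross_scale_cor = list(names = colnames(config$cross_scale_cor),
                           rows = apply(config$cross_scale_cor, 1, c,
                                        simplify = FALSE)),
    outcome_model = list(
      intercept = config$outcome_model$intercept,
      main = as.list(config$outcome_model$main),
      interactions = config$outcome_model$interactions
    ),
    dsrsc = config$dsrsc,
    missingness_rate = config$missingness_rate
  )
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path, cb = default_codebook()) {
  doc <- yaml::read_yaml(path)
  cfg <- default_config(n = doc$n, seed = doc$seed, cb = cb)
  for (nm in names(doc$marginals)) {
    v <- doc$marginals[[nm]]
    cfg$marginals[[nm]] <- if (is.list(v)) unlist(v) else v
  }
  cfg$scale_rho[names(doc$scale_rho)] <- unlist(doc$scale_rho)
  cfg$item_probs[names(doc$item_probs)] <-
    lapply(doc$item_probs, as.numeric)
  cs <- do.call(rbind, doc$cross_scale_cor$rows)
  dimnames(cs) <- list(doc$cross_scale_cor$names, doc$cross_scale_cor$names)
  cfg$cross_scale_cor <- cs
  om <- doc$outcome_model
  cfg$outcome_model <- list(
    intercept = om$intercept,
    main = unlist(om$main),
    interactions = lapply(om$interactions, function(ia)
      list(items = unlist(ia$items), beta = ia$beta))
  )
  cfg$dsrsc <- doc$dsrsc
  cfg$missingness_rate <- doc$missingness_rate
  validate_config(cfg)
  cfg
}
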