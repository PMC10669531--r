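test_that("participant tables round-trip through disk and flag bad cells", {
  cb <- default_codebook()
  cfg <- default_config(n = 30L, seed = 7L)
  cfg$missingness_rate <- 0
  p <- generate_participants(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_participants(p, path)
  p2 <- load_participants(path, cb)
  expect_equal(as.data.frame(p2), as.data.frame(p))

  # header-only file -> empty collection
  empty <- p[0, , drop = FALSE]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_participants(empty, path2)
  expect_identical(nrow(load_participants(path2, cb)), 0L)

  # blank cell -> missing flag; only that record drops in filtering
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  raw <- raw[1:3, ]
  raw$coh_03[2] <- ""
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path3, row.names = FALSE, quote = FALSE, na = "")
  p3 <- load_participants(path3, cb)
  expect_identical(nrow(p3), 3L)
  expect_true(is.na(p3$coh_03[2]))
  expect_identical(nrow(suppressMessages(filter_complete_cases(p3))), 2L)

  # out-of-range response is flagged missing with a warning
  raw$coh_03[2] <- "9"
  write.csv(raw, path3, row.names = FALSE, quote = FALSE, na = "")
  expect_warning(p4 <- load_participants(path3, cb), "out-of-range")
  expect_true(is.na(p4$coh_03[2]))

  # schema errors name the offender
  raw2 <- raw[setdiff(names(raw), "dsrsc_01")]
  write.csv(raw2, path3, row.names = FALSE, quote = FALSE, na = "")
  expect_error(load_participants(path3, cb), "dsrsc_01")
  raw$coh_03[2] <- "oops"
  write.csv(raw, path3, row.names = FALSE, quote = FALSE, na = "")
  expect_error(load_participants(path3, cb), "row 2.*coh_03")
})

test_that("complete-case filtering at the study's missingness rate retains ~2445 of 2800", {
  cfg <- default_config(n = 2800L, seed = 5L)
  p <- generate_participants(cfg)
  kept <- nrow(suppressMessages(filter_complete_cases(p)))
  expected <- 2800 * (1 - cfg$missingness_rate)   # ~2445
  tol <- 3 * sqrt(2800 * cfg$missingness_rate * (1 - cfg$missingness_rate))
  expect_lt(abs(kept - expected), tol)
})

test_that("scale scoring sums items, bounds hold, and order is irrelevant", {
  cb <- default_codebook()
  p <- generate_participants(default_config(n = 1L, seed = 3L))
  df <- as.data.frame(p)
  df[sprintf("coh_%02d", 1:16)] <- 5L
  df[sprintf("dsrsc_%02d", 1:18)] <- 1L
  df[sprintf("con_%02d", 1:9)] <- as.list(c(1L, 0L, 1L, rep(0L, 6)))
  s <- score_scales(df, cb)
  expect_identical(s$cohesion_total, 80L)
  expect_identical(s$depression_score, 18L)
  expect_identical(s$conflict_total, 2L)

  p2 <- generate_participants(default_config(n = 50L, seed = 9L))
  p2 <- suppressMessages(filter_complete_cases(p2))
  s2 <- score_scales(p2)
  for (sc in cb$scales) {
    tot <- if (sc$name == "dsrsc") s2$depression_score
           else s2[[paste0(sc$name, "_total")]]
    expect_true(all(tot >= sc$item_count * sc$response_min))
    expect_true(all(tot <= sc$item_count * sc$response_max))
  }
  # permutation invariance over items within a scale
  df2 <- as.data.frame(p2)
  cols <- sprintf("peer_%02d", 1:13)
  df2[cols] <- df2[sample(cols)]
  s3 <- score_scales(df2, cb)
  expect_identical(s3$peer_total, s2$peer_total)

  # scoring refuses missing data
  df3 <- as.data.frame(p2)
  df3$coh_01[1] <- NA_integer_
  expect_error(score_scales(df3, cb), "missing")
})

test_that("Cronbach's alpha matches hand computation and its degenerate cases", {
  m <- rbind(c(1, 2, 1), c(2, 1, 2), c(3, 3, 2), c(4, 4, 4))
  expect_equal(cronbach_alpha(m), 0.9290323, tolerance = 1e-6)
  two <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(cronbach_alpha(two), 1.0)
  expect_error(cronbach_alpha(matrix(2, 5, 3)), "undefined")
  expect_error(cronbach_alpha(matrix(1:3, 1, 3)), "at least 2")
})

test_that("alpha of a compound-symmetric battery converges to k*rho/(1+(k-1)rho)", {
  set.seed(101)
  n <- 20000L; k <- 8L; rho <- 0.3
  u <- rnorm(n)
  x <- sqrt(rho) * matrix(u, n, k) + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  expect_equal(cronbach_alpha(x), k * rho / (1 + (k - 1) * rho),
               tolerance = 0.02)
})

test_that("codebook round-trips through YAML", {
  cb <- default_codebook()
  path <- withr::local_tempfile(fileext = ".yml")
  write_codebook(cb, path)
  cb2 <- read_codebook(path)
  expect_equal(cb2, cb)
  expect_error(scale_definition("x", 5, 4, 4), "strictly below")
  expect_error(codebook(list(scale_definition("a", 2, 0, 1),
                             scale_definition("a", 3, 0, 1)),
                        list()), "unique")
})
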