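test_that("consistency filter keeps labels attaining the cap", {
  log <- tibble::tibble(
    user = c("u", "u", "u", "v", "v"),
    label_id = c(1L, 1L, 1L, 2L, 2L),
    seniority = c(1L, 2L, 3L, 1L, 2L)
  )
  flt <- consistency_filter(log, 3)
  expect_equal(unique(flt$label_id), 1L)
  expect_equal(attr(flt, "removed")[["records"]], 2L)
  # identity when every label reaches the cap
  expect_equal(nrow(consistency_filter(log, 2)), 5L)
  expect_error(consistency_filter(log, 4), "exceeds")
})

test_that("filtered label set equals a set-comprehension oracle", {
  set.seed(14)
  log <- tibble::tibble(
    user = sample(letters[1:6], 200, TRUE),
    label_id = sample(1:12, 200, TRUE),
    timestamp = 1:200, query = "q"
  )
  enr <- assign_seniority(log)
  for (cap in 1:3) {
    flt <- consistency_filter(enr, cap)
    oracle <- unique(enr$label_id[enr$seniority >= cap])
    expect_setequal(unique(flt$label_id), oracle)
  }
})

test_that("margin of error follows the finite-population-corrected formula", {
  # full coverage: margin collapses to zero
  log <- tibble::tibble(user = rep(c("a", "b"), each = 2),
                        label_id = 1L, seniority = rep(1:2, 2))
  rep_full <- representative_cap(log)
  expect_equal(rep_full$levels$margin_of_error, c(0, 0))
  expect_equal(rep_full$s_max, 2L)

  # plug-in check at N = 1000, n = 516, z = 1.96
  e <- 1.96 * sqrt(0.25 / 516) * sqrt((1000 - 516) / 999)
  expect_equal(round(e, 3), 0.030)
  # the same numbers through the function
  log2 <- tibble::tibble(
    user = sprintf("u%04d", 1:1000), label_id = 1L,
    seniority = 1L
  )
  log2 <- dplyr::bind_rows(
    log2,
    tibble::tibble(user = sprintf("u%04d", 1:516), label_id = 1L,
                   seniority = 2L)
  )
  rp <- representative_cap(log2, margin = 0.031, confidence = 0.95)
  expect_equal(rp$N, 1000L)
  expect_equal(rp$levels$n, c(1000L, 516L))
  expect_lt(abs(rp$levels$margin_of_error[2] - e), 1e-4)
  expect_equal(rp$s_max, 2L)

  # margin is non-increasing in n at fixed N
  ns <- seq(50, 1000, by = 50)
  es <- 1.96 * sqrt(0.25 / ns) * sqrt((1000 - ns) / 999)
  expect_true(all(diff(es) < 0))
})

test_that("seniority curves aggregate mean and population sd per level", {
  log <- tibble::tibble(
    user = "u", label_id = 1L, seniority = c(1L, 2L, 3L),
    distance = c(5, 4, 3)
  )
  cur <- curve_by_seniority(log, "distance")
  expect_equal(cur$mean, c(5, 4, 3))
  expect_equal(cur$std, c(0, 0, 0))

  set.seed(3)
  log2 <- tibble::tibble(
    user = "u", label_id = 1L,
    seniority = rep(1:2, c(6, 4)),
    distance = c(rnorm(6), rnorm(4))
  )
  cur2 <- curve_by_seniority(log2, "distance")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(cur2$mean, c(mean(log2$distance[1:6]), mean(log2$distance[7:10])))
  expect_equal(cur2$std, c(pop_sd(log2$distance[1:6]), pop_sd(log2$distance[7:10])))
  expect_equal(cur2$n, c(6L, 4L))

  # record order does not matter
  cur3 <- curve_by_seniority(log2[sample.int(10), ], "distance")
  expect_equal(cur3, cur2)
})

test_that("savitzky-golay reproduces polynomials and the windowed fit", {
  x <- seq_len(9)
  poly2 <- 2 + 0.5 * x - 0.3 * x^2
  sm <- sgolay_smooth(poly2, window = 5, polyorder = 2)
  expect_equal(sm, poly2, tolerance = 1e-10)
  expect_equal(sgolay_smooth(rep(4, 11), 5, 2), rep(4, 11))

  # windowed least-squares oracle on a 7-point series
  y <- c(2, 7, 1, 8, 2, 8, 1)
  got <- sgolay_smooth(y, window = 5, polyorder = 2)
  oracle <- vapply(seq_along(y), function(i) {
    idx <- max(1, i - 2):min(7, i + 2)
    fit <- stats::lm(y[idx] ~ stats::poly(idx, 2, raw = TRUE))
    unname(stats::predict(fit, newdata = data.frame(idx = i)))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-8)

  # interior points agree with the signal package's filter
  if (requireNamespace("signal", quietly = TRUE)) {
    ref <- signal::sgolayfilt(y, p = 2, n = 5)
    expect_equal(got[3:5], ref[3:5], tolerance = 1e-8)
  }

  expect_error(sgolay_smooth(y, window = 4, polyorder = 2), "odd")
  expect_error(sgolay_smooth(y, window = 5, polyorder = 5), "polyorder")
  expect_error(sgolay_smooth(y, window = 9, polyorder = 2), "exceeds")
})

test_that("smooth_curve appends the smoothed mean column", {
  cur <- tibble::tibble(level = 1:9, n = 5L, mean = (1:9)^2 / 10, std = 0)
  out <- smooth_curve(cur, window = 5, polyorder = 2)
  expect_equal(out$mean_smoothed, cur$mean, tolerance = 1e-10)
})

test_that("the balanced trend bootstrap sees no trend in trendless data", {
  set.seed(8)
  pairs <- 40
  log <- tibble::tibble(
    user = rep(sprintf("u%02d", 1:pairs), each = 10),
    label_id = 1L,
    seniority = rep(1:10, pairs),
    distance = rep(rnorm(pairs, 5), each = 10)  # constant within pair
  )
  ci <- trend_bootstrap_ci(log, "distance", S_max = 10, B = 100)
  expect_true(ci$lower <= 0 && ci$upper >= 0)
  expect_equal(ci$slope, 0)
  # a genuine within-pair decline is detected
  log2 <- log
  log2$distance <- log2$distance - 0.4 * (log2$seniority - 1)
  ci2 <- trend_bootstrap_ci(log2, "distance", S_max = 10, B = 100)
  expect_lt(ci2$upper, 0)
})
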