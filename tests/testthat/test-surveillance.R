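test_that("weekly counts bucket hits into Monday-start weeks and zero-fill", {
  p <- coverage_period("2014-01-06", "2014-03-17")  # 10 Monday-start weeks
  w0 <- weekly_counts(tweet_records(), p)
  expect_equal(nrow(w0), 10L)
  expect_true(all(w0$count == 0L))
  expect_equal(format(w0$week_start[1], "%u"), "1")

  hits <- tweet_records(id = sprintf("d%d", 1:7),
                        timestamp = paste0("2014-01-", 13:19, "T10:00:00Z"),
                        text = "x")
  w <- weekly_counts(hits, p)
  expect_equal(w$count[w$week_start == as.Date("2014-01-13")], 7L)
  expect_equal(sum(w$count), 7L)
})

test_that("weekly counts match brute-force bucketing on random hits", {
  p <- coverage_period("2013-07-01", "2014-06-30")
  recs <- make_random_tweets(500, "2013-07-01", "2014-06-30", seed = 21)
  w <- weekly_counts(recs, p)
  d <- as.Date(recs$timestamp, tz = "UTC")
  brute <- vapply(seq_len(nrow(w)), function(i) {
    sum(d >= w$week_start[i] & d < w$week_start[i] + 7)
  }, integer(1))
  expect_equal(w$count, brute)
  expect_equal(sum(w$count), nrow(recs))
})

test_that("coverage gaps mask whole weeks and flag partial weeks", {
  p <- coverage_period("2014-01-06", "2014-03-17",
                       gaps = list(c("2014-01-27", "2014-02-12")))
  w <- weekly_counts(tweet_records(), p)
  expect_true(w$missing[w$week_start == as.Date("2014-01-27")])
  expect_true(w$missing[w$week_start == as.Date("2014-02-03")])
  expect_true(w$partial[w$week_start == as.Date("2014-02-10")])
  expect_false(w$missing[w$week_start == as.Date("2014-02-10")])
  expect_true(is.na(w$count[w$missing][1]))
})

test_that("acf has unit lag 0, the right bounds, and theory-consistent values", {
  x <- generate_ar(0.8, n = 2000, seed = 31)
  av <- acf_values(x, 10)
  expect_equal(av$acf[1], 1)
  expect_equal(av$bound, 1.96 / sqrt(2000))
  expect_lt(abs(av$acf[2] - 0.8), 0.05)
  wn <- generate_ar(numeric(), n = 1000, seed = 32)
  avw <- acf_values(wn, 10)
  expect_gte(sum(abs(avw$acf[-1]) < avw$bound), 9L)
  expect_error(acf_values(rep(3, 100), 10), "constant")
})

test_that("pacf matches the Durbin-Levinson oracle and AR theory", {
  x <- generate_ar(0.6, n = 2000, seed = 33)
  pv <- pacf_values(x, 6)
  expect_equal(pv$pacf, dl_pacf(x, 6), tolerance = 1e-8)
  expect_lt(abs(pv$pacf[1] - 0.6), 0.06)
  expect_true(all(abs(pv$pacf[2:5]) < 0.1))
  # definitional identity at lag 1
  av <- acf_values(x, 6)
  expect_equal(pv$pacf[1], av$acf[2], tolerance = 1e-10)
})

test_that("order selection follows the PACF rule with manual override", {
  wn_orders <- vapply(1:30, function(s) {
    select_order(generate_ar(numeric(), n = 1000, seed = 100 + s))
  }, integer(1))
  expect_gt(mean(wn_orders == 0L), 0.5)   # white noise mostly selects 0
  # externally chosen lag values pass straight through
  expect_equal(select_order(generate_ar(0.5, 200, seed = 1), override = 5), 5L)
  expect_equal(select_order(generate_ar(0.5, 200, seed = 1), override = 1), 1L)
  x3 <- generate_ar(c(0.4, 0.2, 0.3), n = 5000, seed = 44)
  expect_equal(select_order(x3, max_lag = 3), 3L)
})

test_that("conditional least squares matches the normal equations", {
  # p = 0 mean-centers
  expect_equal(fit_ar(c(1, 2, 3), 0)$residuals, c(-1, 0, 1))
  f0 <- fit_ar(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 0)
  expect_equal(f0$residuals, seq(-4.5, 4.5, by = 1))
  expect_equal(f0$intercept, 5.5)
  # 50-point fixture against an independent solve
  x <- generate_ar(c(0.5, -0.2), n = 50, seed = 55)
  f <- fit_ar(x, 2)
  oracle <- brute_ar_cls(x, 2)
  expect_equal(f$intercept, oracle$intercept, tolerance = 1e-8)
  expect_equal(f$coefficients, oracle$coefficients, tolerance = 1e-8)
  expect_equal(f$residuals, oracle$residuals, tolerance = 1e-8)
  expect_lt(abs(mean(f$residuals)), 1e-8)
  expect_length(f$residuals, 48L)
  # guard and degenerate input
  expect_error(fit_ar(rnorm(20), 3), "too short")
  expect_error(fit_ar(rep(1, 100), 1), "constant")
})

test_that("AR(1) coefficient recovery lands near the truth", {
  phis <- vapply(1:20, function(s) {
    fit_ar(generate_ar(0.6, n = 1000, seed = 200 + s), 1)$coefficients
  }, numeric(1))
  expect_gt(mean(phis > 0.5 & phis < 0.7), 0.9)
})

test_that("diagnostics use the Ljung-Box formula and flag misspecification", {
  x <- generate_ar(c(0.5, -0.3), n = 400, seed = 66)
  f <- fit_ar(x, 2)
  d <- diagnose_fit(f, 10)
  expect_equal(d$ljung_box, brute_ljung_box(f$residuals, 10), tolerance = 1e-8)
  ok <- vapply(1:10, function(s) {
    xx <- generate_ar(c(0.5, -0.3), n = 400, seed = 300 + s)
    diagnose_fit(fit_ar(xx, 2), 10)$independent
  }, logical(1))
  expect_gte(mean(ok), 0.8)
  # an AR(0) fit to strongly autocorrelated data fails the check
  y <- generate_ar(0.8, n = 400, seed = 67)
  expect_false(diagnose_fit(fit_ar(y, 0), 10)$independent)
})

test_that("standardisation yields unit variance and is idempotent", {
  expect_equal(standardize_residuals(c(2, -2)), c(1, -1))
  x <- generate_ar(0.4, n = 300, seed = 71)
  f <- fit_ar(x, 1)
  z <- standardize_residuals(f)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-8)
  expect_lt(abs(mean(z)), 1e-8)
  expect_equal(standardize_residuals(z), z, tolerance = 1e-12)
  expect_error(standardize_residuals(rep(0, 10)), "sd is zero")
})

test_that("the CUSUM recursion matches a hand recursion and brute force", {
  # all-zero input stays at zero
  ch0 <- cusum(rep(0, 20))
  expect_true(all(ch0$c_plus == 0) && all(ch0$c_minus == 0))
  expect_equal(nrow(ch0$violations), 0L)
  # +2 step shift: C+ gains 1.5 per step, crosses h = 5 at the 4th point
  z <- c(rep(0, 6), rep(2, 8))
  ch <- cusum(z, k = 0.5, h = 5)
  first_up <- min(ch$violations$index[ch$violations$direction == "upper"])
  expect_equal(first_up, 6L + 4L)
  expect_equal(ch$c_plus[first_up], 6)
  # brute-force recomputation on random input
  set.seed(81)
  zr <- rnorm(200)
  chr <- cusum(zr, k = 0.5, h = 3)
  br <- brute_cusum(zr, 0.5, 3)
  expect_equal(chr$c_plus, br$c_plus)
  expect_equal(chr$c_minus, br$c_minus)
  expect_equal(chr$violations$index[chr$violations$direction == "upper"], br$upper)
  expect_equal(chr$violations$index[chr$violations$direction == "lower"], br$lower)
  expect_error(cusum(c(1, NA)), "non-finite")
})

test_that("the CUSUM reference value shifts increments exactly", {
  set.seed(82)
  z <- rnorm(100)
  k <- 0.7
  expect_equal(cusum(z + k, k = k)$c_plus, cusum(z, k = 0)$c_plus)
})

test_that("violations map back to calendar weeks offset by the AR order", {
  p <- coverage_period("2013-07-01", "2014-06-30")
  weeks <- weekly_counts(tweet_records(), p)
  z <- rep(0, 30); z[10] <- 6; z[11] <- -3   # one spike, then the chart resets
  ch <- cusum(z, k = 0.5, h = 5)
  ev <- detect_events(ch, weeks, p = 5, segment_start = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$week_start, weeks$week_start[5 + 10])
  expect_equal(ev$direction, "upper")
  expect_equal(nrow(detect_events(cusum(rep(0, 30)), weeks, p = 0)), 0L)
  expect_error(detect_events(cusum(rep(0, 100)), weeks, p = 0), "does not fit")
})

test_that("a +2 sd mean shift is caught within a few points", {
  delays <- vapply(1:40, function(s) {
    z <- standardize_residuals(generate_ar(numeric(), n = 120, seed = 400 + s))
    z <- inject_shift(z, 61, 2)
    ch <- cusum(z)
    up <- ch$violations$index[ch$violations$direction == "upper" &
                                ch$violations$index >= 61]
    if (length(up)) min(up) - 61 + 1 else NA_real_
  }, numeric(1))
  expect_true(all(!is.na(delays)))
  expect_lte(stats::median(delays), 5)
  expect_gt(mean(delays <= 6), 0.9)
})

test_that("prewhitening leaves residual autocorrelation within bounds", {
  exceed <- vapply(1:30, function(s) {
    x <- generate_ar(c(0.6, -0.2), n = 300, seed = 500 + s)
    diagnose_fit(fit_ar(x, 2), 10)$exceedances
  }, numeric(1))
  expect_gte(mean(exceed <= 2), 0.9)
})

test_that("the full pipeline runs on gappy weekly series", {
  p <- coverage_period("2013-07-01", "2015-05-31",
                       gaps = list(c("2014-12-01", "2015-01-31")))
  set.seed(91)
  counts_src <- generate_ar(0.5, n = 100, seed = 92, intercept = 5)
  weeks <- weekly_counts(tweet_records(), p)
  weeks$count[!weeks$missing] <- pmax(0, round(counts_src[seq_len(sum(!weeks$missing))]))
  det <- detect_arrivals(weeks)
  expect_s3_class(det, "arrival_detection")
  seg <- det$segment
  expect_true(all(!weeks$missing[seg[1]:seg[2]]))
  # the fitted segment is the longest contiguous block
  expect_gte(seg[2] - seg[1] + 1, 40)
  expect_equal(length(det$chart$z), (seg[2] - seg[1] + 1) - det$order)
})
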