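test_that("SNR is the relevant/hits ratio with half-away-from-zero percent", {
  s <- compute_snr(88, 98)
  expect_equal(s$snr, 88 / 98)
  expect_equal(s$snr_percent, 90L)
  expect_equal(compute_snr(308, 520)$snr_percent, 59L)
  expect_equal(compute_snr(0, 10)$snr_percent, 0L)
  expect_equal(compute_snr(22, 22)$snr_percent, 100L)
  expect_equal(compute_snr(1, 8)$snr_percent, 13L)  # 12.5 rounds away from zero
  expect_error(compute_snr(0, 0), "no hits")
  expect_error(compute_snr(5, 4), "n_relevant <= n_hits")
})

test_that("SNR is monotone in n_relevant at fixed n_hits", {
  snrs <- vapply(0:50, function(r) compute_snr(r, 50)$snr, numeric(1))
  expect_true(all(diff(snrs) > 0))
  expect_true(all(snrs >= 0 & snrs <= 1))
})

make_month_spread_hits <- function(per_month, year = 2014) {
  months <- rep(seq_len(length(per_month)), per_month)
  ts <- as.POSIXct(sprintf("%d-%02d-15 12:00:00", year, months), tz = "UTC") +
    seq_along(months) * 60
  tweet_records(id = sprintf("h%05d", seq_along(months)), timestamp = ts,
                text = "moth")
}

test_that("stratified sampling respects per-month allocation exactly", {
  hits <- make_month_spread_hits(c(40, 10, 100, 3, 7, 200, 25, 60, 90, 12, 30, 23))
  sub <- stratified_sample(hits, 0.1, seed = 4)
  n_m <- attr(sub, "strata_sizes"); s_m <- attr(sub, "sample_sizes")
  expect_equal(unname(s_m), pmax(1L, as.integer(round(n_m * 0.1 + 1e-9))))
  realized <- table(format(sub$timestamp, "%Y-%m"))
  expect_equal(as.integer(realized[names(s_m)]), unname(s_m))
  # identity at fraction 1, arithmetic at 0.1 in a single month
  expect_equal(nrow(stratified_sample(hits, 1, seed = 1)), nrow(hits))
  one_month <- make_month_spread_hits(1000)
  expect_equal(nrow(stratified_sample(one_month, 0.1, seed = 1)), 100L)
  # non-empty months always contribute at least one record
  tiny <- make_month_spread_hits(c(1, 1, 400))
  s_tiny <- stratified_sample(tiny, 0.01, seed = 2)
  expect_equal(unname(attr(s_tiny, "sample_sizes")), c(1L, 1L, 4L))
})

test_that("stratified sampling is seed-reproducible and months never mix", {
  hits <- make_month_spread_hits(c(50, 80, 120, 60))
  a <- stratified_sample(hits, 0.05, seed = 99)
  b <- stratified_sample(hits, 0.05, seed = 99)
  expect_identical(a, b)
  c2 <- stratified_sample(hits, 0.05, seed = 100)
  expect_false(identical(a$id, c2$id))
  # every sampled record stays in its own month stratum
  for (m in unique(format(hits$timestamp, "%Y-%m"))) {
    ids_m <- hits$id[format(hits$timestamp, "%Y-%m") == m]
    expect_true(all(a$id[format(a$timestamp, "%Y-%m") == m] %in% ids_m))
  }
})

test_that("estimate_snr handles labels, errors and the weighted estimator", {
  hits <- make_month_spread_hits(c(30, 30))
  hits$relevance <- "relevant"
  sub <- stratified_sample(hits, 0.2, seed = 1)
  expect_equal(estimate_snr(sub)$snr_percent, 100L)
  expect_true(estimate_snr(sub)$approximate)

  unlab <- sub; unlab$relevance[1] <- NA
  expect_error(estimate_snr(unlab), unlab$id[1])

  # plain and weighted agree under exactly proportional allocation
  hits2 <- make_month_spread_hits(c(40, 80))
  hits2$relevance <- rep(c("relevant", "irrelevant"), length.out = nrow(hits2))
  sub2 <- stratified_sample(hits2, 0.25, seed = 3)  # 10 and 20: exact
  expect_equal(estimate_snr(sub2, weighted = TRUE)$snr,
               estimate_snr(sub2)$snr, tolerance = 1e-12)
})

test_that("subsampled SNR estimation is unbiased on a known-SNR stream", {
  set.seed(2024)
  per_month <- c(60, 45, 80, 70, 55, 65, 40, 85, 50, 75, 90, 35)
  hits <- make_month_spread_hits(per_month)
  rel <- rep(FALSE, nrow(hits))
  rel[sample(nrow(hits), round(0.47 * nrow(hits)))] <- TRUE
  hits$relevance <- ifelse(rel, "relevant", "irrelevant")
  true_snr <- mean(rel)
  ests <- vapply(1:200, function(s) {
    estimate_snr(stratified_sample(hits, 0.1, seed = s))$snr
  }, numeric(1))
  se_mean <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - true_snr), 3 * se_mean)
  # single draws sit within 3 SE of the truth almost always
  se_one <- stats::sd(ests)
  expect_gt(mean(abs(ests - true_snr) < 3 * se_one), 0.97)
})

test_that("verifiability categories partition the relevant tweets", {
  recs <- tweet_records(
    id = sprintf("v%02d", 1:12),
    timestamp = rep("2013-11-01T00:00:00Z", 12),
    text = "koel",
    relevance = "relevant",
    verifiability = c(rep("unverifiable", 9), rep("verifiable_false_positive", 3))
  )
  v <- verifiability_summary(recs)
  expect_equal(v$n_relevant, 12L)
  expect_equal(v$n_unverifiable, 9L)
  expect_equal(v$n_verifiable_true_positive, 0L)
  expect_equal(v$n_verifiable_false_positive, 3L)
  # empty input
  v0 <- verifiability_summary(tweet_records())
  expect_equal(v0$n_relevant, 0L)
  # brute tally oracle
  expect_equal(v$n_unverifiable, sum(recs$verifiability == "unverifiable"))
  # errors
  bad <- recs; bad$verifiability[1] <- NA
  expect_error(verifiability_summary(bad), "missing verifiability")
  bad2 <- recs; bad2$relevance[1] <- "irrelevant"
  expect_error(verifiability_summary(bad2), "labelled relevant")
})
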