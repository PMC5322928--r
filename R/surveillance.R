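# Weekly aggregation and the four-step change-detection procedure:
# (1) inspect ACF/PACF, (2) fit an AR model, (3) check residual independence,
# (4) CUSUM chart of the standardised residuals.

WEEKDAYS <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
              "Saturday", "Sunday")

floor_week <- function(dates, week_start_day = "Monday") {
  target <- match(week_start_day, WEEKDAYS) # 1 = Monday
  dow <- as.integer(format(dates, "%u"))    # 1 = Monday .. 7 = Sunday
  dates - ((dow - target) %% 7L)
}

#' Aggregate hits into a zero-filled weekly series
#'
#' Counts hits per calendar week (weeks start on `week_start_day`, default
#' Monday) across the whole coverage period, filling weeks without hits with
#' zero. Weeks lying entirely inside a coverage gap are masked as missing
#' (`NA` count); weeks partially covered by a gap keep the count from their
#' available days and are flagged `partial`.
#'
#' @param hits a tweet-record `data.frame` (typically from [run_query()]).
#' @param period a [coverage_period()].
#' @param week_start_day weekday on which weeks begin.
#' @param tz time zone used to turn timestamps into calendar dates
#'   (default UTC; set e.g. `"Australia/Canberra"` for local-day bucketing).
#' @return an object of class `weekly_series`: a `data.frame` with columns
#'   `week_start` (`Date`), `count` (integer, `NA` when missing), `missing`,
#'   `partial`.
#' @export
weekly_counts <- function(hits, period, week_start_day = "Monday", tz = "UTC") {
  stopifnot(inherits(period, "coverage_period"))
  week_start_day <- match.arg(week_start_day, WEEKDAYS)
  dates <- as.Date(hits$timestamp, tz = tz)
  if (nrow(hits) && (any(dates < period$start) || any(dates >= period$end))) {
    stop("hits fall outside the coverage period", call. = FALSE)
  }
  grid <- seq(floor_week(period$start, week_start_day),
              floor_week(period$end - 1L, week_start_day), by = "7 days")
  wk <- floor_week(dates, week_start_day)
  counts <- as.integer(table(factor(as.character(wk), levels = as.character(grid))))
  all_days_gapped <- function(ws) {
    days <- seq(ws, ws + 6L, by = "day")
    days <- days[days >= period$start & days < period$end]
    if (!length(days)) return(c(full = TRUE, part = FALSE))
    g <- in_gap(days, period)
    c(full = all(g), part = any(g) && !all(g))
  }
  gap_status <- vapply(seq_along(grid),
                       function(j) all_days_gapped(grid[j]),
                       c(full = FALSE, part = FALSE))
  missing <- gap_status["full", ]
  partial <- gap_status["part", ]
  counts[missing] <- NA_integer_
  out <- data.frame(week_start = grid, count = counts,
                    missing = unname(missing), partial = unname(partial))
  class(out) <- c("weekly_series", "data.frame")
  attr(out, "period") <- period
  attr(out, "week_start_day") <- week_start_day
  out
}

check_series <- function(x, max_lag) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("series contains missing/non-finite values", call. = FALSE)
  if (length(x) <= max_lag) stop("series shorter than max_lag", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant series: autocorrelation undefined", call. = FALSE)
  x
}

#' Autocorrelation function with sampling bounds
#'
#' Sample ACF (biased estimator: the lag-0 autocovariance in the
#' denominator), with the usual white-noise band `+-1.96/sqrt(n)`.
#'
#' @param x numeric series without missing values.
#' @param max_lag largest lag.
#' @return list with `lag` (0..max_lag), `acf`, `bound`, `n`.
#' @export
acf_values <- function(x, max_lag = 10L) {
  x <- check_series(x, max_lag)
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  list(lag = 0:max_lag, acf = as.numeric(a$acf), bound = 1.96 / sqrt(length(x)),
       n = length(x))
}

#' Partial autocorrelation function with sampling bounds
#'
#' Sample PACF via the Durbin-Levinson recursion on the sample ACF. For an
#' AR(p) process the PACF is approximately the last AR coefficient at lag p
#' and near zero beyond.
#'
#' @inheritParams acf_values
#' @return list with `lag` (1..max_lag), `pacf`, `bound`, `n`.
#' @export
pacf_values <- function(x, max_lag = 10L) {
  x <- check_series(x, max_lag)
  p <- stats::pacf(x, lag.max = max_lag, plot = FALSE)
  list(lag = 1:max_lag, pacf = as.numeric(p$acf), bound = 1.96 / sqrt(length(x)),
       n = length(x))
}

#' Choose an AR order from the PACF
#'
#' Automates the visual rule of reading the order off the PACF plot: the
#' selected order is the largest lag (up to `max_lag`) whose partial
#' autocorrelation exceeds the `+-1.96/sqrt(n)` band, or 0 when none does.
#' `override` short-circuits the rule so that externally chosen lag values
#' (e.g. orders read off published charts) can be injected into the pipeline.
#'
#' @inheritParams acf_values
#' @param max_lag largest order considered (default 8).
#' @param override optional integer; returned as-is when supplied.
#' @return integer order `p >= 0`.
#' @export
select_order <- function(x, max_lag = 8L, override = NULL) {
  if (!is.null(override)) {
    override <- as.integer(override)
    stopifnot(override >= 0L)
    return(override)
  }
  pv <- pacf_values(x, max_lag)
  above <- which(abs(pv$pacf) > pv$bound)
  if (length(above)) max(above) else 0L
}

#' Fit an autoregressive model by conditional least squares
#'
#' Fits \eqn{y_t = c + \phi_1 y_{t-1} + \dots + \phi_p y_{t-p} + e_t} by
#' least squares on the lagged design (conditioning on the first `p`
#' observations), the prewhitening step of the detection procedure. `p = 0`
#' reduces to mean-centering. The normal equations force the residual mean
#' to zero.
#'
#' @param x numeric series.
#' @param p AR order (`>= 0`); the series must have at least `5 p + 10`
#'   points.
#' @return an object of class `ar_fit`: `order`, `intercept`,
#'   `coefficients`, `residuals` (length `n - p`), `sigma` (root mean
#'   square of the residuals; their mean is zero by the normal equations),
#'   `n`.
#' @export
fit_ar <- function(x, p) {
  x <- as.numeric(x)
  p <- as.integer(p)
  stopifnot(p >= 0L)
  n <- length(x)
  if (any(!is.finite(x))) stop("series contains missing/non-finite values", call. = FALSE)
  if (p >= 1L && n < 5L * p + 10L) {
    stop(sprintf("series too short for AR(%d): need >= %d points, have %d",
                 p, 5L * p + 10L, n), call. = FALSE)
  }
  if (p == 0L && n < 2L) stop("need at least 2 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant series: AR fit is singular", call. = FALSE)
  if (p == 0L) {
    res <- x - mean(x)
    fit <- list(order = 0L, intercept = mean(x), coefficients = numeric(),
                residuals = res, sigma = sqrt(mean(res^2)), n = n)
    class(fit) <- "ar_fit"
    return(fit)
  }
  y <- x[(p + 1L):n]
  X <- vapply(seq_len(p), function(i) x[(p + 1L - i):(n - i)], numeric(n - p))
  colnames(X) <- paste0("lag", seq_len(p))
  dat <- data.frame(y = y, X)
  lmfit <- stats::lm(y ~ ., data = dat)
  if (anyNA(stats::coef(lmfit))) stop("singular AR design", call. = FALSE)
  res <- unname(stats::residuals(lmfit))
  fit <- list(order = p,
              intercept = unname(stats::coef(lmfit)[1]),
              coefficients = unname(stats::coef(lmfit)[-1]),
              residuals = res,
              sigma = sqrt(mean(res^2)),
              n = n)
  class(fit) <- "ar_fit"
  fit
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("AR(%d) fit (conditional least squares), n = %d\n", x$order, x$n))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  if (x$order > 0L) {
    cat("  phi:", paste(sprintf("%.4f", x$coefficients), collapse = ", "), "\n")
  }
  cat(sprintf("  residual sd: %.4f\n", x$sigma))
  invisible(x)
}

#' Residual independence diagnostics
#'
#' Checks the prewhitening assumption: counts residual-ACF lags outside the
#' 95% white-noise band and computes the Ljung-Box portmanteau statistic at
#' `max_lag`. The fit is flagged `independent` when at most one lag exceeds
#' the band and the Ljung-Box p-value is above 0.05.
#'
#' @param fit an `ar_fit`.
#' @param max_lag number of residual lags examined (default 10).
#' @return list with `exceedances`, `ljung_box` (statistic), `p_value`,
#'   `independent`, `max_lag`.
#' @export
diagnose_fit <- function(fit, max_lag = 10L) {
  stopifnot(inherits(fit, "ar_fit"))
  res <- fit$residuals
  if (length(res) <= max_lag) stop("too few residuals for diagnostics", call. = FALSE)
  av <- acf_values(res, max_lag)
  exceed <- sum(abs(av$acf[-1]) > av$bound)
  lb <- stats::Box.test(res, lag = max_lag, type = "Ljung-Box")
  list(exceedances = exceed,
       ljung_box = unname(lb$statistic),
       p_value = unname(lb$p.value),
       independent = exceed <= 1L && lb$p.value > 0.05,
       max_lag = max_lag)
}

#' Standardise residuals to unit variance
#'
#' Divides by the residual scale `sigma` (root mean square; the residual
#' mean is zero for conditional least squares fits), so the CUSUM reference
#' value and decision interval are on the standard-deviation scale. Accepts
#' an `ar_fit` or a plain numeric vector; the result always has unit scale,
#' making the operation idempotent.
#'
#' @param x an `ar_fit` or numeric vector.
#' @return numeric vector of standardised residuals.
#' @export
standardize_residuals <- function(x) {
  if (inherits(x, "ar_fit")) {
    res <- x$residuals
    s <- x$sigma
  } else {
    res <- as.numeric(x)
    s <- sqrt(mean(res^2))
  }
  if (!is.finite(s) || s == 0) stop("residual sd is zero", call. = FALSE)
  res / s
}

#' Two-sided CUSUM chart
#'
#' Tabular CUSUM of standardised residuals with reference value `k` and
#' decision interval `h`:
#' \deqn{C^+_t = \max(0, C^+_{t-1} + z_t - k), \quad
#'       C^-_t = \min(0, C^-_{t-1} + z_t + k)}
#' starting from zero. The chart signals an upper violation when
#' \eqn{C^+_t > h} (the upper decision bound, UDB) and a lower violation
#' when \eqn{C^-_t < -h} (LDB). Defaults `k = 0.5`, `h = 5` correspond to a
#' detectable mean shift of one standard deviation and a decision interval
#' of five.
#'
#' @param z numeric vector of standardised residuals (finite).
#' @param k reference value (allowance), standard-deviation units.
#' @param h decision interval, standard-deviation units.
#' @return an object of class `cusum_chart`: `z`, `k`, `h`, `c_plus`,
#'   `c_minus` and `violations` (data frame with `index`, `direction`).
#' @examples
#' cusum(c(rep(0, 5), rep(2, 5)))
#' @export
cusum <- function(z, k = 0.5, h = 5) {
  z <- as.numeric(z)
  if (any(!is.finite(z))) stop("non-finite values in z", call. = FALSE)
  stopifnot(k >= 0, h > 0)
  n <- length(z)
  cp <- numeric(n); cm <- numeric(n)
  prev_p <- 0; prev_m <- 0
  for (t in seq_len(n)) {
    prev_p <- max(0, prev_p + z[t] - k)
    prev_m <- min(0, prev_m + z[t] + k)
    cp[t] <- prev_p; cm[t] <- prev_m
  }
  up <- which(cp > h); dn <- which(cm < -h)
  viol <- data.frame(
    index = c(up, dn),
    direction = rep(c("upper", "lower"), c(length(up), length(dn))),
    stringsAsFactors = FALSE
  )
  viol <- viol[order(viol$index), , drop = FALSE]
  rownames(viol) <- NULL
  structure(list(z = z, k = k, h = h, c_plus = cp, c_minus = cm,
                 violations = viol),
            class = "cusum_chart")
}

#' @export
print.cusum_chart <- function(x, ...) {
  cat(sprintf("CUSUM chart: n = %d, k = %g, h = %g\n", length(x$z), x$k, x$h))
  cat(sprintf("  upper violations: %d, lower violations: %d\n",
              sum(x$violations$direction == "upper"),
              sum(x$violations$direction == "lower")))
  invisible(x)
}

#' @export
plot.cusum_chart <- function(x, main = "CUSUM of standardised residuals", ...) {
  n <- length(x$z)
  ylim <- range(c(x$c_plus, x$c_minus, x$h, -x$h))
  graphics::plot(seq_len(n), x$c_plus, type = "b", pch = 20, ylim = ylim,
                 xlab = "index", ylab = "cumulative sum", main = main, ...)
  graphics::lines(seq_len(n), x$c_minus, type = "b", pch = 20)
  graphics::abline(h = c(x$h, -x$h), lty = 2)
  graphics::mtext(c("UDB", "LDB"), side = 4, at = c(x$h, -x$h), las = 1, cex = 0.8)
  if (nrow(x$violations)) {
    up <- x$violations$index[x$violations$direction == "upper"]
    dn <- x$violations$index[x$violations$direction == "lower"]
    graphics::points(up, x$c_plus[up], col = "red", pch = 19)
    graphics::points(dn, x$c_minus[dn], col = "red", pch = 19)
  }
  invisible(x)
}

#' Map chart violations back to calendar weeks
#'
#' Residual index `t` of an AR(p) fit on a contiguous block of weeks
#' corresponds to week `segment_start + p + t - 1` of the weekly series.
#'
#' @param chart a `cusum_chart`.
#' @param weeks the `weekly_series` the fit was run on.
#' @param p the AR order used.
#' @param segment_start index (into `weeks`) of the first week of the fitted
#'   contiguous segment (default 1).
#' @return data frame with `week_start` (`Date`) and `direction`.
#' @export
detect_events <- function(chart, weeks, p = 0L, segment_start = 1L) {
  stopifnot(inherits(chart, "cusum_chart"), inherits(weeks, "weekly_series"))
  p <- as.integer(p); segment_start <- as.integer(segment_start)
  n_fit <- length(chart$z) + p
  if (segment_start < 1L || segment_start + n_fit - 1L > nrow(weeks)) {
    stop("chart length does not fit the weekly series: expected ",
         "length(z) == fitted weeks - p", call. = FALSE)
  }
  idx <- segment_start + p + chart$violations$index - 1L
  data.frame(week_start = weeks$week_start[idx],
             direction = chart$violations$direction,
             stringsAsFactors = FALSE)
}

# Longest contiguous run of non-missing weeks; returns c(start, end) indices.
longest_segment <- function(weeks) {
  ok <- !weeks$missing
  if (!any(ok)) stop("no non-missing weeks", call. = FALSE)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  c(starts[best], ends[best])
}

#' Run the full arrival-detection procedure on a weekly series
#'
#' The four-step chain: pick (or accept) an AR order from the PACF, fit the
#' AR model by conditional least squares on the longest contiguous block of
#' non-missing weeks, check residual independence, and run the two-sided
#' CUSUM on the standardised residuals, mapping violations back to calendar
#' weeks.
#'
#' @param weeks a `weekly_series` (or a tweet-record `data.frame` of hits
#'   together with `period`, in which case [weekly_counts()] is applied
#'   first).
#' @param period a [coverage_period()], required when `weeks` are raw hits.
#' @param order optional fixed AR order; otherwise [select_order()] decides.
#' @param max_lag order-selection search bound.
#' @param k,h CUSUM parameters, see [cusum()].
#' @return an object of class `arrival_detection`: `weeks`, `order`, `fit`,
#'   `diagnostics`, `chart`, `events` (violations with calendar weeks),
#'   `segment` (fitted week range).
#' @export
detect_arrivals <- function(weeks, period = NULL, order = NULL, max_lag = 8L,
                            k = 0.5, h = 5) {
  if (!inherits(weeks, "weekly_series")) {
    if (is.null(period)) stop("period required when passing raw hits", call. = FALSE)
    weeks <- weekly_counts(weeks, period)
  }
  seg <- longest_segment(weeks)
  x <- weeks$count[seg[1]:seg[2]]
  p <- if (is.null(order)) select_order(x, max_lag) else as.integer(order)
  if (length(x) < 5L * p + 10L) {
    stop("longest contiguous segment too short for the selected AR order", call. = FALSE)
  }
  fit <- fit_ar(x, p)
  diag <- diagnose_fit(fit, max_lag = min(10L, length(fit$residuals) - 1L))
  z <- standardize_residuals(fit)
  chart <- cusum(z, k = k, h = h)
  events <- detect_events(chart, weeks, p = p, segment_start = seg[1])
  structure(list(weeks = weeks, order = p, fit = fit, diagnostics = diag,
                 chart = chart, events = events, segment = seg),
            class = "arrival_detection")
}

#' @export
print.arrival_detection <- function(x, ...) {
  cat(sprintf("Arrival detection: %d weeks (fitted %d..%d), AR order %d\n",
              nrow(x$weeks), x$segment[1], x$segment[2], x$order))
  cat(sprintf("  residuals independent: %s (Ljung-Box p = %.3f)\n",
              x$diagnostics$independent, x$diagnostics$p_value))
  if (nrow(x$events)) {
    cat("  events:\n")
    for (i in seq_len(nrow(x$events))) {
      cat(sprintf("    %s %s\n", x$events$week_start[i], x$events$direction[i]))
    }
  } else cat("  no violations\n")
  invisible(x)
}
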