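# Independent oracles and fixture builders shared across the suite.

# Durbin-Levinson recursion on the sample ACF -- an independent route to the
# partial autocorrelations.
dl_pacf <- function(x, max_lag) {
  r <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1][-1]
  phi <- matrix(0, max_lag, max_lag)
  out <- numeric(max_lag)
  phi[1, 1] <- r[1]
  out[1] <- r[1]
  if (max_lag > 1) {
    for (k in 2:max_lag) {
      num <- r[k] - sum(phi[k - 1, 1:(k - 1)] * r[(k - 1):1])
      den <- 1 - sum(phi[k - 1, 1:(k - 1)] * r[1:(k - 1)])
      phi[k, k] <- num / den
      phi[k, 1:(k - 1)] <- phi[k - 1, 1:(k - 1)] - phi[k, k] * phi[k - 1, (k - 1):1]
      out[k] <- phi[k, k]
    }
  }
  out
}

# Direct recomputation of the tabular CUSUM recursion.
brute_cusum <- function(z, k, h) {
  cp <- numeric(length(z)); cm <- numeric(length(z))
  for (t in seq_along(z)) {
    prev_p <- if (t == 1) 0 else cp[t - 1]
    prev_m <- if (t == 1) 0 else cm[t - 1]
    cp[t] <- max(0, prev_p + z[t] - k)
    cm[t] <- min(0, prev_m + z[t] + k)
  }
  list(c_plus = cp, c_minus = cm,
       upper = which(cp > h), lower = which(cm < -h))
}

# Ljung-Box statistic from its defining formula.
brute_ljung_box <- function(x, max_lag) {
  n <- length(x)
  r <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1][-1]
  n * (n + 2) * sum(r^2 / (n - seq_len(max_lag)))
}

# Normal-equations solve for conditional least squares AR.
brute_ar_cls <- function(x, p) {
  n <- length(x)
  y <- x[(p + 1):n]
  X <- cbind(1, vapply(seq_len(p), function(i) x[(p + 1 - i):(n - i)], numeric(n - p)))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], coefficients = beta[-1],
       residuals = as.numeric(y - X %*% beta))
}

# Random tweet records uniform over a window.
make_random_tweets <- function(n, start, end, texts = "hello world", seed = 1) {
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    ts <- start + stats::runif(n, 0, as.numeric(difftime(end, start, units = "secs")))
    tweet_records(id = sprintf("r%05d", seq_len(n)), timestamp = ts,
                  text = rep_len(texts, n))
  })
}

test_period <- function() coverage_period("2013-07-01", "2015-05-31")
test_arrivals <- function() as.Date(c("2013-09-07", "2014-09-12"))
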