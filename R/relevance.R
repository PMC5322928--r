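#' Signal-to-noise ratio of a query
#'
#' The SNR of a query is the fraction of its hits that were manually judged
#' relevant to the target species: `n_relevant / n_hits`. It is reported both
#' as an exact fraction and as an integer percent, rounded half away from
#' zero (88/98 prints as 90%). A query with zero hits has no defined SNR.
#'
#' @param n_relevant number of relevant hits (`0 <= n_relevant <= n_hits`).
#' @param n_hits total number of hits (`>= 1`).
#' @param approximate flag the summary as coming from a labelled subsample.
#' @return an object of class `relevance_summary` with fields `n_hits`,
#'   `n_relevant`, `snr`, `snr_percent`, `approximate`.
#' @examples
#' compute_snr(88, 98)   # 90%
#' @export
compute_snr <- function(n_relevant, n_hits, approximate = FALSE) {
  n_relevant <- as.integer(n_relevant); n_hits <- as.integer(n_hits)
  if (is.na(n_hits) || n_hits < 1L) {
    stop("SNR undefined: query has no hits", call. = FALSE)
  }
  if (is.na(n_relevant) || n_relevant < 0L || n_relevant > n_hits) {
    stop("need 0 <= n_relevant <= n_hits", call. = FALSE)
  }
  snr <- n_relevant / n_hits
  structure(list(n_hits = n_hits, n_relevant = n_relevant, snr = snr,
                 snr_percent = as.integer(round_half_up(100 * snr)),
                 approximate = isTRUE(approximate)),
            class = "relevance_summary")
}

#' @export
print.relevance_summary <- function(x, ...) {
  cat(sprintf("SNR: %d/%d = %d%%%s\n", x$n_relevant, x$n_hits, x$snr_percent,
              if (x$approximate) " (approximate, from subsample)" else ""))
  invisible(x)
}

month_stratum <- function(timestamps) format(timestamps, "%Y-%m", tz = "UTC")

#' Month-stratified subsample of query hits
#'
#' When a query returns too many hits to label manually, a subsample is drawn
#' stratified by calendar month, so the subsample respects the monthly volume
#' profile. Within each month with `n_m` hits the sample size is
#' `round(fraction * n_m)` (half away from zero), with a minimum of 1 for any
#' non-empty month, drawn by simple random sampling without replacement.
#' Reproducible from `seed` (Mersenne-Twister; recorded in the attributes).
#'
#' @param hits a non-empty tweet-record `data.frame`.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return the sampled rows (original order), with attributes
#'   `strata_sizes` (hits per month), `sample_sizes`, `fraction`, `seed`,
#'   `rng_kind`.
#' @export
stratified_sample <- function(hits, fraction, seed = 1L) {
  validate_tweets(hits)
  if (!nrow(hits)) stop("hits must be non-empty", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  strat <- month_stratum(hits$timestamp)
  months <- sort(unique(strat))
  n_m <- vapply(months, function(m) sum(strat == m), integer(1))
  s_m <- pmin(n_m, pmax(1L, as.integer(round_half_up(fraction * n_m))))
  idx <- integer()
  with_seed(seed, {
    for (j in seq_along(months)) {
      pool <- which(strat == months[j])
      idx <- c(idx, if (length(pool) == 1L) pool else sample(pool, s_m[j]))
    }
  })
  idx <- sort(idx)
  out <- hits[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "strata_sizes") <- stats::setNames(n_m, months)
  attr(out, "sample_sizes") <- stats::setNames(s_m, months)
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- as.integer(seed)
  attr(out, "rng_kind") <- "Mersenne-Twister"
  out
}

#' Approximate SNR from a labelled subsample
#'
#' The default estimator is the plain ratio of relevant to sampled records.
#' With `weighted = TRUE` a stratum-weighted estimator
#' \eqn{\sum_m (n_m/N)(r_m/s_m)} is used instead (it coincides with the
#' plain ratio under exactly proportional allocation).
#'
#' @param subsample labelled records, typically from [stratified_sample()]
#'   (every record must carry a relevance label).
#' @param strata_sizes named vector of total hits per month stratum; taken
#'   from the subsample attributes when absent. Required for `weighted`.
#' @param weighted use the stratum-weighted estimator.
#' @return a `relevance_summary` with `approximate = TRUE`.
#' @export
estimate_snr <- function(subsample, strata_sizes = NULL, weighted = FALSE) {
  validate_tweets(subsample)
  unlab <- is.na(subsample$relevance)
  if (any(unlab)) {
    stop("unlabelled records in subsample: ",
         paste(subsample$id[unlab], collapse = ", "), call. = FALSE)
  }
  rel <- subsample$relevance == "relevant"
  if (!weighted) {
    out <- compute_snr(sum(rel), nrow(subsample), approximate = TRUE)
    return(out)
  }
  strata_sizes <- strata_sizes %||% attr(subsample, "strata_sizes")
  if (is.null(strata_sizes)) {
    stop("weighted estimation needs strata_sizes (hits per month)", call. = FALSE)
  }
  strat <- month_stratum(subsample$timestamp)
  if (!all(strat %in% names(strata_sizes))) {
    stop("subsample months missing from strata_sizes", call. = FALSE)
  }
  N <- sum(strata_sizes)
  snr <- 0
  for (m in unique(strat)) {
    in_m <- strat == m
    snr <- snr + (strata_sizes[[m]] / N) * mean(rel[in_m])
  }
  structure(list(n_hits = as.integer(N), n_relevant = as.integer(sum(rel)),
                 snr = unname(snr),
                 snr_percent = as.integer(round_half_up(100 * snr)),
                 approximate = TRUE),
            class = "relevance_summary")
}

#' Verifiability accounting for relevant tweets
#'
#' A relevant tweet is verifiable when its claim can be checked (typically an
#' attached photo or video), in which case it is a true or false positive;
#' otherwise it is unverifiable. The three categories partition the relevant
#' tweets.
#'
#' @param records tweet records, all labelled `relevant` with a
#'   verifiability label set.
#' @return a list of class `verifiability_summary` with counts
#'   `n_relevant`, `n_unverifiable`, `n_verifiable_true_positive`,
#'   `n_verifiable_false_positive`.
#' @export
verifiability_summary <- function(records) {
  validate_tweets(records)
  if (nrow(records)) {
    if (any(is.na(records$relevance) | records$relevance != "relevant")) {
      stop("all records must be labelled relevant", call. = FALSE)
    }
    if (any(is.na(records$verifiability))) {
      stop("missing verifiability labels: ",
           paste(records$id[is.na(records$verifiability)], collapse = ", "),
           call. = FALSE)
    }
  }
  out <- structure(list(
    n_relevant = nrow(records),
    n_unverifiable = sum(records$verifiability == "unverifiable"),
    n_verifiable_true_positive = sum(records$verifiability == "verifiable_true_positive"),
    n_verifiable_false_positive = sum(records$verifiability == "verifiable_false_positive")
  ), class = "verifiability_summary")
  stopifnot(out$n_unverifiable + out$n_verifiable_true_positive +
              out$n_verifiable_false_positive == out$n_relevant)
  out
}

#' @export
print.verifiability_summary <- function(x, ...) {
  cat(sprintf("Relevant: %d (unverifiable %d, verified true %d, verified false %d)\n",
              x$n_relevant, x$n_unverifiable, x$n_verifiable_true_positive,
              x$n_verifiable_false_positive))
  invisible(x)
}
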