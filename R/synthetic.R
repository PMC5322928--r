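# Synthetic tweet streams and ground truth with the statistical structure
# the analysis assumes: an autocorrelated, overdispersed background of
# irrelevant chatter; an arrival-only pulse of relevant posts (sharp onset,
# exponential decay -- the stream captures the arrival, not the residence);
# optional out-of-season confounder bursts sharing query vocabulary; and
# survey/monthly ground-truth series tied to a latent occupancy curve.

.default_vocab_relevant <- c("bogong", "moth", "swarm", "invasion", "plague",
                             "season", "arrived", "tonight", "lights", "everywhere")
.default_vocab_decoy <- c("game", "football", "traffic", "coffee", "weather",
                          "movie", "concert", "election", "rain", "weekend",
                          "restaurant", "music", "holiday", "market", "phone")

#' Configuration for a synthetic tweet stream
#'
#' The generator superimposes three Poisson processes on a daily grid:
#' \describe{
#'   \item{background}{irrelevant chatter at `baseline_rate` posts/day,
#'     modulated by a stationary AR(1) log-rate (`noise_phi`, `noise_sd`) so
#'     daily counts are overdispersed and autocorrelated, as real chatter
#'     volumes are. A calibrated fraction of background posts contains
#'     `collision_tokens` and therefore hits the target query.}
#'   \item{pulse}{relevant posts around each arrival date: linear onset over
#'     `pulse_rise_days` to `pulse_peak` posts/day, then exponential decay
#'     with half-life `pulse_half_life` days. Every pulse post contains
#'     `signal_tokens`.}
#'   \item{confounders}{optional bursts (`start`, `duration_days`, `rate`)
#'     of irrelevant posts that nevertheless contain the query tokens --
#'     the out-of-season false-peak phenomenon.}
#' }
#' The background collision probability is solved internally so that the
#' expected fraction of query hits that are relevant equals `target_snr`.
#'
#' @param period a [coverage_period()].
#' @param arrival_dates one date per season at which the species arrives.
#' @param baseline_rate background posts/day (Poisson mean).
#' @param noise_phi,noise_sd AR(1) coefficient and stationary sd of the
#'   background log-rate day effects.
#' @param pulse_peak,pulse_rise_days,pulse_half_life pulse shape (posts/day,
#'   days, days).
#' @param confounders list of lists with fields `start`, `duration_days`,
#'   `rate`, and optionally `tokens` (defaults to `collision_tokens`).
#' @param target_snr intended fraction of query hits that are relevant,
#'   in (0, 1].
#' @param collision_prob optional fixed probability that a background post
#'   contains `collision_tokens`; when supplied it overrides the
#'   `target_snr` calibration (useful for holding the noise level fixed
#'   while varying the pulse).
#' @param signal_tokens tokens every relevant post contains (they satisfy
#'   the target query).
#' @param collision_tokens tokens a colliding background post contains.
#' @param vocab_relevant,vocab_decoy extra vocabulary for text assembly.
#' @param words_per_post mean post length in words.
#' @param seed default seed used by [generate_stream()].
#' @return an object of class `stream_config`.
#' @export
stream_config <- function(period,
                          arrival_dates,
                          baseline_rate = 20,
                          noise_phi = 0.8,
                          noise_sd = 0.5,
                          pulse_peak = 8,
                          pulse_rise_days = 2,
                          pulse_half_life = 7,
                          confounders = list(),
                          target_snr = 0.9,
                          collision_prob = NULL,
                          signal_tokens = c("bogong", "moth"),
                          collision_tokens = signal_tokens,
                          vocab_relevant = .default_vocab_relevant,
                          vocab_decoy = .default_vocab_decoy,
                          words_per_post = 8L,
                          seed = 1L) {
  stopifnot(inherits(period, "coverage_period"))
  arrival_dates <- as.Date(arrival_dates)
  if (!length(arrival_dates) || any(is.na(arrival_dates))) {
    stop("need at least one arrival date", call. = FALSE)
  }
  if (any(arrival_dates < period$start | arrival_dates >= period$end)) {
    stop("arrival dates must lie inside the coverage period", call. = FALSE)
  }
  stopifnot(baseline_rate >= 0, pulse_peak >= 0, pulse_rise_days >= 1,
            pulse_half_life > 0, abs(noise_phi) < 1, noise_sd >= 0)
  if (!(target_snr > 0 && target_snr <= 1)) {
    stop("target_snr must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(collision_prob)) {
    stopifnot(collision_prob >= 0, collision_prob <= 1)
  }
  confounders <- lapply(confounders, function(cf) {
    stopifnot(!is.null(cf$start), !is.null(cf$duration_days), !is.null(cf$rate))
    cf$start <- as.Date(cf$start)
    cf$tokens <- cf$tokens %||% collision_tokens
    cf
  })
  structure(list(period = period, arrival_dates = sort(arrival_dates),
                 baseline_rate = baseline_rate, noise_phi = noise_phi,
                 noise_sd = noise_sd, pulse_peak = pulse_peak,
                 pulse_rise_days = pulse_rise_days,
                 pulse_half_life = pulse_half_life,
                 confounders = confounders, target_snr = target_snr,
                 collision_prob = collision_prob,
                 signal_tokens = tolower(signal_tokens),
                 collision_tokens = tolower(collision_tokens),
                 vocab_relevant = tolower(vocab_relevant),
                 vocab_decoy = tolower(vocab_decoy),
                 words_per_post = as.integer(words_per_post),
                 seed = as.integer(seed)),
            class = "stream_config")
}

pulse_rate_per_day <- function(days, arrival, config) {
  dt <- as.numeric(days - arrival)
  rate <- numeric(length(days))
  rising <- dt >= 0 & dt < config$pulse_rise_days
  rate[rising] <- config$pulse_peak * (dt[rising] + 1) / config$pulse_rise_days
  decaying <- dt >= config$pulse_rise_days
  rate[decaying] <- config$pulse_peak *
    2^(-(dt[decaying] - config$pulse_rise_days + 1) / config$pulse_half_life)
  rate
}

# Expected daily hit-rate bookkeeping used to calibrate the background
# collision probability against target_snr.
stream_expectations <- function(config) {
  days <- seq(config$period$start, config$period$end - 1L, by = "day")
  pulse <- rowSums(vapply(config$arrival_dates,
                          function(a) pulse_rate_per_day(days, a, config),
                          numeric(length(days))))
  conf <- numeric(length(days))
  for (cf in config$confounders) {
    hitdays <- days >= cf$start & days < cf$start + cf$duration_days
    conf[hitdays] <- conf[hitdays] + cf$rate
  }
  e_rel <- sum(pulse)
  e_conf <- sum(conf)
  e_bg <- config$baseline_rate * length(days)
  if (!is.null(config$collision_prob)) {
    q <- config$collision_prob
  } else {
    noise_needed <- e_rel * (1 - config$target_snr) / config$target_snr
    q <- if (e_bg > 0) max(0, noise_needed - e_conf) / e_bg else 0
    if (q > 1) {
      stop("baseline_rate too low to reach target_snr; raise it or the SNR",
           call. = FALSE)
    }
  }
  list(days = days, pulse_rate = pulse, confounder_rate = conf,
       expected_relevant = e_rel, expected_confounder_hits = e_conf,
       collision_prob = q)
}

make_texts <- function(n, always_tokens, vocab, filler, words_per_post) {
  if (!n) return(character())
  extra <- pmax(1L, stats::rpois(n, max(1, words_per_post - length(always_tokens))))
  vocab_all <- c(vocab, filler)
  vapply(seq_len(n), function(i) {
    words <- c(always_tokens, sample(vocab_all, extra[i], replace = TRUE))
    paste(sample(words), collapse = " ")
  }, character(1))
}

#' Generate a synthetic tweet stream
#'
#' Draws the three processes of a [stream_config()] on a daily grid,
#' assembles bag-of-words texts from the process vocabularies, drops posts
#' falling into coverage gaps, and returns the records with latent
#' relevance labels (`relevant` = the post came from the pulse process).
#' Deterministic given `seed`.
#'
#' @param config a `stream_config`.
#' @param seed integer seed (defaults to `config$seed`).
#' @return a tweet-record `data.frame` with extra columns `process`
#'   (`background` / `pulse` / `confounder`), and attributes `bookkeeping`
#'   (per-process draws, gap-dropped counts) and `collision_prob`.
#' @export
generate_stream <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "stream_config"))
  exp_info <- stream_expectations(config)
  days <- exp_info$days
  nd <- length(days)
  filler <- utils::head(default_stopwords(), 60)
  with_seed(seed, {
    # background day effects: stationary AR(1) on the log scale
    innov_sd <- config$noise_sd * sqrt(1 - config$noise_phi^2)
    u <- as.numeric(stats::filter(stats::rnorm(nd, 0, innov_sd),
                                  config$noise_phi, method = "recursive",
                                  init = stats::rnorm(1, 0, config$noise_sd)))
    lambda_bg <- config$baseline_rate * exp(u - config$noise_sd^2 / 2)
    n_bg <- stats::rpois(nd, lambda_bg)
    n_pulse <- stats::rpois(nd, exp_info$pulse_rate)

    bg_days <- rep(days, n_bg); pu_days <- rep(days, n_pulse)
    collide <- stats::runif(length(bg_days)) < exp_info$collision_prob

    bg_texts <- character(length(bg_days))
    bg_texts[!collide] <- make_texts(sum(!collide), character(),
                                     config$vocab_decoy, filler,
                                     config$words_per_post)
    bg_texts[collide] <- make_texts(sum(collide), config$collision_tokens,
                                    config$vocab_decoy, filler,
                                    config$words_per_post)
    pu_texts <- make_texts(length(pu_days), config$signal_tokens,
                           config$vocab_relevant, filler, config$words_per_post)
    cf_days <- days[0]; cf_texts <- character(0)
    for (cf in config$confounders) {
      w <- days >= cf$start & days < cf$start + cf$duration_days
      d <- rep(days[w], stats::rpois(sum(w), cf$rate))
      if (length(d)) {
        cf_days <- c(cf_days, d)
        cf_texts <- c(cf_texts, make_texts(length(d), cf$tokens,
                                           config$vocab_decoy, filler,
                                           config$words_per_post))
      }
    }

    all_days <- c(bg_days, pu_days, cf_days)
    all_texts <- c(bg_texts, pu_texts, cf_texts)
    process <- rep(c("background", "pulse", "confounder"),
                   c(length(bg_days), length(pu_days), length(cf_days)))
    secs <- stats::runif(length(all_days), 0, 86399)
    ts <- as.POSIXct(paste(all_days, "00:00:00"), tz = "UTC") + secs

    gapped <- in_gap(all_days, config$period)
    drawn <- c(background = length(bg_days), pulse = length(pu_days),
               confounder = length(cf_days))
    kept_process <- process[!gapped]

    df <- data.frame(
      id = sprintf("syn%07d", seq_len(sum(!gapped))),
      timestamp = ts[!gapped],
      text = all_texts[!gapped],
      lat = NA_real_, lon = NA_real_, user_location = NA_character_,
      relevance = ifelse(kept_process == "pulse", "relevant", "irrelevant"),
      verifiability = NA_character_,
      process = kept_process,
      stringsAsFactors = FALSE
    )
    df <- df[order(df$timestamp), , drop = FALSE]
    df$id <- sprintf("syn%07d", seq_len(nrow(df)))   # ids follow time order
    rownames(df) <- NULL
    attr(df, "bookkeeping") <- list(
      drawn = drawn,
      dropped_in_gaps = sum(gapped),
      kept = nrow(df)
    )
    attr(df, "collision_prob") <- exp_info$collision_prob
    attr(df, "expected_relevant") <- exp_info$expected_relevant
    attr(df, "seed") <- as.integer(seed)
    attr(df, "rng_kind") <- "Mersenne-Twister"
    df
  })
}

#' Configuration for synthetic ground truth
#'
#' @param survey_dates planned survey dates.
#' @param arrival_date true arrival; occupancy is zero before it.
#' @param departure_date start of the post-season decline.
#' @param rise_days length of the logistic rise to full occupancy.
#' @param decline_days length of the decline after departure.
#' @param mean_patches expected number of patches per survey at full
#'   occupancy.
#' @param dim_meanlog,dim_sdlog log-normal parameters of patch dimensions
#'   (cm).
#' @param monthly_peak_month,monthly_concentration shape of the 12-month
#'   sighting profile (a circular bump centred on the peak month).
#' @param years_of_history years of monthly counts to simulate.
#' @param seed default seed.
#' @return an object of class `truth_config`.
#' @export
truth_config <- function(survey_dates, arrival_date, departure_date,
                         rise_days = 14, decline_days = 21,
                         mean_patches = 6, dim_meanlog = 2.3, dim_sdlog = 0.4,
                         monthly_peak_month = 10, monthly_concentration = 2,
                         years_of_history = 10, seed = 1L) {
  survey_dates <- sort(as.Date(survey_dates))
  arrival_date <- as.Date(arrival_date)
  departure_date <- as.Date(departure_date)
  stopifnot(!any(is.na(survey_dates)), !is.na(arrival_date),
            !is.na(departure_date), departure_date > arrival_date,
            rise_days >= 1, decline_days >= 1, mean_patches > 0)
  if (all(survey_dates < arrival_date)) {
    stop("survey schedule ends before the arrival date: no signal to measure",
         call. = FALSE)
  }
  structure(list(survey_dates = survey_dates, arrival_date = arrival_date,
                 departure_date = departure_date, rise_days = rise_days,
                 decline_days = decline_days, mean_patches = mean_patches,
                 dim_meanlog = dim_meanlog, dim_sdlog = dim_sdlog,
                 monthly_peak_month = monthly_peak_month,
                 monthly_concentration = monthly_concentration,
                 years_of_history = years_of_history, seed = as.integer(seed)),
            class = "truth_config")
}

# Occupancy in [0, 1]: zero before arrival, logistic rise, plateau, decline.
occupancy_curve <- function(dates, config) {
  dt <- as.numeric(as.Date(dates) - config$arrival_date)
  occ <- 1 / (1 + exp(-(dt - config$rise_days / 2) / (config$rise_days / 6)))
  occ[dt < 0] <- 0
  dd <- as.numeric(as.Date(dates) - config$departure_date)
  declining <- dd > 0
  occ[declining] <- occ[declining] * pmax(0, 1 - dd[declining] / config$decline_days)
  occ
}

#' Generate synthetic ground truth
#'
#' Survey series: per survey, a Poisson number of patches proportional to the
#' occupancy curve, each with log-normal width/height/depth; summarised with
#' [percent_volume()]. Monthly profile: `years_of_history` years of Poisson
#' monthly counts around a circular seasonal bump, summarised with
#' [monthly_profile()]. Deterministic given `seed`.
#'
#' @param config a [truth_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `survey` (patch-level data frame), `series`
#'   (`ground_truth_series`), `monthly` (`monthly_profile`), `occupancy`,
#'   `true_arrival`.
#' @export
generate_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "truth_config"))
  with_seed(seed, {
    occ <- occupancy_curve(config$survey_dates, config)
    if (all(occ == 0)) stop("occupancy is zero over the whole schedule", call. = FALSE)
    rows <- list()
    for (i in seq_along(config$survey_dates)) {
      n_patch <- stats::rpois(1, config$mean_patches * occ[i])
      if (n_patch == 0) {
        rows[[i]] <- data.frame(survey_date = config$survey_dates[i],
                                site_id = "transect", width_cm = 0,
                                height_cm = 0, depth_cm = 0)
      } else {
        rows[[i]] <- data.frame(
          survey_date = config$survey_dates[i],
          site_id = sprintf("site%02d", sample.int(39, n_patch, replace = TRUE)),
          width_cm = stats::rlnorm(n_patch, config$dim_meanlog, config$dim_sdlog),
          height_cm = stats::rlnorm(n_patch, config$dim_meanlog, config$dim_sdlog),
          depth_cm = stats::rlnorm(n_patch, config$dim_meanlog - 1, config$dim_sdlog)
        )
      }
    }
    survey <- do.call(rbind, rows)
    series <- percent_volume(survey)

    # circular bump over months, peak at monthly_peak_month
    month_dist <- pmin(abs(1:12 - config$monthly_peak_month),
                       12 - abs(1:12 - config$monthly_peak_month))
    intensity <- exp(-(month_dist / config$monthly_concentration)^2 / 2) * 20
    monthly_counts <- data.frame(
      month = rep(1:12, config$years_of_history),
      count = stats::rpois(12 * config$years_of_history,
                           rep(intensity, config$years_of_history))
    )
    monthly <- monthly_profile(monthly_counts)
    list(survey = survey, series = series, monthly = monthly,
         occupancy = occ, true_arrival = config$arrival_date)
  })
}

#' Simulate a stationary AR(p) series
#'
#' Gaussian AR with a burn-in of `10 p` discarded points; the AR polynomial
#' must be stationary (all roots outside the unit circle). Deterministic
#' given `seed`.
#'
#' @param phi AR coefficients (may be empty for white noise).
#' @param n series length.
#' @param sigma innovation standard deviation.
#' @param seed integer seed.
#' @param intercept model intercept `c`; the series mean is
#'   `c / (1 - sum(phi))`.
#' @return numeric vector of length `n`.
#' @export
generate_ar <- function(phi = numeric(), n, sigma = 1, seed = 1L, intercept = 0) {
  phi <- as.numeric(phi)
  p <- length(phi)
  if (p > 0L) {
    roots <- polyroot(c(1, -phi))
    if (any(Mod(roots) <= 1 + 1e-10)) {
      stop("non-stationary AR coefficients", call. = FALSE)
    }
  }
  burn <- 10L * p
  with_seed(seed, {
    e <- stats::rnorm(n + burn, 0, sigma)
    x <- if (p > 0L) {
      as.numeric(stats::filter(e, phi, method = "recursive"))
    } else e
    mu <- if (p > 0L) intercept / (1 - sum(phi)) else intercept
    mu + x[(burn + 1L):(burn + n)]
  })
}

#' Add a level shift from an index onward
#'
#' @param x numeric series.
#' @param t0 1-based index at which the shift starts.
#' @param delta shift size added to every point at index `>= t0`.
#' @export
inject_shift <- function(x, t0, delta) {
  t0 <- as.integer(t0)
  if (t0 < 1L || t0 > length(x)) stop("t0 out of range", call. = FALSE)
  x[t0:length(x)] <- x[t0:length(x)] + delta
  x
}
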