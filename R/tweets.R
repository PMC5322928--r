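TWEET_COLUMNS <- c("id", "timestamp", "text", "lat", "lon",
                   "user_location", "relevance", "verifiability")
RELEVANCE_LEVELS <- c("relevant", "irrelevant")
VERIFIABILITY_LEVELS <- c("verifiable_true_positive",
                          "verifiable_false_positive",
                          "unverifiable")

#' Construct a table of tweet records
#'
#' A tweet record is one post with an opaque id, a UTC timestamp, the post
#' text, and optional geotag, free-text user location, manual relevance label
#' and verifiability label. Records are the unit of everything downstream:
#' query matching, SNR estimation and weekly aggregation.
#'
#' @param id character vector of non-empty, unique identifiers.
#' @param timestamp `POSIXct`/`Date`/ISO 8601 character; stored in UTC.
#' @param text post text.
#' @param lat,lon optional geotag in decimal degrees (`NA` when absent).
#' @param user_location optional free-form profile location string.
#' @param relevance optional label, `"relevant"` or `"irrelevant"`.
#' @param verifiability optional label (`"verifiable_true_positive"`,
#'   `"verifiable_false_positive"` or `"unverifiable"`); may only be set on
#'   records whose `relevance` is set.
#' @return a `data.frame` with columns `id`, `timestamp`, `text`, `lat`,
#'   `lon`, `user_location`, `relevance`, `verifiability`, ordered by
#'   timestamp.
#' @examples
#' tweet_records(id = "a1", timestamp = "2013-09-07T08:00:00Z",
#'               text = "bogong moths are back")
#' @export
tweet_records <- function(id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          text = character(), lat = NA_real_, lon = NA_real_,
                          user_location = NA_character_, relevance = NA_character_,
                          verifiability = NA_character_) {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    timestamp = as_utc(timestamp),
    text = as.character(text),
    lat = rep_len(as.numeric(lat), n),
    lon = rep_len(as.numeric(lon), n),
    user_location = rep_len(as.character(user_location), n),
    relevance = rep_len(as.character(relevance), n),
    verifiability = rep_len(as.character(verifiability), n),
    stringsAsFactors = FALSE
  )
  validate_tweets(df)
  df[order(df$timestamp), , drop = FALSE]
}

validate_tweets <- function(df, where = "records") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(TWEET_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing columns: %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$id) | !nzchar(df$id))) {
    stop(sprintf("%s: empty ids at rows %s", where,
                 paste(which(is.na(df$id) | !nzchar(df$id)), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop(sprintf("%s: duplicate ids: %s", where,
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(is.na(df$timestamp))) {
    stop(sprintf("%s: unparseable timestamps at rows %s", where,
                 paste(which(is.na(df$timestamp)), collapse = ", ")), call. = FALSE)
  }
  bad_rel <- !is.na(df$relevance) & !(df$relevance %in% RELEVANCE_LEVELS)
  if (any(bad_rel)) {
    stop(sprintf("%s: invalid relevance values: %s", where,
                 paste(unique(df$relevance[bad_rel]), collapse = ", ")), call. = FALSE)
  }
  bad_ver <- !is.na(df$verifiability) & !(df$verifiability %in% VERIFIABILITY_LEVELS)
  if (any(bad_ver)) {
    stop(sprintf("%s: invalid verifiability values: %s", where,
                 paste(unique(df$verifiability[bad_ver]), collapse = ", ")), call. = FALSE)
  }
  orphan <- !is.na(df$verifiability) & is.na(df$relevance)
  if (any(orphan)) {
    stop(sprintf("%s: verifiability set without relevance at rows %s", where,
                 paste(which(orphan), collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read tweet records from JSONL or CSV
#'
#' JSONL is the canonical on-disk format: one JSON object per line with keys
#' `id`, `timestamp` (ISO 8601, UTC), `text` and the optional keys `lat`,
#' `lon`, `user_location`, `relevance`, `verifiability`. The CSV format
#' carries the same columns (RFC 4180 quoting). Malformed rows are reported
#' with their line numbers; duplicate ids are an error. Records are returned
#' in ascending timestamp order.
#'
#' @param path file to read.
#' @param format `"jsonl"` or `"csv"`.
#' @return a tweet-record `data.frame` (see [tweet_records()]).
#' @seealso [write_tweets()] for the lossless inverse.
#' @export
read_tweets <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    keep <- nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) return(tweet_records())
    errors <- character()
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) e)
      if (inherits(rec, "error")) {
        errors <- c(errors, sprintf("line %d: invalid JSON (%s)",
                                    lineno[i], conditionMessage(rec)))
        next
      }
      need <- setdiff(c("id", "timestamp", "text"), names(rec))
      if (length(need)) {
        errors <- c(errors, sprintf("line %d: missing field(s) %s",
                                    lineno[i], paste(need, collapse = ", ")))
        next
      }
      ts <- parse_timestamp(rec$timestamp)
      if (is.na(ts)) {
        errors <- c(errors, sprintf("line %d: unparseable timestamp '%s'",
                                    lineno[i], rec$timestamp))
        next
      }
      rows[[i]] <- data.frame(
        id = as.character(rec$id), timestamp = ts, text = as.character(rec$text),
        lat = as.numeric(rec$lat %||% NA_real_),
        lon = as.numeric(rec$lon %||% NA_real_),
        user_location = as.character(rec$user_location %||% NA_character_),
        relevance = as.character(rec$relevance %||% NA_character_),
        verifiability = as.character(rec$verifiability %||% NA_character_),
        stringsAsFactors = FALSE
      )
    }
    if (length(errors)) {
      stop("malformed records:\n", paste(errors, collapse = "\n"), call. = FALSE)
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  } else {
    df <- utils::read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
    missing_cols <- setdiff(c("id", "timestamp", "text"), names(df))
    if (length(missing_cols)) {
      stop("csv missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    for (col in TWEET_COLUMNS) if (!col %in% names(df)) df[[col]] <- NA_character_
    df[df == ""] <- NA
    ts <- parse_timestamp(df$timestamp)
    if (any(is.na(ts))) {
      # +1 for the header line so numbers point at the file, not the frame
      stop("malformed records:\n",
           paste(sprintf("line %d: unparseable timestamp '%s'",
                         which(is.na(ts)) + 1L, df$timestamp[is.na(ts)]),
                 collapse = "\n"), call. = FALSE)
    }
    df$timestamp <- ts
    df$lat <- as.numeric(df$lat)
    df$lon <- as.numeric(df$lon)
    df <- df[TWEET_COLUMNS]
  }
  validate_tweets(df, where = path)
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write tweet records to JSONL or CSV
#'
#' The round trip `read_tweets(write_tweets(x, p), p)` is lossless (geotags
#' keep full precision; absent optional fields stay absent).
#'
#' @inheritParams read_tweets
#' @param records a tweet-record `data.frame`.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  validate_tweets(records)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      rec <- list(id = records$id[i],
                  timestamp = format_timestamp(records$timestamp[i]),
                  text = records$text[i])
      for (col in c("lat", "lon", "user_location", "relevance", "verifiability")) {
        if (!is.na(records[[col]][i])) rec[[col]] <- records[[col]][i]
      }
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    out <- records
    out$timestamp <- format_timestamp(out$timestamp)
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Restrict records to a half-open time window
#'
#' Keeps exactly the records with `start <= timestamp < end`. Half-open
#' windows partition cleanly: `filter_period(x, a, b)` and
#' `filter_period(x, b, c)` together equal `filter_period(x, a, c)`.
#'
#' @param records a tweet-record `data.frame`.
#' @param start,end window bounds (`Date`, `POSIXct` or ISO 8601 character).
#' @export
filter_period <- function(records, start, end) {
  start <- as_utc(start); end <- as_utc(end)
  if (is.na(start) || is.na(end)) stop("unparseable window bound", call. = FALSE)
  if (start > end) stop("start must be <= end", call. = FALSE)
  out <- records[records$timestamp >= start & records$timestamp < end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Declare the coverage period of a captured stream
#'
#' The period over which the stream was captured, with optional gaps where
#' capture was unreliable (the shaded no-capture intervals of a monitoring
#' record). All intervals are half-open `[start, end)` dates.
#'
#' @param start,end `Date` (or coercible); `start < end`.
#' @param gaps list of length-2 date vectors (or a 2-column data frame);
#'   pairwise disjoint, inside `[start, end)`.
#' @return an object of class `coverage_period`.
#' @export
coverage_period <- function(start, end, gaps = list()) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end) {
    stop("coverage period needs start < end", call. = FALSE)
  }
  if (is.data.frame(gaps)) gaps <- lapply(seq_len(nrow(gaps)), function(i) unlist(gaps[i, 1:2]))
  gaps <- lapply(gaps, function(g) {
    g <- as.Date(g)
    if (length(g) != 2L || any(is.na(g)) || g[1] >= g[2]) {
      stop("each gap must be a (start, end) date pair with start < end", call. = FALSE)
    }
    if (g[1] < start || g[2] > end) stop("gap outside coverage period", call. = FALSE)
    g
  })
  if (length(gaps) > 1L) {
    ord <- order(vapply(gaps, function(g) as.numeric(g[1]), numeric(1)))
    gaps <- gaps[ord]
    for (i in seq_len(length(gaps) - 1L)) {
      if (gaps[[i]][2] > gaps[[i + 1L]][1]) stop("gaps must be disjoint", call. = FALSE)
    }
  }
  structure(list(start = start, end = end, gaps = gaps), class = "coverage_period")
}

#' @export
print.coverage_period <- function(x, ...) {
  cat(sprintf("Coverage period: [%s, %s)\n", x$start, x$end))
  if (length(x$gaps)) {
    cat("Gaps:\n")
    for (g in x$gaps) cat(sprintf("  [%s, %s)\n", g[1], g[2]))
  }
  invisible(x)
}

# TRUE for dates that fall inside any coverage gap.
in_gap <- function(dates, period) {
  out <- rep(FALSE, length(dates))
  for (g in period$gaps) out <- out | (dates >= g[1] & dates < g[2])
  out
}
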