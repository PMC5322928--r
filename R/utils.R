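#' @keywords internal
"_PACKAGE"

# Round half away from zero (presentation rounding for integer percents;
# base round() rounds half to even, which would turn 12.5 into 12).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(expr)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(format(x), tz = "UTC"))
  }
  parse_timestamp(as.character(x))
}

# ISO 8601 parser: accepts "2013-09-07T08:00:00Z", with space instead of T,
# fractional seconds, or a bare date. Returns POSIXct (UTC); NA where unparseable.
parse_timestamp <- function(x) {
  x <- sub("Z$", "", sub("T", " ", as.character(x)))
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = "UTC"), tz = "UTC")
  retry <- is.na(out) & !is.na(x)
  if (any(retry)) {
    out[retry] <- as.POSIXct(strptime(x[retry], "%Y-%m-%d", tz = "UTC"), tz = "UTC")
  }
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}
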