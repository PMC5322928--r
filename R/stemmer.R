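# Snowball English ("Porter2") stemmer, implemented from the published
# algorithm definition. Operates on lowercase words; the consonant y is
# marked internally as "Y" so that region and syllable tests see it as a
# non-vowel, and restored on output.

.p2_doubles <- c("bb", "dd", "ff", "gg", "mm", "nn", "pp", "rr", "tt")
.p2_li_valid <- c("c", "d", "e", "g", "h", "k", "m", "n", "r", "t")

.p2_exceptions1 <- c(
  skis = "ski", skies = "sky", dying = "die", lying = "lie", tying = "tie",
  idly = "idl", gently = "gentl", ugly = "ugli", early = "earli",
  only = "onli", singly = "singl",
  sky = "sky", news = "news", howe = "howe", atlas = "atlas",
  cosmos = "cosmos", bias = "bias", andes = "andes"
)
.p2_exceptions2 <- c("inning", "outing", "canning", "herring", "earring",
                     "proceed", "exceed", "succeed")

.p2_is_vowel <- function(ch) ch %in% c("a", "e", "i", "o", "u", "y")

# A "short syllable": a vowel followed by a non-vowel other than w, x or Y,
# preceded by a non-vowel; or, at the start of the word, vowel + non-vowel.
.p2_ends_short_syllable <- function(chars) {
  n <- length(chars)
  if (n == 2L) return(.p2_is_vowel(chars[1]) && !.p2_is_vowel(chars[2]))
  if (n >= 3L) {
    return(!.p2_is_vowel(chars[n - 2L]) && .p2_is_vowel(chars[n - 1L]) &&
             !.p2_is_vowel(chars[n]) && !(chars[n] %in% c("w", "x", "Y")))
  }
  FALSE
}

# R1 = region after the first non-vowel that follows a vowel; R2 the same
# rule applied within R1. Returned as 1-based start positions (n + 1 = null).
.p2_region_start <- function(chars, from) {
  n <- length(chars)
  i <- from
  while (i <= n && !.p2_is_vowel(chars[i])) i <- i + 1L   # find a vowel
  while (i <= n && .p2_is_vowel(chars[i])) i <- i + 1L    # then a non-vowel
  min(i + 1L, n + 1L)
}

.p2_mark_regions <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  r1 <- NULL
  for (pre in c("gener", "commun", "arsen")) {
    if (startsWith(word, pre)) { r1 <- nchar(pre) + 1L; break }
  }
  if (is.null(r1)) r1 <- .p2_region_start(chars, 1L)
  r2 <- .p2_region_start(chars, r1)
  c(r1 = r1, r2 = r2)
}

.p2_has_vowel <- function(chars) any(vapply(chars, .p2_is_vowel, logical(1)))

stem_word_english <- function(word) {
  if (nchar(word) <= 2L) return(word)
  word <- sub("^'", "", word)
  if (word %in% names(.p2_exceptions1)) return(unname(.p2_exceptions1[[word]]))
  if (nchar(word) <= 2L) return(word)

  # prelude: mark consonant y
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (chars[1] == "y") chars[1] <- "Y"
  if (length(chars) >= 2L) {
    for (i in 2:length(chars)) {
      if (chars[i] == "y" && .p2_is_vowel(chars[i - 1L])) chars[i] <- "Y"
    }
  }
  word <- paste(chars, collapse = "")
  reg <- .p2_mark_regions(word)
  r1 <- reg[["r1"]]; r2 <- reg[["r2"]]

  in_r1 <- function(w, suf) (nchar(w) - nchar(suf) + 1L) >= r1
  in_r2 <- function(w, suf) (nchar(w) - nchar(suf) + 1L) >= r2
  chop <- function(w, k) substr(w, 1L, nchar(w) - k)

  # step 0: apostrophe suffixes
  for (suf in c("'s'", "'s", "'")) {
    if (endsWith(word, suf)) { word <- chop(word, nchar(suf)); break }
  }

  # step 1a
  if (endsWith(word, "sses")) {
    word <- paste0(chop(word, 4L), "ss")
  } else if (endsWith(word, "ied") || endsWith(word, "ies")) {
    word <- paste0(chop(word, 3L), if (nchar(word) > 4L) "i" else "ie")
  } else if (endsWith(word, "ss") || endsWith(word, "us")) {
    # leave unchanged
  } else if (endsWith(word, "s")) {
    stem_part <- strsplit(chop(word, 1L), "", fixed = TRUE)[[1]]
    if (length(stem_part) >= 2L && .p2_has_vowel(stem_part[seq_len(length(stem_part) - 1L)])) {
      word <- chop(word, 1L)
    }
  }
  if (word %in% .p2_exceptions2) {
    return(gsub("Y", "y", word, fixed = TRUE))
  }

  # step 1b
  s1b <- c("eedly", "ingly", "edly", "eed", "ing", "ed")
  for (suf in s1b) {
    if (!endsWith(word, suf)) next
    if (suf %in% c("eed", "eedly")) {
      if (in_r1(word, suf)) word <- paste0(chop(word, nchar(suf)), "ee")
    } else {
      stem_part <- strsplit(chop(word, nchar(suf)), "", fixed = TRUE)[[1]]
      if (.p2_has_vowel(stem_part)) {
        word <- chop(word, nchar(suf))
        if (endsWith(word, "at") || endsWith(word, "bl") || endsWith(word, "iz")) {
          word <- paste0(word, "e")
        } else if (substr(word, nchar(word) - 1L, nchar(word)) %in% .p2_doubles) {
          word <- chop(word, 1L)
        } else {
          wc <- strsplit(word, "", fixed = TRUE)[[1]]
          if (r1 > length(wc) && .p2_ends_short_syllable(wc)) word <- paste0(word, "e")
        }
      }
    }
    break
  }

  # step 1c: y -> i after a non-vowel that is not the first letter
  n <- nchar(word)
  last <- substr(word, n, n)
  if (n >= 3L && (last == "y" || last == "Y") &&
      !.p2_is_vowel(substr(word, n - 1L, n - 1L))) {
    word <- paste0(chop(word, 1L), "i")
  }

  # step 2 (longest suffix first; the R1 test applies to the longest match only)
  s2 <- list(
    ization = "ize", ational = "ate", fulness = "ful", ousness = "ous",
    iveness = "ive", tional = "tion", biliti = "ble", lessli = "less",
    entli = "ent", ation = "ate", alism = "al", aliti = "al", ousli = "ous",
    iviti = "ive", fulli = "ful", enci = "ence", anci = "ance", abli = "able",
    izer = "ize", ator = "ate", alli = "al", bli = "ble", ogi = "og", li = ""
  )
  hit <- NULL
  for (suf in names(s2)) if (endsWith(word, suf)) { hit <- suf; break }
  if (!is.null(hit) && in_r1(word, hit)) {
    prev <- substr(word, nchar(word) - nchar(hit), nchar(word) - nchar(hit))
    ok <- if (hit == "ogi") prev == "l" else if (hit == "li") prev %in% .p2_li_valid else TRUE
    if (ok) word <- paste0(chop(word, nchar(hit)), s2[[hit]])
  }

  # step 3
  s3 <- list(ational = "ate", tional = "tion", alize = "al", icate = "ic",
             iciti = "ic", ative = "", ical = "ic", ness = "", ful = "")
  hit <- NULL
  for (suf in names(s3)) if (endsWith(word, suf)) { hit <- suf; break }
  if (!is.null(hit) && in_r1(word, hit)) {
    if (hit != "ative" || in_r2(word, hit)) {
      word <- paste0(chop(word, nchar(hit)), s3[[hit]])
    }
  }

  # step 4 (delete in R2; "ion" only after s or t)
  s4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
          "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic")
  hit <- NULL
  for (suf in s4) if (endsWith(word, suf)) { hit <- suf; break }
  if (!is.null(hit) && in_r2(word, hit)) {
    prev <- substr(word, nchar(word) - nchar(hit), nchar(word) - nchar(hit))
    if (hit != "ion" || prev %in% c("s", "t")) word <- chop(word, nchar(hit))
  }

  # step 5
  n <- nchar(word)
  if (endsWith(word, "e")) {
    if (in_r2(word, "e")) {
      word <- chop(word, 1L)
    } else if (in_r1(word, "e")) {
      wc <- strsplit(chop(word, 1L), "", fixed = TRUE)[[1]]
      if (!.p2_ends_short_syllable(wc)) word <- chop(word, 1L)
    }
  } else if (endsWith(word, "l") && in_r2(word, "l") &&
             endsWith(chop(word, 1L), "l")) {
    word <- chop(word, 1L)
  }

  gsub("Y", "y", word, fixed = TRUE)
}

#' Stem English words (Snowball)
#'
#' The Snowball English stemmer used by the symptomatic-query mining step:
#' common word endings (plural -s/-es, -ed, -ing, and derivational suffixes)
#' are removed so that, for example, `"moths"`, `"plagues"` and `"calling"`
#' count as occurrences of `"moth"`, `"plagu"` and `"call"`.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length.
#' @examples
#' stem_words(c("moths", "plague", "invasion", "calling"))
#' @export
stem_words <- function(words) {
  vapply(as.character(words), stem_word_english, character(1), USE.NAMES = FALSE)
}
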