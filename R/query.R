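QUERY_TYPES <- c("taxonomic", "common_name", "symptomatic")

new_term <- function(tokens, kind = if (length(tokens) > 1L) "phrase" else "word") {
  tokens <- tolower(as.character(tokens))
  stopifnot(length(tokens) >= 1L, all(nzchar(tokens)))
  if (kind == "word") stopifnot(length(tokens) == 1L)
  structure(list(kind = kind, tokens = tokens), class = "query_term")
}

new_clause <- function(terms) {
  stopifnot(length(terms) >= 1L)
  structure(list(terms = terms), class = "query_clause")
}

new_query <- function(type, clauses, source_text = NULL) {
  type <- match.arg(type, QUERY_TYPES)
  stopifnot(length(clauses) >= 1L)
  q <- structure(list(query_type = type, clauses = clauses,
                      source_text = source_text), class = "query")
  if (is.null(q$source_text)) q$source_text <- deparse_query(q)
  q
}

# --- parsing ---------------------------------------------------------------

# Lexer: parentheses, AND/OR keywords, double/curly/single-quoted phrases and
# bare words. Quote characters are normalised first.
lex_query <- function(text) {
  text <- chartr("“”‘’", "\"\"''", text)
  toks <- list(); pos <- 1L; n <- nchar(text)
  push <- function(type, value, at) toks[[length(toks) + 1L]] <<- list(type = type, value = value, at = at)
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("^\\s$", ch)) { pos <- pos + 1L; next }
    if (ch == "(") { push("lparen", "(", pos); pos <- pos + 1L; next }
    if (ch == ")") { push("rparen", ")", pos); pos <- pos + 1L; next }
    if (ch == "\"" || ch == "'") {
      close <- regexpr(ch, substr(text, pos + 1L, n), fixed = TRUE)
      if (close < 0L) stop(sprintf("unbalanced quote at position %d", pos), call. = FALSE)
      phrase <- substr(text, pos + 1L, pos + close - 1L)
      push("phrase", phrase, pos)
      pos <- pos + close + 1L
      next
    }
    m <- regexpr("^[^\\s()\"']+", substr(text, pos, n), perl = TRUE)
    w <- regmatches(substr(text, pos, n), m)
    if (toupper(w) %in% c("AND", "OR")) {
      push(tolower(toupper(w)), toupper(w), pos)
    } else {
      push("word", w, pos)
    }
    pos <- pos + attr(m, "match.length")
  }
  toks
}

#' Parse a boolean keyword query
#'
#' Queries are conjunctions of OR-groups: `AND` combines clauses and has
#' lower precedence than `OR`, which combines words and quoted phrases
#' inside a clause (`"(bogong OR bogan) AND moth"` has two clauses).
#' Matching is case-insensitive, so all tokens are stored lowercase. Curly
#' and single quotes are accepted as phrase delimiters.
#'
#' @param text the query string, e.g. `'"eastern koel"'`.
#' @param type query type tag: `"taxonomic"`, `"common_name"` or
#'   `"symptomatic"`.
#' @return an object of class `query` with fields `query_type`, `clauses`
#'   (each a list of word/phrase terms) and `source_text`.
#' @examples
#' q <- parse_query("(bogong OR bogan) AND moth", type = "common_name")
#' length(q$clauses)
#' @export
parse_query <- function(text, type = "common_name") {
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  toks <- lex_query(text)
  if (!length(toks)) stop("empty query", call. = FALSE)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  advance <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expect_operand <- function(what) {
    t <- peek()
    if (is.null(t)) stop(sprintf("expected %s at end of query", what), call. = FALSE)
    t
  }

  # atom := word | phrase | "(" conj ")"
  # Returns either a list of terms (a pure disjunct) or a full clause list
  # (a parenthesised conjunction, only legal directly under AND).
  parse_atom <- function() {
    t <- expect_operand("a term")
    if (t$type == "word") { advance(); return(list(terms = list(new_term(t$value)))) }
    if (t$type == "phrase") {
      advance()
      toks_ph <- strsplit(trimws(tolower(t$value)), "\\s+")[[1]]
      if (!length(toks_ph) || !all(nzchar(toks_ph))) {
        stop(sprintf("empty phrase at position %d", t$at), call. = FALSE)
      }
      return(list(terms = list(new_term(toks_ph))))
    }
    if (t$type == "lparen") {
      advance()
      inner <- parse_conj()
      t2 <- peek()
      if (is.null(t2) || t2$type != "rparen") {
        stop(sprintf("unbalanced parenthesis opened at position %d", t$at), call. = FALSE)
      }
      advance()
      return(inner)
    }
    stop(sprintf("unexpected '%s' at position %d", t$value, t$at), call. = FALSE)
  }

  # disj := atom ("OR" atom)*
  # A parenthesised sub-expression that reduced to a single clause is folded
  # back into plain terms; a multi-clause conjunction inside OR is rejected
  # (queries are conjunctions of OR-groups).
  parse_disj <- function() {
    unwrap <- function(p) {
      if (!is.null(p$clauses) && length(p$clauses) == 1L) {
        return(list(terms = p$clauses[[1]]$terms))
      }
      p
    }
    acc <- unwrap(parse_atom())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      nxt <- unwrap(parse_atom())
      if (!is.null(acc$clauses) || !is.null(nxt$clauses)) {
        stop("AND inside an OR group is not supported: queries are conjunctions of OR-groups",
             call. = FALSE)
      }
      acc <- list(terms = c(acc$terms, nxt$terms))
    }
    # bare adjacency (two operands with no operator) is an error
    t <- peek()
    if (!is.null(t) && t$type %in% c("word", "phrase", "lparen")) {
      stop(sprintf("missing AND/OR before position %d", t$at), call. = FALSE)
    }
    acc
  }

  # conj := disj ("AND" disj)*
  parse_conj <- function() {
    parts <- list(parse_disj())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      parts <- c(parts, list(parse_disj()))
    }
    clauses <- list()
    for (p in parts) {
      if (!is.null(p$clauses)) clauses <- c(clauses, p$clauses)
      else clauses <- c(clauses, list(new_clause(p$terms)))
    }
    list(clauses = clauses)
  }

  res <- parse_conj()
  t <- peek()
  if (!is.null(t)) {
    stop(sprintf("unexpected '%s' at position %d", t$value, t$at), call. = FALSE)
  }
  new_query(type, res$clauses, source_text = text)
}

#' Serialise a query back to text
#'
#' `parse_query(deparse_query(q))` reproduces `q` (same clauses and terms).
#'
#' @param q a `query`.
#' @return a single query string.
#' @export
deparse_query <- function(q) {
  stopifnot(inherits(q, "query"))
  fmt_term <- function(t) {
    if (t$kind == "phrase") paste0('"', paste(t$tokens, collapse = " "), '"')
    else t$tokens
  }
  fmt_clause <- function(cl) {
    inner <- vapply(cl$terms, fmt_term, character(1))
    if (length(inner) > 1L) paste0("(", paste(inner, collapse = " OR "), ")")
    else inner
  }
  paste(vapply(q$clauses, fmt_clause, character(1)), collapse = " AND ")
}

#' @export
print.query <- function(x, ...) {
  cat(sprintf("<query:%s> %s\n", x$query_type, deparse_query(x)))
  invisible(x)
}

#' @export
format.query <- function(x, ...) deparse_query(x)

#' Read queries from a plain-text query file
#'
#' One query per line, prefixed with a type tag, e.g.
#' `common_name: (bogong OR bogan) AND moth`. Blank lines and `#` comment
#' lines are ignored.
#'
#' @param path file to read.
#' @return a list of `query` objects.
#' @export
read_queries <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    m <- regexec("^([a-z_]+)\\s*:\\s*(.+)$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3L || !(parts[2] %in% QUERY_TYPES)) {
      stop("query lines must look like '<type>: <query>' with type one of ",
           paste(QUERY_TYPES, collapse = ", "), ": ", ln, call. = FALSE)
    }
    parse_query(parts[3], type = parts[2])
  })
}

# --- matching --------------------------------------------------------------

# Match-time tokenizer: URLs removed, "#" and "@" stripped (so a hashtag is
# one token), then maximal runs of Unicode letters, case-folded. No stemming:
# match semantics are exact-token by default.
tokenize_for_match <- function(texts) {
  x <- gsub("(https?://|www\\.)\\S+", " ", as.character(texts), perl = TRUE)
  x <- gsub("[#@]", "", x)
  x <- tolower(x)
  regmatches(x, gregexpr("\\p{L}+", x, perl = TRUE))
}

term_hits_tokens <- function(term, tokens, stem_match = FALSE) {
  tt <- term$tokens
  if (stem_match) {
    tokens <- stem_words(tokens)
    tt <- stem_words(tt)
  }
  if (term$kind == "word" || length(tt) == 1L) return(tt[1] %in% tokens)
  starts <- which(tokens == tt[1])
  k <- length(tt)
  for (s in starts) {
    if (s + k - 1L <= length(tokens) && all(tokens[s:(s + k - 1L)] == tt)) return(TRUE)
  }
  FALSE
}

#' Test whether texts match a query
#'
#' A text matches when every clause has at least one matching term. A word
#' term matches a whole token (so `"moth"` does not match `"moths"`); a
#' phrase matches consecutive tokens. `#` and `@` are stripped before
#' tokenisation, so `"#mothapocalypse"` is a single token and does not match
#' the word `"moth"`. With `stem_match = TRUE` both query terms and text
#' tokens are Snowball-stemmed before comparison.
#'
#' @param query a `query`.
#' @param texts character vector of texts.
#' @param stem_match match on stems instead of exact tokens (default off).
#' @return logical vector, one element per text.
#' @export
match_query <- function(query, texts, stem_match = FALSE) {
  stopifnot(inherits(query, "query"))
  token_lists <- tokenize_for_match(texts)
  vapply(token_lists, function(tokens) {
    for (cl in query$clauses) {
      ok <- FALSE
      for (term in cl$terms) {
        if (term_hits_tokens(term, tokens, stem_match)) { ok <- TRUE; break }
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Run a query over a tweet stream
#'
#' Returns the records whose text matches, in their original order, with the
#' hit count attached as attribute `n_hits`.
#'
#' @param query a `query`.
#' @param records a tweet-record `data.frame`.
#' @param period optional [coverage_period()]; when given, records must fall
#'   inside it.
#' @param stem_match see [match_query()].
#' @export
run_query <- function(query, records, period = NULL, stem_match = FALSE) {
  validate_tweets(records)
  if (!is.null(period)) {
    d <- as.Date(records$timestamp, tz = "UTC")
    if (any(d < period$start | d >= period$end)) {
      stop("records fall outside the declared coverage period", call. = FALSE)
    }
  }
  hit <- if (nrow(records)) match_query(query, records$text, stem_match) else logical()
  out <- records[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_hits") <- nrow(out)
  attr(out, "query") <- deparse_query(query)
  out
}

# --- preprocessing and term mining ----------------------------------------

#' Text preprocessing configuration
#'
#' Controls the mining-side normalisation pipeline, applied in this fixed
#' order: lowercase, remove numbers, remove punctuation (URLs are dropped
#' first; `#` and `@` count as punctuation), tokenize on whitespace, drop
#' stopwords, stem. The stopword list is a fixed English list shipped with
#' the package so results are reproducible across installations.
#'
#' @param lowercase,strip_numbers,strip_punctuation,stem step switches.
#' @param stopword_list character vector of lowercase stopwords.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(lowercase = TRUE, strip_numbers = TRUE,
                              strip_punctuation = TRUE,
                              stopword_list = default_stopwords(),
                              stem = TRUE) {
  stopifnot(all(stopword_list == tolower(stopword_list)))
  structure(list(lowercase = lowercase, strip_numbers = strip_numbers,
                 strip_punctuation = strip_punctuation,
                 stopword_list = stopword_list, stem = stem),
            class = "preprocess_config")
}

#' The packaged English stopword list
#'
#' @return character vector of lowercase stopwords (Snowball English list).
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_english.txt", package = "arrivalwatch")
  if (!nzchar(path)) stop("stopword list not found in installed package", call. = FALSE)
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

#' Preprocess texts into token lists
#'
#' @param texts character vector.
#' @param config a [preprocess_config()].
#' @return a list of character vectors (one per text); tokens reduced to
#'   lowercase stems with numbers, punctuation and stopwords removed.
#' @examples
#' preprocess_text("Moths!! 100s of them")
#' @export
preprocess_text <- function(texts, config = preprocess_config()) {
  x <- gsub("(https?://|www\\.)\\S+", " ", as.character(texts), perl = TRUE)
  if (config$lowercase) x <- tolower(x)
  if (config$strip_numbers) x <- gsub("[0-9]+", "", x)
  if (config$strip_punctuation) x <- gsub("[^\\p{L}\\s]+", "", x, perl = TRUE)
  tokens <- strsplit(trimws(x), "\\s+")
  lapply(tokens, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[!(tk %in% config$stopword_list)]
    if (config$stem && length(tk)) tk <- stem_words(tk)
    tk
  })
}

#' Count term occurrences over a corpus
#'
#' Sums token occurrences over all texts after [preprocess_text()].
#'
#' @inheritParams preprocess_text
#' @return a named integer vector (class `term_table`), sorted by count
#'   (decreasing) then term.
#' @export
term_frequencies <- function(texts, config = preprocess_config()) {
  tokens <- unlist(preprocess_text(texts, config), use.names = FALSE)
  if (!length(tokens)) {
    return(structure(integer(), names = character(), class = "term_table"))
  }
  tab <- table(tokens)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts <- counts[order(-counts, names(counts))]
  structure(counts, class = "term_table")
}

#' @export
print.term_table <- function(x, n = 20L, ...) {
  cat(sprintf("<term_table> %d terms\n", length(x)))
  print(utils::head(unclass(x), n))
  invisible(x)
}

#' Frequent terms above an occurrence threshold
#'
#' Terms that appear at least `min_count` times in the corpus, the rule used
#' to harvest candidate symptomatic-query vocabulary from common-name hits.
#' Ties are broken by descending count, then lexicographically.
#'
#' @param table a `term_table` from [term_frequencies()].
#' @param min_count minimum occurrence count (default 5).
#' @return character vector of terms.
#' @export
frequent_terms <- function(table, min_count = 5L) {
  stopifnot(min_count >= 1L)
  counts <- unclass(table)
  keep <- counts >= min_count
  names(counts)[keep][order(-counts[keep], names(counts)[keep])]
}

#' Build a symptomatic query from anchor and descriptor groups
#'
#' The symptomatic template is an anchor clause (the species stand-in, e.g.
#' `moth` or `bird OR cuckoo`) ANDed with one OR-clause per descriptor
#' group. Elements containing spaces become phrase terms.
#'
#' @param anchor_terms character vector for the anchor clause (ORed).
#' @param groups list of non-empty character vectors, one clause each.
#' @return a `query` of type `"symptomatic"`.
#' @examples
#' build_symptomatic_query("moth",
#'   list(c("first", "invasion", "plague", "season", "today")))
#' @export
build_symptomatic_query <- function(anchor_terms, groups) {
  stopifnot(length(anchor_terms) >= 1L)
  if (!length(groups) || any(!vapply(groups, length, integer(1)))) {
    stop("each descriptor group must be non-empty", call. = FALSE)
  }
  mk_clause <- function(words) {
    new_clause(lapply(words, function(w) {
      tk <- strsplit(trimws(tolower(w)), "\\s+")[[1]]
      new_term(tk)
    }))
  }
  clauses <- c(list(mk_clause(anchor_terms)), lapply(groups, mk_clause))
  new_query("symptomatic", clauses)
}
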