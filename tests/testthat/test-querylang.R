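test_that("the three query templates parse into the expected clause structure", {
  q1 <- parse_query("(bogong OR bogan) AND moth", type = "common_name")
  expect_length(q1$clauses, 2L)
  expect_equal(vapply(q1$clauses[[1]]$terms, function(t) t$tokens, character(1)),
               c("bogong", "bogan"))
  expect_equal(q1$clauses[[2]]$terms[[1]]$tokens, "moth")

  q2 <- parse_query("“common koel”", type = "common_name")
  expect_length(q2$clauses, 1L)
  expect_equal(q2$clauses[[1]]$terms[[1]]$kind, "phrase")
  expect_equal(q2$clauses[[1]]$terms[[1]]$tokens, c("common", "koel"))

  q3 <- parse_query("moth AND (first OR invasion OR plague OR season OR today)")
  expect_length(q3$clauses, 2L)
  expect_equal(vapply(q3$clauses[[2]]$terms, function(t) t$tokens, character(1)),
               c("first", "invasion", "plague", "season", "today"))
})

test_that("parse errors carry positions; malformed queries are rejected", {
  expect_error(parse_query("(moth AND bird"), "unbalanced parenthesis")
  expect_error(parse_query("\"eastern koel"), "unbalanced quote")
  expect_error(parse_query("moth bird"), "missing AND/OR")
  expect_error(parse_query("moth AND"), "expected")
  expect_error(parse_query("(moth AND bird) OR koel"), "conjunctions of OR-groups")
  expect_error(parse_query("   "), "nzchar")
})

test_that("matching is exact-token with phrase adjacency and hashtag stripping", {
  q <- parse_query("(bogong OR bogan) AND moth")
  expect_false(match_query(q, "Bogan moths are back"))   # moths != moth
  expect_true(match_query(q, "bogan moth season again"))
  expect_true(match_query(q, "BOGONG MOTH!"))            # case-insensitive

  ph <- parse_query("\"eastern koel\"")
  expect_true(match_query(ph, "the eastern koel called all night"))
  expect_false(match_query(ph, "koel, eastern variety"))

  expect_false(match_query(parse_query("moth"), "#mothapocalypse is on"))
  expect_true(match_query(parse_query("mothapocalypse"), "#mothapocalypse is on"))
  # URLs are dropped before tokenisation
  expect_false(match_query(parse_query("moth"), "see http://moth.example.com/moth"))
  # opt-in stemmed matching bridges moth/moths
  expect_true(match_query(q, "Bogan moths are back", stem_match = TRUE))
})

test_that("run_query equals a per-record scan and respects OR monotonicity", {
  set.seed(42)
  vocab <- c("bogong", "moth", "bogan", "bird", "koel", "game", "rain", "coffee")
  texts <- vapply(1:1000, function(i) {
    paste(sample(vocab, sample(2:6, 1), replace = TRUE), collapse = " ")
  }, character(1))
  recs <- make_random_tweets(1000, "2013-07-01", "2014-07-01", seed = 5)
  recs$text <- texts
  q <- parse_query("(bogong OR bogan) AND moth")
  hits <- run_query(q, recs)
  brute <- vapply(seq_len(nrow(recs)),
                  function(i) match_query(q, recs$text[i]), logical(1))
  expect_equal(hits$id, recs$id[brute])
  expect_equal(attr(hits, "n_hits"), sum(brute))

  # widening a clause never shrinks the hit set
  q_wide <- parse_query("(bogong OR bogan OR bird) AND moth")
  expect_true(all(hits$id %in% run_query(q_wide, recs)$id))
  # adding a clause never grows it
  q_narrow <- parse_query("(bogong OR bogan) AND moth AND rain")
  expect_true(all(run_query(q_narrow, recs)$id %in% hits$id))
  # a query matching nothing
  expect_equal(nrow(run_query(parse_query("platypus"), recs)), 0L)
})

test_that("preprocessing applies the documented steps in order", {
  expect_equal(preprocess_text("Moths!! 100s of them")[[1]], "moth")
  expect_equal(preprocess_text("")[[1]], character(0))
  expect_equal(preprocess_text("The THE the")[[1]], character(0))
  # numbers and urls vanish, hashtags lose their marker
  expect_equal(preprocess_text("3 moths at http://x.co/y #moths")[[1]],
               c("moth", "moth"))
  cfg <- preprocess_config(stem = FALSE)
  expect_equal(preprocess_text("Moths!! 100s of them", cfg)[[1]], "moths")
})

test_that("preprocessing is idempotent on its own output (stable stems)", {
  set.seed(7)
  vocab <- c("moth", "moths", "plague", "plagues", "invasion", "season",
             "calling", "bird", "birds", "morning", "sighting", "arrival",
             "swarm", "koel", "cuckoo", "annoying", "first", "today", "report")
  words <- sample(vocab, 1000, replace = TRUE)
  out1 <- preprocess_text(paste(words, collapse = " "))[[1]]
  stable <- stem_words(out1) == out1 & !(out1 %in% default_stopwords())
  expect_gt(mean(stable), 0.9)   # most stems of this vocabulary are stable
  out2 <- preprocess_text(paste(out1[stable], collapse = " "))[[1]]
  expect_equal(out2, out1[stable])
})

test_that("term frequencies equal a brute-force tally", {
  texts <- c("plague of moths", "plague again", "a plague", "plague!", "plague")
  tab <- term_frequencies(texts)
  expect_equal(unname(unclass(tab)["plagu"]), 5L)
  expect_equal(length(term_frequencies(character())), 0L)
  # tally oracle
  brute <- table(unlist(preprocess_text(texts)))
  for (term in names(brute)) {
    expect_equal(unclass(tab)[[term]], as.integer(brute[[term]]))
  }
})

test_that("frequent_terms applies the at-least-5 threshold with stable ties", {
  tab <- structure(c(plagu = 7L, moth = 5L, season = 5L, bird = 4L, rain = 1L),
                   class = "term_table")
  expect_equal(frequent_terms(tab), c("plagu", "moth", "season"))
  expect_equal(frequent_terms(tab, min_count = 1L),
               c("plagu", "moth", "season", "bird", "rain"))
  # seeded high-frequency vocabulary is recovered from a synthetic corpus
  set.seed(3)
  seeded <- c("koel", "call", "morning", "annoy")
  corpus <- vapply(1:50, function(i) {
    paste(c(sample(seeded, 2), sample(c("the", "xyzzy", "quux"), 3, TRUE)),
          collapse = " ")
  }, character(1))
  ft <- frequent_terms(term_frequencies(corpus), 5L)
  expect_true(all(c("koel", "call", "morn", "annoy") %in% ft))
})

test_that("symptomatic query construction reproduces the templates", {
  q <- build_symptomatic_query("moth",
                               list(c("first", "invasion", "plague", "season", "today")))
  expect_equal(deparse_query(q),
               "moth AND (first OR invasion OR plague OR season OR today)")
  expect_equal(q$query_type, "symptomatic")

  q4 <- build_symptomatic_query(c("bird", "cuckoo"),
                                list(c("call", "sound", "song"),
                                     c("alarm clock", "shut up", "morning")))
  expect_length(q4$clauses, 3L)
  expect_equal(q4$clauses[[3]]$terms[[1]]$kind, "phrase")
  expect_error(build_symptomatic_query("moth", list(character())), "non-empty")
})

test_that("serialise/parse round trip preserves semantics", {
  queries <- list(
    parse_query("(bogong OR bogan) AND moth"),
    parse_query("\"common koel\""),
    parse_query("(bird OR cuckoo) AND (call OR sound) AND (\"alarm clock\" OR morning)"),
    build_symptomatic_query("moth", list(c("first", "plague")))
  )
  set.seed(9)
  vocab <- c("bogong", "bogan", "moth", "bird", "cuckoo", "call", "sound",
             "alarm", "clock", "morning", "koel", "common", "plague", "first")
  texts <- vapply(1:60, function(i) {
    paste(sample(vocab, sample(3:8, 1), replace = TRUE), collapse = " ")
  }, character(1))
  for (q in queries) {
    q2 <- parse_query(deparse_query(q), type = q$query_type)
    expect_equal(match_query(q2, texts), match_query(q, texts))
    expect_equal(deparse_query(q2), deparse_query(q))
  }
})

test_that("query files round-trip through the type-tagged text format", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# species queries",
               "taxonomic: \"agrotis infusa\"",
               "common_name: (bogong OR bogan) AND moth"), path)
  qs <- read_queries(path)
  expect_length(qs, 2L)
  expect_equal(qs[[1]]$query_type, "taxonomic")
  expect_equal(deparse_query(qs[[2]]), "(bogong OR bogan) AND moth")
  writeLines("badtag: moth", path)
  expect_error(read_queries(path), "type")
})
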