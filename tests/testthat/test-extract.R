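test_that("sentence spans are disjoint, ordered, and cover non-whitespace", {
  expect_equal(nrow(segment_sentences("")), 0L)
  expect_equal(nrow(segment_sentences("   \n ")), 0L)

  s <- segment_sentences("Pt denies snoring. Sleeps well.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$start, c(0L, 19L))
  expect_equal(substr("Pt denies snoring. Sleeps well.", s$start[2] + 1, s$end[2]),
               "Sleeps well.")

  s <- segment_sentences("no terminal punctuation here")
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end), c(0L, 28L))

  for (text in c("One. Two! Three? Four", "a.b. c\nd e.", " x ",
                 replicate(5, random_small_text(120L)))) {
    s <- segment_sentences(text)
    if (nrow(s) > 1L) {
      expect_true(all(diff(s$start) > 0))
      expect_true(all(s$end[-nrow(s)] <= s$start[-1]))
    }
    covered <- logical(nchar(text))
    for (i in seq_len(nrow(s))) covered[(s$start[i] + 1):s$end[i]] <- TRUE
    nonws <- which(strsplit(text, "")[[1]] != " " &
                   strsplit(text, "")[[1]] != "\n")
    expect_true(all(covered[nonws]))
  }
})

test_that("dictionary matching is word-bounded with longest-match-wins", {
  rs <- tiny_ruleset()
  m <- match_lexicon("Patient reports snoring nightly.", rs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$matched_text, "snoring")
  expect_equal(c(m$start, m$end), c(16L, 23L))
  expect_equal(m$concept_key, "SLEEP:SNORING")

  expect_equal(nrow(match_lexicon("", rs)), 0L)

  # longer surface shadows its prefix
  rs2 <- tiny_ruleset(surfaces = c("sleep", "sleep problems"),
                      concepts = c("SLEEP_GENERIC", "SLEEP_PROBLEMS"))
  m <- match_lexicon("sleep problems persist", rs2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$concept_key, "SLEEP:SLEEP_PROBLEMS")

  # word boundaries: embedded occurrences do not match
  expect_equal(nrow(match_lexicon("snoringly loud; unsnoring", rs)), 0L)

  # case-insensitive by default
  expect_equal(nrow(match_lexicon("SNORING and Snoring", rs)), 2L)
})

test_that("matcher agrees with the brute-force oracle on random small texts", {
  rs <- tiny_ruleset()
  set.seed(11)
  for (i in 1:25) {
    text <- random_small_text(150L)
    got <- match_lexicon(text, rs)
    want <- naive_match_oracle(text, rs)
    expect_equal(got$start, want$start, info = text)
    expect_equal(got$end, want$end, info = text)
    expect_equal(got$entry, want$entry, info = text)
  }
})

test_that("context triggers set attributes within scope, defaults otherwise", {
  rs <- tiny_ruleset()
  extract1 <- function(text) extract_mentions(document("n1", text), rs)

  m <- extract1("Patient denies snoring.")
  expect_equal(m$certainty, "NEGATED")
  expect_equal(m$experiencer, "PATIENT")
  expect_equal(m$temporality, "PRESENT")

  m <- extract1("Patient reports snoring.")
  expect_equal(c(m$certainty, m$experiencer, m$temporality),
               c("POSITIVE", "PATIENT", "PRESENT"))

  m <- extract1("Father had snoring.")
  expect_equal(m$experiencer, "OTHER")

  # trigger scope stops at a termination phrase
  m <- extract1("No fever but snoring persists.")
  expect_equal(m$certainty, "POSITIVE")

  # and never crosses a sentence boundary
  m <- extract1("Patient denies fever. Snoring was noted.")
  expect_equal(m$certainty, "POSITIVE")

  # backward trigger
  m <- extract1("Snoring is ruled out.")
  expect_equal(m$certainty, "NEGATED")

  # history / hypothetical temporality
  expect_equal(extract1("History of snoring.")$temporality, "HISTORICAL")
  expect_equal(extract1("Return if snoring recurs.")$temporality, "HYPOTHETICAL")
})

test_that("every mention carries closed-vocabulary attributes and exact spans", {
  corpus <- generate_corpus(gen_spec(seed = 5, n_docs = 40))
  m <- extract_corpus(corpus$documents, corpus$ruleset)
  expect_gt(nrow(m), 0)
  expect_true(all(m$certainty %in% c("POSITIVE", "NEGATED", "POSSIBLE")))
  expect_true(all(m$experiencer %in% c("PATIENT", "OTHER")))
  expect_true(all(m$temporality %in% c("PRESENT", "HISTORICAL", "HYPOTHETICAL")))
  texts <- corpus$documents$text[match(m$note_id, corpus$documents$note_id)]
  expect_equal(m$matched_text, substr(texts, m$start + 1, m$end))
})

test_that("extraction is deterministic and monotone under lexicon growth", {
  rs <- tiny_ruleset()
  doc <- document("n1", "Snoring and sleep problems; daytime sleepiness denied.")
  expect_identical(extract_mentions(doc, rs), extract_mentions(doc, rs))

  # adding an unrelated entry never removes an existing mention
  before <- extract_mentions(doc, rs)
  rs_big <- ruleset("001", "SLEEP", entries = rbind(
    rs$entries, lexicon_entry("bruxism", "BRUXISM", project = "SLEEP")))
  after <- extract_mentions(doc, rs_big)
  key <- function(m) paste(m$start, m$end, m$concept_key)
  expect_true(all(key(before) %in% key(after)))
})
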