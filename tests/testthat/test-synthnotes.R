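test_that("generation is deterministic per seed and respects rates", {
  s <- gen_spec(seed = 101, n_docs = 25)
  a <- generate_corpus(s)
  b <- generate_corpus(s)
  expect_identical(a$documents, b$documents)
  expect_identical(a$gold$labels, b$gold$labels)
  expect_identical(a$diagnoses, b$diagnoses)

  none <- generate_corpus(gen_spec(seed = 1, n_docs = 20, mention_rate = 0))
  expect_equal(nrow(none$gold$labels), 0L)

  one <- ruleset("001", "SLEEP",
                 entries = lexicon_entry("snoring", "SNORING", "SLEEP"))
  full <- generate_corpus(gen_spec(seed = 2, n_docs = 100, ruleset = one,
                                   mention_rate = 1))
  expect_gte(nrow(full$gold$labels), 100L)
})

test_that("planted spans and diagnosis codes are internally consistent", {
  corpus <- generate_corpus(gen_spec(seed = 8, n_docs = 40))
  g <- corpus$gold$labels
  texts <- corpus$documents$text[match(g$doc_id, corpus$documents$note_id)]
  expect_equal(substr(texts, g$start + 1, g$end), g$surface)

  spec <- corpus$spec
  planted <- corpus$diagnoses$code[!corpus$diagnoses$code %in%
                                   c("I10", "E11.9", "J45.909", "K21.9", "M54.5")]
  ok <- vapply(planted, function(cd)
    any(vapply(names(spec$diag_rules), function(p)
      match_code_pattern(cd, p), logical(1))), logical(1))
  expect_true(all(ok))
})

test_that("extraction on an uncorrupted corpus reproduces the gold set exactly", {
  corpus <- generate_corpus(gen_spec(seed = 55, n_docs = 60))
  m <- extract_corpus(corpus$documents, corpus$ruleset)
  g <- corpus$gold$labels
  key <- function(id, s, e, k) sort(paste(id, s, e, k))
  expect_equal(key(m$note_id, m$start, m$end, m$concept_key),
               key(g$doc_id, g$start, g$end, g$concept))
  idx <- match(paste(g$doc_id, g$start, g$end),
               paste(m$note_id, m$start, m$end))
  expect_equal(m$certainty[idx], g$certainty)
  expect_equal(m$experiencer[idx], g$experiencer)
  expect_equal(m$temporality[idx], g$temporality)
})

test_that("noise injection corrupts at the stated rates with a manifest", {
  corpus <- generate_corpus(gen_spec(seed = 23, n_docs = 40))

  clean <- inject_noise(corpus, noise_spec())
  expect_identical(clean$documents, corpus$documents)
  expect_identical(clean$gold$labels, corpus$gold$labels)
  expect_equal(nrow(clean$manifest), 0L)

  typoed <- inject_noise(corpus, noise_spec(typo_rate = 1, seed = 4))
  m <- extract_corpus(typoed$documents, corpus$ruleset)
  cc <- confusion(mentions_to_annotations(m), typoed$gold)
  expect_lt(prf_from_counts(cc$pooled)[["recall"]], 1)
  expect_true(all(typoed$manifest$error_type == "LINGUISTIC"))

  n_gold <- nrow(corpus$gold$labels)
  flipped <- inject_noise(corpus, noise_spec(gold_flip_rate = 0.1, seed = 6))
  n_flips <- sum(flipped$manifest$error_type == "ANNOTATION")
  # ~10% of labels, within a generous binomial band
  expect_gte(n_flips, qbinom(0.001, n_gold, 0.1))
  expect_lte(n_flips, qbinom(0.999, n_gold, 0.1))
  # text untouched by pure label flips
  expect_identical(flipped$documents, corpus$documents)
})

test_that("cue swaps shift gold spans correctly and induce attribute misses", {
  corpus <- generate_corpus(gen_spec(seed = 77, n_docs = 50,
                                     cue_rates = c(NEGATED = 0.5)))
  swapped <- inject_noise(corpus, noise_spec(cue_swap_rate = 1, seed = 2))
  expect_gt(nrow(swapped$manifest), 0)
  expect_true(all(swapped$manifest$error_type == "CONTEXTUAL"))
  # spans still point at the planted surfaces after length-changing edits
  g <- swapped$gold$labels
  texts <- swapped$documents$text[match(g$doc_id, swapped$documents$note_id)]
  expect_equal(substr(texts, g$start + 1, g$end), g$surface)
  # extractor now misses the held-out cue for swapped negations
  m <- extract_corpus(swapped$documents, corpus$ruleset)
  idx <- match(paste(g$doc_id, g$start, g$end),
               paste(m$note_id, m$start, m$end))
  neg <- g$certainty == "NEGATED" & !is.na(g$cue)
  expect_true(any(m$certainty[idx[neg]] != "NEGATED"))
})

test_that("deleting lexicon entries degrades recall monotonically", {
  corpus <- generate_corpus(gen_spec(seed = 12, n_docs = 60))
  e <- corpus$ruleset$entries
  recalls <- vapply(c(nrow(e), 4L, 2L, 1L), function(k) {
    rs <- ruleset("001", "SLEEP", entries = e[seq_len(k), , drop = FALSE])
    m <- extract_corpus(corpus$documents, rs)
    cc <- confusion(mentions_to_annotations(m), corpus$gold)
    prf_from_counts(cc$pooled)[["recall"]]
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
})
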