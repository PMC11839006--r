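test_that("concept and modifier encodings follow the templates exactly", {
  expect_identical(
    encode_concept_cd(concept_ref("STANDARD", vocab = "ICD-10-CM",
                                  code = "S92.4"), "001"),
    "NLP|001|ICD-10-CM:S92.4")
  expect_identical(
    encode_concept_cd(concept_ref("CUSTOM", project = "SLEEP",
                                  concept = "SNORING"), "001"),
    "NLP|001|CUSTOM|SLEEP:SNORING")
  expect_identical(encode_modifier_cd("EXPERIENCER", "PATIENT"),
                   "NLP|EXPERIENCER:PATIENT")
  expect_identical(encode_modifier_cd("CERTAINTY", "NEGATED"),
                   "NLP|CERTAINTY:NEGATED")
  expect_error(encode_modifier_cd("", "X"), "non-empty")
  expect_error(encode_concept_cd(concept_ref("CUSTOM", project = "SLEEP",
                                             concept = "SNORING"), "01a"),
               "digits")
  # over-length codes error rather than silently truncate
  long <- concept_ref("CUSTOM", project = "SLEEP",
                      concept = paste(rep("X", 60), collapse = ""))
  expect_error(encode_concept_cd(long, "001"), "exceeds")
})

test_that("parse_concept_cd inverts encoding and classifies non-NLP codes", {
  p <- parse_concept_cd("NLP|001|ICD-10-CM:S92.4")
  expect_false(p$not_nlp)
  expect_equal(p$ref$mode, "STANDARD")
  expect_equal(p$ref$vocab, "ICD-10-CM")
  expect_equal(p$ref$code, "S92.4")
  expect_equal(p$project_num, "001")

  expect_true(parse_concept_cd("ICD10CM:S92.4")$not_nlp)
  expect_error(parse_concept_cd("NLP|001|CUSTOM|SLEEP"), "malformed")

  set.seed(21)
  for (i in 1:200) {
    ref <- random_concept_ref()
    pn <- formatC(sample(0:999, 1), width = 3, flag = "0")
    cd <- encode_concept_cd(ref, pn, max_len = 200L)
    back <- parse_concept_cd(cd)
    expect_equal(back$project_num, pn)
    expect_equal(unclass(back$ref), unclass(ref))
  }
})

test_that("the NLP| prefix exactly partitions a mixed code table", {
  mixed <- c("NLP|001|ICD-10-CM:S92.4", "ICD10CM:S92.4", "LOINC:1234-5",
             "NLP|002|CUSTOM|SLEEP:SNORING", "DEM|SEX:M")
  expect_equal(is_nlp_code(mixed), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(sum(is_nlp_code(mixed)) + sum(!is_nlp_code(mixed)),
               length(mixed))
})

test_that("a mention encodes to a base row plus modifier rows sharing instance_num", {
  corpus <- generate_corpus(gen_spec(seed = 3, n_docs = 5))
  m <- extract_corpus(corpus$documents, corpus$ruleset)[1, ]
  facts <- mention_to_facts(m, encode_options(project_num = "001"))
  expect_equal(nrow(facts), 4L)  # base + 3 contextual attributes
  expect_equal(facts$modifier_cd[1], "@")
  expect_equal(length(unique(facts$instance_num)), 1L)
  expect_equal(length(unique(facts$concept_cd)), 1L)
  expect_true(all(startsWith(facts$concept_cd, "NLP|")))
  expect_true(all(facts$observation_blob == ""))

  withblob <- mention_to_facts(m, encode_options(include_blob = TRUE))
  expect_equal(withblob$observation_blob[1], m$sentence_snippet)

  dosed <- mention_to_facts(m, encode_options(),
                            numeric_attrs = data.frame(name = "DOSE",
                                                       value = 325,
                                                       unit = "mg"))
  num <- dosed[dosed$valtype_cd == "N", ]
  expect_equal(nrow(num), 1L)
  expect_equal(num$modifier_cd, "NLP|DOSE:VALUE")
  expect_equal(num$nval_num, 325)
  expect_equal(num$tval_char, "mg")
})

test_that("instance grouping recovers exactly one group per source mention", {
  corpus <- generate_corpus(gen_spec(seed = 9, n_docs = 30))
  m <- extract_corpus(corpus$documents, corpus$ruleset)
  facts <- mentions_to_facts(m, encode_options(cohort_query_id = "Q42"))
  expect_equal(nrow(facts), 4L * nrow(m))
  grp <- paste(facts$patient_num, facts$encounter_num, facts$concept_cd,
               facts$start_date, facts$instance_num)
  expect_equal(length(unique(grp)), nrow(m))
  expect_true(all(table(grp) == 4L))
  expect_true(all(facts$cohort_query_id == "Q42"))
})

test_that("fact CSV write -> read is the identity", {
  facts <- mentions_to_facts(
    extract_corpus(generate_corpus(gen_spec(seed = 13, n_docs = 20))$documents,
                   toy_ruleset()),
    encode_options(include_blob = TRUE, cohort_query_id = "QID-7"))
  path <- withr::local_tempfile(fileext = ".csv")
  n <- write_facts(facts, path)
  expect_equal(n, nrow(facts))
  expect_identical(read_facts(path), facts)

  # empty fact table -> header-only file that still round-trips
  empty <- facts[0, ]
  write_facts(empty, path)
  expect_equal(length(readLines(path)), 1L)
  expect_identical(read_facts(path), empty)
})

test_that("note-type codes render in both schemes", {
  expect_identical(note_type_cd("59258-4", "STD", "LOINC"),
                   "STD|LOINC:59258-4")
  expect_identical(note_type_cd("ED_NOTE"), "CUS|ED_NOTE")
})
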