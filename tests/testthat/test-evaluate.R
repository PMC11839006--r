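test_that("wildcard code patterns use dot-aware prefix semantics", {
  expect_true(match_code_pattern("F11.20", "F11.*"))
  expect_true(match_code_pattern("T43.61", "T43.6*"))
  expect_false(match_code_pattern("T43.8", "T43.6*"))
  expect_true(match_code_pattern("G90.51", "G90.5*"))
  expect_true(match_code_pattern("f1120", "F11.*"))      # undotted, lowercase
  expect_true(match_code_pattern("J84.112", "J84.112")) # literal
  expect_false(match_code_pattern("J84.113", "J84.112"))
  expect_error(match_code_pattern("F11.20", "F*1.1"), "end of a pattern")
})

test_that("cohort selection matches patients and samples deterministically", {
  diagnoses <- data.frame(
    patient_num = c(1L, 1L, 2L, 3L),
    code = c("I10", "F14.10", "E11.9", "M54.5"))
  spec <- eval_spec(c("F11.*", "F14.*", "F15.*", "T40.*", "T43.6*"))
  expect_equal(select_cohort(diagnoses, spec), 1L)

  big <- data.frame(patient_num = 1:50, code = sprintf("F11.%02d", 1:50))
  spec_n <- eval_spec("F11.*", sampling = list(method = "random_n", n = 10,
                                               seed = 99))
  c1 <- select_cohort(big, spec_n)
  c2 <- select_cohort(big, spec_n)
  expect_equal(c1, c2)
  expect_length(c1, 10L)

  expect_warning(select_cohort(diagnoses, eval_spec("Z99.*")), "no patients")
  expect_error(eval_spec(character()), "non-empty")
})

test_that("silver standards derive purely from structured codes", {
  diagnoses <- data.frame(
    patient_num = c(10L, 11L, 12L),
    code = c("T40.1X1A", "I10", "E11.9"))
  rule <- c("T40.*" = "positive")
  s1 <- derive_silver(diagnoses, rule)
  expect_s3_class(s1, "annotation_set")
  expect_equal(s1$standard, "SILVER")
  expect_equal(s1$labels$label[s1$labels$doc_id == "10"], "positive")
  expect_equal(s1$labels$label[s1$labels$doc_id == "11"], "negative")
  expect_identical(derive_silver(diagnoses, rule), s1)

  contradictory <- c("T40.*" = "positive", "T40.1*" = "borderline")
  expect_error(derive_silver(diagnoses, contradictory), "contradictory")
})

test_that("confusion counts satisfy the marginal identities", {
  mk <- function(ids) annotation_set("PRED", "document",
    data.frame(doc_id = as.character(1:12),
               label = ifelse(1:12 %in% ids, "positive", "negative")))
  ref <- mk(1:10)
  same <- confusion(mk(1:10), ref)
  expect_equal(same$pooled[c("tp", "fp", "fn")],
               list(tp = 10L, fp = 0L, fn = 0L), ignore_attr = TRUE)

  none <- confusion(mk(integer()), ref)
  expect_equal(none$pooled$tp, 0L)
  expect_equal(none$pooled$fn, 10L)

  c822 <- confusion(mk(c(1:8, 11:12)), ref)
  expect_equal(c822$pooled[c("tp", "fp", "fn")],
               list(tp = 8L, fp = 2L, fn = 2L), ignore_attr = TRUE)
  expect_equal(unname(prf_from_counts(c822$pooled)), c(0.8, 0.8, 0.8))

  ment <- annotation_set("GOLD", "mention",
                         data.frame(doc_id = "a", start = 0L, end = 3L,
                                    concept = "X:Y"))
  expect_error(confusion(mk(1), ment), "unit mismatch")
})

test_that("mention matching honours overlap mode", {
  ref <- annotation_set("GOLD", "mention",
                        data.frame(doc_id = "d1", start = 10L, end = 17L,
                                   concept = "SLEEP:SNORING"))
  pred_off <- annotation_set("PRED", "mention",
                             data.frame(doc_id = "d1", start = 12L, end = 17L,
                                        concept = "SLEEP:SNORING"))
  expect_equal(confusion(pred_off, ref, overlap = "any")$pooled$tp, 1L)
  expect_equal(confusion(pred_off, ref, overlap = "exact")$pooled$tp, 0L)
  # different concept never matches even with identical span
  pred_other <- annotation_set("PRED", "mention",
                               data.frame(doc_id = "d1", start = 10L,
                                          end = 17L, concept = "SLEEP:APNEA"))
  expect_equal(confusion(pred_other, ref)$pooled$tp, 0L)
})

test_that("metric arithmetic handles edge cases by the zero conventions", {
  expect_equal(unname(prf_from_counts(list(tp = 0, fp = 0, fn = 0))),
               c(0, 0, 0))
  expect_equal(unname(prf_from_counts(list(tp = 10, fp = 0, fn = 0))),
               c(1, 1, 1))
  expect_equal(f1_from_pr(0, 0), 0)
  expect_error(f1_from_pr(1.2, 0.5), "lie in")

  # f1 consistency and betweenness over random counts
  set.seed(31)
  for (i in 1:50) {
    cnt <- list(tp = sample(0:20, 1), fp = sample(0:20, 1),
                fn = sample(0:20, 1))
    m <- prf_from_counts(cnt)
    expect_equal(m[["f1"]], f1_from_pr(m[["precision"]], m[["recall"]]))
    expect_gte(m[["f1"]], min(m[["precision"]], m[["recall"]]) - 1e-12)
    expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
  }
})

test_that("micro pools counts while macro averages metrics", {
  one <- data.frame(concept = "A", tp = 8L, fp = 2L, fn = 2L)
  expect_equal(aggregate_metrics(one, "micro"), aggregate_metrics(one, "macro"))

  two <- data.frame(concept = c("A", "B"), tp = c(10L, 0L), fp = c(0L, 10L),
                    fn = c(0L, 10L))
  expect_equal(aggregate_metrics(two, "micro")[["precision"]], 0.5)
  expect_equal(aggregate_metrics(two, "macro")[["precision"]], 0.5)

  # imbalanced fixture where the two modes disagree
  imb <- data.frame(concept = c("A", "B"), tp = c(90L, 1L), fp = c(10L, 9L),
                    fn = c(0L, 0L))
  micro <- aggregate_metrics(imb, "micro")
  macro <- aggregate_metrics(imb, "macro")
  expect_false(isTRUE(all.equal(micro[["precision"]], macro[["precision"]])))
  expect_error(aggregate_metrics(one[0, ], "micro"), "empty")
})

test_that("gold/silver comparison reports agreement and silver quality", {
  mk <- function(pos, n = 10, std = "GOLD") annotation_set(std, "patient",
    data.frame(doc_id = as.character(1:n),
               label = ifelse(1:n %in% pos, "positive", "negative")))
  same <- compare_gold_silver(mk(1:10), mk(1:10, std = "SILVER"))
  expect_equal(same$agreement, 1.0)

  miss1 <- compare_gold_silver(mk(1:10), mk(1:9, std = "SILVER"))
  expect_equal(miss1$recall, 0.9)

  far <- annotation_set("SILVER", "patient",
                        data.frame(doc_id = as.character(101:110),
                                   label = "negative"))
  expect_error(compare_gold_silver(mk(1:5), far), "disjoint")
})

test_that("error tallies zero-fill the four-class taxonomy", {
  t0 <- tally_errors(NULL)
  expect_equal(t0$counts,
               c(LOGIC = 0L, LINGUISTIC = 0L, CONTEXTUAL = 0L, ANNOTATION = 0L))

  recs <- rbind(error_record("LOGIC", "n1"), error_record("LOGIC", "n2"),
                error_record("CONTEXTUAL", "n3", task = "sleep"))
  t1 <- tally_errors(recs)
  expect_equal(sum(t1$counts), nrow(recs))
  expect_equal(t1$counts[["LOGIC"]], 2L)
  expect_equal(t1$counts[["LINGUISTIC"]], 0L)

  expect_error(error_record("OTHER", "n4"), "unknown error type")
  recs$error_type[1] <- "OTHER"
  expect_error(tally_errors(recs), "unknown error type")
})

test_that("cross-site tables have one column per site, rounded half-up", {
  rep_for <- function(site, tp, fp, fn)
    metric_report(site, data.frame(concept = "A", tp = tp, fp = fp, fn = fn))
  # recall 0.919 with perfect precision gives F1 0.95779... -> "0.958"
  r1 <- rep_for("siteA", 919L, 0L, 81L)
  tab <- cross_site_report(list(r1))
  expect_equal(unname(tab["F1", 1]), 0.958)
  expect_equal(unname(tab["Precision", 1]), 1)

  tab3 <- cross_site_report(list(r1, rep_for("siteB", 8L, 2L, 2L),
                                 rep_for("siteC", 5L, 5L, 0L)))
  expect_equal(colnames(tab3), c("siteA", "siteB", "siteC"))
  expect_equal(rownames(tab3), c("F1", "Recall", "Precision"))
  expect_equal(unname(tab3["Precision", "siteC"]), 0.5)

  path <- withr::local_tempfile(fileext = ".csv")
  write_cross_site_report(tab3, path)
  lines <- readLines(path)
  expect_equal(lines[1], "Metrics,siteA,siteB,siteC")
  expect_match(lines[2], "^F1,0.958,")

  expect_error(cross_site_report(list(r1, r1)), "duplicate")
})
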