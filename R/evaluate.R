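# Federated evaluation: ICD wildcard cohorts, computable silver standards,
# gold/silver agreement, precision/recall/F1 per concept and aggregated, the
# four-class error taxonomy, and cross-site report tables.

ERROR_TYPES <- c("LOGIC", "LINGUISTIC", "CONTEXTUAL", "ANNOTATION")

#' Match a diagnosis code against a wildcard pattern
#'
#' Cohort definitions use ICD patterns that are either literal codes or a
#' prefix ending in `*` (e.g. `"F11.*"`, `"T43.6*"`, `"G90.5*"`). Matching is
#' case-insensitive and dot-aware: dots are stripped from both sides before
#' comparison, so `"F11.*"` matches `F11.20` as well as the undotted form
#' `F1120`.
#'
#' @param code Character vector of diagnosis codes.
#' @param pattern A single pattern string.
#' @return Logical vector, one element per code.
#' @export
match_code_pattern <- function(code, pattern) {
  stopifnot(is_string(pattern))
  star <- gregexpr("*", pattern, fixed = TRUE)[[1]]
  if (star[1] != -1L && (length(star) > 1L || star != nchar(pattern)))
    stop("'*' may only appear at the end of a pattern: ", pattern, call. = FALSE)
  norm <- function(x) gsub(".", "", toupper(x), fixed = TRUE)
  if (star[1] == -1L) norm(code) == norm(pattern)
  else startsWith(norm(code), norm(sub("\\*$", "", pattern)))
}

#' Evaluation specification
#'
#' The shared definition a development site publishes: the cohort (ICD
#' wildcard patterns over structured diagnoses), the applicable note type,
#' and the note-sampling method.
#'
#' @param cohort_patterns Character vector of ICD wildcard patterns
#'   (non-empty).
#' @param note_type Rendered note-type code the algorithm applies to, or
#'   `NA` for any.
#' @param sampling List: `method` (`"all"` or `"random_n"`), and for
#'   `random_n` a positive `n` and an integer `seed`.
#' @return A list of class `"eval_spec"`.
#' @export
eval_spec <- function(cohort_patterns, note_type = NA_character_,
                      sampling = list(method = "all")) {
  if (length(cohort_patterns) == 0L || any(!nzchar(cohort_patterns)))
    stop("cohort_patterns must be a non-empty list of patterns", call. = FALSE)
  sampling$method <- match.arg(sampling$method, c("all", "random_n"))
  if (sampling$method == "random_n") {
    if (is.null(sampling$n) || sampling$n <= 0)
      stop("random_n sampling requires n > 0", call. = FALSE)
    if (is.null(sampling$seed))
      stop("random_n sampling requires a seed", call. = FALSE)
  }
  structure(list(cohort_patterns = cohort_patterns, note_type = note_type,
                 sampling = sampling), class = "eval_spec")
}

#' Select a patient cohort from structured diagnoses
#'
#' A patient enters the cohort if at least one of their diagnosis codes
#' matches at least one cohort pattern; sampling (if any) is applied
#' afterwards under the spec's seed, so repeated runs give identical cohorts.
#'
#' @param diagnoses data.frame with columns `patient_num`, `code`.
#' @param spec An [eval_spec()].
#' @return Sorted integer vector of patient numbers.
#' @export
select_cohort <- function(diagnoses, spec) {
  stopifnot(inherits(spec, "eval_spec"),
            all(c("patient_num", "code") %in% names(diagnoses)))
  hit <- Reduce(`|`, lapply(spec$cohort_patterns, function(p)
    match_code_pattern(diagnoses$code, p)), rep(FALSE, nrow(diagnoses)))
  patients <- sort(unique(diagnoses$patient_num[hit]))
  if (length(patients) == 0L)
    warning("no patients match the cohort patterns", call. = FALSE)
  if (spec$sampling$method == "random_n" &&
      length(patients) > spec$sampling$n) {
    patients <- with_seed(spec$sampling$seed,
                          sort(sample(patients, spec$sampling$n)))
  }
  patients
}

#' Annotation set
#'
#' A reference or prediction label set. For `unit = "mention"`, `labels` has
#' one row per positive mention (`doc_id`, `start`, `end`, `concept`); for
#' `unit = "document"` or `"patient"`, one row per unit (`doc_id`, `label`,
#' optional `concept`).
#'
#' @param standard `"GOLD"` or `"SILVER"` (or `"PRED"` for algorithm output).
#' @param unit `"mention"`, `"document"` or `"patient"`.
#' @param labels The label data.frame (see Details).
#' @return A list of class `"annotation_set"`.
#' @export
annotation_set <- function(standard = c("GOLD", "SILVER", "PRED"),
                           unit = c("mention", "document", "patient"),
                           labels) {
  standard <- match.arg(standard); unit <- match.arg(unit)
  stopifnot(is.data.frame(labels))
  need <- if (unit == "mention") c("doc_id", "start", "end", "concept")
          else c("doc_id", "label")
  if (!all(need %in% names(labels)))
    stop("annotation labels missing columns: ",
         paste(setdiff(need, names(labels)), collapse = ", "), call. = FALSE)
  structure(list(standard = standard, unit = unit, labels = labels),
            class = "annotation_set")
}

#' Convert extracted mentions to a prediction annotation set
#'
#' Mentions asserted about someone other than the patient, negated, or
#' non-present can optionally be dropped first — the usual convention when a
#' gold standard only annotates current, affirmed patient findings.
#'
#' @param mentions Output of [extract_corpus()].
#' @param positive_only Keep only POSITIVE/PATIENT/PRESENT mentions.
#' @return An [annotation_set()] with `unit = "mention"`.
#' @export
mentions_to_annotations <- function(mentions, positive_only = FALSE) {
  m <- mentions
  if (positive_only)
    m <- m[m$certainty == "POSITIVE" & m$experiencer == "PATIENT" &
           m$temporality == "PRESENT", , drop = FALSE]
  annotation_set("PRED", "mention",
                 data.frame(doc_id = m$note_id, start = m$start, end = m$end,
                            concept = m$concept_key,
                            stringsAsFactors = FALSE))
}

#' Derive a silver standard from structured diagnoses
#'
#' Labels units purely from structured codes: a rule maps code patterns to a
#' label; a patient whose codes match any pattern of a rule receives that
#' rule's label, and patients with no qualifying codes receive
#' `negative_label`. Two rules assigning different labels to the same patient
#' is a specification error. Deterministic: the output depends only on the
#' inputs.
#'
#' @param diagnoses data.frame with `patient_num`, `code`.
#' @param rule Named character vector: names are wildcard patterns, values
#'   labels (e.g. `c("T40.*" = "positive")`).
#' @param spec Optional [eval_spec()]; when given, labelling is restricted to
#'   the selected cohort.
#' @param unit `"patient"` (default) or `"document"`; document labelling
#'   requires `corpus` and propagates each patient's label to their notes.
#' @param corpus Corpus data.frame (for `unit = "document"`).
#' @param negative_label Label for units with no qualifying codes.
#' @return An [annotation_set()] with `standard = "SILVER"`.
#' @export
derive_silver <- function(diagnoses, rule, spec = NULL,
                          unit = c("patient", "document"), corpus = NULL,
                          negative_label = "negative") {
  unit <- match.arg(unit)
  if (length(rule) == 0L || is.null(names(rule)) || any(!nzchar(names(rule))))
    stop("rule must be a named pattern -> label map", call. = FALSE)
  patients <- sort(unique(diagnoses$patient_num))
  if (!is.null(spec)) patients <- intersect(patients, select_cohort(diagnoses, spec))
  lab <- vapply(patients, function(p) {
    codes <- diagnoses$code[diagnoses$patient_num == p]
    hits <- unique(unlist(lapply(seq_along(rule), function(j)
      if (any(match_code_pattern(codes, names(rule)[j]))) rule[[j]] else NULL)))
    if (length(hits) > 1L)
      stop("contradictory silver labels for patient ", p, ": ",
           paste(hits, collapse = ", "), call. = FALSE)
    if (length(hits) == 0L) negative_label else hits
  }, character(1))
  labels <- data.frame(doc_id = as.character(patients), label = lab,
                       stringsAsFactors = FALSE)
  if (unit == "document") {
    if (is.null(corpus)) stop("document-level silver requires a corpus", call. = FALSE)
    idx <- match(corpus$patient_num, patients)
    keep <- !is.na(idx)
    labels <- data.frame(doc_id = corpus$note_id[keep],
                         label = lab[idx[keep]], stringsAsFactors = FALSE)
  }
  annotation_set("SILVER", unit, labels)
}

new_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_counts")
}

match_mentions_one <- function(pred, ref, overlap) {
  used <- logical(nrow(pred)); tp <- 0L
  for (i in seq_len(nrow(ref))) {
    cand <- which(!used & pred$doc_id == ref$doc_id[i])
    ok <- if (overlap == "exact")
      pred$start[cand] == ref$start[i] & pred$end[cand] == ref$end[i]
    else
      pred$start[cand] < ref$end[i] & ref$start[i] < pred$end[cand]
    cand <- cand[ok]
    if (length(cand)) { used[cand[1]] <- TRUE; tp <- tp + 1L }
  }
  new_counts(tp = tp, fp = sum(!used), fn = nrow(ref) - tp)
}

#' Confusion counts between prediction and reference sets
#'
#' Mention unit: per concept, reference mentions are matched one-to-one to
#' predicted mentions of the same concept in the same document; the default
#' match requires any character overlap, `overlap = "exact"` requires span
#' equality. Document/patient unit: binary comparison of labels against
#' `positive`, over the union of unit ids (a unit absent from one set counts
#' as negative there). Always satisfies `tp + fn = reference positives` and
#' `tp + fp = predicted positives`.
#'
#' @param pred,ref [annotation_set()]s with the same unit.
#' @param overlap Mention matching rule: `"any"` or `"exact"`.
#' @param positive Label counted as positive for document/patient units.
#' @return List with `per_concept` (data.frame `concept`, `tp`, `fp`, `fn`)
#'   and `pooled` (a `confusion_counts`).
#' @export
confusion <- function(pred, ref, overlap = c("any", "exact"),
                      positive = "positive") {
  overlap <- match.arg(overlap)
  stopifnot(inherits(pred, "annotation_set"), inherits(ref, "annotation_set"))
  if (pred$unit != ref$unit)
    stop("unit mismatch: ", pred$unit, " vs ", ref$unit, call. = FALSE)
  if (pred$unit == "mention") {
    concepts <- sort(unique(c(pred$labels$concept, ref$labels$concept)))
    per <- lapply(concepts, function(k)
      match_mentions_one(pred$labels[pred$labels$concept == k, , drop = FALSE],
                         ref$labels[ref$labels$concept == k, , drop = FALSE],
                         overlap))
    per_df <- data.frame(concept = concepts,
                         tp = vapply(per, `[[`, integer(1), "tp"),
                         fp = vapply(per, `[[`, integer(1), "fp"),
                         fn = vapply(per, `[[`, integer(1), "fn"),
                         stringsAsFactors = FALSE)
    pooled <- new_counts(sum(per_df$tp), sum(per_df$fp), sum(per_df$fn))
  } else {
    has_concept <- "concept" %in% names(ref$labels) &&
                   "concept" %in% names(pred$labels)
    split_by <- function(s) if (has_concept) split(s$labels, s$labels$concept)
                            else list(ALL = s$labels)
    ps <- split_by(pred); rs <- split_by(ref)
    concepts <- sort(unique(c(names(ps), names(rs))))
    rows <- lapply(concepts, function(k) {
      p <- ps[[k]]; r <- rs[[k]]
      ids <- union(p$doc_id %||% character(), r$doc_id %||% character())
      pp <- ids %in% (if (is.null(p)) character() else p$doc_id[p$label == positive])
      rp <- ids %in% (if (is.null(r)) character() else r$doc_id[r$label == positive])
      data.frame(concept = k, tp = sum(pp & rp), fp = sum(pp & !rp),
                 fn = sum(!pp & rp), tn = sum(!pp & !rp),
                 stringsAsFactors = FALSE)
    })
    per_df <- do.call(rbind, rows)
    pooled <- new_counts(sum(per_df$tp), sum(per_df$fp), sum(per_df$fn),
                         sum(per_df$tn))
  }
  list(per_concept = per_df, pooled = pooled)
}

#' Precision, recall and F1 from confusion counts
#'
#' `p = tp/(tp+fp)`, `r = tp/(tp+fn)`, `f1 = 2pr/(p+r)`; each is defined as 0
#' when its denominator is 0.
#'
#' @param counts A `confusion_counts` (or list/row with `tp`, `fp`, `fn`).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
prf_from_counts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(precision = p, recall = r, f1 = f1_from_pr(p, r))
}

#' F1 from precision and recall
#'
#' The harmonic mean `2pr/(p+r)`, 0 when `p + r = 0`.
#'
#' @param p,r Precision and recall, each in \[0, 1\].
#' @return The F1 score.
#' @examples
#' f1_from_pr(0.928, 0.992)  # 0.9589...
#' @export
f1_from_pr <- function(p, r) {
  if (any(p < 0 | p > 1 | r < 0 | r > 1, na.rm = TRUE))
    stop("precision and recall must lie in [0, 1]", call. = FALSE)
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' Aggregate per-concept counts into site-level metrics
#'
#' Micro-averaging pools the confusion counts across concepts and computes
#' one metric triple from the pooled counts; macro-averaging computes the
#' triple per concept and averages each of precision, recall and F1 (the
#' macro F1 is the mean of per-concept F1s, not recomputed from the macro
#' precision/recall).
#'
#' @param per_concept data.frame with columns `concept`, `tp`, `fp`, `fn`.
#' @param mode `"micro"` or `"macro"`.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
aggregate_metrics <- function(per_concept, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (nrow(per_concept) == 0L)
    stop("cannot aggregate an empty per-concept table", call. = FALSE)
  if (mode == "micro") {
    prf_from_counts(list(tp = sum(per_concept$tp), fp = sum(per_concept$fp),
                         fn = sum(per_concept$fn)))
  } else {
    m <- t(vapply(seq_len(nrow(per_concept)), function(i)
      prf_from_counts(per_concept[i, ]), numeric(3)))
    c(precision = mean(m[, 1]), recall = mean(m[, 2]), f1 = mean(m[, 3]))
  }
}

#' Site-level metric report
#'
#' @param site_id Site identifier.
#' @param per_concept Per-concept confusion counts (`concept`, `tp`, `fp`,
#'   `fn`).
#' @return An object of class `"metric_report"`: per-concept metrics plus
#'   micro and macro aggregates.
#' @export
metric_report <- function(site_id, per_concept) {
  stopifnot(is_string(site_id))
  m <- t(vapply(seq_len(nrow(per_concept)), function(i)
    prf_from_counts(per_concept[i, ]), numeric(3)))
  per <- cbind(per_concept,
               as.data.frame(matrix(m, ncol = 3,
                                    dimnames = list(NULL, c("precision", "recall", "f1")))))
  structure(list(site_id = site_id, per_concept = per,
                 micro = aggregate_metrics(per_concept, "micro"),
                 macro = aggregate_metrics(per_concept, "macro")),
            class = "metric_report")
}

#' Evaluate predictions against a reference standard
#'
#' @param pred,ref [annotation_set()]s sharing a unit.
#' @param site_id Site identifier stamped on the report.
#' @param overlap,positive Passed to [confusion()].
#' @return A [metric_report()].
#' @export
evaluate_predictions <- function(pred, ref, site_id = "site",
                                 overlap = c("any", "exact"),
                                 positive = "positive") {
  cc <- confusion(pred, ref, overlap = match.arg(overlap), positive = positive)
  metric_report(site_id, cc$per_concept)
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("<metric_report> site ", x$site_id, " (", nrow(x$per_concept),
      " concepts)\n", sep = "")
  fmt <- function(v) formatC(round_half_up(v, digits), format = "f", digits = digits)
  cat("  micro: P=", fmt(x$micro[1]), " R=", fmt(x$micro[2]),
      " F1=", fmt(x$micro[3]), "\n", sep = "")
  cat("  macro: P=", fmt(x$macro[1]), " R=", fmt(x$macro[2]),
      " F1=", fmt(x$macro[3]), "\n", sep = "")
  invisible(x)
}

#' Compare gold and silver standards
#'
#' Development sites check that the computable silver standard is adequate
#' before validation sites rely on it. Both sets must be document- or
#' patient-level and share unit ids; comparison runs on the common ids.
#'
#' @param gold,silver [annotation_set()]s with the same non-mention unit.
#' @param positive Positive label.
#' @return List: `n_common`, `agreement` (fraction of common units with equal
#'   labels), `counts` (both_positive / gold_only / silver_only /
#'   both_negative), and silver-vs-gold `precision` and `recall` treating
#'   gold as truth.
#' @export
compare_gold_silver <- function(gold, silver, positive = "positive") {
  stopifnot(inherits(gold, "annotation_set"), inherits(silver, "annotation_set"))
  if (gold$unit == "mention" || silver$unit == "mention")
    stop("gold/silver comparison is defined for document or patient units",
         call. = FALSE)
  ids <- intersect(gold$labels$doc_id, silver$labels$doc_id)
  if (length(ids) == 0L)
    stop("gold and silver annotate disjoint unit sets", call. = FALSE)
  g <- gold$labels$label[match(ids, gold$labels$doc_id)]
  s <- silver$labels$label[match(ids, silver$labels$doc_id)]
  gp <- g == positive; sp <- s == positive
  counts <- c(both_positive = sum(gp & sp), gold_only = sum(gp & !sp),
              silver_only = sum(!gp & sp), both_negative = sum(!gp & !sp))
  prf <- prf_from_counts(list(tp = counts[["both_positive"]],
                              fp = counts[["silver_only"]],
                              fn = counts[["gold_only"]]))
  list(n_common = length(ids), agreement = mean(g == s), counts = counts,
       precision = unname(prf["precision"]), recall = unname(prf["recall"]))
}

#' Record an error-analysis finding
#'
#' @param error_type One of `LOGIC`, `LINGUISTIC`, `CONTEXTUAL`,
#'   `ANNOTATION`.
#' @param unit_ref Reference to the misclassified unit (note id, span, ...).
#' @param note Free-text explanation.
#' @param task,focus_area,method Task metadata.
#' @return A one-row data.frame.
#' @export
error_record <- function(error_type, unit_ref, note = "", task = NA_character_,
                         focus_area = NA_character_, method = NA_character_) {
  if (!error_type %in% ERROR_TYPES)
    stop("unknown error type '", error_type, "'; must be one of ",
         paste(ERROR_TYPES, collapse = ", "), call. = FALSE)
  data.frame(error_type = error_type, unit_ref = unit_ref, note = note,
             task = task, focus_area = focus_area, method = method,
             stringsAsFactors = FALSE)
}

#' Tally error-analysis records by error type
#'
#' Counts over the closed four-class taxonomy (logic, linguistic, contextual,
#' annotation), zero-filled so every class is always reported, plus
#' cross-tabulations by any task metadata columns present.
#'
#' @param records data.frame of [error_record()] rows (possibly zero rows).
#' @return List: `counts` (named integer vector over the four classes) and
#'   `by` (list of error_type x metadata tables).
#' @export
tally_errors <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    counts <- stats::setNames(integer(length(ERROR_TYPES)), ERROR_TYPES)
    return(list(counts = counts, by = list()))
  }
  bad <- setdiff(unique(records$error_type), ERROR_TYPES)
  if (length(bad))
    stop("unknown error type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  f <- factor(records$error_type, levels = ERROR_TYPES)
  counts <- table(f)
  by <- list()
  for (col in intersect(c("task", "focus_area", "method"), names(records))) {
    if (any(!is.na(records[[col]])))
      by[[col]] <- table(f, records[[col]])
  }
  list(counts = stats::setNames(as.integer(counts), ERROR_TYPES), by = by)
}

#' Cross-site comparison table
#'
#' One column per site, rows F1 / Recall / Precision, in the layout used for
#' multi-site validation summaries. Values are rounded half-up to 3 decimals.
#'
#' @param reports List of [metric_report()]s with distinct site ids.
#' @param mode Which aggregate to tabulate: `"micro"` or `"macro"`.
#' @return A matrix of class `"cross_site_report"` (rows F1/Recall/Precision).
#' @export
cross_site_report <- function(reports, mode = c("micro", "macro")) {
  mode <- match.arg(mode)
  if (length(reports) == 0L) stop("need at least one report", call. = FALSE)
  sites <- vapply(reports, `[[`, character(1), "site_id")
  if (anyDuplicated(sites))
    stop("duplicate site_id: ", sites[duplicated(sites)][1], call. = FALSE)
  m <- vapply(reports, function(r) {
    v <- r[[mode]]
    round_half_up(c(v[["f1"]], v[["recall"]], v[["precision"]]), 3L)
  }, numeric(3))
  m <- matrix(m, nrow = 3, dimnames = list(c("F1", "Recall", "Precision"), sites))
  structure(m, class = c("cross_site_report", "matrix"))
}

#' @export
print.cross_site_report <- function(x, ...) {
  cat("Cross-site validation\n")
  m <- unclass(x)
  print(matrix(formatC(m, format = "f", digits = 3), nrow = nrow(m),
               dimnames = dimnames(m)), quote = FALSE)
  invisible(x)
}

#' Write a cross-site report to CSV
#'
#' @param x A [cross_site_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cross_site_report <- function(x, path) {
  m <- unclass(x)
  df <- data.frame(Metrics = rownames(m),
                   matrix(formatC(m, format = "f", digits = 3), nrow = nrow(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- colnames(m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
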