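# Synthetic clinical-note corpora with planted, ground-truth-annotated
# mentions. Sentences are built from slot-filled templates so every planted
# term's character span and intended contextual attributes are known exactly;
# that exact bookkeeping is what makes the generator usable as a reference
# standard for the extractor without any PHI.

# One unambiguous template per attribute category. The cue phrases are drawn
# from the shipped trigger list; the surrounding words deliberately avoid
# every trigger phrase so each template exercises exactly one cue.
SENT_TEMPLATES <- data.frame(
  category = c("DEFAULT", "DEFAULT2", "NEGATED", "POSSIBLE", "HISTORICAL",
               "OTHER", "HYPOTHETICAL"),
  template = c("Patient reports %s on most nights.",
               "The patient describes %s during the visit.",
               "Patient denies %s at this time.",
               "Possible %s under evaluation.",
               "History of %s documented in earlier charts.",
               "Father had %s for years.",
               "Return if %s recurs."),
  cue = c(NA, NA, "denies", "Possible", "History of", "Father", "if"),
  certainty = c("POSITIVE", "POSITIVE", "NEGATED", "POSSIBLE", "POSITIVE",
                "POSITIVE", "POSITIVE"),
  experiencer = c("PATIENT", "PATIENT", "PATIENT", "PATIENT", "PATIENT",
                  "OTHER", "PATIENT"),
  temporality = c("PRESENT", "PRESENT", "PRESENT", "PRESENT", "HISTORICAL",
                  "PRESENT", "HYPOTHETICAL"),
  stringsAsFactors = FALSE)

# Neutral filler vocabulary; contains no lexicon surface token and no trigger
# phrase token, so distractor sentences can never assemble a dictionary match
# or a context cue.
DISTRACTOR_WORDS <- c(
  "vitals", "stable", "afebrile", "ambulating", "alert", "oriented",
  "cooperative", "breathing", "comfortably", "labs", "reviewed",
  "unremarkable", "medications", "reconciled", "gait", "steady", "appetite",
  "normal", "hydration", "adequate", "mood", "euthymic", "skin", "warm",
  "dry", "pulses", "intact", "abdomen", "soft", "nontender", "lungs",
  "clear", "heart", "regular", "rhythm", "extremities", "edema", "neuro",
  "grossly", "baseline", "tolerating", "diet", "ambulatory", "discharge",
  "planned", "counseling", "provided", "immunizations", "current",
  "screening", "completed", "bloodwork", "pending", "imaging", "ordered",
  "wound", "healing", "well", "incision", "approximated")

#' Toy sleep-phenotyping ruleset
#'
#' A small project ruleset (project 001, SLEEP) mixing custom concepts
#' (SNORING, DAY_SLEEP, SLEEP_PROBLEMS, INSOMNIA, RESTLESS_LEGS) with one
#' standard-terminology concept (ICD-10-CM G47.33, obstructive sleep apnea).
#' Ships as the default vocabulary for the synthetic-note generator.
#'
#' @return A [ruleset()].
#' @export
toy_ruleset <- function() {
  entries <- lexicon_entry(
    surface = c("snoring", "daytime sleepiness", "sleep problems",
                "insomnia", "restless legs", "obstructive sleep apnea"),
    concept = c("SNORING", "DAY_SLEEP", "SLEEP_PROBLEMS", "INSOMNIA",
                "RESTLESS_LEGS", "ICD-10-CM:G47.33"),
    project = "SLEEP")
  ruleset("001", "SLEEP", entries = entries)
}

#' Generation specification for synthetic corpora
#'
#' All randomness in generation flows from the single `seed`.
#'
#' @param seed Integer seed.
#' @param n_docs Number of notes to generate.
#' @param ruleset The vocabulary to plant; defaults to [toy_ruleset()].
#' @param mention_rate Per-concept probability that a note plants a mention
#'   of that concept.
#' @param cue_rates Named probabilities that a planted mention is wrapped in
#'   an attribute cue (names from `NEGATED`, `POSSIBLE`, `HISTORICAL`,
#'   `OTHER`, `HYPOTHETICAL`); the remainder are plain present/positive/
#'   patient mentions. Must sum to at most 1.
#' @param distractor_vocab Number of filler words available to distractor
#'   sentences.
#' @param note_type_mix Named probability vector over rendered note-type
#'   codes.
#' @param diag_rules Named probability vector: ICD wildcard pattern ->
#'   per-patient probability of carrying a concrete code drawn from it.
#' @return A list of class `"gen_spec"`.
#' @export
gen_spec <- function(seed = 1L, n_docs = 200L, ruleset = toy_ruleset(),
                     mention_rate = 0.35,
                     cue_rates = c(NEGATED = 0.2, POSSIBLE = 0.05,
                                   HISTORICAL = 0.1, OTHER = 0.1,
                                   HYPOTHETICAL = 0.05),
                     distractor_vocab = 40L,
                     note_type_mix = c("CUS|CLIN_ENC_NOTE" = 0.8,
                                       "STD|LOINC:59258-4" = 0.2),
                     diag_rules = c("F11.*" = 0.15, "T43.6*" = 0.1,
                                    "G90.5*" = 0.1)) {
  stopifnot(n_docs >= 0, inherits(ruleset, "ruleset"))
  rates <- c(mention_rate, cue_rates, unname(diag_rules), unname(note_type_mix))
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (sum(cue_rates) > 1)
    stop("cue_rates must sum to at most 1", call. = FALSE)
  bad <- setdiff(names(cue_rates),
                 c("NEGATED", "POSSIBLE", "HISTORICAL", "OTHER", "HYPOTHETICAL"))
  if (length(bad)) stop("unknown cue categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 ruleset = ruleset, mention_rate = mention_rate,
                 cue_rates = cue_rates,
                 distractor_vocab = min(as.integer(distractor_vocab),
                                        length(DISTRACTOR_WORDS)),
                 note_type_mix = note_type_mix, diag_rules = diag_rules),
            class = "gen_spec")
}

draw_category <- function(cue_rates) {
  u <- stats::runif(1)
  acc <- 0
  for (nm in names(cue_rates)) {
    acc <- acc + cue_rates[[nm]]
    if (u < acc) return(nm)
  }
  sample(c("DEFAULT", "DEFAULT2"), 1L)
}

make_distractor <- function(vocab) {
  w <- sample(vocab, sample(3:6, 1L), replace = FALSE)
  w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])))
  paste0(paste(w, collapse = " "), ".")
}

concretize_pattern <- function(pattern) {
  if (grepl("\\*$", pattern)) {
    prefix <- sub("\\*$", "", pattern)
    paste0(prefix, paste(sample(0:9, 2L, replace = TRUE), collapse = ""))
  } else pattern
}

#' Generate a synthetic annotated corpus
#'
#' Builds `n_docs` notes from slot-filled sentence templates. Every planted
#' mention is recorded in the gold annotation set with its exact character
#' span, concept, intended contextual attributes, and (when a cue was used)
#' the cue phrase and its span. Structured diagnosis records are planted per
#' patient from the spec's wildcard rules. Deterministic per seed.
#'
#' @param spec A [gen_spec()].
#' @return A list of class `"synth_corpus"`: `documents` (corpus data.frame),
#'   `gold` (an [annotation_set()], unit `"mention"`), `diagnoses`
#'   (patient_num, code, date), and the `ruleset` used.
#' @export
generate_corpus <- function(spec = gen_spec()) {
  stopifnot(inherits(spec, "gen_spec"))
  with_seed(spec$seed, {
    vocab <- DISTRACTOR_WORDS[seq_len(spec$distractor_vocab)]
    e <- spec$ruleset$entries
    docs <- list(); gold <- list(); diags <- list()
    for (i in seq_len(spec$n_docs)) {
      note_id <- sprintf("note%05d", i)
      patient <- 1000L + i
      encounter <- 5000L + i
      ntype <- sample(names(spec$note_type_mix), 1L,
                      prob = unname(spec$note_type_mix))
      dt <- sprintf("2024-%02d-%02d 09:00:00", sample(1:12, 1L), sample(1:28, 1L))
      sents <- list()
      for (k in seq_len(1L + stats::rbinom(1L, 2L, 0.7)))
        sents[[length(sents) + 1L]] <- list(text = make_distractor(vocab))
      for (j in seq_len(nrow(e))) {
        if (stats::runif(1) >= spec$mention_rate) next
        cat_name <- draw_category(spec$cue_rates)
        tmpl <- SENT_TEMPLATES[SENT_TEMPLATES$category == cat_name, ]
        text <- sprintf(tmpl$template, e$surface[j])
        term_start <- regexpr("%s", tmpl$template, fixed = TRUE)[1] - 1L
        cue_start <- cue_end <- NA_integer_
        if (!is.na(tmpl$cue)) {
          cm <- regexpr(tmpl$cue, text, fixed = TRUE)
          cue_start <- cm[1] - 1L
          cue_end <- cue_start + attr(cm, "match.length")
        }
        sents[[length(sents) + 1L]] <- list(
          text = text, term_start = term_start,
          term_end = term_start + nchar(e$surface[j]),
          concept = concept_key(as.list(e[j, ])), surface = e$surface[j],
          certainty = tmpl$certainty, experiencer = tmpl$experiencer,
          temporality = tmpl$temporality, category = tmpl$category,
          cue = tmpl$cue, cue_start = cue_start, cue_end = cue_end)
      }
      sents <- sents[sample(seq_along(sents))]
      offset <- 0L; parts <- character(length(sents))
      for (k in seq_along(sents)) {
        s <- sents[[k]]
        parts[k] <- s$text
        if (!is.null(s$concept)) {
          gold[[length(gold) + 1L]] <- data.frame(
            doc_id = note_id, start = offset + s$term_start,
            end = offset + s$term_end, concept = s$concept,
            surface = s$surface, certainty = s$certainty,
            experiencer = s$experiencer, temporality = s$temporality,
            category = s$category, cue = s$cue %||% NA_character_,
            cue_start = if (is.na(s$cue_start)) NA_integer_ else offset + s$cue_start,
            cue_end = if (is.na(s$cue_end)) NA_integer_ else offset + s$cue_end,
            stringsAsFactors = FALSE)
        }
        offset <- offset + nchar(s$text) + 1L  # sentences joined by one space
      }
      docs[[i]] <- data.frame(note_id = note_id, patient_num = patient,
                              encounter_num = encounter, note_type_cd = ntype,
                              note_datetime = dt,
                              text = paste(parts, collapse = " "),
                              stringsAsFactors = FALSE)
      for (p in names(spec$diag_rules)) {
        if (stats::runif(1) < spec$diag_rules[[p]])
          diags[[length(diags) + 1L]] <- data.frame(
            patient_num = patient, code = concretize_pattern(p),
            date = substr(dt, 1, 10), stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < 0.5)
        diags[[length(diags) + 1L]] <- data.frame(
          patient_num = patient,
          code = sample(c("I10", "E11.9", "J45.909", "K21.9", "M54.5"), 1L),
          date = substr(dt, 1, 10), stringsAsFactors = FALSE)
    }
    documents <- if (length(docs)) do.call(rbind, docs) else
      data.frame(note_id = character(), patient_num = integer(),
                 encounter_num = integer(), note_type_cd = character(),
                 note_datetime = character(), text = character(),
                 stringsAsFactors = FALSE)
    gold_df <- if (length(gold)) do.call(rbind, gold) else
      data.frame(doc_id = character(), start = integer(), end = integer(),
                 concept = character(), surface = character(),
                 certainty = character(), experiencer = character(),
                 temporality = character(), category = character(),
                 cue = character(), cue_start = integer(),
                 cue_end = integer(), stringsAsFactors = FALSE)
    diagnoses <- if (length(diags)) do.call(rbind, diags) else
      data.frame(patient_num = integer(), code = character(),
                 date = character(), stringsAsFactors = FALSE)
    structure(list(documents = documents,
                   gold = annotation_set("GOLD", "mention", gold_df),
                   diagnoses = diagnoses, ruleset = spec$ruleset,
                   spec = spec),
              class = "synth_corpus")
  })
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("<synth_corpus> ", nrow(x$documents), " notes, ",
      nrow(x$gold$labels), " planted mentions, ",
      nrow(x$diagnoses), " diagnosis records\n", sep = "")
  invisible(x)
}

#' Noise specification for corpus corruption
#'
#' @param typo_rate Per-mention probability of a character typo inside the
#'   planted surface (a linguistic error source).
#' @param cue_swap_rate Per-cued-mention probability of replacing the cue
#'   phrase with a held-out synonym the trigger list does not know (a
#'   contextual error source).
#' @param gold_flip_rate Per-mention probability of flipping the recorded
#'   gold certainty (an annotation error source).
#' @param seed Integer seed for the corruption draw.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(typo_rate = 0, cue_swap_rate = 0, gold_flip_rate = 0,
                       seed = 1L) {
  rates <- c(typo_rate, cue_swap_rate, gold_flip_rate)
  if (any(rates < 0 | rates > 1))
    stop("noise rates must lie in [0, 1]", call. = FALSE)
  structure(list(typo_rate = typo_rate, cue_swap_rate = cue_swap_rate,
                 gold_flip_rate = gold_flip_rate, seed = as.integer(seed)),
            class = "noise_spec")
}

# Held-out cue synonyms, deliberately absent from the default trigger list,
# so a swapped cue is an honest contextual miss for the extractor.
CUE_SYNONYMS <- c("denies" = "disavows", "Possible" = "Conceivably",
                  "History of" = "Remote course of", "Father" = "Paternal parent",
                  "if" = "supposing")

splice <- function(text, start0, end0, replacement) {
  paste0(substr(text, 1, start0), replacement,
         substr(text, end0 + 1L, nchar(text)))
}

#' Corrupt a synthetic corpus at controlled rates
#'
#' Applies typos to planted surfaces, swaps attribute cues for held-out
#' synonyms, and flips gold certainty labels, each at its specified rate. A
#' manifest records every corruption with the error class it is designed to
#' induce: `LINGUISTIC` for typos, `CONTEXTUAL` for cue swaps, `ANNOTATION`
#' for gold flips. Mention spans in the gold set are shifted to stay correct
#' after length-changing edits.
#'
#' @param corpus A `synth_corpus` from [generate_corpus()].
#' @param noise A [noise_spec()].
#' @return A `synth_corpus` with corrupted `documents`/`gold` plus a
#'   `manifest` data.frame (`doc_id`, `error_type`, `detail`).
#' @export
inject_noise <- function(corpus, noise = noise_spec()) {
  stopifnot(inherits(corpus, "synth_corpus"), inherits(noise, "noise_spec"))
  docs <- corpus$documents
  gold <- corpus$gold$labels
  manifest <- list()
  with_seed(noise$seed, {
    for (d in seq_len(nrow(docs))) {
      id <- docs$note_id[d]
      rows <- which(gold$doc_id == id)
      rows <- rows[order(gold$start[rows])]
      # cue swaps first: they change lengths, so downstream spans shift
      for (g in rows) {
        if (is.na(gold$cue[g]) || stats::runif(1) >= noise$cue_swap_rate) next
        syn <- CUE_SYNONYMS[[gold$cue[g]]]
        delta <- nchar(syn) - (gold$cue_end[g] - gold$cue_start[g])
        docs$text[d] <- splice(docs$text[d], gold$cue_start[g],
                               gold$cue_end[g], syn)
        edit_at <- gold$cue_end[g]
        shift <- function(v) ifelse(!is.na(v) & v >= edit_at, v + delta, v)
        here <- gold$doc_id == id
        gold$start[here] <- shift(gold$start[here])
        gold$end[here] <- shift(gold$end[here])
        gold$cue_start[here] <- shift(gold$cue_start[here])
        gold$cue_end[here] <- shift(gold$cue_end[here])
        gold$cue_end[g] <- gold$cue_start[g] + nchar(syn)
        manifest[[length(manifest) + 1L]] <- data.frame(
          doc_id = id, error_type = "CONTEXTUAL",
          detail = paste0("cue '", gold$cue[g], "' -> '", syn, "'"),
          stringsAsFactors = FALSE)
      }
      rows <- which(gold$doc_id == id)
      for (g in rows) {
        if (stats::runif(1) >= noise$typo_rate) next
        span_len <- gold$end[g] - gold$start[g]
        pos <- gold$start[g] + sample(seq_len(span_len), 1L) - 1L
        ch <- substr(docs$text[d], pos + 1L, pos + 1L)
        repl <- if (tolower(ch) == "z") "q" else "z"
        docs$text[d] <- splice(docs$text[d], pos, pos + 1L, repl)
        manifest[[length(manifest) + 1L]] <- data.frame(
          doc_id = id, error_type = "LINGUISTIC",
          detail = paste0("typo in '", gold$surface[g], "' at ", pos),
          stringsAsFactors = FALSE)
      }
      for (g in rows) {
        if (stats::runif(1) >= noise$gold_flip_rate) next
        gold$certainty[g] <- if (gold$certainty[g] == "NEGATED") "POSITIVE"
                             else "NEGATED"
        manifest[[length(manifest) + 1L]] <- data.frame(
          doc_id = id, error_type = "ANNOTATION",
          detail = paste0("certainty flipped for '", gold$surface[g], "'"),
          stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(doc_id = character(), error_type = character(),
               detail = character(), stringsAsFactors = FALSE)
  out <- corpus
  out$documents <- docs
  out$gold <- annotation_set("GOLD", "mention", gold)
  out$manifest <- manifest
  out
}
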