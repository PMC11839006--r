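# Sentence-scoped dictionary matching and ConText-style attribute assignment.
# All offsets are 0-based, half-open, into the raw note text, so snippets
# round-trip exactly via substr(text, start + 1, end).

ATTRIBUTE_VALUES <- list(
  certainty   = c("POSITIVE", "NEGATED", "POSSIBLE"),
  experiencer = c("PATIENT", "OTHER"),
  temporality = c("PRESENT", "HISTORICAL", "HYPOTHETICAL"))

ATTRIBUTE_DEFAULTS <- c(certainty = "POSITIVE", experiencer = "PATIENT",
                        temporality = "PRESENT")

#' Construct a clinical note document
#'
#' @param note_id Unique note identifier.
#' @param text Note text (may be empty).
#' @param patient_num,encounter_num Integer patient and encounter numbers.
#' @param note_type_cd Rendered note-type code, e.g. `"STD|LOINC:59258-4"`
#'   or `"CUS|ED_NOTE"`.
#' @param note_datetime Note timestamp string (`"YYYY-MM-DD HH:MM:SS"`).
#' @return A list of class `"clin_document"`.
#' @export
document <- function(note_id, text, patient_num = 0L, encounter_num = 0L,
                     note_type_cd = "CUS|NOTE",
                     note_datetime = "1970-01-01 00:00:00") {
  stopifnot(is_string(note_id), is.character(text), length(text) == 1L)
  structure(list(note_id = note_id, patient_num = as.integer(patient_num),
                 encounter_num = as.integer(encounter_num),
                 note_type_cd = note_type_cd, note_datetime = note_datetime,
                 text = text),
            class = "clin_document")
}

empty_spans <- function() data.frame(start = integer(), end = integer())

#' Segment text into sentence spans
#'
#' Splits on runs of terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace or end-of-text, and on newlines. Returned spans are 0-based
#' half-open character offsets, disjoint, ordered, trimmed of surrounding
#' whitespace, and jointly cover every non-whitespace character. Text without
#' terminal punctuation yields a single span.
#'
#' @param text A single string.
#' @return data.frame with integer columns `start`, `end`.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  if (n == 0L || !grepl("\\S", text)) return(empty_spans())
  m <- gregexpr("[.!?]+[\")\\]']*(\\s+|$)|\\n+", text, perl = TRUE)[[1]]
  cuts <- if (m[1] == -1L) integer() else
    as.integer(m) + attr(m, "match.length") - 1L  # last char of separator, 1-based
  starts <- integer(); ends <- integer()
  a <- 1L
  for (b in c(cuts, n)) {
    if (b < a) next
    piece <- substr(text, a, b)
    lead <- regmatches(piece, regexpr("^\\s*", piece))
    trail <- regmatches(piece, regexpr("\\s*$", piece))
    s <- a + nchar(lead); e <- b - nchar(trail)
    if (s <= e) { starts <- c(starts, s - 1L); ends <- c(ends, e) }
    a <- b + 1L
  }
  data.frame(start = starts, end = ends)
}

# Word-bounded pattern for a literal surface: no word character may abut the
# match on either side.
surface_pattern <- function(surface, is_regex) {
  if (is_regex) surface
  else paste0("(?<![[:alnum:]_])",
              gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", surface, perl = TRUE),
              "(?![[:alnum:]_])")
}

#' Match a lexicon against note text
#'
#' Dictionary matching with word boundaries. Candidate matches from all
#' lexicon entries are resolved by a longest-match-wins rule: candidates are
#' ranked by span length (longest first), then leftmost start, then lexicon
#' order, and kept greedily if they do not overlap an already-kept match.
#' Matching is case-insensitive unless an entry sets `case_sensitive`.
#'
#' @param doc A [document()] (or a bare string).
#' @param rs A [ruleset()].
#' @return data.frame of raw matches: `start`, `end` (0-based half-open),
#'   `matched_text`, `entry` (lexicon row index), concept columns and
#'   `concept_key`.
#' @export
match_lexicon <- function(doc, rs) {
  stopifnot(inherits(rs, "ruleset"))
  text <- if (inherits(doc, "clin_document")) doc$text else doc
  e <- rs$entries
  cand <- list()
  if (nchar(text) > 0L && nrow(e) > 0L) {
    for (i in seq_len(nrow(e))) {
      pat <- surface_pattern(e$surface[i], e$is_regex[i])
      m <- gregexpr(pat, text, perl = TRUE,
                    ignore.case = !(e$case_sensitive[i] || rs$case_sensitive))[[1]]
      if (m[1] == -1L) next
      cand[[length(cand) + 1L]] <-
        data.frame(start = as.integer(m) - 1L,
                   end = as.integer(m) + attr(m, "match.length") - 1L,
                   entry = i)
    }
  }
  if (length(cand) == 0L) {
    out <- data.frame(start = integer(), end = integer(),
                      matched_text = character(), entry = integer())
  } else {
    cand <- do.call(rbind, cand)
    cand <- cand[cand$end > cand$start, , drop = FALSE]
    ord <- order(-(cand$end - cand$start), cand$start, cand$entry)
    cand <- cand[ord, , drop = FALSE]
    keep <- logical(nrow(cand))
    taken_start <- integer(); taken_end <- integer()
    for (i in seq_len(nrow(cand))) {
      if (!any(cand$start[i] < taken_end & taken_start < cand$end[i])) {
        keep[i] <- TRUE
        taken_start <- c(taken_start, cand$start[i])
        taken_end <- c(taken_end, cand$end[i])
      }
    }
    out <- cand[keep, , drop = FALSE]
    out <- out[order(out$start), , drop = FALSE]
    out$matched_text <- substr(rep(text, nrow(out)), out$start + 1L, out$end)
    out <- out[, c("start", "end", "matched_text", "entry")]
  }
  ek <- e[out$entry, c("mode", "vocab", "code", "project", "concept"),
          drop = FALSE]
  rownames(ek) <- NULL
  out <- cbind(out, ek)
  out$concept_key <- if (nrow(out)) concept_key(out) else character()
  rownames(out) <- NULL
  out
}

# Locate word-bounded phrase occurrences (case-insensitive) within a sentence
# substring; returns 0-based offsets relative to the full text.
find_phrases <- function(text, phrases, sent_start, sent_end) {
  res <- list()
  sent <- substr(text, sent_start + 1L, sent_end)
  for (j in seq_along(phrases)) {
    pat <- surface_pattern(phrases[j], is_regex = FALSE)
    m <- gregexpr(pat, sent, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    res[[length(res) + 1L]] <-
      data.frame(idx = j,
                 start = sent_start + as.integer(m) - 1L,
                 end = sent_start + as.integer(m) + attr(m, "match.length") - 1L)
  }
  if (length(res) == 0L)
    data.frame(idx = integer(), start = integer(), end = integer())
  else do.call(rbind, res)
}

#' Assign contextual attributes to raw matches
#'
#' ConText-style scoping: each trigger phrase claims a scope inside its
#' sentence — forward (trigger end to sentence end), backward (sentence start
#' to trigger start), or both — clipped at the nearest termination phrase. A
#' match lying inside a trigger's scope takes that trigger's attribute value;
#' with several competing triggers for one attribute the one nearest the
#' match wins. Matches outside any scope take the defaults
#' POSITIVE/PATIENT/PRESENT.
#'
#' @param matches Raw matches from [match_lexicon()].
#' @param sentences Sentence spans from [segment_sentences()].
#' @param triggers A [context_triggers()] object.
#' @param text The note text the offsets refer to.
#' @return `matches` extended with `certainty`, `experiencer`, `temporality`
#'   and `sentence_snippet` columns.
#' @export
apply_context <- function(matches, sentences, triggers, text) {
  stopifnot(inherits(triggers, "context_triggers"))
  n <- nrow(matches)
  matches$certainty <- rep("POSITIVE", n)
  matches$experiencer <- rep("PATIENT", n)
  matches$temporality <- rep("PRESENT", n)
  matches$sentence_snippet <- rep("", n)
  if (n == 0L) return(matches)
  tr <- triggers$triggers
  for (i in seq_len(n)) {
    si <- which(sentences$start <= matches$start[i] &
                matches$start[i] < sentences$end)
    if (length(si) == 0L) { # match in inter-sentence whitespace: nearest prior
      si <- max(which(sentences$start <= matches$start[i]), 1L)
    }
    s0 <- sentences$start[si[1]]; s1 <- sentences$end[si[1]]
    matches$sentence_snippet[i] <- substr(text, s0 + 1L, s1)
    hits <- find_phrases(text, tr$phrase, s0, s1)
    terms <- find_phrases(text, triggers$terminations, s0, s1)
    if (nrow(hits) == 0L) next
    ms <- matches$start[i]; me <- matches$end[i]
    for (attr_name in c("certainty", "experiencer", "temporality")) {
      attr_cd <- toupper(attr_name)
      rows <- which(tr$attribute[hits$idx] == attr_cd)
      best <- NULL; best_dist <- Inf
      for (h in rows) {
        t0 <- hits$start[h]; t1 <- hits$end[h]
        if (ms < t1 && t0 < me) next  # trigger inside/overlapping the mention
        dir <- tr$direction[hits$idx[h]]
        in_scope <- FALSE
        if (dir %in% c("forward", "bidirectional")) {
          lim <- s1
          after <- terms$start[terms$start >= t1]
          if (length(after)) lim <- min(after)
          if (ms >= t1 && ms < lim) in_scope <- TRUE
        }
        if (!in_scope && dir %in% c("backward", "bidirectional")) {
          lim <- s0
          before <- terms$end[terms$end <= t0]
          if (length(before)) lim <- max(before)
          if (me <= t0 && ms >= lim) in_scope <- TRUE
        }
        if (in_scope) {
          dist <- if (t1 <= ms) ms - t1 else t0 - me
          if (dist < best_dist) { best_dist <- dist; best <- hits$idx[h] }
        }
      }
      if (!is.null(best)) matches[[attr_name]][i] <- tr$value[best]
    }
  }
  matches
}

#' Extract concept mentions from a document
#'
#' Runs the full pipeline — sentence segmentation, dictionary matching, and
#' contextual attribute assignment — for one note. Deterministic for fixed
#' inputs.
#'
#' @param doc A [document()].
#' @param rs A [ruleset()].
#' @return A mention data.frame: document identifiers, `start`/`end` offsets,
#'   `matched_text`, concept columns, `concept_key`, the three contextual
#'   attributes and `sentence_snippet`.
#' @export
extract_mentions <- function(doc, rs) {
  stopifnot(inherits(doc, "clin_document"), inherits(rs, "ruleset"))
  m <- match_lexicon(doc, rs)
  sent <- segment_sentences(doc$text)
  m <- apply_context(m, sent, rs$triggers, doc$text)
  meta <- data.frame(note_id = rep(doc$note_id, nrow(m)),
                     patient_num = rep(doc$patient_num, nrow(m)),
                     encounter_num = rep(doc$encounter_num, nrow(m)),
                     note_type_cd = rep(doc$note_type_cd, nrow(m)),
                     note_datetime = rep(doc$note_datetime, nrow(m)),
                     stringsAsFactors = FALSE)
  out <- cbind(meta, m[, c("start", "end", "matched_text", "mode", "vocab",
                           "code", "project", "concept", "concept_key",
                           "certainty", "experiencer", "temporality",
                           "sentence_snippet")])
  rownames(out) <- NULL
  out
}

#' Extract mentions from a corpus
#'
#' @param docs Corpus data.frame with columns `note_id`, `patient_num`,
#'   `encounter_num`, `note_type_cd`, `note_datetime`, `text` (as produced by
#'   [generate_corpus()] or [read_corpus()]).
#' @param rs A [ruleset()].
#' @return One mention data.frame for the whole corpus.
#' @export
extract_corpus <- function(docs, rs) {
  stopifnot(is.data.frame(docs))
  out <- lapply(seq_len(nrow(docs)), function(i) {
    d <- document(docs$note_id[i], docs$text[i], docs$patient_num[i],
                  docs$encounter_num[i], docs$note_type_cd[i],
                  docs$note_datetime[i])
    extract_mentions(d, rs)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- extract_mentions(document("x", ""), rs)[0, ]
  rownames(res) <- NULL
  res
}
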