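# Project rulesets: the lexicon mapping surface forms to concepts, plus the
# context trigger lists used for certainty/experiencer/temporality.

#' Concept reference
#'
#' A concept is either drawn from a standard terminology (a vocabulary prefix
#' such as `"ICD-10-CM"` plus a code) or from a project's custom terminology
#' (an uppercase project token plus an uppercase concept token, underscores
#' allowed). Exactly one of the two forms is populated.
#'
#' @param mode `"STANDARD"` or `"CUSTOM"`.
#' @param vocab Standard vocabulary prefix (STANDARD only), e.g. `"ICD-10-CM"`.
#' @param code Concept code in that vocabulary (STANDARD only), e.g. `"S92.4"`.
#' @param project Project name token (CUSTOM only), e.g. `"SLEEP"`.
#' @param concept Custom concept token (CUSTOM only), e.g. `"SNORING"`.
#' @return An object of class `"concept_ref"`.
#' @examples
#' concept_ref("STANDARD", vocab = "ICD-10-CM", code = "S92.4")
#' concept_ref("CUSTOM", project = "SLEEP", concept = "SNORING")
#' @export
concept_ref <- function(mode = c("STANDARD", "CUSTOM"), vocab = NULL,
                        code = NULL, project = NULL, concept = NULL) {
  mode <- match.arg(mode)
  if (mode == "STANDARD") {
    check_token(vocab, "vocab")
    check_token(code, "code")
    if (!is.null(project) || !is.null(concept))
      stop("STANDARD concept must not carry project/concept tokens", call. = FALSE)
    ref <- list(mode = mode, vocab = vocab, code = code,
                project = NA_character_, concept = NA_character_)
  } else {
    check_token(project, "project")
    check_token(concept, "concept")
    if (!grepl("^[A-Z][A-Z0-9_]*$", project))
      stop("project must be an uppercase token: ", project, call. = FALSE)
    if (!grepl("^[A-Z][A-Z0-9_]*$", concept))
      stop("concept must be an uppercase token: ", concept, call. = FALSE)
    if (!is.null(vocab) || !is.null(code))
      stop("CUSTOM concept must not carry vocab/code tokens", call. = FALSE)
    ref <- list(mode = mode, vocab = NA_character_, code = NA_character_,
                project = project, concept = concept)
  }
  structure(ref, class = "concept_ref")
}

#' @export
print.concept_ref <- function(x, ...) {
  if (x$mode == "STANDARD")
    cat("<concept_ref> STANDARD ", x$vocab, ":", x$code, "\n", sep = "")
  else
    cat("<concept_ref> CUSTOM ", x$project, ":", x$concept, "\n", sep = "")
  invisible(x)
}

# Canonical "VOCAB:CODE" / "PROJECT:CONCEPT" key used to identify a concept
# across the extractor, the fact encoder and the ontology builder.
concept_key <- function(ref) {
  if (inherits(ref, "concept_ref")) {
    if (ref$mode == "STANDARD") paste0(ref$vocab, ":", ref$code)
    else paste0(ref$project, ":", ref$concept)
  } else {
    ifelse(ref$mode == "STANDARD",
           paste0(ref$vocab, ":", ref$code),
           paste0(ref$project, ":", ref$concept))
  }
}

#' Context trigger set
#'
#' Trigger phrases drive the assignment of contextual attributes to concept
#' mentions. Each trigger carries the attribute it sets (`CERTAINTY`,
#' `EXPERIENCER` or `TEMPORALITY`), the value it assigns, and a scope
#' direction. Termination phrases clip a trigger's scope inside a sentence.
#'
#' @param triggers data.frame with columns `phrase`, `attribute`, `value`,
#'   `direction` (`"forward"`, `"backward"` or `"bidirectional"`).
#' @param terminations Character vector of scope-terminating phrases.
#' @return An object of class `"context_triggers"`.
#' @seealso [default_context_triggers()]
#' @export
context_triggers <- function(triggers, terminations = character()) {
  stopifnot(is.data.frame(triggers),
            all(c("phrase", "attribute", "value", "direction") %in% names(triggers)))
  triggers <- triggers[, c("phrase", "attribute", "value", "direction")]
  if (any(!nzchar(triggers$phrase)))
    stop("trigger phrases must be non-empty", call. = FALSE)
  ok_attr <- c("CERTAINTY", "EXPERIENCER", "TEMPORALITY")
  if (!all(triggers$attribute %in% ok_attr))
    stop("trigger attribute must be one of ", paste(ok_attr, collapse = ", "),
         call. = FALSE)
  allowed <- list(CERTAINTY = c("POSITIVE", "NEGATED", "POSSIBLE"),
                  EXPERIENCER = c("PATIENT", "OTHER"),
                  TEMPORALITY = c("PRESENT", "HISTORICAL", "HYPOTHETICAL"))
  bad <- !mapply(function(a, v) v %in% allowed[[a]],
                 triggers$attribute, triggers$value)
  if (any(bad))
    stop("trigger values outside the closed vocabulary: ",
         paste(triggers$value[bad], collapse = ", "), call. = FALSE)
  if (!all(triggers$direction %in% c("forward", "backward", "bidirectional")))
    stop("trigger direction must be forward, backward or bidirectional",
         call. = FALSE)
  structure(list(triggers = triggers,
                 terminations = as.character(terminations)),
            class = "context_triggers")
}

#' Default English context trigger list
#'
#' A compact general-purpose cue list in the ConText tradition: negation and
#' uncertainty cues for certainty, family-member cues for experiencer, and
#' history/hypothetical cues for temporality, plus conjunction-style
#' termination phrases that clip trigger scope. Rulesets may override it.
#'
#' @return A [context_triggers()] object.
#' @export
default_context_triggers <- function() {
  t <- rbind(
    data.frame(phrase = c("denies", "denied", "no evidence of", "no sign of",
                          "no signs of", "negative for", "without", "no",
                          "not", "absence of", "free of", "ruled out"),
               attribute = "CERTAINTY", value = "NEGATED",
               direction = "forward"),
    data.frame(phrase = c("is ruled out", "was ruled out", "unlikely"),
               attribute = "CERTAINTY", value = "NEGATED",
               direction = "backward"),
    data.frame(phrase = c("possible", "probable", "suspected", "suspect",
                          "may have", "question of", "concern for"),
               attribute = "CERTAINTY", value = "POSSIBLE",
               direction = "forward"),
    data.frame(phrase = c("father", "mother", "brother", "sister", "wife",
                          "husband", "son", "daughter", "family history of",
                          "family member"),
               attribute = "EXPERIENCER", value = "OTHER",
               direction = "forward"),
    data.frame(phrase = c("history of", "h/o", "past medical history",
                          "previously", "in the past"),
               attribute = "TEMPORALITY", value = "HISTORICAL",
               direction = "forward"),
    data.frame(phrase = c("if", "should", "return for", "watch for",
                          "in case of"),
               attribute = "TEMPORALITY", value = "HYPOTHETICAL",
               direction = "forward"))
  context_triggers(t, terminations = c("but", "however", "although",
                                       "aside from", "except", ";"))
}

new_lexicon <- function() {
  data.frame(surface = character(), mode = character(), vocab = character(),
             code = character(), project = character(), concept = character(),
             case_sensitive = logical(), is_regex = logical(),
             stringsAsFactors = FALSE)
}

lexicon_entry_row <- function(surface, ref, case_sensitive = FALSE,
                              is_regex = FALSE) {
  data.frame(surface = surface, mode = ref$mode, vocab = ref$vocab,
             code = ref$code, project = ref$project, concept = ref$concept,
             case_sensitive = case_sensitive, is_regex = is_regex,
             stringsAsFactors = FALSE)
}

#' Construct a project ruleset
#'
#' A ruleset bundles a project's identity (its zero-padded project number and
#' uppercase project name), the lexicon mapping surface forms to concepts, and
#' the context trigger set used for attribute assignment.
#'
#' @param project_num Project number, digits only; zero-padded to `num_width`.
#' @param project_name Uppercase project token, e.g. `"SLEEP"`.
#' @param entries Lexicon as a data.frame with columns `surface`, `mode`,
#'   `vocab`, `code`, `project`, `concept`, `case_sensitive`, `is_regex`.
#'   Helper [lexicon_entry()] builds single rows.
#' @param triggers A [context_triggers()] object; defaults to the shipped
#'   English list.
#' @param num_width Width of the zero-padded project number (default 3).
#' @param case_sensitive Default matching case sensitivity for entries that do
#'   not set their own flag.
#' @return An object of class `"ruleset"`.
#' @examples
#' rs <- ruleset("1", "SLEEP",
#'               entries = lexicon_entry("snoring", "SNORING"))
#' rs$project_num  # "001"
#' @export
ruleset <- function(project_num, project_name, entries = new_lexicon(),
                    triggers = default_context_triggers(), num_width = 3L,
                    case_sensitive = FALSE) {
  if (!grepl("^[0-9]+$", project_num))
    stop("project_num must be digits: ", project_num, call. = FALSE)
  if (nchar(project_num) > num_width)
    stop("project_num wider than num_width (", num_width, "): ", project_num,
         call. = FALSE)
  project_num <- formatC(as.integer(project_num), width = num_width,
                         flag = "0", format = "d")
  check_token(project_name, "project_name")
  stopifnot(is.data.frame(entries), inherits(triggers, "context_triggers"))
  need <- c("surface", "mode", "vocab", "code", "project", "concept",
            "case_sensitive", "is_regex")
  if (!all(need %in% names(entries)))
    stop("lexicon entries missing columns: ",
         paste(setdiff(need, names(entries)), collapse = ", "), call. = FALSE)
  entries <- entries[, need]
  rownames(entries) <- NULL
  structure(list(project_num = project_num, project_name = project_name,
                 num_width = as.integer(num_width),
                 case_sensitive = isTRUE(case_sensitive),
                 entries = entries, triggers = triggers),
            class = "ruleset")
}

#' Build lexicon entry rows
#'
#' Convenience constructor for lexicon rows. A `concept` token of the form
#' `"VOCAB:CODE"` creates a STANDARD entry; a bare uppercase token creates a
#' CUSTOM entry under `project`.
#'
#' @param surface Surface form (term, phrase, or regex).
#' @param concept Concept token (see Details above).
#' @param project Project name used for CUSTOM entries.
#' @param case_sensitive Match case sensitively.
#' @param is_regex Treat `surface` as a Perl regular expression.
#' @return A one-row (or, vectorized over `surface`/`concept`, multi-row)
#'   lexicon data.frame.
#' @export
lexicon_entry <- function(surface, concept, project = "PROJECT",
                          case_sensitive = FALSE, is_regex = FALSE) {
  n <- max(length(surface), length(concept))
  surface <- rep_len(surface, n); concept <- rep_len(concept, n)
  case_sensitive <- rep_len(case_sensitive, n)
  is_regex <- rep_len(is_regex, n)
  rows <- lapply(seq_len(n), function(i) {
    ref <- parse_concept_token(concept[i], project)
    lexicon_entry_row(surface[i], ref, case_sensitive[i], is_regex[i])
  })
  do.call(rbind, rows)
}

# "ICD-10-CM:S92.4" -> STANDARD; "SNORING" -> CUSTOM under the project.
parse_concept_token <- function(token, project) {
  if (grepl(":", token, fixed = TRUE)) {
    parts <- strsplit(token, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(nzchar(parts)))
      stop("malformed concept token: ", token, call. = FALSE)
    concept_ref("STANDARD", vocab = parts[1], code = parts[2])
  } else {
    concept_ref("CUSTOM", project = project, concept = token)
  }
}

#' Load a ruleset from a project config file
#'
#' The on-disk format is a small YAML config naming the project plus a
#' tab-delimited lexicon and (optionally) a tab-delimited trigger file,
#' resolved relative to the config's directory:
#'
#' ```yaml
#' project_num: "001"
#' project_name: SLEEP
#' lexicon: lexicon.tsv      # surface <TAB> concept [<TAB> flags]
#' triggers: triggers.tsv    # optional; defaults to the shipped list
#' ```
#'
#' Lexicon lines are `surface<TAB>concept` with an optional third field of
#' comma-separated flags (`cs` = case sensitive, `re` = regex). The concept
#' field is either `VOCAB:CODE` (standard terminology) or a bare uppercase
#' token (custom concept under the project). Lines starting with `#` and
#' blank lines are ignored. Trigger lines are
#' `phrase<TAB>attribute<TAB>value<TAB>direction`, with
#' `phrase<TAB>TERMINATION` rows declaring termination phrases.
#'
#' @param path Path to the YAML config.
#' @return A validated [ruleset()].
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop("ruleset config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (f in c("project_num", "project_name", "lexicon"))
    if (is.null(cfg[[f]])) stop("ruleset config missing field: ", f, call. = FALSE)
  dir <- dirname(path)
  lex_path <- file.path(dir, cfg$lexicon)
  if (!file.exists(lex_path)) stop("lexicon file not found: ", lex_path, call. = FALSE)
  entries <- read_lexicon(lex_path, project = cfg$project_name)
  triggers <- if (!is.null(cfg$triggers)) {
    trig_path <- file.path(dir, cfg$triggers)
    if (!file.exists(trig_path)) stop("trigger file not found: ", trig_path, call. = FALSE)
    read_trigger_file(trig_path)
  } else default_context_triggers()
  rs <- ruleset(as.character(cfg$project_num), cfg$project_name,
                entries = entries, triggers = triggers,
                num_width = cfg$num_width %||% 3L,
                case_sensitive = cfg$case_sensitive %||% FALSE)
  issues <- validate_ruleset(rs)
  if (any(issues$severity == "error"))
    stop("invalid ruleset ", path, ":\n  ",
         paste(issues$message[issues$severity == "error"], collapse = "\n  "),
         call. = FALSE)
  rs
}

read_lexicon <- function(path, project) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) {
    warning("lexicon file has no entries: ", path, call. = FALSE)
    return(new_lexicon())
  }
  rows <- lapply(keep, function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[1]) || !nzchar(parts[2]))
      stop("malformed lexicon line ", i, " in ", path, ": ", lines[i],
           call. = FALSE)
    flags <- if (length(parts) >= 3L)
      strsplit(parts[3], ",", fixed = TRUE)[[1]] else character()
    ref <- tryCatch(parse_concept_token(parts[2], project),
                    error = function(e)
                      stop("lexicon line ", i, " in ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    lexicon_entry_row(parts[1], ref,
                      case_sensitive = "cs" %in% flags,
                      is_regex = "re" %in% flags)
  })
  do.call(rbind, rows)
}

read_trigger_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  trig <- list(); term <- character()
  for (i in keep) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[2] == "TERMINATION") {
      term <- c(term, parts[1])
    } else if (length(parts) == 4L) {
      trig[[length(trig) + 1L]] <-
        data.frame(phrase = parts[1], attribute = parts[2], value = parts[3],
                   direction = parts[4], stringsAsFactors = FALSE)
    } else {
      stop("malformed trigger line ", i, " in ", path, ": ", lines[i],
           call. = FALSE)
    }
  }
  if (length(trig) == 0L) stop("trigger file has no triggers: ", path, call. = FALSE)
  context_triggers(do.call(rbind, trig), terminations = term)
}

#' Write a ruleset to a directory
#'
#' Emits `config.yaml`, `lexicon.tsv` and `triggers.tsv` in the format
#' [read_ruleset()] loads, such that load -> write -> load is the identity on
#' ruleset content.
#'
#' @param rs A [ruleset()].
#' @param dir Output directory (created if missing).
#' @return The config path, invisibly.
#' @export
write_ruleset <- function(rs, dir) {
  stopifnot(inherits(rs, "ruleset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- rs$entries
  token <- ifelse(e$mode == "STANDARD", paste0(e$vocab, ":", e$code), e$concept)
  flags <- paste0(ifelse(e$case_sensitive, "cs", ""),
                  ifelse(e$case_sensitive & e$is_regex, ",", ""),
                  ifelse(e$is_regex, "re", ""))
  lex <- ifelse(nzchar(flags), paste(e$surface, token, flags, sep = "\t"),
                paste(e$surface, token, sep = "\t"))
  writeLines(lex, file.path(dir, "lexicon.tsv"), useBytes = TRUE)
  tr <- rs$triggers$triggers
  trig_lines <- c(paste(tr$phrase, tr$attribute, tr$value, tr$direction, sep = "\t"),
                  if (length(rs$triggers$terminations))
                    paste(rs$triggers$terminations, "TERMINATION", sep = "\t"))
  writeLines(trig_lines, file.path(dir, "triggers.tsv"), useBytes = TRUE)
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(project_num = rs$project_num,
                        project_name = rs$project_name,
                        num_width = rs$num_width,
                        case_sensitive = rs$case_sensitive,
                        lexicon = "lexicon.tsv",
                        triggers = "triggers.tsv"), cfg)
  invisible(cfg)
}

#' Validate a ruleset
#'
#' Checks the structural invariants of a ruleset and returns the problems
#' found as data, not exceptions: forbidden delimiters in surfaces or tokens,
#' empty or non-compiling surfaces, duplicate surfaces within a concept, and
#' the same surface mapped to two different concepts (ambiguity).
#'
#' @param rs A [ruleset()].
#' @return A data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `location`, `message`; zero rows when the ruleset is clean.
#' @export
validate_ruleset <- function(rs) {
  stopifnot(inherits(rs, "ruleset"))
  issues <- no_issues()
  e <- rs$entries
  if (nrow(e) == 0L) return(issues)
  keys <- concept_key(e)
  for (i in seq_len(nrow(e))) {
    loc <- paste0("entry ", i, " ('", e$surface[i], "')")
    if (!nzchar(e$surface[i]))
      issues <- rbind(issues, new_issue("error", loc, "empty surface"))
    if (grepl("|", e$surface[i], fixed = TRUE))
      issues <- rbind(issues, new_issue("error", loc,
        paste0("surface contains forbidden delimiter '|': ", e$surface[i])))
    toks <- if (e$mode[i] == "STANDARD") c(e$vocab[i], e$code[i])
            else c(e$project[i], e$concept[i])
    if (any(grepl("[|:]", toks)))
      issues <- rbind(issues, new_issue("error", loc,
        "concept tokens contain forbidden delimiter '|' or ':'"))
    if (e$is_regex[i]) {
      ok <- tryCatch({ grepl(e$surface[i], "x", perl = TRUE); TRUE },
                     error = function(err) FALSE, warning = function(w) FALSE)
      if (!ok)
        issues <- rbind(issues, new_issue("error", loc,
          paste0("regex does not compile: ", e$surface[i])))
    }
  }
  folded <- tolower(e$surface)
  for (s in unique(folded[duplicated(folded)])) {
    idx <- which(folded == s)
    if (length(unique(keys[idx])) > 1L) {
      issues <- rbind(issues, new_issue("error",
        paste0("entries ", paste(idx, collapse = ",")),
        paste0("ambiguous surface '", s, "' maps to multiple concepts: ",
               paste(unique(keys[idx]), collapse = ", "))))
    } else {
      issues <- rbind(issues, new_issue("warning",
        paste0("entries ", paste(idx, collapse = ",")),
        paste0("duplicate surface '", s, "' within concept ", keys[idx[1]])))
    }
  }
  issues
}

#' @export
print.ruleset <- function(x, ...) {
  cat("<ruleset> project ", x$project_num, " (", x$project_name, ")\n",
      "  lexicon entries: ", nrow(x$entries),
      " (", sum(x$entries$mode == "STANDARD"), " standard, ",
      sum(x$entries$mode == "CUSTOM"), " custom)\n",
      "  context triggers: ", nrow(x$triggers$triggers),
      ", terminations: ", length(x$triggers$terminations), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ruleset <- function(object, ...) {
  print(object)
  if (nrow(object$entries)) {
    cat("  concepts:\n")
    keys <- sort(unique(concept_key(object$entries)))
    for (k in keys) cat("    -", k, "\n")
  }
  invisible(object)
}
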