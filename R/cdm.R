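# Bit-exact encoding of mentions as i2b2 observation_fact rows.
#
# CONCEPT_CD templates:
#   standard terminology:  NLP|<PROJECT_NUM>|<VOCAB_PREFIX>:<CODE>
#   custom terminology:    NLP|<PROJECT_NUM>|CUSTOM|<PROJECT_NAME>:<CONCEPT>
# MODIFIER_CD template:    NLP|<ATTRIBUTE>:<VALUE>
# The "NLP|" prefix is what separates NLP-derived facts from structured EHR
# facts sharing the same table.

FACT_COLUMNS <- c("patient_num", "encounter_num", "concept_cd", "provider_id",
                  "start_date", "modifier_cd", "instance_num", "valtype_cd",
                  "tval_char", "nval_num", "observation_blob",
                  "cohort_query_id", "note_type_cd")

#' Encoding options for the fact table
#'
#' @param project_num Digit string identifying the project (zero-padded).
#' @param cohort_query_id Network cohort Query ID stamped on every row
#'   (optional; `NA` to omit).
#' @param include_blob Populate `observation_blob` with the sentence snippet.
#'   Off by default: snippets may carry protected health information.
#' @param include_extra_cols Emit the two extension columns
#'   (`cohort_query_id`, `note_type_cd`); switch off for vanilla i2b2 schemas.
#' @param provider_id Value for the `provider_id` column; `"NLP@"` marks rows
#'   produced by an NLP pipeline.
#' @param max_len Length cap for `concept_cd` (common i2b2 DDL uses
#'   VARCHAR(50)); over-length codes are an error, never truncated.
#' @return A list of class `"encode_options"`.
#' @export
encode_options <- function(project_num = "001", cohort_query_id = NA_character_,
                           include_blob = FALSE, include_extra_cols = TRUE,
                           provider_id = "NLP@", max_len = 50L) {
  if (!grepl("^[0-9]+$", project_num))
    stop("project_num must be digits: ", project_num, call. = FALSE)
  structure(list(project_num = project_num,
                 cohort_query_id = cohort_query_id,
                 include_blob = isTRUE(include_blob),
                 include_extra_cols = isTRUE(include_extra_cols),
                 provider_id = provider_id, max_len = as.integer(max_len)),
            class = "encode_options")
}

#' Encode a concept reference as an i2b2 CONCEPT_CD
#'
#' @param ref A [concept_ref()] (or list with the same fields).
#' @param project_num Digit string, e.g. `"001"`.
#' @param max_len Maximum code length; exceeding it is an error.
#' @return The CONCEPT_CD string, e.g. `"NLP|001|ICD-10-CM:S92.4"` or
#'   `"NLP|001|CUSTOM|SLEEP:SNORING"`.
#' @export
encode_concept_cd <- function(ref, project_num, max_len = 50L) {
  if (!grepl("^[0-9]+$", project_num))
    stop("project_num must be digits: ", project_num, call. = FALSE)
  cd <- if (ref$mode == "STANDARD") {
    check_token(ref$vocab, "vocab"); check_token(ref$code, "code")
    paste0("NLP|", project_num, "|", ref$vocab, ":", ref$code)
  } else if (ref$mode == "CUSTOM") {
    check_token(ref$project, "project"); check_token(ref$concept, "concept")
    paste0("NLP|", project_num, "|CUSTOM|", ref$project, ":", ref$concept)
  } else stop("unknown concept mode: ", ref$mode, call. = FALSE)
  if (nchar(cd) > max_len)
    stop("concept_cd exceeds ", max_len, " characters: ", cd, call. = FALSE)
  cd
}

#' Parse an i2b2 CONCEPT_CD back to a concept reference
#'
#' Total inverse of [encode_concept_cd()] on its range. Codes that do not
#' start with `"NLP|"` are structured-EHR codes, classified as `NOT_NLP`
#' rather than rejected (the prefix is the filter separating NLP-derived from
#' structured facts); strings that start with `"NLP|"` but match neither
#' template are an error.
#'
#' @param cd A CONCEPT_CD string.
#' @return For NLP codes, `list(ref = concept_ref, project_num = ...)`; for
#'   structured codes, `list(ref = NULL, project_num = NULL, not_nlp = TRUE)`.
#' @export
parse_concept_cd <- function(cd) {
  stopifnot(is_string(cd))
  if (!startsWith(cd, "NLP|"))
    return(list(ref = NULL, project_num = NULL, not_nlp = TRUE))
  m <- regmatches(cd, regexec("^NLP\\|([0-9]+)\\|CUSTOM\\|([^|:]+):([^|:]+)$", cd))[[1]]
  if (length(m) == 4L)
    return(list(ref = concept_ref("CUSTOM", project = m[3], concept = m[4]),
                project_num = m[2], not_nlp = FALSE))
  m <- regmatches(cd, regexec("^NLP\\|([0-9]+)\\|([^|:]+):([^|:]+)$", cd))[[1]]
  if (length(m) == 4L)
    return(list(ref = concept_ref("STANDARD", vocab = m[3], code = m[4]),
                project_num = m[2], not_nlp = FALSE))
  stop("malformed NLP concept_cd: ", cd, call. = FALSE)
}

#' Test which codes are NLP-derived
#'
#' The `"NLP|"` prefix partitions a mixed observation_fact table into
#' NLP-derived and structured rows.
#'
#' @param cd Character vector of CONCEPT_CD values.
#' @return Logical vector.
#' @export
is_nlp_code <- function(cd) startsWith(cd, "NLP|")

#' Encode a contextual attribute as an i2b2 MODIFIER_CD
#'
#' @param attribute Attribute token, e.g. `"EXPERIENCER"`.
#' @param value Value token, e.g. `"PATIENT"`.
#' @return `"NLP|<ATTRIBUTE>:<VALUE>"`, e.g. `"NLP|EXPERIENCER:PATIENT"`.
#' @export
encode_modifier_cd <- function(attribute, value) {
  check_token(attribute, "attribute")
  check_token(value, "value")
  paste0("NLP|", attribute, ":", value)
}

#' Render a note-type code
#'
#' @param code Code string; for the STD scheme, the code within `vocabulary`.
#' @param scheme `"STD"` (standard terminology, e.g. LOINC document ontology)
#'   or `"CUS"` (site-local custom term).
#' @param vocabulary Vocabulary name for STD, e.g. `"LOINC"`.
#' @return `"STD|<vocab>:<code>"` or `"CUS|<code>"`.
#' @examples
#' note_type_cd("59258-4", "STD", "LOINC")  # "STD|LOINC:59258-4"
#' note_type_cd("ED_NOTE")                  # "CUS|ED_NOTE"
#' @export
note_type_cd <- function(code, scheme = c("CUS", "STD"), vocabulary = NULL) {
  scheme <- match.arg(scheme)
  check_token(code, "code")
  if (scheme == "STD") {
    check_token(vocabulary, "vocabulary")
    paste0("STD|", vocabulary, ":", code)
  } else paste0("CUS|", code)
}

empty_facts <- function() {
  f <- data.frame(patient_num = integer(), encounter_num = integer(),
                  concept_cd = character(), provider_id = character(),
                  start_date = character(), modifier_cd = character(),
                  instance_num = integer(), valtype_cd = character(),
                  tval_char = character(), nval_num = numeric(),
                  observation_blob = character(),
                  cohort_query_id = character(), note_type_cd = character(),
                  stringsAsFactors = FALSE)
  f
}

mention_ref <- function(m) {
  if (m[["mode"]] == "STANDARD")
    list(mode = "STANDARD", vocab = m[["vocab"]], code = m[["code"]])
  else
    list(mode = "CUSTOM", project = m[["project"]], concept = m[["concept"]])
}

#' Encode one mention as observation_fact rows
#'
#' Emits one base row (`modifier_cd = "@"`, the i2b2 convention for "no
#' modifier"), one modifier row per contextual attribute, and one row per
#' numeric attribute. All rows of a mention share
#' (patient_num, encounter_num, concept_cd, start_date, instance_num), which
#' is what groups them back into a single source mention.
#'
#' @param m One mention: a single row of [extract_mentions()] output (or a
#'   list with the same fields).
#' @param opts An [encode_options()] object.
#' @param instance_num Instance number distinguishing repeat mentions of the
#'   same concept in the same note; see [mentions_to_facts()].
#' @param numeric_attrs Optional data.frame of numeric attributes with
#'   columns `name`, `value`, `unit` (e.g. DOSE 325 "mg"); encoded as
#'   modifier rows `"NLP|<NAME>:VALUE"` with `valtype_cd = "N"`,
#'   `nval_num = value`, `tval_char = unit`.
#' @return A fact data.frame with one row per emitted fact.
#' @export
mention_to_facts <- function(m, opts = encode_options(), instance_num = 1L,
                             numeric_attrs = NULL) {
  if (is.data.frame(m)) { stopifnot(nrow(m) == 1L); m <- as.list(m) }
  cd <- encode_concept_cd(mention_ref(m), opts$project_num, opts$max_len)
  base <- data.frame(
    patient_num = as.integer(m$patient_num),
    encounter_num = as.integer(m$encounter_num),
    concept_cd = cd, provider_id = opts$provider_id,
    start_date = m$note_datetime, modifier_cd = "@",
    instance_num = as.integer(instance_num), valtype_cd = "",
    tval_char = "", nval_num = NA_real_,
    observation_blob = if (opts$include_blob) m$sentence_snippet else "",
    cohort_query_id = if (is.na(opts$cohort_query_id)) "" else opts$cohort_query_id,
    note_type_cd = m$note_type_cd %||% "",
    stringsAsFactors = FALSE)
  rows <- list(base)
  for (attr_name in c("certainty", "experiencer", "temporality")) {
    r <- base
    r$modifier_cd <- encode_modifier_cd(toupper(attr_name), m[[attr_name]])
    r$observation_blob <- ""
    rows[[length(rows) + 1L]] <- r
  }
  if (!is.null(numeric_attrs) && nrow(numeric_attrs) > 0L) {
    for (i in seq_len(nrow(numeric_attrs))) {
      if (!is.finite(numeric_attrs$value[i]))
        stop("numeric attribute value must be finite: ",
             numeric_attrs$name[i], call. = FALSE)
      r <- base
      r$modifier_cd <- encode_modifier_cd(numeric_attrs$name[i], "VALUE")
      r$valtype_cd <- "N"
      r$nval_num <- as.numeric(numeric_attrs$value[i])
      r$tval_char <- if ("unit" %in% names(numeric_attrs))
        numeric_attrs$unit[i] else ""
      r$observation_blob <- ""
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  if (!opts$include_extra_cols)
    out <- out[, setdiff(FACT_COLUMNS, c("cohort_query_id", "note_type_cd"))]
  rownames(out) <- NULL
  out
}

#' Encode a mention table as an observation_fact table
#'
#' Assigns `instance_num` as a running counter (starting at 1) within each
#' (patient_num, encounter_num, concept_cd, start_date) group, so repeat
#' mentions of one concept in one note stay distinguishable, then encodes
#' every mention via [mention_to_facts()].
#'
#' @param mentions Mention data.frame from [extract_mentions()] /
#'   [extract_corpus()].
#' @param opts An [encode_options()] object.
#' @return The combined fact data.frame.
#' @export
mentions_to_facts <- function(mentions, opts = encode_options()) {
  if (nrow(mentions) == 0L) {
    f <- empty_facts()
    if (!opts$include_extra_cols)
      f <- f[, setdiff(FACT_COLUMNS, c("cohort_query_id", "note_type_cd"))]
    return(f)
  }
  cds <- vapply(seq_len(nrow(mentions)), function(i)
    encode_concept_cd(mention_ref(as.list(mentions[i, ])), opts$project_num,
                      opts$max_len), character(1))
  grp <- paste(mentions$patient_num, mentions$encounter_num, cds,
               mentions$note_datetime, sep = "\r")
  inst <- stats::ave(seq_len(nrow(mentions)), grp, FUN = seq_along)
  out <- lapply(seq_len(nrow(mentions)), function(i)
    mention_to_facts(mentions[i, ], opts, instance_num = inst[i]))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write an observation_fact table to CSV
#'
#' RFC 4180 CSV, UTF-8, with the i2b2 observation_fact column set (plus the
#' two extension columns when present). `NA` numeric values are written as
#' empty fields. [read_facts()] is its exact inverse.
#'
#' @param facts Fact data.frame.
#' @param path Output path.
#' @return The number of data rows written, invisibly.
#' @export
write_facts <- function(facts, path) {
  utils::write.csv(facts, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(nrow(facts))
}

#' Read an observation_fact CSV
#'
#' @param path Path written by [write_facts()].
#' @return Fact data.frame; errors if the column set does not match the
#'   observation_fact schema.
#' @export
read_facts <- function(path) {
  x <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  core <- setdiff(FACT_COLUMNS, c("cohort_query_id", "note_type_cd"))
  if (!all(core %in% names(x)) || !all(names(x) %in% FACT_COLUMNS))
    stop("file does not match the observation_fact schema: ", path,
         call. = FALSE)
  for (col in c("patient_num", "encounter_num", "instance_num"))
    x[[col]] <- as.integer(x[[col]])
  x$nval_num <- suppressWarnings(as.numeric(ifelse(x$nval_num == "", NA, x$nval_num)))
  x
}

#' Render facts as SQL INSERT statements
#'
#' @param facts Fact data.frame.
#' @param table Target table name.
#' @return Character vector, one INSERT per fact row.
#' @export
facts_to_sql <- function(facts, table = "observation_fact") {
  cols <- paste(names(facts), collapse = ", ")
  vapply(seq_len(nrow(facts)), function(i) {
    vals <- vapply(names(facts), function(col) {
      v <- facts[[col]][i]
      if (is.numeric(v)) { if (is.na(v)) "NULL" else format(v, scientific = FALSE) }
      else paste0("'", gsub("'", "''", v), "'")
    }, character(1))
    paste0("INSERT INTO ", table, " (", cols, ") VALUES (",
           paste(vals, collapse = ", "), ");")
  }, character(1))
}
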