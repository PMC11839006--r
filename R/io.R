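# Plain-text interchange: note corpora (CSV or JSON-lines), mention tables
# (JSON-lines), and annotation sets (CSV).

CORPUS_COLUMNS <- c("note_id", "patient_num", "encounter_num", "note_type_cd",
                    "note_datetime", "text")

#' Read a note corpus
#'
#' Accepts CSV or JSON-lines (one JSON object per line), detected by file
#' extension (`.jsonl`/`.ndjson` vs anything else). Required columns/keys:
#' `note_id`, `patient_num`, `encounter_num`, `note_type_cd`,
#' `note_datetime`, `text`.
#'
#' @param path Input path.
#' @return Corpus data.frame.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    rows <- lapply(lines, function(l)
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
    x <- do.call(rbind, rows)
  } else {
    x <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  }
  if (!all(CORPUS_COLUMNS %in% names(x)))
    stop("corpus missing columns: ",
         paste(setdiff(CORPUS_COLUMNS, names(x)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$note_id))
    stop("note_id values must be unique within a corpus", call. = FALSE)
  x$patient_num <- as.integer(x$patient_num)
  x$encounter_num <- as.integer(x$encounter_num)
  x[, CORPUS_COLUMNS]
}

#' Write a note corpus to CSV
#'
#' @param docs Corpus data.frame.
#' @param path Output path.
#' @return Row count, invisibly.
#' @export
write_corpus <- function(docs, path) {
  utils::write.csv(docs[, CORPUS_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(nrow(docs))
}

#' Write mentions as JSON-lines
#'
#' @param mentions Mention data.frame from [extract_corpus()].
#' @param path Output path.
#' @return Row count, invisibly.
#' @export
write_mentions <- function(mentions, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(mentions)))
    writeLines(jsonlite::toJSON(as.list(mentions[i, ]), auto_unbox = TRUE,
                                na = "null"), con)
  invisible(nrow(mentions))
}

#' Read a mention JSON-lines file
#'
#' @param path Path written by [write_mentions()].
#' @return Mention data.frame.
#' @export
read_mentions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out
}

#' Write an annotation set to CSV
#'
#' Columns: `doc_id`, (`start`, `end`, `concept` for mention unit or `label`
#' otherwise), then `standard` and `unit` stamped on every row.
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return Row count, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  x <- ann$labels
  x$standard <- ann$standard
  x$unit <- ann$unit
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(nrow(x))
}

#' Read an annotation set from CSV
#'
#' @param path Path written by [write_annotations()].
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  x <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("standard", "unit") %in% names(x)))
    stop("annotation file missing standard/unit columns: ", path, call. = FALSE)
  standard <- unique(x$standard); unit <- unique(x$unit)
  if (length(standard) != 1L || length(unit) != 1L)
    stop("annotation file mixes standards or units: ", path, call. = FALSE)
  labels <- x[, setdiff(names(x), c("standard", "unit")), drop = FALSE]
  for (col in intersect(c("start", "end", "cue_start", "cue_end"), names(labels)))
    labels[[col]] <- as.integer(labels[[col]])
  annotation_set(standard, unit, labels)
}
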