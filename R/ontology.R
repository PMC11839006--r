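# i2b2 metadata (ontology) table generation: the Note Types tree built on the
# LOINC document-ontology axes, and per-project Clinical Concepts subtrees
# whose leaf basecodes are the encoded CONCEPT_CDs — the join that makes
# NLP-derived facts queryable.

ONTOLOGY_COLUMNS <- c("c_hlevel", "c_fullname", "c_name", "c_basecode",
                      "c_visualattributes", "c_tooltip", "c_facttablecolumn",
                      "c_tablename", "c_columnname", "c_operator", "c_dimcode")

path_segments <- function(fullname) {
  s <- strsplit(fullname, "\\", fixed = TRUE)[[1]]
  s[nzchar(s)]
}

parent_path <- function(fullname) {
  seg <- path_segments(fullname)
  if (length(seg) <= 1L) return(NA_character_)
  paste0("\\", paste(seg[-length(seg)], collapse = "\\"), "\\")
}

ontology_row <- function(fullname, name, basecode = "", leaf = FALSE,
                         tooltip = name, facttablecolumn = "concept_cd",
                         tablename = "concept_dimension",
                         columnname = "concept_path", operator = "LIKE") {
  data.frame(c_hlevel = length(path_segments(fullname)) - 1L,
             c_fullname = fullname, c_name = name, c_basecode = basecode,
             c_visualattributes = if (leaf) "LA" else "FA",
             c_tooltip = tooltip, c_facttablecolumn = facttablecolumn,
             c_tablename = tablename, c_columnname = columnname,
             c_operator = operator, c_dimcode = fullname,
             stringsAsFactors = FALSE)
}

# Folder rows for every ancestor level of `root` ("\ENACT\NLP\" -> rows for
# \ENACT\ and \ENACT\NLP\), so the emitted table satisfies the parent-exists
# invariant on its own.
root_folders <- function(root) {
  seg <- path_segments(root)
  rows <- lapply(seq_along(seg), function(k)
    ontology_row(paste0("\\", paste(seg[seq_len(k)], collapse = "\\"), "\\"),
                 seg[k]))
  do.call(rbind, rows)
}

display_name <- function(token) {
  token <- gsub("_", " ", token, fixed = TRUE)
  gsub("\\b([a-z])", "\\U\\1", tolower(token), perl = TRUE)
}

#' Build the Clinical Concepts by Project subtree for a ruleset
#'
#' Emits the i2b2 metadata rows for one project: folder rows for the root
#' path levels, one folder for the project, and one leaf per distinct concept
#' in the ruleset's lexicon. Each leaf's `c_basecode` is the
#' [encode_concept_cd()] encoding of that concept, which is exactly what
#' links the ontology to the fact table. Output ordering is deterministic
#' (sorted by concept key), so rebuilding from the same ruleset is
#' byte-identical.
#'
#' @param rs A [ruleset()].
#' @param root Backslash-delimited path the subtree hangs under.
#' @param names Optional named character vector overriding display names,
#'   keyed by concept key (`"SLEEP:SNORING"`).
#' @return An ontology-node data.frame (see [validate_hierarchy()]).
#' @export
build_project_subtree <- function(rs, root = "\\ENACT\\NLP\\", names = NULL) {
  stopifnot(inherits(rs, "ruleset"))
  issues <- validate_ruleset(rs)
  if (any(issues$severity == "error"))
    stop("ruleset fails validation; fix before building an ontology",
         call. = FALSE)
  nodes <- root_folders(root)
  proj_path <- paste0(root, rs$project_name, "\\")
  nodes <- rbind(nodes, ontology_row(proj_path, display_name(rs$project_name),
                                     tooltip = paste("Project", rs$project_num,
                                                     rs$project_name)))
  e <- rs$entries
  if (nrow(e)) {
    keys <- concept_key(e)
    uniq <- !duplicated(keys)
    e <- e[uniq, , drop = FALSE]; keys <- keys[uniq]
    ord <- order(keys)
    e <- e[ord, , drop = FALSE]; keys <- keys[ord]
    disp <- vapply(seq_len(nrow(e)), function(i) {
      if (!is.null(names) && keys[i] %in% base::names(names))
        return(unname(names[keys[i]]))
      if (e$mode[i] == "STANDARD") paste(e$vocab[i], e$code[i])
      else display_name(e$concept[i])
    }, character(1))
    if (anyDuplicated(disp)) {
      warning("duplicate concept display names disambiguated with suffixes",
              call. = FALSE)
      disp <- make.unique(disp, sep = " #")
    }
    for (i in seq_len(nrow(e))) {
      ref <- mention_ref(as.list(e[i, ]))
      nodes <- rbind(nodes, ontology_row(
        paste0(proj_path, disp[i], "\\"), disp[i],
        basecode = encode_concept_cd(ref, rs$project_num), leaf = TRUE,
        tooltip = keys[i]))
    }
  }
  rownames(nodes) <- NULL
  nodes
}

#' Note-type ontology axes
#'
#' The five axes of the LOINC document ontology. Each axis is a character
#' vector of controlled terms; an element of the form `"VOCAB:CODE"` is a
#' standard-terminology term (leaf basecode `"STD|VOCAB:CODE"`), any other
#' token a custom term (`"CUS|<token>"`). Names, when given, become display
#' names.
#'
#' @param type_of_service,kind_of_document,setting,role,subject_matter_domain
#'   Character vectors of terms, each non-empty with unique values.
#' @return A named list of class `"note_type_axes"`.
#' @export
note_type_axes <- function(type_of_service, kind_of_document, setting, role,
                           subject_matter_domain) {
  axes <- list(type_of_service = type_of_service,
               kind_of_document = kind_of_document,
               setting = setting, role = role,
               subject_matter_domain = subject_matter_domain)
  for (a in names(axes)) {
    if (length(axes[[a]]) == 0L || any(!nzchar(axes[[a]])))
      stop("axis '", a, "' must be a non-empty list of terms", call. = FALSE)
    if (anyDuplicated(axes[[a]]))
      stop("axis '", a, "' has duplicate terms", call. = FALSE)
  }
  structure(axes, class = "note_type_axes")
}

#' Build the Note Types subtree
#'
#' One folder per document-ontology axis, one leaf per controlled term. Leaf
#' basecodes use the note-type rendering (`"STD|LOINC:59258-4"`,
#' `"CUS|ED_NOTE"`).
#'
#' @param axes A [note_type_axes()] object.
#' @param root Path the subtree hangs under.
#' @return An ontology-node data.frame.
#' @export
build_note_type_subtree <- function(axes, root = "\\ENACT\\Note Types\\") {
  stopifnot(inherits(axes, "note_type_axes"))
  nodes <- root_folders(root)
  for (a in names(axes)) {
    axis_disp <- display_name(a)
    axis_path <- paste0(root, axis_disp, "\\")
    nodes <- rbind(nodes, ontology_row(axis_path, axis_disp))
    terms <- axes[[a]]
    disp <- if (!is.null(names(terms)) && any(nzchar(names(terms))))
      ifelse(nzchar(names(terms)), names(terms), terms) else terms
    for (i in seq_along(terms)) {
      base <- if (grepl(":", terms[i], fixed = TRUE)) {
        parts <- strsplit(terms[i], ":", fixed = TRUE)[[1]]
        note_type_cd(parts[2], "STD", parts[1])
      } else note_type_cd(terms[i], "CUS")
      nodes <- rbind(nodes, ontology_row(paste0(axis_path, disp[i], "\\"),
                                         disp[i], basecode = base,
                                         leaf = TRUE, tooltip = base,
                                         facttablecolumn = "note_type_cd",
                                         tablename = "observation_fact",
                                         columnname = "note_type_cd",
                                         operator = "="))
    }
  }
  rownames(nodes) <- NULL
  nodes
}

#' Validate an ontology node table
#'
#' Table-wide invariant checks: `c_hlevel` must equal the path depth minus
#' one, every non-root node's parent path must exist in the table, fullnames
#' must be unique, leaves must carry a basecode and folders must not.
#'
#' @param nodes Ontology-node data.frame.
#' @return Issue data.frame (`severity`, `location`, `message`); zero rows
#'   when clean.
#' @export
validate_hierarchy <- function(nodes) {
  issues <- no_issues()
  if (nrow(nodes) == 0L) return(issues)
  for (i in seq_len(nrow(nodes))) {
    fn <- nodes$c_fullname[i]
    depth <- length(path_segments(fn)) - 1L
    if (nodes$c_hlevel[i] != depth)
      issues <- rbind(issues, new_issue("error", fn,
        paste0("c_hlevel ", nodes$c_hlevel[i], " != path depth ", depth)))
    pp <- parent_path(fn)
    if (!is.na(pp) && !(pp %in% nodes$c_fullname))
      issues <- rbind(issues, new_issue("error", fn,
        paste0("orphan node: parent path ", pp, " missing")))
    if (nodes$c_visualattributes[i] == "LA" && !nzchar(nodes$c_basecode[i]))
      issues <- rbind(issues, new_issue("error", fn, "leaf with empty c_basecode"))
    if (nodes$c_visualattributes[i] == "FA" && nzchar(nodes$c_basecode[i]))
      issues <- rbind(issues, new_issue("warning", fn, "folder carries a basecode"))
  }
  dup <- nodes$c_fullname[duplicated(nodes$c_fullname)]
  for (d in unique(dup))
    issues <- rbind(issues, new_issue("error", d, "duplicate c_fullname"))
  issues
}

#' Write an ontology table to CSV
#'
#' @param nodes Ontology-node data.frame.
#' @param path Output path.
#' @return Row count, invisibly.
#' @export
write_ontology <- function(nodes, path) {
  utils::write.csv(nodes[, ONTOLOGY_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(nrow(nodes))
}
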