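# Shared fixtures: tiny rulesets built in code, an independent brute-force
# matcher oracle, and random-object generators for property tests.

tiny_ruleset <- function(surfaces = c("snoring", "sleep problems",
                                      "daytime sleepiness"),
                         concepts = c("SNORING", "SLEEP_PROBLEMS",
                                      "DAY_SLEEP")) {
  ruleset("001", "SLEEP",
          entries = lexicon_entry(surfaces, concepts, project = "SLEEP"))
}

write_tiny_ruleset_files <- function(dir,
                                     lexicon_lines = c("snoring\tSNORING"),
                                     config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(lexicon_lines, file.path(dir, "lexicon.tsv"))
  cfg <- config %||% list(project_num = "001", project_name = "SLEEP",
                          lexicon = "lexicon.tsv")
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force matching oracle, independent of the package's matcher: tests
# every substring of every lexicon surface length at every position, keeps
# word-bounded case-folded equals, then greedily retains longest
# non-overlapping candidates (ties: leftmost, then lexicon order).
naive_match_oracle <- function(text, rs) {
  e <- rs$entries
  n <- nchar(text)
  is_word <- function(ch) nzchar(ch) && grepl("[[:alnum:]_]", ch)
  cand <- list()
  for (k in seq_len(nrow(e))) {
    L <- nchar(e$surface[k])
    if (L == 0L || L > n) next
    for (a in seq_len(n - L + 1L)) {
      sub <- substr(text, a, a + L - 1L)
      hit <- if (e$case_sensitive[k]) sub == e$surface[k]
             else tolower(sub) == tolower(e$surface[k])
      if (!hit) next
      if (a > 1L && is_word(substr(text, a - 1L, a - 1L))) next
      if (a + L - 1L < n && is_word(substr(text, a + L, a + L))) next
      cand[[length(cand) + 1L]] <-
        data.frame(start = a - 1L, end = a + L - 1L, entry = k)
    }
  }
  if (length(cand) == 0L)
    return(data.frame(start = integer(), end = integer(), entry = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$start, cand$entry), ,
               drop = FALSE]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < kept$end & kept$start < cand$end[i]))
      kept <- rbind(kept, cand[i, ])
  }
  kept <- kept[order(kept$start), ]
  rownames(kept) <- NULL
  kept
}

random_concept_ref <- function() {
  tok <- function(chars, len) paste(sample(chars, len, replace = TRUE),
                                    collapse = "")
  if (runif(1) < 0.5) {
    concept_ref("STANDARD",
                vocab = tok(c(LETTERS, "-"), sample(3:8, 1)),
                code = tok(c(LETTERS, 0:9, "."), sample(3:7, 1)))
  } else {
    concept_ref("CUSTOM",
                project = paste0(tok(LETTERS, 1), tok(c(LETTERS, 0:9, "_"), sample(2:7, 1))),
                concept = paste0(tok(LETTERS, 1), tok(c(LETTERS, 0:9, "_"), sample(2:9, 1))))
  }
}

# Small word soup for random matcher texts: lexicon surfaces, their tokens,
# near-miss words and plain fillers, plus punctuation.
random_small_text <- function(max_chars = 200L) {
  words <- c("snoring", "sleep", "problems", "sleep problems",
             "daytime sleepiness", "snoringly", "unsleep", "problemsx",
             "patient", "reports", "mild", "severe", "denies", "the", "and",
             "clinic", "visit", "stable")
  out <- ""
  repeat {
    w <- sample(words, 1)
    sep <- sample(c(" ", " ", " ", ". ", ", "), 1)
    nxt <- if (nzchar(out)) paste0(out, sep, w) else w
    if (nchar(nxt) > max_chars) break
    out <- nxt
  }
  out
}
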