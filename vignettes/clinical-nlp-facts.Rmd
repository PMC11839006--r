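---
title: "From clinical text to queryable facts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From clinical text to queryable facts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinfacts)
```

This vignette is the package's own account of its methods: the extraction
model and its assumptions, the fact-encoding conventions, the evaluation
arithmetic, the synthetic-data generator that stands in for private EHR
corpora, and the design choices made where the conventions left the design
genuinely open.

## 1. The extraction model

### Dictionary matching

Extraction is ontology-driven and dictionary-based: a project **ruleset**
carries a lexicon of surface forms, each mapped to a concept from a standard
terminology (`ICD-10-CM:S92.4`) or a project-custom one (`SLEEP:SNORING`).
Matching is case-insensitive by default (clinical notes mix case freely; an
entry can opt into case sensitivity), word-bounded (no alphanumeric or
underscore character may abut a match on either side), and supports
per-entry Perl regexes.

When candidate matches overlap, **longest match wins**: candidates are
ranked by span length, then leftmost start, then lexicon file order, and
kept greedily if they do not overlap an already-kept match. So with entries
`sleep` and `sleep problems`, the text "sleep problems persist" yields only
the `sleep problems` mention. This rule makes output deterministic and has
a simple independent specification — it is exactly equivalent to a
brute-force oracle that tests every substring against the lexicon and
greedily keeps longest non-overlapping word-bounded hits, which is how the
test suite checks it. A consequence worth stating: two different concepts
whose matches overlap at *different* spans are also resolved to the longer
one rather than both emitted; same-span duplicates keep the first entry in
lexicon order. We chose the globally consistent greedy rule over
"emit all overlaps" because it keeps the matcher equal to its oracle and
avoids double-counting in downstream fact tables.

### Sentence scope and contextual attributes

Sentences are the scope unit for context. Segmentation splits on runs of
terminal punctuation followed by whitespace, and on newlines; spans are
0-based half-open character offsets, trimmed, disjoint, and jointly cover
all non-whitespace text, so snippets round-trip exactly.

Attribute assignment follows the ConText family of rule-based algorithms.
Each trigger phrase (e.g. "denies", "father", "history of", "if") carries
the attribute it sets, the value it assigns, and a direction. Its scope runs
from the trigger to the sentence end (forward), the sentence start
(backward), or both — clipped at the nearest termination phrase ("but",
"however", ...). A mention inside a trigger's scope takes the trigger's
value; when several triggers of the same attribute scope over one mention,
the **nearest trigger wins** (ties go to the first in the trigger list) —
the conventions do not prescribe a resolution, and nearest-wins matches
standard ConText practice. Mentions outside any scope take the defaults
POSITIVE / PATIENT / PRESENT. The attribute value sets are closed:

* certainty: POSITIVE, NEGATED, POSSIBLE
* experiencer: PATIENT, OTHER
* temporality: PRESENT, HISTORICAL, HYPOTHETICAL

The attributes themselves are the conventional ones; their value sets are a
design choice following the ConText convention, since the encoding template
`NLP|<ATTRIBUTE>:<VALUE>` is agnostic to the vocabulary. A default English
trigger list of about forty cues ships with the package
(`default_context_triggers()`) and is overridable per ruleset.

### Ruleset file format

Rulesets load from a small YAML config plus a tab-delimited lexicon and an
optional tab-delimited trigger file (`read_ruleset()`). The format is
self-defined and documented at the loader: a portable, diffable dictionary
format was the goal, not ingestion of any particular toolkit's native
serialization (a stated non-goal). `validate_ruleset()` returns issues as
data — forbidden delimiters (`|`, `:`) in tokens, non-compiling regexes,
and the same surface mapped to two concepts (an ambiguity error).

## 2. Encoding into the observation_fact table

One mention becomes one **base row** with `modifier_cd = "@"` (the i2b2
convention for "no modifier"; the conventions are silent on the base row,
so the standard i2b2 sentinel is used) plus one modifier row per contextual
attribute and per numeric attribute. All rows of a mention share
`(patient_num, encounter_num, concept_cd, start_date, instance_num)`;
`instance_num` is a running counter within that key, starting at 1, which
keeps repeat mentions of a concept in one note distinguishable and makes
the grouping invertible — grouping an encoded table by that key recovers
exactly one group per source mention.

Numerical and policy choices:

* **concept_cd length cap**: 50 characters by default (the common i2b2 DDL
  width), configurable; an over-length code is an *error*, never a silent
  truncation, which would corrupt codes.
* **Numeric attributes** use modifier token `NLP|<NAME>:VALUE` with
  `valtype_cd = "N"`, `nval_num` the magnitude and `tval_char` the unit —
  keeping the printed `NLP|ATTRIBUTE:VALUE` shape while routing numbers to
  the numeric column.
* **observation_blob** (the sentence snippet) is off by default: snippets
  may inadvertently contain protected health information. `start_date` is
  the note timestamp; `provider_id` defaults to `"NLP@"`.
* The two extension columns (`cohort_query_id`, `note_type_cd`) are emitted
  by default and switchable off for vanilla i2b2 schemas. Note-type
  terminology is not yet standardized across networks, so both the
  `STD|<vocab>:<code>` and `CUS|<code>` schemes are supported and neither
  is mandated.

`parse_concept_cd()` is the total inverse of `encode_concept_cd()` on its
range; codes without the `NLP|` prefix are classified `NOT_NLP` rather than
rejected, because the prefix test is precisely the filter that partitions a
mixed fact table into NLP-derived and structured rows.

## 3. The query ontologies

`build_project_subtree()` emits i2b2 metadata rows: folders for each level
of the root path, a folder per project, and a leaf per distinct lexicon
concept whose `c_basecode` is the encoded `concept_cd`. That basecode join
is the property that makes facts queryable, and it is asserted end-to-end
in the tests (every distinct `concept_cd` in an encoded table joins to
exactly one leaf). `build_note_type_subtree()` does the same for the five
document-ontology axes (type of service, kind of document, setting, role,
subject matter domain).

Published network ontologies are shown only as interface screenshots, so
exact paths are self-defined here: the default roots are `\ENACT\NLP\` and
`\ENACT\Note Types\`. Ancestor folders of the root are emitted too, so the
generated table satisfies the parent-exists invariant on its own; display
names derive from concept tokens (underscore to space, title case) and are
overridable. Node ordering is sorted, so rebuilding from the same ruleset
is byte-identical. `c_hlevel` equals path depth minus one, and
`validate_hierarchy()` checks depth, orphans, duplicate paths and leaf
basecodes table-wide.

## 4. Evaluation arithmetic

Precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, `F1 = 2PR/(P+R)`. The
**zero-division convention** is: each metric is 0 when its denominator is 0
(this matters for empty-prediction edge cases and is asserted in tests).

**Micro vs macro.** Micro-averaging pools confusion counts across concepts
then computes one triple; macro-averaging computes per-concept triples and
averages each metric (macro-F1 is the mean of per-concept F1s, not the
harmonic mean of macro-P and macro-R). Both are first-class outputs of
every `metric_report()`. Neither mode is claimed to reproduce every
published site column: in the multi-site sleep-phenotyping table, two
columns print an F1 that is *not* the harmonic mean of the printed
precision and recall (e.g. 0.776 printed vs 0.800 recomputed), while the
other published columns are exactly harmonic — evidence that some sites
averaged per-concept while others pooled. The test suite asserts the
harmonic identity where it holds and the inequality where it does not.

**Matching granularity.** Mention-level truth matching defaults to *same
concept + any character overlap*, with strict span equality behind a flag;
published validations never define span granularity, and any-overlap is the
forgiving common denominator across annotation tools. Reference mentions
are matched one-to-one greedily in document order.

**Silver standards** derive purely from structured diagnosis codes via
wildcard rules (pattern → label); a patient matching rules with two
different labels is a specification error, surfaced as such. Whether silver
labels live at patient or document level is site-dependent in practice, so
both units are supported (`derive_silver(unit =)`, document labels
propagated from the patient). Wildcard matching is case-insensitive and
dot-aware (dots stripped from both code and pattern before the prefix
test), so `F11.*` matches both `F11.20` and `F1120` as recorded in
real-world feeds. **Gold/silver agreement** is reported as percent
agreement plus silver-vs-gold precision/recall treating gold as truth;
chance-corrected coefficients are deliberately out of scope since the
evaluation framework names none.

**Error analysis** uses the closed four-class taxonomy — LOGIC (rule or
algorithm defects), LINGUISTIC (lexical variation, typos), CONTEXTUAL
(attribute/scope misses), ANNOTATION (reference-label mistakes) — with
zero-filled tallies so every class is always reported. Cross-site tables
are rendered with rows F1/Recall/Precision and one column per site,
**rounded half-up to 3 decimals** (so 0.95779 prints 0.958), matching the
presentation convention of published tables; base R's half-even `round()`
is not used for presentation.

## 5. The synthetic-note generator

Real corpora in this setting are private EHR text, so the generator is the
package's reference data source. It emulates: notes containing planted
lexicon terms; negation / uncertainty / experiencer / temporality cue
phrases drawn from the shipped trigger list; distractor sentences from a
filler vocabulary; a note-type mix; and structured diagnosis records
planted from wildcard rules (so cohort selection and silver derivation are
exercisable). Sentences are built by **slot-filling fixed templates**
rather than free generation — that is what makes exact span bookkeeping
possible, and exact spans are what let the gold set serve as ground truth.

Default study conditions: 200 notes per corpus; per-concept mention rate
0.35; cue rates NEGATED 0.20, HISTORICAL 0.10, OTHER 0.10, POSSIBLE 0.05,
HYPOTHETICAL 0.05 (the ~20% negation share reflects the widely reported
prevalence of negated findings in clinical text; the remaining categories
are smaller but non-negligible); a 40-word distractor vocabulary; an 80/20
custom/LOINC note-type mix. All randomness flows from the single seed in
`gen_spec()`; generation restores the caller's RNG state.

The keystone property is **self-consistency**: extracting with the
generator's own ruleset on an uncorrupted corpus reproduces the gold set
exactly — spans, concepts and all three attributes. The templates are
deliberately unambiguous (each contains exactly one cue and no other
trigger word), so this is a meaningful check of the matcher and the scoping
logic, not a tautology.

What the generator does **not** emulate — and therefore what passing tests
do *not* show about real data: real clinical language (section headers,
abbreviations, telegraphic style, copy-forward), misspellings beyond the
injected typo model, ambiguous cue scoping ("no change in snoring"),
inter-annotator disagreement, or realistic concept co-occurrence. Perfect
synthetic scores certify the machinery (matching, scoping, encoding,
metric arithmetic), not clinical-grade accuracy.

`inject_noise()` corrupts a corpus at controlled rates and writes a
manifest labelling each corruption with the error class it is designed to
induce: in-surface typos (LINGUISTIC), cue swaps to held-out synonyms the
trigger list does not know (CONTEXTUAL — an honest miss, not a rigged one),
and gold certainty flips (ANNOTATION). Length-changing edits shift all
downstream gold spans so the corrupted gold remains span-correct.

## 6. Problem sizes and determinism

The shipped tests and the acceptance script run at deliberately small
scale, chosen as comfortable desk-scale sizes for a rule-based pipeline:
200-note corpora for end-to-end checks, 1,000-case randomized round-trips
for the codecs, 100 random texts against the brute-force matching oracle
(texts ≤ 200 characters, ≤ 10 lexicon entries, where exhaustive substring
enumeration is cheap). Every stochastic step is seeded; extraction and
encoding are fully deterministic, and ontology generation is byte-stable.

## 7. Known limitations

* The matcher is a dictionary matcher: no machine-learned NER, section
  detection, coreference or de-identification (all stated non-goals).
* Trigger scoping is sentence-bounded; cues whose scope legitimately
  crosses sentences ("No complaints. Sleeping well.") are out of reach.
* The ruleset format is this package's own; compatibility with external
  toolkit serializations is not attempted.
* Site-level published metrics from private EHR corpora are not
  reproducible here; the package reproduces their *arithmetic* and provides
  the machinery to compute the same reports on local data.
* SHRINE-style federated query brokering and database ETL orchestration are
  out of scope; facts and ontologies are emitted as files.
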