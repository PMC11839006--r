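# clinfacts

Clinical NLP concept extraction, i2b2 fact encoding, and federated
evaluation.

## The problem

Large clinical research networks harmonize structured EHR data in the
i2b2/ACT common data model, but most of the clinical record lives in
free-text notes. Making NLP-derived findings queryable alongside structured
data requires three things that this package implements end to end:

1. **Extraction.** A ruleset-driven, dictionary-based concept extractor:
   a project lexicon maps surface forms (terms, phrases, regexes) to either
   standard-terminology concepts (e.g. ICD-10-CM codes) or project-custom
   concepts, and ConText-style trigger rules assign each mention three
   contextual attributes — *certainty* (POSITIVE / NEGATED / POSSIBLE),
   *experiencer* (PATIENT / OTHER) and *temporality* (PRESENT / HISTORICAL /
   HYPOTHETICAL) — scoped within sentences and clipped at termination
   phrases.

2. **Encoding.** Bit-exact translation of mentions into `observation_fact`
   entity–attribute–value rows. Concepts render as
   `NLP|<PROJECT_NUM>|<VOCAB>:<CODE>` (standard) or
   `NLP|<PROJECT_NUM>|CUSTOM|<PROJECT>:<CONCEPT>` (custom); contextual
   attributes as `NLP|<ATTRIBUTE>:<VALUE>` modifier rows; numeric attributes
   (doses etc.) via `VALTYPE_CD`/`NVAL_NUM`. The `NLP|` prefix cleanly
   partitions NLP-derived facts from structured EHR facts in the same
   table. Two extension columns carry the network cohort Query ID and the
   note-type code (`STD|LOINC:59258-4` style or site-custom `CUS|...`).

3. **Query & evaluation.** Generation of i2b2 metadata (ontology) tables —
   a Note Types tree over the five LOINC document-ontology axes, and
   per-project Clinical Concepts subtrees whose leaf basecodes join exactly
   to the encoded fact table — plus a federated evaluation harness:
   ICD-wildcard cohort selection, computable silver standards derived from
   structured diagnoses, gold/silver agreement, per-concept and
   micro/macro-aggregated precision / recall / F1
   (`P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`), cross-site
   report tables, and the four-class error taxonomy
   (LOGIC / LINGUISTIC / CONTEXTUAL / ANNOTATION).

A synthetic-note generator (`generate_corpus()`) plants lexicon terms and
cue phrases into template sentences with exact span bookkeeping, so the
whole pipeline is testable without any protected health information.

## Worked example

```r
library(clinfacts)

rs <- toy_ruleset()   # project 001 "SLEEP": 5 custom concepts + ICD-10-CM G47.33
doc <- document("note1",
  "Patient denies snoring. Father had insomnia. History of sleep problems.",
  patient_num = 101, encounter_num = 9001,
  note_type_cd = "CUS|CLIN_ENC_NOTE", note_datetime = "2024-03-05 09:00:00")

m <- extract_mentions(doc, rs)
m[, c("matched_text", "concept_key", "certainty", "experiencer", "temporality")]
#>     matched_text          concept_key certainty experiencer temporality
#> 1        snoring        SLEEP:SNORING   NEGATED     PATIENT     PRESENT
#> 2       insomnia       SLEEP:INSOMNIA  POSITIVE       OTHER     PRESENT
#> 3 sleep problems SLEEP:SLEEP_PROBLEMS  POSITIVE     PATIENT  HISTORICAL
```

Each mention's attributes follow from its sentence: "denies" negates
*snoring*, "Father" reassigns *insomnia* to another experiencer, "History
of" marks *sleep problems* historical. Encoding turns each mention into one
base fact row (`modifier_cd = "@"`) plus one modifier row per attribute,
all sharing an `instance_num`:

```r
facts <- mentions_to_facts(m, encode_options(project_num = "001",
                                             cohort_query_id = "Q2024"))
facts[, c("concept_cd", "modifier_cd", "instance_num")]
#>                             concept_cd                modifier_cd instance_num
#> 1         NLP|001|CUSTOM|SLEEP:SNORING                          @            1
#> 2         NLP|001|CUSTOM|SLEEP:SNORING      NLP|CERTAINTY:NEGATED            1
#> 3         NLP|001|CUSTOM|SLEEP:SNORING    NLP|EXPERIENCER:PATIENT            1
#> 4         NLP|001|CUSTOM|SLEEP:SNORING    NLP|TEMPORALITY:PRESENT            1
#> ...
```

`write_facts()` emits the observation_fact CSV; `build_project_subtree()`
produces the matching ontology rows; `evaluate_predictions()` scores the
output against a gold or silver `annotation_set()` and `cross_site_report()`
lays site reports out as an F1/Recall/Precision table.

A thin command-line wrapper over these functions ships in
`inst/cli/clinfacts.R` (subcommands `synth`, `ruleset-validate`, `extract`,
`encode`, `ontology`, `evaluate`).

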