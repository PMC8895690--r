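# vcase

Virtual clinical cases from source medical records, free-text question
matching, and a five-indicator clinical-thinking rubric.

## The problem

Medical educators want learners to practise the full diagnostic loop —
history taking, physical examination, investigations, diagnosis, treatment
— on realistic cases without a ward, a tutor, or a patient. Building such
cases by hand does not scale and does not reflect real disease
progression. `vcase` implements the computational core of a virtual-patient
system that manufactures playable cases from records and scores the
learner's reasoning automatically:

- **Text normalisation** for delimiter-free clinical text: dictionary word
  segmentation via a trie scan, a word-graph DAG and a
  maximum-probability dynamic program over unigram frequencies; a rule
  model for numeric/template spans; a character-level B/M/E/S hidden
  Markov model decoded with Viterbi for out-of-vocabulary words; negation
  qualifiers with clause-bounded scope.
- **Semantic matching**: PPMI+SVD word vectors map colloquial tokens onto
  the nearest standard term by cosine similarity; token-level Levenshtein
  distance then routes a free-text question onto the standard question
  library — distance 0 answers directly, distance in (0, 5) yields a
  ranked candidate list to confirm, distance ≥ 5 returns
  *"You have deviated from the correct process"*.
- **Case building**: matching-rate computation and the ≥ 90% review gate,
  irreversible `*`-mask de-identification with a release-time leak scan,
  and difficulty levels 1–4 (guided answers → seeded distractors →
  free-entry for top-weighted items → fully independent self-study).
- **Session engine**: event-sourced scenes (consultation, physical exam,
  auxiliary exam, diagnosis, treatment) with replayable action logs,
  ICD-checked diagnosis submission, and missing-item analysis.
- **Evaluation**: the five rubric indicators, each on [0, 100] —

  | indicator | formula |
  |---|---|
  | rigor | 100 · bases selected / bases total (correct ones) |
  | logic | 100 · max(0, inq_sel − inq_missed + pe_sel − pe_missed) / (inq_tot + pe_tot) |
  | systematic | 100 · correct items selected / correct items total |
  | agility | 100 · 4·T_rec / (4·T_rec + T_act) · selected score / total score |
  | expansion | 100 · selected diagnosis+basis score / total diagnosis+basis score |

  plus the unweighted-mean total, a radar payload, and teacher-facing
  error-diagnosis records.

Every input has a seeded generator (lexicons, tagged corpora, question
libraries, source records with embedded PII, simulated learners), so the
whole pipeline runs and is tested offline.

## Worked example

```r
library(vcase)

lex  <- generate_lexicon(26, 400, seed = 7)
lib  <- generate_question_library(lex, n_questions = 12, seed = 8)
hmm  <- train_hmm(generate_tagged_corpus(lex, 200, oov_rate = 0.1, seed = 9))
pipe <- match_pipeline(lex, hmm = hmm)

rec <- generate_source_record("inguinal_hernia", lib, 1.0, lex, seed = 10)
compute_matching_rate(rec, lib, pipe)
#> [1] 1

pii  <- unname(rec$pii_manifest)                      # held only here
case <- build_case(deidentify(rec), lib, pipe, seed = 11)
case <- review_actions(case, "submit")
case <- review_actions(case, "release", pii_values = pii)
playable <- apply_difficulty(case, 2, seed = 12)      # level 2: distractors

s <- start_session(playable, "demo-student")
q <- subset(playable$base$questions, scene == "consultation")[1, ]
s <- ask(s, q$display_text)
str(s$last_response)
#> List of 3
#>  $ outcome    : chr "EXACT"
#>  $ question_id: chr "q002"
#>  $ answer     : chr "Finding reported for q002"

s <- switch_scene(s, "diagnosis")
s <- submit_diagnosis(s, "Lipoma in the groin area")  # recorded as error
s <- submit_diagnosis(s, "Right inguinal hernia")     # ICD match: correct
s <- select_items(s, "bases", case$bases$item_id[case$bases$is_correct])
s <- finish(s, at = 700)
build_report(s)
#> <evaluation_report> clinical thinking indicators
#>   rigor       100.00
#>   logic         0.00
#>   systematic   42.86
#>   agility      27.82
#>   expansion   100.00
#>   total        54.14
#>   error diagnoses: Lipoma in the groin area
#>   important missing items: q007, q008
```

Reading the report: every correct diagnosis basis was selected (rigor
100), but no physical examination and only one inquiry happened, so the
logic numerator clamps at zero and systematic credit is partial; the
session overran the recommended 600 s with a partial score, depressing
agility; the wrong differential ("Lipoma in the groin area") lands in the
error-diagnosis record the teacher sees, and the two highest-weighted
uncollected items are flagged as important misses.

`run_demo(seed = 1)` plays the whole pipeline end to end with two
simulated cohorts (competence 0.5 vs 0.85, 20 learners each) and returns
their mean indicator table; the higher-competence cohort scores higher on
every indicator.

A command-line wrapper is installed at `inst/scripts/vcase`
(`vcase demo --seed 1`, `vcase fixtures --what lexicon --out lex.tsv`, …);
it is a thin shell over the exported functions.

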