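---
title: "Methods: virtual clinical cases, question matching and the clinical-thinking rubric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual clinical cases, question matching and the clinical-thinking rubric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcase)
```

# What the package models

`vcase` implements the computational core of a virtual-patient learning
system: source medical records are converted into de-identified,
question-and-answer *virtual cases*; a learner (human or simulated)
interrogates a case in free text across consultation, physical-exam and
auxiliary-exam scenes; free-text input is routed onto a *standard question
library*; and a finished session is scored on five clinical-thinking
indicators with a radar payload and a teacher feedback report.

All text is modelled as sequences over a finite symbol alphabet.
Segmentation, tagging and matching are defined on abstract symbols, with
real scripts (the motivating deployment was Chinese clinical text, which has
no word delimiters) as one instantiation. This choice makes every
natural-language claim testable against brute-force oracles using seeded
synthetic lexicons, without shipping a real clinical dictionary.

# Word segmentation

## Dictionary path

A lexicon maps words to positive frequencies. `build_trie()` realises the
dictionary as a hashed prefix index (word, frequency, and all proper
prefixes), which supports the member/prefix/frequency queries of a pointer
trie during left-to-right sentence scanning. `build_word_graph()` then
produces the directed acyclic word graph: an edge covers a span iff the
span is a lexicon word, and every single symbol always carries an edge, so
a full path exists for any input.

`max_prob_segment()` scores a segmentation as the sum of unigram log
probabilities $\log(f_w / N)$, where $f_w$ is the word's lexicon frequency
and $N$ the lexicon total. Out-of-vocabulary single symbols receive a floor
probability $\texttt{oov\_floor}/N$ (default $10^{-3}/N$), which makes any
dictionary word strictly preferable to spelling the same span symbol by
symbol. The maximisation runs by dynamic programming right-to-left over the
graph. Ties are broken by (1) fewer tokens, then (2) the lexicographically
earliest boundary set — determinism matters more than the particular
convention, and both quantities compose additively so they ride along in
the same DP.

The DP is verified against exhaustive enumeration of *all* admissible
segmentations for hundreds of random sentences of length at most 12; at
that length enumeration is exact and cheap, and the equality is bitwise up
to floating-point tolerance $10^{-9}$.

## Rule spans

Numeric and template spans (measurement-with-unit such as "10days", dates,
value ranges) are matched by anchored regular patterns *before* graph
construction and frozen as single tokens. Overlaps resolve
leftmost-longest, ties by rule order, so overlapping rule sets stay
deterministic. The unit suffix of the number rule is capped at four symbols
because, with no delimiters in the input, an unbounded suffix would
swallow the following word.

## Unknown words: BMES character HMM

Spans that the dictionary DP can only cover as runs of single out-of-vocabulary
symbols are re-decoded by a character-level hidden Markov model over the
tags B/M/E/S (begin, middle, end of a multi-symbol word; single-symbol
word). Structure is enforced in the model itself: transitions that cannot
occur in a well-formed tagging (B→B, S→M, …) carry $-\infty$ log
probability, sequences must start in {B, S} and end in {E, S}. Training
(`train_hmm()`) is maximum likelihood with additive smoothing (default
0.5) spread only over legal transitions; emissions reserve one smoothed
bucket for symbols never seen in training, so decoding never encounters an
all-$-\infty$ column. `viterbi_decode()` breaks score ties by the fixed
state order B < M < E < S at every backpointer.

Viterbi is verified against enumeration of all legal tag sequences for
spans of length at most 6. Parameter recovery is checked by sampling
corpora from a known fixture model (`fixture_hmm_model()`, four emission
blocks of the alphabet, one per state, sharpness 0.9) and re-training: with
10,000 sentences of at least 15 symbols the transition matrix is recovered
to within $L_\infty$ 0.05 (typically < 0.01) and held-out boundary F1
exceeds 0.9. Those problem sizes are the package's documented study
conditions for this claim; the F1 threshold is an artifact target for
identifiable synthetic data, not a claim about clinical text. Sentence
sampling stops at the first legal word end after the minimum length, which
conditions the chain slightly; at these lengths the bias on transition
estimates is well below the tolerance.

The dictionary path wins whenever both could explain a span (the jieba
convention): rule spans are frozen first, the DP runs over the rest, and
only maximal runs of two or more single-symbol OOV fallbacks are handed to
the HMM. A global joint decode over dictionary and character model is a
known alternative and is deliberately not implemented.

## Negation

Qualifier words (no, not, without, …, configurable and curated by hand in a
deployment) flip the polarity of following tokens. Scope is the
clause-bounded forward window: negation ends at the next clause break, and
a second qualifier inside the same clause flips polarity back. Misspellings
are *not* corrected; they surface as OOV tokens for the reviewing teacher.
Negation is carried as annotation metadata and does not enter edit
distance — whether a negated finding should count as a different question
is a modelling question the routing layer leaves to the library designer.

# Synonym conversion and question routing

`train_vectors()` builds distributional word vectors from a token corpus:
symmetric co-occurrence within a window (default 2), reweighted to
positive pointwise mutual information, factorised by truncated SVD, with
vectors $U \Sigma$ so that full-rank cosine geometry of the PPMI rows is
preserved. A count-based factorisation was chosen over a stochastic
skip-gram trainer because the contract that matters downstream is only
*cosine-nearest standard term*, and the closed-form route is exactly
reproducible. A deterministic sign convention plus a seeded jitter of
magnitude $10^{-8}$ removes the two residual indeterminacies (SVD sign,
zero rows).

`nearest_standard_term()` replaces an in-vocabulary token by its
argmax-cosine standard term when similarity reaches the threshold (default
0.7, configurable; the threshold is a free parameter of the method and 0.7
keeps near-synonyms while rejecting topical neighbours in the synthetic
corpora). Standard terms map to themselves; unknown words pass through
unchanged.

Routing (`match_question()`) computes the token-level Levenshtein distance
between the normalised input and every library question. Distance 0
returns the question's answer directly; a minimum distance in $(0, 5)$
returns *all* questions under 5, ascending, ties by question id, and the
learner must confirm one; minimum distance $\ge 5$ returns the fixed
deviation message. The source system's printed inequalities left distances
1 and 5 uncovered; this implementation closes the partition as
$0 < d < 5$ / $d \ge 5$ so the outcome is a total function of the distance.
Distance is over tokens, not symbols, because synonym conversion operates
on tokens and a symbol-level distance would undo it.

# Case construction

**Matching rate.** The fraction of library questions for which some
narrative clause of the record reaches distance < 5 after normalisation.
This is the gate quantity: records at $\ge 0.90$ are ranked (descending,
ties by record id) and flagged for teacher review. The gate is computed
against the library supplied for the record's disease template.

**De-identification.** Configured PII fields (defaults: name, id number,
admission time) are replaced by `*` masks of equal length, and every
occurrence of an original value anywhere else in the record — narrative
included — is masked too. The operation is irreversible: the returned
manifest holds masks only. Release of a case re-scans its full JSON
serialisation against the original values, which the build pipeline holds
transiently and passes as an argument; storing them in the case for later
scanning would itself be the leak.

**Difficulty levels.** Level 1 shows the full case with visible answers.
Level 2 injects seeded distractor items (default 30% of the question
count) into the three examination scenes, sampled from a cross-case pool
when one is supplied; distractors are always incorrect and original items
are never modified. Level 3 turns the top-weighted 30% of correct scoring
items into free-entry. Level 4 makes *every* scoring item free-entry
(fully independent self-study; this is the superset reading of the level-4
contract and is what the playable-case invariant enforces). Free-entry
items are graded through the same text-matching machinery as questions.

Case difficulty class (simple / moderately difficult / complex) is
teacher-assigned metadata; no classifier is implied by the method.

# Sessions and evaluation

Sessions are event-sourced: every operation appends to an action log with
monotone timestamps, and `replay_log()` reconstructs the final state
exactly from the log alone — the property the tests fuzz. Selections are
sets, so repeating a question or selection is idempotent. Diagnoses are
matched case-insensitively against the case's ICD-coded list; a correct
match joins the learner's differential, anything else is recorded as an
error diagnosis for the teacher report.

The five indicators, each scaled to [0, 100]:

| indicator | formula |
|---|---|
| rigor | $100 \cdot$ correct bases selected / correct bases total |
| logic | $100 \cdot \max(0,\; \text{inq}_{sel} - \text{inq}_{miss} + \text{pe}_{sel} - \text{pe}_{miss}) / (\text{inq}_{tot} + \text{pe}_{tot})$ |
| systematic | $100 \cdot$ correct items selected / correct items total (inquiries, physical exams, diagnoses, bases, treatments) |
| agility | $100 \cdot \frac{4 T_{rec}}{4 T_{rec} + T_{act}} \cdot \frac{\text{selected score}}{\text{total score}}$ |
| expansion | $100 \cdot$ selected diagnosis+basis score / total diagnosis+basis score |

Numerical conventions, chosen once and logged when triggered: the logic
numerator is clamped at 0 (as printed it goes negative when misses exceed
hits); an empty category scores a vacuous 100 so absent categories never
penalise; agility requires a positive total score and is the one indicator
that cannot be made vacuous. The total is the unweighted mean of the five.
Auxiliary-exam questions contribute to the score-weighted agility ratio
but not to the count-based formulas, whose categories are fixed by the
rubric. Times are seconds; the recommended completion time is case
metadata. The narrative prose description of "logic" mentions the *order*
of consultation → examination → diagnosis, but the rubric formula contains
no order term; the formula is implemented as printed and an
order-violation penalty is left unimplemented.

# Simulated learners and what they can show

`simulate_student()` selects each correct item independently with
probability equal to a scalar competence in [0, 1], picks incorrect items
with probability $0.3(1-\text{competence})$, and completes in
$T_{rec}(2-\text{competence})$ times a small lognormal factor (sd 0.05).
`run_demo()` plays cohorts of 20 such learners at competence 0.5 and 0.85
— a before/after-learning contrast — and tabulates mean indicator scores.
These defaults are the package's study conditions for the
direction-of-effect check: higher competence must yield higher totals.

The generators emulate the *structure* of the data (answer content
recoverable from narrative clauses at a controlled coverage, PII embedded
in free text, Zipf lexicons, boundary-tagged corpora) and none of its
clinical content: no realistic prose, no behavioural coupling between a
learner's selections (independent Bernoulli is the whole model), no
colloquial spelling variation. Passing tests therefore certify the
algorithms and their contracts, not performance on real records; published
human-study effect sizes are not reproduction targets at this scale.
Question libraries are generated with pairwise token distance at least 5
and re-segmentable canonical sequences, so matching outcomes on fixtures
are unambiguous by construction — real libraries must be curated to keep
questions separable under the same distance bound.

# Problem sizes and runtime

The verification suite uses: 500 sentences (length ≤ 12) for the
segmentation oracle, 500 spans (length ≤ 6) for the Viterbi oracle, 10,000
training / 300 held-out sentences for HMM recovery, 200 token pairs
(length ≤ 8) for the edit-distance oracle, 200 seeded records for the
de-identification fuzz, 20-question libraries for the gate checks, 1,000
fuzzed score-input draws plus engine-level fuzzed sessions for rubric
bounds, and cohorts of 20 simulated learners per arm for the
direction-of-effect demonstration. All sizes are set in the tests and in
`scripts/acceptance.R` and scale linearly if larger runs are wanted.

# Known limitations

- Dictionary-first reconciliation can shadow a better joint HMM analysis
  of a span that mixes known and unknown words.
- The PPMI+SVD vector model has no subword structure; a misspelled
  synonym is simply out of vocabulary.
- Free-entry grading of bases and treatments uses normalised exact text
  match, not the full distance pipeline, because those items carry short
  curated labels rather than token sequences.
- The session engine is single-user per session; no concurrency semantics
  beyond per-session isolation are provided.
- De-identification masks exact substrings; paraphrased identity clues
  (rare in structured PII, possible in free text) are out of scope, as is
  masking-aware search.
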