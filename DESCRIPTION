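Package: vcase
Title: Virtual Clinical Case Construction, Question Matching and Clinical
    Thinking Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds playable virtual clinical cases from source medical
    records and scores the clinical thinking of simulated or real learners.
    Provides dictionary word segmentation (trie scan, word-graph dynamic
    programming over unigram frequencies), a character-level BMES hidden
    Markov model decoded with Viterbi for out-of-vocabulary spans, rule
    patterns for numeric/template spans, negation qualifiers, count-based
    word vectors for synonym normalisation, token-level edit-distance
    routing of free-text questions onto a standard question library,
    record de-identification with leak scanning, difficulty-graded case
    play with replayable action logs, and a five-indicator rubric
    (rigor, logic, systematic, agility, knowledge expansion) with radar
    output. Seeded fixture generators make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
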