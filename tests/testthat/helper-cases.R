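# One shared mid-sized world for the case/session/evaluation tests:
# lexicon, library, trained HMM and vectors, a released case and a level-1
# playable. Built once per test run.

tfx <- local({
  lex <- generate_lexicon(26L, 400L, seed = 11L)
  lib <- generate_question_library(lex, n_questions = 12L, seed = 12L)
  corpus <- generate_tagged_corpus(lex, 120L, oov_rate = 0.1, seed = 13L)
  hmm <- train_hmm(corpus)
  vectors <- train_vectors(c(lapply(corpus$sentences, `[[`, "words"),
                             lib$canonical_tokens),
                           dim = 12L, seed = 14L,
                           standard_terms = unique(unlist(lib$canonical_tokens)))
  pipeline <- match_pipeline(lex, hmm = hmm, vectors = vectors)
  record <- generate_source_record("inguinal_hernia", lib, 1.0, lex, seed = 15L)
  pii <- unname(record$pii_manifest)
  clean <- deidentify(record)
  case <- build_case(clean, lib, pipeline, seed = 16L)
  case <- review_actions(case, "submit")
  case <- review_actions(case, "release", pii_values = pii)
  playable <- apply_difficulty(case, 1L, seed = 17L)
  list(lex = lex, lib = lib, corpus = corpus, hmm = hmm, vectors = vectors,
       pipeline = pipeline, record = record, pii = pii, clean = clean,
       case = case, playable = playable)
})

# a tiny released case with hand-set items, for exact-score tests
make_manual_playable <- function(pipeline = tfx$pipeline, t_rec = 600) {
  lib <- tfx$lib
  case <- build_case(tfx$clean, lib, pipeline, seed = 21L,
                     recommended_time = t_rec)
  case <- review_actions(case, "submit")
  case <- review_actions(case, "release", pii_values = tfx$pii)
  apply_difficulty(case, 1L, seed = 22L)
}

# score inputs with editable fields, all-correct defaults
mkinputs <- function(bases_sel = 3, bases_tot = 4,
                     inq_sel = 4, inq_tot = 4,
                     pe_sel = 4, pe_tot = 4,
                     all_sel = 10, all_tot = 20,
                     t_rec = 600, t_act = 600,
                     sel_score = 10, tot_score = 10,
                     dx_sel = 8, dx_tot = 10) {
  score_inputs(bases_sel, bases_tot, inq_sel, inq_tot, pe_sel, pe_tot,
               all_sel, all_tot, t_rec, t_act, sel_score, tot_score,
               dx_sel, dx_tot)
}

perfect_session <- function(playable = tfx$playable, t_act = NULL) {
  case <- playable$base
  s <- start_session(playable, "perfect", at = 0)
  for (scene in c("consultation", "physical_exam", "auxiliary_exam")) {
    q <- case$questions[case$questions$is_correct_item &
                          case$questions$scene == scene, ]
    if (nrow(q) == 0L) next
    s <- switch_scene(s, scene)
    for (i in seq_len(nrow(q))) s <- ask(s, q$display_text[i])
  }
  s <- switch_scene(s, "diagnosis")
  for (lab in case$diagnoses$label[case$diagnoses$is_correct])
    s <- submit_diagnosis(s, lab)
  s <- select_items(s, "bases", case$bases$item_id[case$bases$is_correct])
  s <- select_items(s, "treatments",
                    case$treatments$item_id[case$treatments$is_correct])
  finish(s, at = if (is.null(t_act)) case$recommended_completion_time else t_act)
}
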