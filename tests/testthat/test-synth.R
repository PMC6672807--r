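term <- build_fixture_terminology()
form <- chd_form()

test_that("fixture terminology covers the published bindings and all categories", {
  expect_identical(get_concept(term, "SCT:3006004")$preferred_term,
                   "disturbance of consciousness")
  expect_identical(get_concept(term, "SCT:42842009")$category,
                   "medical_problem")
  expect_identical(get_concept(term, "SCT:246116008")$category, "observable")
  expect_identical(get_concept(term, "RID3277")$preferred_term,
                   "ventricular septal defect")
  cats <- table(term$concepts$category)
  expect_setequal(names(cats), c("medical_problem", "test", "treatment",
                                 "body_structure", "observable", "qualifier",
                                 "value"))
  expect_gte(sum(grepl("^SYN:", term$concepts$concept_id)), 20L)
  ## deterministic
  expect_identical(build_fixture_terminology(), term)
})

test_that("degenerate generator configs force the planted truth", {
  cfg <- quiet_generator(seed = 3, finding_prevalence = 1, negation_prob = 0)
  cs <- generate_case(form, cfg, term)
  tf_vals <- vapply(Filter(function(a) a$kind == "true_false",
                           cs$gold$answers), `[[`, character(1), "value")
  expect_true(all(tf_vals == "true"))
  ## every tri-state concept's preferred term appears affirmed in its document
  expect_true(grepl("disturbance of consciousness",
                    cs$documents[[1]]$text, fixed = TRUE))
  expect_false(grepl(" no ", tolower(cs$documents[[1]]$text), fixed = TRUE))

  cfg <- quiet_generator(seed = 3, finding_prevalence = 1, negation_prob = 1)
  cs <- generate_case(form, cfg, term)
  tf_vals <- vapply(Filter(function(a) a$kind == "true_false",
                           cs$gold$answers), `[[`, character(1), "value")
  expect_true(all(tf_vals == "false"))
  mc <- Filter(function(a) a$kind == "multiple_choice", cs$gold$answers)
  expect_true(all(lengths(lapply(mc, `[[`, "value")) == 0))

  ## identical seeds give byte-identical cases
  cfg <- generator_config(seed = 17)
  c1 <- generate_case(form, cfg, term)
  c2 <- generate_case(form, cfg, term)
  expect_identical(c1$documents[[1]]$text, c2$documents[[1]]$text)
  expect_equal(c1$gold, c2$gold)
})

test_that("cohorts have two documents per case and are seed-reproducible", {
  cfg <- generator_config(seed = 8)
  co1 <- generate_cohort(form, cfg, 5, term)
  expect_length(co1, 5L)
  for (cs in co1) {
    expect_length(cs$documents, 2L)
    expect_setequal(vapply(cs$documents, `[[`, character(1), "doc_type"),
                    c("admission_record", "imaging_report"))
  }
  co2 <- generate_cohort(form, cfg, 5, term)
  expect_equal(co1, co2)
  ## distinct cases differ
  expect_false(identical(co1[[1]]$documents[[1]]$text,
                         co1[[2]]$documents[[1]]$text))
})

test_that("zero-noise extraction and prepopulation reproduce the gold exactly", {
  cohort <- generate_cohort(form, quiet_generator(seed = 23), 10, term)
  for (cs in cohort) {
    bundle <- extract_case(cs$gold$case_id, cs$documents, term)
    pre <- prepopulate_case(form, bundle)
    expect_true(answer_sets_match(pre, cs$gold, form))
    ## extraction recovers exactly the planted (concept, assertion) pairs
    for (i in seq_along(cs$documents)) {
      planted <- cs$planted[cs$planted$doc_type ==
                              cs$documents[[i]]$doc_type, ]
      found <- bundle$extractions[[i]]$mentions
      expect_identical(sort(paste(found$concept_id, found$assertion)),
                       sort(paste(planted$concept_id, planted$assertion)))
    }
  }
})

test_that("prepopulation accuracy does not improve with more typo noise", {
  acc_at <- function(typo, seed) {
    cfg <- generator_config(synonym_variant_prob = 0,
                            typo_char_edit_prob = typo, seed = seed)
    cohort <- generate_cohort(form, cfg, 5, term)
    correct <- 0L; total <- 0L
    els <- form_elements(form)
    for (cs in cohort) {
      pre <- prepopulate_case(form,
                              extract_case(cs$gold$case_id, cs$documents,
                                           term))
      for (eid in names(els)) {
        correct <- correct +
          answer_values_equal(els[[eid]]$element_kind,
                              pre$answers[[eid]]$value,
                              cs$gold$answers[[eid]]$value)
        total <- total + 1L
      }
    }
    correct / total
  }
  for (seed in c(2, 9)) {
    a0 <- acc_at(0, seed); a9 <- acc_at(0.9, seed)
    expect_identical(a0, 1)
    expect_lte(a9, a0)
  }
})

test_that("simulated participants obey the behaviour probabilities", {
  cfg <- quiet_generator(seed = 31)
  cs <- generate_case(form, cfg, term)
  prepop <- empty_answer_set(form, cs$gold$case_id)

  ## never noticing: final == prefill
  beh <- behavior_config(p_notice_error = 0, p_fix_correct = 1, seed = 41)
  r <- simulate_participant(cs$gold, prepop, beh, form)
  expect_true(answer_sets_match(r$final, prepop, form))

  ## perfect behaviour: final == gold, entry modes flipped to modified
  beh <- behavior_config(p_notice_error = 1, p_fix_correct = 1,
                         p_spurious_change = 0,
                         timing = ecrfpop:::timing_defaults("manual"),
                         seed = 41)
  r <- simulate_participant(cs$gold, prepop, beh, form)
  expect_true(answer_sets_match(r$final, cs$gold, form))
  modes <- vapply(r$final$answers, `[[`, character(1), "entry_mode")
  wrong_prefill <- !vapply(names(modes), function(eid)
    answer_values_equal(r$final$answers[[eid]]$kind,
                        prepop$answers[[eid]]$value,
                        cs$gold$answers[[eid]]$value), logical(1))
  expect_true(all(modes[wrong_prefill] == "modified"))
  ## timing: one positive draw per section
  expect_identical(nrow(r$timings), 4L)
  expect_true(all(r$timings$elapsed_seconds > 0))

  ## seeded determinism
  r2 <- simulate_participant(cs$gold, prepop, beh, form)
  expect_equal(r2$final, r$final)
})

test_that("the in-silico experiment produces a coherent report", {
  rep <- run_experiment(form, gen_cfg = quiet_generator(seed = 1),
                        beh_manual = manual_behavior(),
                        beh_assisted = assisted_behavior(),
                        n_cases = 6, n_participants_per_arm = 4,
                        master_seed = 13)
  expect_s3_class(rep, "ecrf_experiment_report")
  ## assisted arm reviews zero-noise prefills: prepopulation itself is 100%
  pp <- rep$accuracy_prepopulation$per_participant
  expect_true(all(pp$accuracy == 100))
  ## geometric-ratio identity holds on the computed comparison
  expect_equal(rep$accuracy_comparison$geometric_ratio,
               exp(rep$accuracy_comparison$md), tolerance = 1e-15)
  ## error labels partition all assisted answers
  expect_identical(nrow(rep$error_labels), 6L * 28L * 4L)
  ## assisted arm is faster by construction of the timing defaults
  expect_lt(rep$time_comparison$md, 0)
})
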