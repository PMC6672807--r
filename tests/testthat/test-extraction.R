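term <- build_fixture_terminology()
cfg <- extraction_config()

test_that("segmentation splits on terminators but not inside decimals", {
  expect_length(segment_text("No murmur. VSD present."), 2L)
  expect_length(segment_text(""), 0L)
  s <- segment_text("one sentence with no terminator at all")
  expect_length(s, 1L)
  expect_identical(substr("one sentence with no terminator at all",
                          s[[1]]$start + 1, s[[1]]$end),
                   "one sentence with no terminator at all")
  s <- segment_text("The lesion size was 0.5 cm.")
  expect_length(s, 1L)
  expect_true("0.5" %in% s[[1]]$tokens$text)
  ## CJK terminators and single-character tokens
  s <- segment_text("无发热，未见紫绀。")
  expect_length(s, 2L)
  expect_identical(s[[1]]$tokens$text, c("无", "发", "热"))
})

test_that("entity recognition finds dictionary concepts, longest match wins", {
  doc <- new_document("c1", "admission_record", "cardiac murmur heard at apex")
  m <- recognize_entities(doc, term, cfg)
  expect_identical(m$concept_id[1], "SCT:42842009")
  expect_identical(m$category[1], "medical_problem")

  doc <- new_document("c2", "admission_record", "nothing relevant here")
  expect_identical(nrow(recognize_entities(doc, term, cfg)), 0L)

  ## overlapping candidates: the longer dictionary hit survives
  nested <- terminology_from_table(data.frame(
    concept_id = c("X:1", "X:2"), category = "medical_problem",
    preferred_term = c("septal defect", "ventricular septal defect"),
    synonyms = "", stringsAsFactors = FALSE))
  doc <- new_document("c3", "imaging_report",
                      "The study showed ventricular septal defect.")
  m <- recognize_entities(doc, nested, cfg)
  expect_identical(nrow(m), 1L)
  expect_identical(m$concept_id, "X:2")
  expect_identical(m$surface, "ventricular septal defect")
})

test_that("fuzzy recognition tolerates a typo and records provenance", {
  doc <- new_document("c4", "admission_record",
                      "Physical examination revealed cardiac murmr.")
  m <- recognize_entities(doc, term, cfg)
  expect_identical(m$concept_id, "SCT:42842009")
  expect_lt(m$score, 1)
  expect_identical(substr(doc$text, m$start + 1, m$end), m$surface)
})

test_that("assertion classification applies cues, windows and boundaries", {
  run <- function(text, target) {
    doc <- new_document("a", "admission_record", text)
    ex <- extract_document(doc, term, cfg)
    ex$mentions$assertion[ex$mentions$surface == target]
  }
  expect_identical(run("No cardiac murmur was heard.", "cardiac murmur"),
                   "absent")
  expect_identical(run("cardiac murmur grade 2", "cardiac murmur"), "present")
  ## scope of "no" is terminated at the conjunction: cyanosis stays present
  expect_identical(run("no fever, but cyanosis observed.", "fever"), "absent")
  expect_identical(run("no fever, but cyanosis observed.", "cyanosis"),
                   "present")
  ## cue beyond the token window does not negate
  expect_identical(
    run("no better explanation given the findings than severe cyanosis.",
        "cyanosis"), "present")
})

test_that("relations link nearest arguments within one sentence", {
  doc <- new_document("r1", "imaging_report",
    "The lesion size of the ventricular septal defect was measured.")
  ex <- extract_document(doc, term, cfg)
  r <- ex$relations[ex$relations$rel_type == "problem_observable", ]
  expect_identical(nrow(r), 1L)
  obs <- ex$mentions[ex$mentions$mention_id == r$arg2, ]
  prob <- ex$mentions[ex$mentions$mention_id == r$arg1, ]
  expect_identical(obs$concept_id, "SCT:246116008")
  expect_identical(prob$concept_id, "RID3277")

  ## across sentences: no relation
  doc <- new_document("r2", "imaging_report",
                      "Ventricular septal defect was seen. The lesion size was measured.")
  ex <- extract_document(doc, term, cfg)
  expect_identical(nrow(ex$relations), 0L)

  ## two candidate problems: the nearer one is linked
  doc <- new_document("r3", "imaging_report",
    "Atrial septal defect noted with ventricular septal defect lesion size measured.")
  ex <- extract_document(doc, term, cfg)
  r <- ex$relations[ex$relations$rel_type == "problem_observable", ]
  prob <- ex$mentions[ex$mentions$mention_id == r$arg1, ]
  expect_identical(prob$concept_id, "RID3277")
})

test_that("value association attaches numbers to observables or drops them", {
  doc <- new_document("v1", "imaging_report",
                      "ventricular septal defect lesion size 0.5 cm")
  ex <- extract_document(doc, term, cfg)
  expect_identical(nrow(ex$values), 1L)
  expect_identical(ex$values$value, 0.5)
  expect_identical(ex$values$unit, "cm")
  obs <- ex$mentions[ex$mentions$mention_id == ex$values$observable, ]
  expect_identical(obs$concept_id, "SCT:246116008")
  rp <- ex$mentions[ex$mentions$mention_id == ex$values$related_problem, ]
  expect_identical(rp$concept_id, "RID3277")
  ## provenance span covers number and unit
  expect_identical(substr(doc$text, ex$values$start + 1, ex$values$end),
                   "0.5 cm")

  doc <- new_document("v2", "admission_record", "temperature 38.5")
  ex <- extract_document(doc, term, cfg)
  expect_identical(ex$values$value, 38.5)
  expect_identical(ex$values$unit, "")

  doc <- new_document("v3", "imaging_report", "Measured 0.5 cm.")
  ex <- extract_document(doc, term, cfg)
  expect_identical(nrow(ex$values), 0L)
  expect_identical(nrow(ex$dropped_values), 1L)
})

test_that("extraction is deterministic, consistent and span-sound", {
  doc <- new_document("p0", "admission_record", "")
  ex <- extract_document(doc, term, cfg)
  expect_identical(nrow(ex$mentions), 0L)
  expect_identical(nrow(ex$relations), 0L)
  expect_identical(nrow(ex$values), 0L)

  cohort <- generate_cohort(chd_form(), generator_config(seed = 99), 4)
  for (cs in cohort) {
    for (doc in cs$documents) {
      ex1 <- extract_document(doc, term, cfg)
      ex2 <- extract_document(doc, term, cfg)
      expect_identical(extraction_to_json(ex1), extraction_to_json(ex2))
      m <- ex1$mentions
      ## provenance round-trip: text[span] == surface
      expect_identical(substring(doc$text, m$start + 1, m$end), m$surface)
      ## every relation satisfies its category signature and references
      ## listed mentions
      for (k in seq_len(nrow(ex1$relations))) {
        r <- ex1$relations[k, ]
        sig <- ecrfpop:::REL_SIGS[[r$rel_type]]
        expect_identical(m$category[m$mention_id == r$arg1], sig[1])
        expect_identical(m$category[m$mention_id == r$arg2], sig[2])
      }
      if (nrow(ex1$values)) {
        expect_true(all(ex1$values$observable %in% m$mention_id))
        expect_true(all(m$category[match(ex1$values$observable,
                                         m$mention_id)] == "observable"))
      }
    }
  }
})
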