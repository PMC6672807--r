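## Synthetic clinical cases with known gold answers, plus a stochastic model
## of participant data-entry behaviour (noticing, fixing, or keeping wrong
## prefills; spurious changes; right-skewed per-section timings), so the
## whole pipeline and its evaluation statistics can be exercised with no
## access to real medical records. All identifiers outside the handful of
## real SNOMED-CT / RadLex bindings use the "SYN:" namespace to mark
## them as synthetic.

fixture_concepts <- function() {
  C <- function(id, cat, pref, ...) {
    syn <- c(...)
    data.frame(concept_id = id, category = cat, preferred_term = pref,
               synonyms = paste(c(pref, syn), collapse = "|"),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    ## the four real SNOMED-CT / RadLex bindings
    C("SCT:3006004", "medical_problem", "disturbance of consciousness",
      "impaired consciousness"),
    C("SCT:42842009", "medical_problem", "cardiac murmur", "heart murmur"),
    C("SCT:246116008", "observable", "lesion size"),
    C("RID3277", "medical_problem", "ventricular septal defect", "vsd"),
    ## admission-record problems (true-false I pools)
    C("SYN:MP001", "medical_problem", "fever", "pyrexia"),
    C("SYN:MP002", "medical_problem", "cough"),
    C("SYN:MP003", "medical_problem", "feeding difficulty", "poor feeding"),
    C("SYN:MP004", "medical_problem", "failure to thrive"),
    C("SYN:MP005", "medical_problem", "recurrent respiratory infection"),
    C("SYN:MP006", "medical_problem", "lower limb edema"),
    C("SYN:MP007", "medical_problem", "chest pain"),
    C("SYN:MP008", "medical_problem", "syncope", "fainting"),
    C("SYN:MP009", "medical_problem", "hepatomegaly", "enlarged liver"),
    C("SYN:MP010", "medical_problem", "wheezing", "wheeze"),
    C("SYN:MP011", "medical_problem", "poor appetite"),
    C("SYN:MP012", "medical_problem", "vomiting", "emesis"),
    C("SYN:MP013", "medical_problem", "diarrhea"),
    C("SYN:MP014", "medical_problem", "lethargy"),
    C("SYN:MP015", "medical_problem", "rhinorrhea", "runny nose"),
    C("SYN:MP016", "medical_problem", "sore throat"),
    ## imaging findings (true-false II pools)
    C("SYN:MP020", "medical_problem", "atrial septal defect", "asd"),
    C("SYN:MP021", "medical_problem", "patent ductus arteriosus", "pda"),
    C("SYN:MP022", "medical_problem", "patent foramen ovale", "pfo"),
    C("SYN:MP023", "medical_problem", "tricuspid regurgitation"),
    C("SYN:MP024", "medical_problem", "mitral regurgitation"),
    C("SYN:MP025", "medical_problem", "pulmonary hypertension"),
    C("SYN:MP026", "medical_problem", "left atrial enlargement"),
    C("SYN:MP027", "medical_problem", "pericardial effusion"),
    C("SYN:MP028", "medical_problem", "aortic coarctation"),
    C("SYN:MP029", "medical_problem", "right ventricular hypertrophy"),
    C("SYN:MP030", "medical_problem", "patchy infiltration"),
    C("SYN:MP031", "medical_problem", "lobar consolidation"),
    C("SYN:MP032", "medical_problem", "pleural effusion"),
    C("SYN:MP033", "medical_problem", "hilar lymphadenopathy"),
    C("SYN:MP034", "medical_problem", "atelectasis"),
    C("SYN:MP035", "medical_problem", "pneumothorax"),
    C("SYN:MP036", "medical_problem", "bronchial wall thickening"),
    C("SYN:MP037", "medical_problem", "increased lung markings"),
    C("SYN:MP038", "medical_problem", "cardiomegaly", "enlarged heart"),
    C("SYN:MP039", "medical_problem", "interstitial infiltration"),
    ## multiple-choice option pools
    C("SYN:MP040", "medical_problem", "cyanosis"),
    C("SYN:MP041", "medical_problem", "dyspnea", "shortness of breath"),
    C("SYN:MP042", "medical_problem", "diaphoresis", "excessive sweating"),
    C("SYN:MP043", "medical_problem", "palpitations"),
    C("SYN:MP044", "medical_problem", "fatigue"),
    C("SYN:MP045", "medical_problem", "hemoptysis"),
    C("SYN:MP046", "medical_problem", "night sweats"),
    C("SYN:MP047", "medical_problem", "chills", "rigors"),
    C("SYN:MP048", "medical_problem", "tuberculosis exposure"),
    C("SYN:MP049", "medical_problem", "influenza contact"),
    C("SYN:MP050", "medical_problem", "allergic rhinitis"),
    ## fill-in-the-blank problems
    C("SYN:MP060", "medical_problem", "left ventricular dysfunction"),
    C("SYN:MP061", "medical_problem", "pulmonary valve stenosis"),
    C("SYN:MP062", "medical_problem", "aortic dilatation"),
    ## treatments
    C("SYN:TR001", "treatment", "digoxin"),
    C("SYN:TR002", "treatment", "furosemide"),
    C("SYN:TR003", "treatment", "captopril"),
    C("SYN:TR004", "treatment", "azithromycin"),
    C("SYN:TR005", "treatment", "amoxicillin"),
    C("SYN:TR006", "treatment", "oseltamivir"),
    ## tests
    C("SYN:TE001", "test", "echocardiography", "cardiac ultrasound"),
    C("SYN:TE002", "test", "electrocardiogram", "ecg"),
    C("SYN:TE003", "test", "chest radiograph", "chest x ray"),
    C("SYN:TE004", "test", "sputum culture"),
    C("SYN:TE005", "test", "blood culture"),
    C("SYN:TE006", "test", "c reactive protein", "crp"),
    ## observables (fill-in-the-blank)
    C("SYN:OB001", "observable", "ejection fraction"),
    C("SYN:OB002", "observable", "pressure gradient"),
    C("SYN:OB003", "observable", "ascending aorta diameter"),
    C("SYN:OB004", "observable", "body temperature", "temperature"),
    ## body structures, qualifiers, values (category coverage)
    C("SYN:BS001", "body_structure", "left ventricle"),
    C("SYN:BS002", "body_structure", "right atrium"),
    C("SYN:BS003", "body_structure", "pulmonary artery"),
    C("SYN:BS004", "body_structure", "mitral valve"),
    C("SYN:QU001", "qualifier", "mild"),
    C("SYN:QU002", "qualifier", "moderate"),
    C("SYN:QU003", "qualifier", "severe"),
    C("SYN:VA001", "value", "positive"),
    C("SYN:VA002", "value", "trace")))
}

#' Built-in fixture terminology
#'
#' A deterministic coded vocabulary covering all seven concept categories,
#' including four real SNOMED-CT / RadLex bindings (SCT:3006004 disturbance of
#' consciousness, SCT:42842009 cardiac murmur, SCT:246116008 lesion size,
#' RID3277 ventricular septal defect); everything else is synthetic
#' ("SYN:" namespace).
#'
#' @return an `ecrf_terminology`.
#' @export
build_fixture_terminology <- function() {
  terminology_from_table(fixture_concepts())
}

#' Default value ranges for fill-in-the-blank observables
#' @return named list by observable concept id: list(min, max, unit).
#' @export
fixture_value_ranges <- function() {
  list("SCT:246116008" = list(min = 0.2, max = 2.0, unit = "cm"),
       "SYN:OB001" = list(min = 40, max = 75, unit = "%"),
       "SYN:OB002" = list(min = 10, max = 80, unit = "mmHg"),
       "SYN:OB003" = list(min = 18, max = 40, unit = "mm"),
       "SYN:OB004" = list(min = 36, max = 41, unit = "°C"))
}

tf_element <- function(id, label, cid, src)
  list(element_id = id, label = label, element_kind = "true_false",
       source_doc_type = src, binding = list(concept_id = cid))

mc_element <- function(id, label, options, src = "admission_record")
  list(element_id = id, label = label, element_kind = "multiple_choice",
       source_doc_type = src,
       binding = list(options = lapply(names(options), function(l)
         list(option_label = l, concept_id = options[[l]]))))

fib_element <- function(id, label, obs, prob, unit,
                        src = "imaging_report")
  list(element_id = id, label = label, element_kind = "fill_in_blank",
       source_doc_type = src,
       binding = list(observable_concept_id = obs,
                      related_problem_concept_id = prob,
                      expected_unit = unit))

#' Fixture congenital-heart-disease style eCRF
#'
#' 28 elements in 4 sections: 10 tri-state elements from the admission
#' record, 10 from the imaging report, 4 multiple-choice elements, and 4
#' fill-in-the-blank elements (e.g. "the lesion size of ventricular septal
#' defect is ___ cm").
#'
#' @return an `ecrf_form`.
#' @export
chd_form <- function() {
  tf1 <- list(
    c("chd_tf1_01", "Disturbance of consciousness", "SCT:3006004"),
    c("chd_tf1_02", "Fever", "SYN:MP001"),
    c("chd_tf1_03", "Feeding difficulty", "SYN:MP003"),
    c("chd_tf1_04", "Failure to thrive", "SYN:MP004"),
    c("chd_tf1_05", "Recurrent respiratory infection", "SYN:MP005"),
    c("chd_tf1_06", "Lower limb edema", "SYN:MP006"),
    c("chd_tf1_07", "Chest pain", "SYN:MP007"),
    c("chd_tf1_08", "Syncope", "SYN:MP008"),
    c("chd_tf1_09", "Hepatomegaly", "SYN:MP009"),
    c("chd_tf1_10", "Wheezing", "SYN:MP010"))
  tf2 <- list(
    c("chd_tf2_01", "Atrial septal defect", "SYN:MP020"),
    c("chd_tf2_02", "Patent ductus arteriosus", "SYN:MP021"),
    c("chd_tf2_03", "Patent foramen ovale", "SYN:MP022"),
    c("chd_tf2_04", "Tricuspid regurgitation", "SYN:MP023"),
    c("chd_tf2_05", "Mitral regurgitation", "SYN:MP024"),
    c("chd_tf2_06", "Pulmonary hypertension", "SYN:MP025"),
    c("chd_tf2_07", "Left atrial enlargement", "SYN:MP026"),
    c("chd_tf2_08", "Pericardial effusion", "SYN:MP027"),
    c("chd_tf2_09", "Aortic coarctation", "SYN:MP028"),
    c("chd_tf2_10", "Right ventricular hypertrophy", "SYN:MP029"))
  form_from_list(list(
    form_id = "chd_demo", condition_label = "congenital heart disease",
    sections = list(
      list(section_kind = "true_false_I",
           elements = lapply(tf1, function(x)
             tf_element(x[1], x[2], x[3], "admission_record"))),
      list(section_kind = "true_false_II",
           elements = lapply(tf2, function(x)
             tf_element(x[1], x[2], x[3], "imaging_report"))),
      list(section_kind = "multiple_choice", elements = list(
        mc_element("chd_mc_01", "Chief complaints",
                   c("cardiac murmur" = "SCT:42842009",
                     "cyanosis" = "SYN:MP040",
                     "dyspnea" = "SYN:MP041")),
        mc_element("chd_mc_02", "Accompanying symptoms",
                   c("diaphoresis" = "SYN:MP042",
                     "palpitations" = "SYN:MP043",
                     "fatigue" = "SYN:MP044")),
        mc_element("chd_mc_03", "Medication before admission",
                   c("digoxin" = "SYN:TR001",
                     "furosemide" = "SYN:TR002",
                     "captopril" = "SYN:TR003")),
        mc_element("chd_mc_04", "Examinations performed",
                   c("echocardiography" = "SYN:TE001",
                     "electrocardiogram" = "SYN:TE002",
                     "chest radiograph" = "SYN:TE003")))),
      list(section_kind = "fill_in_blank", elements = list(
        fib_element("chd_fib_01",
                    "Lesion size of ventricular septal defect (cm)",
                    "SCT:246116008", "RID3277", "cm"),
        fib_element("chd_fib_02",
                    "Ejection fraction with left ventricular dysfunction (%)",
                    "SYN:OB001", "SYN:MP060", "%"),
        fib_element("chd_fib_03",
                    "Pressure gradient of pulmonary valve stenosis (mmHg)",
                    "SYN:OB002", "SYN:MP061", "mmHg"),
        fib_element("chd_fib_04",
                    "Ascending aorta diameter with aortic dilatation (mm)",
                    "SYN:OB003", "SYN:MP062", "mm"))))))
}

#' Fixture pneumonia style eCRF
#'
#' 24 elements in 3 sections (no fill-in-the-blank part): 10 tri-state
#' elements from the admission record, 10 from the chest imaging report and
#' 4 multiple-choice elements.
#'
#' @return an `ecrf_form`.
#' @export
pneumonia_form <- function() {
  tf1 <- list(
    c("pn_tf1_01", "Fever", "SYN:MP001"),
    c("pn_tf1_02", "Cough", "SYN:MP002"),
    c("pn_tf1_03", "Poor appetite", "SYN:MP011"),
    c("pn_tf1_04", "Vomiting", "SYN:MP012"),
    c("pn_tf1_05", "Diarrhea", "SYN:MP013"),
    c("pn_tf1_06", "Lethargy", "SYN:MP014"),
    c("pn_tf1_07", "Rhinorrhea", "SYN:MP015"),
    c("pn_tf1_08", "Sore throat", "SYN:MP016"),
    c("pn_tf1_09", "Chest pain", "SYN:MP007"),
    c("pn_tf1_10", "Wheezing", "SYN:MP010"))
  tf2 <- list(
    c("pn_tf2_01", "Patchy infiltration", "SYN:MP030"),
    c("pn_tf2_02", "Lobar consolidation", "SYN:MP031"),
    c("pn_tf2_03", "Pleural effusion", "SYN:MP032"),
    c("pn_tf2_04", "Hilar lymphadenopathy", "SYN:MP033"),
    c("pn_tf2_05", "Atelectasis", "SYN:MP034"),
    c("pn_tf2_06", "Pneumothorax", "SYN:MP035"),
    c("pn_tf2_07", "Bronchial wall thickening", "SYN:MP036"),
    c("pn_tf2_08", "Increased lung markings", "SYN:MP037"),
    c("pn_tf2_09", "Cardiomegaly", "SYN:MP038"),
    c("pn_tf2_10", "Interstitial infiltration", "SYN:MP039"))
  form_from_list(list(
    form_id = "pneumonia_demo", condition_label = "pneumonia",
    sections = list(
      list(section_kind = "true_false_I",
           elements = lapply(tf1, function(x)
             tf_element(x[1], x[2], x[3], "admission_record"))),
      list(section_kind = "true_false_II",
           elements = lapply(tf2, function(x)
             tf_element(x[1], x[2], x[3], "imaging_report"))),
      list(section_kind = "multiple_choice", elements = list(
        mc_element("pn_mc_01", "Accompanying symptoms",
                   c("hemoptysis" = "SYN:MP045",
                     "night sweats" = "SYN:MP046",
                     "chills" = "SYN:MP047")),
        mc_element("pn_mc_02", "Antimicrobial treatment",
                   c("azithromycin" = "SYN:TR004",
                     "amoxicillin" = "SYN:TR005",
                     "oseltamivir" = "SYN:TR006")),
        mc_element("pn_mc_03", "Microbiological tests",
                   c("sputum culture" = "SYN:TE004",
                     "blood culture" = "SYN:TE005",
                     "c reactive protein" = "SYN:TE006")),
        mc_element("pn_mc_04", "Relevant history",
                   c("tuberculosis exposure" = "SYN:MP048",
                     "influenza contact" = "SYN:MP049",
                     "allergic rhinitis" = "SYN:MP050")))))))
}

#' Synthetic case generator configuration
#'
#' @param condition_style "chd_like" or "pneumonia_like" (selects the matching
#'   fixture form in helpers; the generator itself takes any form).
#' @param finding_prevalence probability an element's finding is addressed in
#'   the narrative at all (vs not mentioned).
#' @param negation_prob probability an addressed finding is negated.
#' @param synonym_variant_prob probability a planted term is rendered with a
#'   non-preferred synonym.
#' @param typo_char_edit_prob probability a planted term receives one random
#'   character edit (deletion, substitution or transposition).
#' @param value_ranges named list by observable concept id
#'   (`list(min, max, unit)`); defaults to [fixture_value_ranges()].
#' @param seed integer seed.
#' @return a list of class `ecrf_generator_config`.
#' @export
generator_config <- function(condition_style = c("chd_like", "pneumonia_like"),
                             finding_prevalence = 0.7,
                             negation_prob = 0.25,
                             synonym_variant_prob = 0.3,
                             typo_char_edit_prob = 0.05,
                             value_ranges = fixture_value_ranges(),
                             seed = 20260923) {
  probs <- c(finding_prevalence, negation_prob, synonym_variant_prob,
             typo_char_edit_prob)
  stopifnot(all(probs >= 0), all(probs <= 1))
  for (vr in value_ranges) stopifnot(vr$min < vr$max)
  structure(list(condition_style = match.arg(condition_style),
                 finding_prevalence = finding_prevalence,
                 negation_prob = negation_prob,
                 synonym_variant_prob = synonym_variant_prob,
                 typo_char_edit_prob = typo_char_edit_prob,
                 value_ranges = value_ranges, seed = as.integer(seed)),
            class = "ecrf_generator_config")
}

apply_typo <- function(s) {
  ch <- split_chars(s)
  n <- length(ch)
  if (n < 2) return(s)
  pos <- sample.int(n, 1)
  op <- sample(c("delete", "substitute", "transpose"), 1)
  if (op == "delete") {
    ch <- ch[-pos]
  } else if (op == "substitute") {
    ch[pos] <- sample(letters, 1)
  } else {
    if (pos == n) pos <- n - 1L
    tmp <- ch[pos]; ch[pos] <- ch[pos + 1L]; ch[pos + 1L] <- tmp
  }
  paste(ch, collapse = "")
}

render_term <- function(term, concept_id, cfg) {
  syns <- get_concept(term, concept_id)$synonyms[[1]]
  s <- syns[1]
  if (length(syns) > 1 && runif(1) < cfg$synonym_variant_prob)
    s <- sample(syns[-1], 1)
  if (runif(1) < cfg$typo_char_edit_prob) s <- apply_typo(s)
  s
}

AFFIRM_ADM <- c("The patient had %s.", "%s was noted on admission.",
                "Physical examination revealed %s.",
                "History was significant for %s.")
NEGATE_ADM <- c("There was no %s.", "The patient denied %s.",
                "No %s was noted.")
AFFIRM_IMG <- c("The study showed %s.", "%s was seen.",
                "Imaging demonstrated %s.")
NEGATE_IMG <- c("No %s was seen.", "There was no %s.")
AFFIRM_ACT <- c("The patient received %s.", "%s was given.")
NEGATE_ACT <- c("The patient did not receive %s.", "No %s was given.")
AFFIRM_TEST <- c("%s was performed.", "The patient underwent %s.")
NEGATE_TEST <- c("No %s was performed.")

sentence_for <- function(surface, category, doc_type, negated) {
  pool <- if (category %in% c("treatment")) {
    if (negated) NEGATE_ACT else AFFIRM_ACT
  } else if (category %in% c("test")) {
    if (negated) NEGATE_TEST else AFFIRM_TEST
  } else if (doc_type == "imaging_report") {
    if (negated) NEGATE_IMG else AFFIRM_IMG
  } else {
    if (negated) NEGATE_ADM else AFFIRM_ADM
  }
  tpl <- sample(pool, 1)
  s <- sprintf(tpl, surface)
  ## sentence-initial surfaces keep their case; capitalisation is cosmetic
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

#' Generate one synthetic case
#'
#' Draws a ground-truth state for every element of the form (addressed with
#' probability `finding_prevalence`, negated with `negation_prob` when
#' addressed; fill-in values uniform over the observable's range, one
#' decimal), renders template sentences into the admission record or imaging
#' report matching each element's source document type (with synonym and
#' typo noise), and records the drawn truth as the gold answer set.
#'
#' @param form an `ecrf_form` (validated against the fixture terminology).
#' @param cfg a [generator_config()].
#' @param term terminology used for surface forms (default fixture).
#' @return list with `documents` (admission record, imaging report), `gold`
#'   (an `ecrf_answer_set`), and `planted` (data.frame of planted concept
#'   mentions with their assertions).
#' @export
generate_case <- function(form, cfg = generator_config(),
                          term = build_fixture_terminology()) {
  set.seed(cfg$seed)
  case_id <- sprintf("case%08d", cfg$seed %% 1e8)
  texts <- list(admission_record = sprintf("Record %s.", case_id),
                imaging_report = sprintf("Report %s.", case_id))
  planted <- list()
  plant <- function(doc_type, concept_id, negated) {
    surface <- render_term(term, concept_id, cfg)
    sen <- sentence_for(surface,
                        get_concept(term, concept_id)$category,
                        doc_type, negated)
    texts[[doc_type]] <<- paste(texts[[doc_type]], sen)
    planted[[length(planted) + 1L]] <<- data.frame(
      doc_type = doc_type, concept_id = concept_id,
      assertion = if (negated) "absent" else "present",
      surface = surface, stringsAsFactors = FALSE)
  }
  answers <- list()
  for (el in form_elements(form)) {
    src <- el$source_doc_type
    if (el$element_kind == "true_false") {
      if (runif(1) < cfg$finding_prevalence) {
        neg <- runif(1) < cfg$negation_prob
        plant(src, el$binding$concept_id, neg)
        val <- if (neg) "false" else "true"
      } else val <- "not_mentioned"
      answers[[length(answers) + 1L]] <-
        new_answer(el$element_id, "true_false", val, entry_mode = "manual")
    } else if (el$element_kind == "multiple_choice") {
      sel <- character(0)
      for (op in el$binding$options) {
        if (runif(1) < cfg$finding_prevalence) {
          neg <- runif(1) < cfg$negation_prob
          plant(src, op$concept_id, neg)
          if (!neg) sel <- c(sel, op$option_label)
        }
      }
      answers[[length(answers) + 1L]] <-
        new_answer(el$element_id, "multiple_choice", sel,
                   entry_mode = "manual")
    } else {
      b <- el$binding
      if (runif(1) < cfg$finding_prevalence) {
        vr <- cfg$value_ranges[[b$observable_concept_id]] %||%
          list(min = 0, max = 10, unit = "")
        val <- round_half_up(runif(1, vr$min, vr$max), 1)
        obs_surface <- render_term(term, b$observable_concept_id, cfg)
        prob_surface <- render_term(term, b$related_problem_concept_id, cfg)
        sen <- sprintf("The %s of the %s was %s %s.", obs_surface,
                       prob_surface, sprintf("%.1f", val), vr$unit)
        sen <- paste0(toupper(substr(sen, 1, 1)), substr(sen, 2, nchar(sen)))
        texts[[src]] <- paste(texts[[src]], sen)
        planted[[length(planted) + 1L]] <- data.frame(
          doc_type = src, concept_id = b$observable_concept_id,
          assertion = "present", surface = obs_surface,
          stringsAsFactors = FALSE)
        planted[[length(planted) + 1L]] <- data.frame(
          doc_type = src, concept_id = b$related_problem_concept_id,
          assertion = "present", surface = prob_surface,
          stringsAsFactors = FALSE)
        ans_val <- list(value = val, unit = vr$unit)
      } else ans_val <- NULL
      answers[[length(answers) + 1L]] <-
        new_answer(el$element_id, "fill_in_blank", ans_val,
                   entry_mode = "manual")
    }
  }
  docs <- list(new_document(case_id, "admission_record",
                            texts$admission_record),
               new_document(case_id, "imaging_report",
                            texts$imaging_report))
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(doc_type = character(0), concept_id = character(0),
               assertion = character(0), surface = character(0),
               stringsAsFactors = FALSE)
  list(documents = docs, gold = new_answer_set(case_id, answers),
       planted = planted)
}

#' Generate a cohort of synthetic cases
#'
#' @param form an `ecrf_form`.
#' @param cfg a [generator_config()]; per-case seeds derive from `cfg$seed`.
#' @param n_cases number of cases (two documents each).
#' @param term terminology for surface forms.
#' @return list of [generate_case()] results.
#' @export
generate_cohort <- function(form, cfg = generator_config(), n_cases = 60,
                            term = build_fixture_terminology()) {
  stopifnot(n_cases >= 1)
  set.seed(cfg$seed)
  case_seeds <- sample.int(2^30, n_cases)
  lapply(seq_len(n_cases), function(i) {
    ci <- cfg
    ci$seed <- case_seeds[i]
    generate_case(form, ci, term)
  })
}

#' Participant data-entry behaviour configuration
#'
#' @param p_notice_error probability the participant detects a wrong prefill.
#' @param p_fix_correct probability a modification of a detected error lands
#'   on the gold answer.
#' @param p_spurious_change probability a correct prefill is altered anyway.
#' @param timing named list by section kind of `c(meanlog, sdlog)` for the
#'   lognormal per-section elapsed time (seconds); right-skewed, as reaction
#'   times are.
#' @param seed integer seed.
#' @return a list of class `ecrf_behavior_config`.
#' @export
behavior_config <- function(p_notice_error, p_fix_correct,
                            p_spurious_change = 0,
                            timing = NULL, seed = 1L) {
  probs <- c(p_notice_error, p_fix_correct, p_spurious_change)
  stopifnot(all(probs >= 0), all(probs <= 1))
  if (!is.null(timing))
    for (t in timing) stopifnot(length(t) == 2, t[2] > 0)
  structure(list(p_notice_error = p_notice_error,
                 p_fix_correct = p_fix_correct,
                 p_spurious_change = p_spurious_change,
                 timing = timing, seed = as.integer(seed)),
            class = "ecrf_behavior_config")
}

## default timing parameters: meanlog = log of the reference per-section
## median seconds (lognormal median = exp(meanlog)), sdlog 0.3
timing_defaults <- function(arm = c("manual", "assisted")) {
  arm <- match.arg(arm)
  med <- if (arm == "manual")
    c(true_false_I = 26.43, true_false_II = 49.48, multiple_choice = 9.70,
      fill_in_blank = 18.41)
  else
    c(true_false_I = 13.84, true_false_II = 35.47, multiple_choice = 7.34,
      fill_in_blank = 12.38)
  lapply(as.list(med), function(m) c(meanlog = log(m), sdlog = 0.3))
}

#' Default manual-entry behaviour
#' @param seed integer seed.
#' @return an `ecrf_behavior_config`.
#' @export
manual_behavior <- function(seed = 1L) {
  behavior_config(p_notice_error = 0.95, p_fix_correct = 0.95,
                  p_spurious_change = 0, timing = timing_defaults("manual"),
                  seed = seed)
}

#' Default assisted-entry (prefill-review) behaviour
#' @param seed integer seed.
#' @return an `ecrf_behavior_config`.
#' @export
assisted_behavior <- function(seed = 1L) {
  behavior_config(p_notice_error = 0.5, p_fix_correct = 0.9,
                  p_spurious_change = 0.02,
                  timing = timing_defaults("assisted"), seed = seed)
}

#' Default double-entry researcher behaviour (gold-standard raters)
#' @param seed integer seed.
#' @return an `ecrf_behavior_config`.
#' @export
researcher_behavior <- function(seed = 1L) {
  behavior_config(p_notice_error = 0.98, p_fix_correct = 0.98,
                  p_spurious_change = 0.005,
                  timing = timing_defaults("manual"), seed = seed)
}

random_wrong_value <- function(el, gold, current, value_ranges) {
  if (el$element_kind == "true_false") {
    pool <- setdiff(TRI_STATE, c(gold, current))
    return(sample(pool, 1))
  }
  if (el$element_kind == "multiple_choice") {
    labels <- vapply(el$binding$options, `[[`, character(1), "option_label")
    for (i in 1:20) {
      k <- sample(0:length(labels), 1)
      cand <- if (k == 0) character(0) else sample(labels, k)
      if (!setequal(cand, gold %||% character(0)) &&
          !setequal(cand, current %||% character(0))) return(cand)
    }
    return(setdiff(labels, gold))
  }
  ## fill_in_blank
  vr <- value_ranges[[el$binding$observable_concept_id]]
  unit <- if (!is.null(vr)) vr$unit else (gold$unit %||% "")
  for (i in 1:20) {
    v <- if (!is.null(vr)) round_half_up(runif(1, vr$min, vr$max), 1)
    else if (!is.null(gold)) round_half_up(gold$value * runif(1, 0.5, 1.5), 1)
    else round_half_up(runif(1, 0, 10), 1)
    cand <- list(value = v, unit = unit)
    if (!answer_values_equal("fill_in_blank", cand, gold) &&
        !answer_values_equal("fill_in_blank", cand, current)) return(cand)
  }
  NULL
}

#' Simulate one participant completing one case
#'
#' Per element: a wrong prefill is noticed with `p_notice_error` and then
#' corrected to gold with `p_fix_correct` (otherwise changed to a random
#' wrong value); unnoticed wrong prefills are kept (commission errors).
#' Correct prefills are spuriously altered with `p_spurious_change`. Changed
#' answers get entry_mode "modified". Per-section elapsed times are drawn
#' lognormal from `beh$timing`.
#'
#' @param gold gold `ecrf_answer_set` for the case.
#' @param prepop the prefill baseline the participant reviews (use
#'   [empty_answer_set()] for a manual-entry participant).
#' @param beh a [behavior_config()].
#' @param form the `ecrf_form`.
#' @param value_ranges value ranges used when sampling wrong fill-in values.
#' @param seed optional seed; when NULL the current RNG stream is consumed.
#' @return list with `final` (`ecrf_answer_set`) and `timings` (data.frame
#'   section_kind, elapsed_seconds).
#' @export
simulate_participant <- function(gold, prepop, beh, form,
                                 value_ranges = fixture_value_ranges(),
                                 seed = beh$seed) {
  if (!is.null(seed)) set.seed(seed)
  els <- form_elements(form)
  answers <- lapply(names(els), function(eid) {
    el <- els[[eid]]
    g <- gold$answers[[eid]]; p <- prepop$answers[[eid]]
    if (is.null(g) || is.null(p))
      stop("gold and prefill must share element ", eid)
    correct <- answer_values_equal(el$element_kind, p$value, g$value)
    if (!correct) {
      if (runif(1) < beh$p_notice_error) {
        v <- if (runif(1) < beh$p_fix_correct) g$value
        else random_wrong_value(el, g$value, p$value, value_ranges)
        new_answer(eid, el$element_kind, v, entry_mode = "modified")
      } else p  # kept wrong prefill
    } else if (runif(1) < beh$p_spurious_change) {
      v <- random_wrong_value(el, g$value, p$value, value_ranges)
      new_answer(eid, el$element_kind, v, entry_mode = "modified")
    } else p
  })
  timings <- NULL
  if (!is.null(beh$timing)) {
    secs <- vapply(form$sections, `[[`, character(1), "section_kind")
    timings <- do.call(rbind, lapply(secs, function(sk) {
      par <- beh$timing[[sk]]
      if (is.null(par)) return(NULL)
      data.frame(section_kind = sk,
                 elapsed_seconds = rlnorm(1, par[1], par[2]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(final = new_answer_set(gold$case_id, answers,
                              participant_id = NULL, timings = timings),
       timings = timings)
}

#' Run a full in-silico data-entry experiment
#'
#' Generates a synthetic cohort, extracts and prepopulates every case, then
#' simulates two arms of participants: the manual arm enters answers from an
#' all-empty baseline, the assisted arm reviews the pipeline's prefills.
#' Produces the accuracy report, log-scale group comparisons for accuracy
#' and elapsed time, and the commission/cognitive error breakdown — the
#' synthetic analogue of an assisted-data-entry field study.
#'
#' @param form an `ecrf_form`.
#' @param gen_cfg a [generator_config()].
#' @param beh_manual,beh_assisted [behavior_config()]s for the two arms.
#' @param n_cases cases in the cohort.
#' @param n_participants_per_arm participants per arm.
#' @param master_seed seed from which all arm/participant seeds derive.
#' @param term terminology (default fixture).
#' @return list of class `ecrf_experiment_report`.
#' @export
run_experiment <- function(form, gen_cfg = generator_config(),
                           beh_manual = manual_behavior(),
                           beh_assisted = assisted_behavior(),
                           n_cases = 60, n_participants_per_arm = 12,
                           master_seed = 20260923,
                           term = build_fixture_terminology()) {
  set.seed(master_seed)
  gen_cfg$seed <- sample.int(2^30, 1)
  part_seeds <- matrix(sample.int(2^30, 2 * n_participants_per_arm),
                       nrow = 2)
  cohort <- generate_cohort(form, gen_cfg, n_cases, term)
  gold <- lapply(cohort, `[[`, "gold")
  names(gold) <- vapply(gold, `[[`, character(1), "case_id")
  xcfg <- extraction_config()
  pcfg <- prepopulate_config()
  prepop <- lapply(cohort, function(cs) {
    bundle <- extract_case(cs$gold$case_id, cs$documents, term, xcfg)
    prepopulate_case(form, bundle, pcfg)
  })
  names(prepop) <- names(gold)
  run_arm <- function(arm, beh, seeds) {
    out <- list()
    for (j in seq_len(n_participants_per_arm)) {
      set.seed(seeds[j])
      pid <- sprintf("%s_%02d", arm, j)
      sets <- lapply(names(gold), function(cid) {
        base <- if (arm == "manual")
          empty_answer_set(form, cid) else prepop[[cid]]
        r <- simulate_participant(gold[[cid]], base, beh, form,
                                  gen_cfg$value_ranges, seed = NULL)
        r$final$participant_id <- pid
        r$final
      })
      out[[pid]] <- sets
    }
    out
  }
  manual_sets <- run_arm("manual", beh_manual, part_seeds[1, ])
  assisted_sets <- run_arm("assisted", beh_assisted, part_seeds[2, ])

  acc_manual <- score_accuracy(manual_sets, gold, form)
  acc_assisted <- score_accuracy(assisted_sets, gold, form)
  acc_prepop <- score_accuracy(list(nlp_only = unname(prepop)), gold, form)
  overall <- function(rep) {
    d <- rep$per_participant
    d$accuracy[d$kind == "overall"][order(d$participant_id[d$kind == "overall"])]
  }
  acc_cmp <- compare_groups_log(overall(acc_manual), overall(acc_assisted))
  mean_case_time <- function(sets_by_pid)
    vapply(sets_by_pid, function(sets)
      mean(vapply(sets, function(s) sum(s$timings$elapsed_seconds),
                  numeric(1))), numeric(1))
  time_cmp <- compare_groups_log(mean_case_time(manual_sets),
                                 mean_case_time(assisted_sets))
  labels <- do.call(rbind, lapply(names(assisted_sets), function(pid) {
    do.call(rbind, lapply(assisted_sets[[pid]], function(s)
      classify_errors(prepop[[s$case_id]], s, gold[[s$case_id]])))
  }))
  structure(list(form_id = form$form_id, n_cases = n_cases,
                 n_participants_per_arm = n_participants_per_arm,
                 accuracy_manual = acc_manual,
                 accuracy_assisted = acc_assisted,
                 accuracy_prepopulation = acc_prepop,
                 accuracy_comparison = acc_cmp,
                 time_comparison = time_cmp,
                 error_labels = labels,
                 error_breakdown = error_percentages(labels)),
            class = "ecrf_experiment_report")
}

#' @export
print.ecrf_experiment_report <- function(x, ...) {
  cat(sprintf("<ecrf_experiment_report> %s: %d cases x %d participants/arm\n",
              x$form_id, x$n_cases, x$n_participants_per_arm))
  cat("accuracy: "); print(x$accuracy_comparison)
  cat("elapsed time: "); print(x$time_comparison)
  eb <- x$error_breakdown
  tot <- eb[eb$kind == "total", ]
  cat(sprintf("errors (assisted arm): %d total, %.2f%% without modification\n",
              tot$n_errors, tot$pct_without))
  invisible(x)
}
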