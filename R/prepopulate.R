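## Fill an eCRF from extraction results, answer by answer, carrying text
## provenance so every prefilled value can be traced back to the narrative
## ("back to" behaviour).

#' Prepopulation configuration
#'
#' @param conflict_policy how to resolve conflicting assertions of the same
#'   concept: "last_mention_wins" (document order; later statements in
#'   clinical notes tend to be conclusions) or "present_wins".
#' @param require_source_doc_type_match consult only documents of the
#'   element's source type (the true-false I/II split); default TRUE.
#' @return a list of class `ecrf_prepop_config`.
#' @export
prepopulate_config <- function(conflict_policy = c("last_mention_wins",
                                                   "present_wins"),
                               require_source_doc_type_match = TRUE) {
  structure(list(conflict_policy = match.arg(conflict_policy),
                 require_source_doc_type_match = require_source_doc_type_match),
            class = "ecrf_prepop_config")
}

#' Bundle a case's documents with their extractions
#'
#' @param case_id case identifier.
#' @param extractions list of `ecrf_extraction`, one per document (typically
#'   one admission record and one imaging report).
#' @return an `ecrf_case_bundle`.
#' @export
new_case_bundle <- function(case_id, extractions) {
  stopifnot(length(extractions) >= 1)
  structure(list(case_id = case_id, extractions = extractions),
            class = "ecrf_case_bundle")
}

#' Extract and bundle a case's documents
#' @param case_id case identifier.
#' @param docs list of `ecrf_document` for this case.
#' @param term an `ecrf_terminology`.
#' @param cfg an [extraction_config()].
#' @return an `ecrf_case_bundle`.
#' @export
extract_case <- function(case_id, docs, term, cfg = extraction_config()) {
  new_case_bundle(case_id, lapply(docs, extract_document, term = term,
                                  cfg = cfg))
}

## mentions of one concept across the bundle's documents (optionally
## restricted by doc type), in document order, with doc_type attached
bundle_mentions <- function(bundle, concept_id, source_doc_type, cfg) {
  out <- list()
  for (ex in bundle$extractions) {
    dt <- ex$document$doc_type
    if (cfg$require_source_doc_type_match && dt != source_doc_type) next
    m <- ex$mentions[ex$mentions$concept_id == concept_id, , drop = FALSE]
    if (nrow(m) == 0) next
    m$doc_type <- dt
    out[[length(out) + 1L]] <- m
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## resolve a concept's assertion across its mentions; returns NULL when the
## concept is unmentioned, else list(assertion, provenance rows)
resolve_assertion <- function(bundle, concept_id, source_doc_type, cfg) {
  m <- bundle_mentions(bundle, concept_id, source_doc_type, cfg)
  if (is.null(m)) return(NULL)
  if (length(unique(m$assertion)) > 1)
    log_msg("debug", "prepopulate",
            sprintf("conflicting assertions for %s in case %s (policy %s)",
                    concept_id, bundle$case_id, cfg$conflict_policy))
  if (cfg$conflict_policy == "present_wins" && any(m$assertion == "present")) {
    deciding <- m[m$assertion == "present", , drop = FALSE]
  } else {
    deciding <- m[m$assertion == m$assertion[nrow(m)], , drop = FALSE]
  }
  prov <- lapply(seq_len(nrow(deciding)), function(i)
    list(doc_type = deciding$doc_type[i], start = deciding$start[i],
         end = deciding$end[i]))
  list(assertion = deciding$assertion[1], provenance = prov)
}

#' Prepopulate a tri-state true-false element
#'
#' No mention of the bound concept in the element's source documents yields
#' "not_mentioned"; otherwise the resolved assertion (conflicts settled by
#' the configured policy) yields "true" or "false", with the deciding
#' mentions' spans as provenance.
#'
#' @param element a form element (from [form_elements()]).
#' @param bundle an `ecrf_case_bundle`.
#' @param cfg a [prepopulate_config()].
#' @return an answer (see [new_answer()]).
#' @export
answer_true_false <- function(element, bundle, cfg = prepopulate_config()) {
  stopifnot(element$element_kind == "true_false")
  r <- resolve_assertion(bundle, element$binding$concept_id,
                         element$source_doc_type, cfg)
  if (is.null(r))
    return(new_answer(element$element_id, "true_false", "not_mentioned"))
  new_answer(element$element_id, "true_false",
             if (r$assertion == "present") "true" else "false", r$provenance)
}

#' Prepopulate a multiple-choice element
#'
#' An option is selected iff its bound concept's resolved assertion is
#' "present" in the element's source documents.
#'
#' @inheritParams answer_true_false
#' @return an answer whose value is the set of selected option labels.
#' @export
answer_multiple_choice <- function(element, bundle,
                                   cfg = prepopulate_config()) {
  stopifnot(element$element_kind == "multiple_choice")
  sel <- character(0); prov <- list()
  for (op in element$binding$options) {
    r <- resolve_assertion(bundle, op$concept_id, element$source_doc_type, cfg)
    if (!is.null(r) && r$assertion == "present") {
      sel <- c(sel, op$option_label)
      prov <- c(prov, r$provenance)
    }
  }
  new_answer(element$element_id, "multiple_choice", sel, prov)
}

#' Prepopulate a fill-in-the-blank element
#'
#' Chooses the value assignment whose observable maps to the bound
#' observable concept and whose related problem maps to the bound problem
#' concept; the problem match is waived when no candidate assignment carries
#' one. Multiple survivors: first in document order (logged). A unit
#' differing from the binding's expected unit is still filled but logged.
#'
#' @inheritParams answer_true_false
#' @return an answer whose value is `list(value=, unit=)` or NULL.
#' @export
answer_fill_in_blank <- function(element, bundle,
                                 cfg = prepopulate_config()) {
  stopifnot(element$element_kind == "fill_in_blank")
  b <- element$binding
  cand <- list()
  for (ex in bundle$extractions) {
    dt <- ex$document$doc_type
    if (cfg$require_source_doc_type_match && dt != element$source_doc_type)
      next
    v <- ex$values
    if (nrow(v) == 0) next
    obs_concept <- ex$mentions$concept_id[match(v$observable,
                                                ex$mentions$mention_id)]
    prob_concept <- ex$mentions$concept_id[match(v$related_problem,
                                                 ex$mentions$mention_id)]
    keep <- which(obs_concept == b$observable_concept_id)
    for (i in keep) {
      cand[[length(cand) + 1L]] <- list(
        value = v$value[i], unit = v$unit[i],
        problem_concept = prob_concept[i],
        prov = list(doc_type = dt, start = v$start[i], end = v$end[i]))
    }
  }
  if (!length(cand))
    return(new_answer(element$element_id, "fill_in_blank", NULL))
  has_prob <- vapply(cand, function(c) !is.na(c$problem_concept), logical(1))
  if (any(has_prob)) {
    matched <- Filter(function(c) !is.na(c$problem_concept) &&
                        c$problem_concept == b$related_problem_concept_id,
                      cand)
    if (length(matched)) cand <- matched
    ## else: no assignment names the bound problem; fall through with all
    ## candidates (problem match waived only when none carries a problem)
    else if (all(has_prob))
      return(new_answer(element$element_id, "fill_in_blank", NULL))
    else cand <- cand[!has_prob]
  }
  if (length(cand) > 1)
    log_msg("debug", "prepopulate",
            sprintf("multiple value assignments for element %s; first wins",
                    element$element_id))
  ch <- cand[[1]]
  if (nzchar(b$expected_unit %||% "") && ch$unit != b$expected_unit)
    log_msg("warn", "prepopulate",
            sprintf("unit mismatch for element %s: got '%s', expected '%s'",
                    element$element_id, ch$unit, b$expected_unit))
  new_answer(element$element_id, "fill_in_blank",
             list(value = ch$value, unit = ch$unit), list(ch$prov))
}

#' Prepopulate a whole case
#'
#' Applies the kind-specific answer rule to every element of the form. The
#' form must validate against the terminology used for extraction
#' ([validate_bindings()]) — pass it as `term` to enforce this.
#'
#' @param form an `ecrf_form`.
#' @param bundle an `ecrf_case_bundle`.
#' @param cfg a [prepopulate_config()].
#' @param term optional `ecrf_terminology`; when supplied,
#'   [validate_bindings()] must come back clean or an error is raised.
#' @return an `ecrf_answer_set` with entry_mode "prepopulated" throughout.
#' @export
prepopulate_case <- function(form, bundle, cfg = prepopulate_config(),
                             term = NULL) {
  if (!is.null(term)) {
    rep <- validate_bindings(form, term)
    if (nrow(rep) > 0)
      stop("form failed binding validation: ",
           paste(sprintf("%s[%s]:%s", rep$element_id, rep$slot, rep$problem),
                 collapse = "; "))
  }
  answers <- lapply(form_elements(form), function(el) {
    switch(el$element_kind,
           true_false = answer_true_false(el, bundle, cfg),
           multiple_choice = answer_multiple_choice(el, bundle, cfg),
           fill_in_blank = answer_fill_in_blank(el, bundle, cfg))
  })
  new_answer_set(bundle$case_id, unname(answers))
}

#' An all-empty answer set for a form
#'
#' The baseline a manual data-entry participant starts from: every tri-state
#' element "not_mentioned", every choice empty, every blank unfilled.
#'
#' @param form an `ecrf_form`.
#' @param case_id case identifier.
#' @param entry_mode entry mode to stamp on the answers (default "manual").
#' @return an `ecrf_answer_set`.
#' @export
empty_answer_set <- function(form, case_id, entry_mode = "manual") {
  answers <- lapply(form_elements(form), function(el) {
    v <- switch(el$element_kind, true_false = "not_mentioned",
                multiple_choice = character(0), fill_in_blank = NULL)
    new_answer(el$element_id, el$element_kind, v, entry_mode = entry_mode)
  })
  new_answer_set(case_id, unname(answers))
}
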