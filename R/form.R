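## eCRF definitions: sections of data elements (tri-state true-false,
## multiple-choice, fill-in-the-blank) bound to terminology concepts, plus
## answer sets with provenance and entry mode.

section_source <- c(true_false_I = "admission_record",
                    true_false_II = "imaging_report")

kind_of_section <- function(section_kind) {
  switch(section_kind,
         true_false_I = , true_false_II = "true_false",
         multiple_choice = "multiple_choice",
         fill_in_blank = "fill_in_blank")
}

#' Load an eCRF definition from JSON
#'
#' A form has a `form_id`, a `condition_label` and 3 or 4 `sections`
#' (`true_false_I`, `true_false_II`, `multiple_choice`, `fill_in_blank`),
#' each holding data elements whose bindings name terminology concepts.
#'
#' @param path path to a form JSON file.
#' @return an `ecrf_form`.
#' @export
read_form <- function(path) {
  if (!file.exists(path)) stop("form file not found: ", path)
  form_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' Build an eCRF definition from a nested list
#'
#' @param x list mirroring the form JSON schema.
#' @return an `ecrf_form`; structural violations raise descriptive errors.
#' @export
form_from_list <- function(x) {
  for (f in c("form_id", "condition_label", "sections"))
    if (is.null(x[[f]])) stop("form is missing field '", f, "'")
  ns <- length(x$sections)
  if (ns < 3 || ns > 4)
    stop("a form must have 3 or 4 sections, got ", ns)
  seen_ids <- character(0)
  sections <- lapply(x$sections, function(sec) {
    sk <- sec$section_kind %||% stop("section missing section_kind")
    if (!sk %in% SECTION_KINDS)
      stop("unknown section_kind '", sk, "'")
    elements <- lapply(sec$elements, function(el) {
      for (f in c("element_id", "label", "element_kind", "binding"))
        if (is.null(el[[f]]))
          stop("element missing field '", f, "' in section ", sk)
      if (el$element_kind != kind_of_section(sk))
        stop("element '", el$element_id, "' of kind ", el$element_kind,
             " not allowed in section ", sk)
      src <- el$source_doc_type %||% section_source[[sk]] %||%
        stop("element '", el$element_id, "' missing source_doc_type")
      if (!src %in% DOC_TYPES)
        stop("bad source_doc_type '", src, "'")
      if (sk %in% names(section_source) && src != section_source[[sk]])
        stop("element '", el$element_id, "' in section ", sk,
             " must source from ", section_source[[sk]])
      b <- el$binding
      if (el$element_kind == "true_false") {
        if (is.null(b$concept_id)) stop("true_false element '", el$element_id,
                                        "' binding needs concept_id")
      } else if (el$element_kind == "multiple_choice") {
        if (is.null(b$options) || !length(b$options))
          stop("multiple_choice element '", el$element_id,
               "' binding needs options")
        for (op in b$options)
          if (is.null(op$option_label) || is.null(op$concept_id))
            stop("option of element '", el$element_id,
                 "' needs option_label and concept_id")
      } else {
        for (f in c("observable_concept_id", "related_problem_concept_id"))
          if (is.null(b[[f]]))
            stop("fill_in_blank element '", el$element_id,
                 "' binding needs ", f)
        b$expected_unit <- b$expected_unit %||% ""
      }
      list(element_id = el$element_id, label = el$label,
           element_kind = el$element_kind, source_doc_type = src, binding = b)
    })
    ids <- vapply(elements, `[[`, character(1), "element_id")
    seen_ids <<- c(seen_ids, ids)
    list(section_kind = sk, elements = elements)
  })
  if (anyDuplicated(seen_ids))
    stop("duplicate element_id in form: ",
         paste(unique(seen_ids[duplicated(seen_ids)]), collapse = ", "))
  structure(list(form_id = x$form_id, condition_label = x$condition_label,
                 sections = sections),
            class = "ecrf_form")
}

#' Write a form definition to JSON
#' @param form an `ecrf_form`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_form <- function(form, path) {
  js <- jsonlite::toJSON(unclass(form), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  writeLines(js, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.ecrf_form <- function(x, ...) {
  cat(sprintf("<ecrf_form> %s (%s): %d sections, %d elements\n", x$form_id,
              x$condition_label, length(x$sections), length(form_elements(x))))
  for (sec in x$sections)
    cat(sprintf("  %-16s %d elements\n", sec$section_kind,
                length(sec$elements)))
  invisible(x)
}

#' Flatten a form to its elements
#'
#' @param form an `ecrf_form`.
#' @return named list of elements (by element_id), each annotated with its
#'   `section_kind`.
#' @export
form_elements <- function(form) {
  out <- list()
  for (sec in form$sections) {
    for (el in sec$elements) {
      el$section_kind <- sec$section_kind
      out[[el$element_id]] <- el
    }
  }
  out
}

#' Check a form's concept bindings against a terminology
#'
#' @param form an `ecrf_form`.
#' @param term an `ecrf_terminology`.
#' @return data.frame report; zero rows means every binding resolves and has
#'   an acceptable category (true-false / choice slots: any non-value
#'   category; fill-in observable slot: category observable; related problem
#'   slot: medical_problem).
#' @export
validate_bindings <- function(form, term) {
  findings <- list()
  note <- function(el, slot, concept_id, problem)
    findings[[length(findings) + 1L]] <<- data.frame(
      element_id = el, slot = slot, concept_id = concept_id,
      problem = problem, stringsAsFactors = FALSE)
  check <- function(el, slot, cid, allowed) {
    i <- match(cid, term$concepts$concept_id)
    if (is.na(i)) { note(el, slot, cid, "missing_concept"); return() }
    if (!term$concepts$category[i] %in% allowed)
      note(el, slot, cid, "category_mismatch")
  }
  non_value <- setdiff(CATEGORIES, "value")
  for (el in form_elements(form)) {
    b <- el$binding
    switch(el$element_kind,
      true_false = check(el$element_id, "concept", b$concept_id, non_value),
      multiple_choice = for (op in b$options)
        check(el$element_id, paste0("option:", op$option_label),
              op$concept_id, non_value),
      fill_in_blank = {
        check(el$element_id, "observable", b$observable_concept_id,
              "observable")
        check(el$element_id, "related_problem", b$related_problem_concept_id,
              "medical_problem")
      })
  }
  if (!length(findings))
    return(data.frame(element_id = character(0), slot = character(0),
                      concept_id = character(0), problem = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

## ---- answers ----------------------------------------------------------

#' Construct a single answer
#'
#' Value shapes by element kind: true_false — one of "true", "false",
#' "not_mentioned"; multiple_choice — character vector of selected option
#' labels (order-free); fill_in_blank — list(value = number, unit = string)
#' or NULL when empty.
#'
#' @param element_id element identifier.
#' @param kind element kind.
#' @param value answer value in the kind's shape.
#' @param provenance list of spans, each
#'   `list(doc_type =, start =, end =)` (0-based half-open).
#' @param entry_mode one of "prepopulated", "manual", "modified".
#' @return an answer list.
#' @export
new_answer <- function(element_id, kind, value, provenance = list(),
                       entry_mode = "prepopulated") {
  kind <- match.arg(kind, ELEMENT_KINDS)
  entry_mode <- match.arg(entry_mode, ENTRY_MODES)
  if (kind == "true_false" && !(is.character(value) && value %in% TRI_STATE))
    stop("true_false answer must be one of ",
         paste(TRI_STATE, collapse = ", "))
  if (kind == "multiple_choice" && !is.character(value) &&
      !(is.null(value) || length(value) == 0))
    stop("multiple_choice answer must be a character vector of option labels")
  if (kind == "fill_in_blank" && !is.null(value)) {
    if (!is.list(value) || is.null(value$value))
      stop("fill_in_blank answer must be NULL or list(value=, unit=)")
    value$unit <- value$unit %||% ""
  }
  if (kind == "multiple_choice" && is.null(value)) value <- character(0)
  list(element_id = element_id, kind = kind, value = value,
       provenance = provenance, entry_mode = entry_mode)
}

#' Construct an answer set
#' @param case_id case identifier.
#' @param answers list of answers from [new_answer()].
#' @param participant_id optional participant identifier.
#' @param timings optional data.frame (section_kind, elapsed_seconds).
#' @return an `ecrf_answer_set`.
#' @export
new_answer_set <- function(case_id, answers, participant_id = NULL,
                           timings = NULL) {
  names(answers) <- vapply(answers, `[[`, character(1), "element_id")
  structure(list(case_id = case_id, answers = answers,
                 participant_id = participant_id, timings = timings),
            class = "ecrf_answer_set")
}

#' @export
print.ecrf_answer_set <- function(x, ...) {
  cat(sprintf("<ecrf_answer_set> case %s: %d answers%s\n", x$case_id,
              length(x$answers),
              if (is.null(x$participant_id)) ""
              else paste0(", participant ", x$participant_id)))
  invisible(x)
}

#' Test two answer values for equality under the scoring rules
#'
#' Tri-state answers compare exactly; multiple-choice selections compare as
#' label sets; fill-in-the-blank answers compare by exact unit match and
#' numeric agreement within 1e-9 (empty equals empty only).
#'
#' @param kind element kind.
#' @param a,b answer values in the kind's shape.
#' @return logical scalar.
#' @export
answer_values_equal <- function(kind, a, b) {
  switch(kind,
    true_false = identical(a, b),
    multiple_choice = setequal(a %||% character(0), b %||% character(0)),
    fill_in_blank = {
      ea <- is.null(a) || is.null(a$value); eb <- is.null(b) || is.null(b$value)
      if (ea || eb) return(ea && eb)
      identical(a$unit %||% "", b$unit %||% "") &&
        abs(a$value - b$value) <= 1e-9
    },
    stop("unknown element kind: ", kind))
}

answer_to_list <- function(a) {
  v <- a$value
  if (a$kind == "multiple_choice") v <- as.list(v %||% character(0))
  list(element_id = a$element_id, kind = a$kind, value = v,
       provenance = lapply(a$provenance, function(p)
         list(doc_type = p$doc_type, start = p$start, end = p$end)),
       entry_mode = a$entry_mode)
}

#' Serialize an answer set to JSON
#' @param x an `ecrf_answer_set`.
#' @param path optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
serialize_answers <- function(x, path = NULL) {
  obj <- list(case_id = x$case_id,
              participant_id = x$participant_id,
              answers = lapply(unname(x$answers), answer_to_list),
              timings = if (is.null(x$timings)) NULL else x$timings)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}

#' Parse an answer set from JSON
#'
#' @param txt JSON string, or a file path when `file = TRUE`.
#' @param form optional `ecrf_form`; when given, element ids and value shapes
#'   are validated against it.
#' @param file whether `txt` is a path.
#' @return an `ecrf_answer_set`.
#' @export
parse_answers <- function(txt, form = NULL, file = FALSE) {
  obj <- jsonlite::fromJSON(if (file) txt else as.character(txt),
                            simplifyVector = FALSE)
  els <- if (!is.null(form)) form_elements(form) else NULL
  answers <- lapply(obj$answers, function(a) {
    if (!is.null(els) && is.null(els[[a$element_id]]))
      stop("unknown element_id in answer set: ", a$element_id)
    kind <- a$kind
    if (!is.null(els)) kind <- els[[a$element_id]]$element_kind
    v <- a$value
    if (kind == "multiple_choice") {
      v <- as.character(unlist(v))
    } else if (kind == "true_false") {
      if (!is.character(v) || length(v) != 1 || !v %in% TRI_STATE)
        stop("invalid tri-state value for element ", a$element_id, ": ",
             deparse(v))
    } else if (kind == "fill_in_blank" && !is.null(v)) {
      v <- list(value = as.numeric(v$value), unit = v$unit %||% "")
    }
    prov <- lapply(a$provenance, function(p)
      list(doc_type = p$doc_type, start = as.integer(p$start),
           end = as.integer(p$end)))
    new_answer(a$element_id, kind, v, prov, a$entry_mode %||% "manual")
  })
  timings <- NULL
  if (!is.null(obj$timings) && length(obj$timings)) {
    timings <- do.call(rbind, lapply(obj$timings, function(t)
      data.frame(section_kind = t$section_kind,
                 elapsed_seconds = as.numeric(t$elapsed_seconds),
                 stringsAsFactors = FALSE)))
  }
  new_answer_set(obj$case_id, answers, obj$participant_id, timings)
}
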