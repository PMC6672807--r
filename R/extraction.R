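## Deterministic extraction pipeline over clinical narratives:
## sentence/token segmentation -> dictionary + fuzzy entity recognition ->
## assertion (negation) classification -> relation extraction -> numeric
## value association. All offsets are 0-based, half-open character offsets
## into the document text, so every mention can be highlighted in place.

#' Construct a clinical document
#'
#' @param case_id case identifier.
#' @param doc_type "admission_record" or "imaging_report".
#' @param text narrative text (may be empty).
#' @return an `ecrf_document`.
#' @export
new_document <- function(case_id, doc_type, text = "") {
  doc_type <- match.arg(doc_type, DOC_TYPES)
  structure(list(case_id = as.character(case_id), doc_type = doc_type,
                 text = as.character(text)),
            class = "ecrf_document")
}

#' @export
print.ecrf_document <- function(x, ...) {
  cat(sprintf("<ecrf_document> case %s, %s, %d chars\n",
              x$case_id, x$doc_type, nchar(x$text)))
  invisible(x)
}

doc_slice <- function(text, start, end) substr(text, start + 1L, end)

#' Default extraction configuration
#'
#' @param threshold fuzzy-match similarity threshold in \[0, 1\].
#' @param top_k candidates kept per fuzzy lookup.
#' @param max_window maximum entity window, in tokens.
#' @param negation_window negation cue scope, in tokens on either side.
#' @param max_token_distance maximum argument separation for relations.
#' @param units recognised unit tokens for value association.
#' @param neg_pre,neg_post,boundary_cues negation cue lexicons (ConText-style
#'   pre/post cues and scope-terminating conjunction/comma cues); lowercase.
#' @return a list of class `ecrf_extraction_config`.
#' @export
extraction_config <- function(threshold = 0.8,
                              top_k = 5,
                              max_window = 6,
                              negation_window = 5,
                              max_token_distance = 12,
                              units = c("cm", "mm", "m", "kg", "g", "mg", "%",
                                        "°c", "bpm", "mmhg", "s", "min",
                                        "l", "ml"),
                              neg_pre = c("no", "not", "without", "denies",
                                          "denied", "negative", "non", "free",
                                          "无", "未", "非",
                                          "没", "否"),
                              neg_post = c("absent", "unremarkable", "excluded"),
                              boundary_cues = c(",", "but", "however", "though",
                                                "except", "apart", "aside",
                                                "但", "然")) {
  stopifnot(threshold >= 0, threshold <= 1, max_window >= 1,
            negation_window >= 0, max_token_distance >= 0)
  structure(list(threshold = threshold, top_k = top_k, max_window = max_window,
                 negation_window = negation_window,
                 max_token_distance = max_token_distance,
                 units = tolower(units), neg_pre = tolower(neg_pre),
                 neg_post = tolower(neg_post),
                 boundary_cues = tolower(boundary_cues)),
            class = "ecrf_extraction_config")
}

## the seven relation signatures: left-argument category, right-argument
## category (the right argument is the one being linked to its nearest left)
REL_SIGS <- list(
  problem_treatment        = c("medical_problem", "treatment"),
  problem_test             = c("medical_problem", "test"),
  problem_problem          = c("medical_problem", "medical_problem"),
  bodystructure_observable = c("body_structure", "observable"),
  problem_observable       = c("medical_problem", "observable"),
  observable_qualifier     = c("observable", "qualifier"),
  observable_value         = c("observable", "value"))

#' Segment text into sentences and tokens
#'
#' Sentences split on terminators (., ;, !, ?, newline and their CJK
#' counterparts including the CJK comma), with the Latin period kept inside
#' decimal numbers. Tokens are words, decimal numbers, single CJK characters,
#' or single punctuation marks; offsets are 0-based half-open.
#'
#' @param text character scalar.
#' @return list of sentences; each has `start`, `end` and a `tokens`
#'   data.frame (start, end, text).
#' @export
segment_text <- function(text) {
  if (is.null(text) || !nzchar(text)) return(list())
  term_pat <- "[。，；！？;!?\n]|\\.(?![0-9])"
  m <- gregexpr(term_pat, text, perl = TRUE)[[1]]
  bounds <- if (m[1] == -1) integer(0) else as.integer(m)
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds - 1L, nchar(text))
  sentences <- list()
  tok_pat <- paste0("\\p{Han}|[0-9]+(?:\\.[0-9]+)?|[[:alpha:]]+|",
                    "[^\\p{Han}[:alnum:][:space:]]")
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    if (e < s) next
    seg <- substr(text, s, e)
    ## trim whitespace, keeping absolute offsets
    lead <- attr(regexpr("^[[:space:]]*", seg), "match.length")
    trail <- attr(regexpr("[[:space:]]*$", seg), "match.length")
    s2 <- s + lead; e2 <- e - trail
    if (e2 < s2) next
    seg2 <- substr(text, s2, e2)
    tm <- gregexpr(tok_pat, seg2, perl = TRUE)[[1]]
    if (tm[1] == -1) next
    tstart <- as.integer(tm) + s2 - 1L          # 1-based absolute
    tlen <- attr(tm, "match.length")
    tokens <- data.frame(start = tstart - 1L,   # 0-based half-open
                         end = tstart + tlen - 1L,
                         text = substring(text, tstart, tstart + tlen - 1L),
                         stringsAsFactors = FALSE)
    sentences[[length(sentences) + 1L]] <-
      list(start = s2 - 1L, end = e2, tokens = tokens)
  }
  sentences
}

## all candidate mentions in one sentence: exact dictionary hits plus fuzzy
## windows, each as (start, end, token range, concept, score)
sentence_candidates <- function(text, sent, term, cfg) {
  tk <- sent$tokens
  nt <- nrow(tk)
  syn <- term$synonyms
  ## windows never start or end on a bare punctuation token, so mention
  ## surfaces stay clean ("fever", not "fever,")
  punct <- !grepl("[[:alnum:]]|\\p{Han}", tk$text, perl = TRUE)
  out <- list()
  for (i in seq_len(nt)) {
    if (punct[i]) next
    for (w in seq_len(min(cfg$max_window, nt - i + 1L))) {
      j <- i + w - 1L
      if (punct[j]) next
      start <- tk$start[i]; end <- tk$end[j]
      raw <- doc_slice(text, start, end)
      norm <- normalize_term(raw)
      if (!nzchar(norm)) next
      if (grepl("^[0-9.]+$", norm)) next      # numbers handled by values
      exact <- which(syn$norm == norm)
      if (length(exact)) {
        k <- exact[order(syn$concept_id[exact])][1]
        out[[length(out) + 1L]] <- list(
          start = start, end = end, tok_start = i, tok_end = j,
          surface = raw, concept_id = syn$concept_id[k],
          matched_synonym = syn$synonym[k], score = 1.0)
      } else if (nchar(norm) >= 3) {
        ## fuzzy: length pruning (2*min/(la+lb) bounds the score), then one
        ## batched DP pass; tie-break score desc, synonym length desc, id asc
        lw <- nchar(norm)
        idx <- which(2 * pmin(lw, syn$nlen) / (lw + syn$nlen) >= cfg$threshold)
        if (!length(idx)) next
        sc <- lcs_sim_batch_cpp(split_chars(norm), syn$chars[idx])
        ok <- sc >= cfg$threshold
        if (!any(ok)) next
        idx <- idx[ok]; sc <- sc[ok]
        k <- order(-sc, -syn$nlen[idx], syn$concept_id[idx])[1]
        out[[length(out) + 1L]] <- list(
          start = start, end = end, tok_start = i, tok_end = j,
          surface = raw, concept_id = syn$concept_id[idx[k]],
          matched_synonym = syn$synonym[idx[k]], score = sc[k])
      }
    }
  }
  out
}

#' Recognise concept mentions in a document
#'
#' Greedy longest-match scan per sentence: exact normalized dictionary hits
#' score 1, remaining windows are scored by the LCS fuzzy matcher at
#' `cfg$threshold`; overlapping candidates are resolved by longer span, then
#' higher score, then leftmost position.
#'
#' @param doc an `ecrf_document`.
#' @param term an `ecrf_terminology`.
#' @param cfg an [extraction_config()].
#' @param sentences optional precomputed [segment_text()] output.
#' @return data.frame of mentions (one row each) with span, surface, category,
#'   concept_id, score, sentence and token-range columns; assertion is
#'   initialised to "present".
#' @export
recognize_entities <- function(doc, term, cfg = extraction_config(),
                               sentences = NULL) {
  if (is.null(sentences)) sentences <- segment_text(doc$text)
  rows <- list()
  for (si in seq_along(sentences)) {
    cand <- sentence_candidates(doc$text, sentences[[si]], term, cfg)
    if (!length(cand)) next
    len <- vapply(cand, function(c) c$end - c$start, numeric(1))
    sc <- vapply(cand, function(c) c$score, numeric(1))
    st <- vapply(cand, function(c) c$start, numeric(1))
    ## exact dictionary hits outrank fuzzy windows; within a tier longer
    ## spans win, then higher score, then leftmost
    ord <- order(-(sc == 1), -len, -sc, st)
    taken <- logical(0); acc_start <- integer(0); acc_end <- integer(0)
    for (k in ord) {
      c <- cand[[k]]
      if (any(c$start < acc_end & c$end > acc_start)) next
      acc_start <- c(acc_start, c$start); acc_end <- c(acc_end, c$end)
      rows[[length(rows) + 1L]] <- data.frame(
        start = c$start, end = c$end, surface = c$surface,
        concept_id = c$concept_id,
        category = get_concept(term, c$concept_id)$category,
        score = c$score, sentence = si,
        tok_start = c$tok_start, tok_end = c$tok_end,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mention_id = character(0), start = integer(0),
                      end = integer(0), surface = character(0),
                      concept_id = character(0), category = character(0),
                      assertion = character(0), score = numeric(0),
                      sentence = integer(0), tok_start = integer(0),
                      tok_end = integer(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  m <- m[order(m$start, m$end), , drop = FALSE]
  m$mention_id <- sprintf("m%d", seq_len(nrow(m)))
  m$assertion <- "present"
  rownames(m) <- NULL
  m[, c("mention_id", "start", "end", "surface", "concept_id", "category",
        "assertion", "score", "sentence", "tok_start", "tok_end")]
}

#' Classify a mention's assertion (present vs absent)
#'
#' A mention is "absent" when a negation cue appears in the same sentence
#' within `cfg$negation_window` tokens before (pre-cues such as "no",
#' "denies", "without") or after it (post-cues such as "absent"), with the
#' cue's scope terminated by an intervening conjunction/comma boundary cue.
#'
#' @param tok_start,tok_end the mention's token range (1-based, inclusive)
#'   within `tokens`.
#' @param tokens the sentence token data.frame from [segment_text()].
#' @param cfg an [extraction_config()].
#' @return "present" or "absent".
#' @export
classify_assertion <- function(tok_start, tok_end, tokens,
                               cfg = extraction_config()) {
  nt <- nrow(tokens)
  txt <- tolower(tokens$text)
  k <- tok_start - 1L
  while (k >= 1L && k >= tok_start - cfg$negation_window) {
    if (txt[k] %in% cfg$boundary_cues) break
    if (txt[k] %in% cfg$neg_pre) return("absent")
    k <- k - 1L
  }
  k <- tok_end + 1L
  while (k <= nt && k <= tok_end + cfg$negation_window) {
    if (txt[k] %in% cfg$boundary_cues) break
    if (txt[k] %in% cfg$neg_post) return("absent")
    k <- k + 1L
  }
  "present"
}

#' Extract relations between recognised mentions
#'
#' For each of the seven relation signatures, each right-argument mention is
#' linked to its nearest left-argument mention in the same sentence within
#' `cfg$max_token_distance` tokens (ties broken toward the preceding
#' mention); a mention heads at most one relation of each type.
#'
#' @param mentions mention data.frame from [recognize_entities()].
#' @param cfg an [extraction_config()].
#' @return data.frame with columns rel_type, arg1, arg2 (mention ids).
#' @export
extract_relations <- function(mentions, cfg = extraction_config()) {
  out <- list()
  for (rt in names(REL_SIGS)) {
    sig <- REL_SIGS[[rt]]
    for (si in unique(mentions$sentence)) {
      ms <- mentions[mentions$sentence == si, , drop = FALSE]
      rights <- ms[ms$category == sig[2], , drop = FALSE]
      for (r in seq_len(nrow(rights))) {
        lefts <- ms[ms$category == sig[1] &
                      ms$mention_id != rights$mention_id[r], , drop = FALSE]
        if (nrow(lefts) == 0) next
        d <- ifelse(lefts$tok_end < rights$tok_start[r],
                    rights$tok_start[r] - lefts$tok_end,
                    ifelse(lefts$tok_start > rights$tok_end[r],
                           lefts$tok_start - rights$tok_end[r], 0L))
        ok <- d <= cfg$max_token_distance
        if (!any(ok)) next
        lefts <- lefts[ok, , drop = FALSE]; d <- d[ok]
        pick <- order(d, lefts$tok_start)[1]
        out[[length(out) + 1L]] <- data.frame(
          rel_type = rt, arg1 = lefts$mention_id[pick],
          arg2 = rights$mention_id[r], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(rel_type = character(0), arg1 = character(0),
                      arg2 = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## try to read a unit starting at token index k; returns list(unit, end) or NULL
match_unit <- function(tokens, k, units) {
  nt <- nrow(tokens)
  if (k > nt) return(NULL)
  if (k + 1L <= nt) {
    two <- tolower(paste0(tokens$text[k], tokens$text[k + 1L]))
    if (two %in% units)
      return(list(unit = paste0(tokens$text[k], tokens$text[k + 1L]),
                  end = tokens$end[k + 1L]))
  }
  one <- tolower(tokens$text[k])
  if (one %in% units)
    return(list(unit = tokens$text[k], end = tokens$end[k]))
  NULL
}

#' Associate numeric values with observable mentions
#'
#' Each numeric token (decimal number, optionally followed by a unit token)
#' is attached to the nearest preceding observable mention in its sentence,
#' falling back to the nearest following one; the related problem is taken
#' from an existing problem-observable (preferred) or body
#' structure-observable relation on that observable. Numbers with no
#' observable in the sentence are dropped and logged.
#'
#' @param doc an `ecrf_document`.
#' @param mentions,relations outputs of the upstream stages.
#' @param sentences [segment_text()] output for `doc$text`.
#' @param cfg an [extraction_config()].
#' @return list with `values` (data.frame: observable, related_problem,
#'   value, unit, start, end) and `dropped` (data.frame of unattached
#'   numbers).
#' @export
associate_values <- function(doc, mentions, relations, sentences,
                             cfg = extraction_config()) {
  vals <- list(); dropped <- list()
  for (si in seq_along(sentences)) {
    tk <- sentences[[si]]$tokens
    ms <- mentions[mentions$sentence == si, , drop = FALSE]
    obs <- ms[ms$category == "observable", , drop = FALSE]
    for (k in seq_len(nrow(tk))) {
      if (!grepl("^[0-9]+(\\.[0-9]+)?$", tk$text[k])) next
      ## skip numbers that sit inside a recognised mention span
      if (nrow(ms) > 0 &&
          any(tk$start[k] >= ms$start & tk$end[k] <= ms$end)) next
      u <- match_unit(tk, k + 1L, cfg$units)
      span_end <- if (is.null(u)) tk$end[k] else u$end
      unit <- if (is.null(u)) "" else u$unit
      if (nrow(obs) == 0) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          sentence = si, start = tk$start[k], end = span_end,
          text = doc_slice(doc$text, tk$start[k], span_end),
          stringsAsFactors = FALSE)
        log_msg("debug", "values",
                sprintf("dropped numeric '%s' (no observable in sentence %d)",
                        tk$text[k], si))
        next
      }
      before <- obs[obs$tok_end < k, , drop = FALSE]
      target <- if (nrow(before) > 0) {
        before[which.max(before$tok_end), , drop = FALSE]
      } else {
        after <- obs[obs$tok_start > k, , drop = FALSE]
        after[which.min(after$tok_start), , drop = FALSE]
      }
      rel_prob <- NA_character_
      ro <- relations[relations$arg2 == target$mention_id &
                        relations$rel_type == "problem_observable", , drop = FALSE]
      if (nrow(ro) == 0)
        ro <- relations[relations$arg2 == target$mention_id &
                          relations$rel_type == "bodystructure_observable", ,
                        drop = FALSE]
      if (nrow(ro) > 0) rel_prob <- ro$arg1[1]
      vals[[length(vals) + 1L]] <- data.frame(
        observable = target$mention_id, related_problem = rel_prob,
        value = as.numeric(tk$text[k]), unit = unit,
        start = tk$start[k], end = span_end, stringsAsFactors = FALSE)
    }
  }
  empty_vals <- data.frame(observable = character(0),
                           related_problem = character(0), value = numeric(0),
                           unit = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
  empty_drop <- data.frame(sentence = integer(0), start = integer(0),
                           end = integer(0), text = character(0),
                           stringsAsFactors = FALSE)
  list(values = if (length(vals)) do.call(rbind, vals) else empty_vals,
       dropped = if (length(dropped)) do.call(rbind, dropped) else empty_drop)
}

#' Run the full extraction pipeline on one document
#'
#' Composes [segment_text()], [recognize_entities()], [classify_assertion()],
#' [extract_relations()] and [associate_values()]. The result is internally
#' consistent: every relation argument and value reference names a listed
#' mention, and each mention's surface equals the text slice at its span.
#'
#' @param doc an `ecrf_document`.
#' @param term an `ecrf_terminology`.
#' @param cfg an [extraction_config()].
#' @return an `ecrf_extraction` (list with document, sentences, mentions,
#'   relations, values, dropped_values).
#' @export
extract_document <- function(doc, term, cfg = extraction_config()) {
  sentences <- segment_text(doc$text)
  mentions <- recognize_entities(doc, term, cfg, sentences)
  if (nrow(mentions) > 0) {
    mentions$assertion <- vapply(seq_len(nrow(mentions)), function(i) {
      classify_assertion(mentions$tok_start[i], mentions$tok_end[i],
                         sentences[[mentions$sentence[i]]]$tokens, cfg)
    }, character(1))
  }
  relations <- extract_relations(mentions, cfg)
  av <- associate_values(doc, mentions, relations, sentences, cfg)
  structure(list(document = doc, sentences = sentences, mentions = mentions,
                 relations = relations, values = av$values,
                 dropped_values = av$dropped),
            class = "ecrf_extraction")
}

#' @export
print.ecrf_extraction <- function(x, ...) {
  cat(sprintf("<ecrf_extraction> case %s %s: %d mentions, %d relations, %d values\n",
              x$document$case_id, x$document$doc_type, nrow(x$mentions),
              nrow(x$relations), nrow(x$values)))
  invisible(x)
}

#' Serialize an extraction result to JSON
#' @param x an `ecrf_extraction`.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
extraction_to_json <- function(x, path = NULL) {
  m <- x$mentions[, c("mention_id", "start", "end", "surface", "concept_id",
                      "category", "assertion", "score")]
  obj <- list(case_id = x$document$case_id, doc_type = x$document$doc_type,
              mentions = m, relations = x$relations,
              values = x$values, dropped_values = x$dropped_values)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path, useBytes = TRUE)
  invisible(js)
}
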