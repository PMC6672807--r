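## Coded vocabulary: concepts with categories and synonyms, plus the
## longest-common-subsequence fuzzy matcher used to map surface mentions
## onto SNOMED-CT / RadLex style concept identifiers.

#' Normalize a term for dictionary lookup and fuzzy matching
#'
#' Lowercases and strips all whitespace and punctuation (ASCII and common
#' CJK punctuation) so that e.g. "Cardiac murmur." and "cardiac murmur"
#' compare equal. Matching afterwards is per character, which doubles as a
#' language-agnostic treatment of CJK text.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(x)
  gsub("[[:space:][:punct:]。，；！？、：“”‘’（）·]+",
       "", x, perl = TRUE)
}

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Longest common subsequence length
#'
#' Classic dynamic-programming LCS on the characters of two strings (symbols
#' need not be contiguous). Symmetric; returns 0 when either string is empty.
#'
#' @param a,b character scalars (compared as symbol sequences).
#' @return non-negative integer LCS length.
#' @examples
#' lcs_length("ABCBDAB", "BDCABA")  # 4
#' @export
lcs_length <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  lcs_length_cpp(split_chars(a), split_chars(b))
}

#' Dice-normalized LCS similarity
#'
#' `2 * L / (|a| + |b|)` where `L` is the LCS length: 1 iff the strings are
#' identical, 0 when they share no symbols. Inputs are compared verbatim;
#' callers wanting surface-form robustness should [normalize_term()] first.
#'
#' @param a,b character scalars, not both empty.
#' @return similarity in \[0, 1\].
#' @export
lcs_similarity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  la <- nchar(a); lb <- nchar(b)
  if (la + lb == 0L) stop("lcs_similarity is undefined for two empty strings")
  2 * lcs_length_cpp(split_chars(a), split_chars(b)) / (la + lb)
}

new_terminology <- function(concepts, synonyms) {
  ## synonyms: data.frame(concept_id, synonym, norm) one row per synonym
  synonyms$chars <- lapply(synonyms$norm, split_chars)
  synonyms$nlen <- nchar(synonyms$norm)
  structure(list(concepts = concepts, synonyms = synonyms),
            class = "ecrf_terminology")
}

#' @export
print.ecrf_terminology <- function(x, ...) {
  cat(sprintf("<ecrf_terminology> %d concepts, %d synonyms\n",
              nrow(x$concepts), nrow(x$synonyms)))
  tab <- table(x$concepts$category)
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Load a terminology from a tab-separated table
#'
#' Expects a UTF-8 TSV with header
#' `concept_id<TAB>category<TAB>preferred_term<TAB>synonyms`, synonyms
#' pipe-separated (the preferred term is added to the synonym set if absent).
#' Categories must be one of the seven recognised kinds: medical_problem,
#' test, treatment, body_structure, observable, qualifier, value.
#'
#' @param path path to the TSV file.
#' @return an `ecrf_terminology` object.
#' @export
read_terminology <- function(path) {
  if (!file.exists(path)) stop("terminology file not found: ", path)
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                   encoding = "UTF-8", colClasses = "character")
  need <- c("concept_id", "category", "preferred_term", "synonyms")
  if (!all(need %in% names(df)))
    stop("terminology table must have columns: ", paste(need, collapse = ", "))
  terminology_from_table(df)
}

#' Build a terminology from an in-memory table
#'
#' @param df data.frame with columns concept_id, category, preferred_term,
#'   synonyms (pipe-separated string) or a list column of character vectors.
#' @return an `ecrf_terminology` object.
#' @export
terminology_from_table <- function(df) {
  if (nrow(df) == 0) stop("terminology source is empty")
  if (anyDuplicated(df$concept_id)) {
    dup <- unique(df$concept_id[duplicated(df$concept_id)])
    stop("duplicate concept_id in terminology: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(df$concept_id))) stop("empty concept_id in terminology")
  bad <- setdiff(unique(df$category), CATEGORIES)
  if (length(bad))
    stop("unknown category '", paste(bad, collapse = "', '"),
         "'; allowed categories: ", paste(CATEGORIES, collapse = ", "))
  syn_list <- if (is.list(df$synonyms)) df$synonyms else
    strsplit(df$synonyms, "|", fixed = TRUE)
  syn_list <- Map(function(s, pref) {
    s <- trimws(s[nzchar(trimws(s))])
    unique(c(pref, s))
  }, syn_list, df$preferred_term)
  concepts <- data.frame(concept_id = df$concept_id, category = df$category,
                         preferred_term = df$preferred_term,
                         stringsAsFactors = FALSE)
  concepts$synonyms <- syn_list
  syn_tab <- data.frame(
    concept_id = rep(df$concept_id, lengths(syn_list)),
    synonym = unlist(syn_list, use.names = FALSE),
    stringsAsFactors = FALSE)
  syn_tab$norm <- normalize_term(syn_tab$synonym)
  syn_tab <- syn_tab[nzchar(syn_tab$norm), , drop = FALSE]
  new_terminology(concepts, syn_tab)
}

#' Write a terminology to TSV
#' @param term an `ecrf_terminology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_terminology <- function(term, path) {
  df <- term$concepts
  out <- data.frame(concept_id = df$concept_id, category = df$category,
                    preferred_term = df$preferred_term,
                    synonyms = vapply(df$synonyms, paste, character(1),
                                      collapse = "|"),
                    stringsAsFactors = FALSE)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a concept by id
#' @param term an `ecrf_terminology`.
#' @param concept_id identifier string.
#' @return one-row data.frame (or error if absent).
#' @export
get_concept <- function(term, concept_id) {
  i <- match(concept_id, term$concepts$concept_id)
  if (is.na(i)) stop("unknown concept_id: ", concept_id)
  term$concepts[i, , drop = FALSE]
}

#' Map a surface mention onto terminology concepts
#'
#' Scores the normalized mention against every synonym of every concept
#' passing `category_filter` with the Dice-normalized LCS similarity and
#' returns matches at or above `threshold`, ordered by score (descending),
#' then matched-synonym length (descending), then concept id, truncated to
#' `top_k` (at most one row per concept, its best synonym).
#'
#' @param text surface string to map.
#' @param term an `ecrf_terminology`.
#' @param category_filter optional character vector of categories.
#' @param threshold minimum similarity in \[0, 1\] (default 0.8).
#' @param top_k maximum number of matches (default 5).
#' @return data.frame with columns concept_id, matched_synonym, score.
#' @export
map_mention <- function(text, term, category_filter = NULL, threshold = 0.8,
                        top_k = 5) {
  stopifnot(threshold >= 0, threshold <= 1, top_k >= 1)
  empty <- data.frame(concept_id = character(0), matched_synonym = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  q <- normalize_term(text)
  if (!nzchar(q)) return(empty)
  syn <- term$synonyms
  if (!is.null(category_filter)) {
    keep_ids <- term$concepts$concept_id[term$concepts$category %in% category_filter]
    syn <- syn[syn$concept_id %in% keep_ids, , drop = FALSE]
  }
  if (nrow(syn) == 0) return(empty)
  ## length pruning: 2*min(la,lb)/(la+lb) is an upper bound on the score
  lq <- nchar(q)
  ub <- 2 * pmin(lq, syn$nlen) / (lq + syn$nlen)
  syn <- syn[ub >= threshold, , drop = FALSE]
  if (nrow(syn) == 0) return(empty)
  score <- lcs_sim_batch_cpp(split_chars(q), syn$chars)
  keep <- score >= threshold
  if (!any(keep)) return(empty)
  res <- data.frame(concept_id = syn$concept_id[keep],
                    matched_synonym = syn$synonym[keep],
                    score = score[keep], nlen = syn$nlen[keep],
                    stringsAsFactors = FALSE)
  res <- res[order(-res$score, -res$nlen, res$concept_id), , drop = FALSE]
  res <- res[!duplicated(res$concept_id), , drop = FALSE]
  res$nlen <- NULL
  rownames(res) <- NULL
  utils::head(res, top_k)
}
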