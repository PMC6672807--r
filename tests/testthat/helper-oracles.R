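## Independent oracles and tiny fixtures shared across tests.

## Brute-force LCS: enumerate every subsequence of the shorter string and
## keep the longest that is also a subsequence of the other. Exponential —
## only for strings of length <= 10.
is_subsequence <- function(sub, s) {
  if (!length(sub)) return(TRUE)
  j <- 1L
  for (ch in s) {
    if (ch == sub[j]) {
      j <- j + 1L
      if (j > length(sub)) return(TRUE)
    }
  }
  FALSE
}

lcs_length_bruteforce <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) > length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  n <- length(ca)
  if (n == 0) return(0L)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sub <- ca[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L]
    if (length(sub) > best && is_subsequence(sub, cb))
      best <- length(sub)
  }
  best
}

## Welch two-sample t test from first principles (two-sided p)
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## four-concept terminology around the published bindings
tiny_terminology <- function() {
  terminology_from_table(data.frame(
    concept_id = c("SCT:3006004", "SCT:42842009", "SCT:246116008", "RID3277"),
    category = c("medical_problem", "medical_problem", "observable",
                 "medical_problem"),
    preferred_term = c("disturbance of consciousness", "cardiac murmur",
                       "lesion size", "ventricular septal defect"),
    synonyms = c("impaired consciousness", "heart murmur", "",
                 "vsd"),
    stringsAsFactors = FALSE))
}

## random lowercase string over a small alphabet
rand_string <- function(len, alphabet = letters[1:4]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

## a noise-free generator configuration
quiet_generator <- function(seed = 1, ...) {
  generator_config(synonym_variant_prob = 0, typo_char_edit_prob = 0,
                   seed = seed, ...)
}

## do two answer sets carry equal values for every element of a form?
answer_sets_match <- function(x, y, form) {
  els <- form_elements(form)
  all(vapply(names(els), function(eid)
    answer_values_equal(els[[eid]]$element_kind, x$answers[[eid]]$value,
                        y$answers[[eid]]$value), logical(1)))
}
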