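---
title: "Terminology-driven eCRF prepopulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terminology-driven eCRF prepopulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrfpop)
```

## The problem and the approach

Observational clinical research collects most of its per-patient variables
from narrative documents. `ecrfpop` models the assisted version of that
workflow: an extraction pipeline reads admission records and imaging
reports, recognises coded concepts, and prefills the study's electronic
case report form; a human then reviews the prefills. The package deliberately
uses a deterministic dictionary-and-rule pipeline rather than trained
statistical models. Clinical corpora suitable for training are rarely
shareable, and a deterministic pipeline keeps the interesting contracts —
concept categories, assertions, relations, value binding, provenance —
fully testable: identical inputs always give identical extractions, and on
noise-free synthetic text the pipeline is provably exact (the test suite
asserts 100% recovery on a 60-case cohort).

## Concept matching

Mentions map to concepts through a normalized longest-common-subsequence
similarity, `2L/(|a|+|b|)` with `L` the LCS length of the two character
sequences. Normalization lowercases and removes whitespace and punctuation;
matching is per character, which handles CJK text (where a "word" is not
whitespace-delimited) and Latin text uniformly. Properties worth noting:

* the score is 1 exactly when the normalized strings are equal, 0 when they
  share no characters, and symmetric;
* it is *not* a metric (no triangle inequality), which is fine for
  thresholded retrieval;
* the dynamic-programming implementation is verified in the tests against a
  brute-force enumeration of all common subsequences on a thousand random
  string pairs.

The similarity threshold defaults to **0.8** with **top_k = 5** candidates.
0.8 admits one character edit on terms of typical clinical length (a
substitution in a 13-character term scores 0.92; in a 5-character term,
0.8) while rejecting most unrelated vocabulary; it is a tunable of
`extraction_config()` and `map_mention()`, not a constant. Ties break by
score, then longer matched synonym, then concept id — determinism over
cleverness. During entity recognition, exact dictionary hits always outrank
fuzzy windows, overlaps resolve to the longer span (so "ventricular septal
defect" beats an embedded "septal defect"), and windows never start or end
on a punctuation token.

## Assertion, relations, values

Negation follows ConText-style conventions: pre-cues ("no", "denies",
"without", single-character CJK cues 无/未/非/没/否) and post-cues
("absent", "unremarkable") within a **5-token** window, with the cue's
scope cut off by conjunction/comma boundary cues ("but", "however", ","…).
The label set is {present, absent}; a form-level "not mentioned" arises
from the *absence* of any mention rather than from a third mention label.

Relations use seven category-pair signatures (the three classic
problem–treatment/test/problem pairs plus body structure–observable,
problem–observable, observable–qualifier, observable–value). Each
right-argument mention links to its nearest left-argument mention in the
same sentence within **12 tokens** (`max_token_distance`), at most one
relation of each type per mention. Numeric values (decimal token plus an
optional unit from a configurable list) attach to the nearest preceding —
falling back to nearest following — observable in the sentence; the
related problem is inherited from a problem–observable (preferred) or body
structure–observable relation. Numbers with no observable in reach are
dropped and logged, never fatal. The nearest-neighbour rules are stand-ins
chosen for determinism and auditability; they are the weakest link on
genuinely complex sentences and are flagged as such below.

## Prepopulation

Tri-state elements consult only documents of their section's source type
(admission record for part I, imaging report for part II). No mention →
`not_mentioned`; otherwise the resolved assertion decides true/false.
Conflicting assertions across mentions default to **last_mention_wins** in
document order — later statements in clinical notes tend to be conclusions —
with `present_wins` available, and every conflict logged. Multiple-choice
options select on a resolved `present`; fill-in-the-blank picks the value
assignment whose observable matches the binding, preferring a matching
related problem (the problem filter is waived only when no candidate
carries a problem at all); among survivors the first in document order wins.
Every non-empty answer carries provenance spans (0-based, half-open
character offsets) that slice the source document to the supporting text;
the tests enforce provenance soundness and the equivalence
*empty answer ⇔ empty provenance*.

## Evaluation statistics

Accuracy compares answer values under kind-specific equality: exact for
tri-states, set equality for choice selections, exact unit plus numeric
agreement within 1e-9 for blanks (values are transcribed decimals, so this
is exact equality with floating-point hygiene). Group comparisons
log-transform the per-participant outcomes — test scores and reaction-type
times are right-skewed, so raw-scale t tests would be dominated by the tail
— and report MD = mean(ln b) − mean(ln a), its 95% CI, and exp(MD), the
ratio of geometric means (an algebraic identity the tests verify to
machine precision). The t test defaults to **Welch** (unequal variances),
with the pooled test behind `var_equal = TRUE`: the flavor is a genuinely
open choice and Welch is the robust default. Raw-scale medians and IQRs are
reported alongside. No multiple-testing correction is applied. Table-style
percentages round half *up* to two decimals (`round_half_up()`); headline
percent changes round to integers (`percent_change_from_md()`).

The error taxonomy partitions reviewed elements: correct final answers are
`no_error`; wrong answers equal to the prefill are commission errors
(`error_without_modification`); wrong answers differing from the prefill
are cognitive errors (`error_with_modification`). The taxonomy requires a
prefill baseline for every element and errors out otherwise.

## The synthetic generator: what it emulates, what it does not

`generate_case()` draws a ground truth per element — addressed with
probability `finding_prevalence` (**0.7**), negated when addressed with
`negation_prob` (**0.25**), fill-in values uniform over the observable's
clinical range, one decimal — and renders short template sentences into the
matching document, optionally swapping synonyms (**0.3**) and injecting a
one-character typo (**0.05**). The prevalence and noise defaults were fixed
once as plausible for short paediatric admission/imaging narratives with
occasional transcription noise; they are configuration, not constants. The
cohort default is **60 cases** per condition (two documents each), and the
fixture forms carry **28** (CHD-style, four sections) and **24**
(pneumonia-style, three sections — no fill-in part) elements, giving the
familiar 1680 / 1440 element-entry denominators for double-entry
consistency.

The behaviour simulator reviews a prefill per element: a wrong prefill is
noticed with `p_notice_error` and fixed to gold with `p_fix_correct`
(otherwise changed to a random wrong value — uniform over the element's
value space excluding gold and the current value, with a multiplicative
perturbation fallback for blanks when no range is configured); unnoticed
wrong prefills are kept, which is exactly what the commission-error label
captures. Correct prefills are spuriously altered with
`p_spurious_change`. Default arm parameters: manual entry (from an
all-empty baseline) notices 0.95 / fixes 0.95; assisted review notices
0.5 / fixes 0.9 / spuriously changes 0.02; double-entry researchers notice
0.98 / fix 0.98. Per-section elapsed times are lognormal with meanlog set
to the log of the reference per-section median times in seconds (26.43/49.48/9.70/18.41
manual; 13.84/35.47/7.34/12.38 assisted) and sdlog 0.3 — the lognormal
matches the right-skew of reaction-time measurements and makes the
time ratio interpretable in closed form (the ratio of geometric means of
lognormals is exp(Δmeanlog)).

What the generator does **not** emulate: discourse structure (templated
single-finding sentences, no coreference, no temporality, no section
headers), inter-annotator ambiguity in the gold standard (the drawn truth
*is* the gold), learning or fatigue across a session, and realistic
Chinese clinical prose (an optional CJK cue set ships, but templates are
English). Passing tests therefore demonstrate contract correctness and
statistical behaviour, not clinical-grade NLP recall on real records.

## Numerical and degenerate-input choices

* LCS of anything with the empty string is 0; the similarity of two empty
  strings is an error (undefined), as is a consistency rate over zero
  entries and a log comparison with non-positive values.
* Sentence segmentation keeps the Latin period inside decimals
  ("0.5 cm" stays one number) and treats the CJK comma as a terminator.
* Empty documents produce empty extractions and fully
  `not_mentioned`/empty answer sets, never errors.
* Error-percentage tables mark kinds with zero errors as NA rather than
  0/0.
* All randomness flows through explicit integer seeds; cohort and
  participant seeds derive from a master seed via `sample.int`, and the
  test suite asserts byte-identical artefacts across reruns.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use a 60-case zero-noise cohort
for the exactness check, 60 cases × 12 participants per arm for the
in-silico experiment, 60 × 28 element entries for simulated double-entry
consistency, and ≥500 wrong prefills for behaviour-parameter recovery —
sizes chosen to make binomial intervals informative while keeping the
default check run in well under a minute per property on one CPU.

## Known limitations

The nearest-neighbour relation and value-association rules mis-pair
arguments in sentences with parallel structures; the negation scope rule
is token-window based and can both over- and under-negate around unusual
punctuation; fuzzy matching can conflate near-identical sibling terms
under heavy typo noise (the tests only assert that accuracy is
non-increasing in typo probability, not that it is high); and the
simulated participants are memoryless Bernoulli reviewers — adequate for
validating the error taxonomy and the statistics, not a cognitive model.
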