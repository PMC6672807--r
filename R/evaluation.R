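## Evaluation framework: double-entry adjudication into a gold standard,
## per-participant accuracy, log-scale group comparison (geometric-mean
## ratio), and the commission/cognitive error taxonomy for assisted entry.

## section kinds reported in accuracy tables
ACC_KINDS <- c("true_false_I", "true_false_II", "multiple_choice",
               "fill_in_blank", "overall")

answers_by_case <- function(sets) {
  names(sets) <- vapply(sets, `[[`, character(1), "case_id")
  sets
}

#' Adjudicate double data entry into a gold standard
#'
#' Element-by-element, where the two independent entries agree the agreed
#' answer is kept; disagreements are settled by the third (resolver) entry.
#'
#' @param entries_a,entries_b lists of `ecrf_answer_set` (same cases).
#' @param resolver list of `ecrf_answer_set` covering at least every
#'   disagreement.
#' @param form the `ecrf_form` the entries answer.
#' @return list with `gold` (answer sets by case), `n_agree`, `n_total`,
#'   `resolved_by_third`.
#' @export
adjudicate <- function(entries_a, entries_b, resolver, form) {
  a <- answers_by_case(entries_a); b <- answers_by_case(entries_b)
  r <- answers_by_case(resolver)
  els <- form_elements(form)
  if (!setequal(names(a), names(b)))
    stop("rater A and B cover different cases")
  n_agree <- 0L; n_total <- 0L
  gold <- lapply(names(a), function(cid) {
    if (is.null(b[[cid]])) stop("rater B missing case ", cid)
    ans <- lapply(names(els), function(eid) {
      aa <- a[[cid]]$answers[[eid]]; bb <- b[[cid]]$answers[[eid]]
      if (is.null(aa) || is.null(bb))
        stop("missing answer for element ", eid, " in case ", cid)
      n_total <<- n_total + 1L
      if (answer_values_equal(aa$kind, aa$value, bb$value)) {
        n_agree <<- n_agree + 1L
        aa
      } else {
        rr <- r[[cid]]$answers[[eid]]
        if (is.null(rr))
          stop("resolver missing disagreed element ", eid, " in case ", cid)
        rr
      }
    })
    new_answer_set(cid, ans)
  })
  names(gold) <- names(a)
  list(gold = gold, n_agree = n_agree, n_total = n_total,
       resolved_by_third = n_total - n_agree)
}

#' Interoperator consistency rate
#'
#' `100 * n_agree / n_total`, rounded half up to 2 decimals (so 1627 of 1680
#' agreements print as 96.85).
#'
#' @param n_agree agreements.
#' @param n_total compared element entries (> 0).
#' @return percent, 2 decimals.
#' @export
consistency_rate <- function(n_agree, n_total) {
  if (n_total <= 0) stop("consistency_rate undefined for n_total == 0")
  stopifnot(n_agree >= 0, n_agree <= n_total)
  round_half_up(100 * n_agree / n_total, 2)
}

element_kind_map <- function(form) {
  els <- form_elements(form)
  setNames(vapply(els, `[[`, character(1), "section_kind"), names(els))
}

#' Score participant answer sets against the gold standard
#'
#' An element is correct iff its value equals gold under the kind-specific
#' rule ([answer_values_equal()]). Accuracies are percentages per section
#' kind and overall, per participant; the group summary gives median and IQR
#' across participants.
#'
#' @param participant_sets named list (by participant id) of lists of
#'   `ecrf_answer_set`.
#' @param gold list of gold `ecrf_answer_set` (by case).
#' @param form the `ecrf_form`.
#' @return list of class `ecrf_accuracy_report`: `per_participant`
#'   (data.frame participant_id, kind, accuracy) and `summary` (data.frame
#'   kind, median, q1, q3).
#' @export
score_accuracy <- function(participant_sets, gold, form) {
  gold <- answers_by_case(gold)
  kinds <- element_kind_map(form)
  rows <- list()
  for (pid in names(participant_sets)) {
    sets <- answers_by_case(participant_sets[[pid]])
    correct <- setNames(numeric(length(ACC_KINDS)), ACC_KINDS)
    total <- correct
    for (cid in names(sets)) {
      g <- gold[[cid]]
      if (is.null(g)) stop("participant ", pid, " answered unknown case ", cid)
      for (eid in names(g$answers)) {
        ga <- g$answers[[eid]]; pa <- sets[[cid]]$answers[[eid]]
        if (is.null(pa))
          stop("participant ", pid, " missing element ", eid, " in case ", cid)
        ok <- answer_values_equal(ga$kind, pa$value, ga$value)
        k <- kinds[[eid]]
        correct[k] <- correct[k] + ok; total[k] <- total[k] + 1
        correct["overall"] <- correct["overall"] + ok
        total["overall"] <- total["overall"] + 1
      }
    }
    for (k in ACC_KINDS) {
      if (total[k] == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, kind = k,
        accuracy = 100 * correct[k] / total[k], stringsAsFactors = FALSE)
    }
  }
  pp <- do.call(rbind, rows)
  rownames(pp) <- NULL
  summ <- do.call(rbind, lapply(split(pp, pp$kind), function(d) {
    q <- quantile(d$accuracy, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(kind = d$kind[1], median = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_participant = pp, summary = summ),
            class = "ecrf_accuracy_report")
}

#' @export
print.ecrf_accuracy_report <- function(x, ...) {
  cat("<ecrf_accuracy_report> median (IQR) accuracy by element kind:\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %6.2f (%6.2f, %6.2f)\n", s$kind[i], s$median[i],
                s$q1[i], s$q3[i]))
  invisible(x)
}

#' Compare two groups on the log scale
#'
#' Log-transforms both groups and runs an independent two-sample t test
#' (Welch by default). The mean difference MD = mean(log b) − mean(log a)
#' exponentiates to the ratio of geometric means, the effect measure used
#' for accuracy (ratio > 1: group b better) and elapsed time (ratio < 1:
#' group b faster).
#'
#' @param values_a reference group (e.g. manual entry), positive reals.
#' @param values_b comparison group (e.g. NLP-assisted entry), positive reals.
#' @param var_equal use the pooled (equal-variance) t test instead of Welch.
#' @return list of class `ecrf_group_comparison`: md, ci_low, ci_high,
#'   geometric_ratio, ratio_ci, percent_change, p_value, df, and per-group
#'   raw-scale median/IQR.
#' @export
compare_groups_log <- function(values_a, values_b, var_equal = FALSE) {
  if (any(values_a <= 0) || any(values_b <= 0))
    stop("log-scale comparison requires strictly positive values")
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 observations")
  la <- log(values_a); lb <- log(values_b)
  tt <- t.test(lb, la, var.equal = var_equal, conf.level = 0.95)
  md <- mean(lb) - mean(la)
  grp <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    list(median = q[2], q1 = q[1], q3 = q[3], n = length(v))
  }
  structure(list(md = md,
                 ci_low = unname(tt$conf.int[1]),
                 ci_high = unname(tt$conf.int[2]),
                 geometric_ratio = exp(md),
                 ratio_ci = exp(unname(tt$conf.int)),
                 percent_change = percent_change_from_md(md),
                 p_value = unname(tt$p.value), df = unname(tt$parameter),
                 var_equal = var_equal,
                 group_a = grp(values_a), group_b = grp(values_b)),
            class = "ecrf_group_comparison")
}

#' @export
print.ecrf_group_comparison <- function(x, ...) {
  cat(sprintf(paste0("<ecrf_group_comparison> MD %.3f (95%% CI %.3f to %.3f),",
                     " geometric ratio %.3f, change %+d%%, p = %.4g\n"),
              x$md, x$ci_low, x$ci_high, x$geometric_ratio,
              x$percent_change, x$p_value))
  invisible(x)
}

#' Classify assisted-entry errors against prefill and gold
#'
#' For each element: correct final answers are `no_error`; wrong final
#' answers still equal to the prefill are `error_without_modification`
#' (commission error — the participant kept a wrong prefill); wrong final
#' answers differing from the prefill are `error_with_modification`
#' (cognitive error — the participant changed to a wrong value).
#'
#' @param prepop prepopulated `ecrf_answer_set`.
#' @param final the participant's final `ecrf_answer_set`.
#' @param gold the gold `ecrf_answer_set`.
#' @return data.frame (element_id, kind, label).
#' @export
classify_errors <- function(prepop, final, gold) {
  rows <- lapply(names(gold$answers), function(eid) {
    g <- gold$answers[[eid]]; f <- final$answers[[eid]]
    p <- prepop$answers[[eid]]
    if (is.null(f)) stop("final answers missing element ", eid)
    if (is.null(p)) stop("element ", eid,
                         " has no prepopulated baseline; taxonomy undefined")
    label <- if (answer_values_equal(g$kind, f$value, g$value)) "no_error"
    else if (answer_values_equal(g$kind, f$value, p$value))
      "error_without_modification"
    else "error_with_modification"
    data.frame(element_id = eid, kind = g$kind, label = label,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Tabulate error percentages by element kind
#'
#' Percentages are of each kind's total errors (errors with + without
#' modification), rounded half up to 2 decimals; kinds with zero errors get
#' NA percentages.
#'
#' @param labels data.frame from (possibly row-bound) [classify_errors()]
#'   output.
#' @return data.frame of class `ecrf_error_breakdown` with one row per
#'   element kind plus "total": n_errors, n_with, n_without, pct_with,
#'   pct_without.
#' @export
error_percentages <- function(labels) {
  tab_row <- function(kind, d) {
    n_with <- sum(d$label == "error_with_modification")
    n_without <- sum(d$label == "error_without_modification")
    n <- n_with + n_without
    data.frame(kind = kind, n_errors = n, n_with = n_with,
               n_without = n_without,
               pct_with = if (n > 0) round_half_up(100 * n_with / n, 2)
                          else NA_real_,
               pct_without = if (n > 0) round_half_up(100 * n_without / n, 2)
                             else NA_real_,
               stringsAsFactors = FALSE)
  }
  kinds <- unique(labels$kind)
  out <- do.call(rbind, c(lapply(kinds, function(k)
    tab_row(k, labels[labels$kind == k, , drop = FALSE])),
    list(tab_row("total", labels))))
  rownames(out) <- NULL
  class(out) <- c("ecrf_error_breakdown", class(out))
  out
}
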