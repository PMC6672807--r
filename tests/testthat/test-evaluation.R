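## small 5-element form: 2 + 2 tri-state, 1 multiple choice
mini_form <- form_from_list(list(
  form_id = "mini", condition_label = "test", sections = list(
    list(section_kind = "true_false_I", elements = list(
      list(element_id = "t1", label = "fever", element_kind = "true_false",
           binding = list(concept_id = "SYN:MP001")),
      list(element_id = "t2", label = "cough", element_kind = "true_false",
           binding = list(concept_id = "SYN:MP002")))),
    list(section_kind = "true_false_II", elements = list(
      list(element_id = "t3", label = "asd", element_kind = "true_false",
           binding = list(concept_id = "SYN:MP020")),
      list(element_id = "t4", label = "pda", element_kind = "true_false",
           binding = list(concept_id = "SYN:MP021")))),
    list(section_kind = "multiple_choice", elements = list(
      list(element_id = "m1", label = "sym", element_kind = "multiple_choice",
           source_doc_type = "admission_record",
           binding = list(options = list(
             list(option_label = "cyanosis", concept_id = "SYN:MP040"),
             list(option_label = "dyspnea", concept_id = "SYN:MP041")))))))))

tf_set <- function(case_id, values) {
  ans <- Map(function(eid, v) {
    if (eid == "m1") new_answer(eid, "multiple_choice", v)
    else new_answer(eid, "true_false", v)
  }, names(values), values)
  new_answer_set(case_id, unname(ans))
}

base_values <- list(t1 = "true", t2 = "false", t3 = "not_mentioned",
                    t4 = "true", m1 = c("cyanosis"))

test_that("adjudication keeps agreements and defers to the resolver", {
  cases <- sprintf("c%d", 1:2)
  A <- lapply(cases, tf_set, values = base_values)
  B <- lapply(cases, tf_set, values = base_values)
  R <- lapply(cases, tf_set, values = base_values)
  adj <- adjudicate(A, B, R, mini_form)
  expect_identical(adj$n_agree, 10L)
  expect_identical(adj$n_total, 10L)
  expect_identical(adj$resolved_by_third, 0L)
  expect_identical(adj$gold$c1$answers$t1$value, "true")

  ## one disagreement; resolver sides with B
  vB <- base_values; vB$t2 <- "true"
  vR <- base_values; vR$t2 <- "true"
  B2 <- lapply(cases, tf_set, values = vB)
  R2 <- lapply(cases, tf_set, values = vR)
  adj <- adjudicate(A, B2, R2, mini_form)
  expect_identical(adj$n_agree, 8L)
  expect_identical(adj$resolved_by_third, 2L)
  expect_identical(adj$gold$c1$answers$t2$value, "true")

  ## resolver missing a disagreed element
  R3 <- lapply(cases, function(cid) {
    s <- tf_set(cid, base_values)
    s$answers$t2 <- NULL
    s
  })
  expect_error(adjudicate(A, B2, R3, mini_form), "t2")
})

test_that("consistency rate reproduces the printed arithmetic", {
  expect_identical(consistency_rate(1627, 1680), 96.85)
  expect_identical(consistency_rate(10, 10), 100)
  expect_identical(consistency_rate(0, 7), 0)
  expect_error(consistency_rate(0, 0), "undefined")
  ## complement sums to 100 up to rounding
  set.seed(3)
  for (i in 1:50) {
    n <- sample(1:2000, 1); k <- sample(0:n, 1)
    expect_equal(consistency_rate(k, n) + consistency_rate(n - k, n), 100,
                 tolerance = 0.011)
  }
})

test_that("accuracy scoring matches hand arithmetic and summarises groups", {
  cases <- sprintf("c%d", 1:4)
  gold <- lapply(cases, tf_set, values = base_values)
  perfect <- lapply(cases, tf_set, values = base_values)
  one_off <- perfect
  one_off[[1]] <- tf_set("c1", utils::modifyList(base_values,
                                                 list(t1 = "false")))
  rep <- score_accuracy(list(p_perfect = perfect, p_one = one_off),
                        gold, mini_form)
  pp <- rep$per_participant
  get <- function(pid, kind)
    pp$accuracy[pp$participant_id == pid & pp$kind == kind]
  expect_identical(get("p_perfect", "overall"), 100)
  ## one wrong element out of 20 -> 95.00 overall
  expect_identical(get("p_one", "overall"), 95)
  expect_identical(get("p_one", "true_false_I"), 100 * 7 / 8)
  expect_identical(get("p_one", "multiple_choice"), 100)
  expect_identical(rep$summary$median[rep$summary$kind == "overall"], 97.5)
})

test_that("log-scale comparison: identity, antisymmetry, Welch agreement", {
  ## null case: identical groups
  cmp <- compare_groups_log(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cmp$md, 0)
  expect_equal(cmp$geometric_ratio, 1)
  expect_equal(cmp$p_value, 1)

  ## headline percent-change conversions
  expect_identical(percent_change_from_md(0.14), 15L)
  expect_identical(percent_change_from_md(-0.40), -33L)
  expect_identical(percent_change_from_md(-0.37), -31L)

  set.seed(11)
  for (i in 1:100) {
    a <- exp(rnorm(sample(3:12, 1), mean = 1))
    b <- exp(rnorm(sample(3:12, 1), mean = 1.2))
    cmp <- compare_groups_log(a, b)
    ## exp(MD) is exactly the ratio of geometric means
    gm <- function(v) exp(mean(log(v)))
    expect_equal(cmp$geometric_ratio, gm(b) / gm(a), tolerance = 1e-12)
    ## swapping the groups negates MD and inverts the ratio
    rev <- compare_groups_log(b, a)
    expect_equal(rev$md, -cmp$md, tolerance = 1e-12)
    expect_equal(rev$geometric_ratio, 1 / cmp$geometric_ratio,
                 tolerance = 1e-12)
    expect_equal(rev$p_value, cmp$p_value, tolerance = 1e-12)
    ## Welch p-value against a from-first-principles implementation
    w <- welch_oracle(log(b), log(a))
    expect_equal(cmp$p_value, w$p, tolerance = 1e-10)
    expect_equal(cmp$df, w$df, tolerance = 1e-8)
    ## CI brackets the MD
    expect_lte(cmp$ci_low, cmp$md); expect_gte(cmp$ci_high, cmp$md)
  }
  expect_error(compare_groups_log(c(1, -1, 2), c(1, 2, 3)), "positive")
})

test_that("error taxonomy partitions elements by the modification rule", {
  gold <- tf_set("c1", base_values)
  prepop <- tf_set("c1", utils::modifyList(base_values,
                                           list(t1 = "false", t2 = "true")))
  ## t1 kept wrong (commission), t2 modified to gold, t4 modified to wrong
  final <- tf_set("c1", utils::modifyList(base_values,
                                          list(t1 = "false",
                                               t4 = "not_mentioned")))
  lab <- classify_errors(prepop, final, gold)
  get <- function(eid) lab$label[lab$element_id == eid]
  expect_identical(get("t1"), "error_without_modification")
  expect_identical(get("t2"), "no_error")
  expect_identical(get("t4"), "error_with_modification")
  ## labels partition the element set
  expect_identical(nrow(lab), 5L)
  expect_true(all(lab$label %in% c("no_error", "error_with_modification",
                                   "error_without_modification")))
  ## prepop wrong, final changed to a different wrong value
  final2 <- tf_set("c1", utils::modifyList(base_values,
                                           list(t1 = "not_mentioned")))
  expect_identical(classify_errors(prepop, final2, gold)$label[1],
                   "error_with_modification")
  ## a missing prefill baseline is an error
  broken <- prepop; broken$answers$t1 <- NULL
  expect_error(classify_errors(broken, final, gold), "t1")
})

test_that("error percentages reproduce the printed table arithmetic", {
  mk <- function(kind, with, without) data.frame(
    element_id = sprintf("%s_%d", kind, seq_len(with + without)),
    kind = kind,
    label = c(rep("error_with_modification", with),
              rep("error_without_modification", without)),
    stringsAsFactors = FALSE)
  labels <- rbind(mk("true_false", 325, 842),
                  mk("multiple_choice", 158, 281),
                  mk("fill_in_blank", 16, 105))
  eb <- error_percentages(labels)
  g <- function(kind, col) eb[eb$kind == kind, col]
  expect_identical(g("true_false", "pct_with"), 27.85)
  expect_identical(g("true_false", "n_errors"), 1167L)
  expect_identical(g("fill_in_blank", "pct_without"), 86.78)
  expect_identical(g("total", "pct_without"), 71.11)
  expect_identical(g("total", "n_errors"), 1727L)
  ## zero-error kinds report counts 0 and undefined percents
  none <- data.frame(element_id = "x", kind = "true_false",
                     label = "no_error", stringsAsFactors = FALSE)
  eb0 <- error_percentages(none)
  expect_identical(eb0$n_errors, c(0L, 0L))
  expect_true(all(is.na(eb0$pct_with)))
})
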