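test_that("combination enumeration is exhaustive, canonical and deterministic", {
  panel14 <- marker_panel(include_diagnosis = TRUE)$name
  expect_length(enumerate_combinations(panel14, 2), choose(14, 2))
  expect_length(enumerate_combinations(panel14, 1), 14)
  expect_length(enumerate_combinations(c("a", "b", "c"), 3), 1)
  expect_identical(enumerate_combinations(c("b", "a"), 1),
                   list("a", "b"))
  expect_error(enumerate_combinations(c("a", "b"), 3), "out of range")
  expect_error(enumerate_combinations(c("a", "a"), 1), "duplicate")
})

test_that("re-substitution estimates match hand enumeration", {
  # perfectly separating marker
  X <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), ncol = 1,
              dimnames = list(NULL, "m"))
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  m <- resubstitution_estimate(X, y, "m", alpha = 0)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  # constant marker, equal priors: every cell ties, tie rule predicts
  # positive everywhere
  Xc <- matrix(0L, 4, 1, dimnames = list(NULL, "m"))
  yc <- c(TRUE, TRUE, FALSE, FALSE)
  mc <- resubstitution_estimate(Xc, yc, "m", alpha = 0)
  expect_equal(mc$sensitivity, 1)
  expect_equal(mc$specificity, 0)

  fx <- eight_sample_fixture()
  mf <- resubstitution_estimate(fx$profiles, fx$labels, "m", alpha = 0)
  expect_equal(mf$sensitivity, 0.75)
  expect_equal(mf$specificity, 0.75)
})

test_that("per-fold selection applies the criterion, floor and tie-breaks", {
  df <- tibble::tibble(
    combination = list("A", "B"),
    sensitivity = c(0.9, 0.8), specificity = c(0.4, 0.6),
    f1 = c(0.7, 0.6))
  expect_identical(select_best(df, specificity_floor = 0.5)$combination, "B")

  df2 <- tibble::tibble(
    combination = list("A", "B"),
    sensitivity = c(0.9, 0.8), specificity = c(0.6, 0.9),
    f1 = c(0.7, 0.8))
  expect_identical(select_best(df2, specificity_floor = 0.5)$combination,
                   "A")
  expect_identical(select_best(df2, criterion = "max_f1")$combination, "B")

  # equal metrics: fewer markers first, then lexicographic
  df3 <- tibble::tibble(
    combination = list(c("m1", "m2"), "m1"),
    sensitivity = c(0.8, 0.8), specificity = c(0.7, 0.7),
    f1 = c(0.75, 0.75))
  expect_identical(select_best(df3)$combination, "m1")

  # empty feasible set falls back to F1 and flags it
  df4 <- tibble::tibble(
    combination = list("A", "B"),
    sensitivity = c(0.9, 0.95), specificity = c(0.1, 0.2),
    f1 = c(0.5, 0.6))
  sel <- select_best(df4, specificity_floor = 0.5)
  expect_true(sel$fallback)
  expect_identical(sel$combination, "B")
  expect_error(select_best(df4[0, ]), "no combinations")
})

test_that("a perfectly separating marker wins every leave-one-out fold", {
  set.seed(21)
  n <- 40
  truth <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
  M <- cbind(m1 = as.integer(truth),
             m2 = sample(0:1, n, replace = TRUE),
             m3 = sample(0:1, n, replace = TRUE))
  cohort <- binary_marker_cohort(M, truth)
  panel <- binary_panel(c("m1", "m2", "m3"))
  res <- loo_select(cohort, candidates = c("m1", "m2", "m3"), sizes = 1,
                    alpha = 0, panel = panel)[[1]]
  expect_identical(res$winner, "m1")
  expect_equal(res$tally$freq[res$tally$combination == "m1"], n)
  expect_equal(sum(res$tally$freq), res$n_folds)

  # cumulative search across sizes: dominance plus the fewer-markers
  # tie-break keeps the single perfect marker on top
  cres <- loo_select(cohort, candidates = c("m1", "m2", "m3"), sizes = 1:2,
                     alpha = 0, cumulative = TRUE, panel = panel)
  expect_identical(cres$winner, "m1")
})

test_that("selection is deterministic and its log is internally consistent", {
  cohort <- generate_cohort(cohort_config(n = 80), seed = 22)
  part <- stratify_by_diagnosis(cohort)[["non-PDAC"]]
  r1 <- loo_select(part, sizes = 1:2)
  r2 <- loo_select(part, sizes = 1:2)
  expect_identical(r1, r2)
  for (res in r1) {
    expect_equal(sum(res$tally$freq), res$n_folds)
    expect_equal(res$n_folds, nrow(part))
    expect_true(all(res$folds$combination %in% res$tally$combination))
    expect_identical(res$folds$held_out_id, part$id)
  }
})

test_that("the fast LOO engine agrees with per-fold refitting", {
  cohort <- generate_cohort(cohort_config(n = 30, separation = "strong"),
                            seed = 23)
  part <- stratify_by_diagnosis(cohort)[["non-PDAC"]]
  cands <- c("mpd_index", "bmi", "diabetes", "sex")
  fast <- loo_select(part, candidates = cands, sizes = 2, alpha = 1)[[1]]
  X <- discretize_cohort(part, markers = cands)
  y <- part$cr_popf
  combos <- enumerate_combinations(cands, 2)
  slow <- character(0)
  for (i in seq_len(nrow(part))) {
    mets <- lapply(combos, function(cmb)
      resubstitution_estimate(X[-i, , drop = FALSE], y[-i], cmb, alpha = 1))
    df <- tibble::tibble(
      combination = combos,
      sensitivity = vapply(mets, `[[`, numeric(1), "sensitivity"),
      specificity = vapply(mets, `[[`, numeric(1), "specificity"),
      f1 = vapply(mets, `[[`, numeric(1), "f1"))
    slow <- c(slow, paste(sort(select_best(df)$combination),
                          collapse = "+"))
  }
  expect_identical(fast$folds$combination, slow)
})

test_that("selection requires labels and two samples per class", {
  cohort <- generate_cohort(cohort_config(n = 20), seed = 24)
  unl <- cohort; unl$cr_popf <- NA
  expect_error(loo_select(unl), "labeled")
  onesided <- cohort; onesided$cr_popf <- c(TRUE, rep(FALSE, 19))
  expect_error(loo_select(onesided), "2 samples per")
  expect_error(loo_select(cohort, candidates = character(0)), "empty")
})

test_that("held-out LOO performance is reported alongside selection", {
  cohort <- generate_cohort(cohort_config(n = 200, separation = "strong"),
                            seed = 25)
  part <- stratify_by_diagnosis(cohort)[["PDAC"]]
  held <- loo_holdout_estimate(part, "mpd_index")
  resub <- resubstitution_estimate(
    discretize_cohort(part, markers = "mpd_index"), part$cr_popf,
    "mpd_index")
  for (v in c("sensitivity", "specificity"))
    expect_true(held[[v]] >= 0 && held[[v]] <= 1)
  # with a strongly planted single marker both estimates find the signal
  expect_gt(held$sensitivity, 0.5)
  expect_gt(resub$sensitivity, 0.5)
})
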