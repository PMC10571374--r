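# The strongly separated planted configuration is used where a test needs a
# decisive learned decision table; with the calibrated configuration the
# PDAC low-index cell sits exactly at coin-flip risk (the training PPV of
# 50% pins it there) and its finite-sample decision is genuinely unstable.

strong_training <- function(seed = 50, n = 200)
  generate_cohort(cohort_config(n = n, separation = "strong"), seed = seed)

test_that("the final model learns the planted risk directions", {
  model <- build_final_model(strong_training())
  dt <- decision_table(model)
  expect_equal(nrow(dt), 6)
  expect_true(all(dt$posterior >= 0 & dt$posterior <= 1))
  # PDAC: low MPD index (bin 0) is the risk cell
  expect_true(dt$predicted[dt$stratum == "PDAC" & dt$cell == "0"])
  expect_false(dt$predicted[dt$stratum == "PDAC" & dt$cell == "1"])
  # non-PDAC: positive except for (high index, low BMI)
  np <- dt[dt$stratum == "non-PDAC", ]
  expect_false(np$predicted[np$cell == "10"])
  expect_true(all(np$predicted[np$cell != "10"]))
})

test_that("building requires both strata", {
  cohort <- strong_training()
  expect_error(build_final_model(cohort[cohort$diagnosis == "PDAC", ]),
               "no non-PDAC records")
})

test_that("patient-level prediction routes by diagnosis and reports posteriors", {
  model <- build_final_model(strong_training())
  cohort <- strong_training(seed = 51, n = 30)
  pred <- predict_popf(model, cohort)
  expect_identical(pred$id, cohort$id)
  expect_true(all(pred$posterior >= 0 & pred$posterior <= 1))

  # a PDAC patient with a low duct index is flagged
  pdac_low <- cohort[cohort$diagnosis == "PDAC", ][1, ]
  pdac_low$mpd_index <- 0.25
  pdac_low$mpd_size <- 0.25 * pdac_low$parenchymal_thickness
  expect_true(predict_popf(model, pdac_low)$predicted)
  # a non-PDAC patient with high index and low BMI is not
  np <- cohort[cohort$diagnosis == "non-PDAC", ][1, ]
  np$mpd_index <- 0.6; np$mpd_size <- 0.6 * np$parenchymal_thickness
  np$bmi <- 22; np$weight <- 22 * np$height^2
  expect_false(predict_popf(model, np)$predicted)

  miss <- np; miss$bmi <- NA
  expect_error(predict_popf(model, miss), "'bmi'")
})

test_that("prediction agrees with the decision-table lookup for every record", {
  model <- build_final_model(strong_training())
  cohort <- strong_training(seed = 52, n = 150)
  pred <- predict_popf(model, cohort)
  dt <- decision_table(model)
  for (st in c("PDAC", "non-PDAC")) {
    rows <- cohort$diagnosis == st
    markers <- if (st == "PDAC") "mpd_index" else c("mpd_index", "bmi")
    key <- apply(discretize_cohort(cohort[rows, ], markers = markers), 1,
                 paste, collapse = "")
    lookup <- dt$predicted[dt$stratum == st][match(
      key, dt$cell[dt$stratum == st])]
    expect_identical(unname(pred$predicted[rows]), unname(lookup))
  }
})

test_that("evaluation partitions the cohort and pools exactly", {
  model <- build_final_model(strong_training())
  cohort <- strong_training(seed = 53, n = 400)
  ev <- evaluate_model(model, cohort)
  sizes <- vapply(ev$confusion, function(cm) cm$tp + cm$fp + cm$fn + cm$tn,
                  integer(1))
  expect_equal(unname(sizes["PDAC"] + sizes["non-PDAC"]), nrow(cohort))
  expect_equal(unname(sizes["pooled"]), nrow(cohort))
  expect_equal(ev$confusion$pooled,
               pool_confusions(ev$confusion[c("PDAC", "non-PDAC")]))
  # a perfect predictor scores 1 on everything
  oracle <- cohort
  ev_perfect <- evaluate_model(model, {
    dt <- decision_table(model)
    for (st in c("PDAC", "non-PDAC")) {
      rows <- oracle$diagnosis == st
      markers <- if (st == "PDAC") "mpd_index" else c("mpd_index", "bmi")
      key <- apply(discretize_cohort(oracle[rows, ], markers = markers), 1,
                   paste, collapse = "")
      oracle$cr_popf[rows] <-
        dt$predicted[dt$stratum == st][match(key, dt$cell[dt$stratum == st])]
    }
    oracle
  })
  expect_equal(ev_perfect$metrics$pooled$sensitivity, 1)
  expect_equal(ev_perfect$metrics$pooled$specificity, 1)

  unlabeled <- cohort; unlabeled$cr_popf <- NA
  expect_error(evaluate_model(model, unlabeled), "labeled")
})

test_that("large-sample evaluation converges to the implied operating point", {
  cfg <- cohort_config(n = 200, separation = "strong")
  model <- build_final_model(generate_cohort(cfg, seed = 54))
  big <- generate_cohort(cohort_config(n = 8000, separation = "strong"),
                         seed = 55)
  ev <- evaluate_model(model, big)
  for (st in c("PDAC", "non-PDAC")) {
    imp <- implied_operating_point(cfg, st)
    row <- ev$report[ev$report$stratum == st, ]
    n_pos <- row$tp + row$fn; n_neg <- row$tn + row$fp
    expect_lt(abs(row$sensitivity - imp$sensitivity),
              3 * sqrt(imp$sensitivity * (1 - imp$sensitivity) / n_pos))
    expect_lt(abs(row$specificity - imp$specificity),
              3 * sqrt(imp$specificity * (1 - imp$specificity) / n_neg))
  }
})

test_that("model JSON serialization round-trips counts and decisions exactly", {
  model <- build_final_model(strong_training())
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_identical(back$pdac$counts, model$pdac$counts)
  expect_identical(back$nonpdac$counts, model$nonpdac$counts)
  expect_equal(back$pdac$priors, model$pdac$priors)
  expect_equal(decision_table(back), decision_table(model))
  cohort <- strong_training(seed = 56, n = 40)
  expect_identical(predict_popf(back, cohort), predict_popf(model, cohort))
})
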