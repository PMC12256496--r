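test_that("published confusion counts yield the published metrics", {
  rows <- list(
    list(cc = confusion_counts(19, 1, 4, 9, 33),
         want = c(95.00, 30.77, 69.70, 62.88, 100.00)),
    list(cc = confusion_counts(18, 2, 10, 3, 33),
         want = c(90.00, 76.92, 84.85, 83.46, 100.00)),
    list(cc = confusion_counts(13, 5, 10, 3, 33),
         want = c(72.22, 76.92, 74.19, 74.57, 93.94)),
    list(cc = confusion_counts(15, 5, 9, 4, 33),
         want = c(75.00, 69.23, 72.73, 72.12, 100.00)))
  for (r in rows) {
    pm <- performance(r$cc)
    got <- round(c(pm$se, pm$sp, pm$acc, pm$ba, pm$cov), 2)
    expect_equal(got, r$want)
  }
})

test_that("balanced accuracy uses unrounded sensitivity and specificity", {
  pm <- performance(confusion_counts(19, 1, 4, 9, 33))
  expect_equal(round(pm$ba, 2), 62.88)
  # the unrounded mean is 62.8846...; averaging the rounded SE/SP instead
  # gives 62.885, which no longer reproduces the printed value reliably
  expect_equal(pm$ba, (95 + 100 * 4 / 13) / 2)
})

test_that("accuracy denominator is evaluable calls, not all labelled", {
  pm <- performance(confusion_counts(13, 5, 10, 3, 33))
  expect_equal(pm$acc, 100 * 23 / 31)
  expect_equal(pm$cov, 100 * 31 / 33)
})

test_that("not_predicted keeps chemicals in the denominator but out of cells", {
  rec <- data.frame(
    chemical_id = paste0("c", 1:5), model_id = "m",
    call = "not_predicted",
    truth = c("toxic", "toxic", "nontoxic", "nontoxic", "nontoxic"))
  cc <- tally_confusion(rec, "m")
  expect_equal(c(cc$tp, cc$fn, cc$tn, cc$fp), c(0, 0, 0, 0))
  expect_equal(cc$total_labelled, 5)
  expect_equal(performance(cc)$cov, 0)
})

test_that("unknown-truth chemicals are dropped before tallying", {
  rec <- data.frame(
    chemical_id = paste0("c", 1:4), model_id = "m",
    call = c("toxic", "toxic", "nontoxic", "toxic"),
    truth = c("toxic", "unknown", "unknown", "nontoxic"))
  cc <- tally_confusion(rec, "m")
  expect_equal(cc$total_labelled, 2)
  expect_equal(cc$tp, 1)
  expect_equal(cc$fp, 1)
})

test_that("tally matches a brute-force count and ignores record order", {
  for (seed in 1:5) {
    rec <- gen_prediction_records(n_chemicals = 100, fn_rate = 0.2,
                                  fp_rate = 0.15, np_rate = 0.1,
                                  unknown_rate = 0.1, seed = seed)
    cc <- tally_confusion(rec, "synthetic")
    bf <- brute_confusion(rec, "synthetic")
    expect_equal(c(cc$tp, cc$fn, cc$tn, cc$fp, cc$total_labelled),
                 unname(bf))
    shuffled <- rec[sample(nrow(rec)), ]
    cc2 <- tally_confusion(shuffled, "synthetic")
    expect_equal(cc2, cc)
  }
})

test_that("degenerate inputs error or flag rather than mislead", {
  rec <- data.frame(chemical_id = c("a", "a"), model_id = "m",
                    call = "toxic", truth = "toxic")
  expect_error(tally_confusion(rec, "m"), "duplicate")
  expect_error(tally_confusion(rec, "absent"), "no records")
  pm <- performance(confusion_counts(0, 0, 5, 1, 6))
  expect_true(is.na(pm$se))        # no positives: sensitivity undefined
  expect_true(is.na(pm$ba))
  expect_false(is.na(pm$sp))
  perfect <- performance(confusion_counts(4, 0, 3, 0, 7))
  expect_equal(c(perfect$se, perfect$sp, perfect$acc, perfect$ba,
                 perfect$cov), c(100, 100, 100, 100, 100))
})
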