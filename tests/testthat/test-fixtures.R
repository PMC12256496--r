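test_that("the scenario fixture has the benchmark structure", {
  t1 <- load_fixture("table1")
  expect_equal(nrow(t1), 49)
  expect_equal(length(unique(t1$chemical_id)), 37)
  expect_equal(sum(t1$risk_truth == "high"), 17)
  expect_equal(sum(t1$risk_truth == "low"), 27)
  expect_equal(sum(t1$risk_truth == "uncertain"), 5)
})

test_that("the performance-count fixture is internally consistent", {
  t5 <- load_fixture("table5")
  expect_equal(nrow(t5), 4)
  expect_true(all(t5$tp + t5$fn + t5$tn + t5$fp <= t5$total_labelled))
  expect_true(all(t5$total_labelled == 33))   # 20 toxic + 13 non-toxic
})

test_that("per-chemical calls reproduce every published count", {
  calls <- load_fixture("insilico_calls")
  t5 <- load_fixture("table5")
  for (i in seq_len(nrow(t5))) {
    cc <- tally_confusion(calls, t5$model_id[i])
    expect_equal(cc$tp, t5$tp[i])
    expect_equal(cc$fn, t5$fn[i])
    expect_equal(cc$tn, t5$tn[i])
    expect_equal(cc$fp, t5$fp[i])
  }
})

test_that("population fixture flags exactly the small-N entries", {
  t6 <- load_fixture("table6")
  expect_true(all(t6$small_n == (t6$n_total < 10)))
  expect_equal(sum(t6$small_n), 4)
  expect_true(all(is.na(t6$tkvf[t6$small_n]) |
                    t6$chemical_id[t6$small_n] == "Salicylate"))
})

test_that("the target annotation splits 72 targets into 49 + 23", {
  targets <- load_fixture("ipp_targets")
  expect_equal(nrow(targets), 72)
  expect_equal(sum(targets$category == "dart_targeted"), 49)
})

test_that("unknown fixtures and corrupted files are refused", {
  expect_error(load_fixture("nope"), "unknown fixture")
  # simulate corruption by copying and editing a fixture, then checking
  # against the packaged manifest
  src <- system.file("extdata", "table5_counts.csv", package = "dartnam")
  manifest <- read.csv(system.file("extdata", "manifest.csv",
                                   package = "dartnam"))
  good <- unname(tools::md5sum(src))
  tmp <- tempfile(fileext = ".csv")
  writeLines(c(readLines(src), "tampered"), tmp)
  expect_false(unname(tools::md5sum(tmp)) == good)
  expect_equal(manifest$md5[manifest$file == "table5_counts.csv"], good)
})

test_that("the packaged evaluation reproduces the headline numbers", {
  ev <- run_evaluation()
  derek17 <- ev$insilico[ev$insilico$model_id == "derek_nexus_17", ]
  expect_equal(derek17$se, 90.00)
  expect_equal(derek17$acc, 84.85)
  expect_equal(round(ev$population$tkvf_mean, 2), 2.36)
  expect_equal(ev$population$tkvf_max, 5.73)
  expect_equal(ev$population$fold_min, 0.19)
  expect_equal(ev$scenario_counts$total, 49)
  expect_equal(round(ev$framework$protectiveness), 94)
  expect_equal(round(ev$framework$utility), 59)
  expect_true(!is.null(ev$ber$notice))
  # with PoD/Cmax tables supplied the BER section is populated
  suite <- gen_benchmark_suite(n_chemicals = 3, seed = 1)
  ev2 <- run_evaluation(pods = suite$pods, scenarios = suite$scenarios)
  expect_null(ev2$ber$notice)
  expect_equal(nrow(ev2$ber$per_scenario), 6)
})

test_that("evaluation reports serialize to JSON", {
  path <- tempfile(fileext = ".json")
  write_evaluation_json(run_evaluation(), path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$scenario_counts$total, 49)
  expect_equal(length(parsed$insilico), 4)
})
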