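test_that("minimum PoD selection matches brute force with tie rules", {
  pods <- gen_benchmark_suite(n_chemicals = 1, pods_per_chemical = 50,
                              seed = 6)$pods
  win <- min_pod(pods)
  expect_equal(win$pod_uM, min(pods$pod_uM))

  single <- pods[3, ]
  expect_equal(min_pod(single)$endpoint, single$endpoint)

  tie <- data.frame(chemical_id = "c", platform = c("calux", "ipp"),
                    endpoint = c("e2", "e1"), pod_uM = c(1, 1),
                    category = "broad")
  w <- min_pod(tie)
  expect_equal(w$platform, "ipp")   # platform precedence breaks the tie
  expect_true(w$tied)

  expect_error(min_pod(pods[pods$category == "none", ]), "no PoD")
})

test_that("category subset restricts the search to targeted assays", {
  pods <- data.frame(chemical_id = "c",
                     platform = c("httr_hepg2", "reprotracker"),
                     endpoint = c("global", "BMP4"), pod_uM = c(0.1, 5),
                     category = c("broad", "dart_targeted"))
  expect_equal(min_pod(pods)$pod_uM, 0.1)
  expect_equal(min_pod(pods, subset = "dart_targeted")$pod_uM, 5)
})

test_that("the BER boundary calls 1 as uncertain risk", {
  expect_equal(ber(1, 1)$call, "uncertain_risk")
  expect_equal(ber(10, 1)$call, "low_risk")
  b <- ber(0.8, 1)
  expect_equal(b$ber, 0.8)
  expect_equal(b$call, "uncertain_risk")
  miss <- ber(1, NA_real_)
  expect_equal(miss$call, "no_call")
  expect_true(miss$cmax_missing)
})

test_that("lowering any PoD can only lower the scenario BER", {
  suite <- gen_benchmark_suite(n_chemicals = 5, seed = 2)
  base <- evaluate_ber(suite$pods, suite$scenarios)$per_scenario$ber
  pods2 <- suite$pods
  pods2$pod_uM[7] <- pods2$pod_uM[7] / 100
  after <- evaluate_ber(pods2, suite$scenarios)$per_scenario$ber
  expect_true(all(after <= base + 1e-12))
})

test_that("framework metrics reproduce the benchmark count arithmetic", {
  calls <- c(rep("uncertain_risk", 16), "low_risk",
             rep("low_risk", 16), rep("uncertain_risk", 11))
  truth <- c(rep("high", 17), rep("low", 27))
  m <- framework_metrics(calls, truth)
  expect_equal(round(m$protectiveness), 94)    # 16 of 17
  expect_equal(round(m$utility), 59)           # 16 of 27
  expect_equal(m$protectiveness, 100 * 16 / 17)
  expect_equal(m$utility, 100 * 16 / 27)

  perfect <- framework_metrics(c("uncertain_risk", "low_risk"),
                               c("high", "low"))
  expect_equal(perfect$protectiveness, 100)
  expect_equal(perfect$utility, 100)
})

test_that("uncertain-truth scenarios enter neither metric", {
  m <- framework_metrics(
    c("uncertain_risk", "low_risk", "uncertain_risk", "low_risk"),
    c("high", "low", "uncertain", "uncertain"))
  expect_equal(m$protectiveness, 100)
  expect_equal(m$utility, 100)
  expect_equal(sum(m$counts), 4)
})

test_that("metrics are invariant to scenario order", {
  set.seed(12)
  calls <- sample(c("uncertain_risk", "low_risk"), 30, replace = TRUE)
  truth <- sample(c("high", "low", "uncertain"), 30, replace = TRUE)
  m1 <- framework_metrics(calls, truth)
  ord <- sample(30)
  m2 <- framework_metrics(calls[ord], truth[ord])
  expect_equal(m1$protectiveness, m2$protectiveness)
  expect_equal(m1$utility, m2$utility)
})

test_that("a well-separated synthetic suite scores 100/100", {
  suite <- gen_benchmark_suite(n_chemicals = 15, separation = 10, seed = 4)
  res <- evaluate_ber(suite$pods, suite$scenarios)
  expect_equal(res$metrics$protectiveness, 100)
  expect_equal(res$metrics$utility, 100)
})
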