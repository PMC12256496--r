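test_that("summary imputation follows the documented precedence", {
  expect_equal(impute_summary(list(conc_min = 2, conc_max = 8))$sd, 1.0)
  expect_equal(impute_summary(list(conc_mean = 4, conc_sem = 2, n = 25))$sd,
               10.0)
  r <- impute_summary(list(conc_mean = 4, conc_sd = 3.3, conc_sem = 2,
                           n = 25))
  expect_equal(r$sd, 3.3)
  expect_equal(r$sd_source, "reported")
  # mean from range: midpoint by default, half-range only in compat mode
  expect_equal(impute_summary(list(conc_min = 2, conc_max = 8))$mean, 5)
  expect_equal(impute_summary(list(conc_min = 2, conc_max = 8),
                              mean_from_range = "compat_half_range")$mean, 3)
  none <- impute_summary(list(conc_mean = 4))
  expect_true(none$sd_missing)
})

test_that("dose and concentration unit conversions are exact", {
  expect_equal(external_dose_mg_per_day(5, "mg_per_kg", 1), 350)
  expect_equal(external_dose_mg_per_day(100, "mg_per_m2", 1), 170)
  expect_equal(external_dose_mg_per_day(200, "mg", 2), 400)
  expect_error(external_dose_mg_per_day(1, "stones"), "unknown")
  expect_equal(internal_conc_uM(1, "ug_per_mL", 200), 5)
  expect_equal(internal_conc_uM(1, "mg_per_L", 1000), 1)
  expect_equal(internal_conc_uM(250, "nM"), 0.25)
  expect_error(internal_conc_uM(1, "ug_per_mL"), "molecular weight")
})

test_that("unit conversion round-trips to 1e-9 relative tolerance", {
  for (u in c("ug_per_mL", "mg_per_L", "ng_per_mL", "uM", "nM")) {
    x <- 3.7
    back <- uM_to_unit(internal_conc_uM(x, u, mw = 151.2), u, mw = 151.2)
    expect_equal(back, x, tolerance = 1e-9)
  }
})

test_that("CDR scales mean and sd linearly with dose", {
  r <- cdr(10, 100, conc_sd_uM = 4, n = 12)
  expect_equal(r$cdr_mean, 0.1)
  expect_equal(r$cdr_sd, 0.04)
  expect_equal(cdr(0, 50)$cdr_mean, 0)
  expect_equal(cdr(1, 8, conc_sd_uM = 4)$cdr_sd, 0.5)
  expect_error(cdr(1, 0), "positive")
})

test_that("weighted SD equals the SD of the reconstructed pooled sample", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    ns <- sample(5:50, k, replace = TRUE)
    ms <- runif(k, 0.5, 3)
    ss <- runif(k, 0.1, 1)
    recs <- lapply(seq_len(k), function(i)
      list(cdr_mean = ms[i], cdr_sd = ss[i], n = ns[i]))
    s <- weighted_population_summary(recs)
    pooled <- unlist(lapply(seq_len(k), function(i)
      exact_sample(ns[i], ms[i], ss[i])))
    expect_equal(s$weighted_mean, mean(pooled), tolerance = 1e-9)
    expect_equal(s$weighted_sd, sd(pooled), tolerance = 1e-9)
  }
})

test_that("single-study pooling collapses to that study", {
  s <- weighted_population_summary(list(list(cdr_mean = 2, cdr_sd = 0.5,
                                             n = 30)))
  expect_equal(s$weighted_mean, 2)
  expect_equal(s$weighted_sd, 0.5)
  expect_equal(s$p95, 2 + 1.64 * 0.5)
})

test_that("weighted mean is invariant under splitting a study in half", {
  whole <- weighted_population_summary(list(
    list(cdr_mean = 1.4, cdr_sd = 0.3, n = 40)))
  halves <- weighted_population_summary(list(
    list(cdr_mean = 1.4, cdr_sd = 0.3, n = 20),
    list(cdr_mean = 1.4, cdr_sd = 0.3, n = 20)))
  expect_equal(halves$weighted_mean, whole$weighted_mean)
})

test_that("sd-missing studies feed the mean but not the SD", {
  s <- weighted_population_summary(list(
    list(cdr_mean = 1, cdr_sd = 0.2, n = 10),
    list(cdr_mean = 3, cdr_sd = NA, n = 10)))
  expect_equal(s$weighted_mean, 2)
  expect_equal(s$n_sd, 10)
  expect_false(is.na(s$weighted_sd))
})

test_that("TKVF is 1 + z*CV, at least 1, and increasing in the SD", {
  mk <- function(m, sdv) weighted_population_summary(list(
    list(cdr_mean = m, cdr_sd = sdv, n = 30)))
  expect_equal(tkvf(mk(1, 0)), 1.0)
  expect_equal(tkvf(mk(1, 1)), 2.64)
  expect_equal(tkvf(mk(2, 1)), 1.82)
  sds <- seq(0, 2, by = 0.25)
  tks <- vapply(sds, function(s) tkvf(mk(1.5, s)), 0)
  expect_true(all(diff(tks) > 0))
  expect_true(all(tks >= 1))
  # p95 consistency with the normal quantile at the z approximation
  s <- mk(2, 0.5)
  expect_equal(s$p95, qnorm(0.95, 2, 0.5), tolerance = 0.01)
})

test_that("population comparison reports fold, Welch p, and small-N flag", {
  a <- weighted_population_summary(list(list(cdr_mean = 2, cdr_sd = 0.5,
                                             n = 200)))
  same <- compare_populations(a, a)
  expect_equal(same$fold_difference, 1.0)
  expect_gt(same$p_value, 0.99)

  set.seed(7)
  x <- exact_sample(200, 2, 0.6); y <- exact_sample(200, 4, 0.6)
  g1 <- weighted_population_summary(list(list(cdr_mean = mean(x),
                                              cdr_sd = sd(x), n = 200)))
  g2 <- weighted_population_summary(list(list(cdr_mean = mean(y),
                                              cdr_sd = sd(y), n = 200)))
  cmpr <- compare_populations(g1, g2)
  expect_equal(cmpr$fold_difference, 2, tolerance = 1e-9)
  expect_lt(cmpr$p_value, 0.01)
  # oracle: Welch t test on the reconstructed samples agrees closely
  expect_equal(cmpr$p_value, t.test(y, x)$p.value, tolerance = 1e-3)

  tiny <- weighted_population_summary(list(list(cdr_mean = 2.2,
                                                cdr_sd = 0.4, n = 3)))
  flagged <- compare_populations(a, tiny)
  expect_true(flagged$small_n_flag)
  expect_true(is.na(flagged$p_value))
})

test_that("pipeline recovers the generating CDR from mixed-unit studies", {
  ps <- gen_pk_studies(n_studies = 12, cdr_mean = 0.05, cdr_cv = 0.4,
                       n_range = c(50, 200), seed = 3)
  out <- pk_population_summaries(ps$records)
  expect_equal(out$summaries$weighted_mean, ps$truth$cdr_mean,
               tolerance = 0.05)
  # doseless records are excluded with a reason, not dropped silently
  rec <- ps$records
  rec$dose_amount[1] <- NA
  out2 <- pk_population_summaries(rec)
  expect_equal(out2$excluded$reason, "no_defined_dose")
})
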