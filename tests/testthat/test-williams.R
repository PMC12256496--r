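test_that("flat data give p = 1 and strong trends give tiny p", {
  flat <- list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_equal(williams_trend_p(flat, n_perm = 200, seed = 1), 1)
  set.seed(10)
  strong <- lapply(0:4, function(d) rnorm(3, mean = 5 * d, sd = 0.5))
  expect_lt(williams_trend_p(strong, direction = "up", n_perm = 3000,
                             seed = 2), 0.001)
})

test_that("permutation p matches full enumeration on a tiny design", {
  # 3 groups x 2 replicates: all 6!/(2!2!2!) = 90 label assignments
  y <- c(0.1, 0.4, 1.2, 0.9, 2.1, 2.4)
  groups <- list(y[1:2], y[3:4], y[5:6])
  perms <- combn(6, 2, simplify = FALSE)
  stat_for <- function(assign_ctrl, assign_mid) {
    rest <- setdiff(1:6, c(assign_ctrl, assign_mid))
    g <- list(y[assign_ctrl], y[assign_mid], y[rest])
    # statistic recomputed via the package on a degenerate 1-perm call is
    # not independent; use an explicit isotonic contrast instead
    means <- vapply(g, mean, 0)
    iso <- if (means[2] > means[3]) rep(mean(c(means[2], means[3])), 2) else
      means[2:3]
    s2 <- sum((y[assign_ctrl] - means[1])^2, (y[assign_mid] - means[2])^2,
              (y[rest] - means[3])^2) / 3
    (iso[2] - means[1]) / sqrt(s2 * (1 / 2 + 1 / 2))
  }
  t_obs <- stat_for(1:2, 3:4)
  all_t <- unlist(lapply(perms, function(ctrl) {
    remaining <- setdiff(1:6, ctrl)
    lapply(combn(remaining, 2, simplify = FALSE), function(mid)
      stat_for(ctrl, mid))
  }))
  exact_p <- mean(all_t >= t_obs - 1e-12)
  p_hat <- williams_trend_p(groups, direction = "up", n_perm = 4000,
                            seed = 5)
  expect_equal(p_hat, exact_p, tolerance = 0.03)
})

test_that("prefilter needs both trend significance and fold change", {
  set.seed(21)
  up <- lapply(c(1, 1.2, 1.6, 2.0), function(m) rnorm(4, m, 0.05))
  weak <- lapply(c(1, 1.05, 1.1, 1.15), function(m) rnorm(4, m, 0.05))
  r_up <- prefilter_gene(up, n_perm = 500, seed = 3)
  expect_true(r_up$pass)
  expect_gte(r_up$max_fold_change, 1.5)
  r_weak <- prefilter_gene(weak, n_perm = 500, seed = 3)
  expect_false(r_weak$pass)   # fold change below 1.5
  # downregulation counts through the folded ratio
  down <- lapply(c(1, 0.8, 0.6, 0.4), function(m) rnorm(4, m, 0.05))
  r_down <- prefilter_gene(down, n_perm = 500, seed = 3)
  expect_true(r_down$pass)
})

test_that("Pfaffl ratio corrects for amplification efficiencies", {
  expect_equal(pfaffl_relative_expression(19, 20, 20, 20, 2, 2), 2)
  expect_equal(pfaffl_relative_expression(20, 20, 20, 20, 2, 2), 1)
  expect_equal(pfaffl_relative_expression(18, 20, 19, 20, 1.9, 2.0),
               1.9^2 / 2)
  expect_error(pfaffl_relative_expression(1, 1, 1, 1, 0.9, 2), "in \\(1, 2\\]")
})
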