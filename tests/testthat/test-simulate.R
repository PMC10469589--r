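test_that("log-normal shape calibration inverts the CV formula", {
  expect_equal(calibrate_sigma(0), 0)
  expect_equal(calibrate_sigma(0.72), 0.6462639932, tolerance = 1e-9)
  expect_equal(calibrate_sigma(0.37), 0.3581972364, tolerance = 1e-9)
  # round trip: CV of LogNormal(0, sigma) is sqrt(exp(sigma^2) - 1)
  for (cv in c(0.1, 0.37, 0.72, 2)) {
    s <- calibrate_sigma(cv)
    expect_equal(sqrt(exp(s^2) - 1), cv, tolerance = 1e-12)
  }
})

test_that("the generator recovers the target CV at large n", {
  set.seed(99)
  w <- stats::rlnorm(10000, 0, calibrate_sigma(0.72))
  expect_equal(stats::sd(w) / mean(w), 0.72, tolerance = 0.05 * 0.72)
})

test_that("simulation config validates the plate capacity", {
  expect_error(sim_config(n_samples = 370, n_blanks = 32), "exceeds the 384")
  cfg <- sim_config()
  expect_equal(cfg$n_samples, 352L)
  expect_equal(cfg$n_blanks, 32L)
  expect_equal(cfg$depth_first, 5000000L)
  expect_equal(cfg$depth_second, 5700000L)
})

test_that("first-run counts sum exactly to depth and are seed-reproducible", {
  cfg <- sim_config(n_samples = 20, n_blanks = 4, depth_first = 123457,
                    seed = 42)
  r1 <- simulate_first_run(cfg)
  r2 <- simulate_first_run(cfg)
  expect_identical(r1$first_run$reads_pf, r2$first_run$reads_pf)
  expect_identical(r1$weights, r2$weights)
  expect_equal(total_depth(r1$first_run), 123457)
  expect_identical(r1$first_run$role, r1$plate$role)

  r3 <- simulate_first_run(sim_config(n_samples = 20, n_blanks = 4,
                                      depth_first = 123457, seed = 43))
  expect_false(identical(r1$first_run$reads_pf, r3$first_run$reads_pf))
})

test_that("a zero-dispersion pool sequences evenly up to multinomial noise", {
  r <- simulate_first_run(sim_config(n_samples = 4, n_blanks = 0,
                                     target_cv = 0, depth_first = 1e6,
                                     seed = 3))
  # each library expects 250k reads; allow 5 binomial sds
  sd_bin <- sqrt(1e6 * 0.25 * 0.75)
  expect_true(all(abs(r$first_run$reads_pf - 250000) < 5 * sd_bin))
})

test_that("blanks are depleted relative to samples in the first run", {
  r <- simulate_first_run(sim_config(seed = 8))
  blank <- r$first_run$role == "blank"
  expect_lt(stats::median(r$first_run$reads_pf[blank]),
            0.1 * stats::median(r$first_run$reads_pf[!blank]))
})

test_that("resequencing follows the volume-weighted contributions", {
  # uniform everything: uniform expectation
  idx <- index_from_p(rep(0.25, 4))
  v <- compute_volumes(idx)
  ct <- simulate_resequencing(rep(1, 4), v, depth_second = 4e5, seed = 9)
  expect_equal(total_depth(ct), 4e5)
  expect_true(all(abs(ct$reads_pf - 1e5) < 5 * sqrt(4e5 * 0.25 * 0.75)))

  # worked example: empirical proportions track the projection oracle
  idx2 <- index_from_p(c(0.1, 0.2, 0.7))
  v2 <- compute_volumes(idx2)
  pr <- project_proportions(v2, idx2)
  ct2 <- simulate_resequencing(c(1, 2, 7), v2, depth_second = 4e6, seed = 10)
  emp <- ct2$reads_pf / sum(ct2$reads_pf)
  expect_equal(emp, pr$projected_proportion, tolerance = 0.005)
})

test_that("the end-to-end experiment is reproducible and corrects the CV", {
  res1 <- run_pool_experiment(sim_config(seed = 21))
  res2 <- run_pool_experiment(sim_config(seed = 21))
  expect_identical(res1$second_run$reads_pf, res2$second_run$reads_pf)
  expect_equal(res1$stats_second$cv, res2$stats_second$cv)

  for (s in 1:5) {
    res <- run_pool_experiment(sim_config(seed = 200 + s))
    expect_lt(res$stats_second$cv, res$stats_first$cv)
  }

  # nothing to correct: both runs at sampling-noise CV
  res0 <- run_pool_experiment(sim_config(target_cv = 0, seed = 33))
  noise <- 1 / sqrt(res0$config$depth_first / 384)
  expect_lt(res0$stats_first$cv, 3 * noise)
  expect_lt(res0$stats_second$cv, 3 * noise)
})

test_that("within the clamp window the residual CV is the multinomial limit", {
  # tight weights (CV 0.3 spans ~10x at n=100, well inside the 100x window):
  # after normalization the only variance left is sampling noise
  cfg <- sim_config(n_samples = 100, n_blanks = 0, target_cv = 0.3,
                    depth_second = 2e6, seed = 77)
  res <- run_pool_experiment(cfg)
  expect_false(any(has_flag(res$volumes, "clamped_low") |
                     has_flag(res$volumes, "clamped_high")))
  limit <- sqrt(100 / 2e6)
  expect_lt(res$stats_second$cv, 2 * limit)
  expect_gt(res$stats_second$cv, limit / 2)
})

test_that("Dirichlet-multinomial overdispersion inflates the sampling CV", {
  base <- run_pool_experiment(sim_config(target_cv = 0, seed = 55))
  over <- run_pool_experiment(sim_config(target_cv = 0, overdispersion = 0.1,
                                         seed = 55))
  expect_gt(over$stats_second$cv, 2 * base$stats_second$cv)
  expect_equal(total_depth(over$second_run), over$config$depth_second)
})
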