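test_that("relative MSE has its algebraic identities", {
  set.seed(6)
  P <- runif(50, 5, 25)
  mask <- rep(c(TRUE, FALSE), 25)
  expect_equal(relative_mse(P, P, mask), 0)
  expect_equal(relative_mse(1.1 * P, P, mask), 0.01, tolerance = 1e-12)
  expect_equal(relative_mse(3 * 1.1 * P, 3 * P, mask),
               relative_mse(1.1 * P, P, mask), tolerance = 1e-12)
  expect_error(relative_mse(P, rep(0, 50), mask), "zero")
  expect_error(relative_mse(P, P, rep(FALSE, 50)), "empty")
})

test_that("cohort summaries reproduce hand-computed statistics", {
  s <- summarize_cohort(c(10, 20, 30))
  expect_equal(s$mean, 20)
  expect_equal(s$min, 10); expect_equal(s$max, 30)
  expect_equal(s$sem, 10 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$sem, 5.7735, tolerance = 1e-4)
  # permutation invariance
  expect_equal(summarize_cohort(c(30, 10, 20)), s)
  one <- summarize_cohort(42)
  expect_equal(one$min, one$max)
  expect_equal(one$sem, 0)
  expect_false(one$sem_defined)
})

test_that("the sensitivity harness is reproducible and well-formed", {
  cases <- sensitivity_cases("baseline")
  r1 <- run_sensitivity(cases, replicates = 2, bootstrap_n = 200, seed = 5,
                        nx = 50, q = 8, config = quick_config())
  r2 <- run_sensitivity(cases, replicates = 2, bootstrap_n = 200, seed = 5,
                        nx = 50, q = 8, config = quick_config())
  expect_identical(r1$errors$error, r2$errors$error)
  expect_identical(r1$summary, r2$summary)
  expect_equal(nrow(r1$errors), 2)
  expect_true(all(is.finite(r1$errors$error)) && all(r1$errors$error >= 0))
  s <- r1$summary
  expect_true(s$ci_lo <= s$mean && s$mean <= s$ci_hi)
  # a different master seed draws different noise/initializations
  r3 <- run_sensitivity(cases, replicates = 2, bootstrap_n = 200, seed = 6,
                        nx = 50, q = 8, config = quick_config())
  expect_false(identical(r1$errors$error, r3$errors$error))
})

test_that("recovery error does not degrade below noise, up to CI overlap", {
  res <- run_sensitivity(sensitivity_cases(c("noise_min", "baseline", "noise_max")),
                         replicates = 2, bootstrap_n = 200, seed = 9,
                         nx = 50, q = 8, config = quick_config())
  s <- res$summary
  # nondecreasing in the noise level, allowing overlapping intervals
  expect_lte(s$ci_lo[s$case == "noise_min"], s$ci_hi[s$case == "baseline"])
  expect_lte(s$ci_lo[s$case == "baseline"], s$ci_hi[s$case == "noise_max"])
})

test_that("the imaging-time sweep scores candidates and rejects bad input", {
  case <- baseline_case(noise_level = 0, seed = 4, nx = 50)
  tt <- case$conc$times
  sw <- imaging_time_sweep(case$conc, case$geom, tt[c(75, 149)], case$params,
                           case$plasma, config = quick_config(), q = 8)
  expect_equal(nrow(sw$summary), 2)
  expect_true(all(is.finite(sw$summary$mean_ifp)))
  expect_true(all(sw$summary$mse >= 0))
  expect_length(sw$curves, 2)
  expect_error(imaging_time_sweep(case$conc, case$geom, 0, case$params,
                                  case$plasma), "after the initial")
})
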