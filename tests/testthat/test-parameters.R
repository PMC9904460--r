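test_that("median-to-probability conversion matches the constant-hazard closed form", {
  # published 3-decimal values for both arms, plus the trivial half-life case
  cases <- tibble::tribble(
    ~median, ~expected3,
    17.5, 0.039, # anlotinib PFS -> progression from stable
    30.9, 0.022, # anlotinib OS -> death from stable
    13.4, 0.050, # anlotinib post-progression interval -> death after progression
    16.6, 0.041, # sunitinib PFS
    30.5, 0.022, # sunitinib OS
    13.9, 0.049, # sunitinib post-progression interval
    1, 0.500
  )
  expect_equal(round(median_to_cycle_prob(cases$median), 3), cases$expected3)
  # equivalent rate form: 1 - exp(-log(2)/m * cycle)
  m <- c(3.7, 12, 100)
  expect_equal(median_to_cycle_prob(m, 2), 1 - exp(-log(2) / m * 2))
})

test_that("conversion is monotone in median and cycle length, and invertible", {
  medians <- seq(0.5, 60, by = 0.5)
  p <- median_to_cycle_prob(medians)
  expect_true(all(diff(p) < 0))
  cycles <- seq(0.25, 6, by = 0.25)
  expect_true(all(diff(median_to_cycle_prob(20, cycles)) > 0))
  expect_true(all(p > 0 & p < 1))
  # round trip: m = cycle / log2(1 / (1 - p))
  recovered <- 1 / log2(1 / (1 - p))
  expect_equal(recovered, medians, tolerance = 1e-9)
})

test_that("invalid medians and cycle lengths are rejected", {
  expect_error(median_to_cycle_prob(0), "positive")
  expect_error(median_to_cycle_prob(-3), "positive")
  expect_error(median_to_cycle_prob(10, 0), "positive")
})

test_that("derive_transitions reproduces the published per-arm probabilities", {
  out <- derive_transitions(mrcc_trial_summaries())
  expect_equal(round(out$p_stable_prog, 3), c(0.039, 0.041))
  expect_equal(round(out$p_stable_dead, 3), c(0.022, 0.022))
  expect_equal(round(out$p_prog_dead, 3), c(0.050, 0.049))
  # closed form: os = 2 * pfs = 2 -> progression probability 1 - 0.5^(1/1)
  toy <- derive_transitions(tibble::tibble(arm = "x", median_pfs = 1, median_os = 2))
  expect_equal(toy$p_stable_prog, 0.5)
})

test_that("derive_transitions rejects a non-positive post-progression interval", {
  bad <- tibble::tibble(arm = "x", median_pfs = 10, median_os = 10)
  expect_error(derive_transitions(bad), "median_os must exceed median_pfs")
  expect_error(
    derive_transitions(tibble::tibble(arm = "x", median_pfs = -1, median_os = 5)),
    "positive"
  )
})

test_that("annual-to-cycle discount conversion preserves the annual rate", {
  expect_equal(annual_to_cycle_discount(0.05, 1), 1.05^(1 / 12) - 1)
  expect_equal(annual_to_cycle_discount(0, 1), 0)
  expect_equal(annual_to_cycle_discount(0.05, 12), 0.05)
  # compounding the monthly rate over a year recovers the annual rate exactly
  expect_equal((1 + annual_to_cycle_discount(0.08, 1))^12 - 1, 0.08)
  expect_equal(annual_to_cycle_discount(0.05, 1, method = "simple"), 0.05 / 12)
  expect_error(annual_to_cycle_discount(-1.5), "greater than -1")
})

test_that("method-of-moments fits hit the requested mean and sd", {
  # range read as a 95% interval: sd = (high - low) / (2 * 1.96)
  b <- fit_distribution("beta", 0.730, 0.584, 0.876)
  expect_equal(b$sd, (0.876 - 0.584) / (2 * qnorm(0.975)))
  expect_equal(b$sd, 0.0745, tolerance = 1e-3)
  expect_equal(with(b$shape, shape1 / (shape1 + shape2)), 0.730, tolerance = 1e-9)

  g <- fit_distribution("gamma", 864.76, 691.81, 1037.71)
  expect_equal(with(g$shape, shape * scale), 864.76, tolerance = 1e-9)

  d <- fit_distribution("gamma", 5, 5, 5)
  expect_identical(d$family, "degenerate")
  expect_identical(sample_distribution(d, 3), rep(5, 3))
})

test_that("fitted distributions recover their mean in large samples", {
  dists <- list(
    fit_distribution("beta", 0.730, 0.584, 0.876),
    fit_distribution("beta", 0.05, 0.04, 0.061),
    fit_distribution("gamma", 864.76, 691.81, 1037.71),
    fit_distribution("gamma", 4535.08, 3628.06, 5442.10)
  )
  withr::with_seed(11, {
    for (d in dists) {
      x <- sample_distribution(d, 10000)
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - d$mean), 3 * se)
      # sampled sd close to the requested one (moment fit, not a tuning knob)
      expect_equal(sd(x), d$sd, tolerance = 0.05)
    }
  })
})

test_that("infeasible moment combinations are rejected", {
  expect_error(fit_distribution("beta", 0.5, -2, 3), "variance")
  expect_error(fit_distribution("beta", 1.5, 1.4, 1.6), "inside")
  expect_error(fit_distribution("gamma", 0, 0, 0.1), "positive mean")
  expect_error(fit_distribution("beta", 0.5, 0.6, 0.7), "low <= mean <= high")
})

test_that("strategy and settings constructors enforce their invariants", {
  expect_error(model_settings(horizon = 0), "horizon")
  expect_error(model_settings(discount_annual = -0.01), "discount_annual")
  good <- build_strategies(toy_config())$a
  expect_s3_class(good, "strategy_params")
  expect_error(
    strategy_params("x", list(p_stable_prog = 0.7, p_stable_dead = 0.5,
                              p_prog_dead = 0.1),
                    good$utilities, good$costs, 0.1),
    "must not exceed 1"
  )
  expect_error(
    strategy_params("x", good$transitions,
                    list(stable = 0.6, progressive = 0.7, ae_disutility = 0.1),
                    good$costs, 0.1),
    "progressive-state utility"
  )
  expect_error(
    strategy_params("x", good$transitions, good$utilities,
                    utils::modifyList(good$costs, list(drug = -1)), 0.1),
    "costs\\$drug"
  )
})
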