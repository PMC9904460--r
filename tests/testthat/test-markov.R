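anlo_tr <- list(p_stable_prog = 0.039, p_stable_dead = 0.022, p_prog_dead = 0.050)

test_that("cohort trace conserves mass, starts stable and absorbs into death", {
  withr::with_seed(3, {
    for (i in 1:20) {
      p <- sort(runif(2))
      tr <- list(p_stable_prog = p[2] - p[1], p_stable_dead = p[1],
                 p_prog_dead = runif(1))
      trace <- run_cohort(tr, model_settings(horizon = 60))
      expect_equal(nrow(trace), 61)
      expect_equal(unlist(trace[1, c("stable", "progressive", "dead")]),
                   c(stable = 1, progressive = 0, dead = 0))
      expect_equal(trace$stable + trace$progressive + trace$dead,
                   rep(1, 61), tolerance = 1e-12)
      expect_true(all(trace$stable >= 0 & trace$progressive >= 0 & trace$dead >= 0))
      expect_true(all(diff(trace$dead) >= 0))
    }
  })
})

test_that("one cohort step reproduces the hand-computed matrix product", {
  trace <- run_cohort(anlo_tr, model_settings(horizon = 1))
  expect_equal(unlist(trace[2, c("stable", "progressive", "dead")]),
               c(stable = 0.939, progressive = 0.039, dead = 0.022))
})

test_that("degenerate transitions leave the whole cohort stable", {
  tr0 <- list(p_stable_prog = 0, p_stable_dead = 0, p_prog_dead = 0)
  trace <- run_cohort(tr0, model_settings(horizon = 12))
  expect_equal(trace$stable, rep(1, 13))
})

test_that("nearly the whole cohort is dead at the 10-year horizon in both arms", {
  for (st in build_strategies(ref_config())) {
    trace <- run_cohort(st$transitions, model_settings())
    expect_gte(trace$dead[121], 0.99)
  }
})

test_that("infeasible stable-state exits are rejected", {
  expect_error(
    run_cohort(list(p_stable_prog = 0.7, p_stable_dead = 0.5, p_prog_dead = 0.1),
               model_settings()),
    "Infeasible"
  )
})

test_that("a full-health immortal cohort accrues exactly the horizon in LY and QALY", {
  st <- strategy_params(
    "immortal",
    transitions = list(p_stable_prog = 0, p_stable_dead = 0, p_prog_dead = 0),
    utilities = list(stable = 1, progressive = 1, ae_disutility = 0),
    costs = list(drug = 0, tests = 0, outpatient = 0, societal = 0, ae = 0,
                 progressive_state = 0),
    ae_rate = 0
  )
  for (counting in c("start", "end", "half")) {
    out <- accrue_outcomes(st, model_settings(discount_annual = 0, counting = counting))
    expect_equal(out$life_years, 10)
    expect_equal(out$qalys, 10)
    expect_equal(out$total_cost, 0)
  }
})

test_that("with no progression the engine matches the two-state geometric closed form", {
  p_sd <- 0.03
  st <- strategy_params(
    "two-state",
    transitions = list(p_stable_prog = 0, p_stable_dead = p_sd, p_prog_dead = 0),
    utilities = list(stable = 1, progressive = 1, ae_disutility = 0),
    costs = list(drug = 0, tests = 0, outpatient = 0, societal = 0, ae = 0,
                 progressive_state = 0),
    ae_rate = 0
  )
  s <- model_settings()
  out <- accrue_outcomes(st, s)
  v <- (1 - p_sd) / (1 + annual_to_cycle_discount(0.05))
  # start-of-cycle counting: sum over boundaries 0..119 of ((1-p)/(1+r))^t / 12
  closed_form <- (1 - v^120) / (1 - v) / 12
  expect_equal(out$life_years, closed_form, tolerance = 1e-9)
})

test_that("outcome aggregates respect basic monotonicity and ordering", {
  cfg <- toy_config()
  base <- accrue_outcomes(build_strategies(cfg)$a, cfg$settings)
  expect_lte(base$qalys, base$life_years)
  expect_true(all(c(base$life_years, base$qalys, base$total_cost) >= 0))

  # raising any cost component weakly increases total cost
  for (comp in c("a.costs.drug", "shared.costs.tests", "shared.costs.societal",
                 "shared.costs.progressive_state")) {
    bumped <- set_parameter(cfg, comp, 1e4)
    out <- accrue_outcomes(build_strategies(bumped)$a, cfg$settings)
    expect_gte(out$total_cost, base$total_cost)
  }
  # raising a death probability weakly decreases LY and QALY
  for (comp in c("a.transitions.p_stable_dead", "a.transitions.p_prog_dead")) {
    bumped <- set_parameter(cfg, comp, 0.5)
    out <- accrue_outcomes(build_strategies(bumped)$a, cfg$settings)
    expect_lte(out$life_years, base$life_years)
    expect_lte(out$qalys, base$qalys)
  }
})

test_that("positive discounting strictly shrinks every aggregate", {
  st <- build_strategies(ref_config())$anlotinib
  disc <- accrue_outcomes(st, model_settings(discount_annual = 0.05))
  undisc <- accrue_outcomes(st, model_settings(discount_annual = 0))
  expect_lt(disc$life_years, undisc$life_years)
  expect_lt(disc$qalys, undisc$qalys)
  expect_lt(disc$total_cost, undisc$total_cost)
})

test_that("cohort aggregates agree with the individual-level microsimulation oracle", {
  settings <- model_settings()
  for (st in build_strategies(ref_config())) {
    cohort <- accrue_outcomes(st, settings)
    sim <- microsim_oracle(st, settings, n_patients = 100000, seed = 202)
    expect_within_band(cohort$life_years, mc_band(sim$ly))
    expect_within_band(cohort$qalys, mc_band(sim$qaly))
    expect_within_band(cohort$total_cost, mc_band(sim$cost))
  }
})

test_that("total person-time equals the integral of the survival curve", {
  settings <- model_settings(discount_annual = 0, counting = "start")
  st <- build_strategies(ref_config())$anlotinib
  out <- accrue_outcomes(st, settings)
  trace <- out$trace
  expect_equal(out$life_years,
               sum(1 - trace$dead[1:settings$horizon]) / 12,
               tolerance = 1e-12)
})
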