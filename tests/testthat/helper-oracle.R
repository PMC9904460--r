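# Independent individual-level microsimulation oracle.
#
# Simulates N patients one at a time through the same three-state chain the
# cohort engine integrates analytically: the number of cycles survived in the
# stable state before the first exit event is geometric with exit probability
# p_sp + p_sd; the exit is a death with probability p_sd / (p_sp + p_sd);
# post-progression survival is geometric with p_pd. Rewards are accrued with
# the start-of-cycle counting convention (state at the beginning of each
# cycle, discount exponent = cycle index) and the per-cycle adverse-event
# disutility, i.e. the package defaults, but through a completely different
# computation: per-patient closed-form partial geometric sums instead of a
# cohort transition matrix.
#
# Returns per-patient vectors so callers can form Monte Carlo standard
# errors.
microsim_oracle <- function(strategy, settings, n_patients, seed) {
  stopifnot(settings$counting == "start",
            settings$ae_disutility_mode == "per_cycle")
  tr <- strategy$transitions
  q <- tr$p_stable_prog + tr$p_stable_dead
  r <- (1 + settings$discount_annual)^(settings$cycle_length / 12) - 1
  v <- 1 / (1 + r)
  h <- settings$horizon
  yrs <- settings$cycle_length / 12

  # discounted count of boundaries a..b (clipped to 0..h-1): sum_{t=a}^{b} v^t
  geom_sum <- function(a, b) {
    a <- pmax(a, 0)
    b <- pmin(b, h - 1)
    out <- ifelse(b < a, 0, (v^a - v^(b + 1)) / (1 - v))
    out
  }

  withr::with_seed(seed, {
    k_stable <- stats::rgeom(n_patients, q) # boundaries 0..k_stable are stable
    dies_from_stable <- stats::runif(n_patients) < tr$p_stable_dead / q
    k_prog <- stats::rgeom(n_patients, tr$p_prog_dead)
    ae <- stats::runif(n_patients) < strategy$ae_rate

    s_time <- geom_sum(0, k_stable)
    p_start <- k_stable + 1
    p_end <- ifelse(dies_from_stable, p_start - 1, k_stable + 1 + k_prog)
    p_time <- geom_sum(p_start, p_end)

    u <- strategy$utilities
    co <- strategy$costs
    stable_cost <- co$drug + co$tests + co$outpatient + co$societal + co$ae
    prog_cost <- co$progressive_state + co$societal

    ly <- (s_time + p_time) * yrs
    qaly <- (s_time * u$stable + p_time * u$progressive) * yrs -
      s_time * ifelse(ae, u$ae_disutility, 0) * yrs
    cost <- s_time * stable_cost + p_time * prog_cost
    list(ly = ly, qaly = qaly, cost = cost)
  })
}

# mean and 3 Monte Carlo standard errors of a per-patient vector
mc_band <- function(x) {
  m <- mean(x)
  se <- stats::sd(x) / sqrt(length(x))
  c(mean = m, lo = m - 3 * se, hi = m + 3 * se)
}

expect_within_band <- function(value, band) {
  expect_gte(value, band[["lo"]])
  expect_lte(value, band[["hi"]])
}
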