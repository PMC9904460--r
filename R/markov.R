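#' Run the three-state cohort simulation
#'
#' Advances the whole cohort through the stable / progressive / dead model one
#' cycle at a time using the transition matrix
#' \preformatted{
#'   [ 1 - p_sp - p_sd   p_sp        p_sd ]
#'   [ 0                 1 - p_pd    p_pd ]
#'   [ 0                 0           1    ]
#' }
#' Everyone starts stable; death is absorbing.
#'
#' @param transitions Named list (or one-row data frame) with `p_stable_prog`,
#'   `p_stable_dead`, `p_prog_dead`.
#' @param settings A [model_settings()] object (only `horizon` is used here).
#' @return A tibble with `horizon + 1` rows and columns `cycle` (0..horizon),
#'   `stable`, `progressive`, `dead`; every row sums to 1.
#' @examples
#' tr <- list(p_stable_prog = 0.039, p_stable_dead = 0.022, p_prog_dead = 0.050)
#' trace <- run_cohort(tr, model_settings())
#' tail(trace, 1) # ~99% dead after 120 monthly cycles
#' @export
run_cohort <- function(transitions, settings = model_settings()) {
  stopifnot(inherits(settings, "model_settings"))
  tr <- as.list(transitions)
  p_sp <- as.numeric(tr$p_stable_prog)
  p_sd <- as.numeric(tr$p_stable_dead)
  p_pd <- as.numeric(tr$p_prog_dead)
  if (any(is.na(c(p_sp, p_sd, p_pd)))) {
    rlang::abort("`transitions` must supply p_stable_prog, p_stable_dead and p_prog_dead.")
  }
  if (any(c(p_sp, p_sd, p_pd) < 0) || any(c(p_sp, p_sd, p_pd) > 1)) {
    rlang::abort("Transition probabilities must lie in [0, 1].")
  }
  if (p_sp + p_sd > 1) {
    rlang::abort("Infeasible transitions: p_stable_prog + p_stable_dead exceeds 1.")
  }
  h <- settings$horizon
  occ <- matrix(0, nrow = h + 1, ncol = 3,
                dimnames = list(NULL, c("stable", "progressive", "dead")))
  occ[1, ] <- c(1, 0, 0)
  m <- rbind(
    c(1 - p_sp - p_sd, p_sp, p_sd),
    c(0, 1 - p_pd, p_pd),
    c(0, 0, 1)
  )
  for (t in seq_len(h)) occ[t + 1, ] <- occ[t, ] %*% m
  tibble::tibble(
    cycle = 0:h,
    stable = occ[, "stable"],
    progressive = occ[, "progressive"],
    dead = occ[, "dead"]
  )
}

# Cycle weights implementing the state-counting convention: returns, for
# cycles 1..horizon, the occupancy fractions to reward and the discount
# exponent attached to each. "start" rewards row t-1 at discount exponent
# t-1 (TreeAge-style stage rewards); "end" rewards row t at exponent t;
# "half" averages adjacent rows at exponent t.
cycle_weights <- function(trace, settings) {
  h <- settings$horizon
  r <- annual_to_cycle_discount(
    settings$discount_annual, settings$cycle_length, settings$discount_method
  )
  first <- 1:h
  second <- 2:(h + 1)
  s <- switch(settings$counting,
    start = trace$stable[first],
    end = trace$stable[second],
    half = (trace$stable[first] + trace$stable[second]) / 2
  )
  p <- switch(settings$counting,
    start = trace$progressive[first],
    end = trace$progressive[second],
    half = (trace$progressive[first] + trace$progressive[second]) / 2
  )
  expo <- switch(settings$counting, start = 0:(h - 1), end = first, half = first)
  list(stable = s, progressive = p, discount = (1 + r)^(-expo))
}

#' Accrue discounted life-years, QALYs and costs for one strategy
#'
#' Runs the cohort trace for the strategy's transition probabilities and sums
#' per-cycle rewards: alive person-time (in years) for life-years, person-time
#' weighted by state utility for QALYs, and per-cycle cost components for
#' total cost. Treatment-phase costs (drug, tests, outpatient, adverse-event
#' management) accrue while stable; the progressive-state cost takes over
#' after progression; societal costs accrue in both alive states. All three
#' streams are discounted at the same rate. The grade >= 3 adverse-event
#' disutility is charged according to `settings$ae_disutility_mode`.
#'
#' @param strategy A [strategy_params()] object.
#' @param settings A [model_settings()] object.
#' @return An object of class `"strategy_outcome"`: list with `name`,
#'   `life_years`, `qalys`, `total_cost`, the cohort `trace` (tibble) and the
#'   `settings` used.
#' @examples
#' arm <- build_strategies(mrcc_reference())$anlotinib
#' accrue_outcomes(arm, model_settings())
#' @export
accrue_outcomes <- function(strategy, settings = model_settings()) {
  stopifnot(inherits(strategy, "strategy_params"),
            inherits(settings, "model_settings"))
  trace <- run_cohort(strategy$transitions, settings)
  w <- cycle_weights(trace, settings)
  months_per_cycle <- settings$cycle_length
  yrs <- months_per_cycle / 12
  alive <- w$stable + w$progressive
  life_years <- sum(alive * yrs * w$discount)
  u <- strategy$utilities
  qalys <- sum((w$stable * u$stable + w$progressive * u$progressive) * yrs * w$discount)
  qalys <- qalys - switch(settings$ae_disutility_mode,
    none = 0,
    # single undiscounted lump at model entry, one affected month
    one_time = strategy$ae_rate * u$ae_disutility * yrs,
    # charged for every (discounted) month spent stable, i.e. on treatment
    per_cycle = sum(w$stable * strategy$ae_rate * u$ae_disutility * yrs * w$discount)
  )
  co <- strategy$costs
  stable_cost <- co$drug + co$tests + co$outpatient + co$societal + co$ae
  prog_cost <- co$progressive_state + co$societal
  total_cost <- sum((w$stable * stable_cost + w$progressive * prog_cost) * w$discount)
  structure(
    list(name = strategy$name, life_years = life_years, qalys = qalys,
         total_cost = total_cost, trace = trace, settings = settings),
    class = "strategy_outcome"
  )
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf(
    "<strategy_outcome> %s: %.3f LY, %.3f QALY, $%.2f (discounted)\n",
    x$name, x$life_years, x$qalys, x$total_cost
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a strategy outcome into a one-row tibble
#'
#' @param x A `"strategy_outcome"`.
#' @param ... Unused.
#' @method tidy strategy_outcome
#' @export
tidy.strategy_outcome <- function(x, ...) {
  tibble::tibble(
    strategy = x$name,
    life_years = x$life_years,
    qalys = x$qalys,
    total_cost = x$total_cost,
    dead_at_horizon = x$trace$dead[nrow(x$trace)]
  )
}

#' @rdname tidy.strategy_outcome
#' @method glance strategy_outcome
#' @export
glance.strategy_outcome <- function(x, ...) tidy.strategy_outcome(x, ...)
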