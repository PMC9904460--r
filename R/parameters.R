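#' Convert a median time-to-event into a per-cycle transition probability
#'
#' Under a constant hazard, a median time-to-event `m` implies the event rate
#' `R = log(2) / m`, and the probability that the event occurs within one model
#' cycle of length `cycle_length` is `1 - exp(-R * cycle_length)`, i.e.
#' `1 - 0.5^(cycle_length / m)`.
#'
#' @param median_time Median time to event, in months. Must be positive.
#'   Vectorised.
#' @param cycle_length Model cycle length, in months (default 1).
#' @return Per-cycle event probability in (0, 1), same length as `median_time`.
#' @examples
#' median_to_cycle_prob(17.5) # monthly progression probability, median PFS 17.5 mo
#' median_to_cycle_prob(1)    # 0.5: one median elapses per cycle
#' @export
median_to_cycle_prob <- function(median_time, cycle_length = 1) {
  if (any(!is.finite(median_time)) || any(median_time <= 0)) {
    rlang::abort("`median_time` must be positive and finite.")
  }
  if (any(!is.finite(cycle_length)) || any(cycle_length <= 0)) {
    rlang::abort("`cycle_length` must be positive and finite.")
  }
  1 - 0.5^(cycle_length / median_time)
}

#' Derive per-cycle transition probabilities from trial survival medians
#'
#' Maps per-arm median progression-free survival (PFS) and overall survival
#' (OS) onto the three transition probabilities of the stable/progressive/dead
#' cohort model:
#' * stable to progressive, from the PFS median;
#' * stable to dead, from the OS median;
#' * progressive to dead, from the post-progression interval `OS - PFS`
#'   (the time lived after progression).
#'
#' @param summaries Data frame with one row per arm and columns `arm`,
#'   `median_pfs`, `median_os` (months) and optionally `ae_grade3_rate`.
#' @param cycle_length Cycle length in months (default 1).
#' @return The input as a tibble with added columns `p_stable_prog`,
#'   `p_stable_dead`, `p_prog_dead` (probabilities per cycle).
#' @examples
#' trial <- tibble::tibble(
#'   arm = c("anlotinib", "sunitinib"),
#'   median_pfs = c(17.5, 16.6),
#'   median_os = c(30.9, 30.5)
#' )
#' derive_transitions(trial)
#' @export
derive_transitions <- function(summaries, cycle_length = 1) {
  summaries <- tibble::as_tibble(summaries)
  required <- c("arm", "median_pfs", "median_os")
  missing <- setdiff(required, names(summaries))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "`summaries` is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  if (any(summaries$median_pfs <= 0) || any(summaries$median_os <= 0)) {
    rlang::abort("Survival medians must be positive.")
  }
  bad <- summaries$median_os <= summaries$median_pfs
  if (any(bad)) {
    rlang::abort(paste0(
      "median_os must exceed median_pfs (post-progression interval must be ",
      "positive); offending arm(s): ",
      paste(summaries$arm[bad], collapse = ", "), "."
    ))
  }
  if ("ae_grade3_rate" %in% names(summaries)) {
    r <- summaries$ae_grade3_rate
    if (any(r < 0 | r > 1)) rlang::abort("`ae_grade3_rate` must lie in [0, 1].")
  }
  dplyr::mutate(
    summaries,
    p_stable_prog = median_to_cycle_prob(.data$median_pfs, cycle_length),
    p_stable_dead = median_to_cycle_prob(.data$median_os, cycle_length),
    p_prog_dead = median_to_cycle_prob(.data$median_os - .data$median_pfs, cycle_length)
  )
}

#' Convert an annual discount rate to a per-cycle rate
#'
#' The default compound-equivalent convention solves
#' `(1 + cycle_rate)^(12 / cycle_length) = 1 + annual_rate`, so the annual
#' rate is preserved exactly; `method = "simple"` divides the annual rate
#' proportionally (`annual_rate * cycle_length / 12`).
#'
#' @param annual_rate Annual discount rate (e.g. 0.05 for 5 percent per year).
#' @param cycle_length Cycle length in months (default 1).
#' @param method `"compound"` (default) or `"simple"`.
#' @return Per-cycle discount rate.
#' @examples
#' annual_to_cycle_discount(0.05)        # 1.05^(1/12) - 1
#' annual_to_cycle_discount(0.05, 12)    # 0.05
#' @export
annual_to_cycle_discount <- function(annual_rate, cycle_length = 1,
                                     method = c("compound", "simple")) {
  method <- match.arg(method)
  if (any(!is.finite(annual_rate)) || any(annual_rate <= -1)) {
    rlang::abort("`annual_rate` must be finite and greater than -1.")
  }
  if (cycle_length <= 0) rlang::abort("`cycle_length` must be positive.")
  switch(method,
    compound = (1 + annual_rate)^(cycle_length / 12) - 1,
    simple = annual_rate * cycle_length / 12
  )
}

#' Fit a sampling distribution from a base-case value and a range
#'
#' Builds the probabilistic-sensitivity-analysis distribution for one model
#' parameter by the method of moments. The `(low, high)` range is treated as a
#' central 95% interval, so `sd = (high - low) / (2 * 1.96)`. Probabilities
#' and utilities use a beta distribution, costs a gamma distribution; a
#' degenerate "distribution" returns the mean exactly (used for parameters
#' held fixed). The fitted distribution's mean equals `mean` exactly.
#'
#' @param family `"beta"`, `"gamma"` or `"degenerate"`.
#' @param mean Base-case value (beta requires `mean` in (0, 1), gamma a
#'   positive mean).
#' @param low,high Range bounds with `low <= mean <= high`. Equal bounds give
#'   a degenerate distribution regardless of `family`.
#' @return An object of class `"param_dist"`: a list with the family, the
#'   moments and the derived shape parameters.
#' @examples
#' d <- fit_distribution("beta", 0.730, 0.584, 0.876)
#' d$sd # 0.0745 (range read as a 95% interval)
#' @export
fit_distribution <- function(family = c("beta", "gamma", "degenerate"),
                             mean, low = mean, high = mean) {
  family <- match.arg(family)
  if (!(is.finite(mean) && is.finite(low) && is.finite(high))) {
    rlang::abort("`mean`, `low` and `high` must be finite.")
  }
  if (low > mean || mean > high) {
    rlang::abort("Need `low <= mean <= high`.")
  }
  sd <- (high - low) / (2 * stats::qnorm(0.975))
  if (sd == 0) family <- "degenerate"
  shape <- switch(family,
    degenerate = list(),
    beta = {
      if (mean <= 0 || mean >= 1) {
        rlang::abort("Beta family requires `mean` strictly inside (0, 1).")
      }
      v <- sd^2
      if (v >= mean * (1 - mean)) {
        rlang::abort(
          "Infeasible beta moments: variance must be below mean * (1 - mean)."
        )
      }
      nu <- mean * (1 - mean) / v - 1
      list(shape1 = mean * nu, shape2 = (1 - mean) * nu)
    },
    gamma = {
      if (mean <= 0) rlang::abort("Gamma family requires a positive mean.")
      list(shape = mean^2 / sd^2, scale = sd^2 / mean)
    }
  )
  structure(
    list(family = family, mean = mean, low = low, high = high, sd = sd,
         shape = shape),
    class = "param_dist"
  )
}

#' Draw samples from a fitted parameter distribution
#'
#' @param dist A `"param_dist"` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Degenerate distributions repeat the
#'   mean.
#' @export
sample_distribution <- function(dist, n) {
  stopifnot(inherits(dist, "param_dist"), n >= 0)
  switch(dist$family,
    degenerate = rep(dist$mean, n),
    beta = stats::rbeta(n, dist$shape$shape1, dist$shape$shape2),
    gamma = stats::rgamma(n, shape = dist$shape$shape, scale = dist$shape$scale)
  )
}

#' @export
print.param_dist <- function(x, ...) {
  cat(sprintf(
    "<param_dist> %s | mean %.6g | range [%.6g, %.6g] | sd %.6g\n",
    x$family, x$mean, x$low, x$high, x$sd
  ))
  invisible(x)
}

#' Model settings for the cohort simulation
#'
#' @param cycle_length Cycle length in months (default 1).
#' @param horizon Number of cycles (default 120, i.e. 10 years of monthly
#'   cycles).
#' @param discount_annual Annual discount rate applied to life-years, QALYs
#'   and costs (default 0.05).
#' @param wtp Willingness-to-pay threshold in USD per QALY (default 34340.50,
#'   three times China's 2021 per-capita GDP).
#' @param counting State-membership counting convention: `"start"` (default;
#'   rewards accrue on the state occupied at the beginning of each cycle),
#'   `"end"`, or `"half"` (half-cycle correction: average of start and end
#'   occupancy).
#' @param ae_disutility_mode How the grade >= 3 adverse-event disutility is
#'   charged: `"per_cycle"` (default; `ae_rate * disutility / 12` per stable
#'   cycle, discounted), `"one_time"` (a single undiscounted lump
#'   `ae_rate * disutility / 12` at model entry) or `"none"`.
#' @param discount_method Passed to [annual_to_cycle_discount()].
#' @return A validated list of class `"model_settings"`.
#' @export
model_settings <- function(cycle_length = 1, horizon = 120,
                           discount_annual = 0.05, wtp = 34340.50,
                           counting = c("start", "end", "half"),
                           ae_disutility_mode = c("per_cycle", "one_time", "none"),
                           discount_method = c("compound", "simple")) {
  counting <- match.arg(counting)
  ae_disutility_mode <- match.arg(ae_disutility_mode)
  discount_method <- match.arg(discount_method)
  problems <- character()
  if (!(is.numeric(cycle_length) && length(cycle_length) == 1 && cycle_length > 0)) {
    problems <- c(problems, "cycle_length: must be a single positive number")
  }
  if (!(is.numeric(horizon) && length(horizon) == 1 && horizon >= 1 &&
        horizon == round(horizon))) {
    problems <- c(problems, "horizon: must be a whole number >= 1")
  }
  if (!(is.numeric(discount_annual) && length(discount_annual) == 1 &&
        discount_annual >= 0)) {
    problems <- c(problems, "discount_annual: must be a single number >= 0")
  }
  if (!(is.numeric(wtp) && length(wtp) == 1 && wtp >= 0)) {
    problems <- c(problems, "wtp: must be a single number >= 0")
  }
  if (length(problems) > 0) {
    rlang::abort(c("Invalid model settings:", problems))
  }
  structure(
    list(
      cycle_length = cycle_length, horizon = as.integer(horizon),
      discount_annual = discount_annual, wtp = wtp, counting = counting,
      ae_disutility_mode = ae_disutility_mode, discount_method = discount_method
    ),
    class = "model_settings"
  )
}

#' @export
print.model_settings <- function(x, ...) {
  cat(sprintf(
    paste0("<model_settings> %d cycles of %g month(s), %.1f%% annual discount",
           " (%s), WTP $%.2f/QALY, counting=%s, AE disutility=%s\n"),
    x$horizon, x$cycle_length, 100 * x$discount_annual, x$discount_method,
    x$wtp, x$counting, x$ae_disutility_mode
  ))
  invisible(x)
}

#' Bundle one treatment strategy's model inputs
#'
#' @param name Strategy label.
#' @param transitions Named list or one-row data frame with per-cycle
#'   probabilities `p_stable_prog`, `p_stable_dead`, `p_prog_dead`.
#' @param utilities Named list with annual utilities `stable`, `progressive`
#'   (both in `[0, 1]`, `progressive <= stable`) and `ae_disutility` (>= 0).
#' @param costs Named list of per-cycle USD cost components: `drug`, `tests`,
#'   `outpatient`, `societal`, `ae` (all accrued while stable) and
#'   `progressive_state` (accrued, together with `societal`, after
#'   progression). All must be >= 0.
#' @param ae_rate Incidence of grade >= 3 adverse events in `[0, 1]`.
#' @param check_ordering Enforce `progressive <= stable` on the utilities
#'   (default `TRUE`). Sensitivity analyses relax this: published
#'   one-way ranges legitimately let the two utilities cross.
#' @return A validated list of class `"strategy_params"`.
#' @export
strategy_params <- function(name, transitions, utilities, costs, ae_rate,
                            check_ordering = TRUE) {
  problems <- character()
  tr <- as.list(transitions)[c("p_stable_prog", "p_stable_dead", "p_prog_dead")]
  if (any(vapply(tr, is.null, logical(1)))) {
    problems <- c(problems,
      "transitions: need p_stable_prog, p_stable_dead and p_prog_dead")
  } else {
    tr <- lapply(tr, as.numeric)
    p <- unlist(tr)
    if (any(p < 0 | p > 1)) {
      problems <- c(problems, "transitions: probabilities must lie in [0, 1]")
    } else if (tr$p_stable_prog + tr$p_stable_dead > 1) {
      problems <- c(problems,
        "transitions: p_stable_prog + p_stable_dead must not exceed 1")
    }
  }
  ut <- as.list(utilities)
  for (f in c("stable", "progressive")) {
    v <- ut[[f]]
    if (is.null(v) || v < 0 || v > 1) {
      problems <- c(problems,
        sprintf("utilities$%s: required, must lie in [0, 1]", f))
    }
  }
  if (is.null(ut$ae_disutility) || ut$ae_disutility < 0) {
    problems <- c(problems, "utilities$ae_disutility: required, must be >= 0")
  }
  if (check_ordering && !is.null(ut$stable) && !is.null(ut$progressive) &&
      isTRUE(ut$progressive > ut$stable)) {
    problems <- c(problems,
      "utilities: progressive-state utility must not exceed stable-state utility")
  }
  co <- as.list(costs)
  for (f in c("drug", "tests", "outpatient", "societal", "ae", "progressive_state")) {
    v <- co[[f]]
    if (is.null(v) || v < 0) {
      problems <- c(problems, sprintf("costs$%s: required, must be >= 0", f))
    }
  }
  if (!(is.numeric(ae_rate) && length(ae_rate) == 1 && ae_rate >= 0 && ae_rate <= 1)) {
    problems <- c(problems, "ae_rate: must be a single probability in [0, 1]")
  }
  if (length(problems) > 0) {
    rlang::abort(c(sprintf("Invalid strategy '%s':", name), problems))
  }
  structure(
    list(name = name, transitions = tr, utilities = ut, costs = co,
         ae_rate = ae_rate),
    class = "strategy_params"
  )
}

#' @export
print.strategy_params <- function(x, ...) {
  cat(sprintf(
    "<strategy_params> %s | transitions (%.4g, %.4g, %.4g) | AE rate %.3f\n",
    x$name, x$transitions$p_stable_prog, x$transitions$p_stable_dead,
    x$transitions$p_prog_dead, x$ae_rate
  ))
  invisible(x)
}
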