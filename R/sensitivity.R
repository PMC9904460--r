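#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full base case twice per parameter - once at its low bound,
#' once at its high bound, everything else held at base - and records the
#' incremental outcome at each bound. Two outcome metrics are carried for
#' every row: net monetary benefit at the configured willingness-to-pay
#' (the recommended tornado metric: it is continuous through the dominance
#' region, whereas the ICER diverges as the QALY difference approaches zero)
#' and the ICER per QALY. Rows are sorted by descending spread of the chosen
#' metric.
#'
#' Bounds that would breach a type invariant (a utility or probability above
#' 1, a negative cost) are clamped to the feasible range with a warning.
#'
#' @param config A [cea_config()].
#' @param parameters Optional character vector of parameter ids (see
#'   [parameter_table()]) to restrict the analysis; default all.
#' @param metric `"nmb"` (default) or `"icer"`: which outcome's spread sorts
#'   the tornado.
#' @return A tibble of class `"cea_owsa"`: one row per parameter with the
#'   bounds, both outcomes at each bound, and `spread`.
#' @examples
#' tornado <- one_way_sensitivity(mrcc_reference())
#' head(tornado, 3)
#' @export
one_way_sensitivity <- function(config, parameters = NULL,
                                metric = c("nmb", "icer")) {
  stopifnot(inherits(config, "cea_config"))
  metric <- match.arg(metric)
  params <- parameter_table(config)
  if (!is.null(parameters)) {
    unknown <- setdiff(parameters, params$parameter)
    if (length(unknown) > 0) {
      rlang::abort(paste0("Unknown parameter(s): ", paste(unknown, collapse = ", ")))
    }
    params <- dplyr::filter(params, .data$parameter %in% parameters)
  }
  base <- glance(run_base_case(config))
  # published one-way ranges may cross the base-case utility ordering
  config$relax_utility_ordering <- TRUE
  eval_at <- function(id, component, value) {
    clamped <- clamp_parameter(component, value, id)
    g <- glance(run_base_case(set_parameter(config, id, clamped)))
    tibble::tibble(value = clamped, nmb = g$nmb_at_wtp, icer = g$icer_per_qaly)
  }
  rows <- purrr::pmap(
    list(params$parameter, params$component, params$low, params$high),
    function(id, component, low, high) {
      at_low <- eval_at(id, component, low)
      at_high <- eval_at(id, component, high)
      tibble::tibble(
        parameter = id,
        low = at_low$value, high = at_high$value,
        nmb_at_low = at_low$nmb, nmb_at_high = at_high$nmb,
        icer_at_low = at_low$icer, icer_at_high = at_high$icer
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  out <- dplyr::left_join(
    out, dplyr::select(params, "parameter", "arm", "component", "base"),
    by = "parameter"
  )
  out$spread <- if (metric == "nmb") {
    abs(out$nmb_at_high - out$nmb_at_low)
  } else {
    abs(out$icer_at_high - out$icer_at_low)
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$spread))
  out <- structure(out, class = c("cea_owsa", class(out)))
  attr(out, "metric") <- metric
  attr(out, "base_nmb") <- base$nmb_at_wtp
  attr(out, "base_icer") <- base$icer_per_qaly
  attr(out, "wtp") <- config$settings$wtp
  out
}

clamp_parameter <- function(component, value, id) {
  bounds <- switch(component,
    transition = c(0, 1),
    utility = c(0, 1),
    cost = c(0, Inf),
    settings = c(0, Inf)
  )
  clamped <- min(max(value, bounds[1]), bounds[2])
  if (clamped != value) {
    rlang::warn(sprintf(
      "Bound %g for parameter '%s' violates its type invariant; clamped to %g.",
      value, id, clamped
    ))
  }
  clamped
}

#' Probabilistic sensitivity analysis
#'
#' Draws every sampled parameter independently from its method-of-moments
#' distribution (beta for probabilities and utilities, gamma for costs; see
#' [fit_distribution()] and [parameter_table()]), re-runs both strategies per
#' draw and records the incremental cost, life-years and QALYs. Draws whose
#' sampled transition probabilities are jointly infeasible (stable-state exit
#' probabilities summing above 1) are
#' rejected and redrawn, preserving the stated marginal distributions;
#' the rejection count is reported. Because the state utilities are sampled
#' independently from their published distributions, individual draws may
#' place the progressive-state utility above the stable-state utility; such
#' draws are kept (the utilities are shared between arms, so the incremental
#' comparison is unaffected). Fully reproducible for a fixed seed.
#'
#' @param config A [cea_config()].
#' @param n Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed; required for reproducibility.
#' @return An object of class `"psa_result"`: list with `draws` (tibble:
#'   `draw`, `delta_cost`, `delta_ly`, `delta_qaly`, `nmb`), `n`, `seed`,
#'   `n_rejected`, `wtp` and the strategy names.
#' @examples
#' psa <- run_psa(mrcc_reference(), n = 50, seed = 1)
#' glance(psa)
#' @export
run_psa <- function(config, n = 1000, seed) {
  stopifnot(inherits(config, "cea_config"), n >= 1)
  if (missing(seed)) rlang::abort("`seed` is required: PSA draws must be reproducible.")
  params <- dplyr::filter(parameter_table(config), .data$in_psa)
  dists <- purrr::pmap(
    list(params$family, params$base, params$low, params$high),
    function(family, base, low, high) {
      if (family == "none" || low == high) {
        fit_distribution("degenerate", base)
      } else {
        fit_distribution(family, base, low, high)
      }
    }
  )
  names(dists) <- params$parameter
  # utilities are sampled independently; their base-case ordering may cross
  config$relax_utility_ordering <- TRUE
  arm_names <- names(config$arms)
  n_rejected <- 0L
  draw_one <- function() {
    repeat {
      values <- vapply(dists, sample_distribution, numeric(1), n = 1)
      cfg <- config
      for (id in names(values)) cfg <- set_parameter(cfg, id, values[[id]])
      feasible <- all(vapply(arm_names, function(a) {
        tr <- cfg$arms[[a]]$transitions
        tr$p_stable_prog + tr$p_stable_dead <= 1
      }, logical(1)))
      if (feasible) return(cfg)
      n_rejected <<- n_rejected + 1L
    }
  }
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      g <- glance(run_base_case(draw_one()))
      tibble::tibble(
        draw = i, delta_cost = g$delta_cost, delta_ly = g$delta_ly,
        delta_qaly = g$delta_qaly, nmb = g$nmb_at_wtp
      )
    })
  })
  if (n_rejected > 0) {
    rlang::inform(sprintf("PSA: %d infeasible draw(s) rejected and resampled.",
                          n_rejected))
  }
  structure(
    list(draws = dplyr::bind_rows(draws), n = as.integer(n),
         seed = as.integer(seed), n_rejected = n_rejected,
         wtp = config$settings$wtp,
         reference = arm_names[1], comparator = arm_names[2]),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf(
    "<psa_result> %s vs %s | %d draws (seed %d, %d rejected)\n",
    x$reference, x$comparator, x$n, x$seed, x$n_rejected
  ))
  cat(sprintf(
    "  P(cost-effective at $%.2f/QALY) = %.3f\n",
    x$wtp, mean(x$draws$nmb > 0)
  ))
  invisible(x)
}

#' Tidy PSA draws
#'
#' `tidy()` returns the per-draw incremental results; `glance()` a one-row
#' summary (means and the probability of cost-effectiveness at the
#' configured threshold).
#'
#' @param x A `"psa_result"`.
#' @param ... Unused.
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' @rdname tidy.psa_result
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, seed = x$seed, n_rejected = x$n_rejected,
    mean_delta_cost = mean(x$draws$delta_cost),
    mean_delta_qaly = mean(x$draws$delta_qaly),
    prob_cost_effective = mean(x$draws$nmb > 0),
    wtp = x$wtp
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda` on the grid, the probability
#' that the reference strategy is cost-effective is the fraction of PSA draws
#' with positive net monetary benefit, `lambda * delta_qaly - delta_cost > 0`.
#'
#' @param psa A `"psa_result"` from [run_psa()].
#' @param wtp_grid Ascending willingness-to-pay values (USD/QALY); default
#'   0 to three times the configured threshold in 100 steps.
#' @return A tibble of class `"cea_ceac"` with `wtp` and
#'   `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  wtp_grid <- wtp_grid %||% seq(0, 3 * psa$wtp, length.out = 100)
  if (length(wtp_grid) == 0 || nrow(psa$draws) == 0) {
    rlang::abort("Need a non-empty WTP grid and at least one PSA draw.")
  }
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    rlang::abort("`wtp_grid` must be strictly ascending.")
  }
  prob <- vapply(wtp_grid, function(lambda) {
    mean(lambda * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
  }, numeric(1))
  out <- tibble::tibble(wtp = wtp_grid, prob_cost_effective = prob)
  structure(out, class = c("cea_ceac", class(out)),
            reference = psa$reference, comparator = psa$comparator)
}
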