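# Shared fixtures: the bundled mRCC reference configuration and the trial
# summary table it was derived from.

ref_config <- function(...) mrcc_reference(model_settings(...))

mrcc_trial_summaries <- function() {
  tibble::tibble(
    arm = c("anlotinib", "sunitinib"),
    median_pfs = c(17.5, 16.6),
    median_os = c(30.9, 30.5),
    ae_grade3_rate = c(0.289, 0.558)
  )
}

# A minimal hand-rolled two-arm configuration for structural tests.
toy_config <- function(settings = model_settings(horizon = 24)) {
  cea_config(
    settings = settings,
    arms = list(
      a = list(
        ae_rate = 0.1,
        transitions = list(p_stable_prog = 0.05, p_stable_dead = 0.02,
                           p_prog_dead = 0.08),
        costs = list(drug = 100, ae = 5)
      ),
      b = list(
        ae_rate = 0.3,
        transitions = list(p_stable_prog = 0.06, p_stable_dead = 0.02,
                           p_prog_dead = 0.07),
        costs = list(drug = 250, ae = 20)
      )
    ),
    shared = list(
      utilities = list(stable = 0.8, progressive = 0.6, ae_disutility = 0.2),
      costs = list(tests = 30, outpatient = 2, societal = 10,
                   progressive_state = 400)
    )
  )
}
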