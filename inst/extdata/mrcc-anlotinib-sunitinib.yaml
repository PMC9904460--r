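# Reference parameter set: first-line anlotinib vs sunitinib in metastatic
# renal cell carcinoma. All costs are per-cycle 2022 USD (exchange rate
# 6.3017 CNY/USD); transition probabilities are per one-month cycle.
settings:
  cycle_length: 1
  horizon: 120
  discount_annual: 0.05
  wtp: 34340.50
strategies:
  anlotinib:
    ae_rate: 0.289
    transitions:
      p_stable_prog: 0.039
      p_stable_dead: 0.022
      p_prog_dead: 0.050
    costs:
      drug: 864.76
      ae: 23.76
  sunitinib:
    ae_rate: 0.558
    transitions:
      p_stable_prog: 0.041
      p_stable_dead: 0.022
      p_prog_dead: 0.049
    costs:
      drug: 1830.48
      ae: 265.44
shared:
  utilities:
    stable: 0.730
    progressive: 0.660
    ae_disutility: 0.157
  costs:
    tests: 248.96
    outpatient: 6.32
    societal: 54.58
    progressive_state: 4535.08
ranges:
  anlotinib.transitions.p_stable_prog: [0.031, 0.047]
  anlotinib.transitions.p_stable_dead: [0.018, 0.026]
  anlotinib.transitions.p_prog_dead: [0.040, 0.061]
  sunitinib.transitions.p_stable_prog: [0.033, 0.049]
  sunitinib.transitions.p_stable_dead: [0.018, 0.026]
  sunitinib.transitions.p_prog_dead: [0.039, 0.059]
  shared.utilities.stable: [0.584, 0.876]
  shared.utilities.progressive: [0.528, 0.792]
  shared.utilities.ae_disutility: [0.126, 0.188]
  anlotinib.costs.drug: [691.81, 1037.71]
  sunitinib.costs.drug: [1464.38, 2196.58]
  shared.costs.societal: [43.66, 65.50]
  shared.costs.tests: [199.17, 298.75]
  shared.costs.outpatient: [5.06, 7.58]
  anlotinib.costs.ae: [19.01, 28.51]
  sunitinib.costs.ae: [212.35, 318.53]
  shared.costs.progressive_state: [3628.06, 5442.10]
  settings.discount_annual: [0.0, 0.08]
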