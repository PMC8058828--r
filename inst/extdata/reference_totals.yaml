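# Published reference totals for the German base-case labeling analysis
# (2017 population, 10-y horizon). Used only by the identity audit; the
# simulation never reads them.
unit_cost: 74.10
total_lesions: 2370715
total_cost_million: 175.67
male_lesions: 1319452
female_lesions: 1051263
dalys: 677.62
productivity_million: 27.33
gdp_per_capita: 40332
dsa:
  low:
    effect_fraction: 0.044
    lesions: 1592392
    cost_million: 118.00
    dalys: 455.15
    productivity_million: 18.36
  high:
    effect_fraction: 0.088
    lesions: 3143636
    cost_million: 232.94
    dalys: 898.55
    productivity_million: 36.24
cost_scenarios:
  copayment_total_million: 280.01
  restoration_failure_total_million: 352.60
implementation_cost_million: [5.29, 9.56]
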