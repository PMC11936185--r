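settings:
  cycle_days: 21.0
  cost_cycle_days: 21.0
  horizon_years: 10.0
  days_per_year: 365.25
  discount_rate: 0.05
  wtp: 39855.790000000000873
  half_cycle: no
  max_treatment_cycles: .inf
  currency: USD
  rmb_per_usd: 7.05
survival:
  tislelizumab:
    os:
      family: loglogistic
      shape: 1.78
      scale: 0.0068
    pfs:
      family: loglogistic
      shape: 1.92
      scale: 0.035
  chemotherapy:
    os:
      family: loglogistic
      shape: 2.37
      scale: 0.0019
    pfs:
      family: loglogistic
      shape: 3.97
      scale: 0.0022
patient:
  body_weight_kg: 60.0
  bsa_m2: 1.72
  gfr_ml_min: 70.0
prices:
  tislelizumab: 1.78
  etoposide: 0.45
  cisplatin: 0.22
  carboplatin: 0.086
regimen:
  induction_cycles: 4.0
  tislelizumab_mg: 200.0
  etoposide_mg_m2: 100.0
  etoposide_days: 3.0
  cisplatin_mg_m2: 75.0
  carboplatin_auc: 5.0
  cisplatin_fraction: 0.5
ae:
  costs:
    anaemia: 531.720000000000027
    leukopenia: 461.25
    neutropenia: 84.209999999999994
    thrombocytopenia: 1054.0
  disutilities:
    anaemia: 0.073
    leukopenia: 0.2
    neutropenia: 0.2
    thrombocytopenia: 0.19
  incidence:
    tislelizumab:
      anaemia: 0.16
      leukopenia: 0.11
      neutropenia: 0.56
      thrombocytopenia: 0.19
    chemotherapy:
      anaemia: 0.17
      leukopenia: 0.1
      neutropenia: 0.55
      thrombocytopenia: 0.25
care:
  followup: 55.600000000000001
  labs: 92.5
  ct: 105.900000000000006
  bsc: 359.519999999999982
subsequent:
  cost: 854.049999999999955
  uptake:
    tislelizumab: 0.6
    chemotherapy: 0.74
utilities:
  pf: 0.67
  pd: 0.47
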