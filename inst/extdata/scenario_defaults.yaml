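# Default occupational exposure scenario configuration shipped with
# nmpglove. Mirrors default_scenario_config() and documents the schema
# accepted by read_scenario_config(). The exposure values are an
# illustrative parameterization (see the package vignette); the liquid
# level (mid_range_solution vs high_end_neat) binds the skin Kp used.
chronic_days: 5
vapor_exposed_area: 3000
respirator_factor: 0.90
tasks:
  miscellaneous_stripping:
    exposure_hours: 8
    exposed_area: 890
    mid_range_solution:
      air_mg_m3: 24
      liquid_mg_cm3: 450
    high_end_neat:
      air_mg_m3: 60
      liquid_mg_cm3: 1030
  graffiti_removal:
    exposure_hours: 6
    exposed_area: 890
    mid_range_solution:
      air_mg_m3: 24
      liquid_mg_cm3: 540
    high_end_neat:
      air_mg_m3: 60
      liquid_mg_cm3: 1030
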