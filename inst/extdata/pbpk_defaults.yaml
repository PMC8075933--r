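# Default human PBPK parameterization for NMP shipped with nmpglove.
# This file mirrors default_pbpk_parameters() and documents the config
# schema accepted by read_pbpk_config(); edit a copy to override values.
# Units: body_mass kg; flows L/h; v_frac fractions of body mass;
# q_frac fractions of cardiac output; partitions unitless; vmax mg/h;
# km mg/L; cl_renal L/h; kp_vapor cm/h.
body_mass: 70
alveolar_ventilation: 300
cardiac_output: 348
v_frac:
  liver: 0.026
  fat: 0.19
  skin: 0.037
  rapid: 0.05
  slow: 0.54
  blood: 0.079
q_frac:
  liver: 0.25
  fat: 0.05
  skin: 0.058
  rapid: 0.44
  slow: 0.202
partition:
  liver: 1.0
  fat: 0.3
  skin: 1.0
  rapid: 1.0
  slow: 0.85
blood_air_partition: 5000
vmax: 420
km: 90
cl_renal: 4.6
kp_vapor: 5
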