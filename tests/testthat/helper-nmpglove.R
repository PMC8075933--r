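# Shared test helpers.

# A small, well-conditioned parameter set for fast PBPK tests.
test_params <- function(...) {
  p <- default_pbpk_parameters()
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  validate_fun <- getFromNamespace("validate_pbpk_parameters", "nmpglove")
  validate_fun(p)
}

# Dermal-liquid-only exposure, constant contact over [0, hours].
dermal_exposure <- function(kp, hours = 8, area = 1000, conc = 1) {
  exposure_input(
    liquid_schedule = schedule(0, hours, 1),
    liquid_concentration = conc,
    exposed_area = area,
    kp_dermal_liquid = kp
  )
}

# Independent closed-form oracle for the steady-state venous blood
# concentration under a constant dermal uptake rate J (mg/h), derived by
# setting every compartment balance of the flow-limited system to zero:
#   liver:  Ql (CA - CVl) = CLh CVl        => CVl = Ql CA / (Ql + CLh)
#   skin:   Qs (CA - CVs) + J = 0          => CVs = CA + J/Qs
#   other tissues: CVi = CA
#   lung:   CA = QC CV / (QC + QP/PB)
#   blood:  sum Qi CVi = (QC + CLr) CV
# with CLh the linearized hepatic clearance vmax/km.
steady_state_blood_oracle <- function(params, J) {
  qc <- params$cardiac_output
  qp <- params$alveolar_ventilation
  ql <- params$q_frac[["liver"]] * qc
  clh <- params$vmax / params$km
  a <- qc / (qc + qp / params$blood_air_partition)
  denom <- qc + params$cl_renal - a * (qc - ql + ql^2 / (ql + clh))
  J / denom
}

# Build a minimal permeation dataset in memory.
make_records <- function(rates, concs, hints = NULL) {
  df <- data.frame(
    material = paste0("m", seq_along(rates)),
    brand = paste0("b", seq_along(rates)),
    test_material = "t",
    permeation_rate = as.character(rates),
    nmp_concentration_mg_per_cm3 = concs,
    source = "test",
    stringsAsFactors = FALSE
  )
  if (!is.null(hints)) df$category_hint <- hints
  permeation_records(df)
}
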