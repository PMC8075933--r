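test_that("parameter validation enforces physiological consistency", {
  expect_s3_class(default_pbpk_parameters(), "pbpk_parameters")
  p <- default_pbpk_parameters()
  p$q_frac[["liver"]] <- 0.5  # flows no longer sum to 1
  expect_error(pbpk_simulate(p, dermal_exposure(0.001), 1), "sum to 1")
  p2 <- default_pbpk_parameters()
  p2$v_frac[["slow"]] <- 0.9  # volumes exceed body mass
  expect_error(pbpk_simulate(p2, dermal_exposure(0.001), 1), "more than 1")
})

test_that("config files override defaults key by key", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("vmax: 100", "partition:", "  fat: 0.5"), tmp)
  p <- read_pbpk_config(tmp)
  expect_equal(p$vmax, 100)
  expect_equal(p$partition[["fat"]], 0.5)
  expect_equal(p$km, default_pbpk_parameters()$km)  # untouched key
  expect_error(read_pbpk_config("no/such/file.yaml"), "not found")
})

test_that("schedules are validated and repeat across days", {
  expect_error(schedule(0, 0, 1), "end > start")
  expect_error(schedule(c(0, 4), c(5, 8), c(1, 1)), "overlap")
  s <- repeat_daily(schedule(0, 8, 2), 3)
  expect_equal(nrow(s), 3)
  expect_equal(s$start, c(0, 24, 48))
  expect_equal(s$end, c(8, 32, 56))
})

test_that("dermal liquid flux is Fick's law with exact unit bookkeeping", {
  expect_equal(dermal_liquid_flux(0.000478, 1000, 0.515),
               0.000478 * 1000 * 0.515)
  expect_identical(dermal_liquid_flux(0, 1000, 0.5), 0)
  expect_equal(dermal_liquid_flux(0.001, 2000, 0.5),
               2 * dermal_liquid_flux(0.001, 1000, 0.5))
  expect_error(dermal_liquid_flux(-1, 1, 1), "non-negative")
})

test_that("zero exposure yields zero concentrations and doses", {
  sim <- pbpk_simulate(default_pbpk_parameters(), exposure_input(), 24)
  expect_equal(max(abs(sim$c_blood)), 0)
  expect_equal(cmax(sim), 0)
  expect_equal(auc(sim), 0)
  expect_equal(sim$mass_balance$absorbed_total, 0)
})

test_that("mass balance closes within 0.1% for aggregate exposure", {
  exp_in <- exposure_input(
    air_schedule = schedule(0, 8, 50),
    liquid_schedule = schedule(0, 8, 1),
    liquid_concentration = 1030, exposed_area = 890,
    kp_dermal_liquid = 0.00205, vapor_exposed_area = 3000,
    respirator = TRUE)
  sim <- pbpk_simulate(default_pbpk_parameters(), exp_in, 24)
  mb <- sim$mass_balance
  expect_lt(abs(mb$relative_closure_error), 1e-3)
  expect_equal(mb$absorbed_total,
               mb$absorbed_inhaled + mb$absorbed_dermal_liquid +
                 mb$absorbed_dermal_vapor)
  expect_true(all(unlist(mb[1:8]) >= 0))
})

test_that("steady-state blood concentration matches the closed-form oracle", {
  # pure first-order renal clearance: C_ss = J / CLr exactly
  p <- test_params(vmax = 0, blood_air_partition = 1e9, cl_renal = 5)
  J <- dermal_liquid_flux(0.001, 890, 200)
  sim <- pbpk_simulate(p, dermal_exposure(0.001, hours = 600,
                                          area = 890, conc = 200), 600)
  expect_equal(tail(sim$c_blood, 1), J / 5, tolerance = 1e-5)
  # full closed form with linearized hepatic metabolism and exhalation
  p2 <- linearize_metabolism(test_params())
  sim2 <- pbpk_simulate(p2, dermal_exposure(0.001, hours = 600,
                                            area = 890, conc = 200), 600)
  expect_equal(tail(sim2$c_blood, 1), steady_state_blood_oracle(p2, J),
               tolerance = 1e-5)
})

test_that("internal doses scale proportionally with dermal Kp in the linear limit", {
  p <- linearize_metabolism(default_pbpk_parameters())
  kp <- 0.002
  sim1 <- pbpk_simulate(p, dermal_exposure(kp), 24)
  sim2 <- pbpk_simulate(p, dermal_exposure(kp / 2), 24)
  expect_equal(sim2$auc / sim1$auc, 0.5, tolerance = 1e-6)
  expect_equal(sim2$cmax / sim1$cmax, 0.5, tolerance = 1e-6)
})

test_that("doses increase monotonically in Kp, air concentration and duration", {
  p <- default_pbpk_parameters()
  kps <- c(5e-5, 5e-4, 2e-3)
  sims <- lapply(kps, function(k) pbpk_simulate(p, dermal_exposure(k), 24))
  expect_true(all(diff(vapply(sims, cmax, 0)) > 0))
  expect_true(all(diff(vapply(sims, auc, 0)) > 0))
  airs <- c(10, 50, 250)
  asims <- lapply(airs, function(a) {
    pbpk_simulate(p, exposure_input(air_schedule = schedule(0, 8, a)), 24)
  })
  expect_true(all(diff(vapply(asims, cmax, 0)) > 0))
  expect_true(all(diff(vapply(asims, auc, 0)) > 0))
  hrs <- c(2, 4, 8)
  hsims <- lapply(hrs, function(h) {
    pbpk_simulate(p, dermal_exposure(0.002, hours = h), 24)
  })
  expect_true(all(diff(vapply(hsims, cmax, 0)) > 0))
  expect_true(all(diff(vapply(hsims, auc, 0)) > 0))
})

test_that("saturable metabolism makes AUC grow superlinearly in uptake", {
  # at uptake rates driving blood NMP near and above Km, doubling the
  # dermal Kp more than doubles the AUC
  p <- default_pbpk_parameters()
  lo <- pbpk_simulate(p, dermal_exposure(0.001, area = 890, conc = 1030), 24)
  hi <- pbpk_simulate(p, dermal_exposure(0.002, area = 890, conc = 1030), 24)
  expect_gt(hi$auc / lo$auc, 2)
})

test_that("respirator reduces inhaled uptake only, never dermal-vapor uptake", {
  base <- exposure_input(air_schedule = schedule(0, 8, 100),
                         vapor_exposed_area = 3000)
  resp <- exposure_input(air_schedule = schedule(0, 8, 100),
                         vapor_exposed_area = 3000, respirator = TRUE)
  p <- default_pbpk_parameters()
  s1 <- pbpk_simulate(p, base, 10)
  s2 <- pbpk_simulate(p, resp, 10)
  expect_equal(s2$mass_balance$absorbed_inhaled,
               0.1 * s1$mass_balance$absorbed_inhaled, tolerance = 1e-6)
  expect_equal(s2$mass_balance$absorbed_dermal_vapor,
               s1$mass_balance$absorbed_dermal_vapor, tolerance = 1e-9)
})

test_that("Cmax and AUC metrics behave on synthetic concentration series", {
  # constant concentration c over T hours: AUC = c*T
  flat <- structure(list(time = seq(0, 10, 0.5), c_blood = rep(2, 21),
                         cmax = 2, auc = 20), class = "pbpk_result")
  expect_equal(auc(flat), 20)
  expect_equal(auc(flat, c(2, 7)), 10)
  # additivity over adjacent windows
  expect_equal(auc(flat, c(0, 4)) + auc(flat, c(4, 10)), auc(flat, c(0, 10)))
  # triangular pulse: Cmax is the apex
  tri <- structure(list(time = 0:4, c_blood = c(0, 1, 3, 1, 0),
                        cmax = 3, auc = 5), class = "pbpk_result")
  expect_equal(cmax(tri), 3)
  expect_error(auc(flat, c(5, 20)), "outside the simulated span")
  expect_error(auc(flat, c(7, 2)), "t0 < t1")
})
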