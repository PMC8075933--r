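#' Default human PBPK parameterization for NMP
#'
#' A flow-limited, perfusion-based PBPK model with compartments for liver,
#' fat, skin, rapidly perfused and slowly perfused tissue plus venous
#' blood, saturable hepatic metabolism, a first-order renal/urinary
#' clearance of parent NMP, and pulmonary exchange through the blood:air
#' partition coefficient. This is the standard structure of published NMP
#' PBPK models. The numeric values here are a documented illustrative
#' human parameterization ("USEPA-like, not USEPA-exact"): physiological
#' values are standard reference-human values, partition coefficients
#' reflect NMP's high water solubility and low lipophilicity, and the
#' metabolic/clearance constants are round-number values of plausible
#' magnitude. Every value can be overridden via [read_pbpk_config()] or by
#' editing the returned list.
#'
#' Units: body mass kg; flows L/h; volumes as fraction of body mass
#' (tissue density taken as 1 kg/L); partition coefficients unitless;
#' `vmax` mg/h; `km` mg/L; `cl_renal` L/h; `kp_vapor` cm/h.
#'
#' @return list of class `pbpk_parameters`.
#' @export
default_pbpk_parameters <- function() {
  p <- list(
    body_mass = 70,              # kg
    alveolar_ventilation = 300,  # L/h
    cardiac_output = 348,        # L/h (blood)
    # fractional tissue volumes (of body mass); sum 0.922 <= 1
    v_frac = c(liver = 0.026, fat = 0.19, skin = 0.037,
               rapid = 0.05, slow = 0.54, blood = 0.079),
    # fractional blood flows (of cardiac output); sum exactly 1
    q_frac = c(liver = 0.25, fat = 0.05, skin = 0.058,
               rapid = 0.44, slow = 0.202),
    # tissue:blood partition coefficients (NMP: water-soluble, low log Kow)
    partition = c(liver = 1.0, fat = 0.3, skin = 1.0,
                  rapid = 1.0, slow = 0.85),
    blood_air_partition = 5000,  # NMP is of low volatility
    vmax = 420,                  # mg/h, saturable hepatic metabolism
    km = 90,                     # mg/L
    cl_renal = 4.6,              # L/h, first-order parent clearance
    kp_vapor = 5                 # cm/h, skin permeability to NMP vapor
  )
  class(p) <- "pbpk_parameters"
  validate_pbpk_parameters(p)
}

validate_pbpk_parameters <- function(p) {
  comps <- c("liver", "fat", "skin", "rapid", "slow")
  stopifnot(setequal(names(p$q_frac), comps),
            setequal(names(p$partition), comps),
            setequal(names(p$v_frac), c(comps, "blood")))
  scalars <- c(p$body_mass, p$alveolar_ventilation, p$cardiac_output,
               p$blood_air_partition)
  if (any(scalars <= 0)) stop("physiological scalars must be > 0", call. = FALSE)
  if (any(c(p$vmax, p$km, p$cl_renal, p$kp_vapor) < 0) || p$km == 0) {
    stop("vmax, cl_renal, kp_vapor must be >= 0 and km > 0", call. = FALSE)
  }
  if (any(p$v_frac <= 0) || any(p$q_frac <= 0) || any(p$partition <= 0)) {
    stop("volumes, flows and partitions must be > 0", call. = FALSE)
  }
  if (sum(p$v_frac) > 1) {
    stop("fractional tissue volumes sum to more than 1", call. = FALSE)
  }
  if (abs(sum(p$q_frac) - 1) > 1e-6) {
    stop("fractional blood flows must sum to 1 (within 1e-6)", call. = FALSE)
  }
  p
}

#' Read (and merge) a PBPK parameter configuration
#'
#' Reads a YAML or JSON file whose keys mirror
#' [default_pbpk_parameters()]; any key absent from the file keeps its
#' default value.
#'
#' @param path path to a YAML/JSON config file, or `NULL` for defaults.
#' @return list of class `pbpk_parameters`.
#' @export
read_pbpk_config <- function(path = NULL) {
  p <- unclass(default_pbpk_parameters())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    over <- yaml::read_yaml(path)
    for (nm in c("v_frac", "q_frac", "partition")) {
      if (!is.null(over[[nm]])) over[[nm]] <- unlist(over[[nm]])
    }
    for (nm in names(over)) {
      if (nm %in% c("v_frac", "q_frac", "partition")) {
        merged <- p[[nm]]
        merged[names(over[[nm]])] <- over[[nm]]
        p[[nm]] <- merged
      } else p[[nm]] <- over[[nm]]
    }
  }
  class(p) <- "pbpk_parameters"
  validate_pbpk_parameters(p)
}

#' Linearize the metabolic terms of a parameter set
#'
#' Returns a parameter set whose hepatic metabolism is first-order with
#' the same low-concentration intrinsic clearance (`vmax/km` held fixed
#' while `km` is pushed far above any attainable blood concentration).
#' Used for linear-limit analyses in which internal doses must scale
#' proportionally with uptake.
#'
#' @param params a `pbpk_parameters` list.
#' @param factor multiplier applied to both `vmax` and `km` (default 1e6).
#' @return modified `pbpk_parameters` list.
#' @export
linearize_metabolism <- function(params, factor = 1e6) {
  params$vmax <- params$vmax * factor
  params$km <- params$km * factor
  params
}

#' Build a piecewise-constant schedule
#'
#' @param start,end interval bounds, h.
#' @param value value on each interval (concentration, or 1/0 for contact).
#' @return data.frame of class `schedule`; intervals must not overlap.
#' @export
schedule <- function(start, end, value) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end),
                   value = as.numeric(value))
  if (nrow(df)) {
    if (any(df$end <= df$start)) stop("schedule intervals must have end > start",
                                      call. = FALSE)
    if (any(df$value < 0)) stop("schedule values must be >= 0", call. = FALSE)
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)] - 1e-12)) {
      stop("schedule intervals must not overlap", call. = FALSE)
    }
  }
  class(df) <- c("schedule", "data.frame")
  df
}

schedule_value <- function(sched, t) {
  if (is.null(sched) || nrow(sched) == 0) return(0)
  hit <- sched$start <= t + 1e-12 & t < sched$end - 1e-12
  if (any(hit)) sched$value[which(hit)[1]] else 0
}

#' Repeat a daily schedule over several days
#'
#' @param sched a [schedule()] defined over one 24-h day.
#' @param n_days number of consecutive days.
#' @return a [schedule()] spanning `n_days * 24` h.
#' @export
repeat_daily <- function(sched, n_days) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  pieces <- lapply(seq_len(n_days) - 1L, function(d) {
    data.frame(start = sched$start + 24 * d, end = sched$end + 24 * d,
               value = sched$value)
  })
  out <- do.call(rbind, pieces)
  schedule(out$start, out$end, out$value)
}

#' Exposure input for a PBPK simulation
#'
#' @param air_schedule [schedule()] of air NMP concentration, mg/m3.
#' @param liquid_schedule [schedule()] of dermal liquid contact (1 = on).
#' @param liquid_concentration NMP concentration in the liquid phase on
#'   skin/glove, mg/cm3 (assumed constant while contact is on).
#' @param exposed_area skin area in liquid contact, cm2.
#' @param kp_dermal_liquid dermal-liquid permeability coefficient, cm/h
#'   (skin Kp, or gloved-skin net Kp).
#' @param vapor_exposed_area skin area exposed to vapor, cm2.
#' @param respirator logical; if `TRUE` the inhaled concentration is
#'   reduced by `respirator_factor`. Dermal-vapor uptake always sees the
#'   unreduced air concentration (skin is not covered by a respirator).
#' @param respirator_factor fraction of inhaled concentration removed
#'   (default 0.90).
#' @return list of class `exposure_input`.
#' @export
exposure_input <- function(air_schedule = schedule(numeric(0), numeric(0), numeric(0)),
                           liquid_schedule = schedule(numeric(0), numeric(0), numeric(0)),
                           liquid_concentration = 0,
                           exposed_area = 0,
                           kp_dermal_liquid = 0,
                           vapor_exposed_area = 0,
                           respirator = FALSE,
                           respirator_factor = 0.90) {
  stop_if_negative(c(liquid_concentration, exposed_area, kp_dermal_liquid,
                     vapor_exposed_area), "exposure quantities")
  if (respirator_factor < 0 || respirator_factor > 1) {
    stop("respirator_factor must be in [0, 1]", call. = FALSE)
  }
  structure(list(air_schedule = air_schedule,
                 liquid_schedule = liquid_schedule,
                 liquid_concentration = liquid_concentration,
                 exposed_area = exposed_area,
                 kp_dermal_liquid = kp_dermal_liquid,
                 vapor_exposed_area = vapor_exposed_area,
                 respirator = isTRUE(respirator),
                 respirator_factor = respirator_factor),
            class = "exposure_input")
}

#' Dermal uptake rate from liquid contact
#'
#' Fick's-law steady flux through the (possibly gloved) skin barrier:
#' `kp (cm/h) x area (cm2) x concentration (mg/cm3)` gives mg/h directly.
#' The donor concentration is treated as constant and inexhaustible while
#' contact is on, and the flux is zero while contact is off.
#'
#' @param kp permeability coefficient, cm/h.
#' @param area exposed area, cm2.
#' @param concentration liquid NMP concentration, mg/cm3.
#' @return uptake rate, mg/h.
#' @export
dermal_liquid_flux <- function(kp, area, concentration) {
  stop_if_negative(c(kp, area, concentration), "flux inputs")
  kp * area * concentration
}

# Dermal uptake rate from vapor: kp (cm/h) x area (cm2) x C_air (mg/m3)
# x 1e-6 m3/cm3 -> mg/h.
dermal_vapor_flux <- function(kp_vapor, area, air_concentration) {
  kp_vapor * area * air_concentration * 1e-6
}

# Right-hand side of the PBPK ODE system. State (all mg), by position:
#  1 A_liver, 2 A_fat, 3 A_skin, 4 A_rapid, 5 A_slow, 6 A_blood (venous),
#  cumulative: 7 inhaled, 8 dermal_liquid, 9 dermal_vapor, 10 exhaled,
#  11 metabolized, 12 cleared.
# parms is a flat list precomputed by pbpk_simulate(): Vt/Qt/Pt are
# 5-vectors ordered liver, fat, skin, rapid, slow.
pbpk_rhs <- function(t, state, parms) {
  cv <- state[6] / parms$v_blood
  cvt <- state[1:5] / parms$Vt / parms$Pt  # tissue venous concentrations
  ci_l <- parms$ci_inhaled * 1e-3          # mg/m3 -> mg/L
  ca <- (parms$qc * cv + parms$qp * ci_l) / (parms$qc + parms$qp / parms$pb)
  cx <- ca / parms$pb
  ram <- parms$vmax * cvt[1] / (parms$km + cvt[1])
  dA <- parms$Qt * (ca - cvt)
  dA[1] <- dA[1] - ram
  dA[3] <- dA[3] + parms$j_liq + parms$j_vap
  d_blood <- sum(parms$Qt * cvt) - parms$qc * cv - parms$cl_renal * cv
  list(c(dA, d_blood,
         parms$qp * ci_l, parms$j_liq, parms$j_vap,
         parms$qp * cx, ram, parms$cl_renal * cv),
       c(c_blood = unname(cv)))
}

#' Simulate blood NMP concentration for an exposure
#'
#' Integrates the flow-limited PBPK system over `duration` hours with a
#' stiff-capable implicit solver (`deSolve::lsoda`), restarting the
#' integration at every exposure-schedule discontinuity so that
#' piecewise-constant inputs are handled exactly.
#'
#' @param params a `pbpk_parameters` list.
#' @param exposure an [exposure_input()].
#' @param duration simulated time, h (> 0).
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-10).
#' @param dt_out output grid spacing, h (default 0.05).
#' @return list of class `pbpk_result` with `time` (h), `c_blood` (mg/L),
#'   `cmax` (mg/L), `auc` (mg.h/L over the full span), a `mass_balance`
#'   ledger (mg: absorbed by route, exhaled, metabolized, cleared,
#'   in_body, relative closure error) and the raw state matrix.
#' @export
pbpk_simulate <- function(params, exposure, duration,
                          rtol = 1e-8, atol = 1e-10, dt_out = 0.05) {
  params <- validate_pbpk_parameters(params)
  stopifnot(inherits(exposure, "exposure_input"))
  stop_if_not_positive(duration, "duration")

  V <- params$v_frac * params$body_mass  # L (density 1)
  Q <- params$q_frac * params$cardiac_output

  breaks <- sort(unique(c(0, duration,
                          exposure$air_schedule$start, exposure$air_schedule$end,
                          exposure$liquid_schedule$start, exposure$liquid_schedule$end)))
  breaks <- breaks[breaks >= 0 & breaks <= duration]
  if (breaks[length(breaks)] < duration) breaks <- c(breaks, duration)

  state <- c(A_liver = 0, A_fat = 0, A_skin = 0, A_rapid = 0, A_slow = 0,
             A_blood = 0, inhaled = 0, dermal_liquid = 0, dermal_vapor = 0,
             exhaled = 0, metabolized = 0, cleared = 0)
  rows <- list()
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    tmid <- (t0 + t1) / 2
    ci_air <- schedule_value(exposure$air_schedule, tmid)
    ci_inhaled <- if (exposure$respirator) {
      ci_air * (1 - exposure$respirator_factor)
    } else ci_air
    contact <- schedule_value(exposure$liquid_schedule, tmid)
    j_liq <- if (contact > 0) {
      dermal_liquid_flux(exposure$kp_dermal_liquid, exposure$exposed_area,
                         exposure$liquid_concentration) * contact
    } else 0
    comps <- c("liver", "fat", "skin", "rapid", "slow")
    parms <- list(
      Vt = unname(V[comps]), Qt = unname(Q[comps]),
      Pt = unname(params$partition[comps]),
      v_blood = unname(V[["blood"]]),
      qp = params$alveolar_ventilation, qc = params$cardiac_output,
      pb = params$blood_air_partition,
      vmax = params$vmax, km = params$km, cl_renal = params$cl_renal,
      ci_inhaled = ci_inhaled, j_liq = j_liq,
      j_vap = dermal_vapor_flux(params$kp_vapor,
                                exposure$vapor_exposed_area, ci_air))
    times <- unique(c(seq(t0, t1, by = dt_out), t1))
    sol <- deSolve::lsoda(y = state, times = times, func = pbpk_rhs,
                          parms = parms, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE integration failed on interval [", t0, ", ", t1, "] h",
           call. = FALSE)
    }
    state <- sol[nrow(sol), names(state)]
    rows[[i]] <- if (i == 1) sol else sol[-1, , drop = FALSE]
  }
  out <- do.call(rbind, rows)

  amounts <- out[, c("A_liver", "A_fat", "A_skin", "A_rapid", "A_slow",
                     "A_blood")]
  if (min(amounts) < -1e-6) {
    stop("negative compartment amount detected (min ",
         format(min(amounts)), " mg): integration unreliable", call. = FALSE)
  }
  c_blood <- pmax(out[, "c_blood"], 0)
  tgrid <- out[, "time"]

  final <- out[nrow(out), ]
  absorbed <- final[["inhaled"]] + final[["dermal_liquid"]] +
    final[["dermal_vapor"]]
  in_body <- sum(final[c("A_liver", "A_fat", "A_skin", "A_rapid", "A_slow",
                         "A_blood")])
  eliminated <- final[["exhaled"]] + final[["metabolized"]] + final[["cleared"]]
  closure <- if (absorbed > 0) (absorbed - in_body - eliminated) / absorbed else 0

  res <- structure(list(
    time = tgrid,
    c_blood = c_blood,
    cmax = max(c_blood),
    auc = trapz(tgrid, c_blood),
    mass_balance = list(
      absorbed_inhaled = final[["inhaled"]],
      absorbed_dermal_liquid = final[["dermal_liquid"]],
      absorbed_dermal_vapor = final[["dermal_vapor"]],
      absorbed_total = absorbed,
      exhaled = final[["exhaled"]],
      metabolized = final[["metabolized"]],
      cleared = final[["cleared"]],
      in_body = in_body,
      relative_closure_error = closure
    ),
    states = out
  ), class = "pbpk_result")
  res
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Peak blood concentration of a simulation
#'
#' @param result a `pbpk_result`.
#' @return Cmax, mg/L (global maximum over the simulated span).
#' @export
cmax <- function(result) {
  stopifnot(inherits(result, "pbpk_result"))
  result$cmax
}

#' Area under the blood concentration curve over a window
#'
#' Trapezoidal integration on the solver output grid.
#'
#' @param result a `pbpk_result`.
#' @param window `c(t0, t1)` in h; default the full simulated span.
#' @return AUC, mg.h/L.
#' @export
auc <- function(result, window = NULL) {
  stopifnot(inherits(result, "pbpk_result"))
  tg <- result$time
  if (is.null(window)) return(result$auc)
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("window must be c(t0, t1) with t0 < t1", call. = FALSE)
  }
  if (window[1] < min(tg) - 1e-9 || window[2] > max(tg) + 1e-9) {
    stop("requested AUC window [", window[1], ", ", window[2],
         "] h lies outside the simulated span", call. = FALSE)
  }
  cb <- result$c_blood
  # interpolate endpoints onto the grid
  keep <- tg > window[1] & tg < window[2]
  xs <- c(window[1], tg[keep], window[2])
  ys <- c(stats::approx(tg, cb, xout = window[1])$y, cb[keep],
          stats::approx(tg, cb, xout = window[2])$y)
  trapz(xs, ys)
}

#' @export
print.pbpk_result <- function(x, ...) {
  cat(sprintf("PBPK simulation: %.1f h, Cmax %.4g mg/L, AUC %.4g mg.h/L\n",
              max(x$time), x$cmax, x$auc))
  cat(sprintf("  mass balance closure: %.3g%%\n",
              100 * abs(x$mass_balance$relative_closure_error)))
  invisible(x)
}

#' Write a simulated concentration time series to delimited text
#'
#' @param result a `pbpk_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  utils::write.table(
    data.frame(time_h = result$time, c_blood_mg_per_L = result$c_blood),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
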