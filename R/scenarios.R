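#' Default occupational exposure scenario configuration
#'
#' Exposure parameters for the eight occupational paint-stripping
#' scenarios assessed here: two tasks (miscellaneous stripping, graffiti
#' removal) at two liquid-exposure levels (mid-range NMP solution,
#' high-end neat NMP), each with and without a respirator. The liquid
#' level binds the skin permeability coefficient (0.000478 cm/h for
#' solutions, 0.00205 cm/h for neat NMP).
#'
#' The numeric values (air concentrations, liquid concentrations, exposed
#' areas, task durations) are an illustrative parameterization chosen so
#' that the no-glove margins of exposure fall in the bands reported for
#' these scenarios (acute roughly 0.7-14, chronic roughly 0.1-6.1); they
#' are not asserted to equal any regulatory assessment's values, which
#' are not public in primary-literature form. All values are
#' config-overridable via [read_scenario_config()].
#'
#' @return list of class `scenario_config`.
#' @export
default_scenario_config <- function() {
  cfg <- list(
    chronic_days = 5,           # consecutive workdays simulated
    vapor_exposed_area = 3000,  # cm2 of uncovered skin (head, forearms)
    respirator_factor = 0.90,
    tasks = list(
      miscellaneous_stripping = list(
        exposure_hours = 8,
        exposed_area = 890,     # cm2, both hands
        mid_range_solution = list(air_mg_m3 = 24, liquid_mg_cm3 = 450),
        high_end_neat = list(air_mg_m3 = 60, liquid_mg_cm3 = 1030)
      ),
      graffiti_removal = list(
        exposure_hours = 6,
        exposed_area = 890,     # cm2, both hands
        mid_range_solution = list(air_mg_m3 = 24, liquid_mg_cm3 = 540),
        high_end_neat = list(air_mg_m3 = 60, liquid_mg_cm3 = 1030)
      )
    )
  )
  class(cfg) <- "scenario_config"
  cfg
}

#' Read (and merge) a scenario configuration
#'
#' @param path YAML/JSON file mirroring [default_scenario_config()] keys,
#'   or `NULL` for the defaults.
#' @return list of class `scenario_config`.
#' @export
read_scenario_config <- function(path = NULL) {
  cfg <- unclass(default_scenario_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  class(cfg) <- "scenario_config"
  cfg
}

#' Build the eight base exposure scenarios
#'
#' Expands the configuration into 2 tasks x 2 liquid levels x 2
#' respirator states = 8 scenario specifications, each later expandable
#' over glove options.
#'
#' @param config a `scenario_config` (default [default_scenario_config()]).
#' @return list of `scenario_spec` objects.
#' @export
build_scenarios <- function(config = default_scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  specs <- list()
  for (task in c("miscellaneous_stripping", "graffiti_removal")) {
    tcfg <- config$tasks[[task]]
    if (is.null(tcfg)) stop("missing config key: tasks$", task, call. = FALSE)
    for (key in c("exposure_hours", "exposed_area")) {
      if (is.null(tcfg[[key]])) {
        stop("missing config key: tasks$", task, "$", key, call. = FALSE)
      }
    }
    for (level in c("mid_range_solution", "high_end_neat")) {
      lcfg <- tcfg[[level]]
      if (is.null(lcfg)) {
        stop("missing config key: tasks$", task, "$", level, call. = FALSE)
      }
      for (key in c("air_mg_m3", "liquid_mg_cm3")) {
        if (is.null(lcfg[[key]])) {
          stop("missing config key: tasks$", task, "$", level, "$", key,
               call. = FALSE)
        }
      }
      for (resp in c(FALSE, TRUE)) {
        specs[[length(specs) + 1L]] <- structure(list(
          task = task,
          level = level,
          respirator = resp,
          respirator_factor = config$respirator_factor,
          kp_skin = if (level == "high_end_neat") {
            kp_skin_defaults[["neat"]]
          } else kp_skin_defaults[["solution"]],
          air_mg_m3 = lcfg$air_mg_m3,
          liquid_mg_cm3 = lcfg$liquid_mg_cm3,
          exposed_area = tcfg$exposed_area,
          vapor_exposed_area = config$vapor_exposed_area,
          exposure_hours = tcfg$exposure_hours,
          chronic_days = config$chronic_days
        ), class = "scenario_spec")
      }
    }
  }
  specs
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario: %s / %s / respirator %s\n", x$task, x$level,
              if (x$respirator) "on" else "off"))
  cat(sprintf("  air %g mg/m3, liquid %g mg/cm3, area %g cm2, %g h/day, Kp_skin %g cm/h\n",
              x$air_mg_m3, x$liquid_mg_cm3, x$exposed_area,
              x$exposure_hours, x$kp_skin))
  invisible(x)
}

scenario_exposure <- function(spec, kp_dermal, n_days, dermal_only = FALSE) {
  day_air <- schedule(0, spec$exposure_hours,
                      if (dermal_only) 0 else spec$air_mg_m3)
  day_liq <- schedule(0, spec$exposure_hours, 1)
  exposure_input(
    air_schedule = repeat_daily(day_air, n_days),
    liquid_schedule = repeat_daily(day_liq, n_days),
    liquid_concentration = spec$liquid_mg_cm3,
    exposed_area = spec$exposed_area,
    kp_dermal_liquid = kp_dermal,
    vapor_exposed_area = if (dermal_only) 0 else spec$vapor_exposed_area,
    respirator = spec$respirator,
    respirator_factor = spec$respirator_factor
  )
}

run_one <- function(spec, kp_dermal, params, horizon, dermal_only, ...) {
  if (horizon == "acute") {
    exp_in <- scenario_exposure(spec, kp_dermal, 1, dermal_only)
    sim <- pbpk_simulate(params, exp_in, duration = 24, ...)
    list(cmax = cmax(sim), auc = auc(sim))
  } else {
    n <- spec$chronic_days
    exp_in <- scenario_exposure(spec, kp_dermal, n, dermal_only)
    sim <- pbpk_simulate(params, exp_in, duration = 24 * n, ...)
    window <- c(24 * (n - 1), 24 * n)  # steady-periodic last day
    list(cmax = cmax(sim), auc = auc(sim, window))
  }
}

#' Run one scenario under a glove option
#'
#' Runs the full-route simulation (inhalation + dermal vapor + dermal
#' liquid) and a dermal-liquid-only simulation (used to isolate glove
#' protection factors). With a glove category summary, the dermal-liquid
#' permeability takes the category's mean, minimum and maximum gloved-skin
#' net Kp in turn, propagating the category range into a result range.
#' Acute results are single-day simulations (Cmax is the relevant
#' metric); chronic results repeat the daily schedule and report the AUC
#' of the final, steady-periodic 24-h day.
#'
#' @param spec a `scenario_spec` from [build_scenarios()].
#' @param glove `NULL` (no glove), a `category_kp_summary` (its net Kp
#'   values are used directly), or a single numeric gloved-skin net Kp in
#'   cm/h.
#' @param params a `pbpk_parameters` list.
#' @param horizon `"acute"`, `"chronic"` or `"both"`.
#' @param ... passed to [pbpk_simulate()] (solver options).
#' @return data.frame of class `scenario_result`: one row per
#'   (horizon, kp level) with columns `task`, `level`, `respirator`,
#'   `glove`, `horizon`, `kp_level` (mean/min/max/none), `kp_dermal`,
#'   `cmax`, `auc`, `dermal_only_cmax`, `dermal_only_auc`.
#' @export
run_scenario <- function(spec, glove = NULL, params = default_pbpk_parameters(),
                         horizon = c("both", "acute", "chronic"), ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  horizon <- match.arg(horizon)
  horizons <- if (horizon == "both") c("acute", "chronic") else horizon

  if (is.null(glove)) {
    kp_levels <- c(none = spec$kp_skin)
    glove_label <- "none"
  } else if (inherits(glove, "category_kp_summary")) {
    # category net Kp values recomputed against this scenario's skin Kp,
    # so a summary built for either formulation can be reused
    g <- c(glove$mean_kp_glove, glove$min_kp_glove, glove$max_kp_glove)
    kp_levels <- c(mean = kp_net(spec$kp_skin, g[1]),
                   min = kp_net(spec$kp_skin, g[2]),
                   max = kp_net(spec$kp_skin, g[3]))
    glove_label <- glove$category
  } else if (is.numeric(glove) && length(glove) == 1) {
    kp_levels <- c(mean = glove)
    glove_label <- "explicit"
  } else {
    stop("glove must be NULL, a category_kp_summary, or a single Kp value",
         call. = FALSE)
  }

  rows <- list()
  for (h in horizons) {
    for (lv in names(kp_levels)) {
      kp <- kp_levels[[lv]]
      full <- run_one(spec, kp, params, h, dermal_only = FALSE, ...)
      dermal <- run_one(spec, kp, params, h, dermal_only = TRUE, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        task = spec$task, level = spec$level, respirator = spec$respirator,
        glove = glove_label, horizon = h, kp_level = lv, kp_dermal = kp,
        cmax = full$cmax, auc = full$auc,
        dermal_only_cmax = dermal$cmax, dermal_only_auc = dermal$auc,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_result", "data.frame")
  out
}
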