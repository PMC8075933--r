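#' Points of departure for NMP internal dose
#'
#' Internal-dose points of departure (PODs) for the developmental
#' endpoints driving the NMP assessment: an acute POD of 216 mg/L
#' (BMDL01 for fetal resorptions, on a peak-blood-concentration basis)
#' and a chronic POD of 411 mg.h/L (BMDL05 for decreased fetal body
#' weight, on an AUC basis). Each POD is bound to its internal-dose
#' metric; using an AUC against the Cmax POD (or vice versa) is an error.
#'
#' @param acute_pod acute POD, mg/L (Cmax basis). Default 216.
#' @param chronic_pod chronic POD, mg.h/L (AUC basis). Default 411.
#' @return list of class `pod_constants`.
#' @export
pod_constants <- function(acute_pod = 216, chronic_pod = 411) {
  stop_if_not_positive(c(acute_pod, chronic_pod), "points of departure")
  structure(list(acute = list(value = acute_pod, metric = "cmax"),
                 chronic = list(value = chronic_pod, metric = "auc")),
            class = "pod_constants")
}

#' Margin of exposure
#'
#' \deqn{MOE = ID_{TA} / ID_{EA}}: the ratio of the toxicity-assessment
#' internal dose (the POD) to the exposure-assessment internal dose. The
#' POD entry and the internal dose must be on the same metric (Cmax or
#' AUC).
#'
#' @param pod one entry of [pod_constants()] (e.g. `pods$acute`), or a
#'   bare positive number taken at face value.
#' @param internal_dose exposure internal dose, same metric and units.
#' @param metric metric of `internal_dose` (`"cmax"` or `"auc"`);
#'   required (and checked) when `pod` is a typed entry.
#' @return MOE (unitless, full precision; `Inf` for a zero dose).
#' @export
#' @examples
#' pods <- pod_constants()
#' moe(pods$acute, 2.16, "cmax")   # 100
moe <- function(pod, internal_dose, metric = NULL) {
  if (is.list(pod)) {
    if (is.null(metric)) {
      stop("metric must be given when pod is a typed entry", call. = FALSE)
    }
    if (!identical(pod$metric, metric)) {
      stop("internal-dose metric '", metric, "' does not match the POD's '",
           pod$metric, "' basis", call. = FALSE)
    }
    pod <- pod$value
  }
  stop_if_not_positive(pod, "POD")
  stop_if_negative(internal_dose, "internal dose")
  ifelse(internal_dose == 0, Inf, pod / internal_dose)
}

#' Glove protection factor
#'
#' \deqn{PF = ID_{no\,gloves} / ID_{gloves}} computed from
#' dermal-liquid-pathway-only internal doses (the pathway gloves act on),
#' for a matched scenario and internal-dose metric.
#'
#' @param dose_no_gloves,dose_gloves internal doses, same metric.
#' @return PF (unitless, full precision; `Inf` for a zero gloved dose).
#' @export
protection_factor <- function(dose_no_gloves, dose_gloves) {
  stop_if_not_positive(dose_no_gloves, "ungloved internal dose")
  stop_if_negative(dose_gloves, "gloved internal dose")
  ifelse(dose_gloves == 0, Inf, dose_no_gloves / dose_gloves)
}

#' Classify an MOE against the acceptability threshold
#'
#' An MOE at or above the threshold (default 30, the uncertainty-factor
#' product used for NMP: 3 interspecies toxicodynamics x 10 intraspecies)
#' indicates no concern. Data-derived intraspecies toxicokinetic factors
#' have been argued to support thresholds of 20-21 instead; the threshold
#' is therefore configurable.
#'
#' @param moe MOE value(s).
#' @param threshold acceptability threshold (default 30).
#' @return logical: `TRUE` if acceptable (`moe >= threshold`).
#' @export
#' @examples
#' classify_moe(30)                 # TRUE
#' classify_moe(24, threshold = 21) # TRUE
classify_moe <- function(moe, threshold = 30) {
  stop_if_not_positive(threshold, "threshold")
  moe >= threshold
}

#' Full risk assessment across scenarios and glove options
#'
#' Runs every base scenario under each glove option, computes acute
#' (Cmax-based) and chronic (AUC-based) margins of exposure against the
#' PODs, dermal-liquid-only protection factors relative to the matched
#' no-glove run, and acceptability flags.
#'
#' @param records a `permeation_records` dataset (default the bundled
#'   reference dataset) from which per-category glove Kp summaries are
#'   built.
#' @param scenario_config a `scenario_config`.
#' @param params a `pbpk_parameters` list.
#' @param glove_options character subset of
#'   `c("none", "minimal", "moderate", "maximal")`.
#' @param threshold MOE acceptability threshold (default 30).
#' @param ... solver options passed to [pbpk_simulate()].
#' @return tidy data.frame of class `risk_table`: one row per scenario x
#'   glove x horizon x kp level, with internal doses, `moe`, `pf`,
#'   `acceptable`, and 2-significant-figure report columns `moe_report`
#'   and `pf_report`.
#' @export
assess <- function(records = reference_permeation_data(),
                   scenario_config = default_scenario_config(),
                   params = default_pbpk_parameters(),
                   glove_options = c("none", "minimal", "moderate", "maximal"),
                   threshold = 30, ...) {
  glove_options <- match.arg(glove_options, several.ok = TRUE)
  specs <- build_scenarios(scenario_config)
  pods <- pod_constants()
  rows <- list()
  for (spec in specs) {
    # glove summaries composed against this scenario's skin Kp
    by_glove <- list()
    for (g in glove_options) {
      glove <- if (g == "none") NULL else {
        category_summary(records, g, spec$kp_skin)
      }
      by_glove[[g]] <- run_scenario(spec, glove, params, horizon = "both", ...)
    }
    if (!"none" %in% names(by_glove)) {
      by_glove[["none"]] <- run_scenario(spec, NULL, params,
                                         horizon = "both", ...)
    }
    none <- by_glove[["none"]]
    for (g in glove_options) {
      res <- by_glove[[g]]
      for (i in seq_len(nrow(res))) {
        r <- res[i, ]
        base <- none[none$horizon == r$horizon, ]
        if (r$horizon == "acute") {
          dose <- r$cmax
          pod <- pods$acute
          metric <- "cmax"
          pf <- protection_factor(base$dermal_only_cmax, r$dermal_only_cmax)
        } else {
          dose <- r$auc
          pod <- pods$chronic
          metric <- "auc"
          pf <- protection_factor(base$dermal_only_auc, r$dermal_only_auc)
        }
        m <- moe(pod, dose, metric)
        rows[[length(rows) + 1L]] <- cbind(
          r, data.frame(internal_dose = dose, pod = pod$value,
                        moe = m, pf = pf,
                        acceptable = classify_moe(m, threshold),
                        threshold = threshold,
                        moe_report = report_signif(m),
                        pf_report = report_signif(pf),
                        stringsAsFactors = FALSE))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("risk_table", "data.frame")
  out
}
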