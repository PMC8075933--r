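#' Skin permeability coefficients for NMP (cm/h)
#'
#' Default dermal permeability coefficients for N-methylpyrrolidone through
#' (ungloved) human skin, as used in the TSCA occupational assessment:
#' 0.00205 cm/h for neat NMP and 0.000478 cm/h for aqueous NMP solutions.
#' Both are overridable wherever a `kp_skin` argument is accepted.
#'
#' @format Named numeric vector with elements `neat` and `solution`.
#' @export
kp_skin_defaults <- c(neat = 0.00205, solution = 0.000478)

# Conversion factor from (ug/cm^2/min) / (mg/cm^3) to cm/h:
# 0.001 mg/ug * 60 min/h = 0.06
KP_CONVERSION <- 0.06

#' Parse a possibly censored permeation rate
#'
#' Permeation-cell measurements are reported either as exact steady-state
#' rates, as below-detection values (`"<0.1"`), as above-range values
#' (`">34"`), or as "not detected" with no stated detection limit.
#'
#' @param x character or numeric vector of permeation rates in ug/cm2/min.
#'   Accepted forms: a number, `"<x"`, `">x"`, or `"nd"` / `"not detected"`.
#' @return data.frame with columns `value` (numeric, NA for not-detected)
#'   and `censor` (one of `"exact"`, `"lt"`, `"gt"`, `"nd"`).
#' @export
parse_permeation_rate <- function(x) {
  x <- trimws(as.character(x))
  censor <- rep("exact", length(x))
  value <- rep(NA_real_, length(x))
  is_nd <- grepl("^(nd|not detected)$", x, ignore.case = TRUE) | x == ""
  is_lt <- grepl("^<", x)
  is_gt <- grepl("^>", x)
  censor[is_nd] <- "nd"
  censor[is_lt] <- "lt"
  censor[is_gt] <- "gt"
  plain <- !(is_nd | is_lt | is_gt)
  value[plain] <- suppressWarnings(as.numeric(x[plain]))
  value[is_lt | is_gt] <- suppressWarnings(as.numeric(sub("^[<>]\\s*", "", x[is_lt | is_gt])))
  bad <- plain & is.na(value) | ((is_lt | is_gt) & is.na(value))
  if (any(bad)) {
    stop("unparseable permeation rate: ", paste(x[bad], collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(value) & value <= 0)) {
    stop("permeation rates and censoring bounds must be > 0", call. = FALSE)
  }
  data.frame(value = value, censor = censor, stringsAsFactors = FALSE)
}

#' Resolve a censored permeation rate to an effective rate
#'
#' Below-detection measurements (`"<x"`) are substituted with half the
#' detection limit (x/2), the standard convention for left-censored
#' occupational-hygiene data. Above-range measurements (`">x"`) are taken
#' at their face value x, which understates the true rate and is therefore
#' conservative for the glove (not the worker); this choice is validated
#' against the reference dataset's printed permeability coefficients.
#' "Not detected" with no stated detection limit cannot be quantified and
#' is excluded (returns `NA`).
#'
#' @param rate a rate as accepted by [parse_permeation_rate()].
#' @return numeric effective rate in ug/cm2/min, or `NA` if excluded.
#' @export
#' @examples
#' resolve_censored_rate("<0.1")  # 0.05
#' resolve_censored_rate(">34")   # 34
#' resolve_censored_rate(94)      # 94
#' resolve_censored_rate("nd")    # NA (excluded)
resolve_censored_rate <- function(rate) {
  p <- parse_permeation_rate(rate)
  out <- numeric(nrow(p))
  out[p$censor == "exact"] <- p$value[p$censor == "exact"]
  out[p$censor == "lt"] <- p$value[p$censor == "lt"] / 2
  out[p$censor == "gt"] <- p$value[p$censor == "gt"]
  out[p$censor == "nd"] <- NA_real_
  out
}

#' Permeability coefficient from a permeation rate
#'
#' Converts a steady-state permeation rate (flux) and the donor-side NMP
#' concentration into a permeability coefficient
#' \deqn{Kp = PR / C \times CF}
#' where PR is in ug/cm2/min, C in mg/cm3 and CF = 0.001 mg/ug x 60 min/h,
#' giving Kp in cm/h.
#'
#' @param rate effective permeation rate, ug/cm2/min (>= 0).
#' @param concentration NMP test concentration, mg/cm3 (> 0).
#' @return permeability coefficient, cm/h, at full precision.
#' @export
#' @examples
#' kp_from_rate(94, 773)    # ~0.0073 cm/h
#' kp_from_rate(1.6, 464)   # ~0.00021 cm/h
kp_from_rate <- function(rate, concentration) {
  stop_if_not_positive(concentration, "NMP test concentration")
  stop_if_negative(rate, "permeation rate")
  rate / concentration * KP_CONVERSION
}

#' Classify a glove by its effective permeation rate
#'
#' Three protection categories are used: minimal (rate > 2 ug/cm2/min),
#' moderate (1 to 2), and maximal (<= 0.3). Rates in the uncovered gap
#' (0.3, 1) are assigned to the adjacent less-protective category
#' (moderate) — the conservative choice for the worker — with a warning.
#'
#' @param rate effective (resolved) permeation rate, ug/cm2/min.
#' @return character vector with levels `"minimal"`, `"moderate"`,
#'   `"maximal"`.
#' @export
classify_glove <- function(rate) {
  stop_if_negative(rate, "effective permeation rate")
  out <- character(length(rate))
  out[rate > 2] <- "minimal"
  out[rate >= 1 & rate <= 2] <- "moderate"
  out[rate <= 0.3] <- "maximal"
  gap <- rate > 0.3 & rate < 1
  if (any(gap)) {
    warning("permeation rate(s) in the unclassified gap (0.3, 1) ug/cm2/min ",
            "assigned to the moderate category", call. = FALSE)
    out[gap] <- "moderate"
  }
  out
}

#' Net permeability of gloved skin (series barrier)
#'
#' Glove and skin act as resistances in series under Fick's law; the
#' composite permeability is the harmonic composition
#' \deqn{Kp_{net} = 1 / (1/Kp_{skin} + 1/Kp_{glove}).}
#' An infinite `kp_glove` means "no glove" and returns `kp_skin` exactly.
#' An explicit zero for either layer is a valid edge case returning 0
#' (an impermeable layer).
#'
#' @param kp_skin skin permeability coefficient, cm/h.
#' @param kp_glove glove permeability coefficient, cm/h (may be `Inf`).
#' @return composite permeability coefficient, cm/h.
#' @export
#' @examples
#' kp_net(0.000478, 0.000047)  # ~0.000043 cm/h
#' kp_net(0.00205, Inf)        # 0.00205 (no glove)
kp_net <- function(kp_skin, kp_glove) {
  if (any(is.na(kp_skin)) || any(is.na(kp_glove)) ||
      any(kp_skin < 0) || any(kp_glove < 0)) {
    stop("permeability coefficients must be non-negative (Inf allowed)",
         call. = FALSE)
  }
  n <- max(length(kp_skin), length(kp_glove))
  ks <- rep_len(kp_skin, n)
  kg <- rep_len(kp_glove, n)
  out <- numeric(n)
  zero <- ks == 0 | kg == 0
  skin_inf <- !zero & is.infinite(ks)
  glove_inf <- !zero & is.infinite(kg) & !skin_inf
  fin <- !zero & is.finite(ks) & is.finite(kg)
  out[skin_inf] <- kg[skin_inf]   # Inf if both infinite
  out[glove_inf] <- ks[glove_inf] # exact no-glove limit
  out[fin] <- 1 / (1 / ks[fin] + 1 / kg[fin])
  nm <- if (length(kp_glove) == n) names(kp_glove) else names(kp_skin)
  if (!is.null(nm)) names(out) <- nm
  out
}

#' Build a permeation-record table
#'
#' Canonical in-memory form of a glove permeation dataset: one row per
#' measurement, with the rate kept verbatim (possibly censored) alongside
#' its resolved effective value, computed permeability coefficient and
#' protection category. When a `category_hint` is present it takes
#' precedence over the rate rule: permeation datasets group records by
#' glove material family, and a single atypical measurement (e.g. a low
#' rate for a natural-rubber glove) stays with its family.
#'
#' @param data data.frame with columns `material`, `brand`, `test_material`,
#'   `permeation_rate` (number, `"<x"`, `">x"` or `"nd"`),
#'   `nmp_concentration_mg_per_cm3`, `source`, and optionally
#'   `category_hint`.
#' @return data.frame of class `permeation_records` with added columns
#'   `effective_rate`, `kp_cm_per_h` (NA for excluded records) and
#'   `category`.
#' @export
permeation_records <- function(data) {
  required <- c("material", "brand", "test_material", "permeation_rate",
                "nmp_concentration_mg_per_cm3", "source")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$effective_rate <- resolve_censored_rate(data$permeation_rate)
  quant <- !is.na(data$effective_rate)
  data$kp_cm_per_h <- NA_real_
  if (any(quant)) {
    conc <- data$nmp_concentration_mg_per_cm3[quant]
    stop_if_not_positive(conc, "NMP test concentration")
    data$kp_cm_per_h[quant] <- kp_from_rate(data$effective_rate[quant], conc)
  }
  hinted <- if ("category_hint" %in% names(data)) {
    !is.na(data$category_hint) & nzchar(data$category_hint)
  } else {
    rep(FALSE, nrow(data))
  }
  data$category <- NA_character_
  data$category[hinted] <- data$category_hint[hinted]
  need <- !hinted & quant
  if (any(need)) data$category[need] <- classify_glove(data$effective_rate[need])
  bad_cat <- !is.na(data$category) &
    !data$category %in% c("minimal", "moderate", "maximal")
  if (any(bad_cat)) {
    stop("unknown glove category: ",
         paste(unique(data$category[bad_cat]), collapse = ", "), call. = FALSE)
  }
  class(data) <- c("permeation_records", "data.frame")
  data
}

#' Read a permeation dataset from delimited text
#'
#' Accepts comma- or tab-separated UTF-8 text with a header row and the
#' columns documented in [permeation_records()].
#'
#' @param path file path.
#' @return a `permeation_records` data.frame.
#' @export
read_permeation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0 || !nzchar(header)) {
    stop("empty input file: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no records in input file: ", path, call. = FALSE)
  df$nmp_concentration_mg_per_cm3 <- as.numeric(df$nmp_concentration_mg_per_cm3)
  permeation_records(df)
}

#' Write a permeation table (with computed Kp) to delimited text
#'
#' @param records a `permeation_records` data.frame.
#' @param path output path.
#' @param sep field separator (default comma).
#' @param kp_digits significant figures for the reported Kp column.
#' @return `path`, invisibly.
#' @export
write_permeation <- function(records, path, sep = ",", kp_digits = 2) {
  out <- as.data.frame(records)
  out$kp_cm_per_h <- report_signif(out$kp_cm_per_h, kp_digits)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-category permeability summary for gloved skin
#'
#' Summarizes the glove permeability coefficients of one protection
#' category and composes them with a skin permeability coefficient into
#' net (gloved-skin) values. Aggregation is aggregate-then-compose: the
#' mean, minimum and maximum of the unrounded per-record glove Kp values
#' are computed first, and the series-barrier composition is applied once
#' to each of those three statistics. Records without a quantifiable rate
#' (not detected, no limit) are excluded.
#'
#' @param records a `permeation_records` data.frame.
#' @param category `"minimal"`, `"moderate"` or `"maximal"`.
#' @param kp_skin skin permeability coefficient, cm/h.
#' @return list of class `category_kp_summary` with fields `category`,
#'   `n`, `mean_kp_glove`, `min_kp_glove`, `max_kp_glove`, `mean_kp_net`,
#'   `min_kp_net`, `max_kp_net` (all cm/h, full precision).
#' @export
category_summary <- function(records, category, kp_skin) {
  stopifnot(inherits(records, "permeation_records"))
  if (!category %in% c("minimal", "moderate", "maximal")) {
    stop("unknown category: ", category, call. = FALSE)
  }
  stop_if_not_positive(kp_skin, "kp_skin")
  kp <- records$kp_cm_per_h[!is.na(records$kp_cm_per_h) &
                              records$category == category]
  if (length(kp) == 0) {
    stop("no quantifiable records in category '", category, "'",
         call. = FALSE)
  }
  glove <- c(mean = mean(kp), min = min(kp), max = max(kp))
  net <- kp_net(kp_skin, glove)
  structure(
    list(category = category, n = length(kp), kp_skin = kp_skin,
         mean_kp_glove = glove[["mean"]], min_kp_glove = glove[["min"]],
         max_kp_glove = glove[["max"]],
         mean_kp_net = net[["mean"]], min_kp_net = net[["min"]],
         max_kp_net = net[["max"]]),
    class = "category_kp_summary"
  )
}

#' @export
print.category_kp_summary <- function(x, ...) {
  cat(sprintf(
    "Glove category: %s (n = %d quantifiable records)\n", x$category, x$n))
  cat(sprintf("  Kp glove (cm/h): mean %s (range %s - %s)\n",
              format(report_signif(x$mean_kp_glove)),
              format(report_signif(x$min_kp_glove)),
              format(report_signif(x$max_kp_glove))))
  cat(sprintf("  Kp net, gloved skin (cm/h; Kp skin %s): mean %s (range %s - %s)\n",
              format(x$kp_skin),
              format(report_signif(x$mean_kp_net)),
              format(report_signif(x$min_kp_net)),
              format(report_signif(x$max_kp_net))))
  invisible(x)
}

#' Summaries for all categories present in a dataset
#'
#' @param records a `permeation_records` data.frame.
#' @param kp_skin skin permeability coefficient, cm/h.
#' @return data.frame, one row per category present, with glove and net
#'   Kp statistics at full precision.
#' @export
all_category_summaries <- function(records, kp_skin) {
  cats <- intersect(c("minimal", "moderate", "maximal"),
                    unique(records$category[!is.na(records$kp_cm_per_h)]))
  rows <- lapply(cats, function(cc) {
    s <- category_summary(records, cc, kp_skin)
    data.frame(category = s$category, n = s$n,
               mean_kp_glove = s$mean_kp_glove, min_kp_glove = s$min_kp_glove,
               max_kp_glove = s$max_kp_glove, mean_kp_net = s$mean_kp_net,
               min_kp_net = s$min_kp_net, max_kp_net = s$max_kp_net,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
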