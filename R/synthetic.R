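#' Reference glove permeation dataset for NMP
#'
#' The bundled reference dataset of published steady-state NMP permeation
#' rates through glove materials (natural rubber, nitrile, latex,
#' polyethylene, butyl, laminate) against neat NMP and NMP-containing
#' paint-stripper formulations, compiled from three permeation studies.
#' It contains 34 records: 11 minimal-, 2 moderate- and 21
#' maximal-protection rows, the last including one butyl-rubber record in
#' which NMP was never detected and no detection limit was stated (that
#' record is excluded from permeability computations).
#'
#' @return a [permeation_records()] data.frame with 34 rows.
#' @export
#' @examples
#' recs <- reference_permeation_data()
#' nrow(recs)  # 34
reference_permeation_data <- function() {
  path <- system.file("extdata", "nmp_glove_permeation.csv",
                      package = "nmpglove", mustWork = TRUE)
  read_permeation(path)
}

#' Generate a synthetic glove permeation dataset
#'
#' Draws permeation rates log-uniformly over 0.05 to 100 ug/cm2/min —
#' emulating the roughly three orders of magnitude spanned by measured
#' NMP permeation rates across glove materials — and test concentrations
#' uniformly over 371 to 1030 mg/cm3 (the span of reported test
#' formulations, up to neat NMP). Rates below the detection limit are
#' emitted censored as `"<limit"`. Rates and concentrations are
#' independent draws: no glove-material covariance is modelled, because
#' downstream analysis consumes only marginal Kp values.
#'
#' @param n_records number of records (>= 1).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param detection_limit detection limit in ug/cm2/min (default 0.1).
#' @return a [permeation_records()] data.frame with `n_records` rows; the
#'   seed is recorded in `attr(, "seed")`.
#' @export
generate_permeation_dataset <- function(n_records, seed, detection_limit = 0.1) {
  if (!is.numeric(n_records) || length(n_records) != 1 || n_records < 1 ||
      n_records != round(n_records)) {
    stop("n_records must be a positive integer", call. = FALSE)
  }
  stop_if_not_positive(detection_limit, "detection_limit")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  rate <- 10^stats::runif(n_records, log10(0.05), log10(100))
  conc <- stats::runif(n_records, 371, 1030)
  rate_chr <- ifelse(rate < detection_limit,
                     paste0("<", format(detection_limit, scientific = FALSE)),
                     format(rate, digits = 15, scientific = FALSE, trim = TRUE))
  df <- data.frame(
    material = sprintf("synthetic material %d", seq_len(n_records)),
    brand = sprintf("synthetic brand %d", seq_len(n_records)),
    test_material = "synthetic NMP formulation",
    permeation_rate = rate_chr,
    nmp_concentration_mg_per_cm3 = conc,
    source = "synthetic",
    stringsAsFactors = FALSE
  )
  out <- permeation_records(df)
  attr(out, "seed") <- as.integer(seed)
  out
}
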