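#' Round to significant figures for reporting
#'
#' All internal arithmetic in this package is carried at full double
#' precision; rounding to two significant figures happens only at the
#' reporting boundary, matching the convention of regulatory risk
#' assessments. `signif()` implements round-half-even.
#'
#' @param x numeric vector.
#' @param digits significant figures (default 2).
#' @return `x` rounded to `digits` significant figures.
#' @export
report_signif <- function(x, digits = 2) {
  signif(x, digits)
}

stop_if_not_positive <- function(x, what) {
  if (any(!is.finite(x) | x <= 0)) {
    stop(sprintf("%s must be a positive finite number", what), call. = FALSE)
  }
  invisible(x)
}

stop_if_negative <- function(x, what) {
  if (any(is.na(x) | x < 0)) {
    stop(sprintf("%s must be non-negative", what), call. = FALSE)
  }
  invisible(x)
}

# Recursive list merge: values in `override` win over `base`.
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
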