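#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (the convention used when
#' printing percentages in summary tables), unlike [base::round()], which
#' rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' roundHalfUp(c(0.125, 0.135), 2)
#' @export
roundHalfUp <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by one ulp so values printed as x.xx5 but stored just below do not
  # fall on the wrong side
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

.assertScalarCount <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) ||
      x < 1) {
    stop("'", name, "' must be a single positive integer", call. = FALSE)
  }
  as.integer(x)
}

.assertFraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop("'", name, "' must be a single value in [0, 1]", call. = FALSE)
  }
  as.numeric(x)
}

.assertCountMatrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("'counts' must be non-negative with no missing values",
         call. = FALSE)
  }
  invisible(counts)
}
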