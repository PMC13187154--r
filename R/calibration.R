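#' Fit a phenol-red pH standard curve
#'
#' Fits pH as an ordinary least-squares affine function of absorbance at
#' 560 nm from a calibration table, the direction actually needed downstream
#' (each kinetic absorbance read is converted straight to a pH).  Phenol red
#' responds approximately linearly between pH 6.5 and 7.5, the range the
#' acidification assay operates in.
#'
#' @param calib data frame with numeric columns `ph` and `a560`
#'   (one calibration point per row), or a path to a delimited file with
#'   those columns.
#' @return an object of class `standard_curve`: a list with elements
#'   `slope` (pH per absorbance unit), `intercept` (pH), `r_squared`,
#'   `calib_range` (range of calibration absorbances) and `n`.
#' @export
#' @examples
#' curve <- fit_standard_curve(data.frame(ph = c(6.5, 7.5), a560 = c(0.5, 1)))
#' curve$slope     # 2: two points determine the line
fit_standard_curve <- function(calib) {
  if (is.character(calib)) calib <- read_delim_auto(calib)
  nm <- deparse(substitute(calib))
  if (!all(c("ph", "a560") %in% names(calib)))
    stopf("calibration table must have columns 'ph' and 'a560'")
  ph <- as.numeric(calib$ph)
  a560 <- as.numeric(calib$a560)
  ok <- is.finite(ph) & is.finite(a560)
  ph <- ph[ok]; a560 <- a560[ok]
  if (length(ph) < 2L)
    stopf("calibration table '%s' has fewer than 2 usable points", nm)
  if (anyDuplicated(ph))
    stopf("calibration table '%s' has duplicated pH values", nm)
  if (any(a560 < 0))
    stopf("calibration table '%s' has negative absorbances", nm)
  if (diff(range(a560)) == 0)
    stopf("calibration table '%s' is degenerate: all absorbances identical", nm)
  fit <- stats::lm(ph ~ a560)
  sst <- sum((ph - mean(ph))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope     = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 calib_range = range(a560),
                 n = length(ph)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Phenol-red standard curve: pH = %.4f * A560 + %.4f  (R2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("Calibrated over A560 in [%.4f, %.4f]\n",
              x$calib_range[1L], x$calib_range[2L]))
  invisible(x)
}

#' Convert absorbance readings to pH with a standard curve
#'
#' Applies the affine standard curve to each absorbance.  Readings outside
#' the calibrated absorbance range are converted anyway (never clipped) but
#' flagged in the `"extrapolated"` attribute, and a warning is raised.
#'
#' @param a560 numeric vector of absorbance readings at 560 nm.
#' @param curve a [fit_standard_curve()] object.
#' @param warn warn when any reading falls outside the calibration range?
#' @return numeric vector of pH values with a logical attribute
#'   `"extrapolated"`, one flag per timepoint.
#' @export
absorbance_to_ph <- function(a560, curve, warn = TRUE) {
  stopifnot(inherits(curve, "standard_curve"))
  a560 <- as.numeric(a560)
  ph <- curve$slope * a560 + curve$intercept
  extra <- is.finite(a560) &
    (a560 < curve$calib_range[1L] | a560 > curve$calib_range[2L])
  if (warn && any(extra))
    warnf("%d of %d absorbance readings outside the calibration range [%g, %g]",
          sum(extra), length(a560), curve$calib_range[1L], curve$calib_range[2L])
  attr(ph, "extrapolated") <- extra
  ph
}
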