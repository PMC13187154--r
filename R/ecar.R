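#' Ordinary least-squares acidification slope of a pH time course
#'
#' Fits pH against time by OLS over the full measurement window (or an
#' optional sub-window) and reports the slope in pH per hour.  Non-finite
#' (pH, time) pairs are dropped before fitting.
#'
#' @param ph numeric vector of pH values.
#' @param time_min numeric vector of measurement times in minutes, strictly
#'   increasing and the same length as `ph`.
#' @param window optional `c(t_start, t_end)` in minutes restricting the fit.
#' @return list with `slope` (pH/h), `r_squared` and `n` (timepoints used).
#' @export
#' @examples
#' tm <- seq(0, 90, by = 3)
#' acidification_slope(7 - 0.001 * tm, tm)$slope   # -0.06 pH/h
acidification_slope <- function(ph, time_min, window = NULL) {
  ph <- as.numeric(ph); time_min <- as.numeric(time_min)
  if (length(ph) != length(time_min))
    stopf("ph and time_min have different lengths (%d vs %d)",
          length(ph), length(time_min))
  keep <- is.finite(ph) & is.finite(time_min)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1L] < window[2L])
    keep <- keep & time_min >= window[1L] & time_min <= window[2L]
  }
  ph <- ph[keep]; time_min <- time_min[keep]
  if (length(ph) < 3L)
    stopf("need at least 3 finite timepoints to fit a slope, got %d", length(ph))
  if (var(time_min) == 0)
    stopf("zero variance in time: cannot fit a slope")
  hours <- time_min / 60
  fit <- stats::lm(ph ~ hours)
  sst <- sum((ph - mean(ph))^2)
  list(slope = unname(coef(fit)[2L]),
       r_squared = if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst,
       n = length(ph))
}

#' Dextrose-dependent extracellular acidification rate of one replicate
#'
#' Converts a paired carbon (2% dextrose) and water-control well to pH via
#' the standard curve, fits each acidification slope, and returns their
#' difference: the ECAR statistic in pH/h.  Rapid acidification gives a
#' negative ECAR.
#'
#' @param carbon,control well series for the same strain and replicate:
#'   data frames with columns `strain`, `condition` (`"carbon"` /
#'   `"control"`), `replicate`, `time_min`, `a560` (and optionally `well`).
#' @param curve a [fit_standard_curve()] object.
#' @param window optional fitting sub-window in minutes, see
#'   [acidification_slope()].
#' @return one-row data frame with columns `strain`, `replicate`,
#'   `slope_carbon`, `slope_control`, `ecar` (all pH/h), `fit_r2_carbon`,
#'   `fit_r2_control`.
#' @export
dextrose_dependent_ecar <- function(carbon, control, curve, window = NULL) {
  for (d in list(carbon, control))
    if (!all(c("strain", "condition", "replicate", "time_min", "a560") %in% names(d)))
      stopf("well series need columns strain, condition, replicate, time_min, a560")
  if (unique(carbon$condition) != "carbon" || unique(control$condition) != "control")
    stopf("condition labels are not carbon/control (wells %s / %s)",
          paste(unique(carbon$well %||% "?"), collapse = ","),
          paste(unique(control$well %||% "?"), collapse = ","))
  if (!identical(unique(carbon$strain), unique(control$strain)) ||
      !identical(unique(carbon$replicate), unique(control$replicate)))
    stopf("carbon well (%s, rep %s) and control well (%s, rep %s) are not a pair",
          unique(carbon$strain), unique(carbon$replicate),
          unique(control$strain), unique(control$replicate))
  fit_one <- function(d) {
    ph <- absorbance_to_ph(d$a560, curve, warn = FALSE)
    acidification_slope(ph, d$time_min, window = window)
  }
  fc <- fit_one(carbon); f0 <- fit_one(control)
  data.frame(strain = unique(carbon$strain),
             replicate = unique(carbon$replicate),
             slope_carbon = fc$slope,
             slope_control = f0$slope,
             ecar = fc$slope - f0$slope,
             fit_r2_carbon = fc$r_squared,
             fit_r2_control = f0$r_squared,
             stringsAsFactors = FALSE)
}

#' Aggregate replicate ECAR measurements to species level
#'
#' @param results data frame of per-replicate ECAR rows as returned by
#'   [dextrose_dependent_ecar()] / [ecar_from_plate()].
#' @param min_n minimum number of replicates below which a species is
#'   flagged (`low_n`), not removed.
#' @return data frame with one row per strain: `strain`, `mean_ecar`,
#'   `sd_ecar` (`NA` when n < 2), `n`, `low_n`.
#' @export
aggregate_replicates <- function(results, min_n = 2L) {
  if (is.null(results) || nrow(results) == 0L)
    stopf("no ECAR results to aggregate")
  sp <- split(results$ecar, results$strain)
  out <- data.frame(
    strain = names(sp),
    mean_ecar = vapply(sp, mean, 0),
    sd_ecar = vapply(sp, function(v) if (length(v) >= 2L) sd(v) else NA_real_, 0),
    n = vapply(sp, length, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  out$low_n <- out$n < min_n
  out
}

#' Read a plate-reader kinetic absorbance table
#'
#' Accepts either the long dialect (columns `well`, `time_min`, `a560`) or a
#' wide dialect (one row per well, first column `well`, remaining column
#' names the times in minutes); the dialect is detected from the header and
#' the delimiter (comma or tab) is sniffed.
#'
#' @param file path to the delimited plate file.
#' @return long-format data frame with columns `well`, `time_min`, `a560`.
#' @export
read_plate <- function(file) {
  d <- read_delim_auto(file)
  if (all(c("well", "time_min", "a560") %in% names(d))) {
    return(d[, c("well", "time_min", "a560")])
  }
  if (names(d)[1L] == "well" &&
      !anyNA(suppressWarnings(as.numeric(names(d)[-1L])))) {
    times <- as.numeric(names(d)[-1L])
    long <- data.frame(
      well = rep(d$well, each = length(times)),
      time_min = rep(times, times = nrow(d)),
      a560 = as.vector(t(as.matrix(d[, -1L]))),
      stringsAsFactors = FALSE)
    return(long)
  }
  stopf("unrecognised plate dialect in '%s': need well/time_min/a560 columns or a wide table with a leading 'well' column", file)
}

#' Read a plate layout table
#'
#' @param file delimited file with columns `well`, `strain`, `condition`
#'   (`carbon` or `control`) and `replicate`.
#' @return data frame with those columns.
#' @export
read_layout <- function(file) {
  d <- read_delim_auto(file)
  need <- c("well", "strain", "condition", "replicate")
  if (!all(need %in% names(d)))
    stopf("layout '%s' must have columns %s", file, paste(need, collapse = ", "))
  bad <- setdiff(unique(d$condition), c("carbon", "control"))
  if (length(bad))
    stopf("layout '%s': unknown condition value(s) %s", file,
          paste(bad, collapse = ", "))
  d[, need]
}

#' Full plate-to-ECAR analysis
#'
#' Runs the complete quantification for one plate: converts each well's
#' absorbance kinetics to pH with the standard curve, fits acidification
#' slopes, pairs carbon and control wells by (strain, replicate), differences
#' the slopes into per-replicate ECAR values, and aggregates replicates per
#' species.  Unpaired wells are reported and skipped, never silently used.
#'
#' @param plate long plate table (see [read_plate()]) or path to one.
#' @param layout layout table (see [read_layout()]) or path.
#' @param calibration calibration table with columns `ph`/`a560`, a path to
#'   one, or an already fitted `standard_curve`.
#' @param window optional slope-fitting sub-window in minutes.
#' @param min_n replicate threshold passed to [aggregate_replicates()].
#' @return object of class `ecar_analysis`: list with `results`
#'   (per-replicate ECAR rows), `traits` (per-species summary), `curve`,
#'   `unpaired` (skipped well pairs) and `n_extrapolated` (timepoints
#'   outside the calibration range).
#' @export
ecar_from_plate <- function(plate, layout, calibration, window = NULL,
                            min_n = 2L) {
  if (is.character(plate)) plate <- read_plate(plate)
  if (is.character(layout)) layout <- read_layout(layout)
  curve <- if (inherits(calibration, "standard_curve")) calibration
           else fit_standard_curve(calibration)

  d <- merge(plate, layout, by = "well")
  if (nrow(d) == 0L) stopf("no wells shared between plate and layout")
  n_extra <- sum(attr(absorbance_to_ph(d$a560, curve, warn = FALSE),
                      "extrapolated"))
  key <- interaction(d$strain, d$replicate, drop = TRUE)
  res <- list(); unpaired <- character()
  for (k in levels(key)) {
    dk <- d[key == k, ]
    carbon <- dk[dk$condition == "carbon", ]
    control <- dk[dk$condition == "control", ]
    if (nrow(carbon) == 0L || nrow(control) == 0L) {
      unpaired <- c(unpaired, k)
      next
    }
    carbon <- carbon[order(carbon$time_min), ]
    control <- control[order(control$time_min), ]
    res[[k]] <- dextrose_dependent_ecar(carbon, control, curve, window = window)
  }
  if (length(unpaired))
    message("skipped unpaired (strain, replicate) groups: ",
            paste(unpaired, collapse = ", "))
  if (!length(res)) stopf("no paired carbon/control wells found")
  results <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  structure(list(results = results,
                 traits = aggregate_replicates(results, min_n = min_n),
                 curve = curve,
                 unpaired = unpaired,
                 n_extrapolated = n_extra),
            class = "ecar_analysis")
}

#' @export
print.ecar_analysis <- function(x, ...) {
  cat(sprintf("ECAR analysis: %d replicate measurements, %d species\n",
              nrow(x$results), nrow(x$traits)))
  if (length(x$unpaired))
    cat(sprintf("  %d unpaired well group(s) skipped\n", length(x$unpaired)))
  if (x$n_extrapolated > 0)
    cat(sprintf("  %d timepoint(s) outside the calibration range\n",
                x$n_extrapolated))
  print(x$traits, ...)
  invisible(x)
}

#' Export species mean ECAR as an iTOL colour-strip annotation
#'
#' Writes a `DATASET_COLORSTRIP` file mapping each species to a colour along
#' a gradient from the most rapid (most negative, lightest colour) to the
#' slowest acidifier, ready to drop onto a phylogeny in iTOL.
#'
#' @param traits species summary from [aggregate_replicates()].
#' @param file output path.
#' @param colors two colours anchoring the gradient (rapid, slow).
#' @return the output path, invisibly.
#' @export
write_itol_strip <- function(traits, file,
                             colors = c("#b8e186", "#276419")) {
  stopifnot(all(c("strain", "mean_ecar") %in% names(traits)))
  v <- traits$mean_ecar
  f <- if (diff(range(v)) == 0) rep(0, length(v)) else
    (v - min(v)) / diff(range(v))
  ramp <- grDevices::colorRamp(colors)
  cols <- grDevices::rgb(ramp(f), maxColorValue = 255)
  lines <- c("DATASET_COLORSTRIP",
             "SEPARATOR TAB",
             "DATASET_LABEL\tmean ECAR (pH/h)",
             "COLOR\t#276419",
             "DATA",
             paste(traits$strain, cols, sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}
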