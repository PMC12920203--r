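# Quantification of raw in-vitro PGPT assay measurements into the derived
# trait values used for scoring: solubilization halo indices, percent
# units from colorimetric pairs, standard-curve concentrations, drought
# tolerance classes and the PEG / water-potential calibration.

#' Solubilization halo index
#'
#' Ratio of the total (colony + halo) diameter to the colony diameter,
#' expressed as a percentage. Used identically for phosphate (PSI) and
#' potassium (KSI) solubilization plate assays: a value of 100 means no
#' visible halo, larger values mean a proportionally wider clearing zone.
#'
#' @param colony_diameter Colony diameter in mm (> 0).
#' @param total_diameter Colony-plus-halo diameter in mm
#'   (>= `colony_diameter`). Vectorized with `colony_diameter`.
#' @return Numeric vector of index values (percent, >= 100).
#' @examples
#' halo_index(8, 20)   # 250
#' halo_index(10, 10)  # 100, no halo
#' @export
halo_index <- function(colony_diameter, total_diameter) {
  check_numeric(colony_diameter, "colony_diameter")
  check_numeric(total_diameter, "total_diameter")
  if (any(colony_diameter <= 0, na.rm = TRUE)) {
    rr_stop("colony diameter must be > 0", "rr_invalid_measurement")
  }
  if (any(total_diameter < colony_diameter, na.rm = TRUE)) {
    rr_stop("total diameter must be >= colony diameter",
            "rr_invalid_measurement")
  }
  total_diameter / colony_diameter * 100
}

#' Percent units from a reference/sample absorbance pair
#'
#' Converts a colorimetric assay readout into percent units
#' `(Ar - As) / Ar * 100`, where `Ar` is the absorbance of the uninoculated
#' reference and `As` the absorbance of the sample. Used for percent
#' siderophore units (PSU, CAS assay) and percent phosphorus units (PPU,
#' broth acidification assay). Values are not clipped: a sample darker than
#' the reference yields a negative value together with a
#' `rr_negative_percent_unit` warning, so assay anomalies stay visible.
#'
#' @param reference_abs Reference absorbance `Ar` (> 0).
#' @param sample_abs Sample absorbance `As` (>= 0). Vectorized.
#' @return Numeric vector of percent units (<= 100).
#' @examples
#' percent_unit(0.8, 0.2)  # 75
#' @export
percent_unit <- function(reference_abs, sample_abs) {
  check_numeric(reference_abs, "reference_abs")
  check_numeric(sample_abs, "sample_abs")
  if (any(reference_abs <= 0, na.rm = TRUE)) {
    rr_stop("reference absorbance must be > 0", "rr_invalid_reference")
  }
  if (any(sample_abs < 0, na.rm = TRUE)) {
    rr_stop("sample absorbance must be >= 0", "rr_invalid_measurement")
  }
  out <- (reference_abs - sample_abs) / reference_abs * 100
  if (any(out < 0, na.rm = TRUE)) {
    rr_warn("sample absorbance exceeds reference; negative percent units retained",
            "rr_negative_percent_unit")
  }
  out
}

#' Fit a colorimetric standard curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` through calibration points, as used for ammonia (Nessler)
#' and IAA (Salkowski) quantification. A fit-quality warning is emitted
#' when R-squared drops below `r2_warn` (noisy or non-linear standards).
#'
#' @param concentration,absorbance Calibration points (same length, >= 2
#'   distinct concentrations).
#' @param analyte Optional label stored on the curve (e.g. `"IAA"`).
#' @param r2_warn R-squared threshold below which a quality warning is
#'   raised. Default 0.98.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `n`, `analyte`.
#' @examples
#' fit_standard_curve(c(0, 1, 2), c(0, 0.1, 0.2))
#' @export
fit_standard_curve <- function(concentration, absorbance, analyte = NA_character_,
                               r2_warn = 0.98) {
  check_numeric(concentration, "concentration")
  check_numeric(absorbance, "absorbance")
  if (length(concentration) != length(absorbance)) {
    rr_stop("concentration and absorbance must have equal length",
            "rr_invalid_input")
  }
  if (length(unique(concentration)) < 2) {
    rr_stop("standard curve needs at least two distinct concentrations",
            "rr_degenerate_curve")
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope == 0) {
    rr_stop("fitted slope is zero; curve cannot be inverted",
            "rr_degenerate_curve")
  }
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  if (is.finite(r2) && r2 < r2_warn) {
    rr_warn(sprintf("standard curve R^2 = %.4f below %.2f", r2, r2_warn),
            "rr_fit_quality")
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         n = length(concentration), analyte = analyte),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve%s: absorbance = %.6g * conc + %.6g (R^2 = %.4f, n = %d)\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Invert a standard curve to a concentration
#'
#' Returns `(absorbance - intercept) / slope`. Inversions below zero are
#' below the detection limit of the calibrated range: they are reported as
#' 0 with a `rr_below_detection` warning rather than as a negative
#' concentration.
#'
#' @param absorbance Observed absorbance(s).
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @return Numeric vector of concentrations (>= 0) in the units of the
#'   curve's calibration standards.
#' @export
quantify_from_curve <- function(absorbance, curve) {
  if (!inherits(curve, "standard_curve")) {
    rr_stop("`curve` must be a standard_curve object", "rr_invalid_input")
  }
  if (!is.finite(curve$slope) || curve$slope == 0) {
    rr_stop("curve slope is zero", "rr_degenerate_curve")
  }
  check_numeric(absorbance, "absorbance")
  conc <- (absorbance - curve$intercept) / curve$slope
  below <- is.finite(conc) & conc < 0
  if (any(below)) {
    rr_warn(sprintf("%d value(s) below detection limit reported as 0",
                    sum(below)), "rr_below_detection")
    conc[below] <- 0
  }
  conc
}

#' Classify drought tolerance from growth under osmotic stress
#'
#' Classifies a strain by its OD600 after 48 h in 24% PEG 6000:
#' highly sensitive (< 0.3), sensitive (0.3 to < 0.4), tolerant (0.4 to 0.5)
#' and highly tolerant (> 0.5). The intervals partition `[0, Inf)`; 0.5 is
#' "tolerant" because the highly tolerant class is strictly above 0.5.
#' Only highly tolerant strains pass the drought pre-screen.
#'
#' @param od600 OD600 reading at 48 h (>= 0). Vectorized.
#' @return Factor with levels `highly_sensitive`, `sensitive`, `tolerant`,
#'   `highly_tolerant`.
#' @examples
#' classify_drought_tolerance(c(0.25, 0.45, 0.55))
#' @export
classify_drought_tolerance <- function(od600) {
  check_numeric(od600, "od600")
  if (any(od600 < 0, na.rm = TRUE)) {
    rr_stop("OD600 must be >= 0", "rr_invalid_measurement")
  }
  cut(od600, breaks = c(-Inf, 0.3, 0.4, 0.5, Inf),
      labels = c("highly_sensitive", "sensitive", "tolerant", "highly_tolerant"),
      right = FALSE) -> cls
  # right = FALSE makes [0.4, 0.5) tolerant; move 0.5 itself into tolerant
  cls[od600 == 0.5] <- "tolerant"
  cls
}

#' Default PEG 6000 / water potential calibration table
#'
#' Measured relationship between PEG 6000 concentration (% w/v) in TSB and
#' medium water potential (MPa, chilled-mirror dew point): 0% -> -0.72,
#' 12% -> -0.98, 24% -> -1.67, 32% -> -2.26.
#'
#' @return Data frame with columns `peg_percent` and `water_potential_mpa`.
#' @export
peg_calibration_table <- function() {
  data.frame(
    peg_percent = c(0, 12, 24, 32),
    water_potential_mpa = c(-0.72, -0.98, -1.67, -2.26)
  )
}

#' Map a PEG concentration to medium water potential
#'
#' Exact table value at a tabulated concentration, piecewise-linear
#' interpolation in between. The calibration was measured, not modeled, so
#' no extrapolation outside the tabulated range is performed.
#'
#' @param peg_percent PEG 6000 concentration(s), % w/v, within the table
#'   range.
#' @param table Calibration table; defaults to [peg_calibration_table()].
#' @return Water potential in MPa (negative; more negative = drier).
#' @examples
#' peg_to_water_potential(24)  # -1.67
#' @export
peg_to_water_potential <- function(peg_percent, table = peg_calibration_table()) {
  check_numeric(peg_percent, "peg_percent")
  check_columns(table, c("peg_percent", "water_potential_mpa"),
                "PEG calibration table")
  if (is.unsorted(table$peg_percent, strictly = TRUE)) {
    rr_stop("calibration PEG concentrations must be strictly increasing",
            "rr_invalid_input")
  }
  if (any(diff(table$water_potential_mpa) >= 0)) {
    rr_stop("calibration water potentials must be strictly decreasing",
            "rr_invalid_input")
  }
  rng <- range(table$peg_percent)
  if (any(peg_percent < rng[1] | peg_percent > rng[2], na.rm = TRUE)) {
    rr_stop(sprintf("PEG concentration outside calibrated range [%g, %g]; no extrapolation",
                    rng[1], rng[2]), "rr_extrapolation")
  }
  stats::approx(table$peg_percent, table$water_potential_mpa,
                xout = peg_percent, method = "linear")$y
}

#' Percent change between control and stress conditions
#'
#' Signed percent change `(stress - control) / control * 100`; reductions
#' under stress come out negative.
#'
#' @param control_value Value under optimal conditions (> 0).
#' @param stress_value Value under stress. Vectorized.
#' @return Signed percent change.
#' @export
percent_change <- function(control_value, stress_value) {
  check_numeric(control_value, "control_value")
  check_numeric(stress_value, "stress_value")
  if (any(control_value <= 0, na.rm = TRUE)) {
    rr_stop("control value must be > 0 for a percent change",
            "rr_undefined_baseline")
  }
  (stress_value - control_value) / control_value * 100
}

#' Fold change between control and stress conditions
#'
#' @param control_value Value under optimal conditions (> 0).
#' @param stress_value Value under stress.
#' @return `stress_value / control_value`.
#' @export
fold_change <- function(control_value, stress_value) {
  check_numeric(control_value, "control_value")
  check_numeric(stress_value, "stress_value")
  if (any(control_value <= 0, na.rm = TRUE)) {
    rr_stop("control value must be > 0 for a fold change",
            "rr_undefined_baseline")
  }
  stress_value / control_value
}
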