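# Index formulas, standard curves, drought classification and the PEG
# calibration.

test_that("halo index is total/colony x 100 and rejects bad geometry", {
  expect_equal(halo_index(10, 10), 100)
  expect_equal(halo_index(8, 20), 250)
  expect_equal(halo_index(4, 6), 150)
  expect_equal(halo_index(c(10, 8), c(10, 20)), c(100, 250))
  expect_error(halo_index(0, 5), class = "rr_invalid_measurement")
  expect_error(halo_index(-2, 5), class = "rr_invalid_measurement")
  expect_error(halo_index(10, 9), class = "rr_invalid_measurement")
})

test_that("halo index is >= 100, equal to 100 only without a halo", {
  set.seed(11)
  colony <- runif(200, 0.5, 12)
  ext <- c(rep(0, 50), runif(150, 0, 20))
  idx <- halo_index(colony, colony + ext)
  expect_true(all(idx >= 100))
  expect_identical(idx == 100, ext == 0)
})

test_that("percent units follow (Ar - As)/Ar x 100 and flag anomalies", {
  expect_equal(percent_unit(0.5, 0.5), 0)
  expect_equal(percent_unit(1.0, 0.0), 100)
  expect_equal(percent_unit(0.8, 0.2), 75)
  expect_error(percent_unit(0, 0.1), class = "rr_invalid_reference")
  # As > Ar is an anomaly: negative, warned, never clipped
  expect_warning(v <- percent_unit(0.5, 0.6),
                 class = "rr_negative_percent_unit")
  expect_equal(v, -20)
})

test_that("percent units are bounded by 100 and strictly decreasing in As", {
  as_vals <- seq(0, 1.5, by = 0.05)
  pu <- suppressWarnings(percent_unit(rep(0.9, length(as_vals)), as_vals))
  expect_true(all(pu <= 100))
  expect_true(all(diff(pu) < 0))
})

test_that("standard curves recover exact and least-squares lines", {
  c1 <- fit_standard_curve(c(0, 1, 2), c(0, 0.1, 0.2))
  expect_equal(c1$slope, 0.1)
  expect_equal(c1$intercept, 0, tolerance = 1e-12)
  c2 <- fit_standard_curve(c(0, 2), c(0.05, 0.25))
  expect_equal(c2$slope, 0.1)
  expect_equal(c2$intercept, 0.05)
  # closed-form OLS on three points: slope = Sxy/Sxx = 0.19/2
  c3 <- suppressWarnings(fit_standard_curve(c(0, 1, 2), c(0, 0.1, 0.19)))
  expect_equal(c3$slope, 0.095)
  expect_equal(c3$intercept, 0.29 / 3 - 0.095, tolerance = 1e-12)
  expect_error(fit_standard_curve(c(1, 1, 1), c(0, 0.1, 0.2)),
               class = "rr_degenerate_curve")
  expect_warning(fit_standard_curve(c(0, 1, 2, 3), c(0, 0.3, 0.1, 0.4)),
                 class = "rr_fit_quality")
})

test_that("curve inversion is exact on the fitted line and floors at zero", {
  curve <- fit_standard_curve(c(0, 1, 2), c(0.05, 0.15, 0.25))
  expect_equal(quantify_from_curve(0.15, curve), 1)
  # round-trip: concentration -> absorbance -> concentration
  conc <- c(0, 0.4, 1.7, 2)
  abs_pred <- curve$slope * conc + curve$intercept
  expect_equal(quantify_from_curve(abs_pred, curve), conc, tolerance = 1e-9)
  expect_warning(v <- quantify_from_curve(0.01, curve),
                 class = "rr_below_detection")
  expect_equal(v, 0)
})

test_that("drought tolerance classes partition OD600 with the stated cuts", {
  expect_equal(as.character(classify_drought_tolerance(0.25)),
               "highly_sensitive")
  expect_equal(as.character(classify_drought_tolerance(0.45)), "tolerant")
  expect_equal(as.character(classify_drought_tolerance(0.55)),
               "highly_tolerant")
  # boundary membership: 0.3 sensitive, 0.4 tolerant, 0.5 tolerant (strictly
  # above 0.5 is highly tolerant), and every OD maps to exactly one class
  expect_equal(as.character(classify_drought_tolerance(c(0.3, 0.4, 0.5))),
               c("sensitive", "tolerant", "tolerant"))
  grid <- seq(0, 1.2, by = 0.01)
  expect_false(anyNA(classify_drought_tolerance(grid)))
  expect_error(classify_drought_tolerance(-0.1),
               class = "rr_invalid_measurement")
})

test_that("PEG maps to water potential by table lookup and interpolation", {
  expect_equal(peg_to_water_potential(24), -1.67)
  expect_equal(peg_to_water_potential(0), -0.72)
  expect_equal(peg_to_water_potential(32), -2.26)
  # midpoint of (12, -0.98) and (24, -1.67)
  expect_equal(peg_to_water_potential(18), -1.325)
  expect_error(peg_to_water_potential(40), class = "rr_extrapolation")
  expect_error(peg_to_water_potential(-1), class = "rr_extrapolation")
  # monotone decreasing across the calibrated range
  psi <- peg_to_water_potential(seq(0, 32, by = 0.5))
  expect_true(all(diff(psi) < 0))
})

test_that("percent and fold changes use the control as baseline", {
  expect_equal(round(percent_change(46.51, 24.19)), -48)
  expect_equal(round(percent_change(13.58, 22.82)), 68)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 5), class = "rr_undefined_baseline")
  expect_equal(fold_change(1, 1), 1)
  expect_equal(fold_change(2, 0.5), 0.25)
  expect_equal(fold_change(0.03, 4.82), 4.82 / 0.03)
  expect_error(fold_change(0, 1), class = "rr_undefined_baseline")
})

test_that("quantify_assays averages replicates into a tidy trait table", {
  raw <- list(
    halo = data.frame(strain_id = rep("A", 2), assay = "PS_plate",
                      replicate = 1:2, colony_diameter = c(8, 8),
                      total_diameter = c(20, 16)),
    absorbance = data.frame(strain_id = c("A", "B"), assay = "SID",
                            replicate = 1, reference_abs = 0.8,
                            sample_abs = c(0.2, 0.8)),
    colorimetric = data.frame(strain_id = "A", analyte = "IAA",
                              condition = c("optimal", "peg18"),
                              replicate = 1, absorbance = c(0.35, 0.65)),
    standards = data.frame(analyte = "IAA",
                           concentration = c(0, 10, 20),
                           absorbance = c(0.05, 0.35, 0.65)),
    growth = data.frame(strain_id = "A", peg_percent = 24, timepoint_h = 48,
                        replicate = 1:3, od600 = c(0.7, 0.72, 0.74)),
    qualitative = data.frame(strain_id = c("A", "B"), trait = "BF",
                             positive = c(TRUE, FALSE))
  )
  tt <- quantify_assays(raw)
  get <- function(tr, cond = "optimal", strain = "A") {
    tt$value[tt$trait == tr & tt$condition == cond & tt$strain_id == strain]
  }
  expect_equal(get("PS_plate"), mean(c(250, 200)))
  expect_equal(get("SID"), 75)
  expect_equal(get("SID", strain = "B"), 0)
  expect_equal(get("IAA"), 10)          # inverted through the curve
  expect_equal(get("IAA", "peg18"), 20)
  expect_equal(get("DT", "peg24"), 0.72)
  expect_equal(get("BF"), 1)
  expect_equal(get("BF", strain = "B"), 0)
  # replicate SD kept for reporting
  expect_equal(tt$sd[tt$trait == "PS_plate"], sd(c(250, 200)))
  expect_equal(tt$n[tt$trait == "DT"], 3L)
})
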