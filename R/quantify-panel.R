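# Panel-level quantification: raw replicate-level assay tables in, one tidy
# trait table out (strain x trait x condition, replicate mean and SD).
# This is the bridge between bench data (or the synthetic generator) and
# the scoring stage.

#' Quantify a raw assay panel into a tidy trait table
#'
#' Takes replicate-level raw measurement tables and derives one quantitative
#' value per strain, trait and condition: halo indices from plate diameters,
#' percent units from absorbance pairs, concentrations from colorimetric
#' readings via per-analyte standard curves, gravimetric EPS, the 48-h OD600
#' in 24% PEG (drought-tolerance growth, trait `DT`), and 0/1 values for
#' qualitative traits. Triplicate (or any-replicate) measurements are
#' averaged arithmetically; the standard deviation and replicate count are
#' retained so standard errors can be reported.
#'
#' The input is a named list of data frames (any subset may be present):
#' \describe{
#'   \item{halo}{`strain_id`, `assay` (`PS_plate`/`KS`), `replicate`,
#'     `colony_diameter`, `total_diameter` (mm).}
#'   \item{absorbance}{`strain_id`, `assay` (`SID`/`PS_broth`), `replicate`,
#'     `reference_abs`, `sample_abs`.}
#'   \item{colorimetric}{`strain_id`, `analyte` (`NH3`/`IAA`), `condition`,
#'     `replicate`, `absorbance`; quantified against `standards`.}
#'   \item{standards}{`analyte`, `concentration`, `absorbance` calibration
#'     points, one curve per analyte.}
#'   \item{eps}{`strain_id`, `condition`, `replicate`, `eps_g_l`.}
#'   \item{growth}{`strain_id`, `peg_percent`, `timepoint_h`, `replicate`,
#'     `od600`; the `DT` trait is the mean OD600 at `dt_peg`% PEG and
#'     `dt_time` h.}
#'   \item{qualitative}{`strain_id`, `trait` (e.g. `NH4`, `BF`), `positive`
#'     (logical).}
#' }
#'
#' @param raw Named list of raw assay data frames (see Details).
#' @param dt_peg,dt_time PEG concentration (% w/v) and time point (h) that
#'   define the drought-tolerance growth readout. Defaults 24 and 48.
#' @return A tidy data frame with columns `strain_id`, `trait`, `condition`,
#'   `value`, `sd`, `n`. Halo indices and percent units are percentages,
#'   NH3 is mg/L, IAA is ug/mL, EPS is g/L, `DT` is OD600; qualitative
#'   traits are 0/1 with `sd = NA`.
#' @export
quantify_assays <- function(raw, dt_peg = 24, dt_time = 48) {
  stopifnot(is.list(raw))
  out <- list()

  summarize <- function(df, trait, value, condition = "optimal") {
    agg <- stats::aggregate(
      value ~ strain_id + condition,
      data = data.frame(strain_id = df$strain_id,
                        condition = condition,
                        value = value),
      FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
    )
    data.frame(
      strain_id = agg$strain_id,
      trait = trait,
      condition = agg$condition,
      value = agg$value[, "mean"],
      sd = agg$value[, "sd"],
      n = agg$value[, "n"],
      stringsAsFactors = FALSE
    )
  }

  if (!is.null(raw$halo)) {
    check_columns(raw$halo, c("strain_id", "assay", "colony_diameter",
                              "total_diameter"), "halo table")
    idx <- halo_index(raw$halo$colony_diameter, raw$halo$total_diameter)
    for (a in unique(raw$halo$assay)) {
      sel <- raw$halo$assay == a
      out[[length(out) + 1L]] <- summarize(raw$halo[sel, ], a, idx[sel])
    }
  }

  if (!is.null(raw$absorbance)) {
    check_columns(raw$absorbance, c("strain_id", "assay", "reference_abs",
                                    "sample_abs"), "absorbance table")
    pu <- percent_unit(raw$absorbance$reference_abs, raw$absorbance$sample_abs)
    for (a in unique(raw$absorbance$assay)) {
      sel <- raw$absorbance$assay == a
      out[[length(out) + 1L]] <- summarize(raw$absorbance[sel, ], a, pu[sel])
    }
  }

  if (!is.null(raw$colorimetric)) {
    check_columns(raw$colorimetric, c("strain_id", "analyte", "condition",
                                      "absorbance"), "colorimetric table")
    if (is.null(raw$standards)) {
      rr_stop("colorimetric measurements require a `standards` table",
              "rr_schema_error")
    }
    check_columns(raw$standards, c("analyte", "concentration", "absorbance"),
                  "standards table")
    for (a in unique(raw$colorimetric$analyte)) {
      std <- raw$standards[raw$standards$analyte == a, ]
      if (!nrow(std)) {
        rr_stop(sprintf("no standard-curve points for analyte %s", a),
                "rr_schema_error")
      }
      curve <- fit_standard_curve(std$concentration, std$absorbance,
                                  analyte = a)
      sel <- raw$colorimetric$analyte == a
      conc <- quantify_from_curve(raw$colorimetric$absorbance[sel], curve)
      out[[length(out) + 1L]] <- summarize(
        raw$colorimetric[sel, ], a, conc,
        condition = raw$colorimetric$condition[sel]
      )
    }
  }

  if (!is.null(raw$eps)) {
    check_columns(raw$eps, c("strain_id", "condition", "eps_g_l"), "eps table")
    out[[length(out) + 1L]] <- summarize(raw$eps, "EPS", raw$eps$eps_g_l,
                                         condition = raw$eps$condition)
  }

  if (!is.null(raw$growth)) {
    check_columns(raw$growth, c("strain_id", "peg_percent", "timepoint_h",
                                "od600"), "growth table")
    sel <- raw$growth$peg_percent == dt_peg & raw$growth$timepoint_h == dt_time
    if (any(sel)) {
      out[[length(out) + 1L]] <- summarize(raw$growth[sel, ], "DT",
                                           raw$growth$od600[sel],
                                           condition = "peg24")
    }
  }

  if (!is.null(raw$qualitative)) {
    check_columns(raw$qualitative, c("strain_id", "trait", "positive"),
                  "qualitative table")
    q <- raw$qualitative
    out[[length(out) + 1L]] <- data.frame(
      strain_id = q$strain_id,
      trait = q$trait,
      condition = "optimal",
      value = as.numeric(as.logical(q$positive)),
      sd = NA_real_,
      n = 1L,
      stringsAsFactors = FALSE
    )
  }

  if (!length(out)) {
    return(data.frame(strain_id = character(), trait = character(),
                      condition = character(), value = numeric(),
                      sd = numeric(), n = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$strain_id, res$trait, res$condition), ]
  rownames(res) <- NULL
  res
}
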