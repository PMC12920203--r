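# Loaders for the bundled reference tables: the 50-isolate score matrix
# with its category sums, the nine-strain quantitative trait table, the
# pairwise compatibility constraints among the nine, and the PEG
# calibration. Files are verified against packaged MD5 checksums so a
# corrupted install fails loudly instead of silently changing results.

fixture_path <- function(file) {
  system.file("extdata", file, package = "rhizorank", mustWork = TRUE)
}

check_fixture <- function(file) {
  path <- fixture_path(file)
  sums <- utils::read.table(fixture_path("fixtures.md5"),
                            col.names = c("md5", "file"),
                            stringsAsFactors = FALSE)
  want <- sums$md5[sums$file == file]
  if (length(want) == 1 && !identical(unname(tools::md5sum(path)), want)) {
    rr_stop(sprintf("checksum mismatch for bundled table %s", file),
            "rr_integrity_error")
  }
  path
}

#' Reference score table: 50 drought-tolerant isolates
#'
#' The five-level ratio scores of 50 drought-tolerant grapevine rhizosphere
#' isolates across ten traits, with the nutritional (N), drought (D) and
#' total sums and the selection flags of the nine strains carried into the
#' pot experiment. One blank EPS cell (UC4445) is kept as `NA`; three rows
#' were minimally reconciled against their own printed sums (see the
#' packaged `data_quality_notes.md`).
#'
#' @return Data frame with `strain_id`, `taxonomy`, ten trait score
#'   columns, `n_trait`, `d_trait`, `total`, `selected`.
#' @export
ref_score_table <- function() {
  utils::read.delim(check_fixture("isolate_scores.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference quantitative trait table: nine selected strains
#'
#' Quantitative assay values (replicate means and standard errors) for the
#' nine selected strains: PPU and PSI (phosphorus solubilization), SID
#' (percent siderophore units), NH3 (mg/L), KSI, EPS (g/L) and IAA (ug/mL)
#' under optimal conditions and under 18% PEG 6000 osmotic stress, plus
#' qualitative NH4 and biofilm flags. PSI/KSI values are stored verbatim
#' and are known transcription quirks (see `data_quality_notes.md`).
#'
#' @return Data frame, one row per strain.
#' @export
ref_trait_table <- function() {
  utils::read.delim(check_fixture("selected_traits.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference pairwise compatibility constraints
#'
#' Complete symmetric interaction outcomes for the nine selected strains:
#' antagonism of UC4521 toward UC4450, UC4478, UC4490 and UC4439; limited
#' growth of UC4510 with UC4535, UC4553 and UC4449; all other pairs
#' compatible.
#'
#' @return A `compat_matrix` (36 unordered pairs).
#' @export
ref_compatibility <- function() {
  compatibility_matrix(
    utils::read.delim(check_fixture("compatibility_constraints.tsv"),
                      stringsAsFactors = FALSE))
}

#' Reference PEG 6000 / water potential calibration
#'
#' @return Data frame with `peg_percent`, `water_potential_mpa`.
#' @export
ref_peg_calibration <- function() {
  utils::read.delim(check_fixture("peg_calibration.tsv"),
                    stringsAsFactors = FALSE)
}

#' Reference strain exclusions
#'
#' The three high-ranking isolates excluded from selection: two species
#' with clearly associated pathogenicity and one strain too slow-growing
#' for industrial scale-up.
#'
#' @return Data frame with `strain_id`, `reason`.
#' @export
ref_exclusions <- function() {
  data.frame(
    strain_id = c("UC4489", "UC4441", "UC4444"),
    reason = c("pathogenic_species", "pathogenic_species", "slow_growth"),
    stringsAsFactors = FALSE
  )
}
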