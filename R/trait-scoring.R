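# Five-level ratio scoring of quantitative traits, binary scoring of
# qualitative traits, nutritional / drought category aggregation, ranking
# and exclusion-aware selection.

SCORE_LEVELS <- c(0, 0.25, 0.5, 0.75, 1)

#' Default trait catalog
#'
#' The ten traits used in the ranking, each assigned to exactly one
#' category: nutritional (N) traits NH4, KS, PS_plate, PS_broth, SID, NH3;
#' drought-related (D) traits EPS, BF, IAA, DT. `kind` distinguishes
#' quantitative traits (five-level discretization), qualitative traits
#' (binary 0/1) and the PEG growth trait (fixed OD600 window).
#'
#' @return Data frame with columns `trait`, `kind`, `category`.
#' @export
trait_catalog <- function() {
  data.frame(
    trait = c("NH4", "KS", "PS_plate", "PS_broth", "SID", "NH3",
              "EPS", "BF", "IAA", "DT"),
    kind = c("qualitative", "quantitative", "quantitative", "quantitative",
             "quantitative", "quantitative",
             "quantitative", "qualitative", "quantitative", "growth"),
    category = c(rep("N", 6), rep("D", 4)),
    stringsAsFactors = FALSE
  )
}

#' Discretize a quantitative trait into five-level ratio scores
#'
#' The observed range `[min, max]` across strains is split into five
#' equal-width intervals (levels 1..5); level L maps to the ratio score
#' `(L - 1) / 4`, i.e. one of 0, 0.25, 0.5, 0.75, 1. Bins are
#' left-closed/right-open except the last, which is closed, so the maximum
#' always maps to 1. If all strains share one value (degenerate range) they
#' all score 1 when that value is positive and 0 when it is zero: equal
#' producers are not penalized, equal non-producers get no credit.
#'
#' @param values Named numeric vector (names = strain ids) of non-negative
#'   trait values; `NA`s propagate.
#' @param n_levels Number of levels (default 5).
#' @return Named numeric vector of ratio scores in
#'   `{0, 1/(n_levels-1), ..., 1}`.
#' @examples
#' discretize_trait(c(a = 0, b = 1, c = 2, d = 3, e = 4))
#' @export
discretize_trait <- function(values, n_levels = 5) {
  if (!length(values)) return(stats::setNames(numeric(0), character(0)))
  check_numeric(values, "values")
  if (any(values < 0, na.rm = TRUE)) {
    rr_stop("trait values must be >= 0", "rr_invalid_input")
  }
  ok <- !is.na(values)
  if (!any(ok)) return(values)
  lo <- min(values[ok]); hi <- max(values[ok])
  out <- rep(NA_real_, length(values))
  names(out) <- names(values)
  if (hi == lo) {
    out[ok] <- if (hi > 0) 1 else 0
    return(out)
  }
  width <- (hi - lo) / n_levels
  lev <- pmin(floor((values[ok] - lo) / width) + 1L, n_levels)
  out[ok] <- (lev - 1) / (n_levels - 1)
  out
}

#' Score a qualitative (presence/absence) trait
#'
#' @param present Logical vector; `TRUE` -> 1, `FALSE` -> 0. `NA` stays
#'   missing and raises a `rr_missing_score` warning so absent cells are
#'   visible rather than silently zeroed.
#' @return Numeric vector of 0/1 scores (with `NA` for missing).
#' @export
score_qualitative <- function(present) {
  if (!is.logical(present)) {
    if (is.numeric(present) && all(present %in% c(0, 1, NA))) {
      present <- as.logical(present)
    } else {
      rr_stop("qualitative results must be logical (or 0/1)",
              "rr_invalid_input")
    }
  }
  if (anyNA(present)) {
    rr_warn("missing qualitative result(s); cells left missing",
            "rr_missing_score")
  }
  as.numeric(present)
}

#' Score growth under 24% PEG into the drought-tolerance (DT) levels
#'
#' Only strains that passed the drought pre-screen (OD600 > 0.5 at 48 h in
#' 24% PEG) are scored; their ODs span the fixed window 0.51 to 1.00, which
#' is split into five equal levels (bin width 0.098, last bin closed,
#' values above 1.00 clamp to level 5).
#'
#' @param od600 OD600 at 48 h in 24% PEG, must be > 0.5 (pre-screened).
#' @param window Lower and upper OD600 bounds of the scoring window.
#' @return Ratio scores in `{0, 0.25, 0.5, 0.75, 1}`.
#' @examples
#' score_drought_growth(c(0.51, 0.755, 1.0))
#' @export
score_drought_growth <- function(od600, window = c(0.51, 1.00)) {
  check_numeric(od600, "od600")
  out <- rep(NA_real_, length(od600))
  ok <- !is.na(od600)
  if (any(od600[ok] <= 0.5)) {
    rr_stop("OD600 <= 0.5 should have been removed by the drought pre-screen",
            "rr_filter_violation")
  }
  width <- (window[2] - window[1]) / 5
  lev <- pmin(floor((od600[ok] - window[1]) / width) + 1L, 5L)
  lev[od600[ok] < window[1]] <- 1L  # below-window ODs (0.5 < x < 0.51)
  out[ok] <- (lev - 1) / 4
  names(out) <- names(od600)
  out
}

#' Build a score matrix from a tidy trait table
#'
#' Applies the scoring rule of each trait in the catalog: quantitative
#' traits are discretized over the strains present (optimal-condition
#' values), qualitative traits become 0/1, and `DT` uses the fixed
#' 0.51-1.00 OD600 window. Traits absent from the table are skipped.
#'
#' @param trait_table Tidy table from [quantify_assays()] (columns
#'   `strain_id`, `trait`, `condition`, `value`).
#' @param catalog Trait catalog; defaults to [trait_catalog()].
#' @return Data frame, one row per strain (`strain_id` column) and one
#'   column per scored trait, cells in `{0, 0.25, 0.5, 0.75, 1}` or `NA`.
#' @export
build_score_matrix <- function(trait_table, catalog = trait_catalog()) {
  check_columns(trait_table, c("strain_id", "trait", "condition", "value"),
                "trait table")
  strains <- sort(unique(trait_table$strain_id))
  scores <- data.frame(strain_id = strains, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(catalog))) {
    tr <- catalog$trait[i]
    cond <- if (catalog$kind[i] == "growth") "peg24" else "optimal"
    sub <- trait_table[trait_table$trait == tr & trait_table$condition == cond, ]
    if (!nrow(sub)) next
    v <- stats::setNames(rep(NA_real_, length(strains)), strains)
    v[sub$strain_id] <- sub$value
    sc <- switch(catalog$kind[i],
      quantitative = discretize_trait(v),
      qualitative = stats::setNames(score_qualitative(v > 0), names(v)),
      growth = score_drought_growth(v)
    )
    scores[[tr]] <- unname(sc[scores$strain_id])
  }
  scores
}

#' Aggregate per-trait scores into N, D and total sums
#'
#' Sums each strain's scores over the nutritional (N) and drought-related
#' (D) trait categories. Missing cells contribute 0 to the sums but raise a
#' single completeness warning naming the affected strains, mirroring how a
#' blank assay cell is handled in the reference ranking.
#'
#' @param score_matrix Data frame from [build_score_matrix()] (or a
#'   transcribed score table): `strain_id` plus per-trait score columns.
#' @param catalog Trait catalog; every score column must appear in it.
#' @return Data frame with columns `strain_id`, `n_score`, `d_score`,
#'   `total_score`.
#' @export
aggregate_scores <- function(score_matrix, catalog = trait_catalog()) {
  check_columns(score_matrix, "strain_id", "score matrix")
  trait_cols <- setdiff(names(score_matrix), c("strain_id", "taxonomy"))
  unknown <- setdiff(trait_cols, catalog$trait)
  if (length(unknown)) {
    rr_stop(sprintf("trait column(s) not in catalog: %s",
                    paste(unknown, collapse = ", ")), "rr_catalog_error")
  }
  bad <- vapply(trait_cols, function(tc) {
    v <- score_matrix[[tc]]
    v <- v[!is.na(v)]
    length(v) && any(vapply(v, function(x) min(abs(x - SCORE_LEVELS)) > 1e-9,
                            logical(1)))
  }, logical(1))
  if (any(bad)) {
    rr_stop(sprintf("non five-level score values in column(s): %s",
                    paste(trait_cols[bad], collapse = ", ")),
            "rr_invalid_input")
  }
  if (anyNA(score_matrix[trait_cols])) {
    miss <- score_matrix$strain_id[apply(is.na(score_matrix[trait_cols]), 1, any)]
    rr_warn(sprintf("missing score cell(s) for strain(s) %s treated as contributing 0",
                    paste(miss, collapse = ", ")), "rr_completeness")
  }
  sum_cat <- function(cat) {
    cols <- intersect(catalog$trait[catalog$category == cat], trait_cols)
    if (!length(cols)) return(rep(0, nrow(score_matrix)))
    rowSums(score_matrix[cols], na.rm = TRUE)
  }
  data.frame(
    strain_id = score_matrix$strain_id,
    n_score = sum_cat("N"),
    d_score = sum_cat("D"),
    total_score = sum_cat("N") + sum_cat("D"),
    stringsAsFactors = FALSE
  )
}

#' Rank strains by aggregated scores
#'
#' Deterministic total order: descending total score, ties broken by
#' descending N score, then descending D score, then ascending strain id.
#' Re-running on a permuted input yields the identical order.
#'
#' @param records Data frame from [aggregate_scores()].
#' @return The same data frame sorted, with a 1-based `rank` column added.
#' @export
rank_strains <- function(records) {
  if (!nrow(records)) {
    records$rank <- integer(0)
    return(records)
  }
  check_columns(records, c("strain_id", "n_score", "d_score", "total_score"),
                "rank records")
  ord <- order(-records$total_score, -records$n_score, -records$d_score,
               records$strain_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select top strains while skipping excluded ones
#'
#' Walks the ranking top-down, skipping strains flagged as excluded (e.g.
#' species with known pathogenic potential, or strains too slow-growing for
#' industrial scale-up), until `n_select` strains are chosen.
#'
#' @param ranked Ranked data frame from [rank_strains()].
#' @param exclusions Named character vector or data frame
#'   (`strain_id`, `reason`) of strains to skip.
#' @param n_select Number of strains to select (default 9).
#' @return List with `selected` (character vector, ranking order) and
#'   `skipped` (data frame of skipped strains with reasons and ranks).
#' @export
apply_exclusions <- function(ranked, exclusions = NULL, n_select = 9) {
  check_columns(ranked, c("strain_id", "rank"), "ranked table")
  if (is.data.frame(exclusions)) {
    check_columns(exclusions, c("strain_id", "reason"), "exclusion table")
    excl <- stats::setNames(exclusions$reason, exclusions$strain_id)
  } else if (is.null(exclusions)) {
    excl <- character(0)
  } else {
    excl <- exclusions
    if (is.null(names(excl))) {
      excl <- stats::setNames(rep("excluded", length(exclusions)), exclusions)
    }
  }
  if (n_select == 0) {
    return(list(selected = character(0),
                skipped = data.frame(strain_id = character(),
                                     reason = character(), rank = integer())))
  }
  eligible <- !(ranked$strain_id %in% names(excl))
  if (sum(eligible) < n_select) {
    rr_stop(sprintf("only %d non-excluded strains available, %d requested",
                    sum(eligible), n_select), "rr_insufficient_candidates")
  }
  sel <- ranked$strain_id[eligible][seq_len(n_select)]
  last_rank <- ranked$rank[match(sel[n_select], ranked$strain_id)]
  skip <- ranked$strain_id[!eligible & ranked$rank < last_rank]
  list(
    selected = sel,
    skipped = data.frame(
      strain_id = skip,
      reason = unname(excl[skip]),
      rank = ranked$rank[match(skip, ranked$strain_id)],
      stringsAsFactors = FALSE
    )
  )
}
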