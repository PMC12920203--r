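# Compatibility-constrained consortium assembly: strains are combined to
# maximize the number of traits covered at the highest expression level,
# never placing an antagonistic (inhibition halo in co-culture) or
# limited-growth pair in the same consortium.

COMPAT_OUTCOMES <- c("compatible", "antagonistic", "limited_growth")

#' Build a pairwise compatibility table
#'
#' Normalizes a long table of pairwise interaction outcomes into a
#' canonical symmetric form: unordered pairs stored once with
#' `strain_a < strain_b`, outcomes one of `compatible`, `antagonistic`,
#' `limited_growth`. Conflicting duplicate entries for the same pair are an
#' error; self-pairs are dropped.
#'
#' @param pairs Data frame with columns `strain_a`, `strain_b`, `outcome`.
#' @return Data frame of class `compat_matrix`.
#' @export
compatibility_matrix <- function(pairs) {
  check_columns(pairs, c("strain_a", "strain_b", "outcome"),
                "compatibility table")
  if (!all(pairs$outcome %in% COMPAT_OUTCOMES)) {
    rr_stop(sprintf("outcomes must be one of: %s",
                    paste(COMPAT_OUTCOMES, collapse = ", ")),
            "rr_invalid_input")
  }
  a <- pmin(pairs$strain_a, pairs$strain_b)
  b <- pmax(pairs$strain_a, pairs$strain_b)
  keep <- a != b
  df <- unique(data.frame(strain_a = a[keep], strain_b = b[keep],
                          outcome = pairs$outcome[keep],
                          stringsAsFactors = FALSE))
  key <- paste(df$strain_a, df$strain_b)
  if (anyDuplicated(key)) {
    rr_stop(sprintf("conflicting outcomes for pair(s): %s",
                    paste(unique(key[duplicated(key)]), collapse = "; ")),
            "rr_invalid_input")
  }
  df <- df[order(df$strain_a, df$strain_b), ]
  rownames(df) <- NULL
  class(df) <- c("compat_matrix", "data.frame")
  df
}

#' Look up pairwise outcomes
#'
#' @param matrix A `compat_matrix`.
#' @param strain_a,strain_b Strain ids (vectorized). Order does not matter.
#' @param missing What to return for pairs absent from the matrix:
#'   `"error"` (default) raises an incomplete-matrix error, otherwise the
#'   given value (e.g. `"compatible"`) is used.
#' @return Character vector of outcomes.
#' @export
pair_outcome <- function(matrix, strain_a, strain_b, missing = "error") {
  a <- pmin(strain_a, strain_b)
  b <- pmax(strain_a, strain_b)
  idx <- match(paste(a, b), paste(matrix$strain_a, matrix$strain_b))
  out <- matrix$outcome[idx]
  if (anyNA(out)) {
    if (identical(missing, "error")) {
      bad <- paste(a[is.na(out)], b[is.na(out)], sep = " / ")
      rr_stop(sprintf("pair(s) missing from compatibility matrix: %s",
                      paste(unique(bad), collapse = "; ")),
              "rr_incomplete_matrix")
    }
    out[is.na(out)] <- missing
  }
  out
}

#' Validate a candidate consortium against the compatibility matrix
#'
#' A consortium is valid iff no member pair is antagonistic or shows
#' limited growth in co-culture. Limited growth is treated as a hard
#' exclusion like antagonism: the reference workflow also kept such strains
#' in separate consortia.
#'
#' @param members Character vector of strain ids.
#' @param matrix A `compat_matrix` covering all member pairs.
#' @return List with `valid` (logical) and `violations` (data frame of
#'   offending pairs and outcomes; empty when valid).
#' @export
validate_consortium <- function(members, matrix) {
  members <- sort(unique(members))
  if (length(members) < 2) {
    return(list(valid = TRUE,
                violations = data.frame(strain_a = character(),
                                        strain_b = character(),
                                        outcome = character())))
  }
  pr <- utils::combn(members, 2)
  outcome <- pair_outcome(matrix, pr[1, ], pr[2, ])
  bad <- outcome != "compatible"
  list(
    valid = !any(bad),
    violations = data.frame(strain_a = pr[1, bad], strain_b = pr[2, bad],
                            outcome = outcome[bad], stringsAsFactors = FALSE)
  )
}

#' Traits covered by a strain set
#'
#' A trait is covered when at least one member expresses it at or above
#' `threshold` on the ratio-score scale; the default 1.0 counts only
#' level-5 expression, matching how consortium trait coverage is usually
#' displayed.
#'
#' @param members Character vector of strain ids.
#' @param scores Score matrix (`strain_id` + per-trait score columns).
#' @param threshold Minimum score for a trait to count as covered.
#' @return Character vector of covered trait names (catalog order).
#' @export
trait_coverage <- function(members, scores, threshold = 1.0) {
  if (!length(members)) return(character(0))
  check_columns(scores, "strain_id", "score matrix")
  missing <- setdiff(members, scores$strain_id)
  if (length(missing)) {
    rr_stop(sprintf("strain(s) absent from score matrix: %s",
                    paste(missing, collapse = ", ")), "rr_lookup_error")
  }
  trait_cols <- setdiff(names(scores), c("strain_id", "taxonomy"))
  rows <- scores[scores$strain_id %in% members, trait_cols, drop = FALSE]
  covered <- vapply(rows, function(v) any(!is.na(v) & v >= threshold),
                    logical(1))
  trait_cols[covered]
}

# Objective for a candidate set: covered-trait count plus an optional bonus
# per member pair sharing an origin cultivar.
consortium_objective <- function(members, scores, threshold, origin,
                                 origin_bonus) {
  cov <- length(trait_coverage(members, scores, threshold))
  bonus <- 0
  if (origin_bonus > 0 && !is.null(origin) && length(members) >= 2) {
    o <- origin[members]
    pr <- utils::combn(o, 2)
    bonus <- origin_bonus * sum(!is.na(pr[1, ]) & pr[1, ] == pr[2, ])
  }
  cov + bonus
}

#' Assemble consortia under compatibility constraints
#'
#' Builds `n_consortia` strain sets from the candidate pool, maximizing
#' trait coverage (number of traits expressed at `threshold` by at least
#' one member, plus `origin_bonus` per member pair sharing an origin
#' cultivar) while never placing an antagonistic or limited-growth pair in
#' the same consortium. Strains may appear in more than one consortium.
#'
#' Two solvers: `"greedy"` grows one candidate set from every seed strain,
#' always adding the compatible candidate with the largest objective gain
#' (ties broken lexicographically by strain id), and returns the
#' `n_consortia` grown sets with the highest objectives;
#' `"exact"` enumerates every valid subset with size in `size_range` and
#' returns the top `n_consortia` distinct subsets by objective. Exact mode
#' is intended for small pools (it enumerates subsets).
#'
#' @param candidates Character vector of candidate strain ids.
#' @param scores Score matrix covering the candidates.
#' @param matrix `compat_matrix` covering all candidate pairs.
#' @param n_consortia Number of consortia to build.
#' @param size_range Length-2 integer vector `c(min, max)` members.
#' @param origin Optional named character vector strain -> origin cultivar.
#' @param origin_bonus Objective bonus per shared-origin member pair
#'   (default 0.01: a tie-break, never outweighing a covered trait).
#' @param threshold Coverage score threshold (default 1.0 = level 5).
#' @param method `"greedy"` or `"exact"`.
#' @return List of consortium plans, each a list with `consortium_id`,
#'   `members`, `covered_traits`, `coverage_count`, `objective`.
#' @export
assemble_consortia <- function(candidates, scores, matrix,
                               n_consortia = 4, size_range = c(2, 4),
                               origin = NULL, origin_bonus = 0.01,
                               threshold = 1.0,
                               method = c("greedy", "exact")) {
  method <- match.arg(method)
  candidates <- sort(unique(candidates))
  if (n_consortia == 0) return(list())
  if (length(candidates) < size_range[1]) {
    rr_stop("fewer candidates than the minimum consortium size",
            "rr_infeasible")
  }
  obj <- function(m) consortium_objective(m, scores, threshold, origin,
                                          origin_bonus)
  compatible_with <- function(set, s) {
    all(pair_outcome(matrix, rep(s, length(set)), set) == "compatible")
  }

  plans <- if (method == "exact") {
    all_sets <- list()
    for (k in seq(size_range[1], size_range[2])) {
      if (k > length(candidates)) break
      sets <- utils::combn(candidates, k, simplify = FALSE)
      ok <- vapply(sets, function(s) validate_consortium(s, matrix)$valid,
                   logical(1))
      all_sets <- c(all_sets, sets[ok])
    }
    if (!length(all_sets)) {
      rr_stop("no valid consortium of the requested size exists (incompatibility constraints)",
              "rr_infeasible")
    }
    vals <- vapply(all_sets, obj, numeric(1))
    keys <- vapply(all_sets, paste, character(1), collapse = "|")
    ord <- order(-vals, keys)
    all_sets[ord][seq_len(min(n_consortia, length(all_sets)))]
  } else {
    # Greedy: one consortium per seed strain, seeds taken in order of the
    # singleton objective so distinct consortia start from distinct anchors.
    seed_ord <- candidates[order(-vapply(candidates, function(s) obj(s),
                                         numeric(1)), candidates)]
    built <- list()
    for (seed in seed_ord) {
      set <- seed
      repeat {
        if (length(set) >= size_range[2]) break
        pool <- setdiff(candidates, set)
        pool <- pool[vapply(pool, function(s) compatible_with(set, s),
                            logical(1))]
        if (!length(pool)) break
        gains <- vapply(pool, function(s) obj(c(set, s)), numeric(1))
        best <- pool[order(-gains, pool)][1]
        if (length(set) >= size_range[1] && gains[match(best, pool)] <= obj(set)) break
        set <- sort(c(set, best))
      }
      if (length(set) >= size_range[1] &&
          !any(vapply(built, identical, logical(1), set))) {
        built[[length(built) + 1L]] <- set
      }
    }
    if (!length(built)) {
      rr_stop("no valid consortium of the requested size could be grown (incompatibility constraints)",
              "rr_infeasible")
    }
    # best-of-seeds: order grown sets by objective, ties lexicographic
    vals <- vapply(built, obj, numeric(1))
    keys <- vapply(built, paste, character(1), collapse = "|")
    built <- built[order(-vals, keys)]
    built[seq_len(min(n_consortia, length(built)))]
  }

  lapply(seq_along(plans), function(i) {
    m <- sort(plans[[i]])
    cov <- trait_coverage(m, scores, threshold)
    list(consortium_id = sprintf("BC%d", i),
         members = m,
         covered_traits = cov,
         coverage_count = length(cov),
         objective = obj(m))
  })
}

#' Tabulate consortium plans for reporting
#'
#' Flattens a list of plans (from [assemble_consortia()]) into one row per
#' consortium with comma-separated member and trait lists.
#'
#' @param plans List of consortium plans.
#' @return Data frame with columns `consortium_id`, `members`,
#'   `coverage_count`, `covered_traits`.
#' @export
consortium_sheet <- function(plans) {
  data.frame(
    consortium_id = vapply(plans, `[[`, character(1), "consortium_id"),
    members = vapply(plans, function(p) paste(p$members, collapse = ","),
                     character(1)),
    coverage_count = vapply(plans, `[[`, numeric(1), "coverage_count"),
    covered_traits = vapply(plans, function(p)
      paste(p$covered_traits, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Coverage grid of consortium members by trait
#'
#' A strain-by-trait 0/1 grid (1 = trait expressed at the coverage
#' threshold) for one consortium, the plain-text analogue of a coverage
#' heatmap figure.
#'
#' @param plan One consortium plan.
#' @param scores Score matrix.
#' @param threshold Coverage threshold (default 1.0).
#' @return Data frame: `strain_id` plus one 0/1 column per trait.
#' @export
coverage_grid <- function(plan, scores, threshold = 1.0) {
  trait_cols <- setdiff(names(scores), c("strain_id", "taxonomy"))
  rows <- scores[match(plan$members, scores$strain_id), , drop = FALSE]
  grid <- data.frame(strain_id = plan$members, stringsAsFactors = FALSE)
  for (tc in trait_cols) {
    grid[[tc]] <- as.integer(!is.na(rows[[tc]]) & rows[[tc]] >= threshold)
  }
  grid
}
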