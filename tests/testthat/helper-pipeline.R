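# Shared helpers: run the synthetic panel through the full scoring
# pipeline, and an independent brute-force consortium oracle used to check
# the exact solver.

# Raw panel -> ranked table, applying the drought pre-screen (only strains
# with mean OD600 > 0.5 at 48 h in 24% PEG are scored).
rank_synthetic_panel <- function(panel) {
  tt <- suppressWarnings(quantify_assays(panel$raw))
  dt <- tt[tt$trait == "DT", ]
  keep <- dt$strain_id[dt$value > 0.5]
  sm <- suppressWarnings(build_score_matrix(tt[tt$strain_id %in% keep, ]))
  rank_strains(suppressWarnings(aggregate_scores(sm)))
}

# Independent brute-force maximum-coverage oracle: enumerates every subset
# of the given sizes with nested combn loops, drops invalid ones by direct
# pair lookup in the long table (no package lookup helpers), and returns
# the best objective found.
brute_force_best_coverage <- function(candidates, scores, compat_df,
                                      size_range, threshold = 1.0) {
  trait_cols <- setdiff(names(scores), c("strain_id", "taxonomy"))
  bad_pairs <- compat_df[compat_df$outcome != "compatible", , drop = FALSE]
  bad_key <- c(paste(bad_pairs$strain_a, bad_pairs$strain_b),
               paste(bad_pairs$strain_b, bad_pairs$strain_a))
  best <- -Inf
  for (k in seq(size_range[1], min(size_range[2], length(candidates)))) {
    sets <- utils::combn(candidates, k, simplify = FALSE)
    for (s in sets) {
      ok <- TRUE
      if (length(s) > 1) {
        pr <- utils::combn(s, 2)
        for (j in seq_len(ncol(pr))) {
          if (paste(pr[1, j], pr[2, j]) %in% bad_key) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      rows <- scores[scores$strain_id %in% s, trait_cols, drop = FALSE]
      cov <- sum(vapply(rows, function(v) any(!is.na(v) & v >= threshold),
                        logical(1)))
      if (cov > best) best <- cov
    }
  }
  best
}

# Small random instance for consortium solver tests.
random_consortium_instance <- function(n_strains, n_traits, p_bad, seed) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n_strains))
  scores <- data.frame(strain_id = ids, stringsAsFactors = FALSE)
  for (t in seq_len(n_traits)) {
    scores[[paste0("T", t)]] <- sample(c(0, 0.25, 0.5, 0.75, 1), n_strains,
                                       replace = TRUE)
  }
  pr <- utils::combn(ids, 2)
  compat <- compatibility_matrix(data.frame(
    strain_a = pr[1, ], strain_b = pr[2, ],
    outcome = ifelse(stats::runif(ncol(pr)) < p_bad, "antagonistic",
                     "compatible"),
    stringsAsFactors = FALSE
  ))
  list(ids = ids, scores = scores, compat = compat)
}
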