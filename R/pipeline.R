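# End-to-end pipeline: quantify -> score -> rank -> select -> design
# (-> biosafety), driven by a single structured configuration, writing CSV
# stage outputs plus a machine-readable run manifest. Identical config and
# inputs give identical outputs.

#' Default pipeline configuration
#'
#' Returns the full default configuration as a named list; any subset can
#' be overridden via `pipeline_config()` or a YAML file. Paths are `NULL`
#' by default, meaning the bundled reference tables (score matrix,
#' exclusions, compatibility) are used.
#'
#' @return Named list of configuration defaults.
#' @export
default_config <- function() {
  list(
    score_table = NULL,      # path to a pre-scored matrix CSV/TSV, or NULL = bundled
    trait_table = NULL,      # path to a tidy trait table to score from raw values
    compatibility = NULL,    # path to a compatibility CSV/TSV, or NULL = bundled
    exclusions = NULL,       # path to an exclusion CSV, or NULL = bundled
    hit_table = NULL,        # optional ABRicate-style TSV for biosafety
    n_select = 9,
    n_consortia = 4,
    size_range = c(2, 4),
    origin_bonus = 0.01,
    coverage_threshold = 1.0,
    assembly_method = "greedy",
    identity_min = 80,
    coverage_min = 70,
    seed = 1,
    out_dir = NULL
  )
}

#' Build a pipeline configuration
#'
#' Merges defaults, an optional YAML config file, and direct overrides
#' (highest precedence), validating parameter ranges.
#'
#' @param file Optional YAML file of settings.
#' @param ... Direct overrides of [default_config()] entries.
#' @return Named list of validated settings.
#' @export
pipeline_config <- function(file = NULL, ...) {
  cfg <- default_config()
  if (!is.null(file)) {
    if (!file.exists(file)) {
      rr_stop(sprintf("config file not found: %s", file), "rr_config_error")
    }
    over <- yaml::read_yaml(file)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      rr_stop(sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")), "rr_config_error")
    }
    cfg[names(over)] <- over
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    rr_stop(sprintf("unknown config key(s): %s",
                    paste(unknown, collapse = ", ")), "rr_config_error")
  }
  cfg[names(dots)] <- dots
  for (p in c("score_table", "trait_table", "compatibility", "exclusions",
              "hit_table")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      rr_stop(sprintf("configured input `%s` does not exist: %s", p, cfg[[p]]),
              "rr_config_error")
    }
  }
  if (cfg$n_select < 0 || cfg$n_consortia < 0 ||
      length(cfg$size_range) != 2 || cfg$size_range[1] > cfg$size_range[2]) {
    rr_stop("selection/assembly parameters out of range", "rr_config_error")
  }
  cfg
}

read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Run the full prioritization pipeline
#'
#' Executes the staged workflow: obtain a score matrix (from a tidy trait
#' table via [build_score_matrix()], from a pre-scored file, or from the
#' bundled reference table), aggregate N/D/total scores, rank, select the
#' top `n_select` strains past the exclusion list, assemble compatible
#' consortia, and (when a hit table is configured) filter and summarize
#' biosafety hits. When `out_dir` is set, every stage output is written as
#' CSV alongside a JSON run manifest listing inputs, parameters and output
#' checksums.
#'
#' @param config A configuration list from [pipeline_config()].
#' @return List with `scores`, `ranked` (scores + taxonomy + rank columns),
#'   `selection` (list from [apply_exclusions()]), `plans`,
#'   `consortia` (sheet), `biosafety` (or `NULL`), `warnings` (data-quality
#'   messages collected during the run) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  logged <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, rhizorank_warning = function(w) {
      logged <<- c(logged, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # --- scores -----------------------------------------------------------
  taxonomy <- NULL
  if (!is.null(config$trait_table)) {
    trait_table <- read_table_auto(config$trait_table)
    scores <- collect(build_score_matrix(trait_table))
    agg_input <- scores
  } else {
    tab <- if (!is.null(config$score_table)) {
      read_table_auto(config$score_table)
    } else {
      ref_score_table()
    }
    taxonomy <- tab[intersect(c("strain_id", "taxonomy"), names(tab))]
    scores <- tab[setdiff(names(tab),
                          c("taxonomy", "n_trait", "d_trait", "total",
                            "selected"))]
    agg_input <- scores
  }

  ranked <- rank_strains(collect(aggregate_scores(agg_input)))
  if (!is.null(taxonomy) && "taxonomy" %in% names(taxonomy)) {
    ranked$taxonomy <- taxonomy$taxonomy[match(ranked$strain_id,
                                               taxonomy$strain_id)]
  }

  # --- selection --------------------------------------------------------
  exclusions <- if (!is.null(config$exclusions)) {
    read_table_auto(config$exclusions)
  } else {
    ref_exclusions()
  }
  selection <- apply_exclusions(ranked, exclusions, config$n_select)

  # --- consortium design ------------------------------------------------
  plans <- NULL
  if (config$n_consortia > 0 && length(selection$selected)) {
    compat <- if (!is.null(config$compatibility)) {
      compatibility_matrix(read_table_auto(config$compatibility))
    } else {
      ref_compatibility()
    }
    missing_pairs <- setdiff(selection$selected,
                             unique(c(compat$strain_a, compat$strain_b)))
    if (length(missing_pairs)) {
      rr_stop(sprintf("compatibility table lacks entries for: %s",
                      paste(missing_pairs, collapse = ", ")),
              "rr_config_error")
    }
    plans <- assemble_consortia(
      selection$selected, scores, compat,
      n_consortia = config$n_consortia,
      size_range = config$size_range,
      origin_bonus = config$origin_bonus,
      threshold = config$coverage_threshold,
      method = config$assembly_method
    )
  }

  # --- biosafety --------------------------------------------------------
  biosafety <- NULL
  if (!is.null(config$hit_table)) {
    hits <- read_hit_table(config$hit_table)
    retained <- filter_hits(hits, config$identity_min, config$coverage_min)
    biosafety <- summarize_biosafety(retained)
  }

  result <- list(scores = scores, ranked = ranked, selection = selection,
                 plans = plans,
                 consortia = if (!is.null(plans)) consortium_sheet(plans),
                 biosafety = biosafety, warnings = logged, manifest = NULL)

  # --- outputs + manifest ----------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    outputs <- list(
      ranked = ranked,
      selected = data.frame(strain_id = selection$selected,
                            order = seq_along(selection$selected)),
      skipped = selection$skipped
    )
    if (!is.null(result$consortia)) outputs$consortia <- result$consortia
    if (!is.null(biosafety)) outputs$biosafety_counts <- biosafety$counts
    files <- character(0)
    for (nm in names(outputs)) {
      f <- file.path(config$out_dir, paste0(nm, ".csv"))
      utils::write.csv(outputs[[nm]], f, row.names = FALSE)
      files[nm] <- f
    }
    manifest <- list(
      parameters = config[setdiff(names(config), "out_dir")],
      inputs = Filter(Negate(is.null),
                      config[c("score_table", "trait_table", "compatibility",
                               "exclusions", "hit_table")]),
      outputs = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))),
      warnings = logged
    )
    mf <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    result$manifest <- manifest
  }
  result
}
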