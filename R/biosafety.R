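# Biosafety screening of AMR / virulence-factor hit tables: threshold
# filtering per EFSA-style retention rules (identity >= 80%, coverage
# >= 70%) and per-strain categorized summaries.

#' Read an ABRicate-style hit table
#'
#' Reads a tab-separated hit table and normalizes common column aliases to
#' the canonical names `strain_id`, `gene`, `database`, `percent_identity`,
#' `percent_coverage`, `product`, `contig`. Accepts one file per strain
#' (pass `strain_id` explicitly) or a concatenated table with a strain
#' column (`#FILE`, `FILE`, `strain`, `strain_id`).
#'
#' @param path Path to a TSV hit table with a header.
#' @param strain_id Optional strain id applied to all rows (per-strain
#'   files).
#' @return Data frame of hit records.
#' @export
read_hit_table <- function(path, strain_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  aliases <- list(
    strain_id = c("strain_id", "strain", "#FILE", "FILE", "X.FILE"),
    gene = c("gene", "GENE"),
    database = c("database", "DATABASE", "db"),
    percent_identity = c("percent_identity", "%IDENTITY", "identity",
                         "X.IDENTITY", "pident"),
    percent_coverage = c("percent_coverage", "%COVERAGE", "coverage",
                         "X.COVERAGE", "pcov"),
    product = c("product", "PRODUCT"),
    contig = c("contig", "SEQUENCE", "sequence")
  )
  out <- data.frame(row = seq_len(nrow(df)))
  for (canon in names(aliases)) {
    hit <- intersect(aliases[[canon]], names(df))
    out[[canon]] <- if (length(hit)) df[[hit[1]]] else NA
  }
  out$row <- NULL
  if (!is.null(strain_id)) out$strain_id <- strain_id
  if (all(is.na(out$gene))) {
    rr_stop(sprintf("no gene column found in %s", path), "rr_schema_error")
  }
  for (col in c("percent_identity", "percent_coverage")) {
    v <- suppressWarnings(as.numeric(gsub("%", "", out[[col]])))
    bad <- which(is.na(v) & !is.na(out[[col]]))
    if (length(bad)) {
      rr_stop(sprintf("malformed %s in %s at row(s) %s", col, path,
                      paste(bad, collapse = ", ")), "rr_parse_error")
    }
    out[[col]] <- v
  }
  out
}

#' Filter hits by identity and coverage thresholds
#'
#' Retains only hits with `percent_identity >= identity_min` AND
#' `percent_coverage >= coverage_min`; both comparisons inclusive, per the
#' usual genome-screening retention rule (>= 80% identity, >= 70%
#' coverage).
#'
#' @param hits Data frame of hit records (see [read_hit_table()]).
#' @param identity_min,coverage_min Retention thresholds in percent.
#' @return The retained subset of `hits` (same columns).
#' @export
filter_hits <- function(hits, identity_min = 80, coverage_min = 70) {
  check_columns(hits, c("percent_identity", "percent_coverage"), "hit table")
  for (col in c("percent_identity", "percent_coverage")) {
    v <- hits[[col]]
    if (!is.numeric(v) || any(!is.na(v) & (v < 0 | v > 100))) {
      rr_stop(sprintf("%s must be numeric within [0, 100]", col),
              "rr_parse_error")
    }
  }
  keep <- !is.na(hits$percent_identity) & !is.na(hits$percent_coverage) &
    hits$percent_identity >= identity_min &
    hits$percent_coverage >= coverage_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default gene-category map
#'
#' Prefix-matching map from gene symbols to biosafety categories, seeded
#' with the gene families commonly reported in rhizobacterial genome
#' screens: efflux systems (mex/opr/acr/oqx/mdt/opm), beta-lactamases
#' (bla), fosfomycin resistance (fos), global regulators, and VF classes
#' for motility (fli/flg), secretion systems (vip/hcp/clpV), biofilm
#' (alg/pil/waa), adhesion (csg), membrane (omp) and siderophore (ent/pvd)
#' genes. Editable: pass your own table with the same columns.
#'
#' @return Data frame with columns `prefix`, `class` (`AMR`/`VF`),
#'   `category`.
#' @export
default_gene_categories <- function() {
  path <- system.file("extdata", "gene_categories.csv",
                      package = "rhizorank", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Longest-prefix, case-insensitive category lookup for one class.
match_category <- function(genes, map) {
  vapply(genes, function(g) {
    gl <- tolower(g)
    hits <- map[startsWith(gl, tolower(map$prefix)), , drop = FALSE]
    if (!nrow(hits)) return(NA_character_)
    hits$category[order(-nchar(hits$prefix))][1]
  }, character(1), USE.NAMES = FALSE)
}

#' Summarize retained biosafety hits per strain
#'
#' Categorizes already-filtered hits by gene family and tallies them per
#' strain and category. Hits from the VFDB database are virulence factors,
#' all others count as AMR. Genes with no category-map match fall into
#' `AMR-other` / `VF-other` and are listed in the `uncategorized` note.
#'
#' @param retained Filtered hit table (from [filter_hits()]) with columns
#'   `strain_id`, `gene`, `database`.
#' @param category_map Gene-category map; defaults to
#'   [default_gene_categories()].
#' @return List with `counts` (data frame strain_id x category columns,
#'   plus `total`), `hits` (the input with a `category` column added) and
#'   `uncategorized` (character vector of unmatched gene symbols).
#' @export
summarize_biosafety <- function(retained, category_map = default_gene_categories()) {
  check_columns(retained, c("strain_id", "gene", "database"), "hit table")
  check_columns(category_map, c("prefix", "class", "category"),
                "category map")
  cls <- ifelse(tolower(retained$database) == "vfdb", "VF", "AMR")
  cat <- rep(NA_character_, nrow(retained))
  for (cl in c("AMR", "VF")) {
    sel <- cls == cl
    if (any(sel)) {
      cat[sel] <- match_category(retained$gene[sel],
                                 category_map[category_map$class == cl, ])
    }
  }
  uncategorized <- sort(unique(retained$gene[is.na(cat)]))
  cat[is.na(cat)] <- "other"
  full <- paste(cls, cat, sep = "-")
  retained$category <- full

  strains <- sort(unique(retained$strain_id))
  cats <- sort(unique(full))
  counts <- data.frame(strain_id = strains, stringsAsFactors = FALSE)
  for (cc in cats) {
    counts[[cc]] <- vapply(strains, function(s)
      sum(retained$strain_id == s & full == cc), integer(1), USE.NAMES = FALSE)
  }
  counts$total <- vapply(strains, function(s) sum(retained$strain_id == s),
                         integer(1), USE.NAMES = FALSE)
  list(counts = counts, hits = retained, uncategorized = uncategorized)
}
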