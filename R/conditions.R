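# Classed conditions used throughout the package so callers can
# distinguish data problems (bad measurements, degenerate curves, infeasible
# designs) from programming errors and handle them selectively.

rr_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "rhizorank_error")))
}

rr_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "rhizorank_warning")))
}

# Argument checkers -----------------------------------------------------

check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) {
    rr_stop(sprintf("`%s` must be numeric, got %s", name, class(x)[1]),
            "rr_invalid_input")
  }
  if (finite && any(!is.finite(x) & !is.na(x))) {
    rr_stop(sprintf("`%s` contains non-finite values", name),
            "rr_invalid_input")
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    rr_stop(sprintf("%s is missing required column(s): %s",
                    what, paste(missing, collapse = ", ")),
            "rr_schema_error")
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
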