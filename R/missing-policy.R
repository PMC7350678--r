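#' Missing-value policy for table import
#'
#' Quantified metabolite tables routinely contain cells for which no peak was
#' integrated.  Those cells are kept as *missing* throughout the package --
#' they are never imputed and never silently turned into zeros.  A policy
#' object states which text tokens mark a missing cell and two optional,
#' dialect-specific rules: treating explicit zeros as missing (only meaningful
#' for the `compounds_in_columns` layout) and an intensity threshold below
#' which values are discarded as noise (only applied for the
#' `compound_discoverer` and `other_matrix` layouts).
#'
#' The token set always contains the empty string, `"NA"`, `"NaN"`, `"N/F"`
#' and `"N/A"`; `extra_tokens` can only widen it.
#'
#' @param extra_tokens Character vector of additional tokens to treat as
#'   missing, e.g. `"not detected"`.
#' @param zeros_as_missing Logical; convert numeric `0` to missing.  Honoured
#'   only for the `compounds_in_columns` dialect.
#' @param threshold Non-negative number or `NULL`.  Values `>= threshold` are
#'   kept, values below it become missing.  Honoured only for the
#'   `compound_discoverer` and `other_matrix` dialects.
#' @return A list of class `"missing_policy"` with elements `tokens`,
#'   `zeros_as_missing` and `threshold`.
#' @examples
#' missing_policy()
#' missing_policy(threshold = 1000)
#' @export
missing_policy <- function(extra_tokens = character(),
                           zeros_as_missing = FALSE,
                           threshold = NULL) {
  stopifnot(is.character(extra_tokens))
  if (!is.null(threshold)) {
    stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)
  }
  structure(
    list(
      tokens = union(c("", "NA", "NaN", "N/F", "N/A"), extra_tokens),
      zeros_as_missing = isTRUE(zeros_as_missing),
      threshold = threshold
    ),
    class = "missing_policy"
  )
}

#' Classify raw cell contents as intensity or missing
#'
#' Applies the missing-value policy to a vector of raw cell values.  Text
#' tokens from the policy become `NA`; numeric zeros become `NA` only when the
#' policy says so *and* the dialect is `compounds_in_columns`; values below
#' the policy threshold become `NA` for the thresholded dialects
#' (`compound_discoverer`, `other_matrix`); the threshold itself passes
#' (values need to *reach* it).  Anything that is neither numeric nor a known
#' token is an error, reported with its position.
#'
#' Comma decimal separators are accepted when `decimal_mark = ","` (set
#' automatically by [read_metabolite_table()] for semicolon-separated files).
#'
#' @param x Character or numeric vector of raw cell values.
#' @param policy A [missing_policy()].
#' @param dialect One of the five input dialect names.
#' @param decimal_mark `"."` or `","`.
#' @param context Optional text prepended to error messages (e.g. a column
#'   name).
#' @return A numeric vector with `NA` for missing cells.
#' @examples
#' classify_intensity(c("100", "N/F", ""), missing_policy(), "other_list")
#' @export
classify_intensity <- function(x, policy = missing_policy(),
                               dialect = "other_list",
                               decimal_mark = ".",
                               context = NULL) {
  dialect <- match.arg(dialect, metaboplot_dialects())
  if (is.numeric(x)) {
    out <- as.numeric(x)
  } else {
    raw <- stringr::str_trim(as.character(x))
    out <- rep(NA_real_, length(raw))
    is_token <- raw %in% policy$tokens | is.na(raw)
    num_txt <- raw[!is_token]
    if (decimal_mark == ",") num_txt <- gsub(",", ".", num_txt, fixed = TRUE)
    num <- suppressWarnings(as.numeric(num_txt))
    bad <- is.na(num)
    if (any(bad)) {
      where <- which(!is_token)[bad]
      abort(sprintf(
        "%snon-numeric value(s) not recognised as missing tokens: %s (position %s)",
        if (is.null(context)) "" else paste0(context, ": "),
        paste(unique(raw[where]), collapse = ", "),
        paste(head(where, 5), collapse = ", ")
      ))
    }
    out[!is_token] <- num
  }
  if (any(out < 0, na.rm = TRUE)) {
    abort(sprintf("%snegative intensities are not allowed",
                  if (is.null(context)) "" else paste0(context, ": ")))
  }
  if (policy$zeros_as_missing && dialect == "compounds_in_columns") {
    out[!is.na(out) & out == 0] <- NA_real_
  }
  if (!is.null(policy$threshold) &&
      dialect %in% c("compound_discoverer", "other_matrix")) {
    out[!is.na(out) & out < policy$threshold] <- NA_real_
  }
  out
}

#' Supported input dialects
#'
#' @return Character vector with the five table-layout names understood by
#'   [read_metabolite_table()].
#' @export
metaboplot_dialects <- function() {
  c("tracefinder", "compound_discoverer", "compounds_in_columns",
    "other_list", "other_matrix")
}
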