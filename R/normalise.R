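# Normalisation: external correction (cell counts / protein), internal
# standards, and total-peak-sum.  All three reduce to dividing each sample's
# intensities by a per-sample factor c_s; "absolute" keeps the new units
# (I / c_s), "relative" restores the original scale by multiplying with the
# arithmetic mean of the factors over all included samples
# (I / c_s * mean(c)).  Missing values pass through untouched.

apply_sample_factor <- function(tbl, factors, mode) {
  mode <- match.arg(mode, c("absolute", "relative"))
  scale <- if (mode == "relative") mean(factors) else 1
  fac <- unname(factors[as.character(tbl$sample_id)])
  out <- mutate(tbl, intensity = intensity / fac * scale)
  for (a in c("dialect", "metadata", "samples")) {
    attr(out, a) <- attr(tbl, a)
  }
  out
}

#' External correction by cell count or protein content
#'
#' Divides every intensity by the sample's correction value (e.g. cell count
#' or microgram protein).  In `"absolute"` mode the result is expressed per
#' correction unit ("peak area per million cells"); in `"relative"` mode the
#' quotients are rescaled by the mean correction value over all included
#' samples, so intensities keep their original dimension but samples are
#' equalised.
#'
#' @param tbl Annotated measurement tibble with a `correction_value` column.
#' @param mode `"absolute"` or `"relative"`.
#' @return The tibble with corrected intensities.
#' @export
normalise_external <- function(tbl, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  cv <- distinct(tbl, sample_id, correction_value)
  if (anyNA(cv$correction_value) || any(cv$correction_value <= 0)) {
    bad <- cv$sample_id[is.na(cv$correction_value) | cv$correction_value <= 0]
    abort(sprintf("missing or non-positive correction value for sample(s): %s",
                  paste(bad, collapse = ", ")))
  }
  apply_sample_factor(tbl, setNames(cv$correction_value, cv$sample_id), mode)
}

#' Internal-standard normalisation
#'
#' Uses one or more compounds as internal standards: per sample the factor is
#' the *sum* of the standards' intensities (so highly abundant standards
#' dominate), then intensities are divided as in [normalise_external()].  The
#' standards stay in the table and are normalised along with everything else.
#' A standard that is missing in a sample contributes nothing to that
#' sample's sum (with a warning); a sample in which *all* standards are
#' missing is an error.
#'
#' @param tbl Annotated measurement tibble.
#' @param standards Character vector of compound names.
#' @param mode `"absolute"` or `"relative"`.
#' @return The tibble with normalised intensities.
#' @export
normalise_internal <- function(tbl, standards,
                               mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(length(standards) >= 1)
  absent <- setdiff(standards, unique(tbl$compound))
  if (length(absent) > 0) {
    abort(sprintf("internal standard(s) not found in the data: %s",
                  paste(absent, collapse = ", ")))
  }
  std <- tbl %>%
    filter(compound %in% standards) %>%
    group_by(sample_id) %>%
    summarise(factor = sum(intensity, na.rm = TRUE),
              n_missing = sum(is.na(intensity)), .groups = "drop")
  dead <- std$sample_id[std$factor == 0 |
                          std$n_missing == length(standards)]
  if (length(dead) > 0) {
    abort(sprintf("all internal standards missing in sample(s): %s",
                  paste(dead, collapse = ", ")))
  }
  if (any(std$n_missing > 0)) {
    warn(sprintf("internal standard missing in %d sample(s); it contributes 0 to the sum there",
                 sum(std$n_missing > 0)))
  }
  apply_sample_factor(tbl, setNames(std$factor, std$sample_id), mode)
}

#' Total-peak-sum normalisation
#'
#' Normalises each sample by the sum of all its non-missing peak areas,
#' useful when no single metabolite can serve as a representative internal
#' standard.  All detected rows enter the sum, including isotopologue rows.
#'
#' @param tbl Annotated measurement tibble.
#' @param mode `"absolute"` or `"relative"`.
#' @return The tibble with normalised intensities.
#' @export
normalise_total <- function(tbl, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  tot <- tbl %>%
    group_by(sample_id) %>%
    summarise(factor = sum(intensity, na.rm = TRUE),
              all_missing = all(is.na(intensity)), .groups = "drop")
  if (any(tot$all_missing)) {
    abort(sprintf("sample(s) with no non-missing intensity: %s",
                  paste(tot$sample_id[tot$all_missing], collapse = ", ")))
  }
  apply_sample_factor(tbl, setNames(tot$factor, tot$sample_id), mode)
}
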