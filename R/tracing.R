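# Stable-isotope tracing: compound names carry their isotopologue as a
# trailing " +n" suffix ("Lactate +3" = lactate with a 3 Da mass shift).
# These rows are grouped per base compound into mass-isotopomer
# distributions (MIDs).

#' Split isotopologue suffixes off compound labels
#'
#' A label ending in `" +<integer>"` (space, plus, digits) denotes the M+n
#' isotopologue of the base compound; anything else -- including a `"+n"`
#' glued to the name without a space, or internal plus signs as in `"NAD+"`
#' -- is part of the name and means the unlabelled species M+0.  Mass shifts
#' up to M+30 are accepted; larger shifts are an error.
#'
#' @param labels Character vector of compound labels.
#' @return A tibble with columns `label`, `base`, `shift`.
#' @examples
#' parse_isotopologue_label(c("Glucose +6", "Citrate", "NAD+ +5"))
#' @export
parse_isotopologue_label <- function(labels) {
  m <- stringr::str_match(labels, "^(.*\\S) \\+(\\d+)$")
  base <- ifelse(is.na(m[, 2]), labels, m[, 2])
  shift <- ifelse(is.na(m[, 3]), 0L, suppressWarnings(as.integer(m[, 3])))
  if (any(shift > 30)) {
    abort(sprintf("isotopologue shift beyond M+30 in label(s): %s",
                  paste(labels[shift > 30], collapse = ", ")))
  }
  tibble(label = labels, base = base, shift = as.integer(shift))
}

#' Group isotopologues per base compound
#'
#' Parses every compound label and rewrites the table in terms of
#' `base_compound` and `shift`.  Shifts absent from the data stay absent (no
#' zero filling); plotting renders them as zero-height segments.
#'
#' @param tbl Measurement tibble (annotated or not).
#' @return The tibble with `compound` replaced by `base_compound` and an
#'   integer `shift` column; all other columns are preserved.
#' @export
group_isotopologues <- function(tbl) {
  parsed <- parse_isotopologue_label(tbl$compound)
  out <- tbl %>%
    mutate(base_compound = parsed$base, shift = parsed$shift) %>%
    select(-compound)
  dup <- out %>%
    dplyr::count(base_compound, shift, sample_id) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate isotopologue rows for: %s",
                  paste(unique(paste0(dup$base_compound, " +", dup$shift)),
                        collapse = ", ")))
  }
  out
}

#' Relative mass-isotopomer distributions
#'
#' Converts grouped isotopologue intensities into fractions per
#' (base compound, sample): each shift's intensity divided by the sum of the
#' non-missing intensities of that compound in that sample.  Missing shifts
#' contribute 0 to the denominator and get fraction 0 (exported tables keep
#' the intensity itself as missing).  A compound entirely missing in a
#' sample has no defined distribution and is dropped with a warning.
#'
#' @param grouped Output of [group_isotopologues()].
#' @return `grouped` with an added `fraction` column; fractions sum to 1
#'   within each (base_compound, sample_id).
#' @export
relative_mid <- function(grouped) {
  out <- grouped %>%
    group_by(base_compound, sample_id) %>%
    mutate(fraction = {
      tot <- sum(intensity, na.rm = TRUE)
      if (tot > 0) ifelse(is.na(intensity), 0, intensity / tot) else NA_real_
    }) %>%
    ungroup()
  dead <- out %>%
    filter(is.na(fraction)) %>%
    distinct(base_compound, sample_id)
  if (nrow(dead) > 0) {
    warn(sprintf("%d (compound, sample) pair(s) with no signal dropped from relative distributions",
                 nrow(dead)))
    out <- filter(out, !is.na(fraction))
  }
  out
}
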