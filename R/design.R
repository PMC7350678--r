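# Sample design: the user-edited table that attaches conditions, plotting
# order, colours, replicate levels and correction values to samples.

design_headers <- c("Sample", "Condition", "Order", "Colour",
                    "Experimental_Replicate", "Technical_Replicate",
                    "Correction_Value", "Include")

#' Generate a sample-table template
#'
#' Creates the design table skeleton for a parsed measurement table: one row
#' per sample in input order, with empty condition/colour/replicate columns,
#' a default order `1..n` and `Include = TRUE`.  The user fills in at least
#' the `Condition` column before loading it back with
#' [read_sample_design()].
#'
#' @param tbl A measurement tibble from [read_metabolite_table()].
#' @param path Optional output path (`.csv` or `.xlsx`); when given, the
#'   template is also written to disk.
#' @return A tibble with the template columns (`Sample`, `Condition`,
#'   `Order`, `Colour`, `Experimental_Replicate`, `Technical_Replicate`,
#'   `Correction_Value`, `Include`).
#' @export
design_template <- function(tbl, path = NULL) {
  samples <- attr(tbl, "samples") %||% unique(tbl$sample_id)
  out <- tibble(
    Sample = samples,
    Condition = "",
    Order = seq_along(samples),
    Colour = "",
    Experimental_Replicate = "",
    Technical_Replicate = "",
    Correction_Value = NA_real_,
    Include = TRUE
  )
  if (!is.null(path)) write_table_file(out, path)
  out
}

#' Load and validate a sample design table
#'
#' Reads the user-edited template (CSV or XLSX) and validates it against the
#' measurement table:
#'
#' * every sample in the data must have a design row (hard error otherwise);
#'   design rows for unknown samples are dropped with a warning;
#' * every included sample needs a non-empty condition;
#' * colours may be hex values (`"#FFAA25"`) or standard R colour names,
#'   resolved to hex through [grDevices::colours()]; anything else is an
#'   error;
#' * correction values, when present, must be positive;
#' * `Include` accepts TRUE/FALSE, yes/no, 1/0; blank means included.
#'
#' Condition display order follows the `Order` column (smallest first); ties
#' are broken by first appearance in the design file.
#'
#' @param path Path to the edited template, or a data frame with the same
#'   columns.
#' @param tbl The measurement tibble the design belongs to.
#' @return A design tibble with columns `sample_id`, `condition`, `order`,
#'   `colour` (hex or `NA`), `experimental_replicate`,
#'   `technical_replicate`, `correction_value`, `include`.
#' @export
read_sample_design <- function(path, tbl) {
  raw <- if (is.data.frame(path)) {
    as_tibble(path)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("xls", "xlsx")) {
      readxl::read_excel(path, sheet = 1, col_types = "text")
    } else {
      readr::read_delim(path, delim = sniff_delim(path),
                        col_types = readr::cols(.default = "c"),
                        na = character(), trim_ws = TRUE,
                        show_col_types = FALSE)
    }
  }
  idx <- match(norm_header(design_headers), norm_header(names(raw)))
  if (anyNA(idx)) {
    abort(sprintf("sample table is missing column(s): %s",
                  paste(design_headers[is.na(idx)], collapse = ", ")))
  }
  blank_na <- function(x) {
    x <- stringr::str_trim(as.character(x))
    x[x == "" | is.na(x)] <- NA_character_
    x
  }
  design <- tibble(
    sample_id = blank_na(raw[[idx[1]]]),
    condition = blank_na(raw[[idx[2]]]),
    order = suppressWarnings(as.numeric(blank_na(raw[[idx[3]]]))),
    colour = resolve_colour(blank_na(raw[[idx[4]]])),
    experimental_replicate = blank_na(raw[[idx[5]]]),
    technical_replicate = blank_na(raw[[idx[6]]]),
    correction_value = suppressWarnings(as.numeric(blank_na(raw[[idx[7]]]))),
    include = parse_flag(blank_na(raw[[idx[8]]]))
  )
  if (anyNA(design$sample_id)) abort("sample table contains empty sample ids")
  if (anyDuplicated(design$sample_id)) {
    abort("sample table contains duplicated sample ids")
  }

  data_samples <- unique(tbl$sample_id)
  missing_rows <- setdiff(data_samples, design$sample_id)
  if (length(missing_rows) > 0) {
    abort(sprintf("sample(s) in the data have no design row: %s",
                  paste(missing_rows, collapse = ", ")))
  }
  extra <- setdiff(design$sample_id, data_samples)
  if (length(extra) > 0) {
    warn(sprintf("design row(s) for unknown sample(s) dropped: %s",
                 paste(extra, collapse = ", ")))
    design <- filter(design, sample_id %in% data_samples)
  }
  no_cond <- design$sample_id[design$include & is.na(design$condition)]
  if (length(no_cond) > 0) {
    abort(sprintf("condition missing for included sample(s): %s",
                  paste(no_cond, collapse = ", ")))
  }
  bad_c <- design$correction_value[!is.na(design$correction_value)] <= 0
  if (any(bad_c)) abort("correction values must be > 0")
  design$order[is.na(design$order)] <- Inf
  design
}

parse_flag <- function(x) {
  out <- rep(TRUE, length(x))
  x <- tolower(x)
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

# hex colours pass through (normalised to upper case); standard R colour
# names resolve via grDevices; anything else errors.
resolve_colour <- function(x) {
  out <- rep(NA_character_, length(x))
  has <- !is.na(x)
  is_hex <- has & grepl("^#[0-9A-Fa-f]{6}([0-9A-Fa-f]{2})?$", x)
  out[is_hex] <- toupper(x[is_hex])
  named <- has & !is_hex
  if (any(named)) {
    known <- tolower(x[named]) %in% grDevices::colours()
    if (any(!known)) {
      abort(sprintf("unknown colour(s): %s (use hex like #FFAA25 or an R colour name)",
                    paste(unique(x[named][!known]), collapse = ", ")))
    }
    rgb <- grDevices::col2rgb(tolower(x[named]))
    out[named] <- grDevices::rgb(rgb[1, ], rgb[2, ], rgb[3, ],
                                 maxColorValue = 255)
  }
  out
}

# back to user-facing headers for the Inputs/ export
design_as_table <- function(design) {
  tibble(
    Sample = design$sample_id,
    Condition = design$condition,
    Order = ifelse(is.finite(design$order), design$order, NA_real_),
    Colour = design$colour,
    Experimental_Replicate = design$experimental_replicate,
    Technical_Replicate = design$technical_replicate,
    Correction_Value = design$correction_value,
    Include = design$include
  )
}

#' Attach design annotation to measurements
#'
#' Joins the sample design onto the long measurement table and drops samples
#' marked `Include = FALSE` from all downstream computation.  Conditions are
#' turned into a factor ordered by the design's `Order` column so that plots
#' and summaries follow the user-chosen order.
#'
#' @param tbl Measurement tibble.
#' @param design Design tibble from [read_sample_design()].
#' @return The measurement tibble with added columns `condition`, `order`,
#'   `colour`, `experimental_replicate`, `technical_replicate`,
#'   `correction_value`.
#' @export
annotate_design <- function(tbl, design) {
  used <- filter(design, include)
  if (nrow(used) == 0) abort("no samples left after applying Include flags")
  cond_order <- used %>%
    group_by(condition) %>%
    summarise(order = min(order), .groups = "drop") %>%
    arrange(order)
  out <- tbl %>%
    filter(sample_id %in% used$sample_id) %>%
    left_join(select(used, -include), by = "sample_id") %>%
    mutate(condition = factor(condition, levels = cond_order$condition))
  attr(out, "dialect") <- attr(tbl, "dialect")
  attr(out, "metadata") <- attr(tbl, "metadata")
  attr(out, "samples") <- intersect(attr(tbl, "samples") %||% unique(tbl$sample_id),
                                    used$sample_id)
  out
}

#' Average technical replicates
#'
#' When both replicate levels are defined, repeated measurements of the same
#' biological sample (technical replicates) are collapsed to their arithmetic
#' mean per (compound, condition, experimental replicate); the averages are
#' what gets plotted.  Missing values are excluded from the mean -- they are
#' never treated as zero -- and a group that is entirely missing stays
#' missing.
#'
#' @param tbl Annotated measurement tibble ([annotate_design()]).
#' @return Averaged tibble; `sample_id` becomes `"<condition>_<replicate>"`.
#' @export
average_technical <- function(tbl) {
  need <- c("experimental_replicate", "technical_replicate")
  partial <- vapply(need, function(col) anyNA(tbl[[col]]), logical(1))
  if (all(is.na(tbl$experimental_replicate)) &&
      all(is.na(tbl$technical_replicate))) {
    abort("no replicate levels defined; nothing to average")
  }
  if (any(partial)) {
    abort("replicate columns must be filled for every included sample")
  }
  out <- tbl %>%
    group_by(compound, rt, condition, experimental_replicate) %>%
    summarise(
      intensity = if (all(is.na(intensity))) NA_real_ else
        mean(intensity, na.rm = TRUE),
      order = first(order), colour = first(colour),
      correction_value = mean(correction_value),
      .groups = "drop"
    ) %>%
    mutate(sample_id = paste(condition, experimental_replicate, sep = "_"),
           technical_replicate = NA_character_) %>%
    select(compound, rt, sample_id, intensity, condition, order, colour,
           experimental_replicate, technical_replicate, correction_value)
  attr(out, "dialect") <- attr(tbl, "dialect")
  out
}
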