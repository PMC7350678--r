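#' Serialise a measurement table back into an input dialect
#'
#' Inverse of [read_metabolite_table()]: writes the long measurement tibble
#' in any of the five supported layouts.  Missing intensities become empty
#' cells (never zeros).  Used by the fixture generator and for round-trip
#' checks; also handy to convert between layouts.
#'
#' @param tbl Long measurement tibble (`compound`, `rt`, `sample_id`,
#'   `intensity`).
#' @param path Output path; `.csv`/`.tsv`/`.txt` write delimited text,
#'   `.xlsx` writes a minimal Excel file.
#' @param dialect Target layout, see [metaboplot_dialects()].
#' @return `path`, invisibly.
#' @export
write_metabolite_table <- function(tbl, path,
                                   dialect = metaboplot_dialects()) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    tracefinder = tibble(
      Compound = tbl$compound, `Actual RT` = tbl$rt,
      Filename = tbl$sample_id, Area = tbl$intensity
    ),
    other_list = tibble(
      Metabolite = tbl$compound, RT = tbl$rt,
      Filename = tbl$sample_id, Area = tbl$intensity
    ),
    compound_discoverer = {
      wide <- pivot_compounds_wide(tbl)
      samples <- setdiff(names(wide), c("compound", "rt"))
      names(wide) <- c("Compound", "RT [min]",
                       sprintf("Area: %s.raw (F%d)", samples, seq_along(samples)))
      wide
    },
    other_matrix = {
      wide <- pivot_compounds_wide(tbl)
      names(wide)[1:2] <- c("Metabolite", "RT")
      wide
    },
    compounds_in_columns = {
      wide <- tbl %>%
        select(compound, sample_id, intensity) %>%
        tidyr::pivot_wider(names_from = compound, values_from = intensity)
      names(wide)[1] <- "Sample"
      wide
    }
  )
  write_table_file(out, path)
}

pivot_compounds_wide <- function(tbl) {
  tbl %>%
    select(compound, rt, sample_id, intensity) %>%
    tidyr::pivot_wider(names_from = sample_id, values_from = intensity)
}

write_table_file <- function(df, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    write_minimal_xlsx(df, path)
  } else if (ext %in% c("tsv", "txt")) {
    readr::write_tsv(df, path, na = "")
  } else {
    readr::write_csv(df, path, na = "")
  }
  invisible(path)
}

#' Export structured result tables
#'
#' Writes the processed data in three shapes, each as CSV and XLSX, into
#' `dir`/Tables, and preserves the inputs needed to repeat the analysis in
#' `dir`/Inputs:
#'
#' * `measurements_long` -- one row per (compound, sample) with condition
#'   annotation; missing values are empty cells, never zeros.
#' * `measurements_matrix` -- compound x sample intensity matrix.
#' * `condition_summary` -- per (compound, condition) mean, standard
#'   deviation (n-1 denominator) and number of non-missing values.
#' * `Inputs/cleaned_input.csv` -- the cleaned long table in the generic list
#'   layout, re-readable with `dialect = "other_list"`.
#' * `Inputs/sample_table.csv` -- the sample design as loaded (all samples,
#'   including excluded ones, for provenance).
#'
#' @param tbl Annotated measurement tibble (see [annotate_design()]).
#' @param design Sample design tibble from [read_sample_design()].
#' @param dir Output directory; created if absent.
#' @return Character vector of the files written.
#' @export
write_structured_tables <- function(tbl, design, dir) {
  tables_dir <- file.path(dir, "Tables")
  inputs_dir <- file.path(dir, "Inputs")
  ok <- all(vapply(c(tables_dir, inputs_dir), dir.create, logical(1),
                   recursive = TRUE, showWarnings = FALSE) |
              dir.exists(c(tables_dir, inputs_dir)))
  if (!ok) abort(sprintf("cannot create output directory under %s", dir))

  long <- tbl %>%
    select(any_of(c("compound", "rt", "sample_id", "condition",
                    "experimental_replicate", "intensity")))
  wide <- pivot_compounds_wide(tbl)
  summary <- tbl %>%
    group_by(compound, condition) %>%
    summarise(
      mean = if (all(is.na(intensity))) NA_real_ else
        mean(intensity, na.rm = TRUE),
      sd = if (sum(!is.na(intensity)) < 2) NA_real_ else
        sd(intensity, na.rm = TRUE),
      n = sum(!is.na(intensity)),
      .groups = "drop"
    )

  paths <- character(0)
  for (piece in list(list("measurements_long", long),
                     list("measurements_matrix", wide),
                     list("condition_summary", summary))) {
    for (ext in c("csv", "xlsx")) {
      p <- file.path(tables_dir, paste0(piece[[1]], ".", ext))
      write_table_file(piece[[2]], p)
      paths <- c(paths, p)
    }
  }
  p_in <- file.path(inputs_dir, "cleaned_input.csv")
  write_metabolite_table(tbl, p_in, dialect = "other_list")
  p_design <- file.path(inputs_dir, "sample_table.csv")
  readr::write_csv(design_as_table(design), p_design, na = "")
  c(paths, p_in, p_design)
}
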