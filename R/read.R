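#' Read a quantified metabolite table
#'
#' Parses one of five table layouts commonly produced by peak-integration
#' software into a single canonical long table with one row per
#' (compound, sample) pair.  The layouts are:
#'
#' * `tracefinder` -- long list with columns `Compound`, `Filename`, `Area`
#'   and optional `Actual RT`, `Formula`, `Adduct` and m/z columns.
#' * `compound_discoverer` -- wide matrix with `Compound`, `RT [min]` and one
#'   column per sample named `"Area: <file>.raw (F<n>)"` (or `"Norm. Area:"`);
#'   optional `Molecular Weight`, `Mass`, `Formula`.
#' * `compounds_in_columns` -- samples along rows (sample names in the first
#'   column, header ignored), one column per metabolite.  Every column after
#'   the first is taken to be a metabolite, so stray annotation columns end up
#'   as bogus compounds -- keep them out of the file.
#' * `other_list` -- four columns in fixed order: metabolite, retention time
#'   (may be empty but must be present), filename, area.  Further columns are
#'   ignored with a warning.
#' * `other_matrix` -- first two columns metabolite and retention time,
#'   remaining columns one per sample.  As for `compounds_in_columns`, extra
#'   non-sample columns cannot be told apart from samples.
#'
#' Files may be CSV, tab- or semicolon-separated text, or Excel (first sheet,
#' exactly one header row).  For text files the delimiter is sniffed among
#' comma, semicolon and tab unless `delim` is given; with a semicolon
#' delimiter, comma decimal marks are accepted.  Header matching is
#' case-insensitive and whitespace-tolerant.  Sample ids are the file names
#' with any trailing `".raw"` stripped.
#'
#' Compound names that occur with more than one distinct retention time are
#' disambiguated by [merge_duplicate_names()]; duplicated names *without* a
#' retention time are an error.  Missing-value handling follows `policy`, see
#' [missing_policy()]; missing cells are kept as `NA` and never imputed.
#'
#' @param path Path to the input file.
#' @param dialect One of [metaboplot_dialects()].
#' @param policy A [missing_policy()].
#' @param delim Optional explicit delimiter for text files (`","`, `";"` or
#'   `"\t"`); overrides sniffing.
#' @return A tibble with columns `compound`, `rt`, `sample_id`, `intensity`
#'   (`NA` = missing), carrying attributes `dialect` (the layout parsed),
#'   `metadata` (a per-compound tibble of retained extra columns, or `NULL`)
#'   and `samples` (the sample roster in input order).
#' @seealso [write_metabolite_table()] for the inverse operation,
#'   [design_template()] for the next pipeline step.
#' @export
read_metabolite_table <- function(path,
                                  dialect = metaboplot_dialects(),
                                  policy = missing_policy(),
                                  delim = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("csv", "tsv", "txt", "xls", "xlsx")) {
    abort(sprintf("unsupported file extension '.%s' (csv/tsv/txt/xls/xlsx)", ext))
  }
  if (ext %in% c("xls", "xlsx")) {
    raw <- readxl::read_excel(path, sheet = 1, col_types = "text",
                              .name_repair = "minimal")
    decimal_mark <- "."
  } else {
    delim <- delim %||% sniff_delim(path)
    decimal_mark <- if (delim == ";") "," else "."
    raw <- readr::read_delim(
      path, delim = delim, col_types = readr::cols(.default = "c"),
      locale = readr::locale(decimal_mark = decimal_mark),
      na = character(), trim_ws = TRUE, show_col_types = FALSE,
      name_repair = "minimal"
    )
  }
  parser <- switch(dialect,
    tracefinder          = parse_tracefinder,
    compound_discoverer  = parse_compound_discoverer,
    compounds_in_columns = parse_compounds_in_columns,
    other_list           = parse_other_list,
    other_matrix         = parse_other_matrix
  )
  out <- parser(raw, policy, decimal_mark)
  tbl <- merge_duplicate_names(out$tbl)
  dup <- tbl %>% dplyr::count(compound, sample_id) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicated compound names cannot be disambiguated (no distinct retention time): %s",
      paste(unique(dup$compound), collapse = ", ")
    ))
  }
  new_metab_tbl(tbl, dialect = dialect, metadata = out$metadata)
}

new_metab_tbl <- function(tbl, dialect, metadata = NULL, samples = NULL) {
  tbl <- as_tibble(tbl)[, c("compound", "rt", "sample_id", "intensity")]
  attr(tbl, "dialect") <- dialect
  attr(tbl, "metadata") <- metadata
  attr(tbl, "samples") <- samples %||% unique(tbl$sample_id)
  tbl
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  counts <- c(
    "," = stringr::str_count(header, stringr::fixed(",")),
    ";" = stringr::str_count(header, stringr::fixed(";")),
    "\t" = stringr::str_count(header, stringr::fixed("\t"))
  )
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

norm_header <- function(x) stringr::str_squish(tolower(x))

# find a column by normalised header; errors naming dialect when essential
find_col <- function(raw, name, dialect, essential = TRUE) {
  hit <- which(norm_header(names(raw)) == norm_header(name))
  if (length(hit) == 0) {
    if (essential) {
      abort(sprintf("essential column '%s' not found in %s input", name, dialect))
    }
    return(NA_integer_)
  }
  hit[1]
}

strip_raw_suffix <- function(x) {
  stringr::str_remove(stringr::str_trim(x), stringr::regex("\\.raw$", ignore_case = TRUE))
}

check_compounds <- function(compounds, dialect) {
  if (any(is.na(compounds) | stringr::str_trim(compounds) == "")) {
    abort(sprintf("compound names in %s input cannot contain empty values", dialect))
  }
  stringr::str_trim(compounds)
}

parse_rt <- function(x, decimal_mark = ".") {
  if (is.numeric(x)) return(as.numeric(x))
  x <- stringr::str_trim(as.character(x))
  x[x %in% c("", "NA", "NaN")] <- NA_character_
  if (decimal_mark == ",") x <- gsub(",", ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

parse_tracefinder <- function(raw, policy, decimal_mark) {
  i_cmp  <- find_col(raw, "Compound", "tracefinder")
  i_file <- find_col(raw, "Filename", "tracefinder")
  i_area <- find_col(raw, "Area", "tracefinder")
  i_rt   <- find_col(raw, "Actual RT", "tracefinder", essential = FALSE)
  tbl <- tibble(
    compound = check_compounds(raw[[i_cmp]], "tracefinder"),
    rt = if (is.na(i_rt)) NA_real_ else parse_rt(raw[[i_rt]], decimal_mark),
    sample_id = strip_raw_suffix(raw[[i_file]]),
    intensity = classify_intensity(raw[[i_area]], policy, "tracefinder",
                                   decimal_mark, context = "Area")
  )
  meta_names <- c("Formula", "Adduct", "m/z (Apex)", "m/z (Delta (ppm))", "m/z (Delta)")
  idx <- vapply(meta_names, find_col, integer(1),
                raw = raw, dialect = "tracefinder", essential = FALSE)
  metadata <- NULL
  if (any(!is.na(idx))) {
    metadata <- dplyr::bind_cols(
      tibble(compound = tbl$compound),
      setNames(as.list(raw[stats::na.omit(idx)]), meta_names[!is.na(idx)])
    ) %>% distinct(compound, .keep_all = TRUE)
  }
  list(tbl = tbl, metadata = metadata)
}

parse_compound_discoverer <- function(raw, policy, decimal_mark) {
  i_cmp <- find_col(raw, "Compound", "compound_discoverer")
  i_rt  <- find_col(raw, "RT [min]", "compound_discoverer")
  pat <- "^(Norm\\. )?Area: (.+?)(\\.raw)? \\(F\\d+\\)$"
  headers <- stringr::str_trim(names(raw))
  is_sample <- stringr::str_detect(headers, pat)
  if (!any(is_sample)) {
    abort(paste("essential column 'Area: <filename>.raw (F<n>)' not found in",
                "compound_discoverer input"))
  }
  sample_ids <- stringr::str_match(headers[is_sample], pat)[, 3]
  compounds <- check_compounds(raw[[i_cmp]], "compound_discoverer")
  rt <- parse_rt(raw[[i_rt]], decimal_mark)
  long <- purrr::map2_dfr(which(is_sample), sample_ids, function(j, sid) {
    tibble(
      compound = compounds, rt = rt, sample_id = sid,
      intensity = classify_intensity(raw[[j]], policy, "compound_discoverer",
                                     decimal_mark, context = headers[j])
    )
  })
  meta_names <- c("Molecular Weight", "Mass", "Formula")
  idx <- vapply(meta_names, find_col, integer(1),
                raw = raw, dialect = "compound_discoverer", essential = FALSE)
  metadata <- NULL
  if (any(!is.na(idx))) {
    metadata <- dplyr::bind_cols(
      tibble(compound = compounds),
      setNames(as.list(raw[stats::na.omit(idx)]), meta_names[!is.na(idx)])
    ) %>% distinct(compound, .keep_all = TRUE)
  }
  list(tbl = long, metadata = metadata)
}

parse_compounds_in_columns <- function(raw, policy, decimal_mark) {
  if (ncol(raw) < 2) {
    abort("compounds_in_columns input needs a sample column plus >=1 metabolite column")
  }
  samples <- strip_raw_suffix(raw[[1]])
  compounds <- check_compounds(names(raw)[-1], "compounds_in_columns")
  long <- purrr::imap_dfr(as.list(raw[-1]), function(col, nm) {
    tibble(
      compound = stringr::str_trim(nm), rt = NA_real_, sample_id = samples,
      intensity = classify_intensity(col, policy, "compounds_in_columns",
                                     decimal_mark, context = nm)
    )
  })
  # keep compound order as in the file header, samples as in rows
  long <- long[order(match(long$compound, compounds)), ]
  list(tbl = long, metadata = NULL)
}

parse_other_list <- function(raw, policy, decimal_mark) {
  if (ncol(raw) < 4) {
    abort("other_list input needs 4 columns in order: metabolite, RT, filename, area")
  }
  if (ncol(raw) > 4) {
    warn(sprintf("other_list: ignoring %d extra column(s): %s",
                 ncol(raw) - 4, paste(names(raw)[-(1:4)], collapse = ", ")))
  }
  tbl <- tibble(
    compound = check_compounds(raw[[1]], "other_list"),
    rt = parse_rt(raw[[2]], decimal_mark),
    sample_id = strip_raw_suffix(raw[[3]]),
    intensity = classify_intensity(raw[[4]], policy, "other_list",
                                   decimal_mark, context = names(raw)[4])
  )
  list(tbl = tbl, metadata = NULL)
}

parse_other_matrix <- function(raw, policy, decimal_mark) {
  if (ncol(raw) < 3) {
    abort("other_matrix input needs metabolite and RT columns plus >=1 sample column")
  }
  compounds <- check_compounds(raw[[1]], "other_matrix")
  rt <- parse_rt(raw[[2]], decimal_mark)
  long <- purrr::imap_dfr(as.list(raw[-(1:2)]), function(col, nm) {
    tibble(
      compound = compounds, rt = rt, sample_id = strip_raw_suffix(nm),
      intensity = classify_intensity(col, policy, "other_matrix",
                                     decimal_mark, context = nm)
    )
  })
  list(tbl = long, metadata = NULL)
}

#' Disambiguate duplicated compound names by retention time
#'
#' Compound names in targeted libraries are often not unique (the same name
#' at two chromatographic peaks).  Any name occurring with more than one
#' distinct retention time is rewritten as `"name@RT"` with the retention
#' time formatted to two decimals; unique names are left untouched.  A
#' duplicated name without a retention time cannot be disambiguated and is an
#' error.
#'
#' @param tbl A long measurement tibble with columns `compound`, `rt`,
#'   `sample_id`, `intensity`.
#' @return The tibble with unique compound display names.
#' @examples
#' tbl <- tibble::tibble(
#'   compound = c("Leucine", "Leucine"), rt = c(7.31, 9.02),
#'   sample_id = "s1", intensity = c(1, 2)
#' )
#' merge_duplicate_names(tbl)$compound
#' @export
merge_duplicate_names <- function(tbl) {
  if (nrow(tbl) == 0) return(tbl)
  per_sample <- tbl %>%
    dplyr::count(compound, sample_id) %>%
    group_by(compound) %>%
    summarise(max_per_sample = max(n), .groups = "drop")
  info <- tbl %>%
    group_by(compound) %>%
    summarise(n_rt = dplyr::n_distinct(rt[!is.na(rt)]),
              any_na_rt = anyNA(rt), .groups = "drop") %>%
    left_join(per_sample, by = "compound")
  dup <- info$compound[info$n_rt > 1 | info$max_per_sample > 1]
  if (length(dup) == 0) return(tbl)
  bad <- info$compound[info$compound %in% dup & info$any_na_rt]
  if (length(bad) > 0) {
    abort(sprintf("duplicated compound name(s) with missing retention time: %s",
                  paste(bad, collapse = ", ")))
  }
  tbl %>%
    mutate(compound = ifelse(compound %in% dup,
                             sprintf("%s@%.2f", compound, rt),
                             compound))
}
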