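# End-to-end run: parse -> design -> normalise -> QC -> (tracing ->
# correction) -> statistics -> plots -> tables -> zip.  Driven by a single
# config (an R list or a YAML file) so a run can be repeated exactly.

default_config <- function() {
  list(
    input = NULL,
    dialect = "other_list",
    delim = NULL,
    missing = list(extra_tokens = character(), zeros_as_missing = FALSE,
                   threshold = NULL),
    sample_table = NULL,
    external = list(mode = "off"),
    internal = list(mode = "off", standards = character(),
                    timing = "after_external"),
    total_peak_sum = FALSE,
    qc = list(enabled = TRUE, tolerance = 2),
    average_technical = NULL,   # NULL = auto when both replicate levels set
    tracing = FALSE,
    correction = list(enabled = FALSE, formulas = NULL, tracer = "C13",
                      purity = 1, tracer_only = TRUE),
    stats = NULL,
    plots = list(),
    tracing_plots = c("stacked_absolute", "stacked_relative"),
    out_dir = NULL,
    max_upload_mb = 25
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to defaults (see the
#' package vignette for the full key list).
#'
#' @param path YAML file path.
#' @return Config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(user)
}

merge_config <- function(user) {
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Run the full processing and plotting pipeline
#'
#' Executes every configured stage in order: input parsing, sample-design
#' loading, external correction, replicate QC, internal-standard or
#' total-peak-sum normalisation (before or after the external step,
#' per `internal$timing`), technical-replicate averaging, isotopologue
#' grouping and natural-abundance correction for tracing data, group
#' statistics, per-metabolite plot rendering and structured-table export,
#' and finally bundles `Plots/`, `Tables/` and `Inputs/` into
#' `results.zip`.  The zip is only written once every stage has succeeded.
#' Each stage logs one line with its record counts; the log is saved as
#' `run_log.txt`.
#'
#' @param config A config list (see [read_run_config()]) or the path to a
#'   YAML config file.
#' @return Invisibly, a list with `out_dir`, `zip`, `plots` (paths),
#'   `tables` (paths), `qc` (the QC report or `NULL`) and `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(config)
  if (is.null(cfg$input) || is.null(cfg$sample_table) || is.null(cfg$out_dir)) {
    abort("config needs at least: input, sample_table, out_dir")
  }
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log <<- c(log, line)
  }

  size_mb <- file.size(cfg$input) / 2^20
  if (is.na(size_mb)) abort(sprintf("input file not found: %s", cfg$input))
  if (size_mb > cfg$max_upload_mb) {
    abort(sprintf("input file is %.1f MB, above the %g MB limit",
                  size_mb, cfg$max_upload_mb))
  }

  policy <- missing_policy(
    extra_tokens = cfg$missing$extra_tokens %||% character(),
    zeros_as_missing = isTRUE(cfg$missing$zeros_as_missing),
    threshold = cfg$missing$threshold
  )
  tbl <- read_metabolite_table(cfg$input, cfg$dialect, policy,
                               delim = cfg$delim)
  say("parse: %d records, %d compounds, %d samples (%d missing)",
      nrow(tbl), n_distinct(tbl$compound), n_distinct(tbl$sample_id),
      sum(is.na(tbl$intensity)))

  design <- read_sample_design(cfg$sample_table, tbl)
  ann <- annotate_design(tbl, design)
  say("design: %d samples included over %d conditions",
      n_distinct(ann$sample_id), n_distinct(ann$condition))

  run_internal <- function(ann) {
    if (cfg$internal$mode != "off") {
      ann <- normalise_internal(ann, cfg$internal$standards,
                                mode = cfg$internal$mode)
      say("internal normalisation (%s, %d standard(s))",
          cfg$internal$mode, length(cfg$internal$standards))
    } else if (isTRUE(cfg$total_peak_sum)) {
      ann <- normalise_total(ann, mode = "relative")
      say("total-peak-sum normalisation")
    }
    ann
  }

  if (cfg$internal$timing == "before_external") ann <- run_internal(ann)
  if (cfg$external$mode != "off") {
    ann <- normalise_external(ann, mode = cfg$external$mode)
    say("external correction (%s)", cfg$external$mode)
  }

  qc <- NULL
  if (isTRUE(cfg$qc$enabled)) {
    qc <- tryCatch(
      replicate_fold_changes(ann, tolerance = cfg$qc$tolerance %||% 2),
      error = function(e) NULL
    )
    if (!is.null(qc)) {
      say("qc: %d fold changes, flagged: %s", nrow(qc$fold_changes),
          if (length(qc$flagged)) paste(qc$flagged, collapse = ", ")
          else "none")
    }
  }
  if (cfg$internal$timing != "before_external") ann <- run_internal(ann)

  avg <- cfg$average_technical %||%
    (!anyNA(design$experimental_replicate[design$include]) &&
       !anyNA(design$technical_replicate[design$include]) &&
       n_distinct(design$technical_replicate[design$include]) > 1)
  if (isTRUE(avg)) {
    ann <- average_technical(ann)
    say("technical averaging: %d records", nrow(ann))
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  plots_dir <- file.path(cfg$out_dir, "Plots")
  dir.create(plots_dir, showWarnings = FALSE)
  spec <- do.call(plot_spec, cfg$plots)
  allowed <- available_plot_types(design, tracing = isTRUE(cfg$tracing))
  if (!spec$plot_type %in% allowed && !isTRUE(cfg$tracing)) {
    abort(sprintf("plot type '%s' not available for this design (allowed: %s)",
                  spec$plot_type, paste(allowed, collapse = ", ")))
  }

  plot_paths <- character(0)
  tables <- character(0)

  if (isTRUE(cfg$tracing)) {
    grouped <- group_isotopologues(ann)
    say("tracing: %d isotopologue groups",
        n_distinct(grouped$base_compound))
    if (isTRUE(cfg$correction$enabled)) {
      tracer <- tracer_spec(cfg$correction$tracer %||% "C13",
                            purity = cfg$correction$purity %||% 1)
      grouped <- correct_isotopologues(
        grouped, cfg$correction$formulas, tracer,
        tracer_only = cfg$correction$tracer_only %||% TRUE)
      say("natural-abundance correction applied (%s, purity %.3f)",
          tracer$isotope, tracer$purity)
    } else {
      grouped <- relative_mid(grouped)
    }
    bases <- unique(grouped$base_compound)
    stems <- setNames(sanitize_filename(bases), bases)
    for (ptype in intersect(cfg$tracing_plots,
                            c("stacked_absolute", "stacked_relative"))) {
      pspec <- spec
      pspec$plot_type <- ptype
      suffix <- if (ptype == "stacked_relative") "_relative" else "_absolute"
      for (bc in bases) {
        sub <- filter(grouped, base_compound == bc)
        if (all(is.na(sub$intensity) | sub$intensity == 0)) next
        plot_paths <- c(plot_paths, render_metabolite(
          sub, bc, pspec, plots_dir,
          file_stem = paste0(stems[[bc]], suffix)))
      }
    }
    long_out <- grouped %>%
      mutate(compound = ifelse(shift == 0, base_compound,
                               sprintf("%s +%d", base_compound, shift)),
             rt = NA_real_) %>%
      select(any_of(c("compound", "rt", "sample_id", "intensity",
                      "condition", "experimental_replicate",
                      "correction_value", "order", "colour",
                      "technical_replicate")))
    tables <- c(tables, write_structured_tables(long_out, design,
                                                cfg$out_dir))
    tracing_tbl <- file.path(cfg$out_dir, "Tables", "isotopologues_long.csv")
    readr::write_csv(select(grouped, any_of(c(
      "base_compound", "shift", "sample_id", "condition", "intensity",
      "fraction", "residual", "corrected"))), tracing_tbl, na = "")
    tables <- c(tables, tracing_tbl)
  } else {
    stems <- setNames(sanitize_filename(unique(ann$compound)),
                      unique(ann$compound))
    if (!is.null(cfg$stats)) {
      spec$stats <- cfg$stats
    }
    for (cmp in unique(ann$compound)) {
      sub <- filter(ann, compound == cmp)
      if (all(is.na(sub$intensity))) {
        warn(sprintf("compound '%s' has no data; plot skipped", cmp))
        next
      }
      plot_paths <- c(plot_paths,
                      render_metabolite(sub, cmp, spec, plots_dir,
                                        file_stem = stems[[cmp]]))
    }
    tables <- c(tables, write_structured_tables(ann, design, cfg$out_dir))
    if (!is.null(cfg$stats)) {
      plan <- comparison_plan(levels(ann$condition),
                              mode = cfg$stats$mode %||% "all_pairwise",
                              reference = cfg$stats$reference)
      st <- compound_stats(ann, plan,
                           test = cfg$stats$test %||% "t_equal_var",
                           display = cfg$stats$display %||% "symbols")
      st_path <- file.path(cfg$out_dir, "Tables", "statistics.csv")
      readr::write_csv(st, st_path, na = "")
      tables <- c(tables, st_path)
      say("stats: %d comparisons", nrow(st))
    }
  }
  say("plots: %d file(s) written", length(plot_paths))

  if (!is.null(qc)) {
    qc_path <- file.path(cfg$out_dir, "Tables", "qc_fold_changes.csv")
    readr::write_csv(tidy(qc), qc_path, na = "")
    tables <- c(tables, qc_path)
    qc_plot <- file.path(plots_dir, paste0("_QC_replicates.", spec$format))
    ggplot2::ggsave(qc_plot, autoplot(qc), device = ggsave_device(spec$format),
                    width = spec$width * 1.5, height = spec$height,
                    dpi = spec$dpi, units = "in")
    plot_paths <- c(plot_paths, qc_plot)
  }

  writeLines(log, file.path(cfg$out_dir, "run_log.txt"))
  zip_path <- bundle_results(cfg$out_dir)
  say("bundle: %s (%d members)", zip_path,
      nrow(zip::zip_list(zip_path)))

  invisible(list(out_dir = cfg$out_dir, zip = zip_path, plots = plot_paths,
                 tables = tables, qc = qc, log = log))
}
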