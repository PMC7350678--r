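# Per-metabolite plot rendering.  One image per compound; styling is
# declarative via plot_spec() so a whole run uses identical settings.

# Default qualitative palette (Tol bright scheme) for conditions without
# user-defined colours; recycled through hcl.colors for very many conditions.
tol_bright <- c("#4477AA", "#EE6677", "#228833", "#CCBB44",
                "#66CCEE", "#AA3377", "#BBBBBB")

# Fixed tracing scales so isotopologue colours are identical between
# experiments.  The short scale covers M+0..M+7; the long scale is a stepped
# rainbow -- 5 hue blocks in 3 shades each after a neutral M+0 -- covering
# M+0..M+15, letting the reader count isotopologues at a glance.
tracing_scale_short <- c(
  "#781C81", "#413B93", "#4065B1", "#488BC2",
  "#55A1B1", "#63AD99", "#7FB972", "#B5BD4C"
)
tracing_scale_long <- c(
  "#777777",
  "#CAB2D6", "#9A77B8", "#6A3D9A",
  "#A6CEE3", "#6BAED6", "#1F78B4",
  "#B2DF8A", "#74C476", "#33A02C",
  "#FDBF6F", "#FE9929", "#FF7F00",
  "#FB9A99", "#EF6548", "#E31A1C"
)

#' Colour scale for isotopologue stacks
#'
#' @param kind `"short"` (8 colours, M+0..M+7) or `"long"` (16 colours,
#'   M+0..M+15, five hue blocks in three shades).
#' @return Character vector of hex colours, one per mass shift starting at
#'   M+0.
#' @export
tracing_palette <- function(kind = c("short", "long")) {
  kind <- match.arg(kind)
  if (kind == "short") tracing_scale_short else tracing_scale_long
}

plot_types <- c("bar", "points", "violin", "box",
                "replicate_points", "replicate_bars",
                "stacked_absolute", "stacked_relative")

#' Which plot types does a design support?
#'
#' Bar and scatter plots are always available.  Violin and box plots only
#' make sense with enough points and unlock at 5 respectively 10 replicate
#' measurements per condition (the minimum over conditions counts).
#' Replicate-comparison plots require experimental replicates to be defined.
#' Stacked isotopologue plots additionally require grouped tracing data
#' (`tracing = TRUE`).
#'
#' @param design Design tibble from [read_sample_design()].
#' @param tracing Whether grouped isotopologue data are available.
#' @return Character vector of admissible `plot_type` values.
#' @export
available_plot_types <- function(design, tracing = FALSE) {
  used <- filter(design, include)
  min_n <- used %>% dplyr::count(condition) %>% pull(n) %>% min()
  out <- c("bar", "points")
  if (min_n >= 5) out <- c(out, "violin")
  if (min_n >= 10) out <- c(out, "box")
  if (!anyNA(used$experimental_replicate) &&
      !all(is.na(used$experimental_replicate))) {
    out <- c(out, "replicate_points", "replicate_bars")
  }
  if (tracing) out <- c(out, "stacked_absolute", "stacked_relative")
  out
}

#' Declarative plot settings
#'
#' Collects every styling choice for a plotting run.  Defaults give a 4 x 4
#' inch, 300 dpi PNG bar plot with mean and standard deviation, 45 degree
#' x labels and no statistics.
#'
#' @param plot_type One of `r paste0('"', plot_types, '"', collapse = ", ")`.
#' @param hollow Outline instead of filled geometry.
#' @param overlay_points Overlay the individual measurements.
#' @param width,height Plot size in inches.
#' @param dpi Raster resolution.
#' @param format `"png"`, `"pdf"`, `"jpg"` or `"svg"`.
#' @param x_text_angle 0, 45 or 90 degrees.
#' @param font_title,font_axis,font_tick Font sizes in points.
#' @param x_title,y_title Axis titles.
#' @param name_prefix,name_suffix Text pasted around the compound name in
#'   the plot title and file name.
#' @param legend_instead_of_x Replace x labels with a colour legend.
#' @param show_n Annotate the number of values per condition.
#' @param stats `NULL`, or a list with `mode` (`"all_pairwise"` /
#'   `"vs_reference"`), optional `reference`, `test` and `display` -- see
#'   [comparison_plan()], [compare_groups()], [format_significance()].
#' @param colours Optional named vector condition -> colour overriding
#'   design/default colours.
#' @param tracing_scale `"short"` or `"long"`, for stacked plots.
#' @return A list of class `"plot_spec"`.
#' @export
plot_spec <- function(plot_type = "bar", hollow = FALSE,
                      overlay_points = FALSE, width = 4, height = 4,
                      dpi = 300, format = c("png", "pdf", "jpg", "svg"),
                      x_text_angle = 45, font_title = 14, font_axis = 12,
                      font_tick = 10, x_title = NULL, y_title = "Peak area",
                      name_prefix = "", name_suffix = "",
                      legend_instead_of_x = FALSE, show_n = FALSE,
                      stats = NULL, colours = NULL,
                      tracing_scale = c("short", "long")) {
  plot_type <- match.arg(plot_type, plot_types)
  format <- match.arg(format)
  stopifnot(x_text_angle %in% c(0, 45, 90), width > 0, height > 0, dpi > 0)
  structure(list(
    plot_type = plot_type, hollow = hollow,
    overlay_points = overlay_points, width = width, height = height,
    dpi = dpi, format = format, x_text_angle = x_text_angle,
    font_title = font_title, font_axis = font_axis, font_tick = font_tick,
    x_title = x_title, y_title = y_title,
    name_prefix = name_prefix, name_suffix = name_suffix,
    legend_instead_of_x = legend_instead_of_x, show_n = show_n,
    stats = stats, colours = colours,
    tracing_scale = match.arg(tracing_scale)
  ), class = "plot_spec")
}

condition_colours <- function(df, spec) {
  levels <- levels(factor(df$condition))
  if (!is.null(spec$colours)) {
    return(spec$colours[levels])
  }
  from_design <- if ("colour" %in% names(df)) {
    df %>% distinct(condition, colour = .data$colour) %>% filter(!is.na(colour))
  } else {
    tibble(condition = character(0), colour = character(0))
  }
  if (nrow(from_design) > 0) {
    cols <- setNames(rep(NA_character_, length(levels)), levels)
    cols[as.character(from_design$condition)] <- from_design$colour
    pal <- rep(tol_bright, length.out = length(levels))
    cols[is.na(cols)] <- pal[is.na(cols)]
    return(cols)
  }
  if (length(levels) <= length(tol_bright)) {
    setNames(tol_bright[seq_along(levels)], levels)
  } else {
    setNames(grDevices::hcl.colors(length(levels), "Dark 3"), levels)
  }
}

spec_theme <- function(spec) {
  hjust <- c(`0` = 0.5, `45` = 1, `90` = 1)[[as.character(spec$x_text_angle)]]
  vjust <- if (spec$x_text_angle == 90) 0.5 else 1
  ggplot2::theme_bw(base_size = spec$font_axis) +
    ggplot2::theme(
      plot.title = ggplot2::element_text(size = spec$font_title,
                                         hjust = 0.5),
      axis.text = ggplot2::element_text(size = spec$font_tick),
      axis.text.x = if (spec$legend_instead_of_x)
        ggplot2::element_blank()
      else
        ggplot2::element_text(size = spec$font_tick,
                              angle = spec$x_text_angle,
                              hjust = hjust, vjust = vjust),
      axis.ticks.x = if (spec$legend_instead_of_x)
        ggplot2::element_blank() else ggplot2::element_line(),
      panel.grid.major.x = ggplot2::element_blank(),
      legend.position = if (spec$legend_instead_of_x ||
                              spec$plot_type %in%
                              c("replicate_points", "replicate_bars",
                                "stacked_absolute", "stacked_relative"))
        "right" else "none"
    )
}

mean_sd_fun <- function(x) {
  x <- x[!is.na(x)]
  data.frame(y = mean(x),
             ymin = mean(x) - sd(x),
             ymax = mean(x) + sd(x))
}

#' Build the ggplot for one metabolite
#'
#' Quantitative types (`bar`, `points`, `violin`, `box`, `replicate_*`)
#' expect the annotated values of a single compound; stacked types expect
#' that compound's grouped isotopologue rows (with `shift` and, for
#' `stacked_relative`, `fraction`).  Bars and scatterplots show mean and
#' standard deviation (n-1); boxes show the median, quartiles and whiskers
#' at the most extreme point within 1.5 IQR; violins show the density and
#' the median.  Stacked bars average replicates per condition with M+0 at
#' the bottom of the stack.
#'
#' @param df Data for one compound.
#' @param compound Compound display name (used as plot title).
#' @param spec A [plot_spec()].
#' @return A ggplot object.
#' @export
plot_metabolite <- function(df, compound, spec = plot_spec()) {
  if (spec$plot_type %in% c("stacked_absolute", "stacked_relative")) {
    return(plot_isotopologues(df, compound, spec))
  }
  df <- filter(df, !is.na(intensity))
  if (nrow(df) == 0) abort(sprintf("no data for compound '%s'", compound))
  cols <- condition_colours(df, spec)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = condition, y = intensity))
  fill_aes <- ggplot2::aes(fill = condition)
  col_aes <- ggplot2::aes(colour = condition)
  jit <- ggplot2::position_jitter(width = 0.08, height = 0, seed = 1)
  layer <- switch(spec$plot_type,
    bar = if (spec$hollow) {
      ggplot2::stat_summary(col_aes, fun = mean, geom = "col",
                            fill = NA, linewidth = 0.7)
    } else {
      ggplot2::stat_summary(fill_aes, fun = mean, geom = "col",
                            colour = "black", linewidth = 0.3)
    },
    points = ggplot2::geom_point(col_aes, size = 2, position = jit),
    violin = if (spec$hollow) {
      ggplot2::geom_violin(col_aes, fill = NA)
    } else {
      ggplot2::geom_violin(fill_aes)
    },
    box = if (spec$hollow) {
      ggplot2::geom_boxplot(col_aes, fill = NA)
    } else {
      ggplot2::geom_boxplot(fill_aes)
    },
    replicate_points = ggplot2::geom_point(
      ggplot2::aes(colour = experimental_replicate), size = 2,
      position = jit),
    replicate_bars = ggplot2::geom_col(
      ggplot2::aes(fill = experimental_replicate),
      position = ggplot2::position_dodge(), colour = "black",
      linewidth = 0.3)
  )
  p <- p + layer
  if (spec$plot_type %in% c("bar", "points")) {
    p <- p + ggplot2::stat_summary(fun.data = mean_sd_fun,
                                   geom = "errorbar", width = 0.25)
  }
  if (spec$plot_type == "violin") {
    p <- p + ggplot2::stat_summary(fun = median, geom = "point", size = 2)
  }
  if (spec$overlay_points &&
      !spec$plot_type %in% c("points", "replicate_points")) {
    p <- p + ggplot2::geom_point(
      position = ggplot2::position_jitter(width = 0.08, height = 0, seed = 1),
      size = 1.5, colour = "black")
  }
  if (spec$plot_type %in% c("bar", "violin", "box", "points")) {
    p <- p + if (spec$hollow || spec$plot_type == "points") {
      ggplot2::scale_colour_manual(values = cols, drop = FALSE)
    } else {
      ggplot2::scale_fill_manual(values = cols, drop = FALSE)
    }
  }
  if (spec$show_n) {
    p <- p + ggplot2::stat_summary(
      fun.data = function(x) data.frame(y = 0, label = sprintf("n=%d",
                                                               sum(!is.na(x)))),
      geom = "text", vjust = 1.5, size = 3)
  }
  if (!is.null(spec$stats)) {
    p <- add_stat_brackets(p, df, spec)
  }
  p +
    ggplot2::labs(title = paste0(spec$name_prefix, compound,
                                 spec$name_suffix),
                  x = spec$x_title, y = spec$y_title) +
    ggplot2::expand_limits(y = 0) +
    spec_theme(spec)
}

plot_isotopologues <- function(df, compound, spec) {
  relative <- spec$plot_type == "stacked_relative"
  value_col <- if (relative) "fraction" else "intensity"
  if (relative && !"fraction" %in% names(df)) df <- relative_mid(df)
  pal <- tracing_palette(spec$tracing_scale)
  agg <- df %>%
    group_by(condition, shift) %>%
    summarise(value = mean(.data[[value_col]], na.rm = TRUE),
              .groups = "drop") %>%
    mutate(value = ifelse(is.nan(value), 0, value))
  if (relative) {
    agg <- agg %>%
      group_by(condition) %>%
      mutate(value = value / sum(value)) %>%
      ungroup()
  }
  max_shift <- max(agg$shift)
  if (max_shift + 1 > length(pal)) {
    pal <- c(pal, grDevices::hcl.colors(max_shift + 1 - length(pal),
                                        "Dark 3"))
  }
  shifts <- paste0("M+", 0:max_shift)
  agg <- mutate(agg, shift = factor(paste0("M+", shift), levels = shifts))
  ggplot2::ggplot(agg, ggplot2::aes(x = condition, y = value, fill = shift)) +
    ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE),
                      colour = "grey25", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = setNames(pal[seq_along(shifts)],
                                                 shifts),
                               name = NULL, drop = FALSE) +
    ggplot2::labs(title = paste0(spec$name_prefix, compound,
                                 spec$name_suffix),
                  x = spec$x_title,
                  y = if (relative) "Relative peak area (%)" else
                    spec$y_title) +
    (if (relative)
      ggplot2::scale_y_continuous(labels = function(x) 100 * x)
     else ggplot2::scale_y_continuous()) +
    spec_theme(spec)
}

add_stat_brackets <- function(p, df, spec) {
  st <- spec$stats
  plan <- comparison_plan(levels(factor(df$condition)),
                          mode = st$mode %||% "all_pairwise",
                          reference = st$reference)
  res <- purrr::pmap_dfr(plan, function(group_a, group_b) {
    out <- suppressWarnings(compare_groups(
      df$intensity[df$condition == group_a],
      df$intensity[df$condition == group_b],
      test = st$test %||% "t_equal_var"
    ))
    mutate(out, group_a = group_a, group_b = group_b)
  })
  res$label <- format_significance(res$p_value, st$display %||% "symbols")
  y_max <- max(df$intensity, na.rm = TRUE)
  lv <- levels(factor(df$condition))
  step <- 0.08 * y_max
  res <- res %>%
    mutate(x1 = match(group_a, lv), x2 = match(group_b, lv),
           y = y_max + step * row_number())
  p +
    ggplot2::geom_segment(
      data = res, inherit.aes = FALSE,
      ggplot2::aes(x = .data$x1, xend = .data$x2, y = .data$y,
                   yend = .data$y), linewidth = 0.3) +
    ggplot2::geom_text(
      data = res, inherit.aes = FALSE,
      ggplot2::aes(x = (.data$x1 + .data$x2) / 2, y = .data$y,
                   label = .data$label),
      vjust = -0.3, size = 3)
}

#' Make compound names safe and unique as file names
#'
#' Replaces the characters `: ; < > / \ | ? * "` by underscores.  An empty
#' result falls back to `"compound"`.  Names that collide after cleaning
#' get numeric suffixes (`_2`, `_3`, ...) so every compound keeps its own
#' file.
#'
#' @param x Character vector of compound names.
#' @return Character vector of unique, filesystem-safe names.
#' @examples
#' sanitize_filename(c("Glucose-6-P; pool", "A<B", "A>B"))
#' @export
sanitize_filename <- function(x) {
  out <- gsub('[:;<>/\\\\|?*"]', "_", x)
  out[out == ""] <- "compound"
  while (anyDuplicated(out)) {
    i <- which(duplicated(out))[1]
    n <- 2
    cand <- paste0(out[i], "_", n)
    while (cand %in% out) {
      n <- n + 1
      cand <- paste0(out[i], "_", n)
    }
    out[i] <- cand
  }
  out
}

ggsave_device <- function(format) {
  switch(format,
         png = grDevices::png,
         jpg = grDevices::jpeg,
         pdf = grDevices::pdf,
         svg = grDevices::svg)
}

#' Render one metabolite plot to disk
#'
#' @param df Data for one compound (see [plot_metabolite()]).
#' @param compound Compound display name.
#' @param spec A [plot_spec()].
#' @param out_dir Output directory (created if needed).
#' @param file_stem Optional pre-sanitised file stem; defaults to
#'   `sanitize_filename(compound)` with the spec's prefix/suffix.
#' @return The written file path, invisibly.
#' @export
render_metabolite <- function(df, compound, spec = plot_spec(),
                              out_dir = ".", file_stem = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot write to %s", out_dir))
  stem <- file_stem %||%
    sanitize_filename(paste0(spec$name_prefix, compound, spec$name_suffix))
  path <- file.path(out_dir, paste0(stem, ".", spec$format))
  p <- plot_metabolite(df, compound, spec)
  if (spec$format %in% c("png", "jpg")) {
    ggplot2::ggsave(path, p, device = ggsave_device(spec$format),
                    width = spec$width, height = spec$height,
                    dpi = spec$dpi, units = "in")
  } else {
    ggplot2::ggsave(path, p, device = ggsave_device(spec$format),
                    width = spec$width, height = spec$height, units = "in")
  }
  invisible(path)
}

#' Bundle a result folder into a zip archive
#'
#' Packs the `Plots/`, `Tables/` and `Inputs/` subfolders of a run directory
#' into one zip file with those folders at the top level.  Members are added
#' in sorted order so two runs on identical inputs produce identical
#' archive listings.
#'
#' @param dir Run output directory containing at least one of the three
#'   subfolders with files.
#' @param zip_path Destination archive; defaults to `dir/results.zip`.
#' @return The zip path, invisibly.
#' @export
bundle_results <- function(dir, zip_path = file.path(dir, "results.zip")) {
  subdirs <- c("Plots", "Tables", "Inputs")
  files <- sort(unlist(lapply(subdirs, function(d) {
    if (!dir.exists(file.path(dir, d))) return(character(0))
    list.files(file.path(dir, d), recursive = TRUE, full.names = FALSE,
               all.files = FALSE) |>
      (\(x) file.path(d, x))()
  })))
  if (length(files) == 0) abort("nothing to bundle: no files under Plots/, Tables/ or Inputs/")
  if (file.exists(zip_path)) unlink(zip_path)
  zip::zip(normalizePath(zip_path, mustWork = FALSE), files = files,
           root = dir, include_directories = FALSE, mode = "mirror")
  invisible(zip_path)
}
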