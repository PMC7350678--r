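#' Replicate-performance quality control
#'
#' For every metabolite, computes the relative fold change of each replicate
#' against the arithmetic mean of the non-missing replicates of the same
#' condition: `f(m, s) = I(m, s) / mean_cond(I(m, .))`.  With comparable
#' replicates the per-metabolite fold changes are exactly centred at 1, so
#' the distribution of fold changes per sample (and its mean over all
#' metabolites) exposes samples that were systematically too concentrated or
#' too dilute -- independent of outliers in single metabolites and robust to
#' missing values, which simply contribute no fold change.
#'
#' Conditions with a single replicate carry no information about replicate
#' agreement and are skipped with a warning.
#'
#' @param tbl Annotated measurement tibble ([annotate_design()]), optionally
#'   after normalisation.
#' @param tolerance Flagging threshold passed to [flag_outlier_samples()]:
#'   a sample whose mean fold change differs from 1 by more than this factor
#'   (in either direction) is flagged.  Default 2.
#' @return An object of class `"metaboplot_qc"`: a list with `fold_changes`
#'   (tibble of compound, sample_id, condition, fold_change), `per_sample`
#'   (tibble of sample_id, condition, per_sample_mean, n_metabolites),
#'   `flagged` (character vector of sample ids) and `tolerance`.
#' @seealso [flag_outlier_samples()], [autoplot.metaboplot_qc()]
#' @export
replicate_fold_changes <- function(tbl, tolerance = 2) {
  n_rep <- tbl %>%
    distinct(sample_id, condition) %>%
    dplyr::count(condition)
  single <- n_rep$condition[n_rep$n < 2]
  if (length(single) == nrow(n_rep)) {
    abort("no condition has >= 2 replicates; cannot compute fold changes")
  }
  if (length(single) > 0) {
    warn(sprintf("condition(s) with a single replicate skipped: %s",
                 paste(single, collapse = ", ")))
  }
  fc <- tbl %>%
    filter(!condition %in% single) %>%
    group_by(compound, condition) %>%
    mutate(fold_change = intensity / mean(intensity, na.rm = TRUE)) %>%
    ungroup() %>%
    filter(!is.na(fold_change), is.finite(fold_change)) %>%
    select(compound, sample_id, condition, fold_change)
  # leave-one-out fold changes drive outlier flagging: the self-inclusive
  # mean compresses a k-fold deviation to kn/(n+1), so a doubled sample
  # could never reach a 2-fold threshold under the centred statistic.
  loo <- tbl %>%
    filter(!condition %in% single) %>%
    group_by(compound, condition) %>%
    mutate(fold_change_loo = {
      s_tot <- sum(intensity, na.rm = TRUE)
      n_ok <- sum(!is.na(intensity))
      other_mean <- (s_tot - dplyr::coalesce(intensity, 0)) /
        pmax(n_ok - !is.na(intensity), 1)
      intensity / other_mean
    }) %>%
    ungroup() %>%
    filter(!is.na(fold_change_loo), is.finite(fold_change_loo))
  per_sample <- fc %>%
    group_by(sample_id, condition) %>%
    summarise(per_sample_mean = mean(fold_change),
              n_metabolites = n(), .groups = "drop") %>%
    left_join(
      loo %>% group_by(sample_id) %>%
        summarise(loo_mean = mean(fold_change_loo), .groups = "drop"),
      by = "sample_id"
    )
  out <- structure(
    list(fold_changes = fc, per_sample = per_sample,
         flagged = character(0), tolerance = tolerance),
    class = "metaboplot_qc"
  )
  out$flagged <- flag_outlier_samples(out, tolerance)
  out
}

#' Flag outlier samples from a QC report
#'
#' A sample is flagged when its mean leave-one-out fold change (each
#' intensity divided by the mean of the *other* replicates of its
#' condition) reaches the tolerance factor on the log2 scale:
#' `|log2(loo_mean)| >= log2(tolerance)`.  The leave-one-out statistic
#' equals the true deviation factor for a uniformly off sample (a doubled
#' sample scores exactly 2), unlike the centred fold-change mean which
#' compresses it to `2n/(n+1)`.  Such samples differ
#' dramatically from their replicate partners and are candidates for
#' exclusion (set `Include = FALSE` in the sample table and re-run).
#'
#' @param report A `"metaboplot_qc"` object.
#' @param tolerance Fold-change tolerance, default 2; `Inf` disables
#'   flagging.
#' @return Character vector of flagged sample ids.
#' @export
flag_outlier_samples <- function(report, tolerance = 2) {
  stopifnot(inherits(report, "metaboplot_qc"), tolerance >= 1)
  ps <- report$per_sample
  stat <- ps$loo_mean %||% ps$per_sample_mean
  ps$sample_id[abs(log2(stat)) >= log2(tolerance) & is.finite(stat) &
                 tolerance < Inf]
}

#' @export
print.metaboplot_qc <- function(x, ...) {
  cat(sprintf("Replicate QC: %d fold changes, %d samples\n",
              nrow(x$fold_changes), nrow(x$per_sample)))
  cat(sprintf("Flagged (>%g-fold off): %s\n", x$tolerance,
              if (length(x$flagged)) paste(x$flagged, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Tidy a replicate QC report
#'
#' @param x A `"metaboplot_qc"` object.
#' @param ... Unused.
#' @return The per-metabolite fold-change tibble.
#' @export
tidy.metaboplot_qc <- function(x, ...) x$fold_changes

#' One-row-per-sample summary of a QC report
#'
#' @param x A `"metaboplot_qc"` object.
#' @param ... Unused.
#' @return Tibble with per-sample mean fold change and a `flagged` column.
#' @export
glance.metaboplot_qc <- function(x, ...) {
  mutate(x$per_sample, flagged = sample_id %in% x$flagged)
}

#' QC distribution plot
#'
#' One box per sample showing the distribution of per-metabolite fold
#' changes on a log2-scaled axis; well-behaved replicates centre at 1.
#' Flagged samples are coloured.
#'
#' @param object A `"metaboplot_qc"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metaboplot_qc <- function(object, ...) {
  df <- mutate(object$fold_changes,
               flagged = sample_id %in% object$flagged)
  ggplot2::ggplot(df, ggplot2::aes(x = sample_id, y = fold_change,
                                   fill = flagged)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey80",
                                          `TRUE` = "#CC3311")) +
    ggplot2::labs(x = NULL, y = "fold change vs condition mean") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   legend.position = "none")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
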