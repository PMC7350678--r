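# Group-comparison statistics shown on plots.  Deliberately simple: a
# two-sample t test assuming equal variances, or a two-sample Wilcoxon
# rank-sum (Mann-Whitney) test, pairwise or against a reference condition.
# p-values are reported raw -- no multiple-testing correction is applied,
# which users should keep in mind when scanning many metabolites.

#' Compare two groups of intensities
#'
#' Runs the chosen two-sample test on the non-missing values.  The t test
#' pools variances (equal-variance assumption); the Wilcoxon test is the
#' rank-sum test for independent groups, exact for small samples without
#' ties and normal-approximated with continuity correction otherwise.
#' Groups with fewer than two non-missing values cannot be tested: the
#' result row carries `NA` statistics and the display string `"n/a"`.
#'
#' @param values_a,values_b Numeric vectors (NA = missing).
#' @param test `"t_equal_var"` or `"wilcoxon"`.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("t_equal_var", "wilcoxon")) {
  test <- match.arg(test)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    warn("fewer than 2 values in a group; comparison skipped")
    return(tibble(test = test, statistic = NA_real_, p_value = NA_real_,
                  n_a = length(a), n_b = length(b)))
  }
  fit <- if (test == "t_equal_var") {
    t.test(a, b, var.equal = TRUE)
  } else {
    suppressWarnings(wilcox.test(a, b, correct = TRUE))
  }
  tibble(test = test, statistic = unname(fit$statistic),
         p_value = fit$p.value, n_a = length(a), n_b = length(b))
}

#' Plan which condition pairs to compare
#'
#' @param conditions Ordered character vector (or factor levels) of
#'   condition names.
#' @param mode `"all_pairwise"` for every unordered pair, `"vs_reference"`
#'   for each condition against one reference.
#' @param reference Reference condition (required for `"vs_reference"`).
#' @return Tibble with columns `group_a`, `group_b`.
#' @examples
#' comparison_plan(c("ctrl", "a", "b"), "vs_reference", reference = "ctrl")
#' @export
comparison_plan <- function(conditions,
                            mode = c("all_pairwise", "vs_reference"),
                            reference = NULL) {
  mode <- match.arg(mode)
  conditions <- as.character(unique(conditions))
  if (mode == "all_pairwise") {
    if (length(conditions) < 2) abort("need >= 2 conditions to compare")
    pairs <- utils::combn(conditions, 2)
    return(tibble(group_a = pairs[1, ], group_b = pairs[2, ]))
  }
  if (is.null(reference) || !reference %in% conditions) {
    abort(sprintf("reference condition '%s' not found",
                  reference %||% "<missing>"))
  }
  others <- setdiff(conditions, reference)
  tibble(group_a = reference, group_b = others)
}

#' Format p-values for plot annotation
#'
#' `"symbols"` uses the conventional star scheme: `ns` for p > 0.05, then
#' `*`, `**`, `***`, `****` at 0.05, 0.01, 0.001, 0.0001.  `"numeric"`
#' rounds to three significant figures with a display floor of `"<0.001"`.
#' `NA` p-values (untestable comparisons) render as `"n/a"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param style `"symbols"` or `"numeric"`.
#' @return Character vector.
#' @examples
#' format_significance(c(0.03, 0.2, 0.0004))
#' @export
format_significance <- function(p, style = c("symbols", "numeric")) {
  style <- match.arg(style)
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  if (style == "symbols") {
    out <- dplyr::case_when(
      is.na(p) ~ "n/a",
      p <= 1e-4 ~ "****",
      p <= 1e-3 ~ "***",
      p <= 1e-2 ~ "**",
      p <= 0.05 ~ "*",
      TRUE ~ "ns"
    )
  } else {
    out <- ifelse(is.na(p), "n/a",
                  ifelse(p < 1e-3, "<0.001",
                         format(signif(p, 3), scientific = FALSE,
                                trim = TRUE, drop0trailing = TRUE)))
  }
  out
}

#' Per-compound statistics table
#'
#' Applies [compare_groups()] to every compound for every planned condition
#' pair, producing the table exported alongside the plots and used for
#' bracket annotation.
#'
#' @param tbl Annotated measurement tibble (after replicate averaging, if
#'   used).
#' @param plan Pair table from [comparison_plan()]; defaults to all
#'   pairwise comparisons of the conditions present.
#' @param test `"t_equal_var"` or `"wilcoxon"`.
#' @param display `"symbols"` or `"numeric"`.
#' @return Tibble with one row per (compound, pair): `compound`, `group_a`,
#'   `group_b`, `test`, `statistic`, `p_value`, `n_a`, `n_b`, `display`.
#' @export
compound_stats <- function(tbl, plan = NULL,
                           test = c("t_equal_var", "wilcoxon"),
                           display = c("symbols", "numeric")) {
  test <- match.arg(test)
  display <- match.arg(display)
  plan <- plan %||% comparison_plan(levels(factor(tbl$condition)))
  out <- purrr::map_dfr(unique(tbl$compound), function(cmp) {
    sub <- filter(tbl, compound == cmp)
    purrr::pmap_dfr(plan, function(group_a, group_b) {
      res <- suppressWarnings(compare_groups(
        sub$intensity[sub$condition == group_a],
        sub$intensity[sub$condition == group_b],
        test = test
      ))
      mutate(res, compound = cmp, group_a = group_a, group_b = group_b)
    })
  })
  out %>%
    mutate(display = format_significance(p_value, display)) %>%
    select(compound, group_a, group_b, test, statistic, p_value,
           n_a, n_b, display)
}
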