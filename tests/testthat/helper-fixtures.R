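# Shared helpers: tiny in-code fixtures and independent brute-force oracles.

# A small annotated table: n_rep replicates per condition, constant
# intensities unless `values` given (list keyed "compound.condition").
make_annotated <- function(compounds = c("A", "B"),
                           conditions = c("c1", "c2"),
                           n_rep = 3, value = 100,
                           correction = NULL) {
  rows <- expand.grid(compound = compounds, condition = conditions,
                      rep = seq_len(n_rep), stringsAsFactors = FALSE)
  tbl <- tibble::tibble(
    compound = rows$compound,
    rt = NA_real_,
    sample_id = paste(rows$condition, rows$rep, sep = "_"),
    intensity = value,
    condition = factor(rows$condition, levels = conditions),
    order = match(rows$condition, conditions),
    colour = NA_character_,
    experimental_replicate = paste0("r", rows$rep),
    technical_replicate = "t1",
    correction_value = if (is.null(correction)) 1 else
      correction[paste(rows$condition, rows$rep, sep = "_")]
  )
  tbl
}

# Exhaustive enumeration oracle for the isotope-pattern model: every atom is
# assigned each of its isotope states; probabilities multiply, mass shifts
# add.  Only feasible for a handful of atoms.
enum_distribution <- function(formula, tracer = metaboplot::tracer_spec("C13"),
                              labelled = 0,
                              isotopes = metaboplot::default_isotope_table(),
                              tracer_only = TRUE) {
  if (is.character(formula)) formula <- metaboplot::parse_formula(formula)
  atom_states <- list()
  states_of <- function(el) {
    ab <- isotopes[[el]]
    if (length(ab) == 0) return(data.frame(shift = 0, p = 1))
    data.frame(shift = c(0, as.integer(names(ab))), p = c(1 - sum(ab), ab))
  }
  n_tr <- formula[[tracer$element]]
  for (i in seq_len(labelled)) {
    atom_states[[length(atom_states) + 1]] <-
      data.frame(shift = c(0, 1), p = c(1 - tracer$purity, tracer$purity))
  }
  for (i in seq_len(n_tr - labelled)) {
    atom_states[[length(atom_states) + 1]] <- states_of(tracer$element)
  }
  if (!tracer_only) {
    for (el in setdiff(names(formula), tracer$element)) {
      for (i in seq_len(formula[[el]])) {
        atom_states[[length(atom_states) + 1]] <- states_of(el)
      }
    }
  }
  if (length(atom_states) == 0) return(1)
  grid <- do.call(expand.grid, lapply(atom_states, function(s) seq_len(nrow(s))))
  total_shift <- rowSums(mapply(function(s, idx) s$shift[idx],
                                atom_states, grid))
  prob <- apply(mapply(function(s, idx) s$p[idx], atom_states, grid), 1, prod)
  out <- numeric(max(total_shift) + 1)
  for (k in seq_along(total_shift)) {
    out[total_shift[k] + 1] <- out[total_shift[k] + 1] + prob[k]
  }
  out
}

# Exact two-sided rank-sum p-value by enumeration of all assignments of the
# pooled ranks to group A (no ties assumed).
brute_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(length(pooled), length(a))
  w_all <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - length(a) * (length(a) + 1) / 2
  })
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Closed-form pooled-variance two-sample t test (textbook formula).
pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

expect_tables_equal <- function(t1, t2) {
  key <- function(x) dplyr::arrange(
    dplyr::select(tibble::as_tibble(x), compound, rt, sample_id, intensity),
    compound, sample_id)
  expect_equal(as.data.frame(key(t1)), as.data.frame(key(t2)),
               tolerance = 1e-12, ignore_attr = TRUE)
}

# A bare design table with n_rep samples in each of two conditions.
design_with <- function(n_rep, with_reps = FALSE) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(2 * n_rep)),
    condition = rep(c("c1", "c2"), each = n_rep),
    order = rep(1:2, each = n_rep), colour = NA_character_,
    experimental_replicate = if (with_reps)
      rep(paste0("r", seq_len(n_rep)), 2) else NA_character_,
    technical_replicate = NA_character_,
    correction_value = NA_real_, include = TRUE
  )
}
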