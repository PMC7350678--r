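# Synthetic fixture generation.  Emulates what peak-integration software
# exports: log-normally distributed compound abundances, per-condition
# effects, multiplicative replicate noise, missing values concentrated in
# low-abundance compounds, and -- for tracing fixtures -- isotopologue
# intensities forward-simulated through the natural-abundance correction
# matrix so the correction stage has a known ground truth.

#' Specification for a synthetic dataset
#'
#' Defaults describe a typical small targeted experiment: 10 compounds,
#' 3 conditions, 3 biological replicates, single measurement each,
#' peak areas around 1e6 with 2-fold between-compound spread, ~30%
#' between-condition effects and 10% replicate noise; no missing values
#' unless requested.  Tracing mode simulates every compound as a
#' C3--C6 molecule with a condition-specific random true mass-isotopomer
#' distribution and 13C natural abundance baked into the measured signal.
#'
#' @param n_compounds,n_conditions,n_experimental,n_technical Dataset shape.
#' @param tracing Simulate isotopologue data.
#' @param carbon_range Min/max carbon count per compound (tracing only).
#' @param missing_rate Fraction of cells to blank out, preferentially in
#'   low-abundance compounds.
#' @param effect_sd Log-scale standard deviation of per-condition effects.
#' @param noise_sd Log-scale standard deviation of replicate noise.
#' @param base_meanlog,base_sdlog Log-normal parameters of compound
#'   abundances.
#' @param purity Tracer purity used in the forward simulation.
#' @param seed Random seed; fixed seed implies byte-identical files.
#' @return List of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_compounds = 10, n_conditions = 3,
                         n_experimental = 3, n_technical = 1,
                         tracing = FALSE, carbon_range = c(3, 6),
                         missing_rate = 0, effect_sd = 0.3,
                         noise_sd = 0.1, base_meanlog = log(1e6),
                         base_sdlog = log(2), purity = 1, seed = 1) {
  stopifnot(n_compounds >= 1, n_conditions >= 1, n_experimental >= 1,
            n_technical >= 1, missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "fixture_spec")
}

rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

#' Simulate a measurement table and its design
#'
#' Returns in-memory tibbles; [generate_fixture()] writes them to disk in a
#' chosen dialect.
#'
#' @param spec A [fixture_spec()].
#' @return List with `table` (long measurement tibble), `design` (template
#'   columns, pre-filled), `formulas` (tibble or `NULL`) and `truth` (for
#'   tracing: tibble of true fractional MIDs).
#' @export
simulate_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  conds <- sprintf("cond%d", seq_len(spec$n_conditions))
  samples <- tidyr::expand_grid(
    condition = conds,
    exp_rep = sprintf("r%d", seq_len(spec$n_experimental)),
    tech_rep = sprintf("t%d", seq_len(spec$n_technical))
  ) %>%
    mutate(sample_id = paste(condition, exp_rep, tech_rep, sep = "_"))

  if (!spec$tracing) {
    compounds <- sprintf("Metab%02d", seq_len(spec$n_compounds))
    abundance <- rlnorm(spec$n_compounds, spec$base_meanlog, spec$base_sdlog)
    names(abundance) <- compounds
    effects <- matrix(rlnorm(spec$n_compounds * spec$n_conditions,
                             0, spec$effect_sd),
                      nrow = spec$n_compounds,
                      dimnames = list(compounds, conds))
    tbl <- tidyr::expand_grid(compound = compounds,
                              sample_id = samples$sample_id) %>%
      left_join(samples, by = "sample_id") %>%
      mutate(
        rt = NA_real_,
        intensity = abundance[compound] * effects[cbind(compound, condition)] *
          rlnorm(n(), 0, spec$noise_sd)
      ) %>%
      select(compound, rt, sample_id, intensity)
    truth <- NULL
    formulas <- NULL
    base_abund <- setNames(abundance, compounds)
  } else {
    bases <- sprintf("Met%02d", seq_len(spec$n_compounds))
    n_c <- sample(spec$carbon_range[1]:spec$carbon_range[2],
                  spec$n_compounds, replace = TRUE)
    names(n_c) <- bases
    abundance <- rlnorm(spec$n_compounds, spec$base_meanlog, spec$base_sdlog)
    names(abundance) <- bases
    tracer <- tracer_spec("C13", purity = spec$purity)
    truth <- purrr::map_dfr(bases, function(bc) {
      purrr::map_dfr(conds, function(cd) {
        tibble(base_compound = bc, condition = cd,
               shift = 0:n_c[[bc]], true_fraction = rdirichlet1(n_c[[bc]] + 1))
      })
    })
    tbl <- purrr::map_dfr(bases, function(bc) {
      cm <- build_correction_matrix(sprintf("C%d", n_c[[bc]]), tracer)
      purrr::map_dfr(seq_len(nrow(samples)), function(i) {
        s <- samples[i, ]
        mid <- truth$true_fraction[truth$base_compound == bc &
                                     truth$condition == s$condition]
        measured <- as.numeric(cm %*% mid) * abundance[[bc]] *
          rlnorm(n_c[[bc]] + 1, 0, spec$noise_sd)
        tibble(
          compound = c(bc, sprintf("%s +%d", bc, 1:n_c[[bc]])),
          rt = NA_real_, sample_id = s$sample_id, intensity = measured
        )
      })
    })
    formulas <- tibble(compound = bases,
                       formula = sprintf("C%dH%dO%d", n_c, 2 * n_c, n_c))
    base_abund <- abundance
  }

  if (spec$missing_rate > 0) {
    base_of <- if (spec$tracing) {
      parse_isotopologue_label(tbl$compound)$base
    } else {
      tbl$compound
    }
    tert <- stats::quantile(base_abund, 1 / 3)
    weight <- ifelse(base_abund[base_of] <= tert, 3, 1)
    n_miss <- round(spec$missing_rate * nrow(tbl))
    idx <- sample(nrow(tbl), n_miss, prob = weight)
    tbl$intensity[idx] <- NA_real_
  }

  design <- tibble(
    Sample = samples$sample_id,
    Condition = samples$condition,
    Order = match(samples$condition, conds),
    Colour = "",
    Experimental_Replicate = samples$exp_rep,
    Technical_Replicate = samples$tech_rep,
    Correction_Value = 1,
    Include = TRUE
  )
  list(table = tbl, design = design, formulas = formulas, truth = truth)
}

#' Write a synthetic dataset to disk in a given dialect
#'
#' Produces an input file that satisfies the chosen layout's column
#' contract, a pre-filled sample table and, for tracing fixtures, a
#' compound-to-formula table.
#'
#' @param spec A [fixture_spec()].
#' @param dialect Target input layout.
#' @param dir Output directory.
#' @param ext File extension for the input file (`"csv"`, `"tsv"`,
#'   `"xlsx"`).
#' @return List of paths: `input`, `sample_table`, `formulas` (or `NULL`),
#'   plus the simulated `truth` tibble for tracing fixtures.
#' @export
generate_fixture <- function(spec = fixture_spec(),
                             dialect = metaboplot_dialects(),
                             dir = tempdir(), ext = "csv") {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(spec)
  input <- file.path(dir, paste0("input_", dialect, ".", ext))
  write_metabolite_table(sim$table, input, dialect = dialect)
  sample_table <- file.path(dir, "sample_table.csv")
  readr::write_csv(sim$design, sample_table, na = "")
  formulas <- NULL
  if (!is.null(sim$formulas)) {
    formulas <- file.path(dir, "formulas.csv")
    readr::write_csv(sim$formulas, formulas, na = "")
  }
  list(input = input, sample_table = sample_table, formulas = formulas,
       truth = sim$truth)
}
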