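# Natural-abundance correction: formula parsing, isotope-pattern model,
# correction matrices and the NNLS deconvolution.

test_that("sum formulas parse; unsupported elements are rejected", {
  expect_equal(parse_formula("C10H16N5O13P3"),
               c(C = 10L, H = 16L, N = 5L, O = 13L, P = 3L, S = 0L))
  expect_equal(parse_formula("C10H17N3O6S"),
               c(C = 10L, H = 17L, N = 3L, O = 6L, P = 0L, S = 1L))
  expect_equal(parse_formula("CH4")[["H"]], 4L)
  expect_error(parse_formula("SiO2"), "Si")
  expect_error(parse_formula("C6H12Cl"), "Cl")
  expect_error(parse_formula("12C"), "cannot parse")
})

test_that("carbon-only patterns match the binomial closed form", {
  d3 <- natural_distribution("C3")
  expect_equal(d3, dbinom(0:3, 3, 0.011), tolerance = 1e-12)
  expect_equal(d3, c(0.967361669, 0.032277993, 0.000359007, 0.000001331),
               tolerance = 1e-8)
  d10 <- natural_distribution("C10")
  expect_equal(d10[2], 10 * 0.011 * 0.989^9, tolerance = 1e-12)
  # zero natural abundance + full purity = delta at the labelled count
  iso0 <- lapply(default_isotope_table(), function(x) x * 0)
  d <- natural_distribution("C4", labelled = 2, isotopes = iso0)
  expect_equal(d, c(0, 0, 1))
})

test_that("the convolution model equals exhaustive enumeration (<= 6 atoms)", {
  cases <- list(
    list(f = "C3",       lab = 0, purity = 1,    tronly = TRUE),
    list(f = "C4",       lab = 2, purity = 0.95, tronly = TRUE),
    list(f = "C2O2",     lab = 1, purity = 0.99, tronly = FALSE),
    list(f = "C2H2S",    lab = 0, purity = 1,    tronly = FALSE),
    list(f = "C3NO",     lab = 3, purity = 0.9,  tronly = FALSE),
    list(f = "CHNOS",    lab = 1, purity = 0.97, tronly = FALSE)
  )
  for (cs in cases) {
    tracer <- tracer_spec("C13", purity = cs$purity)
    got <- natural_distribution(cs$f, tracer, labelled = cs$lab,
                                tracer_only = cs$tronly)
    want <- enum_distribution(cs$f, tracer, labelled = cs$lab,
                              tracer_only = cs$tronly)
    n <- max(length(got), length(want))
    expect_equal(c(got, numeric(n - length(got))),
                 c(want, numeric(n - length(want))),
                 tolerance = 1e-12, label = cs$f)
  }
})

test_that("15N and 2H tracers use their element's atom count", {
  d <- natural_distribution("C3H7NO2", tracer_spec("N15"), labelled = 1)
  expect_equal(d, c(0, 1))   # one N, fully labelled, tracer-only
  expect_error(natural_distribution("C3H7NO2", tracer_spec("N15"),
                                    labelled = 2), "exceed")
})

test_that("correction matrices are column-stochastic up to truncation", {
  cm <- build_correction_matrix("C3")
  expect_equal(cm[1, 1], 0.967361669, tolerance = 1e-8)
  expect_equal(dim(cm), c(4, 4))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_true(all(abs(colSums(cm) - 1) < 1e-12))  # square: no truncation
  cm_trunc <- build_correction_matrix("C10", max_shift = 3)
  expect_true(all(colSums(cm_trunc) <= 1 + 1e-12))
  # zero abundance and purity 1 gives the identity
  iso0 <- lapply(default_isotope_table(), function(x) x * 0)
  expect_equal(build_correction_matrix("C5", isotopes = iso0),
               diag(6), ignore_attr = TRUE)
})

test_that("NNLS recovers known vectors and matches quadprog", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    A <- matrix(runif(n * n), n, n) + diag(n)
    x_true <- ifelse(runif(n) < 0.4, 0, runif(n))
    b <- as.numeric(A %*% x_true)
    fit <- nnls_solve(A, b)
    expect_lt(max(abs(fit$x - x_true)), 1e-7)
    # independent oracle: quadratic programming solution of the same problem
    qp <- quadprog::solve.QP(crossprod(A), crossprod(A, b), diag(n),
                             numeric(n))
    expect_equal(fit$x, pmax(qp$solution, 0), tolerance = 1e-6)
  }
  # inconsistent system: still non-negative with reported residual
  A <- build_correction_matrix("C4")
  b <- c(1, 0, 0, 0.5, 0)
  fit <- nnls_solve(A, b)
  expect_true(all(fit$x >= 0))
  expect_gt(fit$residual, 0)
})

test_that("correct_mid inverts the forward model", {
  cm <- build_correction_matrix("C6", tracer_spec("C13", purity = 0.97))
  x <- c(0.3, 0, 0.2, 0.5, 0, 0, 0)
  rec <- correct_mid(as.numeric(cm %*% x) * 1e7, cm)
  expect_equal(as.numeric(rec), x * 1e7, tolerance = 1e-6)
  # identity matrix: no-op
  m <- c(1, 2, 3)
  expect_equal(as.numeric(correct_mid(m, diag(3))), m)
  # all-zero measurement: all-zero output, no error
  expect_equal(as.numeric(correct_mid(numeric(4),
                                      build_correction_matrix("C3"))),
               numeric(4))
  # missing entries go in as zero, with a warning and a flag
  expect_warning(out <- correct_mid(c(1, NA, 0, 0), build_correction_matrix("C3")),
                 "missing")
  expect_true(attr(out, "had_missing"))
  expect_error(correct_mid(1:3, build_correction_matrix("C3")), "length")
})

test_that("signal is conserved and purity shifts mass downwards", {
  cm <- build_correction_matrix("C5", tracer_spec("C13", purity = 0.95))
  x <- c(0.1, 0.2, 0.3, 0.2, 0.1, 0.1)
  measured <- as.numeric(cm %*% x)
  rec <- correct_mid(measured, cm)
  expect_gte(sum(rec) + 1e-9, sum(measured))
  # purity monotonicity: mass moves to lower shifts, never higher
  hi <- natural_distribution("C5", tracer_spec("C13", 1.00), labelled = 3)
  lo <- natural_distribution("C5", tracer_spec("C13", 0.90), labelled = 3)
  expect_true(all(cumsum(lo) - cumsum(hi) >= -1e-12))
})

test_that("grouped tracing data are corrected against ground truth", {
  sim <- simulate_dataset(fixture_spec(n_compounds = 5, tracing = TRUE,
                                       noise_sd = 0, seed = 43))
  design <- read_sample_design(sim$design, sim$table)
  g <- group_isotopologues(annotate_design(sim$table, design))
  cc <- correct_isotopologues(g, tibble::deframe(sim$formulas))
  joined <- dplyr::inner_join(cc, sim$truth,
                              by = c("base_compound", "condition", "shift"))
  expect_lt(max(abs(joined$fraction - joined$true_fraction)), 1e-8)
  # a compound showing a shift beyond its carbon count is caught
  bad <- g
  bad$shift[1] <- 20L
  expect_error(suppressWarnings(
    correct_isotopologues(bad, tibble::deframe(sim$formulas))), "atoms")
  # compounds without a formula pass through with a warning
  fa <- tibble::deframe(sim$formulas)[-1]
  expect_warning(out <- correct_isotopologues(g, fa), "no sum formula")
  expect_false(all(out$corrected))
})
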