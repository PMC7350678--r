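# External, internal-standard and total-peak-sum normalisation.

test_that("external correction divides (absolute) and rescales (relative)", {
  tbl <- make_annotated(compounds = "A", conditions = "c1", n_rep = 2,
                        value = 1000,
                        correction = c(c1_1 = 2, c1_2 = 2))
  abs_out <- normalise_external(tbl, "absolute")
  expect_equal(abs_out$intensity, c(500, 500))

  tbl2 <- make_annotated(compounds = "A", conditions = "c1", n_rep = 2,
                         correction = c(c1_1 = 1, c1_2 = 3))
  tbl2$intensity <- c(100, 200)
  rel <- normalise_external(tbl2, "relative")
  expect_equal(rel$intensity, c(100 / 1 * 2, 200 / 3 * 2))  # mean(c) = 2

  # constant correction values: relative mode is the identity
  tbl3 <- make_annotated(correction = setNames(rep(5, 6),
                                               unique(make_annotated()$sample_id)))
  expect_equal(normalise_external(tbl3, "relative")$intensity, tbl3$intensity)

  tbl3$correction_value[1] <- NA
  expect_error(normalise_external(tbl3, "absolute"), "correction value")
})

test_that("internal standards are summed per sample", {
  tbl <- make_annotated(compounds = c("A", "B", "X"), conditions = "c1",
                        n_rep = 2)
  tbl$intensity[tbl$compound == "A"] <- c(100, 100)
  tbl$intensity[tbl$compound == "B"] <- c(300, 300)
  tbl$intensity[tbl$compound == "X"] <- c(800, 400)
  out <- normalise_internal(tbl, c("A", "B"), "absolute")
  expect_equal(out$intensity[out$compound == "X"], c(800, 400) / 400)
  # the standards remain in the table, normalised too
  expect_equal(out$intensity[out$compound == "A"], c(100, 100) / 400)

  # constant single standard in relative mode is the identity
  out2 <- normalise_internal(tbl, "A", "relative")
  expect_equal(out2$intensity[out2$compound == "X"],
               tbl$intensity[tbl$compound == "X"])

  # doubling a standard in one sample halves that sample (absolute mode)
  tbl2 <- tbl
  tbl2$intensity[tbl2$compound == "A" & tbl2$sample_id == "c1_1"] <- 200
  out3 <- normalise_internal(tbl2, "A", "absolute")
  base <- normalise_internal(tbl, "A", "absolute")
  expect_equal(out3$intensity[out3$compound == "X" & out3$sample_id == "c1_1"],
               base$intensity[base$compound == "X" & base$sample_id == "c1_1"] / 2)

  expect_error(normalise_internal(tbl, "Nope", "absolute"), "not found")
  tbl$intensity[tbl$compound == "A" & tbl$sample_id == "c1_1"] <- NA
  expect_warning(normalise_internal(tbl, c("A", "B"), "absolute"),
                 "contributes 0")
  tbl$intensity[tbl$compound == "B" & tbl$sample_id == "c1_1"] <- NA
  expect_error(suppressWarnings(normalise_internal(tbl, c("A", "B"), "absolute")),
               "c1_1")
})

test_that("total peak sum skips missing values and preserves grand totals", {
  tbl <- make_annotated(compounds = c("A", "B", "C", "D"), conditions = "c1",
                        n_rep = 1)
  tbl$intensity <- c(1, 2, 3, NA)
  out <- normalise_total(tbl, "absolute")
  expect_equal(out$intensity[1:3], c(1, 2, 3) / 6)    # c_s = 6, NA skipped
  expect_true(is.na(out$intensity[4]))

  # single sample in relative mode is unchanged (mean of one factor)
  expect_equal(normalise_total(tbl, "relative")$intensity, tbl$intensity)

  # complete fixture: relative mode preserves the grand total
  sim <- simulate_dataset(fixture_spec(n_compounds = 6, n_conditions = 2,
                                       n_experimental = 3, seed = 13))
  design <- read_sample_design(sim$design, sim$table)
  ann <- annotate_design(sim$table, design)
  rel <- normalise_total(ann, "relative")
  expect_equal(sum(rel$intensity), sum(ann$intensity), tolerance = 1e-9)
  # and every per-sample sum equals the pre-normalisation mean of sums
  sums <- as.numeric(tapply(rel$intensity, rel$sample_id, sum))
  expect_equal(sums,
               rep(mean(tapply(ann$intensity, ann$sample_id, sum)),
                   length(sums)),
               tolerance = 1e-9, ignore_attr = TRUE)

  tbl$intensity <- NA_real_
  expect_error(normalise_total(tbl, "absolute"), "no non-missing")
})

test_that("missing counts are invariant and operation order matters", {
  sim <- simulate_dataset(fixture_spec(n_compounds = 6, n_conditions = 2,
                                       n_experimental = 3,
                                       missing_rate = 0.15, seed = 17))
  design <- read_sample_design(sim$design, sim$table)
  design$correction_value <- seq_len(nrow(design))
  ann <- annotate_design(sim$table, design)
  n_missing <- sum(is.na(ann$intensity))
  for (out in list(normalise_external(ann, "absolute"),
                   normalise_external(ann, "relative"),
                   normalise_total(ann, "relative"))) {
    expect_equal(sum(is.na(out$intensity)), n_missing)
  }
  # internal-then-external differs from external-then-internal
  sim2 <- simulate_dataset(fixture_spec(n_compounds = 4, n_conditions = 2,
                                        n_experimental = 2, seed = 19))
  design2 <- read_sample_design(sim2$design, sim2$table)
  design2$correction_value <- c(1, 2, 3, 4)
  ann2 <- annotate_design(sim2$table, design2)
  a <- normalise_external(normalise_internal(ann2, "Metab01", "absolute"),
                          "absolute")
  b <- normalise_internal(normalise_external(ann2, "absolute"),
                          "Metab01", "absolute")
  expect_false(isTRUE(all.equal(a$intensity, b$intensity)))
})
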