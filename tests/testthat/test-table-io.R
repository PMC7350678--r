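# Parsing the five input layouts into the canonical long table.

test_that("other_list parses the minimal 4-column layout", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Metabolite,RT,Filename,Area",
               "Lactate,,s1,100",
               "Lactate,,s2,200",
               "Citrate,,s1,50"), path)
  tbl <- read_metabolite_table(path, "other_list")
  expect_equal(nrow(tbl), 3)
  expect_equal(sort(unique(tbl$compound)), c("Citrate", "Lactate"))
  expect_equal(sort(unique(tbl$sample_id)), c("s1", "s2"))
  expect_equal(tbl$intensity[tbl$compound == "Lactate" & tbl$sample_id == "s2"],
               200)
})

test_that("a header-only file yields an empty table, not an error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("Metabolite,RT,Filename,Area", path)
  tbl <- read_metabolite_table(path, "other_list")
  expect_equal(nrow(tbl), 0)
})

test_that("compounds_in_columns melts losslessly and preserves blanks", {
  sim <- simulate_dataset(fixture_spec(n_compounds = 8, n_conditions = 1,
                                       n_experimental = 5, seed = 11))
  tbl0 <- sim$table
  blank_keys <- head(order(tbl0$intensity), 3)
  tbl0$intensity[blank_keys] <- NA_real_
  path <- withr::local_tempfile(fileext = ".csv")
  write_metabolite_table(tbl0, path, "compounds_in_columns")
  tbl <- read_metabolite_table(path, "compounds_in_columns")
  expect_equal(nrow(tbl), 8 * 5)              # n_compounds x n_samples
  expect_equal(sum(is.na(tbl$intensity)), 3)  # exactly the blanked cells
  expect_tables_equal(tbl, tbl0)
  # re-pivot reproduces the file byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_metabolite_table(tbl, path2, "compounds_in_columns")
  expect_identical(readLines(path2), readLines(path))
})

test_that("classify_intensity applies tokens, zeros and thresholds", {
  pol <- missing_policy()
  expect_true(is.na(classify_intensity("N/F", pol, "other_list")))
  expect_true(is.na(classify_intensity("", pol, "other_list")))
  expect_equal(classify_intensity("0", pol, "compounds_in_columns"), 0)
  pol0 <- missing_policy(zeros_as_missing = TRUE)
  expect_true(is.na(classify_intensity("0", pol0, "compounds_in_columns")))
  expect_equal(classify_intensity("0", pol0, "other_list"), 0)  # dialect-gated
  polt <- missing_policy(threshold = 1000)
  expect_true(is.na(classify_intensity(850, polt, "compound_discoverer")))
  expect_equal(classify_intensity(1000, polt, "compound_discoverer"), 1000)
  expect_equal(classify_intensity(850, polt, "other_list"), 850)
  expect_error(classify_intensity("twelve", pol, "other_list"),
               "non-numeric")
})

test_that("duplicated names are merged with RT to two decimals", {
  tbl <- tibble::tibble(
    compound = c("Leucine", "Leucine", "Valine"),
    rt = c(7.31, 9.02, 5.5),
    sample_id = "s1", intensity = c(1, 2, 3)
  )
  out <- merge_duplicate_names(tbl)
  expect_setequal(out$compound, c("Leucine@7.31", "Leucine@9.02", "Valine"))
  # unique names untouched
  expect_identical(merge_duplicate_names(tbl[3, ]), tbl[3, ])
  # duplicates without RT cannot be rescued
  tbl$rt[1] <- NA
  expect_error(merge_duplicate_names(tbl), "retention time")
})

test_that("duplicated names in a fixture end up collision-free", {
  sim <- simulate_dataset(fixture_spec(n_compounds = 6, seed = 5))
  tbl <- sim$table
  # force 3 duplicated names with distinct RTs
  tbl$rt <- rep(seq_len(6), each = nrow(tbl) / 6)
  tbl$compound[tbl$compound %in% c("Metab04", "Metab05", "Metab06")] <-
    rep(c("Metab01", "Metab02", "Metab03"),
        each = sum(tbl$compound == "Metab04"))
  out <- merge_duplicate_names(tbl)
  counts <- dplyr::count(out, compound, sample_id)
  expect_true(all(counts$n == 1))
})

test_that("essential-column and duplicate errors carry context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Compound,Area", "x,1"), path)
  expect_error(read_metabolite_table(path, "tracefinder"), "Filename")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Metabolite,RT,Filename,Area",
               "Lactate,,s1,100", "Lactate,,s1,120"), path2)
  expect_error(read_metabolite_table(path2, "other_list"), "duplicated")
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Metabolite,RT,Filename,Area,Note", "Lactate,,s1,100,x"), path3)
  expect_warning(read_metabolite_table(path3, "other_list"), "extra column")
})

test_that("compound discoverer columns are matched and .raw is stripped", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    'Compound,RT [min],"Area: sampleA.raw (F1)","Norm. Area: sampleB.raw (F12)"',
    "Glucose,1.2,100,200"), path)
  tbl <- read_metabolite_table(path, "compound_discoverer")
  expect_setequal(tbl$sample_id, c("sampleA", "sampleB"))
  expect_equal(tbl$rt, c(1.2, 1.2))
})

test_that("semicolon-separated files accept comma decimal marks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Metabolite;RT;Filename;Area",
               "Lactate;2,50;s1;1234,5"), path)
  tbl <- read_metabolite_table(path, "other_list")
  expect_equal(tbl$intensity, 1234.5)
  expect_equal(tbl$rt, 2.5)
})

test_that("every dialect round-trips through its own serialisation", {
  sim <- simulate_dataset(fixture_spec(n_compounds = 5, n_conditions = 2,
                                       n_experimental = 3, missing_rate = 0.1,
                                       seed = 21))
  base <- sim$table
  for (d in metaboplot_dialects()) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_metabolite_table(base, path, d)
    t1 <- read_metabolite_table(path, d)
    expect_tables_equal(t1, base)
    path2 <- withr::local_tempfile(fileext = ".csv")
    write_metabolite_table(t1, path2, d)
    t2 <- read_metabolite_table(path2, d)
    expect_tables_equal(t1, t2)
  }
})

test_that("xlsx input parses like csv input", {
  sim <- simulate_dataset(fixture_spec(n_compounds = 4, seed = 9))
  p_csv <- withr::local_tempfile(fileext = ".csv")
  p_xlsx <- withr::local_tempfile(fileext = ".xlsx")
  write_metabolite_table(sim$table, p_csv, "other_matrix")
  write_metabolite_table(sim$table, p_xlsx, "other_matrix")
  expect_tables_equal(read_metabolite_table(p_csv, "other_matrix"),
                      read_metabolite_table(p_xlsx, "other_matrix"))
})

test_that("structured tables export missing as empty and round-trip", {
  sim <- simulate_dataset(fixture_spec(n_compounds = 2, n_conditions = 2,
                                       n_experimental = 2, seed = 2))
  tbl <- sim$table
  tbl$intensity[1] <- NA
  design <- read_sample_design(sim$design, tbl)
  ann <- annotate_design(tbl, design)
  dir <- withr::local_tempdir()
  paths <- write_structured_tables(ann, design, dir)
  expect_true(all(file.exists(paths)))
  # summary shape: compounds x conditions
  summ <- readr::read_csv(file.path(dir, "Tables", "condition_summary.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(summ), 2 * 2)
  expect_true(all(c("mean", "sd", "n") %in% names(summ)))
  # missing cells are empty strings in the csv, not zeros
  long_raw <- readLines(file.path(dir, "Tables", "measurements_long.csv"))
  expect_true(any(grepl(",$", long_raw)))
  # wide matrix re-read reproduces the long table
  wide_back <- read_metabolite_table(
    file.path(dir, "Tables", "measurements_matrix.csv"), "other_matrix")
  expect_tables_equal(wide_back, ann)
  # xlsx export agrees with csv export
  xl <- readxl::read_excel(file.path(dir, "Tables", "condition_summary.xlsx"))
  expect_equal(as.data.frame(xl), as.data.frame(summ), tolerance = 1e-9)
})
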