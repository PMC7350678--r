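# Plot-type gating, rendering, filenames and the result bundle.

test_that("violin unlocks at 5 and box at 10 replicates per condition", {
  expect_setequal(available_plot_types(design_with(3)), c("bar", "points"))
  expect_setequal(available_plot_types(design_with(4)), c("bar", "points"))
  t5 <- available_plot_types(design_with(5))
  expect_true("violin" %in% t5)
  expect_false("box" %in% t5)
  t10 <- available_plot_types(design_with(10))
  expect_true(all(c("violin", "box") %in% t10))
  expect_true(all(c("replicate_points", "replicate_bars") %in%
                    available_plot_types(design_with(3, with_reps = TRUE))))
  expect_true("stacked_relative" %in%
                available_plot_types(design_with(3), tracing = TRUE))
})

test_that("bar and box geometry match hand-computed statistics", {
  df <- make_annotated(compounds = "A", conditions = "c1", n_rep = 3)
  df$intensity <- c(1, 2, 3)
  p <- plot_metabolite(df, "A", plot_spec("bar"))
  built <- ggplot2::ggplot_build(p)
  expect_equal(built$data[[1]]$y, 2)                       # mean
  expect_equal(built$data[[2]]$ymin, 2 - 1)                # mean - sd
  expect_equal(built$data[[2]]$ymax, 2 + 1)

  df11 <- make_annotated(compounds = "A", conditions = "c1", n_rep = 11)
  df11$intensity <- 1:11
  pb <- ggplot2::ggplot_build(plot_metabolite(df11, "A", plot_spec("box")))
  box <- pb$data[[1]]
  expect_equal(box$middle, 6)
  expect_equal(c(box$lower, box$upper), c(3.5, 8.5))
  expect_equal(c(box$ymin, box$ymax), c(1, 11))            # within 1.5 IQR
})

test_that("relative stacks render segments summing to the full bar", {
  g <- tibble::tibble(
    base_compound = "A", shift = rep(0:2, 2),
    sample_id = rep(c("s1", "s2"), each = 3),
    intensity = c(2, 6, 2, 1, 3, 1),
    condition = factor("c1")
  )
  g <- relative_mid(g)
  p <- plot_metabolite(g, "A", plot_spec("stacked_relative"))
  built <- ggplot2::ggplot_build(p)
  expect_equal(sort(built$data[[1]]$ymax - built$data[[1]]$ymin),
               sort(c(0.2, 0.6, 0.2)), tolerance = 1e-9)
  expect_equal(max(built$data[[1]]$ymax), 1, tolerance = 1e-9)
})

test_that("filenames are sanitised and collision-free", {
  expect_equal(sanitize_filename("Glucose-6-P; pool"), "Glucose-6-P_ pool")
  expect_equal(sanitize_filename("Alanine"), "Alanine")
  expect_equal(sanitize_filename(c("A<B", "A>B")), c("A_B", "A_B_2"))
  expect_equal(sanitize_filename('a:b;c<d>e/f\\g|h?i*j"k'),
               "a_b_c_d_e_f_g_h_i_j_k")
})

test_that("rendered files carry their declared format", {
  df <- make_annotated(compounds = "A", n_rep = 3)
  dir <- withr::local_tempdir()
  png_path <- render_metabolite(df, "A", plot_spec(format = "png", dpi = 72,
                                                   width = 2, height = 2), dir)
  expect_identical(readBin(png_path, "raw", 8),
                   as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)))
  jpg_path <- render_metabolite(df, "A", plot_spec(format = "jpg", dpi = 72,
                                                   width = 2, height = 2), dir)
  expect_identical(readBin(jpg_path, "raw", 2), as.raw(c(0xFF, 0xD8)))
  svg_path <- render_metabolite(df, "A", plot_spec(format = "svg",
                                                   width = 2, height = 2), dir)
  expect_silent(xml2::read_xml(svg_path))
  pdf_path <- render_metabolite(df, "A", plot_spec(format = "pdf",
                                                   width = 2, height = 2), dir)
  expect_identical(rawToChar(readBin(pdf_path, "raw", 4)), "%PDF")
})

test_that("styling options produce valid plots", {
  df <- make_annotated(compounds = "A", n_rep = 5)
  df$colour <- ifelse(df$condition == "c1", "#FFAA25", "#4477AA")
  for (spec in list(
    plot_spec("bar", hollow = TRUE, overlay_points = TRUE, x_text_angle = 90),
    plot_spec("points", legend_instead_of_x = TRUE, show_n = TRUE),
    plot_spec("violin"),
    plot_spec("replicate_points"),
    plot_spec("replicate_bars"),
    plot_spec("bar", stats = list(mode = "all_pairwise", test = "wilcoxon",
                                  display = "numeric")),
    plot_spec("bar", name_prefix = "exp1 ", name_suffix = " (liver)")
  )) {
    p <- plot_metabolite(df, "A", spec)
    expect_s3_class(p, "ggplot")
    expect_no_error(ggplot2::ggplot_build(p))
  }
  expect_error(plot_spec("donut"), "arg")
  expect_error(plot_spec("bar", x_text_angle = 30), "x_text_angle")
})

test_that("bundling is deterministic and complete", {
  dir <- withr::local_tempdir()
  for (d in c("Plots", "Tables", "Inputs")) {
    dir.create(file.path(dir, d))
  }
  for (f in c("Plots/b.png", "Plots/a.png", "Tables/t.csv", "Inputs/i.csv")) {
    writeLines("x", file.path(dir, f))
  }
  z1 <- bundle_results(dir)
  l1 <- zip::zip_list(z1)$filename
  expect_equal(l1, sort(c("Plots/a.png", "Plots/b.png", "Tables/t.csv",
                          "Inputs/i.csv")))
  z2 <- bundle_results(dir, file.path(dir, "again.zip"))
  expect_identical(zip::zip_list(z2)$filename, l1)
  empty <- withr::local_tempdir()
  expect_error(bundle_results(empty), "nothing to bundle")
})
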