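test_that("spot tables parse cell-for-cell and round-trip losslessly", {
  spots <- rbind(
    make_spot(probe_id = "gA", col = 1L, fg_median_ch1 = 1024,
              fg_median_ch2 = 256, frac_fg_gt_bg2sd_ch1 = 0.8123456789),
    make_spot(probe_id = "gB", col = 2L, fg_median_ch1 = 333.25,
              bg_sd_ch1 = 12.5),
    make_spot(probe_id = "gC", col = 3L, fg_pixels_ch2 = 31L)
  )
  hyb <- hybridization(spots, "arr1", orientation = -1L, batch = "b2")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(hyb, path)

  back <- read_spot_table(path, array_id = "arr1", orientation = -1L,
                          batch = "b2")
  expect_identical(back$orientation, -1L)
  expect_equal(back$spots$fg_median_ch1, c(1024, 333.25, 1200))
  expect_equal(back$spots$frac_fg_gt_bg2sd_ch1[1], 0.8123456789,
               tolerance = 1e-12)
  expect_identical(back$spots$probe_id, c("gA", "gB", "gC"))
  for (cn in spot_columns()) {
    expect_equal(back$spots[[cn]], spots[[cn]], tolerance = 1e-12)
  }
})

test_that("missing columns and non-numeric cells are reported precisely", {
  spots <- make_spot()
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(spots[, setdiff(names(spots), "bg_sd_ch1")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_spot_table(path), "bg_sd_ch1",
               class = "poe_data_error")

  spots2 <- rbind(make_spot(probe_id = "g1"),
                  make_spot(probe_id = "g2", col = 2L))
  spots2$fg_median_ch2 <- as.character(spots2$fg_median_ch2)
  spots2$fg_median_ch2[2] <- "oops"
  utils::write.table(spots2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_spot_table(path), "row 2", class = "poe_data_error")

  expect_error(read_spot_table(tempfile()), "not found",
               class = "poe_data_error")
})

test_that("GenePix-style dialect maps columns and rescales percentages", {
  spots <- make_spot()
  gp <- data.frame(ID = spots$probe_id, Block = 1, Row = 1, Column = 1,
                   X = 100, Y = 100,
                   `F532 Median` = spots$fg_median_ch1, `F Pixels` = 50,
                   `% > B532+2SD` = 95, `B532 Median` = 100,
                   `B532 SD` = 25, `F635 Median` = spots$fg_median_ch2,
                   `% > B635+2SD` = 90, `B635 Median` = 110,
                   `B635 SD` = 28, check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".gpr.txt")
  utils::write.table(gp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  hyb <- read_spot_table(path, dialect = genepix_dialect(),
                         percent_fraction = TRUE)
  expect_equal(hyb$spots$frac_fg_gt_bg2sd_ch1, 0.95)
  expect_equal(hyb$spots$fg_median_ch2, spots$fg_median_ch2)
})

test_that("hybridization construction validates its invariants", {
  spots <- rbind(make_spot(), make_spot())  # duplicate grid position
  expect_error(hybridization(spots, "a"), "duplicate",
               class = "poe_data_error")
  expect_error(hybridization(make_spot(), "a", orientation = 2),
               class = "poe_data_error")
  expect_error(hybridization(make_spot(fg_median_ch1 = -5), "a"),
               "negative", class = "poe_data_error")
})

test_that("annotation tables validate arms and duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("g1", "g2"), arm = c("X", "2L"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_annotation(path)
  expect_identical(ann$arm[ann$gene_id == "g1"], "X")

  df$arm[2] <- "5R"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation(path), "5R", class = "poe_data_error")

  df$arm[2] <- "2L"; df$gene_id[2] <- "g1"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation(path), "duplicate", class = "poe_data_error")
})

test_that("atlas round trip preserves values and absence calls", {
  sim <- small_experiment()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atlas(sim$atlas, path)
  back <- read_atlas(path)
  expect_equal(back$values, sim$atlas$values, tolerance = 1e-10)
  expect_identical(back$present, sim$atlas$present)
  expect_identical(back$gene_id, sim$atlas$gene_id)
  # an "A" call reads back as present = FALSE
  expect_true(any(!back$present))
})

test_that("stats reports carry the 2x2 inputs verbatim", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_report(list(contingency_test(161, 1103, 205, 1002)), path)
  txt <- readLines(path)
  expect_true(any(grepl("a=161 b=1103 c=205 d=1002", txt)))
  back <- utils::read.delim(path)
  expect_equal(round(back$statistic, 2), 0.71)
})

test_that("result tables carry full precision and annotation columns", {
  sim <- small_experiment()
  ma <- suppressWarnings(lapply(sim$hybridizations, function(h) {
    normalize_hybridization(filter_hybridization(h)$hyb)
  }))
  em <- expression_matrix(ma, sim$truth$orientation, sim$truth$batch)
  fit <- dyeswap_fit(em)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast_results(fit, path, annotation = sim$catalog)
  back <- utils::read.delim(path)
  expect_identical(names(back)[1:3], c("gene_id", "arm", "tissue_class"))
  expect_equal(back$log2FC, fit$table$log2FC, tolerance = 1e-11)
})
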