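test_that("generated dataset has the shape forced by the design", {
  cfg <- simulation_config(n_genes = 1000L, seed = 3L)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$counts), c(1000L, 12L))
  expect_equal(sum(ds$samples$color == "red"), 6L)
  expect_equal(sum(ds$samples$color == "white"), 6L)
  expect_setequal(unique(ds$samples$method), c("laser", "manual"))
  expect_false(anyDuplicated(rownames(ds$counts)) > 0)
  expect_true(all(ds$counts >= 0))
  expect_true(all(ds$counts == floor(ds$counts)))
  # unaccounted genes fill up as silent
  expect_equal(sum(ds$truth$gene_class == "silent"),
               1000L - sum(cfg$class_counts))
})

test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- simulation_config(seed = 42L)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$regional, ds2$regional)
  expect_identical(ds1$stages, ds2$stages)
  expect_identical(ds1$truth, ds2$truth)
  ds3 <- generate_dataset(simulation_config(seed = 43L))
  expect_false(identical(ds1$counts, ds3$counts))
})

test_that("without contamination, MSZ markers are absent from white samples", {
  ds <- generate_dataset(simulation_config(
    seed = 5L, contamination_by_method = c(laser = 0, manual = 0)))
  markers <- ds$truth$gene_id[ds$truth$gene_class == "msz_marker"]
  whites <- ds$samples$sample_id[ds$samples$color == "white"]
  expect_true(all(ds$counts[markers, whites] == 0))
})

test_that("noise-free regional and stage tables match each class's pattern", {
  ds <- generate_dataset(simulation_config(seed = 9L))
  on_regions <- function(gene) {
    sub <- ds$regional[ds$regional$gene_id == gene, ]
    sort(sub$region[sub$value > 0])
  }
  by_class <- split(ds$truth$gene_id, ds$truth$gene_class)
  for (g in by_class$msz_marker) {
    expect_equal(on_regions(g), sort(c("anterior_PS", "anterior_midline")))
  }
  expect_equal(on_regions(by_class$msz_like_transient[1]), "anterior_PS")
  expect_equal(on_regions(by_class$neural[1]),
               sort(c("caudal_neural", "anterior_neural")))
  expect_equal(on_regions(by_class$paraxial[1]), "caudal_PS")
  expect_equal(on_regions(by_class$housekeeping[1]), sort(msz_regions()))
  expect_equal(on_regions(by_class$silent[1]), character())

  st <- ds$stages
  stage_on <- function(gene, stage) {
    sub <- st[st$gene_id == gene & st$stage == stage, ]
    any(sub$value > 0)
  }
  for (g in by_class$msz_marker) {
    expect_false(stage_on(g, "gastrulation"))
    expect_true(stage_on(g, "initiation"))
    sub <- st[st$gene_id == g & st$stage == "elongation", ]
    expect_true(all(tapply(sub$value[sub$region == "anterior_PS"],
                           sub$timepoint[sub$region == "anterior_PS"],
                           max) > 0))
  }
  expect_true(stage_on(by_class$gastrulation_transient[1], "gastrulation"))
  # msz_like_transient loses anterior-PS expression at the last timepoint
  g <- by_class$msz_like_transient[1]
  last_tp <- max(st$timepoint[st$stage == "elongation"])
  sub <- st[st$gene_id == g & st$stage == "elongation" &
              st$region == "anterior_PS", ]
  expect_true(all(sub$value[sub$timepoint < last_tp] > 0))
  expect_equal(sub$value[sub$timepoint == last_tp], 0)
})

test_that("red-sample means recover depth x base_mean at low dispersion", {
  cfg <- simulation_config(
    n_genes = 60L,
    class_counts = c(msz_marker = 4L, housekeeping = 20L),
    n_replicates_per_method = 50L,
    dispersion_by_method = c(laser = 0.01, manual = 0.01),
    dropout_prob_by_method = c(laser = 0, manual = 0),
    contamination_by_method = c(laser = 0, manual = 0),
    depth_factor_by_method = c(laser = 1, manual = 1),
    seed = 21L)
  ds <- generate_dataset(cfg)
  reds <- ds$samples$sample_id[ds$samples$color == "red"]
  marker <- ds$truth$gene_id[ds$truth$gene_class == "msz_marker"][1]
  x <- ds$counts[marker, reds]
  se <- stats::sd(x) / sqrt(length(x))
  expected <- cfg$library_size_mean * cfg$base_mean
  expect_lt(abs(mean(x) - expected), 3 * se)
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(simulation_config(contamination_by_method =
                                   c(laser = 1.5, manual = 0)),
               "contamination_by_method")
  expect_error(simulation_config(dispersion_by_method =
                                   c(laser = 0, manual = 0.1)),
               "dispersion_by_method")
  expect_error(simulation_config(dropout_prob_by_method = c(laser = 0.2)),
               "dropout_prob_by_method")
  expect_error(simulation_config(n_genes = 10L), "class_counts")
  expect_error(simulation_config(base_mean = -1), "base_mean")
  expect_error(simulation_config(class_counts = c(unknown_class = 5L)),
               "class_counts")
})

test_that("dataset round-trips through its on-disk formats", {
  ds <- generate_dataset(simulation_config(n_genes = 50L,
    class_counts = c(msz_marker = 4L, neural = 10L), seed = 2L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, mtx = TRUE)
  counts_tsv <- read_count_matrix(file.path(dir, "counts.tsv"))
  expect_equal(counts_tsv, ds$counts, ignore_attr = FALSE)
  counts_mtx <- read_count_matrix(file.path(dir, "counts.mtx"))
  expect_equal(unname(counts_mtx), unname(ds$counts * 1.0))
  expect_equal(dimnames(counts_mtx), dimnames(ds$counts))
  sheet <- read_sample_sheet(file.path(dir, "samples.csv"))
  expect_equal(as.data.frame(sheet), as.data.frame(ds$samples))
  reg <- read_regional_table(file.path(dir, "regional.tsv"))
  expect_equal(reg$value, ds$regional$value)
  st <- read_stage_table(file.path(dir, "stages.tsv"))
  expect_equal(nrow(st), nrow(ds$stages))
  truth <- read_truth(file.path(dir, "truth.csv"))
  expect_equal(truth$gene_class, ds$truth$gene_class)
})
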