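test_that("activity tables read in ChEMBL dialect, in file order", {
  path <- write_chembl_fixture()
  ds <- read_activity_table(path, receptor = "CXCR3")
  expect_s3_class(ds, "activity_dataset")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$records$compound_id, c("CHEMBL1", "CHEMBL2", "CHEMBL3"))
  expect_equal(ds$records$pchembl, c(7.2, 5.5, 9.4))
  expect_equal(ds$receptor, "CXCR3")
})

test_that("rows without a usable pChEMBL value are removed; 'inactive' maps to 0", {
  rows <- data.frame(
    `Molecule ChEMBL ID` = c("A", "B", "C", "D"),
    Smiles = c("CCO", "CCC", "CCN", "CCF"),
    `pChEMBL Value` = c("7.1", "", "inactive", "6.0"),
    check.names = FALSE)
  ds <- suppressMessages(read_activity_table(write_chembl_fixture(rows)))
  expect_equal(nrow(ds$records), 3)          # B dropped
  expect_equal(ds$records$pchembl[ds$records$compound_id == "C"], 0)
})

test_that("degenerate and malformed tables are handled explicitly", {
  hdr <- write_chembl_fixture(data.frame(
    `Molecule ChEMBL ID` = character(0), Smiles = character(0),
    `pChEMBL Value` = numeric(0), check.names = FALSE))
  expect_warning(ds <- read_activity_table(hdr), "Empty dataset")
  expect_equal(nrow(ds$records), 0)
  expect_error(read_activity_table(tempfile()), "not found")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_activity_table(bad), "Molecule ChEMBL ID")
})

test_that("cleaning canonicalizes, dedupes and drops invalid SMILES, idempotently", {
  ds <- activity_dataset(data.frame(
    compound_id = c("a", "a", "b", "c", "d"),
    smiles = c("OCC", "OCC", "CCO", "C((", "c1ccccc1"),
    pchembl = c(7, 7, 6.2, 5, 8.4)))
  clean <- suppressMessages(clean_dataset(ds))
  # duplicate id collapsed, invalid SMILES dropped
  expect_equal(clean$records$compound_id, c("a", "b", "d"))
  # two spellings of ethanol agree after canonicalization
  expect_equal(clean$records$smiles[1], clean$records$smiles[2])
  expect_equal(clean$records$activity_class, c(5L, 4L, 6L))
  expect_identical(suppressMessages(clean_dataset(clean)), clean)
})

test_that("activity classes follow the seven pChEMBL bins", {
  expect_identical(assign_activity_class(3.5), 1L)   # below 4
  expect_identical(assign_activity_class(9.2), 7L)   # above 9
  expect_identical(assign_activity_class(0), 1L)     # inactive sentinel
  expect_identical(assign_activity_class(5.0), 3L)   # left-closed boundary
  expect_identical(assign_activity_class(c(4, 6.99, 8.2)), c(2L, 4L, 6L))
  expect_error(assign_activity_class(-0.1), "non-negative|>= 0")
  # monotone non-decreasing over a sweep
  p <- seq(0, 12, by = 0.01)
  expect_true(all(diff(assign_activity_class(p)) >= 0))
})

test_that("the splitter partitions 80/20, reproducibly", {
  ds <- activity_dataset(data.frame(
    compound_id = sprintf("m%d", 1:1000), smiles = "C", pchembl = 5))
  sp <- split_dataset(ds, seed = 42)
  expect_length(sp$train_indices, 800)
  expect_length(sp$validation_indices, 200)
  expect_length(intersect(sp$train_indices, sp$validation_indices), 0)
  expect_setequal(c(sp$train_indices, sp$validation_indices), 1:1000)
  expect_identical(sp, split_dataset(ds, seed = 42))
  expect_false(identical(sp$train_indices,
                         split_dataset(ds, seed = 43)$train_indices))
  expect_error(split_dataset(ds, fraction = 1.2), "between 0 and 1")
  expect_error(split_dataset(1), "at least 2")
})

test_that("stratified splitting keeps the fraction within each class", {
  rec <- data.frame(compound_id = sprintf("m%d", 1:200), smiles = "C",
                    pchembl = rep(c(3, 7.5), each = 100))
  ds <- activity_dataset(rec)
  ds$records$activity_class <- assign_activity_class(ds$records$pchembl)
  sp <- split_dataset(ds, seed = 9, stratify = TRUE)
  cls <- ds$records$activity_class[sp$train_indices]
  expect_equal(as.vector(table(cls)), c(80, 80))
})

test_that("class histogram counts match a hand tally and flag unlabeled records", {
  p <- c(9.5, 9.1, 10, 3, 4.2, 5.1, 5.9, 6.5, 7.7, 8.8)
  ds <- activity_dataset(data.frame(
    compound_id = sprintf("m%d", seq_along(p)), smiles = "C", pchembl = p))
  ds$records$activity_class <- assign_activity_class(p)
  h <- class_histogram(ds)
  expect_equal(unname(h), c(1, 1, 2, 1, 1, 1, 3))
  expect_equal(sum(h), nrow(ds$records))
  ds$records$activity_class[2] <- NA
  expect_error(class_histogram(ds), "m2")
})

test_that("write/read round-trip reproduces every retained field", {
  ds <- suppressMessages(clean_dataset(activity_dataset(data.frame(
    compound_id = c("x1", "x2", "x3"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)O"),
    pchembl = c(7.25, 0, 9.875)), receptor = "CCR2")))
  path <- tempfile(fileext = ".csv")
  write_activity_table(ds, path)
  back <- read_activity_table(path, dialect = "plain")
  expect_equal(back$records[, c("compound_id", "smiles", "pchembl")],
               ds$records[, c("compound_id", "smiles", "pchembl")])
  expect_equal(back$receptor, "CCR2")
})

test_that(".smi libraries read with and without explicit ids", {
  path <- tempfile(fileext = ".smi")
  writeLines(c("CCO cpd1", "c1ccccc1 cpd2", "CCN"), path)
  lib <- read_smiles_library(path)
  expect_equal(lib$compound_id, c("cpd1", "cpd2", "lib3"))
  expect_equal(lib$smiles, c("CCO", "c1ccccc1", "CCN"))
})
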