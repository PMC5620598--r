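test_that("feature tables round-trip through CSV at full precision", {
  ds <- labeled_dataset(matrix(c(1.1, 2.2, 3.3, 4.4, 1/3, exp(1), pi, sqrt(2)),
                               4, 2), c(1, 1, 2, 2))
  expect_equal(length(ds$n_per_class), 2)
  expect_equal(ds$n_per_class, c(2L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ds, path)
  back <- read_feature_table(path)
  expect_identical(back$features, ds$features)
  expect_identical(back$labels, ds$labels)

  # irrelevant flag survives the round trip
  ds2 <- labeled_dataset(ds$features, ds$labels,
                         irrelevant = c(FALSE, FALSE, TRUE, TRUE))
  write_feature_table(ds2, path)
  expect_identical(read_feature_table(path)$irrelevant, ds2$irrelevant)
})

test_that("malformed feature tables are reported with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("sensor_1,sensor_2,label", path)
  expect_error(read_feature_table(path), "empty dataset")

  writeLines(c("sensor_1,sensor_2,label", "1.0,oops,1"), path)
  expect_error(read_feature_table(path), "row 1, column 'sensor_2'")

  writeLines(c("sensor_1,sensor_2", "1.0,2.0"), path)
  expect_error(read_feature_table(path), "label")

  expect_error(read_feature_table(file.path(tempdir(), "nope.csv")),
               "file not found")
})

test_that("dataset invariants are enforced at construction", {
  expect_error(labeled_dataset(matrix(1:4, 2), c(0, 1)), "positive integers")
  expect_error(labeled_dataset(matrix(1:4, 2), c(1.5, 2)), "positive integers")
  expect_error(labeled_dataset(matrix(1:4, 2), 1), "length")
  expect_error(labeled_dataset(matrix(numeric(0), 0, 2), integer(0)),
               "empty dataset")
})

test_that("stratified split reproduces the protocol test-set sizes", {
  ds <- make_gaussian_ds(matrix(seq(0, 16, by = 2), 9, 3), n = 20, seed = 7)
  sp30 <- stratified_split(ds, c(0.70, 0, 0.30), seed = 11)
  expect_length(sp30$test_idx, 54)
  expect_length(sp30$val_idx, 0)
  sp15 <- stratified_split(ds, c(0.70, 0.15, 0.15), seed = 11)
  expect_length(sp15$test_idx, 27)
  expect_length(sp15$val_idx, 27)
  expect_length(sp15$train_idx, 126)

  all_train <- stratified_split(ds, c(1, 0, 0), seed = 1)
  expect_length(all_train$train_idx, 180)
  expect_length(all_train$test_idx, 0)
})

test_that("a split is a per-class partition, deterministic per seed", {
  ds <- make_gaussian_ds(matrix(c(0, 3, 6), 3, 1), n = 11, seed = 2)
  sp <- stratified_split(ds, c(0.6, 0.2, 0.2), seed = 5)
  idx <- c(sp$train_idx, sp$val_idx, sp$test_idx)
  expect_setequal(idx, seq_len(33))
  expect_length(idx, 33)
  # per-class proportions: floor train, floor val, remainder to test
  for (m in 1:3) {
    expect_equal(sum(ds$labels[sp$train_idx] == m), 6)
    expect_equal(sum(ds$labels[sp$val_idx] == m), 2)
    expect_equal(sum(ds$labels[sp$test_idx] == m), 3)
  }
  expect_identical(stratified_split(ds, c(0.6, 0.2, 0.2), seed = 5), sp)
  sp2 <- stratified_split(ds, c(0.6, 0.2, 0.2), seed = 6)
  expect_false(identical(sp2$train_idx, sp$train_idx))
})

test_that("impossible split requests raise a sizing error", {
  ds <- make_gaussian_ds(matrix(c(0, 5), 2, 1), n = 2, seed = 3)
  expect_error(stratified_split(ds, c(0.5, 0.25, 0.25), seed = 1),
               "too small")
  expect_error(stratified_split(ds, c(0.5, 0.6, -0.1), seed = 1),
               "summing to 1")
})

test_that("split assignments serialize to JSON and back", {
  ds <- make_gaussian_ds(matrix(c(0, 4), 2, 1), n = 10, seed = 4)
  sp <- stratified_split(ds, c(0.7, 0, 0.3), seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  split_to_json(sp, path)
  back <- split_from_json(path)
  expect_identical(back$train_idx, sp$train_idx)
  expect_identical(back$test_idx, sp$test_idx)
  expect_equal(back$fractions, sp$fractions)
})
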