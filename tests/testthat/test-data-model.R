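test_that("grip labelling applies sex-specific thresholds strictly below", {
  tab <- data.frame(
    sex = c("male", "female", "male", "female", "M", "unknown"),
    grip_kg = c(27.9, 16.0, NA, 15.9, 28.0, 20),
    age = c(70, 71, 72, 73, 74, 75)
  )
  res <- label_by_grip(tab)
  # male 27.9 -> positive; female 16.0 is at the boundary -> negative;
  # missing grip and unmappable sex are dropped
  expect_equal(res$n_dropped, 2L)
  expect_equal(as.character(dataset_labels(res$dataset)),
               c("positive", "negative", "positive", "negative"))
  # grip column removed from features, sex retained
  expect_false("grip_kg" %in% feature_names(res$dataset))
  expect_true("sex" %in% feature_names(res$dataset))
})

test_that("grip labelling is idempotent in its effect and errors on missing columns", {
  tab <- make_grip_table(200, missing_fraction = 0.1, seed = 5)
  res <- label_by_grip(tab)
  expect_equal(res$n_dropped, sum(is.na(tab$grip_kg)))
  # re-deriving labels from the surviving raw records changes nothing
  kept <- tab[!is.na(tab$grip_kg), ]
  res2 <- label_by_grip(kept)
  expect_equal(res2$n_dropped, 0L)
  expect_identical(dataset_labels(res2$dataset), dataset_labels(res$dataset))
  expect_error(label_by_grip(tab, grip_col = "nope"), "grip column")
  expect_error(label_by_grip(tab, sex_col = "nope"), "sex column")
})

test_that("unreliable-feature removal uses the six-response and ID-likeness rules", {
  n <- 20
  df <- data.frame(
    five_resp = c(letters[1:5], rep(NA, n - 5)),     # 5 non-missing -> drop
    six_resp = c(rep("x", 6), rep(NA, n - 6)),       # 6 non-missing -> keep
    id_col = as.character(seq_len(n)),               # all distinct -> drop
    ok_nom = rep(c("a", "b"), n / 2),
    ok_num = seq_len(n) / 2
  )
  res <- drop_unreliable_features(survey_dataset(df))
  expect_equal(res$dropped_names, c("five_resp", "id_col"))
  expect_equal(feature_names(res$dataset), c("six_resp", "ok_nom", "ok_num"))
  # numeric columns are never ID-dropped even when all values are distinct
  expect_true("ok_num" %in% feature_names(res$dataset))
})

test_that("stratified split gives each class floor(fraction * n) training rows", {
  g <- small_synth(n = 200, p = 5, seed = 3)
  ds <- g$dataset
  for (seed in 1:10) {
    parts <- stratified_split(ds, train_fraction = 0.8, seed = seed)
    tr <- table(dataset_labels(parts$train))
    te <- table(dataset_labels(parts$test))
    full <- table(dataset_labels(ds))
    for (cl in names(full)) {
      expect_equal(unname(tr[cl]), floor(0.8 * full[[cl]]), ignore_attr = TRUE)
      expect_equal(unname(tr[cl] + te[cl]), full[[cl]], ignore_attr = TRUE)
    }
    expect_equal(n_instances(parts$train) + n_instances(parts$test),
                 n_instances(ds))
  }
  # exact small-count arithmetic: 5/5 at 0.8 -> train 4/4, test 1/1
  tiny <- survey_dataset(data.frame(x = rnorm(10)),
                         labels = factor(rep(c("positive", "negative"), 5)))
  parts <- stratified_split(tiny, 0.8, seed = 1)
  expect_equal(unname(table(dataset_labels(parts$train))), c(4L, 4L),
               ignore_attr = TRUE)
  expect_equal(unname(table(dataset_labels(parts$test))), c(1L, 1L),
               ignore_attr = TRUE)
})

test_that("stratified split is deterministic under a seed and independent of caller RNG", {
  ds <- small_synth(n = 120, p = 4, seed = 9)$dataset
  a <- stratified_split(ds, seed = 42)
  set.seed(999); runif(10)
  b <- stratified_split(ds, seed = 42)
  expect_identical(a$train$values, b$train$values)
  expect_identical(a$test$values, b$test$values)
})

test_that("stratified k-fold is a balanced partition", {
  # forced per-class balance at 10 = 5P + 5N, k = 5
  ten <- survey_dataset(data.frame(x = rnorm(10)),
                        labels = factor(rep(c("positive", "negative"), 5)))
  folds <- stratified_kfold(ten, k = 5, seed = 1)
  for (f in folds) {
    expect_equal(length(f$valid_idx), 2L)
    expect_equal(as.vector(table(dataset_labels(ten)[f$valid_idx])), c(1L, 1L))
  }
  # partition property over random configurations
  withr::with_seed(11, {
    for (trial in 1:25) {
      n_pos <- sample(10:40, 1)
      n_neg <- sample(10:40, 1)
      ds <- survey_dataset(
        data.frame(x = rnorm(n_pos + n_neg)),
        labels = factor(rep(c("positive", "negative"), c(n_pos, n_neg)),
                        levels = c("positive", "negative")))
      k <- sample(2:5, 1)
      folds <- stratified_kfold(ds, k = k, seed = trial)
      valid <- lapply(folds, `[[`, "valid_idx")
      expect_equal(sort(unlist(valid)), seq_len(n_pos + n_neg))
      expect_equal(sum(lengths(valid)), n_pos + n_neg)  # disjoint + covering
      per_class <- sapply(valid, function(v)
        table(dataset_labels(ds)[v]))
      expect_true(all(apply(per_class, 1, function(s) diff(range(s)) <= 1)))
    }
  })
  expect_error(stratified_kfold(ten, k = 6), "at least k")
})

test_that("per-class fold sizes at the survey scale spread the remainder", {
  ds <- survey_dataset(
    data.frame(x = numeric(2051 + 3139)),
    labels = factor(rep(c("positive", "negative"), c(2051, 3139)),
                    levels = c("positive", "negative")))
  folds <- stratified_kfold(ds, k = 5, seed = 2)
  sizes <- sapply(folds, function(f) table(dataset_labels(ds)[f$valid_idx]))
  expect_equal(sum(sizes["positive", ]), 2051)
  expect_true(all(sizes["positive", ] %in% c(410, 411)))
  expect_true(all(sizes["negative", ] %in% c(627, 628)))
  expect_equal(sum(sizes), 5190)
})

test_that("apply_mask keeps exactly the bit-1 features in order", {
  ds <- label_copy_ds(n = 20)
  all1 <- apply_mask(ds, rep(1, n_features(ds)))
  expect_identical(all1$values, ds$values)
  none <- apply_mask(ds, rep(0, n_features(ds)))
  expect_equal(n_features(none), 0L)
  expect_identical(dataset_labels(none), dataset_labels(ds))
  some <- apply_mask(ds, c(1, 0, 1, 0))
  expect_equal(feature_names(some), feature_names(ds)[c(1, 3)])
  expect_error(apply_mask(ds, c(1, 0)), "length")
})

test_that("dataset constructor validates kinds, labels and coercions", {
  expect_error(survey_dataset(data.frame(x = 1:3), labels = factor(1:2)),
               "length")
  ds <- survey_dataset(data.frame(x = c("1", "2", NA)), kinds = "numeric")
  expect_true(is.numeric(ds$values$x))
  expect_error(survey_dataset(data.frame(x = c("1", "b")), kinds = "numeric"),
               "non-numeric")
  rule <- diagnosis_rule()
  expect_equal(rule$male_threshold_kg, 28)
  expect_equal(rule$female_threshold_kg, 16)
  expect_error(diagnosis_rule(16, 28), "exceed")
})
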