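test_that("nominal likelihoods use add-one smoothing over training categories", {
  # class A sees {1, 1, 0} for the feature -> P(1|A) = (2+1)/(3+2) = 0.6
  ds <- survey_dataset(
    data.frame(f = c("1", "1", "0", "0", "0", "1")),
    labels = factor(c("A", "A", "A", "B", "B", "B"), levels = c("A", "B"))
  )
  model <- nb_fit(ds, 1L)
  f <- model$feats[[1]]
  cats <- model$cats[[1]]
  expect_equal(exp(f$logp[which(cats == "1"), 1]), 3 / 5)
  expect_equal(exp(f$logp[which(cats == "0"), 1]), 2 / 5)
  # class B sees {0, 0, 1} -> P(1|B) = (1+1)/5 = 0.4
  expect_equal(exp(f$logp[which(cats == "1"), 2]), 2 / 5)
  # priors are the class frequencies
  expect_equal(model$priors, c(0.5, 0.5))
})

test_that("posterior follows direct Bayes arithmetic on a single binary feature", {
  # equal priors, P(1|A) = 0.6, P(1|B) = 0.4, observe 1 -> posterior(A) = 0.6
  ds <- survey_dataset(
    data.frame(f = c("1", "1", "0", "0", "0", "1")),
    labels = factor(c("A", "A", "A", "B", "B", "B"), levels = c("A", "B"))
  )
  model <- nb_fit(ds, 1L)
  proba <- nb_predict_proba(model, data.frame(f = "1"))
  expect_equal(unname(proba[1, "A"]), 0.6, tolerance = 1e-12)
  proba0 <- nb_predict_proba(model, data.frame(f = "0"))
  expect_equal(unname(proba0[1, "A"]), 0.4, tolerance = 1e-12)
})

test_that("an all-missing instance falls back to the priors", {
  ds <- survey_dataset(
    data.frame(f = c("1", "1", "0", "1"), g = c(1.2, 0.8, -0.4, 2)),
    labels = factor(c("A", "A", "A", "B"), levels = c("A", "B"))
  )
  model <- nb_fit(ds)
  proba <- nb_predict_proba(model, data.frame(f = NA_character_, g = NA_real_))
  expect_equal(unname(proba[1, ]), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("the all-zeros mask yields the prior-only classifier", {
  ds <- label_copy_ds(n = 30)
  model <- nb_fit(ds, rep(0L, n_features(ds)))
  expect_length(model$feats, 0)
  res <- cv_fitness(ds, rep(0L, n_features(ds)), k = 5, seed = 1)
  # prior-only prediction picks the per-fold majority class
  expect_true(all(res$per_fold_accuracy >= 0.4 & res$per_fold_accuracy <= 0.6))
})

test_that("posteriors normalize to one across random mixed instances", {
  g <- small_synth(n = 100, p = 8, missing_rate = 0.2, seed = 4)
  ds <- g$dataset
  model <- nb_fit(ds)
  proba <- nb_predict_proba(model, ds)
  expect_true(all(abs(rowSums(proba) - 1) < 1e-9))
  expect_true(all(proba >= 0))
})

test_that("log-space posteriors match a direct-product hand computation", {
  ds <- survey_dataset(
    data.frame(f = c("a", "a", "b", "b", "a", "b"),
               x = c(1.0, 1.2, -0.5, -1.0, 0.8, -0.7)),
    labels = factor(c("A", "A", "A", "B", "B", "B"), levels = c("A", "B"))
  )
  model <- nb_fit(ds)
  inst <- data.frame(f = "a", x = 0.5)
  proba <- nb_predict_proba(model, inst)
  # independent oracle: direct products, no logs
  direct <- sapply(1:2, function(c) {
    f <- model$feats[[1]]
    pf <- exp(f$logp[match("a", model$cats[[1]]), c])
    g <- model$feats[[2]]
    pf * dnorm(0.5, g$mean[c], g$sd[c]) * model$priors[c]
  })
  expect_equal(unname(proba[1, ]), direct / sum(direct), tolerance = 1e-9)
})

test_that("numeric SDs are floored and single-class-missing features are skipped", {
  ds <- survey_dataset(
    data.frame(zerovar = c(1, 1, 1, 2), onlyA = c(0.3, 0.4, NA, NA)),
    labels = factor(c("A", "A", "B", "B"), levels = c("A", "B"))
  )
  model <- nb_fit(ds)
  expect_true(all(model$feats[[1]]$sd[model$feats[[1]]$present] > 0))
  # class B never observed `onlyA`: it contributes nothing for B
  expect_false(model$feats[[2]]$present[2])
  proba <- nb_predict_proba(model, data.frame(zerovar = NA_real_, onlyA = 0.35))
  expect_true(all(is.finite(proba)))
})

test_that("cv fitness equals an independently hand-rolled fold loop", {
  g <- small_synth(n = 20, p = 4, n_informative = 2, missing_rate = 0,
                   seed = 6)
  ds <- g$dataset
  mask <- rep(1L, 4)
  res <- cv_fitness(ds, mask, k = 5, seed = 3)
  # oracle: explicit loop over the same folds using the public fit/predict
  folds <- stratified_kfold(ds, k = 5, seed = 3)
  acc <- sapply(folds, function(f) {
    tr <- survey_dataset(ds$values[f$train_idx, , drop = FALSE],
                         kinds = unname(ds$kinds),
                         labels = dataset_labels(ds)[f$train_idx])
    model <- nb_fit(tr, mask)
    pred <- nb_predict(model, ds$values[f$valid_idx, , drop = FALSE])
    mean(as.character(pred) ==
           as.character(dataset_labels(ds)[f$valid_idx]))
  })
  expect_equal(res$per_fold_accuracy, acc, tolerance = 1e-12)
  expect_equal(res$fitness, mean(acc), tolerance = 1e-12)
  expect_equal(res$mask_popcount, 4)
})

test_that("cv fitness is a pure function of (ds, mask, k, seed)", {
  ds <- small_synth(n = 60, p = 6, seed = 8)$dataset
  mask <- c(1, 0, 1, 1, 0, 1)
  a <- cv_fitness(ds, mask, seed = 5)
  set.seed(77); rnorm(3)
  b <- cv_fitness(ds, mask, seed = 5)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, cv_fitness(ds, mask, seed = 6))))
})

test_that("a label-copy feature gives perfect CV fitness and never hurts a mask", {
  ds <- label_copy_ds(n = 50, n_noise = 4)
  perfect <- cv_fitness(ds, c(1, rep(0, 4)), seed = 1)
  expect_equal(perfect$fitness, 1.0)
  withr::with_seed(21, {
    for (trial in 1:20) {
      base <- c(0L, rbinom(4, 1, 0.5))
      with_copy <- base; with_copy[1] <- 1L
      expect_gte(cv_fitness(ds, with_copy, seed = trial)$fitness,
                 cv_fitness(ds, base, seed = trial)$fitness)
    }
  })
})

test_that("the wrapper agrees with an independent naive Bayes on Gaussian data", {
  # e1071 as cross-check on complete numeric columns, where both sides use
  # the same per-(feature, class) Gaussian likelihood and class priors
  withr::with_seed(13, {
    n <- 80
    lab <- factor(sample(c("A", "B"), n, TRUE, prob = c(0.6, 0.4)))
    df <- data.frame(u = rnorm(n, ifelse(lab == "A", 0.5, -0.5)),
                     v = rnorm(n, 0, 2))
    ds <- survey_dataset(df, labels = lab)
    ours <- nb_fit(ds)
    theirs <- e1071::naiveBayes(df, lab)
    p_ours <- nb_predict_proba(ours, df)
    p_theirs <- predict(theirs, df, type = "raw")
    expect_equal(unname(p_ours[, "A"]), unname(p_theirs[, "A"]),
                 tolerance = 1e-6)
  })
})

test_that("models serialize to JSON with priors, counts and moments", {
  ds <- small_synth(n = 40, p = 3, seed = 2)$dataset
  js <- jsonlite::fromJSON(nb_to_json(nb_fit(ds)), simplifyVector = FALSE)
  expect_equal(sum(unlist(js$priors)), 1, tolerance = 1e-12)
  expect_equal(length(js$features), 3)
  expect_error(nb_fit(survey_dataset(data.frame(x = numeric(0)),
                                     labels = factor(character(),
                                                     levels = c("A", "B")))),
               "empty")
})
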