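# Experiment harness: the exhaustive-search oracle, the evaluation-classifier
# registry, and the select -> evaluate runner that produces one result row
# per (method, budget, classifier) with replicate averaging.

#' Exhaustive feature-subset search (test oracle)
#'
#' Enumerates every one of the 2^p masks and scores each with the 5-fold CV
#' naive Bayes fitness under a fixed fold seed. Feasible only at small p; the
#' optimizers are benchmarked against its optimum. Ties break toward the
#' lower popcount, then the lexicographically smallest bitstring.
#'
#' @param ds labelled `survey_dataset` with at most `max_features` features
#' @param max_features refusal bound (default 20)
#' @param k,seed CV folds and fold seed for the fitness
#' @param evaluator optional function mask -> fitness replacing the default
#' @return list with `best_mask`, `best_fitness`, `n_evaluated`
#' @export
exhaustive_oracle <- function(ds, max_features = 20, k = 5, seed = 1L,
                              evaluator = NULL) {
  p <- n_features(ds)
  if (p > max_features) {
    stop_invalid("refusing exhaustive search over %d features (max %d): 2^%d masks",
                 p, max_features, p)
  }
  if (is.null(evaluator)) evaluator <- make_cv_evaluator(ds, k = k, seed = seed)
  best_mask <- NULL
  best_fit <- -Inf
  best_pop <- Inf
  best_key <- ""
  for (m in 0:(2^p - 1)) {
    bits <- as.integer(intToBits(m)[seq_len(p)])
    fit <- evaluator(bits)
    pop <- sum(bits)
    key <- paste(bits, collapse = "")
    better <- fit > best_fit ||
      (fit == best_fit && (pop < best_pop ||
                           (pop == best_pop && key < best_key)))
    if (better) {
      best_mask <- feature_mask(bits)
      best_fit <- fit
      best_pop <- pop
      best_key <- key
    }
  }
  list(best_mask = best_mask, best_fitness = best_fit, n_evaluated = 2^p)
}

# ---- evaluation-classifier registry ---------------------------------------

# Train-side mode/median completion used only inside adapters whose
# underlying learner rejects NA (random forest, SVM). The package's data
# model itself never imputes.
.roughfix_frames <- function(train_df, test_df) {
  for (nm in names(train_df)) {
    col <- train_df[[nm]]
    if (is.factor(col) || is.character(col)) {
      lv <- unique(as.character(col[!is.na(col)]))
      if (length(lv) == 0L) lv <- "none"
      mode_v <- names(sort(table(as.character(col)), decreasing = TRUE))[1L] %||% lv[1L]
      tr <- as.character(train_df[[nm]]); te <- as.character(test_df[[nm]])
      tr[is.na(tr)] <- mode_v
      te[is.na(te) | !(te %in% lv)] <- mode_v
      train_df[[nm]] <- factor(tr, levels = lv)
      test_df[[nm]] <- factor(te, levels = lv)
    } else {
      med <- stats::median(col, na.rm = TRUE)
      if (is.na(med)) med <- 0
      train_df[[nm]][is.na(train_df[[nm]])] <- med
      test_df[[nm]][is.na(test_df[[nm]])] <- med
    }
  }
  list(train = train_df, test = test_df)
}

.as_model_frame <- function(ds) {
  df <- ds$values
  df[] <- lapply(seq_along(df), function(j) {
    if (ds$kinds[[j]] == "nominal") as.character(df[[j]]) else df[[j]]
  })
  names(df) <- make.names(names(df), unique = TRUE)
  df
}

#' Evaluation-classifier registry
#'
#' Name-keyed adapters used to score selected feature sets on held-out data:
#' `"nb"` (this package's naive Bayes), `"tree"` (rpart decision tree,
#' missing values via surrogate splits), `"rf"` (ranger random forest) and
#' `"svm"` (e1071 SVM with probability estimates). The rf and svm adapters
#' complete missing cells with the training mode/median internally, since
#' those learners reject NA; this stays inside the adapter. Each adapter's
#' hyperparameters are its host package's defaults.
#'
#' @return named list of adapters; each has `fit(train, seed)` and
#'   `predict(model, test)` returning `class` (factor) and `score` (numeric
#'   positive-class score).
#' @export
classifier_registry <- function() {
  list(
    nb = list(
      fit = function(train, seed = 1L) nb_fit(train),
      predict = function(model, test) {
        proba <- nb_predict_proba(model, test)
        list(class = factor(model$class_levels[
               max.col(proba, ties.method = "first")],
               levels = model$class_levels),
             score = proba[, 1L])
      }
    ),
    tree = list(
      fit = function(train, seed = 1L) {
        df <- .as_model_frame(train)
        df[] <- lapply(df, function(c) if (is.character(c)) factor(c) else c)
        df$.label <- train$labels
        list(fit = rpart::rpart(.label ~ ., data = df, method = "class"),
             levels = levels(train$labels),
             train_df = df[setdiff(names(df), ".label")])
      },
      predict = function(model, test) {
        df <- .as_model_frame(test)
        for (nm in names(df)) {
          tr <- model$train_df[[nm]]
          if (is.factor(tr)) {
            v <- as.character(df[[nm]])
            v[!(v %in% levels(tr))] <- NA
            df[[nm]] <- factor(v, levels = levels(tr))
          }
        }
        proba <- stats::predict(model$fit, newdata = df, type = "prob")
        cls <- colnames(proba)[max.col(proba, ties.method = "first")]
        list(class = factor(cls, levels = model$levels),
             score = proba[, model$levels[1L]])
      }
    ),
    rf = list(
      fit = function(train, seed = 1L) {
        df <- .as_model_frame(train)
        fixed <- .roughfix_frames(df, df)
        df <- fixed$train
        df$.label <- train$labels
        list(fit = ranger::ranger(.label ~ ., data = df,
                                  probability = TRUE, seed = seed,
                                  num.threads = 1L),
             levels = levels(train$labels),
             train_df = fixed$train)
      },
      predict = function(model, test) {
        df <- .as_model_frame(test)
        fixed <- .roughfix_frames(model$train_df, df)
        proba <- stats::predict(model$fit, data = fixed$test)$predictions
        cls <- colnames(proba)[max.col(proba, ties.method = "first")]
        list(class = factor(cls, levels = model$levels),
             score = proba[, model$levels[1L]])
      }
    ),
    svm = list(
      fit = function(train, seed = 1L) {
        df <- .as_model_frame(train)
        fixed <- .roughfix_frames(df, df)
        df <- fixed$train
        df$.label <- train$labels
        fit <- with_local_seed(seed,
          e1071::svm(.label ~ ., data = df, probability = TRUE))
        list(fit = fit, levels = levels(train$labels),
             train_df = fixed$train)
      },
      predict = function(model, test) {
        df <- .as_model_frame(test)
        fixed <- .roughfix_frames(model$train_df, df)
        pred <- stats::predict(model$fit, newdata = fixed$test,
                               probability = TRUE)
        proba <- attr(pred, "probabilities")
        list(class = factor(as.character(pred), levels = model$levels),
             score = proba[, model$levels[1L]])
      }
    )
  )
}

# ---- selection dispatch ----------------------------------------------------

# Runs one selection method on the TRAINING partition only and times it.
# Returns list(mask, seconds, extra).
.select_features <- function(train, method, cfg, seed) {
  t0 <- proc.time()[["elapsed"]]
  out <- switch(method,
    none = list(mask = feature_mask(rep(1L, n_features(train)))),
    ga = {
      params <- ga_params(population_size = cfg$population_size %||% 30,
                          mutation_rate = cfg$mutation_rate %||% 0.01,
                          parent_selection_rate = cfg$parent_selection_rate %||% 0.5,
                          generations = cfg$generations %||% 100,
                          seed = seed)
      run <- ga_run(train, params,
                    schedule = if (isTRUE(cfg$dynamic)) cfg$schedule %||%
                      schedule_params() else NULL)
      list(mask = run$best_mask, run = run)
    },
    hs = {
      params <- hs_params(hms = cfg$hms %||% 30, hmcr = cfg$hmcr %||% 0.85,
                          par = cfg$par %||% 0.7,
                          iterations = cfg$iterations %||% 1000,
                          par_mode = cfg$par_mode %||% "per_harmony",
                          seed = seed)
      run <- hs_run(train, params,
                    schedule = if (isTRUE(cfg$dynamic)) cfg$schedule %||%
                      schedule_params() else NULL)
      list(mask = run$best_mask, run = run)
    },
    cfs = {
      res <- best_first_cfs(train, n_bins = cfg$n_bins %||% 10)
      list(mask = res$mask, merit = res$merit)
    },
    ig = {
      res <- ig_select(train, threshold = cfg$ig_threshold %||% 0.1,
                       n_bins = cfg$n_bins %||% 10)
      list(mask = res$mask, gains = res$gains)
    },
    stop_invalid("unknown selection method '%s'", method)
  )
  out$seconds <- proc.time()[["elapsed"]] - t0
  out
}

#' Experiment configuration
#'
#' @param method one of `"ga"`, `"hs"`, `"cfs"`, `"ig"`, `"none"` (`"none"`
#'   evaluates the full feature set).
#' @param classifiers names from [classifier_registry()] (default `"nb"`)
#' @param seeds one selection run per seed; metrics are averaged over seeds
#' @param ... method parameters: `generations`, `iterations`, `hmcr`, `par`,
#'   `par_mode`, `mutation_rate`, `population_size`, `hms`,
#'   `parent_selection_rate`, `dynamic`, `schedule`, `ig_threshold`,
#'   `n_bins`, plus `train_fraction` (default 0.8), `split_seed` (default 1),
#'   `label_col`, `sex_col`, `grip_col` for file inputs, and `out_dir`.
#' @export
run_config <- function(method = "none", classifiers = "nb", seeds = 1L, ...) {
  cfg <- c(list(method = method, classifiers = classifiers, seeds = seeds),
           list(...))
  if (method %in% c("ga", "hs") && length(seeds) < 1L) {
    stop_invalid("metaheuristics need at least one seed")
  }
  unknown <- setdiff(classifiers, names(classifier_registry()))
  if (length(unknown) > 0L) {
    stop_invalid("unknown classifier(s): %s", paste(unknown, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Run a select-then-evaluate experiment
#'
#' Splits the data (stratified, training fraction `cfg$train_fraction`),
#' runs the configured selection method on the training partition only —
#' the test partition is never passed to any selection routine — then trains
#' each configured classifier on the masked training set and scores the
#' masked test set with accuracy, support-weighted F1 and AUC. With several
#' seeds, each seed yields an independent selection run and the metrics are
#' averaged; `seconds` is the mean selection wall time. When `cfg$out_dir`
#' is set, results CSV, per-seed mask files and a parameter log are written.
#'
#' @param cfg a [run_config()]
#' @param ds a labelled `survey_dataset`; alternatively set `cfg$input` (path)
#'   to read with [read_table()], with optional `cfg$sex_col`/`cfg$grip_col`
#'   to derive labels via [label_by_grip()].
#' @return data.frame of result rows: method, budget, classifier, accuracy,
#'   weighted_f1, auc, n_selected, seconds (plus per-seed rows in the
#'   attribute `"per_seed"`).
#' @export
run_experiment <- function(cfg, ds = NULL) {
  if (is.null(ds)) {
    if (is.null(cfg$input)) stop_invalid("no dataset and no cfg$input path")
    ds <- read_table(cfg$input, format = cfg$format,
                     label_col = cfg$label_col %||% "label")
    if (is.null(ds$labels) && !is.null(cfg$grip_col)) {
      raw <- ds$values
      lab <- label_by_grip(raw, sex_col = cfg$sex_col %||% "sex",
                           grip_col = cfg$grip_col)
      ds <- lab$dataset
    }
  }
  if (is.null(ds$labels)) stop_invalid("dataset has no labels")
  if (isTRUE(cfg$preprocess)) ds <- drop_unreliable_features(ds)$dataset
  parts <- stratified_split(ds, train_fraction = cfg$train_fraction %||% 0.8,
                            seed = cfg$split_seed %||% 1L)
  train <- parts$train
  test <- parts$test
  registry <- classifier_registry()
  budget <- switch(cfg$method, ga = cfg$generations %||% 100,
                   hs = cfg$iterations %||% 1000, NA_integer_)
  per_seed <- list()
  masks <- list()
  for (seed in cfg$seeds) {
    sel <- .select_features(train, cfg$method, cfg, seed)
    masks[[as.character(seed)]] <- sel$mask
    tr_m <- apply_mask(train, sel$mask)
    te_m <- apply_mask(test, sel$mask)
    for (clf in cfg$classifiers) {
      adapter <- registry[[clf]]
      model <- adapter$fit(tr_m, seed = seed)
      pred <- adapter$predict(model, te_m)
      per_seed[[length(per_seed) + 1L]] <- data.frame(
        method = cfg$method, budget = budget, classifier = clf, seed = seed,
        accuracy = accuracy(test$labels, pred$class),
        weighted_f1 = weighted_f1(test$labels, pred$class),
        auc = auc_score(test$labels, pred$score,
                        positive = levels(test$labels)[1L]),
        n_selected = sum(sel$mask),
        seconds = sel$seconds,
        stringsAsFactors = FALSE)
    }
  }
  per_seed <- do.call(rbind, per_seed)
  agg <- stats::aggregate(
    per_seed[c("accuracy", "weighted_f1", "auc", "n_selected", "seconds")],
    by = per_seed[c("method", "classifier")],
    FUN = mean)
  agg <- cbind(agg[1L], budget = budget, agg[-1L])
  attr(agg, "per_seed") <- per_seed
  attr(agg, "masks") <- masks
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(agg, file.path(cfg$out_dir, "results.csv"),
                     row.names = FALSE)
    for (seed in names(masks)) {
      write_mask(file.path(cfg$out_dir, sprintf("mask_%s_seed%s.txt",
                                                cfg$method, seed)),
                 masks[[seed]], feature_names(train))
    }
    log_cfg <- cfg
    log_cfg$schedule <- if (isTRUE(cfg$dynamic)) {
      unclass(cfg$schedule %||% schedule_params())
    } else NULL
    writeLines(jsonlite::toJSON(
      c(unclass(log_cfg),
        list(train_fraction = cfg$train_fraction %||% 0.8,
             split_seed = cfg$split_seed %||% 1L,
             n_train = n_instances(train), n_test = n_instances(test))),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE),
      file.path(cfg$out_dir, "run_log.json"))
  }
  agg
}
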