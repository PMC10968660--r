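# Naive Bayes wrapper classifier and the cross-validated fitness function.
#
# The classifier tolerates mixed nominal/numeric features and missing cells:
# a missing cell is skipped in both fitting and prediction (no imputation).
# Nominal likelihoods use Laplace add-one smoothing over the category set
# observed in training; numeric likelihoods are a single Gaussian per
# (feature, class) with a floored standard deviation.

# std floor: 1e-6 of the feature's global (training) range, at least 1e-9
.SD_FLOOR_REL <- 1e-6
.SD_FLOOR_ABS <- 1e-9

# Integer-encode a dataset once so repeated fold fits are cheap.
# nominal columns -> integer codes over the categories observed anywhere in
# `ds` (per-fit category universes are recomputed from training rows).
encode_dataset <- function(ds) {
  p <- n_features(ds)
  cols <- vector("list", p)
  cats <- vector("list", p)
  for (j in seq_len(p)) {
    if (ds$kinds[[j]] == "nominal") {
      u <- unique(ds$values[[j]])
      u <- u[!is.na(u)]
      cats[[j]] <- u
      cols[[j]] <- match(ds$values[[j]], u)
    } else {
      cols[[j]] <- as.numeric(ds$values[[j]])
    }
  }
  y <- if (is.null(ds$labels)) NULL else as.integer(ds$labels)
  list(cols = cols, cats = cats, kinds = unname(ds$kinds),
       names = feature_names(ds), y = y,
       class_levels = if (is.null(ds$labels)) NULL else levels(ds$labels),
       n = n_instances(ds))
}

# Fit on encoded data restricted to rows `idx` and features `sel`
# (integer indices of selected features).
.nb_fit_enc <- function(enc, idx, sel) {
  y <- enc$y[idx]
  C <- length(enc$class_levels)
  n_c <- tabulate(y, nbins = C)
  if (sum(n_c) == 0L) stop_invalid("empty training set")
  priors <- n_c / sum(n_c)
  feats <- vector("list", length(sel))
  for (s in seq_along(sel)) {
    j <- sel[[s]]
    x <- enc$cols[[j]][idx]
    if (enc$kinds[[j]] == "nominal") {
      ok <- !is.na(x)
      xo <- x[ok]; yo <- y[ok]
      Kfull <- length(enc$cats[[j]])
      cnt <- matrix(tabulate(xo + Kfull * (yo - 1L), nbins = Kfull * C),
                    nrow = Kfull, ncol = C)
      observed <- rowSums(cnt) > 0L
      K <- sum(observed)
      njc <- colSums(cnt)                      # non-missing count per class
      logp <- matrix(0, nrow = Kfull, ncol = C)
      unseen <- numeric(C)
      for (c in seq_len(C)) {
        if (njc[c] == 0L || K == 0L) next     # (feature, class) contributes nothing
        logp[, c] <- log(cnt[, c] + 1) - log(njc[c] + K)
        logp[!observed, c] <- log(1) - log(njc[c] + K)
        unseen[c] <- -log(njc[c] + K)
      }
      feats[[s]] <- list(kind = "nominal", j = j, logp = logp,
                         observed = observed, unseen_logp = unseen,
                         present = njc > 0L, counts = cnt)
    } else {
      ok <- !is.na(x)
      rng <- if (any(ok)) diff(range(x[ok])) else 0
      floor_sd <- max(.SD_FLOOR_REL * rng, .SD_FLOOR_ABS)
      mu <- rep(NA_real_, C); sdv <- rep(NA_real_, C)
      present <- logical(C)
      for (c in seq_len(C)) {
        xc <- x[ok & y == c]
        if (length(xc) == 0L) next
        present[c] <- TRUE
        mu[c] <- mean(xc)
        s2 <- if (length(xc) > 1L) stats::sd(xc) else 0
        sdv[c] <- max(s2, floor_sd, na.rm = TRUE)
      }
      feats[[s]] <- list(kind = "numeric", j = j, mean = mu, sd = sdv,
                         present = present)
    }
  }
  structure(list(class_levels = enc$class_levels, priors = priors,
                 feature_names = enc$names[sel], sel = sel, feats = feats,
                 cats = enc$cats[sel]),
            class = "nb_model")
}

# Log-posterior matrix (rows = instances in `idx`, cols = classes), already
# normalized to probabilities.
.nb_predict_enc <- function(model, enc, idx) {
  C <- length(model$class_levels)
  n <- length(idx)
  scores <- matrix(rep(log(pmax(model$priors, .Machine$double.xmin)),
                       each = n), nrow = n, ncol = C)
  for (f in model$feats) {
    x <- enc$cols[[f$j]][idx]
    ok <- which(!is.na(x))
    if (length(ok) == 0L) next
    if (f$kind == "nominal") {
      scores[ok, ] <- scores[ok, , drop = FALSE] + f$logp[x[ok], , drop = FALSE]
    } else {
      for (c in seq_len(C)) {
        if (!f$present[c]) next
        scores[ok, c] <- scores[ok, c] +
          stats::dnorm(x[ok], f$mean[c], f$sd[c], log = TRUE)
      }
    }
  }
  # normalize in log space
  m <- apply(scores, 1L, max)
  w <- exp(scores - m)
  w / rowSums(w)
}

#' Fit the naive Bayes wrapper classifier
#'
#' Class priors are the training class frequencies. Nominal likelihoods use
#' Laplace add-one smoothing over the category set observed in training for
#' that feature; numeric likelihoods are Gaussian with per-(feature, class)
#' mean and standard deviation, the latter floored at `1e-6` of the feature's
#' training range (absolute minimum `1e-9`). Missing cells are excluded from
#' all counts and moments.
#'
#' @param train labelled `survey_dataset`
#' @param mask 0/1 vector of length `n_features(train)`; the all-zeros mask is
#'   legal and yields the prior-only classifier.
#' @return an `nb_model`
#' @export
nb_fit <- function(train, mask = rep(1L, n_features(train))) {
  if (is.null(train$labels)) stop_invalid("training data has no labels")
  if (n_instances(train) == 0L) stop_invalid("empty training set")
  mask <- as.integer(mask)
  if (length(mask) != n_features(train)) {
    stop_invalid("mask length (%d) != feature count (%d)",
                 length(mask), n_features(train))
  }
  enc <- encode_dataset(train)
  model <- .nb_fit_enc(enc, seq_len(enc$n), which(mask == 1L))
  model$kinds <- enc$kinds[model$sel]
  model
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> classes: %s; %d features\n",
              paste(x$class_levels, collapse = "/"), length(x$feats)))
  invisible(x)
}

#' Posterior class probabilities
#'
#' Computed in log space as prior times the product of class-conditional
#' likelihoods over the non-missing masked features, normalized to sum to 1.
#' An instance with every feature missing falls back to the priors; a nominal
#' category unseen in training contributes the smoothed floor
#' `1/(n_class + n_categories)`.
#'
#' @param model an `nb_model`
#' @param newdata `survey_dataset` or data.frame whose columns are exactly the
#'   model's selected features (same names, same order).
#' @return numeric matrix, rows = instances, columns = classes (declaration
#'   order), each row summing to 1.
#' @export
nb_predict_proba <- function(model, newdata) {
  df <- if (inherits(newdata, "survey_dataset")) newdata$values else
    as.data.frame(newdata, stringsAsFactors = FALSE)
  if (ncol(df) != length(model$feats)) {
    stop_invalid("newdata has %d columns; model expects %d",
                 ncol(df), length(model$feats))
  }
  n <- nrow(df)
  C <- length(model$class_levels)
  scores <- matrix(rep(log(pmax(model$priors, .Machine$double.xmin)),
                       each = n), nrow = n, ncol = C)
  for (s in seq_along(model$feats)) {
    f <- model$feats[[s]]
    if (f$kind == "nominal") {
      code <- match(as.character(df[[s]]), model$cats[[s]])
      known <- !is.na(code)
      if (any(known)) {
        scores[known, ] <- scores[known, , drop = FALSE] +
          f$logp[code[known], , drop = FALSE]
      }
      # token absent from the training category set but cell not missing
      novel <- is.na(code) & !is.na(df[[s]])
      if (any(novel)) {
        scores[novel, ] <- scores[novel, , drop = FALSE] +
          matrix(f$unseen_logp, nrow = sum(novel), ncol = C, byrow = TRUE)
      }
    } else {
      x <- as.numeric(df[[s]])
      ok <- which(!is.na(x))
      for (c in seq_len(C)) {
        if (!f$present[c]) next
        scores[ok, c] <- scores[ok, c] +
          stats::dnorm(x[ok], f$mean[c], f$sd[c], log = TRUE)
      }
    }
  }
  m <- apply(scores, 1L, max)
  w <- exp(scores - m)
  out <- w / rowSums(w)
  colnames(out) <- model$class_levels
  out
}

#' Predicted classes (argmax posterior, ties to the first declared class)
#' @param model an `nb_model`
#' @param newdata as in [nb_predict_proba()]
#' @export
nb_predict <- function(model, newdata) {
  proba <- nb_predict_proba(model, newdata)
  factor(model$class_levels[max.col(proba, ties.method = "first")],
         levels = model$class_levels)
}

#' Serialize a fitted model to JSON
#'
#' Priors, nominal category counts, and Gaussian moments, for inspection.
#' @param model an `nb_model`
#' @return a JSON string
#' @export
nb_to_json <- function(model) {
  feats <- lapply(seq_along(model$feats), function(s) {
    f <- model$feats[[s]]
    if (f$kind == "nominal") {
      list(name = model$feature_names[[s]], kind = "nominal",
           categories = model$cats[[s]],
           counts = f$counts)
    } else {
      list(name = model$feature_names[[s]], kind = "numeric",
           mean = f$mean, sd = f$sd)
    }
  })
  jsonlite::toJSON(list(classes = model$class_levels,
                        priors = model$priors, features = feats),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' Cross-validated wrapper fitness of a feature mask
#'
#' Stratified k-fold cross-validation: for each fold, the naive Bayes model is
#' fitted on the other k-1 folds and predicts the held-out fold by argmax
#' posterior (ties to the first declared class). Fitness is the mean held-out
#' accuracy. A pure function of `(ds, mask, k, seed)`.
#'
#' @param ds labelled `survey_dataset`
#' @param mask 0/1 vector over features
#' @param k folds (default 5)
#' @param seed integer controlling fold membership
#' @return list of class `fitness_result`: `fitness`, `per_fold_accuracy`,
#'   `mask_popcount`.
#' @export
cv_fitness <- function(ds, mask, k = 5, seed = 1L) {
  enc <- encode_dataset(ds)
  folds <- stratified_kfold(ds, k = k, seed = seed)
  .cv_fitness_enc(enc, folds, as.integer(mask))
}

.cv_fitness_enc <- function(enc, folds, mask) {
  sel <- which(mask == 1L)
  acc <- vapply(folds, function(fold) {
    model <- .nb_fit_enc(enc, fold$train_idx, sel)
    proba <- .nb_predict_enc(model, enc, fold$valid_idx)
    pred <- max.col(proba, ties.method = "first")
    mean(pred == enc$y[fold$valid_idx])
  }, numeric(1))
  structure(list(fitness = mean(acc), per_fold_accuracy = acc,
                 mask_popcount = sum(mask)),
            class = "fitness_result")
}

#' Build a cached mask-fitness evaluator
#'
#' Encodes the dataset and fixes the fold partition once, then returns a
#' function `mask -> fitness` (a bare number). Results are memoised by mask
#' bit-string, which is safe because [cv_fitness()] is a pure function of its
#' arguments; both metaheuristics revisit masks often, so caching matches the
#' evaluation cost a user would observe.
#'
#' @inheritParams cv_fitness
#' @param cache memoise by mask key (default TRUE)
#' @return function taking a 0/1 mask and returning mean CV accuracy; it
#'   carries attributes `n_evaluations` (total calls) and `n_distinct`
#'   (cache misses), query with [evaluator_stats()].
#' @export
make_cv_evaluator <- function(ds, k = 5, seed = 1L, cache = TRUE) {
  enc <- encode_dataset(ds)
  folds <- stratified_kfold(ds, k = k, seed = seed)
  store <- new.env(parent = emptyenv())
  n_calls <- 0L
  n_miss <- 0L
  f <- function(mask) {
    mask <- as.integer(mask)
    n_calls <<- n_calls + 1L
    if (cache) {
      key <- paste(mask, collapse = "")
      hit <- store[[key]]
      if (!is.null(hit)) return(hit)
    }
    n_miss <<- n_miss + 1L
    val <- .cv_fitness_enc(enc, folds, mask)$fitness
    if (cache) store[[key]] <- val
    val
  }
  attr(f, "stats") <- function() list(n_evaluations = n_calls,
                                      n_distinct = n_miss)
  f
}

#' @rdname make_cv_evaluator
#' @param evaluator a function returned by [make_cv_evaluator()]
#' @export
evaluator_stats <- function(evaluator) attr(evaluator, "stats")()
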