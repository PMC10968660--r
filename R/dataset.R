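#' Mixed-type survey dataset
#'
#' The central tabular container: instances by features, where every feature is
#' either `nominal` (category tokens stored as character) or `numeric`, any
#' cell may be missing (`NA`), and an optional binary label is carried
#' alongside the feature grid. Missingness is a first-class cell state; no
#' function in the package imputes.
#'
#' @param values data.frame of feature columns. Character and factor columns
#'   become nominal features; numeric columns become numeric features.
#' @param kinds optional character vector, one of `"nominal"` or `"numeric"`
#'   per column, overriding the inferred kind. A numeric column declared
#'   nominal is stored as its character tokens.
#' @param labels optional factor (or vector coercible to factor) of length
#'   `nrow(values)` with exactly two levels. The level order is the class
#'   declaration order used for prediction tie-breaks.
#'
#' @return An object of class `survey_dataset`: a list with elements `values`
#'   (data.frame), `kinds` (named character vector), and `labels` (factor or
#'   `NULL`).
#' @export
#' @examples
#' ds <- survey_dataset(
#'   data.frame(age = c(61, 72, NA), smokes = c("no", "yes", "no")),
#'   labels = factor(c("positive", "negative", "negative"))
#' )
#' n_features(ds)
survey_dataset <- function(values, kinds = NULL, labels = NULL) {
  if (!is.data.frame(values)) stop_invalid("`values` must be a data.frame")
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  p <- ncol(values)
  inferred <- vapply(values, function(col) {
    if (is.numeric(col)) "numeric" else "nominal"
  }, character(1))
  if (is.null(kinds)) {
    kinds <- inferred
  } else {
    if (length(kinds) != p) stop_invalid("`kinds` must have one entry per feature")
    if (!all(kinds %in% c("nominal", "numeric"))) {
      stop_invalid("`kinds` entries must be 'nominal' or 'numeric'")
    }
  }
  for (j in seq_len(p)) {
    col <- values[[j]]
    if (kinds[[j]] == "nominal") {
      values[[j]] <- as.character(col)
    } else {
      if (!is.numeric(col)) {
        coerced <- suppressWarnings(as.numeric(as.character(col)))
        bad <- !is.na(col) & is.na(coerced)
        if (any(bad)) {
          stop_invalid("column %d declared numeric but has non-numeric tokens",
                       j)
        }
        values[[j]] <- coerced
      }
    }
  }
  names(kinds) <- names(values)
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != nrow(values)) {
      stop_invalid("`labels` length (%d) != instance count (%d)",
                   length(labels), nrow(values))
    }
    if (nlevels(labels) > 2L) {
      stop_invalid("labels must be binary; got %d levels", nlevels(labels))
    }
  }
  structure(list(values = values, kinds = kinds, labels = labels),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %d instances x %d features (%d nominal, %d numeric)\n",
              n_instances(x), n_features(x),
              sum(x$kinds == "nominal"), sum(x$kinds == "numeric")))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat("labels: <none>\n")
  }
  invisible(x)
}

#' @rdname survey_dataset
#' @param ds a `survey_dataset`
#' @export
n_instances <- function(ds) nrow(ds$values)

#' @rdname survey_dataset
#' @export
n_features <- function(ds) ncol(ds$values)

#' @rdname survey_dataset
#' @export
feature_names <- function(ds) names(ds$values)

#' @rdname survey_dataset
#' @export
dataset_labels <- function(ds) ds$labels

#' Binary feature-inclusion mask
#'
#' The solution encoding shared by both metaheuristics: bit `j` is 1 when
#' feature `j` is selected. Stored as a plain integer vector of 0/1.
#'
#' @param bits vector of 0/1 (logical accepted).
#' @return integer vector of class `feature_mask`.
#' @export
feature_mask <- function(bits) {
  bits <- as.integer(bits)
  if (any(is.na(bits)) || !all(bits %in% c(0L, 1L))) {
    stop_invalid("mask bits must all be 0 or 1")
  }
  structure(bits, class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> length %d, %d selected\n", length(x), sum(x)))
  invisible(x)
}

#' Restrict a dataset to the features a mask selects
#'
#' @param ds a `survey_dataset`
#' @param mask 0/1 vector of length `n_features(ds)`
#' @return `survey_dataset` with exactly the bit-1 features, original order,
#'   labels untouched. The all-zeros mask is legal and yields a 0-feature
#'   dataset (the prior-only classifier downstream).
#' @export
apply_mask <- function(ds, mask) {
  mask <- as.integer(mask)
  if (length(mask) != n_features(ds)) {
    stop_invalid("mask length (%d) != feature count (%d)",
                 length(mask), n_features(ds))
  }
  keep <- which(mask == 1L)
  survey_dataset(ds$values[, keep, drop = FALSE],
                 kinds = unname(ds$kinds[keep]),
                 labels = ds$labels)
}

#' Handgrip-strength diagnosis rule
#'
#' Sex-specific cut-offs for low muscle strength: a person is labelled
#' positive when measured handgrip strength is strictly below 28 kg (men) or
#' 16 kg (women). A grip exactly at the threshold is negative.
#'
#' @param male_threshold_kg,female_threshold_kg cut-offs in kilograms.
#' @export
diagnosis_rule <- function(male_threshold_kg = 28, female_threshold_kg = 16) {
  if (male_threshold_kg <= 0 || female_threshold_kg <= 0) {
    stop_invalid("thresholds must be positive")
  }
  if (male_threshold_kg <= female_threshold_kg) {
    stop_invalid("male threshold must exceed female threshold")
  }
  structure(list(male_threshold_kg = male_threshold_kg,
                 female_threshold_kg = female_threshold_kg,
                 comparison = "strictly-below"),
            class = "diagnosis_rule")
}

# token -> "male"/"female"/NA
.map_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m", "man", "men", "1")] <- "male"
  out[x %in% c("female", "f", "woman", "women", "2")] <- "female"
  out
}

#' Derive binary labels from sex and handgrip strength
#'
#' Applies the sex-specific grip threshold to a raw table: each record with a
#' non-missing grip value is labelled `positive` when grip is strictly below
#' its sex threshold, `negative` otherwise. Records with missing grip or an
#' unmappable sex token are dropped and counted. The grip column (and any
#' columns named in `drop_cols`) is removed from the output features, since
#' columns that determine the diagnosis must not be available for selection.
#'
#' @param records data.frame containing at least the sex and grip columns.
#' @param rule a [diagnosis_rule()].
#' @param sex_col,grip_col column names; accepted sex tokens are
#'   male/m/man/1 and female/f/woman/2 (case-insensitive).
#' @param drop_cols additional diagnosis-determining columns to remove.
#' @return list with `dataset` (a labelled `survey_dataset`, levels
#'   `c("positive","negative")`) and `n_dropped`.
#' @export
label_by_grip <- function(records, rule = diagnosis_rule(),
                          sex_col = "sex", grip_col = "grip_kg",
                          drop_cols = character()) {
  if (!sex_col %in% names(records)) {
    stop_invalid("sex column '%s' not found in input", sex_col)
  }
  if (!grip_col %in% names(records)) {
    stop_invalid("grip column '%s' not found in input", grip_col)
  }
  sex <- .map_sex(records[[sex_col]])
  grip <- suppressWarnings(as.numeric(records[[grip_col]]))
  keep <- !is.na(sex) & !is.na(grip)
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  sex <- sex[keep]
  grip <- grip[keep]
  thr <- ifelse(sex == "male", rule$male_threshold_kg, rule$female_threshold_kg)
  labels <- factor(ifelse(grip < thr, "positive", "negative"),
                   levels = c("positive", "negative"))
  drop <- unique(c(grip_col, drop_cols))
  feats <- records[, setdiff(names(records), drop), drop = FALSE]
  list(dataset = survey_dataset(feats, labels = labels), n_dropped = n_dropped)
}

#' Remove unreliable features
#'
#' Drops (left to right) features with `min_responses - 1` or fewer
#' non-missing cells, and ID-like nominal columns whose non-missing tokens are
#' (almost) all distinct: at least `id_distinct_frac` of the non-missing cells
#' hold unique values.
#'
#' @param ds a `survey_dataset`
#' @param min_responses smallest non-missing count a feature must reach to be
#'   kept (default 6, i.e. "five or fewer responses" are excluded).
#' @param id_distinct_frac distinct-token fraction above which a nominal
#'   column is treated as an identifier.
#' @return list with `dataset` and `dropped_names` (in removal order).
#' @export
drop_unreliable_features <- function(ds, min_responses = 6,
                                     id_distinct_frac = 0.99) {
  dropped <- character()
  for (j in seq_len(n_features(ds))) {
    col <- ds$values[[j]]
    nm <- names(ds$values)[j]
    nn <- sum(!is.na(col))
    if (nn < min_responses) {
      dropped <- c(dropped, nm)
      next
    }
    if (ds$kinds[[j]] == "nominal") {
      nd <- length(unique(col[!is.na(col)]))
      if (nd >= id_distinct_frac * nn) dropped <- c(dropped, nm)
    }
  }
  keep <- setdiff(names(ds$values), dropped)
  out <- survey_dataset(ds$values[, keep, drop = FALSE],
                        kinds = unname(ds$kinds[keep]),
                        labels = ds$labels)
  list(dataset = out, dropped_names = dropped)
}

#' Stratified train/test split
#'
#' Per class, `floor(train_fraction * n_class)` instances go to the training
#' partition (chosen uniformly at random under `seed`); the remainder to the
#' test partition. With the default 0.8 fraction this reproduces an even
#' label distribution across both partitions exactly.
#'
#' @param ds labelled `survey_dataset`
#' @param train_fraction in (0, 1)
#' @param seed integer; the split is a pure function of `(ds, fraction, seed)`.
#' @return list with `train` and `test` `survey_dataset`s.
#' @export
stratified_split <- function(ds, train_fraction = 0.8, seed = 1L) {
  if (is.null(ds$labels)) stop_invalid("dataset has no labels")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("train_fraction must be in (0, 1)")
  }
  tab <- table(ds$labels)
  if (any(tab == 0)) stop_invalid("every class needs at least one instance")
  train_idx <- integer()
  with_local_seed(seed, {
    for (cl in levels(ds$labels)) {
      idx <- which(ds$labels == cl)
      n_train <- floor(train_fraction * length(idx))
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_instances(ds)), train_idx)
  subset_ds <- function(idx) {
    survey_dataset(ds$values[idx, , drop = FALSE],
                   kinds = unname(ds$kinds),
                   labels = ds$labels[idx])
  }
  list(train = subset_ds(train_idx), test = subset_ds(test_idx))
}

#' Stratified k-fold partition
#'
#' Splits instances into `k` validation folds with a balanced label ratio:
#' per class, fold sizes differ by at most one. Each instance is validated
#' exactly once.
#'
#' @param ds labelled `survey_dataset`
#' @param k number of folds (default 5)
#' @param seed integer
#' @return list of `k` lists, each with `train_idx` and `valid_idx`.
#' @export
stratified_kfold <- function(ds, k = 5, seed = 1L) {
  if (is.null(ds$labels)) stop_invalid("dataset has no labels")
  tab <- table(ds$labels)
  if (any(tab < k)) {
    stop_invalid("every class needs at least k = %d instances (smallest has %d)",
                 k, min(tab))
  }
  fold_of <- integer(n_instances(ds))
  with_local_seed(seed, {
    for (cl in levels(ds$labels)) {
      idx <- sample(which(ds$labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train_idx = which(fold_of != f), valid_idx = which(fold_of == f))
  })
}
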