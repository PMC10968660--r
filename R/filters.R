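# Filter-method baselines: information-gain thresholding and
# correlation-based feature subset selection (CFS) with forward best-first
# search. Both work on discrete columns; numeric features are discretized by
# equal-frequency binning first. Missing values are excluded pairwise from
# all contingency counts.

#' Shannon entropy of a discrete column (bits)
#'
#' Computed over non-missing cells, log base 2.
#' @param x vector of tokens (any type); `NA` cells are ignored
#' @export
shannon_entropy <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop_invalid("entropy undefined on an all-missing column")
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# joint entropy over pairwise-complete cells
.joint_entropy <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  shannon_entropy(paste(x[ok], y[ok], sep = "\r"))
}

#' Information gain of a feature about the labels (bits)
#'
#' `H(labels) - H(labels | feature)`, computed over pairwise-complete rows.
#' @param feature discrete vector
#' @param labels discrete vector, same length
#' @export
info_gain <- function(feature, labels) {
  ok <- !is.na(feature) & !is.na(labels)
  if (sum(ok) == 0L) stop_invalid("no pairwise-complete rows")
  x <- feature[ok]; y <- labels[ok]
  hy <- shannon_entropy(y)
  # H(y | x) = sum_v p(v) H(y | x = v)
  hyx <- 0
  for (v in unique(x)) {
    sel <- x == v
    hyx <- hyx + mean(sel) * shannon_entropy(y[sel])
  }
  max(0, hy - hyx)
}

#' Equal-frequency discretization
#'
#' Cuts a numeric vector at its empirical quantiles into at most `n_bins`
#' bins (duplicate quantiles are merged). Missing cells stay missing; a
#' non-numeric column is returned unchanged.
#'
#' @param x numeric vector
#' @param n_bins number of bins (default 10)
#' @return character vector of bin tokens with `NA` preserved
#' @export
discretize_ef <- function(x, n_bins = 10) {
  if (n_bins < 2) stop_invalid("n_bins must be >= 2")
  if (!is.numeric(x)) return(as.character(x))
  ok <- !is.na(x)
  if (!any(ok)) return(rep(NA_character_, length(x)))
  br <- unique(stats::quantile(x[ok], probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) {                 # constant column
    out <- rep(NA_character_, length(x))
    out[ok] <- "bin1"
    return(out)
  }
  as.character(cut(x, breaks = br, include.lowest = TRUE,
                   labels = paste0("bin", seq_len(length(br) - 1L))))
}

# discretized view of every feature column
.discretized_columns <- function(ds, n_bins = 10) {
  lapply(seq_len(n_features(ds)), function(j) {
    if (ds$kinds[[j]] == "numeric") discretize_ef(ds$values[[j]], n_bins)
    else as.character(ds$values[[j]])
  })
}

#' Information-gain feature selection
#'
#' Discretizes numeric features, scores each feature's information gain about
#' the labels, and selects every feature with gain at or above `threshold`
#' (the threshold is inclusive).
#'
#' @param ds labelled `survey_dataset`
#' @param threshold minimum gain in bits (default 0.1)
#' @param n_bins equal-frequency bins for numeric features
#' @return list with `mask` (`feature_mask`) and `gains` (named numeric)
#' @export
ig_select <- function(ds, threshold = 0.1, n_bins = 10) {
  if (is.null(ds$labels)) stop_invalid("dataset has no labels")
  cols <- .discretized_columns(ds, n_bins)
  y <- as.character(ds$labels)
  gains <- vapply(cols, function(x) info_gain(x, y), numeric(1))
  names(gains) <- feature_names(ds)
  list(mask = feature_mask(as.integer(gains >= threshold)), gains = gains)
}

#' Symmetrical uncertainty between two discrete columns
#'
#' `2 * (H(x) + H(y) - H(x, y)) / (H(x) + H(y))`, over pairwise-complete
#' cells; defined as 0 when both entropies are 0. Symmetric and in \[0, 1\].
#' @param x,y discrete vectors, same length
#' @export
symmetrical_uncertainty <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) == 0L) stop_invalid("no pairwise-complete rows")
  hx <- shannon_entropy(x[ok])
  hy <- shannon_entropy(y[ok])
  if (hx + hy == 0) return(0)
  hxy <- shannon_entropy(paste(x[ok], y[ok], sep = "\r"))
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  min(1, max(0, su))
}

#' Symmetrical-uncertainty cache for CFS
#'
#' Eagerly computes each feature's SU with the class and lazily fills the
#' pairwise feature-feature SU matrix as the search requests entries.
#'
#' @param ds labelled `survey_dataset`
#' @param n_bins equal-frequency bins for numeric features
#' @return object of class `correlation_cache` with `$su_cf(j)` and
#'   `$su_ff(i, j)` accessors
#' @export
correlation_cache <- function(ds, n_bins = 10) {
  if (is.null(ds$labels)) stop_invalid("dataset has no labels")
  cols <- .discretized_columns(ds, n_bins)
  y <- as.character(ds$labels)
  su_cf <- vapply(cols, function(x) symmetrical_uncertainty(x, y), numeric(1))
  p <- length(cols)
  ff <- matrix(NA_real_, p, p)
  get_ff <- function(i, j) {
    if (i == j) return(1)
    if (is.na(ff[i, j])) {
      v <- symmetrical_uncertainty(cols[[i]], cols[[j]])
      ff[i, j] <<- v
      ff[j, i] <<- v
    }
    ff[i, j]
  }
  structure(list(su_cf = function(j) su_cf[j],
                 su_ff = get_ff,
                 n_features = p),
            class = "correlation_cache")
}

#' CFS merit of a feature subset
#'
#' The Ghiselli-style score `k * r_cf / sqrt(k + k * (k - 1) * r_ff)` where
#' `r_cf` is the mean feature-class SU over the subset and `r_ff` the mean
#' pairwise feature-feature SU: relevance in the numerator, redundancy in the
#' denominator. The empty subset has merit 0.
#'
#' @param subset integer feature indices, or a 0/1 mask
#' @param cache a [correlation_cache()]
#' @export
cfs_merit <- function(subset, cache) {
  idx <- if (length(subset) == cache$n_features && all(subset %in% c(0, 1))) {
    which(as.integer(subset) == 1L)
  } else {
    as.integer(subset)
  }
  k <- length(idx)
  if (k == 0L) return(0)
  rcf <- mean(vapply(idx, cache$su_cf, numeric(1)))
  if (k == 1L) return(rcf)
  pairs <- utils::combn(idx, 2)
  rff <- mean(vapply(seq_len(ncol(pairs)),
                     function(q) cache$su_ff(pairs[1, q], pairs[2, q]),
                     numeric(1)))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' CFS with forward best-first search
#'
#' Starts from the empty subset and expands the best open node by all
#' single-feature additions, keeping a priority queue ordered by merit.
#' Stops after `stale_limit` consecutive expansions without improving the
#' global best merit. Deterministic: merit ties break toward the
#' earlier-created node, and children are generated in feature-index order.
#'
#' @param ds labelled `survey_dataset`
#' @param n_bins equal-frequency bins for numeric features
#' @param stale_limit consecutive non-improving expansions tolerated
#'   (default 5)
#' @return list with `mask`, `merit`, and `n_evaluated` (subsets scored)
#' @export
best_first_cfs <- function(ds, n_bins = 10, stale_limit = 5) {
  cache <- correlation_cache(ds, n_bins)
  p <- n_features(ds)
  key_of <- function(idx) if (length(idx) == 0L) "." else paste(idx, collapse = ",")
  seen <- new.env(parent = emptyenv())
  open_sets <- list(integer(0))
  open_merit <- 0
  seen[[key_of(integer(0))]] <- TRUE
  best_set <- integer(0)
  best_merit <- 0
  n_eval <- 1L
  stale <- 0L
  while (length(open_sets) > 0L && stale < stale_limit) {
    pick <- which.max(open_merit)       # ties -> earliest inserted
    node <- open_sets[[pick]]
    open_sets <- open_sets[-pick]
    open_merit <- open_merit[-pick]
    improved <- FALSE
    for (j in setdiff(seq_len(p), node)) {
      child <- sort(c(node, j))
      key <- key_of(child)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      m <- cfs_merit(child, cache)
      n_eval <- n_eval + 1L
      open_sets[[length(open_sets) + 1L]] <- child
      open_merit <- c(open_merit, m)
      if (m > best_merit) {
        best_merit <- m
        best_set <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  mask <- integer(p)
  mask[best_set] <- 1L
  list(mask = feature_mask(mask), merit = best_merit, n_evaluated = n_eval)
}
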