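# Synthetic survey-data generator with known ground truth.
#
# Emulates the statistical shape of a large longitudinal-aging survey after
# preprocessing: thousands of instances, hundreds of mixed nominal/numeric
# features, a ~39.5% positive binary label, missing cells, and a small
# informative feature subset. Ground-truth informative indices are returned
# so selection quality is measurable.

#' Synthetic-survey specification
#'
#' Defaults mirror the preprocessed survey dimensions the package targets:
#' 6,488 instances with 2,564 positives over 778 mixed-type features.
#'
#' @param n_instances total instances (default 6488)
#' @param n_positive positive-class instances (default 2564)
#' @param n_features feature count (default 778)
#' @param n_informative label-associated features (default 20)
#' @param effect class-conditional effect size: for a nominal feature, the
#'   probability tilt of its first category between classes (delta in
#'   (0, 0.5]); for a numeric feature, the class mean shift in SD units.
#' @param missing_rate i.i.d. cell missingness in \[0, 1) (default 0.1)
#' @param nominal_fraction fraction of nominal features (default 0.8)
#' @param seed integer
#' @export
synth_spec <- function(n_instances = 6488, n_positive = 2564,
                       n_features = 778, n_informative = 20,
                       effect = 0.3, missing_rate = 0.1,
                       nominal_fraction = 0.8, seed = 1L) {
  if (n_positive >= n_instances || n_positive < 1) {
    stop_invalid("need 0 < n_positive < n_instances")
  }
  if (n_informative > n_features) {
    stop_invalid("n_informative must not exceed n_features")
  }
  if (effect <= 0 || effect > 0.5) stop_invalid("effect must be in (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_invalid("missing_rate must be in [0, 1)")
  }
  structure(list(n_instances = n_instances, n_positive = n_positive,
                 n_features = n_features, n_informative = n_informative,
                 effect = effect, missing_rate = missing_rate,
                 nominal_fraction = nominal_fraction, seed = seed),
            class = "synth_spec")
}

#' Generate a labelled synthetic survey dataset
#'
#' Labels are fixed at exactly `n_positive` positives (level order
#' `positive`, `negative`). Noise features are independent of the label:
#' nominal ones uniform over 2-6 categories (category counts drawn per
#' contiguous 20-feature block, imitating survey sections), numeric ones
#' standard normal. Informative nominal features tilt their first category's
#' probability by `+effect` in the positive class and `-effect` (floored) in
#' the negative class; informative numeric features shift the positive-class
#' mean by `effect` SD units. Missing cells are injected i.i.d. at
#' `missing_rate` after generation. Fully reproducible from `spec$seed`.
#'
#' @param spec a [synth_spec()]
#' @return list with `dataset` (labelled `survey_dataset`) and `truth`
#'   (list: `informative_indices`, `effects` named by feature)
#' @export
generate_survey <- function(spec = synth_spec()) {
  with_local_seed(spec$seed, {
    n <- spec$n_instances
    p <- spec$n_features
    lab <- factor(rep(c("positive", "negative"),
                      c(spec$n_positive, n - spec$n_positive)),
                  levels = c("positive", "negative"))
    lab <- sample(lab)
    pos <- lab == "positive"
    informative <- sort(sample.int(p, spec$n_informative))
    is_nominal <- stats::runif(p) < spec$nominal_fraction
    # survey "sections": contiguous blocks share a category-count range
    block <- (seq_len(p) - 1L) %/% 20L
    block_k <- sample(2:6, max(block) + 1L, replace = TRUE)
    cols <- vector("list", p)
    for (j in seq_len(p)) {
      inf <- j %in% informative
      if (is_nominal[j]) {
        K <- block_k[block[j] + 1L]
        if (inf) {
          d <- spec$effect
          base <- 1 / K
          p_pos <- c(min(1, base + d), rep(NA, K - 1L))
          p_pos[-1L] <- (1 - p_pos[1L]) / (K - 1L)
          p_neg <- c(max(0.02, base - d), rep(NA, K - 1L))
          p_neg[-1L] <- (1 - p_neg[1L]) / (K - 1L)
          x <- character(n)
          x[pos] <- sample(paste0("c", seq_len(K)), sum(pos),
                           replace = TRUE, prob = p_pos)
          x[!pos] <- sample(paste0("c", seq_len(K)), sum(!pos),
                            replace = TRUE, prob = p_neg)
        } else {
          x <- sample(paste0("c", seq_len(K)), n, replace = TRUE)
        }
        cols[[j]] <- x
      } else {
        x <- stats::rnorm(n)
        if (inf) x[pos] <- x[pos] + spec$effect
        cols[[j]] <- x
      }
    }
    if (spec$missing_rate > 0) {
      for (j in seq_len(p)) {
        miss <- stats::runif(n) < spec$missing_rate
        cols[[j]][miss] <- NA
      }
    }
    values <- as.data.frame(cols, col.names = sprintf("f%03d", seq_len(p)),
                            stringsAsFactors = FALSE)
    effects <- stats::setNames(rep(0, p), names(values))
    effects[informative] <- spec$effect
    list(dataset = survey_dataset(values,
                                  kinds = ifelse(is_nominal, "nominal", "numeric"),
                                  labels = lab),
         truth = list(informative_indices = informative,
                      effects = effects))
  })
}

#' Generate a raw sex + handgrip table
#'
#' For exercising the grip-threshold labelling end to end: sex is
#' Bernoulli(0.5); grip strength is drawn from sex-specific normals (SD 9 kg
#' for men, 6 kg for women) whose means are placed so the 28/16 kg thresholds
#' yield approximately `n_positive / n_instances` positives; a fraction of
#' grips is then set missing.
#'
#' @param n rows to generate
#' @param positive_fraction target below-threshold fraction (default 0.395)
#' @param missing_fraction grip cells set missing (default 0)
#' @param seed integer
#' @return data.frame with columns `sex`, `grip_kg`, `age`, `smokes`
#' @export
make_grip_table <- function(n = 1000, positive_fraction = 0.395,
                            missing_fraction = 0, seed = 1L) {
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop_invalid("positive_fraction must be in (0, 1)")
  }
  with_local_seed(seed, {
    sex <- sample(c("male", "female"), n, replace = TRUE)
    z <- stats::qnorm(positive_fraction)
    grip <- ifelse(sex == "male",
                   stats::rnorm(n, mean = 28 - z * 9, sd = 9),
                   stats::rnorm(n, mean = 16 - z * 6, sd = 6))
    grip <- pmax(grip, 0.5)
    if (missing_fraction > 0) {
      grip[stats::runif(n) < missing_fraction] <- NA
    }
    data.frame(sex = sex,
               grip_kg = round(grip, 1),
               age = sample(45:95, n, replace = TRUE),
               smokes = sample(c("yes", "no", "former"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
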