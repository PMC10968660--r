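# Small datasets built in code for the unit tests.

# mixed-type dataset with a feature that copies the label
label_copy_ds <- function(n = 40, n_noise = 3, seed = 1) {
  withr::with_seed(seed, {
    lab <- factor(rep(c("positive", "negative"), length.out = n),
                  levels = c("positive", "negative"))
    df <- data.frame(copy = as.character(lab), stringsAsFactors = FALSE)
    for (j in seq_len(n_noise)) {
      df[[paste0("noise", j)]] <- if (j %% 2 == 0) rnorm(n) else
        sample(c("a", "b", "c"), n, replace = TRUE)
    }
    survey_dataset(df, labels = lab)
  })
}

# balanced small synthetic problem with known informative features
small_synth <- function(n = 150, p = 10, n_informative = 3, effect = 0.4,
                        missing_rate = 0.05, seed = 1) {
  generate_survey(synth_spec(n_instances = n, n_positive = round(0.4 * n),
                             n_features = p, n_informative = n_informative,
                             effect = effect, missing_rate = missing_rate,
                             seed = seed))
}

# constant-fitness evaluator counting its calls (for bookkeeping tests)
counting_evaluator <- function(fn = function(mask) mean(mask)) {
  calls <- 0L
  f <- function(mask) {
    calls <<- calls + 1L
    fn(mask)
  }
  attr(f, "calls") <- function() calls
  f
}
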