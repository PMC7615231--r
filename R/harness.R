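#' Seed-sensitivity harness
#'
#' Trains the model under several parameter-initialization seeds on a fixed
#' dataset, evaluates each run on a fixed test set, and reports the
#' across-seed standard deviation of rotation-direction accuracy and gaze
#' pixel error — the reliability check that the model's predictions do not
#' hinge on a particular random initialization.
#'
#' @param train_data,test_data lists of sequences (held fixed across
#'   seeds).
#' @param config a [guidenet_config()].
#' @param tcfg a [guidenet_train_config()]; its `seed` is overridden per
#'   run.
#' @param seeds integer vector of training seeds (default 1:3).
#' @param n_samples sampled trajectories per evaluation step.
#' @return list with `runs` (per-seed data frame of overall direction
#'   accuracy and mean gaze error) and `sd` (named vector with
#'   `direction_accuracy` and `gaze_error_px`).
#' @export
seed_sensitivity <- function(train_data, test_data,
                             config = guidenet_config(),
                             tcfg = guidenet_train_config(),
                             seeds = 1:3, n_samples = 25L) {
  runs <- lapply(seeds, function(sd_i) {
    tc <- tcfg; tc$seed <- as.integer(sd_i)
    fit <- train_guidenet(train_data, config, tc)
    ev <- evaluate_guidenet(fit$model, test_data, n_samples = n_samples,
                            seed = 1L)
    ps <- ev$per_sequence
    data.frame(
      seed = sd_i,
      direction_accuracy = mean(ps$value[ps$metric == "direction_accuracy"]),
      gaze_error_px = mean(ps$value[ps$metric == "gaze_error_px"]))
  })
  runs <- do.call(rbind, runs)
  list(runs = runs,
       sd = c(direction_accuracy = stats::sd(runs$direction_accuracy),
              gaze_error_px = stats::sd(runs$gaze_error_px)))
}
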