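#' Reference 12-experiment performance and importance summary
#'
#' The published summary of the motivating study's twelve experiments
#' (three externalizing-disorder subscales x {new onset, prevailing cases}
#' x {multimodal, neural-only candidate features}): held-out accuracy,
#' precision and recall in percent, AUROC, and the mean group-level SHAP
#' importance of the final predictors. These pairs are the input to the
#' accuracy-importance correlation analysis; the underlying participant data
#' are restricted-access and are emulated by [generate_cohort()].
#'
#' @return data frame with one row per experiment.
#' @export
reference_experiments <- function() {
  data.frame(
    disorder = rep(c("ADHD", "ODD", "CD"), each = 4),
    subscale = rep(c("attention", "aggressive", "rule_breaking"), each = 4),
    mode = rep(c("new_onset", "prevailing"), 6),
    scope = rep(rep(c("multimodal", "neural_only"), each = 2), 3),
    accuracy = c(86.1, 93.7, 79.1, 63.7,
                 96.8, 96.2, 74.2, 56.1,
                 90.0, 96.3, 80.0, 77.5),
    precision = c(81.7, 91.8, 73.9, 59.5,
                  96.8, 94.8, 69.4, 53.9,
                  85.4, 95.1, 75.7, 71.7),
    recall = c(83.7, 91.6, 74.4, 49.5,
               93.5, 95.5, 64.5, 27.2,
               92.0, 95.0, 72.0, 75.0),
    auroc = c(0.919, 0.985, 0.841, 0.654,
              0.996, 0.988, 0.792, 0.567,
              0.922, 0.990, 0.808, 0.816),
    mean_importance = c(0.1206, 0.0617, 0.0400, 0.0200,
                        0.0694, 0.0743, 0.0410, 0.0026,
                        0.0928, 0.0683, 0.0890, 0.0513),
    stringsAsFactors = FALSE
  )
}
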