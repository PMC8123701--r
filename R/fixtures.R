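#' Bundled reference aggregates from the 40-driver fleet study
#'
#' Published aggregate tables from the truck-fleet case study the package's
#' methodology follows, used for arithmetic validation (none of the per-driver
#' raw data are available). Components:
#' \describe{
#'   \item{trait_items}{the 32-item key with per-item reference means/SDs and
#'     the printed per-dimension means/SDs.}
#'   \item{behavior_totals}{three-month totals, printed averages, minima and
#'     maxima of the six behavior counts over 40 drivers.}
#'   \item{risk_gvf_by_k}{GVF of the risk-index Jenks partition for k = 2..7.}
#'   \item{class_accuracy}{per-experiment and average accuracy of the six
#'     behavior-class models.}
#'   \item{risk_performance}{per-experiment and average MAPE / R^2 of the
#'     index-regression model and accuracy of the risk-level model.}
#'   \item{ablation_speeding}{paired accuracies of the speeding-class model
#'     with and without its rank-1 trait (conscientiousness).}
#' }
#'
#' @return A named list of data frames / vectors.
#' @export
reference_tables <- function() {
  list(
    trait_items = big_five_key(),
    dimension_aggregates = data.frame(
      dimension = trait_names(),
      mean = c(3.41, 3.57, 3.56, 2.77, 3.35),
      sd = c(0.67, 0.52, 0.45, 0.44, 0.53)),
    behavior_totals = data.frame(
      behavior = behavior_names(),
      total = c(67055, 5712, 426, 231, 22930, 1404),
      average = c(1676, 143, 11, 6, 573, 35),
      min = c(0, 7, 0, 0, 0, 0),
      max = c(7229, 559, 63, 29, 5131, 191),
      n_drivers = 40),
    risk_gvf_by_k = data.frame(k = 2:7,
                               gvf = c(0.617, 0.887, 0.947, 0.971, 0.976, 0.987)),
    class_accuracy = data.frame(
      model_id = 1:6,
      behavior = behavior_names(),
      e1 = c(80, 50, 60, 50, 80, 70),
      e2 = c(80, 60, 80, 60, 80, 80),
      e3 = c(70, 60, 70, 70, 90, 70),
      e4 = c(60, 60, 70, 70, 90, 80),
      average = c(72.5, 57.5, 70.0, 62.5, 85.0, 75.0)),
    risk_performance = data.frame(
      metric = c("mape", "r_squared", "accuracy"),
      model_id = c(7, 7, 8),
      e1 = c(11.7, 0.79, 60),
      e2 = c(11.1, 0.87, 90),
      e3 = c(7.9, 0.83, 70),
      e4 = c(10.2, 0.86, 70),
      average = c(10.2, 0.84, 72.5)),
    ablation_speeding = data.frame(
      inputs = c("all_five", "without_conscientiousness"),
      e1 = c(80, 70), e2 = c(80, 70), e3 = c(70, 70), e4 = c(60, 50),
      average = c(72.5, 65.0)))
}
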