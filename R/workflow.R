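#' Neighbors-based prediction for a new patient
#'
#' Runs the full chain for one index patient described only by baseline
#' covariates: broken-line anchor imputation on the training cohort,
#' predictive-mean-matching donor selection, and a location-scale-shape
#' fit to the donors' pooled observations, returning percentile curves
#' over postoperative time.
#'
#' @param train training [cohort()] (the donor data)
#' @param covariates one-row data frame: `age`, `sex` (`"male"`/
#'   `"female"`), `bmi`, `preop`
#' @param m number of matches (e.g. the [tune_m()] optimum)
#' @param bs_spec a [brokenstick_spec()]
#' @param traj_spec a [trajectory_spec()]
#' @param times grid of days for the returned band
#' @param probs percentile probabilities of the band
#' @param bs_fit,model optional precomputed [fit_brokenstick()] /
#'   [fit_matching_model()] results to reuse across patients
#' @return list: `band` (a [prediction_band()]), `matches` (the
#'   [select_matches()] result), `fit` (the trajectory fit), `model`,
#'   `bs_fit`
#' @export
neighbors_prediction <- function(train, covariates, m,
                                 bs_spec = brokenstick_spec(),
                                 traj_spec = trajectory_spec(),
                                 times = seq(0, traj_spec$horizon, by = 1),
                                 probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                                 bs_fit = NULL, model = NULL) {
  if (is.null(bs_fit)) bs_fit <- fit_brokenstick(train, bs_spec)
  if (is.null(model)) model <- fit_matching_model(bs_fit$anchors,
                                                  train$covariates)
  matches <- select_matches(model, covariates, train$covariates, m)
  donors <- patient_observations(train, matches$donor_ids)
  fit <- fit_trajectory(donors$time, donors$value, traj_spec)
  list(band = prediction_band(fit, times, probs), matches = matches,
       fit = fit, model = model, bs_fit = bs_fit)
}

#' Run the full reproducible workflow and write its artifacts
#'
#' Executes simulate -> anchor fit -> matching -> tuning -> prediction ->
#' calibration on a synthetic cohort and writes every stage's output as
#' plain CSV plus a JSON manifest (config echo, seed, package version)
#' sufficient to regenerate the run byte-for-byte. All randomness derives
#' from `config$seed`; matching, tuning and calibration are deterministic.
#'
#' @param config a [cohort_config()] for the synthetic cohort
#' @param out_dir output directory (created if needed)
#' @param m_grid match counts for tuning
#' @param new_patient one-row covariate data frame for the prediction
#'   stage (default: 55-year-old male, BMI 30 kg/m^2, preoperative TUG
#'   8 s)
#' @param bs_spec,traj_spec model specifications
#' @return invisibly, a list with the in-memory stage results
#' @export
run_workflow <- function(config, out_dir,
                         m_grid = c(10L, 20L, 35L, 60L, 100L),
                         new_patient = data.frame(age = 55, sex = "male",
                                                  bmi = 30, preop = 8),
                         bs_spec = brokenstick_spec(),
                         traj_spec = trajectory_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  num <- function(d) {
    d[] <- lapply(d, function(x) if (is.numeric(x)) signif(x, 10) else x)
    d
  }
  wr <- function(d, f) utils::write.csv(num(d), p(f), row.names = FALSE,
                                        quote = FALSE)

  sim <- generate_cohort(config)
  write_cohort(sim$cohort, p("cohort.csv"))
  wr(sim$truth, "truth.csv")

  train <- validate_cohort(sim$cohort)$cohort
  bs_fit <- fit_brokenstick(train, bs_spec)
  wr(bs_fit$anchors, "anchors.csv")

  model <- fit_matching_model(bs_fit$anchors, train$covariates)
  wr(data.frame(term = names(model$coefficients),
                coefficient = unname(model$coefficients),
                standardized = c(NA, unname(model$standardized))),
     "matching_model.csv")

  m_grid <- m_grid[m_grid <= n_patients(train) - 1L]
  tuning <- tune_m(train, model, traj_spec, m_grid = m_grid)
  wr(tuning$per_m, "tuning.csv")

  pred <- neighbors_prediction(train, new_patient, tuning$optimal_m,
                               bs_spec, traj_spec,
                               bs_fit = bs_fit, model = model)
  wr(as.data.frame(pred$band), "prediction_band.csv")

  loo <- loo_predictions(train, model, tuning$optimal_m, traj_spec)
  wr(as.data.frame(calibration_table(loo$pairs$predicted,
                                     loo$pairs$observed)),
     "calibration.csv")

  manifest <- list(
    package = "matchcharts",
    version = as.character(utils::packageVersion("matchcharts")),
    seed = config$seed,
    config = config[setdiff(names(config), "dynamics")],
    dynamics = unclass(config$dynamics),
    m_grid = m_grid,
    optimal_m = tuning$optimal_m,
    brokenstick = list(knots = bs_spec$knots, boundary = bs_spec$boundary,
                       anchor_day = bs_spec$anchor_day),
    trajectory = unclass(traj_spec))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(cohort = sim$cohort, truth = sim$truth, bs_fit = bs_fit,
                 model = model, tuning = tuning, prediction = pred,
                 calibration = loo))
}
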