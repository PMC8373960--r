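#' Bias, coverage and precision of one patient's prediction
#'
#' Scores a fitted donor trajectory against the index patient's own
#' realized observations: bias is the mean z-score of the observations
#' under the fitted predictive distribution (standard-deviation units, 0
#' when the prediction is centered correctly); coverage is the fraction of
#' observations falling inside the 50% prediction interval (between the
#' 25th and 75th percentile curves; nominal value 0.50); precision is the
#' mean width of that interval in seconds across the patient's observation
#' times (smaller is sharper).
#'
#' @param fit a [fit_trajectory()] result from the patient's donors
#' @param times,values the index patient's realized observation days and
#'   outcomes (seconds)
#' @return data frame with one row: `bias`, `coverage`, `precision`,
#'   `n_eval`
#' @export
prediction_metrics <- function(fit, times, values) {
  if (is.data.frame(times)) {
    values <- times$value
    times <- times$time
  }
  if (length(times) < 1L) stop("no realized observations to score", call. = FALSE)
  z <- z_score(fit, times, values)
  q25 <- as.vector(quantile_at(fit, times, 0.25))
  q75 <- as.vector(quantile_at(fit, times, 0.75))
  data.frame(bias = mean(z),
             coverage = mean(values >= q25 & values <= q75),
             precision = mean(q75 - q25),
             n_eval = length(times))
}

# per-index donor orderings are computed once: thanks to the deterministic
# tie rule the donor set at m is the first m entries of this ordering
donor_orderings <- function(model, covariates) {
  pm <- predict_mean(model, covariates)
  ids <- covariates$patient_id
  lapply(seq_along(ids), function(i) {
    d <- abs(pm - pm[i])
    ord <- order(d, ids)
    ord[ord != i]
  })
}

#' Tune the number of matches by leave-one-out within-sample testing
#'
#' For every `m` in `m_grid` and every index patient of the training
#' cohort: the `m` nearest donors are selected by predictive mean matching
#' with the index patient excluded from its own pool, the
#' location-scale-shape model is fit to the donors' pooled observations,
#' and the prediction is scored against the index patient's realized
#' observations via [prediction_metrics()]. Metrics are averaged over
#' patients per `m`.
#'
#' The optimal `m` is the admissible value minimizing the mean 50%-interval
#' width, where admissible means cohort coverage within `coverage_tol` of
#' the nominal 0.50 and absolute cohort bias at most `bias_tol` SD. If no
#' `m` is admissible the `m` with coverage closest to 0.50 is returned
#' (with a warning). An `m` whose trajectory fit fails for more than 10% of
#' index patients is marked invalid and never selected.
#'
#' @param train a [cohort()] (the donor/training data)
#' @param model a [fit_matching_model()] result fitted on `train`
#' @param spec a [trajectory_spec()]
#' @param m_grid integer vector of match counts to evaluate
#' @param coverage_tol,bias_tol admissibility tolerances (defaults 0.02
#'   and 0.05 SD)
#' @param progress print one line per evaluated `m`
#' @return object of class `tuning_result`: `per_m` (data frame `m`,
#'   `bias`, `coverage`, `precision`, `n_valid`, `valid`), `optimal_m`,
#'   `selection_rule`
#' @export
tune_m <- function(train, model, spec = trajectory_spec(),
                   m_grid = seq(10L, n_patients(train) - 1L, by = 5L),
                   coverage_tol = 0.02, bias_tol = 0.05, progress = FALSE) {
  stopifnot(inherits(train, "cohort"), inherits(model, "matching_model"))
  cov <- train$covariates
  n <- nrow(cov)
  m_grid <- sort(unique(as.integer(m_grid)))
  if (any(m_grid < 1L) || any(m_grid > n - 1L)) {
    stop("m_grid must lie within [1, n_patients - 1]", call. = FALSE)
  }
  ord <- donor_orderings(model, cov)
  obs_by <- split(train$observations[, c("time", "value")],
                  factor(train$observations$patient_id,
                         levels = cov$patient_id))
  rows <- vector("list", length(m_grid))
  for (k in seq_along(m_grid)) {
    m <- m_grid[k]
    mets <- vector("list", n)
    for (i in seq_len(n)) {
      own <- obs_by[[i]]
      if (nrow(own) == 0L) next
      donors <- do.call(rbind, obs_by[ord[[i]][seq_len(m)]])
      fit <- tryCatch(
        suppressWarnings(fit_trajectory(donors$time, donors$value, spec)),
        error = function(e) NULL)
      if (is.null(fit)) next
      mets[[i]] <- prediction_metrics(fit, own$time, own$value)
    }
    mets <- do.call(rbind, mets)
    n_valid <- if (is.null(mets)) 0L else nrow(mets)
    rows[[k]] <- data.frame(
      m = m,
      bias = if (n_valid) mean(mets$bias) else NA_real_,
      coverage = if (n_valid) mean(mets$coverage) else NA_real_,
      precision = if (n_valid) mean(mets$precision) else NA_real_,
      n_valid = n_valid,
      valid = n_valid >= 0.9 * sum(vapply(obs_by, nrow, 0L) > 0L))
    if (progress) {
      message(sprintf("m = %3d: bias %+.3f, coverage %.3f, width %.2f s (%d patients)",
                      m, rows[[k]]$bias, rows[[k]]$coverage,
                      rows[[k]]$precision, n_valid))
    }
  }
  per_m <- do.call(rbind, rows)
  cand <- per_m[per_m$valid, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no valid m in the grid", call. = FALSE)
  adm <- cand[abs(cand$coverage - 0.5) <= coverage_tol &
                abs(cand$bias) <= bias_tol, , drop = FALSE]
  if (nrow(adm) > 0L) {
    optimal_m <- adm$m[order(adm$precision, adm$m)][1L]
    rule <- "admissible-coverage-and-bias-then-min-width"
  } else {
    optimal_m <- cand$m[order(abs(cand$coverage - 0.5), cand$m)][1L]
    rule <- "fallback-closest-coverage"
    warning("no m met the coverage/bias tolerances; choosing coverage ",
            "closest to 0.50", call. = FALSE)
  }
  structure(list(per_m = per_m, optimal_m = optimal_m,
                 selection_rule = rule,
                 coverage_tol = coverage_tol, bias_tol = bias_tol),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> optimal m = %d (%s)\n", x$optimal_m,
              x$selection_rule))
  i <- match(x$optimal_m, x$per_m$m)
  cat(sprintf("  at m = %d: bias %+.4f SD, coverage %.3f, mean 50%% width %.2f s\n",
              x$optimal_m, x$per_m$bias[i], x$per_m$coverage[i],
              x$per_m$precision[i]))
  invisible(x)
}

#' Population-level reference band (m = everyone)
#'
#' Fits the location-scale-shape model to every observation of the cohort,
#' i.e. the degenerate matching where all patients are donors. This is the
#' conventional population reference chart against which the tuned
#' neighbors-based band is compared.
#'
#' @param train a [cohort()]
#' @param spec a [trajectory_spec()]
#' @return a [fit_trajectory()] result
#' @export
population_band <- function(train, spec = trajectory_spec()) {
  stopifnot(inherits(train, "cohort"))
  fit_trajectory(train$observations$time, train$observations$value, spec)
}

se_median_normal <- function(x) {
  # large-sample normal approximation: se(median) = 1.2533 sd / sqrt(n)
  1.2533 * stats::sd(x) / sqrt(length(x))
}

se_median_bootstrap <- function(x, B = 500L, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::sd(vapply(seq_len(B), function(b) {
    stats::median(sample(x, replace = TRUE))
  }, 0))
}

#' Decile calibration table of predicted vs observed outcomes
#'
#' Pairs of (predicted median, realized observation) pooled over patients
#' and times are ranked by the predicted value and split into 10 bins of
#' near-equal size (counts differ by at most 1). Each bin reports the
#' median predicted value, the median observed value, the standard error of
#' the observed median, and the count. For a well-calibrated prediction the
#' observed medians lie on the diagonal within their standard errors.
#'
#' @param predicted predicted median outcome (seconds) per observation
#' @param observed realized outcome (seconds) per observation
#' @param se_method `"normal"` (1.2533 sd / sqrt(n)) or `"bootstrap"`
#' @param boot_seed,boot_B bootstrap controls when `se_method =
#'   "bootstrap"`
#' @return data frame of class `calibration_table`: `decile`,
#'   `median_predicted`, `median_observed`, `se_observed`, `n`
#' @export
calibration_table <- function(predicted, observed,
                              se_method = c("normal", "bootstrap"),
                              boot_seed = 1L, boot_B = 500L) {
  se_method <- match.arg(se_method)
  stopifnot(length(predicted) == length(observed))
  n <- length(predicted)
  if (n < 10L) stop("need at least 10 (predicted, observed) pairs", call. = FALSE)
  ord <- order(predicted)
  bin <- ceiling(seq_len(n) * 10 / n)  # sizes differ by <= 1
  out <- lapply(1:10, function(b) {
    idx <- ord[bin == b]
    obs_b <- observed[idx]
    se <- if (se_method == "normal") se_median_normal(obs_b) else {
      se_median_bootstrap(obs_b, B = boot_B, seed = boot_seed + b)
    }
    data.frame(decile = b,
               median_predicted = stats::median(predicted[idx]),
               median_observed = stats::median(obs_b),
               se_observed = se,
               n = length(idx))
  })
  structure(do.call(rbind, out),
            class = c("calibration_table", "data.frame"))
}

#' Leave-one-out calibration pairs at a fixed number of matches
#'
#' For every index patient of the cohort, fits the donor trajectory at `m`
#' matches (leave-one-out) and pairs the fitted median at each of the
#' patient's observation times with the realized value — the raw material
#' of [calibration_table()] and the per-patient metric summaries.
#'
#' @param train a [cohort()]
#' @param model a [fit_matching_model()] result
#' @param m number of matches
#' @param spec a [trajectory_spec()]
#' @return list: `pairs` (data frame `patient_id`, `time`, `predicted`,
#'   `observed`), `metrics` (per-patient [prediction_metrics()] rows)
#' @export
loo_predictions <- function(train, model, m, spec = trajectory_spec()) {
  cov <- train$covariates
  ord <- donor_orderings(model, cov)
  obs_by <- split(train$observations[, c("time", "value")],
                  factor(train$observations$patient_id,
                         levels = cov$patient_id))
  pairs <- vector("list", nrow(cov))
  mets <- vector("list", nrow(cov))
  for (i in seq_len(nrow(cov))) {
    own <- obs_by[[i]]
    if (nrow(own) == 0L) next
    donors <- do.call(rbind, obs_by[ord[[i]][seq_len(m)]])
    fit <- tryCatch(
      suppressWarnings(fit_trajectory(donors$time, donors$value, spec)),
      error = function(e) NULL)
    if (is.null(fit)) next
    pairs[[i]] <- data.frame(patient_id = cov$patient_id[i], time = own$time,
                             predicted = as.vector(quantile_at(fit, own$time, 0.5)),
                             observed = own$value)
    mets[[i]] <- cbind(patient_id = cov$patient_id[i],
                       prediction_metrics(fit, own$time, own$value))
  }
  list(pairs = do.call(rbind, pairs), metrics = do.call(rbind, mets))
}
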