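# Small in-code fixtures shared across test files.

# three patients with hand-written covariates and observations
toy_cohort <- function() {
  cov <- data.frame(
    patient_id = c("A", "B", "C"),
    age = c(60, 70.5, 55),
    sex = c("male", "female", "female"),
    bmi = c(28.4, 33.1, 25.0),
    preop = c(9.2, 12.8, 7.5))
  obs <- data.frame(
    patient_id = c("A", "A", "A", "B", "B", "C"),
    time = c(10, 45, 92, 20, 80, 60),
    value = c(15.1, 10.2, 8.9, 18.3, 12.4, 9.7))
  cohort(cov, obs, label = "toy")
}

# cohort whose observations all lie exactly on one common broken line
noiseless_cohort <- function(n = 8L, knot_values = c(20, 14, 11, 10, 9.5),
                             spec = brokenstick_spec()) {
  times <- lapply(seq_len(n), function(i) {
    c(3 * i %% 11, 20 + i, 55 + 2 * i, 95 + 3 * i, 170 - i)
  })
  line_at <- function(t) {
    as.vector(broken_line_basis(t, spec) %*% knot_values)
  }
  cov <- data.frame(patient_id = sprintf("N%02d", seq_len(n)),
                    age = 60 + seq_len(n), sex = rep(c("male", "female"),
                                                     length.out = n),
                    bmi = 30 + seq_len(n) / 10, preop = 10 + seq_len(n) / 5)
  obs <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = cov$patient_id[i], time = times[[i]],
               value = line_at(times[[i]]))
  }))
  cohort(cov, obs)
}

# simulate irregular observations from a known broken-line mixed model
simulate_brokenstick <- function(n_patients, beta, omega_diag, sigma2,
                                 spec = brokenstick_spec(), seed = 1L) {
  set.seed(seed)
  visit_base <- c(2, 10, 30, 70, 120, 170) * spec$boundary / 180
  obs <- lapply(seq_len(n_patients), function(i) {
    b_i <- stats::rnorm(length(beta), 0, sqrt(omega_diag))
    t_i <- pmin(pmax(visit_base + stats::runif(6, -2, 2), 0), spec$boundary)
    B <- broken_line_basis(t_i, spec)
    y <- as.vector(B %*% (beta + b_i)) + stats::rnorm(6, 0, sqrt(sigma2))
    data.frame(patient_id = sprintf("S%04d", i), time = t_i, value = y,
               stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, obs)
  obs <- obs[obs$value > 0, ]
  ids <- unique(obs$patient_id)
  cov <- data.frame(patient_id = ids, age = 64, sex = "male", bmi = 31,
                    preop = 10, stringsAsFactors = FALSE)
  cohort(cov, obs)
}

# the one full-scale tuned pipeline shared by the acceptance checks;
# computed once per test session
.pipeline_cache <- new.env(parent = emptyenv())

tuned_pipeline <- function() {
  if (!is.null(.pipeline_cache$main)) return(.pipeline_cache$main)
  cfg <- cohort_config(n_patients = 400L, seed = 20260L)
  sim <- generate_cohort(cfg)
  train <- validate_cohort(sim$cohort)$cohort
  bs <- fit_brokenstick(train)
  mm <- fit_matching_model(bs$anchors, train$covariates)
  grid <- c(10L, 20L, 35L, 60L, 100L, 180L, n_patients(train) - 1L)
  tuning <- suppressWarnings(tune_m(train, mm, m_grid = grid))
  loo <- loo_predictions(train, mm, tuning$optimal_m)
  .pipeline_cache$main <- list(cfg = cfg, sim = sim, train = train, bs = bs,
                               mm = mm, grid = grid, tuning = tuning,
                               loo = loo)
  .pipeline_cache$main
}

null_pipeline <- function() {
  if (!is.null(.pipeline_cache$null)) return(.pipeline_cache$null)
  cfg <- cohort_config_null(n_patients = 200L, seed = 20261L)
  sim <- generate_cohort(cfg)
  train <- validate_cohort(sim$cohort)$cohort
  bs <- fit_brokenstick(train)
  mm <- fit_matching_model(bs$anchors, train$covariates)
  grid <- c(20L, 60L, 120L, n_patients(train) - 1L)
  tuning <- suppressWarnings(tune_m(train, mm, m_grid = grid))
  .pipeline_cache$null <- list(cfg = cfg, train = train, mm = mm,
                               grid = grid, tuning = tuning)
  .pipeline_cache$null
}
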