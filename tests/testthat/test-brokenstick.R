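spec4 <- brokenstick_spec()  # knots 0/14/50/90, boundary 180

test_that("hat basis takes its analytic values at and between knots", {
  expect_equal(as.vector(broken_line_basis(14, spec4)), c(0, 1, 0, 0, 0))
  expect_equal(as.vector(broken_line_basis(7, spec4)), c(0.5, 0.5, 0, 0, 0))
  # (50 - 32) / (50 - 14) = 0.5
  expect_equal(as.vector(broken_line_basis(32, spec4)), c(0, 0.5, 0.5, 0, 0))
  expect_equal(as.vector(broken_line_basis(0, spec4)), c(1, 0, 0, 0, 0))
  expect_equal(as.vector(broken_line_basis(180, spec4)), c(0, 0, 0, 0, 1))
  expect_error(broken_line_basis(-1, spec4), "outside")
  expect_error(broken_line_basis(181, spec4), "outside")
})

test_that("basis is a partition of unity on random times", {
  set.seed(42)
  t <- runif(500, 0, 180)
  B <- broken_line_basis(t, spec4)
  expect_equal(rowSums(B), rep(1, 500))
  expect_true(all(B >= 0))
  # at most two non-zero weights (the bracketing knots)
  expect_true(all(rowSums(B > 0) <= 2))
})

test_that("spec constructor enforces its invariants", {
  expect_error(brokenstick_spec(knots = c(0, 14), boundary = 10), "boundary")
  expect_error(brokenstick_spec(anchor_day = 45), "anchor_day")
})

test_that("a noiseless common broken line is recovered exactly", {
  kv <- c(20, 14, 11, 10, 9.5)
  co <- noiseless_cohort(knot_values = kv)
  fit <- fit_brokenstick(co)
  expect_equal(unname(fit$beta), kv, tolerance = 1e-4)
  expect_lt(fit$sigma2, 1e-4)
  expect_equal(fit$anchors$anchor, rep(10, n_patients(co)), tolerance = 1e-3)
})

test_that("REML recovers planted parameters on simulated data", {
  beta <- c(20, 14, 11, 10, 9)
  omega <- c(4, 3, 2.5, 2, 2)
  sigma2 <- 1
  co <- simulate_brokenstick(300, beta, omega, sigma2, seed = 2024)
  fit <- fit_brokenstick(co)
  # fixed effects within 2 Monte-Carlo SEs; the dominant variance of the
  # per-knot mean is the between-patient deviation Omega_kk / n
  tol <- 2 * sqrt((omega + sigma2) / 300)
  expect_true(all(abs(unname(fit$beta) - beta) < tol))
  expect_lt(abs(fit$sigma2 - sigma2), 0.25)
  expect_true(all(abs(diag(fit$Omega) - omega) < 2.5))
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  spec <- brokenstick_spec(knots = c(0, 60), boundary = 120, anchor_day = 60)
  set.seed(88)
  co <- simulate_brokenstick(30, c(18, 10, 8), c(3, 2, 2), 0.8, spec = spec,
                             seed = 88)
  fit <- fit_brokenstick(co, spec)
  B <- broken_line_basis(co$observations$time, spec)
  dat <- data.frame(y = co$observations$value, id = co$observations$patient_id,
                    b1 = B[, 1], b2 = B[, 2], b3 = B[, 3])
  ref <- nlme::lme(y ~ 0 + b1 + b2 + b3,
                   random = ~ 0 + b1 + b2 + b3 | id, data = dat,
                   method = "REML",
                   control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                              msMaxIter = 200))
  expect_equal(unname(fit$beta), unname(nlme::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
})

test_that("anchor BLUP equals the brute-force conditional-normal mean", {
  # one patient, three observations, explicit joint covariance
  fit <- structure(list(
    beta = c(k0 = 20, k14 = 14, k50 = 11, k90 = 10, k180 = 9),
    Omega = diag(c(4, 3, 2, 2, 2)) + 0.5, sigma2 = 1.3, spec = spec4,
    ranef_structure = "unstructured"), class = "brokenstick_fit")
  times <- c(7, 40, 100)
  values <- c(19.5, 12.0, 9.1)
  X <- broken_line_basis(times, spec4)
  # oracle: joint normal of (anchor, y); condition on y
  e <- as.numeric(names(fit$beta) == "k90")
  Sigma_ay <- t(e) %*% fit$Omega %*% t(X)
  Sigma_yy <- X %*% fit$Omega %*% t(X) + fit$sigma2 * diag(3)
  oracle <- sum(e * fit$beta) +
    Sigma_ay %*% solve(Sigma_yy) %*% (values - X %*% fit$beta)
  expect_equal(predict_anchor(fit, times, values), as.numeric(oracle),
               tolerance = 1e-8)
})

test_that("a patient with no observations receives the population mean", {
  co <- noiseless_cohort()
  fit <- fit_brokenstick(co)
  expect_equal(predict_anchor(fit), unname(fit$beta["k90"]))
})

test_that("zero random-effect covariance means full shrinkage", {
  fit <- structure(list(
    beta = c(k0 = 20, k14 = 14, k50 = 11, k90 = 10, k180 = 9),
    Omega = matrix(0, 5, 5), sigma2 = 1, spec = spec4,
    ranef_structure = "unstructured"), class = "brokenstick_fit")
  expect_equal(predict_anchor(fit, c(30, 90), c(25, 25)), 10)
})

test_that("the anchor shrinks monotonically toward the patient's own value", {
  fit <- structure(list(
    beta = c(k0 = 20, k14 = 14, k50 = 11, k90 = 10, k180 = 9),
    Omega = diag(c(4, 3, 2, 2, 2)), sigma2 = 2, spec = spec4,
    ranef_structure = "unstructured"), class = "brokenstick_fit")
  # dense noiseless observations on a flat line at 12 s
  anchors <- vapply(c(1, 2, 4, 8, 16, 64), function(k) {
    predict_anchor(fit, rep(c(30, 60, 90), k), rep(12, 3 * k))
  }, 0)
  expect_true(all(diff(abs(anchors - 12)) < 0))     # monotone approach
  expect_gt(anchors[1], fit$beta[["k90"]])          # pulled off the prior
  expect_equal(anchors[length(anchors)], 12, tolerance = 0.05)
})

test_that("degenerate single-time data raises a rank error", {
  cov <- data.frame(patient_id = c("A", "B"), age = 60, sex = "male",
                    bmi = 30, preop = 10)
  obs <- data.frame(patient_id = c("A", "B"), time = c(30, 30),
                    value = c(10, 12))
  expect_error(fit_brokenstick(cohort(cov, obs)), "single time")
})
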