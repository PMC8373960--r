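# baseline covariate pool with deterministic structure for matching tests
make_pool <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(patient_id = sprintf("Q%03d", seq_len(n)),
             age = runif(n, 45, 85),
             sex = sample(c("male", "female"), n, replace = TRUE),
             bmi = runif(n, 20, 45),
             preop = runif(n, 6, 25),
             stringsAsFactors = FALSE)
}

test_that("a planted coefficient is recovered exactly", {
  # anchor = 2 * preop exactly; other covariates carry no signal
  pool <- make_pool(40, seed = 10)
  anchors <- data.frame(patient_id = pool$patient_id,
                        anchor = 2 * pool$preop)
  mod <- fit_matching_model(anchors, pool)
  expect_equal(unname(mod$coefficients["preop"]), 2, tolerance = 1e-8)
  expect_equal(unname(mod$coefficients[c("age", "sex", "bmi")]),
               c(0, 0, 0), tolerance = 1e-8)
  expect_equal(mod$r_squared, 1, tolerance = 1e-10)
})

test_that("coefficients equal the closed-form normal-equations solution", {
  # hand-written 6-row design
  cov6 <- data.frame(patient_id = sprintf("H%d", 1:6),
                     age = c(55, 61, 70, 48, 66, 74),
                     sex = c(1, 0, 1, 0, 0, 1),
                     bmi = c(24.0, 31.5, 29.2, 35.8, 27.1, 33.3),
                     preop = c(7.5, 10.1, 12.4, 9.0, 8.2, 14.6))
  anchors <- data.frame(patient_id = cov6$patient_id,
                        anchor = c(8.2, 9.9, 11.5, 9.4, 8.8, 13.0))
  X <- as.matrix(cbind(1, cov6[, c("age", "sex", "bmi", "preop")]))
  oracle <- solve(t(X) %*% X, t(X) %*% anchors$anchor)
  mod <- fit_matching_model(anchors, cov6)
  expect_equal(unname(mod$coefficients), as.vector(oracle), tolerance = 1e-10)
  # standardized coefficient definition: slope times sample sd
  expect_equal(unname(mod$standardized["preop"]),
               unname(mod$coefficients["preop"]) * sd(cov6$preop))
})

test_that("standardized coefficient arithmetic holds on a constructed slope", {
  pool <- make_pool(30, seed = 3)
  pool$preop <- seq(6, 20, length.out = 30)
  anchors <- data.frame(patient_id = pool$patient_id,
                        anchor = 1 + 2 * pool$preop)
  mod <- fit_matching_model(anchors, pool)
  expect_equal(unname(mod$standardized["preop"]), 2 * sd(pool$preop),
               tolerance = 1e-6)
})

test_that("collinear covariates raise an error naming the column", {
  pool <- make_pool(20, seed = 4)
  pool$bmi <- 2 * pool$age        # exactly collinear
  anchors <- data.frame(patient_id = pool$patient_id, anchor = pool$preop)
  expect_error(fit_matching_model(anchors, pool), "collinear.*(age|bmi)")
})

test_that("predict_mean is the affine linear predictor", {
  pool <- make_pool(25, seed = 6)
  anchors <- data.frame(patient_id = pool$patient_id,
                        anchor = 3 + 0.1 * pool$age + 0.5 * pool$preop +
                          rnorm(25, 0, 0.01))
  mod <- fit_matching_model(anchors, pool)
  b <- mod$coefficients
  # all-zero covariates -> intercept
  zero <- data.frame(age = 0, sex = 0, bmi = 0, preop = 0)
  expect_equal(predict_mean(mod, zero), unname(b["(Intercept)"]))
  # manual dot product on a worked vector
  x <- data.frame(age = 63, sex = "female", bmi = 29.4, preop = 10.2)
  expect_equal(predict_mean(mod, x),
               unname(b["(Intercept)"] + b["age"] * 63 + b["sex"] * 0 +
                        b["bmi"] * 29.4 + b["preop"] * 10.2))
  # affine identity
  x1 <- data.frame(age = 10, sex = 1, bmi = 5, preop = 2)
  x2 <- data.frame(age = 20, sex = 0, bmi = 7, preop = 3)
  x12 <- data.frame(age = 30, sex = 1, bmi = 12, preop = 5)
  expect_equal(predict_mean(mod, x1) + predict_mean(mod, x2) -
                 unname(b["(Intercept)"]),
               predict_mean(mod, x12))
  expect_error(predict_mean(mod, data.frame(age = 60, sex = 1, bmi = 30)),
               "preop")
})

test_that("the nearest donors are selected in predicted-anchor space", {
  # pool engineered so predicted means are {5, 6, 7, 20} and index 6.2
  pool <- data.frame(patient_id = c("a", "b", "c", "d"),
                     age = c(50, 60, 70, 80), sex = "male",
                     bmi = 30, preop = c(5, 6, 7, 20))
  big <- make_pool(30, seed = 8)
  anchors <- data.frame(patient_id = big$patient_id, anchor = big$preop)
  mod <- fit_matching_model(anchors, big)  # learns anchor == preop
  idx <- data.frame(age = 65, sex = "male", bmi = 30, preop = 6.2)
  ms <- select_matches(mod, idx, pool, m = 2)
  expect_equal(ms$donor_ids, c("b", "c"))
  expect_equal(ms$distances, abs(c(6, 7) - 6.2), tolerance = 1e-6)
  # m = pool size returns the whole pool
  expect_setequal(select_matches(mod, idx, pool, m = 4)$donor_ids,
                  pool$patient_id)
  expect_error(select_matches(mod, idx, pool, m = 5), "exceeds")
})

test_that("selection equals brute force and nests across m (property)", {
  big <- make_pool(60, seed = 9)
  anchors <- data.frame(patient_id = big$patient_id,
                        anchor = 2 + 0.05 * big$age + 0.4 * big$preop +
                          rnorm(60, 0, 0.2))
  mod <- fit_matching_model(anchors, big)
  set.seed(17)
  for (rep in 1:50) {
    pool <- make_pool(sample(10:40, 1), seed = 100 + rep)
    idx <- make_pool(1, seed = 500 + rep)[, -1]
    m <- sample(2:8, 1)
    ms <- select_matches(mod, idx, pool, m)
    # brute force: sort all |predicted difference| with the same tie rule
    d <- abs(predict_mean(mod, pool) - predict_mean(mod, idx))
    brute <- pool$patient_id[order(d, pool$patient_id)][1:m]
    expect_identical(ms$donor_ids, brute)
    expect_false(is.unsorted(ms$distances))
    # prefix nesting
    ms1 <- select_matches(mod, idx, pool, m + 1)
    expect_identical(ms1$donor_ids[1:m], ms$donor_ids)
  }
})

test_that("the index patient is never its own donor", {
  pool <- make_pool(15, seed = 12)
  anchors <- data.frame(patient_id = pool$patient_id, anchor = pool$preop)
  mod <- fit_matching_model(anchors, pool)
  for (i in c(1, 7, 15)) {
    ms <- select_matches(mod, pool[i, ], pool, m = 14,
                         exclude = pool$patient_id[i],
                         index_id = pool$patient_id[i])
    expect_false(pool$patient_id[i] %in% ms$donor_ids)
    expect_equal(ms$m, 14L)
  }
})

test_that("matching is invariant to covariate rescaling", {
  # matching happens in predicted-outcome space, so rescaling a covariate
  # (with the model refit) must leave donor sets unchanged
  pool <- make_pool(40, seed = 14)
  anchors <- data.frame(patient_id = pool$patient_id,
                        anchor = 1 + 0.08 * pool$age + 0.3 * pool$preop +
                          rnorm(40, 0, 0.3))
  idx <- data.frame(age = 60, sex = "female", bmi = 30, preop = 11)
  mod <- fit_matching_model(anchors, pool)
  ms <- select_matches(mod, idx, pool, m = 10)
  pool2 <- pool
  pool2$age <- pool2$age / 365.25   # years -> "centuries-ish" rescale
  idx2 <- idx
  idx2$age <- idx$age / 365.25
  mod2 <- fit_matching_model(anchors, pool2)
  ms2 <- select_matches(mod2, idx2, pool2, m = 10)
  expect_identical(ms2$donor_ids, ms$donor_ids)
  expect_equal(ms2$distances, ms$distances, tolerance = 1e-8)
})
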