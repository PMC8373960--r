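covariate_design <- function(covariates) {
  sex_num <- if (is.numeric(covariates$sex)) {
    covariates$sex
  } else {
    as.numeric(tolower(as.character(covariates$sex)) == "male")
  }
  cbind(age = covariates$age, sex = sex_num, bmi = covariates$bmi,
        preop = covariates$preop)
}

#' Fit the predictive-mean-matching linear model
#'
#' Ordinary least squares of the anchor-day outcome estimate on the four
#' matching characteristics: age (years), sex (male = 1, female = 0),
#' BMI (kg/m^2) and preoperative outcome (seconds). The fitted linear
#' predictor defines the one-dimensional space in which donors are matched,
#' so each characteristic is implicitly weighted by the strength of its
#' relation to the anchor outcome. Standardized coefficients (slope times
#' sample sd of the covariate, in seconds) quantify those weights.
#'
#' @param anchors data frame `patient_id`, `anchor` from
#'   [anchor_estimates()]
#' @param covariates covariate table (`patient_id`, `age`, `sex`, `bmi`,
#'   `preop`), e.g. `cohort$covariates`
#' @return object of class `matching_model`: `coefficients` (intercept +
#'   4 slopes), `standardized` (slope x covariate sd, seconds),
#'   `covariate_means`, `covariate_sds`, `r_squared`, `n`
#' @export
fit_matching_model <- function(anchors, covariates) {
  dat <- merge(anchors, covariates, by = "patient_id")
  dat <- dat[stats::complete.cases(dat[, c("anchor", "age", "sex", "bmi",
                                           "preop")]), , drop = FALSE]
  if (nrow(dat) < 5L) stop("need >= 5 patients with anchor and complete covariates",
                           call. = FALSE)
  X <- cbind(`(Intercept)` = 1, covariate_design(dat))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_col <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear matching covariate(s): ", paste(drop_col, collapse = ", "),
         call. = FALSE)
  }
  y <- dat$anchor
  coefs <- qr.coef(qrX, y)
  fitted <- as.vector(X %*% coefs)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  sds <- apply(X[, -1L, drop = FALSE], 2L, stats::sd)
  structure(list(coefficients = coefs,
                 standardized = coefs[-1L] * sds,
                 covariate_means = colMeans(X[, -1L, drop = FALSE]),
                 covariate_sds = sds,
                 r_squared = r2, n = nrow(dat)),
            class = "matching_model")
}

#' @export
print.matching_model <- function(x, ...) {
  cat("<matching_model> anchor ~ age + sex + bmi + preop\n")
  print(round(x$coefficients, 4))
  cat("standardized (s):\n")
  print(round(x$standardized, 4))
  cat(sprintf("R^2 = %.3f, n = %d\n", x$r_squared, x$n))
  invisible(x)
}

#' Predicted anchor outcome for baseline covariates
#'
#' @param model a [fit_matching_model()] result
#' @param covariates data frame (or one-row list) with `age`, `sex`, `bmi`,
#'   `preop`; `sex` as `"male"`/`"female"` or male indicator 0/1
#' @return predicted anchor in seconds, one value per row
#' @export
predict_mean <- function(model, covariates) {
  stopifnot(inherits(model, "matching_model"))
  covariates <- as.data.frame(covariates)
  need <- c("age", "sex", "bmi", "preop")
  miss <- setdiff(need, names(covariates))
  if (length(miss) > 0L) stop("missing covariate(s): ",
                              paste(miss, collapse = ", "), call. = FALSE)
  X <- covariate_design(covariates)
  if (anyNA(X)) stop("covariates contain missing values", call. = FALSE)
  as.vector(cbind(1, X) %*% model$coefficients)
}

#' Select the m nearest donors by predictive mean matching
#'
#' Donors are the `m` members of the pool whose model-predicted anchor is
#' closest (absolute difference, seconds) to the index patient's predicted
#' anchor. Both sides of the distance use the linear predictor on baseline
#' covariates only, so matching works identically for training patients and
#' for new patients without any postoperative data. Ties in distance are
#' broken by ascending patient id, which makes selection deterministic and
#' makes the donor set for `m` a prefix of the donor set for `m + 1`.
#'
#' @param model a [fit_matching_model()] result
#' @param index one-row covariate data frame of the index patient
#' @param pool covariate table of candidate donors (`patient_id` + the four
#'   matching characteristics)
#' @param m number of donors
#' @param exclude patient ids never to select (e.g. the index patient
#'   itself during leave-one-out tuning)
#' @param index_id label for the index patient (default `"external"`)
#' @return object of class `match_set`: `index_id`, `donor_ids` (length m,
#'   by ascending distance), `distances` (seconds), `m`
#' @export
select_matches <- function(model, index, pool, m, exclude = character(),
                           index_id = "external") {
  stopifnot(inherits(model, "matching_model"))
  pool <- pool[!(pool$patient_id %in% c(exclude, index_id)), , drop = FALSE]
  if (m > nrow(pool)) {
    stop("m = ", m, " exceeds the available donor pool (", nrow(pool), ")",
         call. = FALSE)
  }
  d <- abs(predict_mean(model, pool) - predict_mean(model, index))
  ord <- order(d, pool$patient_id)[seq_len(m)]
  structure(list(index_id = index_id,
                 donor_ids = pool$patient_id[ord],
                 distances = d[ord], m = as.integer(m)),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf("<match_set> index '%s': m = %d donors, distances %.3f..%.3f s\n",
              x$index_id, x$m, min(x$distances), max(x$distances)))
  invisible(x)
}
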