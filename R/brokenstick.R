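#' Specification of the broken-line (piecewise-linear) time model
#'
#' The model places knots at fixed postoperative days and represents every
#' trajectory as a linear combination of piecewise-linear "hat" basis
#' functions over those knots. A boundary knot above the last interior knot
#' is required so the basis spans the whole follow-up window; the anchor day
#' is the knot at which per-patient outcome levels are extracted for
#' matching.
#'
#' @param knots strictly increasing knot days; default `c(0, 14, 50, 90)`
#' @param boundary upper boundary knot in days, `> max(knots)`; default 180
#' @param anchor_day day whose knot level is the matching anchor; must be
#'   one of `knots`; default 90
#' @return object of class `brokenstick_spec`
#' @export
brokenstick_spec <- function(knots = c(0, 14, 50, 90), boundary = 180,
                             anchor_day = 90) {
  knots <- sort(unique(as.numeric(knots)))
  if (length(knots) < 2L) stop("need at least two knots", call. = FALSE)
  if (boundary <= max(knots)) stop("boundary must exceed max(knots)", call. = FALSE)
  if (!(anchor_day %in% knots)) stop("anchor_day must be one of the knots", call. = FALSE)
  structure(list(knots = knots, boundary = boundary, anchor_day = anchor_day,
                 all_knots = c(knots, boundary)),
            class = "brokenstick_spec")
}

#' Piecewise-linear hat basis over the knots
#'
#' Each basis function is 1 at its own knot, falls linearly to 0 at the
#' neighbouring knots, and is 0 elsewhere; the functions sum to 1 everywhere
#' on `[0, boundary]` (partition of unity), so a coefficient vector is
#' directly interpretable as outcome levels at the knots.
#'
#' @param time vector of days, each in `[0, boundary]`
#' @param spec a [brokenstick_spec()]
#' @return matrix with `length(time)` rows and one column per knot
#'   (including the boundary knot), columns named by knot day
#' @export
broken_line_basis <- function(time, spec = brokenstick_spec()) {
  k <- spec$all_knots
  if (any(time < k[1L] | time > k[length(k)])) {
    stop("time outside [", k[1L], ", ", k[length(k)], "]", call. = FALSE)
  }
  B <- matrix(0, nrow = length(time), ncol = length(k),
              dimnames = list(NULL, paste0("k", k)))
  j <- findInterval(time, k, rightmost.closed = TRUE)
  for (i in seq_along(time)) {
    ji <- j[i]
    if (time[i] == k[ji]) {
      B[i, ji] <- 1
    } else {
      w <- (time[i] - k[ji]) / (k[ji + 1L] - k[ji])
      B[i, ji] <- 1 - w
      B[i, ji + 1L] <- w
    }
  }
  B
}

#' Fit the broken-line linear mixed-effects model
#'
#' Fits, by REML, \deqn{y_{ij} = \sum_k (\beta_k + b_{ik}) B_k(t_{ij}) +
#' \varepsilon_{ij}} with patient-level deviations `b_i ~ N(0, Omega)` and
#' residual `N(0, sigma^2)`, over all patients' irregular postoperative
#' observations. The per-patient best linear unbiased predictor (BLUP) of
#' the outcome level at the anchor day is returned for every patient — the
#' quantity used downstream as the predictive-mean-matching target.
#'
#' The random-effect covariance is unstructured by default; if that fit
#' fails or does not converge, an independent (diagonal) structure is used
#' instead and reported via `ranef_structure`.
#'
#' @param cohort a [cohort()]; at least 2 patients with observations
#' @param spec a [brokenstick_spec()]
#' @return object of class `brokenstick_fit`: `beta` (fixed-effect outcome
#'   levels at the knots, seconds), `Omega` (random-effect covariance),
#'   `sigma2` (residual variance, s^2), `anchors` (data frame `patient_id`,
#'   `anchor`), `logLik`, `ranef_structure`, `spec`
#' @export
fit_brokenstick <- function(cohort, spec = brokenstick_spec()) {
  stopifnot(inherits(cohort, "cohort"))
  obs <- cohort$observations
  if (length(unique(obs$patient_id)) < 2L) {
    stop("need >= 2 patients with observations", call. = FALSE)
  }
  if (length(unique(obs$time)) < 2L) {
    stop("degenerate data: all observations at a single time", call. = FALSE)
  }
  B <- broken_line_basis(obs$time, spec)
  dat <- as.data.frame(B)
  bn <- names(dat)
  dat$y <- obs$value
  dat$id <- obs$patient_id
  terms <- paste(bn, collapse = " + ")
  ctrl <- lme4::lmerControl(check.nobs.vs.nRE = "ignore",
                            check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  form_un <- stats::as.formula(
    paste0("y ~ 0 + ", terms, " + (0 + ", terms, " | id)"))
  form_dg <- stats::as.formula(
    paste0("y ~ 0 + ", terms, " + (0 + ", terms, " || id)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form_un, data = dat, REML = TRUE, control = ctrl))),
    error = function(e) NULL)
  structure_used <- "unstructured"
  if (is.null(fit)) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(form_dg, data = dat, REML = TRUE, control = ctrl))),
      error = function(e) NULL)
    structure_used <- "diagonal"
  }
  if (is.null(fit)) stop("broken-line mixed model failed to fit", call. = FALSE)

  beta <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  if (structure_used == "unstructured") {
    Omega <- as.matrix(vc$id)
    attr(Omega, "stddev") <- NULL
    attr(Omega, "correlation") <- NULL
  } else {
    Omega <- diag(vapply(vc, function(m) as.numeric(m[1L, 1L]), 0))
  }
  dimnames(Omega) <- list(bn, bn)
  sigma2 <- stats::sigma(fit)^2

  out <- structure(list(beta = beta, Omega = Omega, sigma2 = sigma2,
                        spec = spec, logLik = as.numeric(stats::logLik(fit)),
                        ranef_structure = structure_used,
                        anchors = NULL),
                   class = "brokenstick_fit")
  out$anchors <- anchor_estimates(out, cohort)
  out
}

#' @export
print.brokenstick_fit <- function(x, ...) {
  cat("<brokenstick_fit>\n  fixed effects (s at knots):\n")
  print(round(x$beta, 3))
  cat(sprintf("  sigma^2 = %.4f; random effects: %s; %d anchors\n",
              x$sigma2, x$ranef_structure, nrow(x$anchors)))
  invisible(x)
}

#' BLUP of the anchor-day outcome for one patient
#'
#' Combines the population fixed effects with the patient's own
#' observations through the conditional-normal (shrinkage) formula: with
#' `X` the basis at the patient's observation times,
#' `V = X Omega X' + sigma^2 I`, the predicted random deviation is
#' `Omega X' V^{-1} (y - X beta)` and the anchor is the fixed effect plus
#' the deviation at the anchor knot. A patient with no observations
#' receives the population fixed effect (the prior mean).
#'
#' @param fit a [fit_brokenstick()] result
#' @param times,values the patient's postoperative observation days/values
#'   (may be empty)
#' @return anchor estimate in seconds (length 1)
#' @export
predict_anchor <- function(fit, times = numeric(), values = numeric()) {
  stopifnot(inherits(fit, "brokenstick_fit"))
  a_col <- match(paste0("k", fit$spec$anchor_day), names(fit$beta))
  if (length(times) == 0L) return(unname(fit$beta[a_col]))
  X <- broken_line_basis(times, fit$spec)
  V <- X %*% fit$Omega %*% t(X) + fit$sigma2 * diag(length(times))
  resid <- values - as.vector(X %*% fit$beta)
  b_hat <- fit$Omega %*% t(X) %*% solve(V, resid)
  unname(fit$beta[a_col] + b_hat[a_col])
}

#' Anchor estimates for every patient of a cohort
#'
#' Applies [predict_anchor()] patient-by-patient; patients with no
#' observations receive the population fixed effect.
#'
#' @param fit a [fit_brokenstick()] result
#' @param cohort a [cohort()]
#' @return data frame `patient_id`, `anchor` (seconds)
#' @export
anchor_estimates <- function(fit, cohort) {
  ids <- cohort$covariates$patient_id
  obs_by <- split(cohort$observations[, c("time", "value")],
                  factor(cohort$observations$patient_id, levels = ids))
  anchor <- vapply(ids, function(pid) {
    o <- obs_by[[pid]]
    predict_anchor(fit, o$time, o$value)
  }, 0, USE.NAMES = FALSE)
  data.frame(patient_id = ids, anchor = anchor, stringsAsFactors = FALSE)
}
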