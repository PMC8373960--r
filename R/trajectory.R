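#' Specification of the location-scale-shape trajectory model
#'
#' The donor observations are modeled as Box-Cox Cole-Green with all three
#' parameters varying smoothly with time since surgery: the median
#' `mu(t) = exp(cubic regression spline, location_df)`, the relative scale
#' `sigma(t) = exp(linear predictor, scale_df)` and the Box-Cox skewness
#' power `nu(t)` (identity link, shape_df). A df of 1 means one slope in
#' (scaled) time beyond the intercept; 0 means intercept only.
#'
#' @param location_df effective df of the natural cubic spline for
#'   `log mu` beyond the intercept (default 3)
#' @param scale_df 0 (constant) or 1 (linear in time) for `log sigma`
#' @param shape_df 0 (constant) or 1 (linear in time) for `nu`
#' @param min_obs minimum pooled donor observations required (default 30)
#' @param max_iter maximum outer fitting cycles (default 100)
#' @param tol relative deviance convergence tolerance (default 1e-5)
#' @param horizon upper end of the modeled time range, days (default 180)
#' @return object of class `trajectory_spec`
#' @export
trajectory_spec <- function(location_df = 3, scale_df = 1, shape_df = 1,
                            min_obs = 30L, max_iter = 100L, tol = 1e-5,
                            horizon = 180) {
  if (location_df < 1) stop("location_df must be >= 1", call. = FALSE)
  if (!scale_df %in% 0:1 || !shape_df %in% 0:1) {
    stop("scale_df and shape_df must be 0 or 1", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(location_df = location_df, scale_df = scale_df,
                 shape_df = shape_df, min_obs = as.integer(min_obs),
                 max_iter = as.integer(max_iter), tol = tol,
                 horizon = horizon),
            class = "trajectory_spec")
}

# design matrices for the three predictors at given times; the mu spline's
# interior knots come from the fitted data's time quantiles and are stored
# so fresh times reuse exactly the same basis
trajectory_bases <- function(times, spec, knots = NULL) {
  bk <- c(0, spec$horizon)
  if (is.null(knots)) {
    df <- spec$location_df
    if (df > 1) {
      qs <- seq(0, 1, length.out = df + 1L)[-c(1L, df + 1L)]
      knots <- unique(as.vector(stats::quantile(times, qs)))
    } else {
      knots <- numeric()
    }
  }
  S <- splines::ns(times, knots = knots, Boundary.knots = bk)
  ts <- times / spec$horizon
  list(Xmu = cbind(1, S),
       Xsigma = if (spec$scale_df == 1) cbind(1, ts) else cbind(rep(1, length(ts))),
       Xnu = if (spec$shape_df == 1) cbind(1, ts) else cbind(rep(1, length(ts))),
       knots = knots)
}

#' Fit location-scale-shape percentile curves to pooled donor observations
#'
#' Maximizes the Box-Cox Cole-Green log-likelihood over the coefficients of
#' the three time-varying parameter predictors by cyclic block updates in
#' the style of the RS backfitting algorithm for distributional regression:
#' the location, scale and shape coefficient blocks are updated in turn,
#' each by a quasi-Newton step sequence with the analytic score holding the
#' other blocks fixed, until the relative change in deviance
#' (-2 log-likelihood) falls below `tol`. Deviance is non-increasing across
#' cycles by construction.
#'
#' Starting values: location coefficients from least squares of `log y` on
#' the spline basis, scale intercept from the log residual spread of that
#' fit, shape `nu = 0.5`.
#'
#' @param times,values pooled donor observation days and outcome values
#'   (seconds); typically `patient_observations(cohort, matches$donor_ids)`
#' @param spec a [trajectory_spec()]
#' @return object of class `trajectory_fit`: coefficient blocks, the stored
#'   spline knots, `n_obs`, `deviance`, `converged`, `iterations`, `spec`
#' @export
fit_trajectory <- function(times, values, spec = trajectory_spec()) {
  if (is.data.frame(times)) {
    values <- times$value
    times <- times$time
  }
  n <- length(times)
  p_eff <- (1 + spec$location_df) + (1 + spec$scale_df) + (1 + spec$shape_df)
  if (n < max(spec$min_obs, p_eff + 1L)) {
    stop("too few donor observations (", n, ") for the trajectory model",
         call. = FALSE)
  }
  stopifnot(all(values > 0), all(times >= 0))
  bas <- trajectory_bases(times, spec)
  Xmu <- bas$Xmu; Xsigma <- bas$Xsigma; Xnu <- bas$Xnu
  y <- values

  b_mu <- qr.coef(qr(Xmu), log(y))
  b_mu[is.na(b_mu)] <- 0
  r <- log(y) - as.vector(Xmu %*% b_mu)
  b_sigma <- c(log(max(stats::sd(r), 1e-3)), rep(0, ncol(Xsigma) - 1L))
  b_nu <- c(0.5, rep(0, ncol(Xnu) - 1L))

  blocks <- list(mu = seq_along(b_mu),
                 sigma = length(b_mu) + seq_along(b_sigma),
                 nu = length(b_mu) + length(b_sigma) + seq_along(b_nu))
  par <- c(b_mu, b_sigma, b_nu)

  nll_all <- function(par, grad = FALSE) {
    lp_mu <- as.vector(Xmu %*% par[blocks$mu])
    lp_sg <- as.vector(Xsigma %*% par[blocks$sigma])
    lp_nu <- as.vector(Xnu %*% par[blocks$nu])
    if (any(lp_sg > 10) || any(abs(lp_mu) > 20) || any(abs(lp_nu) > 50)) {
      return(if (grad) NULL else 1e10)
    }
    tt <- bccg_nll_terms(y, lp_mu, lp_sg, lp_nu, grad = grad)
    val <- sum(tt$nll)
    if (!is.finite(val)) return(if (grad) NULL else 1e10)
    if (!grad) return(val)
    list(value = val,
         gradient = c(crossprod(Xmu, tt$d_logmu),
                      crossprod(Xsigma, tt$d_logsigma),
                      crossprod(Xnu, tt$d_nu)))
  }
  fn_block <- function(theta, which, base_par) {
    base_par[blocks[[which]]] <- theta
    nll_all(base_par)
  }
  gr_block <- function(theta, which, base_par) {
    base_par[blocks[[which]]] <- theta
    g <- nll_all(base_par, grad = TRUE)
    if (is.null(g)) return(rep(0, length(theta)))
    g$gradient[blocks[[which]]]
  }

  dev <- 2 * nll_all(par)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(spec$max_iter)) {
    for (wb in names(blocks)) {
      o <- tryCatch(
        stats::optim(par[blocks[[wb]]], fn_block, gr_block, which = wb,
                     base_par = par, method = "BFGS",
                     control = list(maxit = 30)),
        error = function(e) NULL)
      if (!is.null(o) && is.finite(o$value) && 2 * o$value <= dev + 1e-9) {
        par[blocks[[wb]]] <- o$par
      }
    }
    dev_new <- 2 * nll_all(par)
    if (abs(dev - dev_new) < spec$tol * (abs(dev) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  if (!converged) {
    warning("trajectory fit did not converge in ", spec$max_iter,
            " cycles (deviance ", signif(dev, 8), ")", call. = FALSE)
  }
  structure(list(b_mu = par[blocks$mu], b_sigma = par[blocks$sigma],
                 b_nu = par[blocks$nu], knots = bas$knots, n_obs = n,
                 deviance = dev, converged = converged, iterations = iter,
                 time_range = range(times), spec = spec),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(paste0("<trajectory_fit> BCCG on %d observations; deviance ",
                     "%.2f; %s in %d cycle(s)\n"),
              x$n_obs, x$deviance,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Evaluate the fitted distribution parameters at given times
#'
#' @param fit a [fit_trajectory()] result
#' @param times days since surgery, within `[0, horizon]`
#' @return data frame `time`, `mu` (s), `sigma`, `nu`
#' @export
trajectory_params <- function(fit, times) {
  stopifnot(inherits(fit, "trajectory_fit"))
  bas <- trajectory_bases(times, fit$spec, knots = fit$knots)
  data.frame(time = times,
             mu = exp(as.vector(bas$Xmu %*% fit$b_mu)),
             sigma = exp(as.vector(bas$Xsigma %*% fit$b_sigma)),
             nu = as.vector(bas$Xnu %*% fit$b_nu))
}

#' Quantile of the fitted predictive distribution
#'
#' @inheritParams trajectory_params
#' @param p probability in (0, 1); either `times` or `p` scalar (recycled)
#' @return predicted `p`-quantile(s) in seconds; carries attribute
#'   `truncated = TRUE` if a requested quantile hit the distribution
#'   boundary
#' @export
quantile_at <- function(fit, times, p) {
  pp <- trajectory_params(fit, times)
  qbccg(p, pp$mu, pp$sigma, pp$nu)
}

#' Z-score of an observed value under the fitted distribution
#'
#' @inheritParams trajectory_params
#' @param values observed outcome(s) in seconds (> 0)
#' @return standard-normal deviates when the fit is well specified
#' @export
z_score <- function(fit, times, values) {
  stopifnot(all(values > 0))
  pp <- trajectory_params(fit, times)
  zbccg(values, pp$mu, pp$sigma, pp$nu)
}

#' Percentile band of the fitted trajectory on a time grid
#'
#' @inheritParams trajectory_params
#' @param probs probabilities of the percentile curves
#' @return data frame of class `prediction_band`: column `time` plus one
#'   `q<100p>` column per probability, non-decreasing across columns at
#'   every time
#' @export
prediction_band <- function(fit, times = seq(0, fit$spec$horizon, by = 1),
                            probs = c(0.10, 0.25, 0.50, 0.75, 0.90)) {
  probs <- sort(probs)
  out <- data.frame(time = times)
  trunc <- FALSE
  for (p in probs) {
    q <- quantile_at(fit, times, p)
    trunc <- trunc || isTRUE(attr(q, "truncated"))
    out[[sprintf("q%02d", round(100 * p))]] <- as.vector(q)
  }
  if (trunc) attr(out, "truncated") <- TRUE
  class(out) <- c("prediction_band", "data.frame")
  out
}
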