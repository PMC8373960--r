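# Box-Cox Cole-Green (LMS) family: y > 0 with median mu > 0, relative
# dispersion sigma > 0 and Box-Cox skewness power nu. The transformed
# deviate z = ((y/mu)^nu - 1) / (nu sigma) (log(y/mu)/sigma at nu = 0) is
# treated as standard normal. As in the classical LMS method the small
# truncation mass at z < -1/(sigma nu) is neglected.

#' Standardized deviate of the Box-Cox Cole-Green family
#'
#' @param y positive outcome value(s)
#' @param mu median parameter (> 0)
#' @param sigma scale parameter (> 0)
#' @param nu Box-Cox power (skewness) parameter
#' @return z-score(s); standard normal when `y` follows the family
#' @export
zbccg <- function(y, mu, sigma, nu) {
  L <- log(y / mu)
  ifelse(abs(nu) < 1e-8, L / sigma, expm1(nu * L) / (nu * sigma))
}

#' Density, distribution, quantile and random generation for the
#' Box-Cox Cole-Green distribution
#'
#' @param y,q positive quantiles
#' @param p probabilities in (0, 1)
#' @param n number of draws
#' @inheritParams zbccg
#' @param log logical; return log-density
#' @return `dbccg` the density, `pbccg` the CDF, `qbccg` the quantile
#'   function, `rbccg` random draws. For extreme `p` the quantile can hit
#'   the distribution boundary (0 for `nu > 0`, `Inf` for `nu < 0`); the
#'   boundary value is returned with attribute `truncated = TRUE`.
#' @export
dbccg <- function(y, mu, sigma, nu, log = FALSE) {
  z <- zbccg(y, mu, sigma, nu)
  ll <- (nu - 1) * base::log(y) - nu * base::log(mu) - base::log(sigma) +
    stats::dnorm(z, log = TRUE)
  if (log) ll else exp(ll)
}

#' @rdname dbccg
#' @export
pbccg <- function(q, mu, sigma, nu) stats::pnorm(zbccg(q, mu, sigma, nu))

#' @rdname dbccg
#' @export
qbccg <- function(p, mu, sigma, nu) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)", call. = FALSE)
  n <- max(length(p), length(mu), length(sigma), length(nu))
  p <- rep_len(p, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  z <- stats::qnorm(p)
  out <- numeric(n)
  small <- abs(nu) < 1e-8
  out[small] <- mu[small] * exp(sigma[small] * z[small])
  arg <- 1 + nu * sigma * z
  ok <- !small & arg > 0
  out[ok] <- mu[ok] * exp(log(arg[ok]) / nu[ok])
  tr <- !small & arg <= 0
  if (any(tr)) {
    out[tr] <- ifelse(nu[tr] > 0, 0, Inf)
    attr(out, "truncated") <- TRUE
  }
  out
}

#' @rdname dbccg
#' @export
rbccg <- function(n, mu, sigma, nu) qbccg(stats::runif(n), mu, sigma, nu)

# Negative log-likelihood and its gradient with respect to the three
# linear predictors (log mu, log sigma, identity nu), per observation.
bccg_nll_terms <- function(y, logmu, logsigma, nu, grad = FALSE) {
  mu <- exp(logmu)
  sigma <- exp(logsigma)
  L <- log(y) - logmu
  small <- abs(nu) < 1e-8
  u <- exp(nu * L)
  z <- ifelse(small, L / sigma, expm1(nu * L) / (nu * sigma))
  nll <- -((nu - 1) * log(y) - nu * logmu - logsigma +
             stats::dnorm(z, log = TRUE))
  if (!grad) return(list(nll = nll))
  # d z / d nu has a removable singularity at nu = 0 with limit L^2/(2 sigma)
  dz_dnu <- ifelse(small, L^2 / (2 * sigma), (u * L) / (nu * sigma) - z / nu)
  list(nll = nll,
       d_logmu = -(-nu + z * u / sigma),
       d_logsigma = -(-1 + z^2),
       d_nu = -(L - z * dz_dnu))
}
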