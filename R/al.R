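## The asymmetric Laplace (AL) distribution: the working likelihood of
## Bayesian quantile regression. Its location parameter is the tau-th
## conditional quantile of the response.

#' Quantile check loss
#'
#' The piecewise-linear kernel rho_tau(u) = u * (tau - 1\{u < 0\}) whose
#' expectation is minimized at the tau-th quantile.
#'
#' @param u numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @return nonnegative numeric vector.
#' @export
check_loss <- function(u, tau) {
  stopifnot(tau > 0, tau < 1)
  u * (tau - (u < 0))
}

#' Asymmetric Laplace log-density
#'
#' log f(y) = log\[tau (1 - tau) / sigma\] - rho_tau((y - mu) / sigma).
#' At tau = 0.5 this is the Laplace density with scale 2 sigma.
#'
#' @param y observations.
#' @param mu location (the tau-th quantile).
#' @param sigma scale, > 0.
#' @param tau quantile level in (0, 1).
#' @return log-density values.
#' @export
al_logpdf <- function(y, mu, sigma, tau) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  log(tau * (1 - tau) / sigma) - check_loss((y - mu) / sigma, tau)
}

#' Draw from the asymmetric Laplace distribution
#'
#' With probability tau the draw is a negative exponential with rate
#' (1 - tau) / sigma, otherwise a positive exponential with rate tau / sigma,
#' so that P(draw < mu) = tau exactly.
#'
#' @param n number of draws.
#' @inheritParams al_logpdf
#' @return numeric vector of draws.
#' @export
ral <- function(n, mu = 0, sigma = 1, tau = 0.5) {
  stopifnot(sigma > 0, tau > 0, tau < 1)
  neg <- stats::runif(n) < tau
  e <- numeric(n)
  e[neg] <- -stats::rexp(sum(neg), rate = 1 - tau)
  e[!neg] <- stats::rexp(sum(!neg), rate = tau)
  mu + sigma * e
}

#' Highest-density interval of a sample
#'
#' The narrowest contiguous interval containing `ceiling(mass * N)` of the
#' sorted draws; for unimodal posteriors this approximates the
#' highest-posterior-density region, and unlike equal-tailed intervals it
#' handles skew (e.g. it starts at the minimum for exponential-shaped
#' samples).
#'
#' @param draws numeric vector, at least 100 draws.
#' @param mass probability mass, default 0.95.
#' @return numeric vector c(lo, hi).
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100) stop("need at least 100 draws for an HDI")
  s <- sort(draws)
  k <- ceiling(mass * n)
  if (k >= n) return(c(s[1], s[n]))
  widths <- s[k:n] - s[1:(n - k + 1)]
  i <- which.min(widths)
  c(s[i], s[i + k - 1])
}

#' ROPE decision for a regression slope
#'
#' Compares the HDI of the slope posterior with the region of practical
#' equivalence \[-rope_factor * SD(y), +rope_factor * SD(y)\]: `outside_rope`
#' (practically nonzero) when they are disjoint, `inside_rope` (practically
#' zero) when the HDI is contained in the ROPE, else `overlapping`
#' (undecided).
#'
#' @param draws posterior draws of the slope (y units per x unit).
#' @param y the response vector defining the ROPE scale.
#' @param mass HDI mass, default 0.95.
#' @param rope_factor half-width of the ROPE as a fraction of SD(y),
#'   default 0.1.
#' @return list with `hdi_lo`, `hdi_hi`, `rope_lo`, `rope_hi`, `verdict`.
#' @export
rope_decision <- function(draws, y, mass = 0.95, rope_factor = 0.1) {
  if (stats::sd(y) == 0) stop("response is constant; ROPE undefined")
  h <- hdi(draws, mass)
  r <- rope_factor * stats::sd(y)
  verdict <- if (h[2] < -r || h[1] > r) "outside_rope"
  else if (h[1] >= -r && h[2] <= r) "inside_rope"
  else "overlapping"
  list(hdi_lo = h[1], hdi_hi = h[2], rope_lo = -r, rope_hi = r,
       verdict = verdict)
}
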