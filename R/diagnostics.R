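## MCMC convergence diagnostics: split-Rhat and autocorrelation-based
## effective sample size, in the now-standard formulation (chains split in
## half; Geyer's initial monotone positive sequence truncates the
## autocorrelation sum).

#' Split-Rhat and effective sample size
#'
#' @param draws matrix of posterior draws for one parameter, iterations in
#'   rows and chains in columns (at least 2 chains of equal length).
#' @return list with `rhat` and `ess`. Degenerate (constant) chains give
#'   `rhat = NA` and `ess = 1`.
#' @export
rhat_ess <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("Rhat requires at least 2 chains")
  n <- nrow(draws)
  half <- floor(n / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split); len <- nrow(split)
  mu <- colMeans(split)
  v <- apply(split, 2, stats::var)
  W <- mean(v)
  B <- len * stats::var(mu)
  if (!is.finite(W) || W == 0) return(list(rhat = NA_real_, ess = 1))
  var_plus <- (len - 1) / len * W + B / len
  rhat <- sqrt(var_plus / W)

  # combined autocorrelations (Stan-style)
  max_lag <- len - 1
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(split[, j], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / var_plus
  # Geyer: sum paired autocorrelations while positive and monotone
  p <- floor(length(rho) / 2)
  if (p >= 1) {
    pairs <- rho[2 * seq_len(p) - 1] + rho[2 * seq_len(p)]
    pairs <- cummin(pairs)                       # enforce monotonicity
    pos <- which(pairs <= 0)
    if (length(pos)) pairs <- pairs[seq_len(pos[1] - 1)]
    tau <- 1 + 2 * rho[1] + 2 * sum(pairs)
  } else tau <- 1 + 2 * rho[1]
  tau <- max(tau, 1 / (m * len))                 # guard
  ess <- m * len / tau
  ess <- min(ess, m * len)
  list(rhat = rhat, ess = max(ess, 1))
}

#' Diagnostics for a matrix of draws
#'
#' Applies [rhat_ess()] column-wise to named parameters.
#'
#' @param draws_array 3-d array (iterations x chains x parameters) or a named
#'   list of iteration-by-chain matrices.
#' @return data.frame with `parameter`, `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(draws_array) {
  if (is.array(draws_array) && length(dim(draws_array)) == 3) {
    pars <- dimnames(draws_array)[[3]]
    if (is.null(pars)) pars <- paste0("par", seq_len(dim(draws_array)[3]))
    lst <- lapply(seq_along(pars), function(k) draws_array[, , k])
    names(lst) <- pars
  } else lst <- draws_array
  out <- do.call(rbind, lapply(names(lst), function(p) {
    d <- rhat_ess(lst[[p]])
    data.frame(parameter = p, rhat = d$rhat, ess = d$ess,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
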